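# Generalized sparse convolution engine.
#
# A sparse feature map is a set of occupied integer coordinates (columns
# x, y, z, t, b) with a feature vector per coordinate. Convolution is
# evaluated only at predefined output coordinates:
#
#   X_u^out = sum over offsets i with u + i occupied of W_i x_{u+i}^in
#
# Spatial offsets act on (x, y, z); the structure index t participates in the
# kernel only when an offset set carries a temporal extent (the stem's hybrid
# kernel); the batch column b is always a pure partition key. Coordinates are
# stored in absolute lattice units and each map carries its `tensor_stride`:
# a stride-s convolution emits coordinates on the s-times-coarser lattice and
# its kernel offsets are scaled by the input's tensor stride.

#' Kernel offset sets
#'
#' Builds the ordered offset list N^D defining a kernel's shape. `size` is
#' the (odd) cubic spatial extent; `temporal` the extent along the structure
#' index t: 1 gives a purely spatial kernel, 2 the hybrid (non-hypercubic)
#' kernel whose taps also reach the next structure index.
#'
#' @param size Odd spatial kernel size (default 3).
#' @param temporal Temporal extent, 1 or 2 (default 1).
#' @return Integer matrix with columns dx, dy, dz, dt; the zero offset is
#'   always included.
#' @export
kernel_offsets <- function(size = 3L, temporal = 1L) {
  stopifnot(size >= 1L, size %% 2L == 1L, temporal %in% c(1L, 2L))
  r <- (size - 1L) %/% 2L
  sp <- -r:r
  dt <- if (temporal == 1L) 0L else c(0L, 1L)
  g <- as.matrix(expand.grid(dx = sp, dy = sp, dz = sp, dt = dt,
                             KEEP.OUT.ATTRS = FALSE))
  storage.mode(g) <- "integer"
  g
}

#' Construct a sparse feature map
#' @param coords M x 5 integer coordinate matrix (x, y, z, t, b).
#' @param feats M x C feature matrix.
#' @param tensor_stride Lattice stride of this level (default 1).
#' @return A `sparse_feature_map`.
#' @export
sparse_feature_map <- function(coords, feats, tensor_stride = 1L) {
  coords <- as.matrix(coords)
  storage.mode(coords) <- "integer"
  feats <- as.matrix(feats)
  stopifnot(ncol(coords) == 5L, nrow(coords) == nrow(feats))
  if (anyDuplicated(.coord_keys(coords)) > 0L) {
    stop("sparse feature map has duplicate coordinate rows")
  }
  structure(list(coords = coords, feats = feats,
                 tensor_stride = as.integer(tensor_stride)),
            class = "sparse_feature_map")
}

#' @export
print.sparse_feature_map <- function(x, ...) {
  cat("sparse_feature_map: ", nrow(x$coords), " sites x ", ncol(x$feats),
      " channels (tensor stride ", x$tensor_stride, ")\n", sep = "")
  invisible(x)
}

.coord_keys <- function(coords) {
  paste(coords[, 1L], coords[, 2L], coords[, 3L], coords[, 4L], coords[, 5L])
}

# Output coordinates of a stride-s convolution: occupied cells of the
# s-times-coarser lattice (absolute units), in first-occurrence order.
downsample_coords <- function(coords, tensor_stride, stride) {
  step <- tensor_stride * stride
  out <- coords
  out[, 1:3] <- (floor(coords[, 1:3, drop = FALSE] / step)) * step
  storage.mode(out) <- "integer"
  out[!duplicated(.coord_keys(out)), , drop = FALSE]
}

#' Kernel map between two coordinate sets
#'
#' For every kernel offset, pairs each output row with the input row at
#' `out + offset * offset_stride` (offsets applied to x, y, z and t; b must
#' match). The map is the only coordinate-dependent part of a convolution,
#' so it can be computed once and reused across forward/backward passes.
#'
#' @param in_coords,out_coords Integer coordinate matrices (columns
#'   x, y, z, t, b).
#' @param offsets Offset matrix from [kernel_offsets()].
#' @param offset_stride Lattice units per offset step (the input tensor
#'   stride).
#' @return List (one entry per offset) of two-column matrices `(out, in)` of
#'   aligned row indices; offsets with no matches yield zero-row matrices.
#' @export
kernel_map <- function(in_coords, out_coords, offsets, offset_stride = 1L) {
  in_keys <- .coord_keys(in_coords)
  lapply(seq_len(nrow(offsets)), function(k) {
    tgt <- out_coords
    tgt[, 1L] <- tgt[, 1L] + offsets[k, 1L] * offset_stride
    tgt[, 2L] <- tgt[, 2L] + offsets[k, 2L] * offset_stride
    tgt[, 3L] <- tgt[, 3L] + offsets[k, 3L] * offset_stride
    tgt[, 4L] <- tgt[, 4L] + offsets[k, 4L]
    hit <- match(.coord_keys(tgt), in_keys)
    ok <- which(!is.na(hit))
    cbind(out = ok, `in` = hit[ok])
  })
}

# Apply a convolution given its kernel map. W: array (n_offsets, in, out).
conv_apply <- function(in_feats, W, km, n_out) {
  ci <- dim(W)[2L]; co <- dim(W)[3L]
  out <- matrix(0, n_out, co)
  for (k in seq_along(km)) {
    p <- km[[k]]
    if (nrow(p) == 0L) next
    out[p[, 1L], ] <- out[p[, 1L], , drop = FALSE] +
      in_feats[p[, 2L], , drop = FALSE] %*% matrix(W[k, , ], ci, co)
  }
  out
}

# Gradients of conv_apply. Returns list(d_in, d_W).
conv_apply_grad <- function(in_feats, W, km, d_out) {
  ci <- dim(W)[2L]; co <- dim(W)[3L]
  d_in <- matrix(0, nrow(in_feats), ci)
  d_W <- array(0, dim(W))
  for (k in seq_along(km)) {
    p <- km[[k]]
    if (nrow(p) == 0L) next
    g <- d_out[p[, 1L], , drop = FALSE]
    x <- in_feats[p[, 2L], , drop = FALSE]
    d_in[p[, 2L], ] <- d_in[p[, 2L], , drop = FALSE] +
      g %*% t(matrix(W[k, , ], ci, co))
    d_W[k, , ] <- crossprod(x, g)
  }
  list(d_in = d_in, d_W = d_W)
}

#' Convolution layer specification
#'
#' @param in_channels,out_channels Channel counts.
#' @param offsets Kernel offsets ([kernel_offsets()]).
#' @param stride Integer stride (downsampling factor; 1 = same lattice).
#' @param transpose Is this an upsampling (transpose) convolution?
#' @param weights Optional array `(n_offsets, in, out)`; initialized He-style
#'   from `seed` when omitted.
#' @param seed Seed for weight initialization.
#' @return A `conv_layer_spec`.
#' @export
conv_layer_spec <- function(in_channels, out_channels,
                            offsets = kernel_offsets(3L), stride = 1L,
                            transpose = FALSE, weights = NULL, seed = 1L) {
  n_off <- nrow(offsets)
  if (is.null(weights)) {
    rng <- .seeded_rng(seed)
    sd <- sqrt(2 / (n_off * in_channels))
    weights <- array(rng$norm(n_off * in_channels * out_channels) * sd,
                     dim = c(n_off, in_channels, out_channels))
  }
  stopifnot(all(dim(weights) == c(n_off, in_channels, out_channels)))
  structure(list(in_channels = in_channels, out_channels = out_channels,
                 offsets = offsets, stride = as.integer(stride),
                 transpose = transpose, weights = weights),
            class = "conv_layer_spec")
}

# local RNG helper so layer init does not disturb the global RNG stream
.seeded_rng <- function(seed) {
  env <- new.env()
  env$state <- {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(seed)
    s <- get(".Random.seed", globalenv())
    if (is.null(old)) rm(".Random.seed", envir = globalenv()) else assign(".Random.seed", old, globalenv())
    s
  }
  list(
    norm = function(n) {
      old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
      assign(".Random.seed", env$state, globalenv())
      x <- stats::rnorm(n)
      env$state <- get(".Random.seed", globalenv())
      if (is.null(old)) rm(".Random.seed", envir = globalenv()) else assign(".Random.seed", old, globalenv())
      x
    }
  )
}

#' Generalized sparse convolution
#'
#' Evaluates the sparse convolution of `input` under `layer`. With stride 1
#' the output coordinate set equals the input's (sparsity preserved); with
#' stride s the output lives on the s-times-coarser lattice covering the
#' occupied input cells. A custom `out_coords` set may be supplied.
#'
#' @param input A `sparse_feature_map`.
#' @param layer A [conv_layer_spec()] with `transpose = FALSE`.
#' @param out_coords Optional explicit output coordinate matrix.
#' @return A `sparse_feature_map` on the output coordinates.
#' @export
sparse_convolution <- function(input, layer, out_coords = NULL) {
  stopifnot(inherits(layer, "conv_layer_spec"), !layer$transpose)
  if (ncol(input$feats) != layer$in_channels) {
    stop("channel mismatch: input has ", ncol(input$feats),
         ", layer expects ", layer$in_channels)
  }
  if (is.null(out_coords)) {
    out_coords <- if (layer$stride == 1L) input$coords else {
      downsample_coords(input$coords, input$tensor_stride, layer$stride)
    }
  }
  km <- kernel_map(input$coords, out_coords, layer$offsets,
                   offset_stride = input$tensor_stride)
  feats <- conv_apply(input$feats, layer$weights, km, nrow(out_coords))
  # sparsity preservation: drop outputs with no contributing input
  touched <- rep(FALSE, nrow(out_coords))
  for (p in km) touched[p[, 1L]] <- TRUE
  sparse_feature_map(out_coords[touched, , drop = FALSE],
                     feats[touched, , drop = FALSE],
                     tensor_stride = input$tensor_stride * layer$stride)
}

#' Sparse transpose convolution (upsampling)
#'
#' The adjoint of [sparse_convolution()]: output features at a fine
#' coordinate v accumulate `t(W_i)`-weighted contributions from the coarse
#' input coordinates whose receptive field covers v. As a linear map in the
#' input features it is exactly the matrix transpose of the corresponding
#' strided convolution (with weights `W_i` transposed per offset).
#'
#' @param input A `sparse_feature_map` on the coarse lattice.
#' @param layer A [conv_layer_spec()] with `transpose = TRUE`; its `weights`
#'   array is indexed `(offset, in = coarse channels, out = fine channels)`.
#' @param out_coords Fine-lattice coordinate matrix (e.g. remembered from the
#'   matching encoder level).
#' @return A `sparse_feature_map` on `out_coords`.
#' @export
sparse_conv_transpose <- function(input, layer, out_coords) {
  stopifnot(inherits(layer, "conv_layer_spec"), layer$transpose)
  if (ncol(input$feats) != layer$in_channels) {
    stop("channel mismatch: input has ", ncol(input$feats),
         ", layer expects ", layer$in_channels)
  }
  fine_stride <- input$tensor_stride %/% layer$stride
  stopifnot(fine_stride >= 1L)
  # pairs (coarse u, fine v) with v = u + i * fine_stride: this is the kernel
  # map of the matching downsampling conv with roles swapped
  km_down <- kernel_map(out_coords, input$coords, layer$offsets,
                        offset_stride = fine_stride)
  km <- lapply(km_down, function(p) cbind(out = p[, 2L], `in` = p[, 1L]))
  feats <- conv_apply(input$feats, layer$weights, km, nrow(out_coords))
  sparse_feature_map(out_coords, feats, tensor_stride = fine_stride)
}

#' Batch-normalization parameters
#' @param channels Channel count.
#' @param eps Variance floor (default 1e-5).
#' @param momentum Running-statistics update rate (default 0.1).
#' @return A `bn_params` list with `gamma`, `beta`, `running_mean`,
#'   `running_var`.
#' @export
bn_params <- function(channels, eps = 1e-5, momentum = 0.1) {
  structure(list(gamma = rep(1, channels), beta = rep(0, channels),
                 running_mean = rep(0, channels), running_var = rep(1, channels),
                 eps = eps, momentum = momentum),
            class = "bn_params")
}

# core normalization on a plain feature matrix; returns list(out, cache,
# params) where params carries updated running statistics in train mode.
bn_forward <- function(feats, params, train = TRUE) {
  n <- nrow(feats)
  if (n == 0L) stop("batch normalization over zero rows")
  if (train) {
    mu <- colMeans(feats)
    xc <- sweep(feats, 2L, mu)
    var_b <- colMeans(xc^2)            # biased, used for normalization
    inv_sd <- 1 / sqrt(var_b + params$eps)
    xhat <- sweep(xc, 2L, inv_sd, "*")
    var_u <- if (n > 1L) var_b * n / (n - 1L) else var_b
    params$running_mean <- (1 - params$momentum) * params$running_mean +
      params$momentum * mu
    params$running_var <- (1 - params$momentum) * params$running_var +
      params$momentum * var_u
  } else {
    inv_sd <- 1 / sqrt(params$running_var + params$eps)
    xhat <- sweep(sweep(feats, 2L, params$running_mean), 2L, inv_sd, "*")
  }
  out <- sweep(sweep(xhat, 2L, params$gamma, "*"), 2L, params$beta, "+")
  list(out = out, cache = list(xhat = xhat, inv_sd = inv_sd, train = train),
       params = params)
}

bn_backward <- function(cache, params, d_out) {
  d_beta <- colSums(d_out)
  d_gamma <- colSums(d_out * cache$xhat)
  d_xhat <- sweep(d_out, 2L, params$gamma, "*")
  if (cache$train) {
    n <- nrow(d_out)
    d_x <- sweep(d_xhat - matrix(colMeans(d_xhat), n, ncol(d_out), byrow = TRUE) -
                   cache$xhat * matrix(colMeans(d_xhat * cache$xhat), n,
                                       ncol(d_out), byrow = TRUE),
                 2L, cache$inv_sd, "*")
  } else {
    d_x <- sweep(d_xhat, 2L, cache$inv_sd, "*")
  }
  list(d_x = d_x, d_gamma = d_gamma, d_beta = d_beta)
}

#' Batch normalization on a sparse feature map
#'
#' Normalizes each channel over all occupied sites. In train mode batch
#' statistics are used and running statistics updated; in eval mode the
#' stored running statistics apply. Coordinates are untouched.
#'
#' @param input A `sparse_feature_map`.
#' @param params A [bn_params()] object.
#' @param mode `"train"` or `"eval"`.
#' @return List with `output` (a `sparse_feature_map`) and `params` (with
#'   updated running statistics in train mode).
#' @export
sparse_batch_norm <- function(input, params, mode = c("train", "eval")) {
  mode <- match.arg(mode)
  r <- bn_forward(input$feats, params, train = mode == "train")
  list(output = sparse_feature_map(input$coords, r$out, input$tensor_stride),
       params = r$params)
}

#' Rectified linear activation on a sparse feature map
#' @param input A `sparse_feature_map`.
#' @return A `sparse_feature_map` with negative features clamped to zero.
#' @export
sparse_relu <- function(input) {
  sparse_feature_map(input$coords, pmax(input$feats, 0), input$tensor_stride)
}

#' Residual basic block on a sparse feature map
#'
#' `out = relu(bn2(conv2(relu(bn1(conv1(x))))) + x)`, stride 1, channels
#' preserved; the residual addition aligns rows by coordinate (stride-1
#' convolutions keep the input's row order, so addition is row-wise).
#'
#' @param input A `sparse_feature_map`.
#' @param conv1,conv2 Stride-1 [conv_layer_spec()]s with matching channels.
#' @param bn1,bn2 [bn_params()] for the two normalizations.
#' @param mode `"train"` or `"eval"`.
#' @return A `sparse_feature_map` on the input coordinates.
#' @export
sparse_basic_block <- function(input, conv1, conv2, bn1, bn2,
                               mode = c("train", "eval")) {
  mode <- match.arg(mode)
  stopifnot(conv1$stride == 1L, conv2$stride == 1L)
  h <- sparse_convolution(input, conv1)
  h <- sparse_batch_norm(h, bn1, mode)$output
  h <- sparse_relu(h)
  h <- sparse_convolution(h, conv2)
  h <- sparse_batch_norm(h, bn2, mode)$output
  stopifnot(nrow(h$coords) == nrow(input$coords))
  sparse_relu(sparse_feature_map(h$coords, h$feats + input$feats,
                                 h$tensor_stride))
}
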