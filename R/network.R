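# Encoder-decoder segmentation network over sparse protein tensors.
#
# Topology (UNet with residual basic blocks):
#   stem: conv (in -> init_dim, hybrid 3x3x3 spatial x 2 temporal kernel),
#         BN, ReLU, at full resolution;
#   encoder level i = 1..4: stride-2 conv (channels kept), BN, ReLU, then
#         encoder_blocks[i] basic blocks moving channels to
#         encoder_planes[i];
#   decoder level j = 1..4: stride-2 transpose conv to decoder_planes[j],
#         BN, ReLU, concatenation with the matching encoder feature map,
#         then decoder_blocks[j] basic blocks back to decoder_planes[j];
#   head: 1x1 convolution to a single logit (with bias), sigmoid.
# Convolutions carry no bias (normalization follows each); residual
# shortcuts use a 1x1 projection plus BN whenever channels change.

#' Network specification
#'
#' The defaults reproduce the best hyperparameter configuration of the
#' published architecture (encoder out-planes 32/48/128/128, decoder
#' 128/128/48/32, basic-block counts 2,3,1,3 / 3,2,1,3, nine input feature
#' channels), which totals 10,861,601 trainable parameters.
#'
#' @param in_channels Input feature channels (default 9).
#' @param init_dim Stem output channels (default 32).
#' @param encoder_planes,decoder_planes Out-planes of the four encoder and
#'   four decoder levels.
#' @param encoder_blocks,decoder_blocks Basic-block counts per level.
#' @param kernel_size Odd cubic kernel size (default 3).
#' @param stem_temporal Temporal extent of the stem's hybrid kernel
#'   (default 2).
#' @param bn_eps,bn_momentum Batch-normalization constants.
#' @return A `network_spec` object.
#' @export
network_spec <- function(in_channels = 9L, init_dim = 32L,
                         encoder_planes = c(32L, 48L, 128L, 128L),
                         decoder_planes = c(128L, 128L, 48L, 32L),
                         encoder_blocks = c(2L, 3L, 1L, 3L),
                         decoder_blocks = c(3L, 2L, 1L, 3L),
                         kernel_size = 3L, stem_temporal = 2L,
                         bn_eps = 1e-5, bn_momentum = 0.1) {
  stopifnot(length(encoder_planes) == 4L, length(decoder_planes) == 4L,
            length(encoder_blocks) == 4L, length(decoder_blocks) == 4L,
            all(encoder_blocks >= 1L), all(decoder_blocks >= 1L),
            kernel_size %% 2L == 1L)
  structure(list(in_channels = as.integer(in_channels),
                 init_dim = as.integer(init_dim),
                 encoder_planes = as.integer(encoder_planes),
                 decoder_planes = as.integer(decoder_planes),
                 encoder_blocks = as.integer(encoder_blocks),
                 decoder_blocks = as.integer(decoder_blocks),
                 kernel_size = as.integer(kernel_size),
                 stem_temporal = as.integer(stem_temporal),
                 bn_eps = bn_eps, bn_momentum = bn_momentum),
            class = "network_spec")
}

# channel bookkeeping shared by init, forward and backward
.net_plan <- function(spec) {
  pe <- spec$encoder_planes; pd <- spec$decoder_planes
  enc_in <- integer(4L)   # channels entering each encoder level
  ch <- spec$init_dim
  enc <- vector("list", 4L)
  for (i in 1:4) {
    enc_in[i] <- ch
    blocks <- integer(0)
    ci <- ch
    enc[[i]] <- list(down_ch = ch,
                     block_in = c(ci, rep(pe[i], spec$encoder_blocks[i] - 1L)),
                     out = pe[i])
    ch <- pe[i]
  }
  skip_ch <- c(spec$init_dim, pe[1:3])  # level 0..3 skip channels
  dec <- vector("list", 4L)
  for (j in 1:4) {
    cin <- pd[j] + skip_ch[5L - j]
    dec[[j]] <- list(up_in = ch, up_out = pd[j],
                     block_in = c(cin, rep(pd[j], spec$decoder_blocks[j] - 1L)),
                     out = pd[j])
    ch <- pd[j]
  }
  list(enc = enc, dec = dec, head_in = ch)
}

.init_conv <- function(n_off, ci, co, rng) {
  array(rng$norm(n_off * ci * co) * sqrt(2 / (n_off * ci)),
        dim = c(n_off, ci, co))
}

.init_bn <- function(ch) list(gamma = rep(1, ch), beta = rep(0, ch))

.init_block <- function(ci, co, n_off, rng) {
  p <- list(W1 = .init_conv(n_off, ci, co, rng), bn1 = .init_bn(co),
            W2 = .init_conv(n_off, co, co, rng), bn2 = .init_bn(co))
  if (ci != co) {
    p$Wp <- matrix(rng$norm(ci * co) * sqrt(2 / ci), ci, co)
    p$bnp <- .init_bn(co)
  }
  p
}

#' Build the segmentation network
#'
#' Instantiates all trainable weights (He-style normal initialization,
#' deterministic given `seed`) and the batch-norm running state.
#'
#' @param spec A [network_spec()].
#' @param seed Integer seed recorded in the network (and any checkpoint).
#' @return A `sparse_unet` object.
#' @export
build_network <- function(spec = network_spec(), seed = 1L) {
  stopifnot(inherits(spec, "network_spec"))
  rng <- .seeded_rng(seed)
  plan <- .net_plan(spec)
  n_off <- spec$kernel_size^3L
  n_stem <- spec$kernel_size^3L * spec$stem_temporal

  params <- list(
    stem = list(W = .init_conv(n_stem, spec$in_channels, spec$init_dim, rng),
                bn = .init_bn(spec$init_dim))
  )
  params$enc <- lapply(1:4, function(i) {
    e <- plan$enc[[i]]
    list(down = list(W = .init_conv(n_off, e$down_ch, e$down_ch, rng),
                     bn = .init_bn(e$down_ch)),
         blocks = lapply(e$block_in, function(ci)
           .init_block(ci, e$out, n_off, rng)))
  })
  params$dec <- lapply(1:4, function(j) {
    d <- plan$dec[[j]]
    list(up = list(W = .init_conv(n_off, d$up_in, d$up_out, rng),
                   bn = .init_bn(d$up_out)),
         blocks = lapply(d$block_in, function(ci)
           .init_block(ci, d$out, n_off, rng)))
  })
  params$head <- list(W = matrix(rng$norm(plan$head_in) *
                                   sqrt(2 / plan$head_in), plan$head_in, 1L),
                      b = 0)

  structure(list(spec = spec, params = params, state = .init_bn_state(params),
                 seed = as.integer(seed)),
            class = "sparse_unet")
}

# running-statistics container mirroring every bn in params
.init_bn_state <- function(params) {
  walk <- function(node) {
    if (!is.list(node)) return(NULL)
    nms <- names(node)
    if (is.null(nms)) return(lapply(node, walk))
    out <- list()
    for (nm in nms) {
      if (nm %in% c("bn", "bn1", "bn2", "bnp")) {
        ch <- length(node[[nm]]$gamma)
        out[[nm]] <- list(mean = rep(0, ch), var = rep(1, ch))
      } else if (is.list(node[[nm]])) {
        sub <- walk(node[[nm]])
        if (length(sub) > 0L) out[[nm]] <- sub
      }
    }
    out
  }
  walk(params)
}

#' Count trainable parameters of a network
#' @param net A `sparse_unet` (or a `network_spec`, which is then built with
#'   a throwaway seed).
#' @return Named list with `total` and `n_arrays`.
#' @export
count_parameters <- function(net) {
  if (inherits(net, "network_spec")) net <- build_network(net, seed = 1L)
  lens <- integer(0)
  walk <- function(node) {
    if (is.list(node)) lapply(node, walk)
    else lens[[length(lens) + 1L]] <<- length(node)
  }
  walk(net$params)
  list(total = sum(lens), n_arrays = length(lens))
}

#' @export
print.sparse_unet <- function(x, ...) {
  pc <- count_parameters(x)
  cat("sparse_unet: ", x$spec$in_channels, "-channel input, encoder planes [",
      paste(x$spec$encoder_planes, collapse = ","), "], decoder planes [",
      paste(x$spec$decoder_planes, collapse = ","), "], ",
      format(pc$total, big.mark = ","), " trainable parameters (seed ",
      x$seed, ")\n", sep = "")
  invisible(x)
}

#' Precompute the coordinate hierarchy and kernel maps for one tensor
#'
#' The kernel maps depend only on the coordinates, not on the weights, so a
#' geometry object can be built once per input tensor and reused across
#' forward/backward passes and epochs.
#'
#' @param spec A [network_spec()].
#' @param coords M x 5 integer coordinate matrix.
#' @return A `net_geometry` list.
#' @export
build_geometry <- function(spec, coords) {
  off <- kernel_offsets(spec$kernel_size, 1L)
  stem_off <- kernel_offsets(spec$kernel_size, spec$stem_temporal)
  C <- vector("list", 5L)
  s1 <- vector("list", 5L)
  down <- vector("list", 4L)
  C[[1L]] <- coords
  ts <- 1L
  stem_map <- kernel_map(coords, coords, stem_off, 1L)
  s1[[1L]] <- kernel_map(coords, coords, off, ts)
  for (i in 1:4) {
    Ci <- downsample_coords(C[[i]], ts, 2L)
    down[[i]] <- kernel_map(C[[i]], Ci, off, ts)
    ts <- ts * 2L
    C[[i + 1L]] <- Ci
    s1[[i + 1L]] <- kernel_map(Ci, Ci, off, ts)
  }
  structure(list(C = C, s1 = s1, down = down, stem_map = stem_map),
            class = "net_geometry")
}

# ---- forward / backward ----------------------------------------------------

.bn_f <- function(x, bn, st, eps, momentum, train) {
  p <- list(gamma = bn$gamma, beta = bn$beta,
            running_mean = st$mean, running_var = st$var,
            eps = eps, momentum = momentum)
  r <- bn_forward(x, p, train)
  list(out = r$out, cache = r$cache,
       state = list(mean = r$params$running_mean, var = r$params$running_var))
}

.block_f <- function(x, bp, st, km, eps, mom, train) {
  n <- nrow(x)
  h1 <- conv_apply(x, bp$W1, km, n)
  b1 <- .bn_f(h1, bp$bn1, st$bn1, eps, mom, train)
  m1 <- b1$out > 0
  a1 <- b1$out * m1
  h2 <- conv_apply(a1, bp$W2, km, n)
  b2 <- .bn_f(h2, bp$bn2, st$bn2, eps, mom, train)
  if (!is.null(bp$Wp)) {
    sp <- x %*% bp$Wp
    bps <- .bn_f(sp, bp$bnp, st$bnp, eps, mom, train)
    s <- bps$out
  } else {
    bps <- NULL
    s <- x
  }
  pre <- b2$out + s
  mo <- pre > 0
  st_new <- list(bn1 = b1$state, bn2 = b2$state)
  if (!is.null(bps)) st_new$bnp <- bps$state
  list(out = pre * mo,
       cache = list(x = x, b1 = b1$cache, m1 = m1, a1 = a1, b2 = b2$cache,
                    bp_cache = if (is.null(bps)) NULL else bps$cache, mo = mo),
       state = st_new)
}

.block_b <- function(cache, bp, km, d_out) {
  d_pre <- d_out * cache$mo
  g2 <- bn_backward(cache$b2, list(gamma = bp$bn2$gamma), d_pre)
  cg2 <- conv_apply_grad(cache$a1, bp$W2, km, g2$d_x)
  d_h1 <- cg2$d_in * cache$m1
  g1 <- bn_backward(cache$b1, list(gamma = bp$bn1$gamma), d_h1)
  cg1 <- conv_apply_grad(cache$x, bp$W1, km, g1$d_x)
  d_x <- cg1$d_in
  grads <- list(W1 = cg1$d_W, bn1 = list(gamma = g1$d_gamma, beta = g1$d_beta),
                W2 = cg2$d_W, bn2 = list(gamma = g2$d_gamma, beta = g2$d_beta))
  if (!is.null(bp$Wp)) {
    gp <- bn_backward(cache$bp_cache, list(gamma = bp$bnp$gamma), d_pre)
    grads$Wp <- crossprod(cache$x, gp$d_x)
    grads$bnp <- list(gamma = gp$d_gamma, beta = gp$d_beta)
    d_x <- d_x + gp$d_x %*% t(bp$Wp)
  } else {
    d_x <- d_x + d_pre
  }
  list(d_x = d_x, grads = grads)
}

#' Forward pass of the segmentation network
#'
#' @param net A `sparse_unet`.
#' @param tensor A `sparse_protein_tensor` (9 feature channels).
#' @param train Logical; train mode uses batch statistics (and the returned
#'   `state` carries updated running statistics), eval mode uses stored
#'   running statistics.
#' @param geometry Optional precomputed [build_geometry()] result.
#' @param keep_cache Retain layer caches for a subsequent backward pass.
#' @return List with `probs` (per-row probabilities in (0,1), row-aligned
#'   with `tensor$coords`), `logits`, `state`, `geometry`, and (if
#'   requested) `cache`.
#' @export
net_forward <- function(net, tensor, train = FALSE, geometry = NULL,
                        keep_cache = train) {
  spec <- net$spec
  if (ncol(tensor$feats) != spec$in_channels) {
    stop("tensor has ", ncol(tensor$feats), " channels, network expects ",
         spec$in_channels)
  }
  if (nrow(tensor$coords) == 0L) stop("empty tensor")
  if (is.null(geometry)) geometry <- build_geometry(spec, tensor$coords)
  p <- net$params; st <- net$state
  eps <- spec$bn_eps; mom <- spec$bn_momentum
  cache <- list()

  # stem (level 0)
  n0 <- nrow(geometry$C[[1L]])
  h <- conv_apply(tensor$feats, p$stem$W, geometry$stem_map, n0)
  b <- .bn_f(h, p$stem$bn, st$stem$bn, eps, mom, train)
  st$stem$bn <- b$state
  m <- b$out > 0
  x <- b$out * m
  cache$stem <- list(x_in = tensor$feats, bn = b$cache, m = m)

  skips <- vector("list", 4L)  # levels 0..3
  cache$enc <- vector("list", 4L)
  for (i in 1:4) {
    skips[[i]] <- x
    ei <- p$enc[[i]]
    n_i <- nrow(geometry$C[[i + 1L]])
    h <- conv_apply(x, ei$down$W, geometry$down[[i]], n_i)
    b <- .bn_f(h, ei$down$bn, st$enc[[i]]$down$bn, eps, mom, train)
    st$enc[[i]]$down$bn <- b$state
    m <- b$out > 0
    y <- b$out * m
    cache$enc[[i]] <- list(down = list(x_in = x, bn = b$cache, m = m),
                           blocks = vector("list", length(ei$blocks)))
    for (k in seq_along(ei$blocks)) {
      r <- .block_f(y, ei$blocks[[k]], st$enc[[i]]$blocks[[k]],
                    geometry$s1[[i + 1L]], eps, mom, train)
      st$enc[[i]]$blocks[[k]] <- r$state
      cache$enc[[i]]$blocks[[k]] <- r$cache
      y <- r$out
    }
    x <- y
  }

  cache$dec <- vector("list", 4L)
  for (j in 1:4) {
    dj <- p$dec[[j]]
    lvl <- 5L - j  # output level index into C (1-based: C[[lvl]])
    km_up <- lapply(geometry$down[[lvl]], function(q)
      cbind(out = q[, 2L], `in` = q[, 1L]))
    n_f <- nrow(geometry$C[[lvl]])
    h <- conv_apply(x, dj$up$W, km_up, n_f)
    b <- .bn_f(h, dj$up$bn, st$dec[[j]]$up$bn, eps, mom, train)
    st$dec[[j]]$up$bn <- b$state
    m <- b$out > 0
    u <- b$out * m
    z <- cbind(u, skips[[lvl]])
    cache$dec[[j]] <- list(up = list(x_in = x, bn = b$cache, m = m),
                           n_up = ncol(u),
                           blocks = vector("list", length(dj$blocks)))
    y <- z
    for (k in seq_along(dj$blocks)) {
      r <- .block_f(y, dj$blocks[[k]], st$dec[[j]]$blocks[[k]],
                    geometry$s1[[lvl]], eps, mom, train)
      st$dec[[j]]$blocks[[k]] <- r$state
      cache$dec[[j]]$blocks[[k]] <- r$cache
      y <- r$out
    }
    x <- y
  }

  logits <- drop(x %*% p$head$W) + p$head$b
  cache$head <- list(x_in = x)
  probs <- 1 / (1 + exp(-logits))
  out <- list(probs = probs, logits = logits, state = st, geometry = geometry)
  if (keep_cache) out$cache <- cache
  out
}

#' Backward pass: gradients of all trainable parameters
#'
#' @param net A `sparse_unet`.
#' @param fwd The result of [net_forward()] with `keep_cache = TRUE`.
#' @param d_logits Gradient of the loss with respect to the logits
#'   (length = rows of the input tensor).
#' @return A gradient structure parallel to `net$params`.
#' @export
net_backward <- function(net, fwd, d_logits) {
  p <- net$params; cache <- fwd$cache; geometry <- fwd$geometry
  grads <- list()

  xh <- cache$head$x_in
  grads$head <- list(W = crossprod(xh, matrix(d_logits, ncol = 1L)),
                     b = sum(d_logits))
  d_x <- matrix(d_logits, ncol = 1L) %*% t(p$head$W)

  d_skip <- vector("list", 4L)  # gradient into skips[[lvl]], lvl = 1..4
  grads$dec <- vector("list", 4L)
  for (j in 4:1) {
    dj <- p$dec[[j]]
    lvl <- 5L - j
    cj <- cache$dec[[j]]
    gb <- vector("list", length(dj$blocks))
    for (k in rev(seq_along(dj$blocks))) {
      r <- .block_b(cj$blocks[[k]], dj$blocks[[k]], geometry$s1[[lvl]], d_x)
      gb[[k]] <- r$grads
      d_x <- r$d_x
    }
    n_up <- cj$n_up
    d_u <- d_x[, seq_len(n_up), drop = FALSE]
    d_skip[[lvl]] <- d_x[, -seq_len(n_up), drop = FALSE]
    d_h <- d_u * cj$up$m
    g <- bn_backward(cj$up$bn, list(gamma = dj$up$bn$gamma), d_h)
    km_up <- lapply(geometry$down[[lvl]], function(q)
      cbind(out = q[, 2L], `in` = q[, 1L]))
    cg <- conv_apply_grad(cj$up$x_in, dj$up$W, km_up, g$d_x)
    grads$dec[[j]] <- list(up = list(W = cg$d_W,
                                     bn = list(gamma = g$d_gamma,
                                               beta = g$d_beta)),
                           blocks = gb)
    d_x <- cg$d_in
  }

  grads$enc <- vector("list", 4L)
  for (i in 4:1) {
    ei <- p$enc[[i]]
    ci <- cache$enc[[i]]
    gb <- vector("list", length(ei$blocks))
    for (k in rev(seq_along(ei$blocks))) {
      r <- .block_b(ci$blocks[[k]], ei$blocks[[k]], geometry$s1[[i + 1L]], d_x)
      gb[[k]] <- r$grads
      d_x <- r$d_x
    }
    d_h <- d_x * ci$down$m
    g <- bn_backward(ci$down$bn, list(gamma = ei$down$bn$gamma), d_h)
    cg <- conv_apply_grad(ci$down$x_in, ei$down$W, geometry$down[[i]], g$d_x)
    grads$enc[[i]] <- list(down = list(W = cg$d_W,
                                       bn = list(gamma = g$d_gamma,
                                                 beta = g$d_beta)),
                           blocks = gb)
    d_x <- cg$d_in + d_skip[[i]]
  }

  d_h <- d_x * cache$stem$m
  g <- bn_backward(cache$stem$bn, list(gamma = p$stem$bn$gamma), d_h)
  cg <- conv_apply_grad(cache$stem$x_in, p$stem$W, geometry$stem_map, g$d_x)
  grads$stem <- list(W = cg$d_W,
                     bn = list(gamma = g$d_gamma, beta = g$d_beta))
  grads
}

#' Per-cell binding probabilities for a tensor
#'
#' Runs the network in eval mode and returns the sigmoid head output,
#' row-aligned with `tensor$coords`.
#'
#' @inheritParams net_forward
#' @return Numeric vector of probabilities in (0, 1).
#' @export
predict_probabilities <- function(net, tensor, geometry = NULL) {
  net_forward(net, tensor, train = FALSE, geometry = geometry,
              keep_cache = FALSE)$probs
}

#' Save / load a network checkpoint
#'
#' Checkpoints are versioned and carry the spec, all weights, the
#' batch-norm running state and the initialization seed.
#'
#' @param net A `sparse_unet`.
#' @param path Destination file.
#' @return `save_checkpoint` returns `path` invisibly; `load_checkpoint`
#'   returns the `sparse_unet`.
#' @export
save_checkpoint <- function(net, path) {
  saveRDS(list(format = "sparsepocket-checkpoint", version = 1L,
               spec = net$spec, params = net$params, state = net$state,
               seed = net$seed),
          path, compress = "gzip")
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  x <- readRDS(path)
  if (!identical(x$format, "sparsepocket-checkpoint")) {
    stop("'", path, "' is not a network checkpoint")
  }
  structure(list(spec = x$spec, params = x$params, state = x$state,
                 seed = x$seed),
            class = "sparse_unet")
}
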