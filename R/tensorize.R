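# Sparse tensor construction: 5 A binding-atom labeling, grid quantization
# into the (x, y, z, t, b) coordinate / 9-feature / binary-label matrices,
# and batching.

#' Tensorization configuration
#'
#' @param resolution Grid step in Angstrom per lattice unit (default 1.0).
#' @param label_radius Binding-atom labeling radius in Angstrom (default 5.0,
#'   boundary inclusive).
#' @param perception_backend Featurization backend passed to
#'   [featurize_atoms()].
#' @return A `tensorize_config` list.
#' @export
tensorize_config <- function(resolution = 1.0, label_radius = 5.0,
                             perception_backend = rule_perception_backend) {
  stopifnot(resolution > 0, label_radius > 0)
  structure(list(resolution = resolution, label_radius = label_radius,
                 perception_backend = perception_backend),
            class = "tensorize_config")
}

#' Label binding atoms by distance to the ligand
#'
#' An atom is a binding atom when its minimum Euclidean distance to any
#' ligand atom is at most `radius` (boundary inclusive). Distances are found
#' through a uniform cell-list spatial index over the protein atoms, so only
#' atoms in the 27 cells around each ligand atom are examined.
#'
#' @param structure A `protein_structure`.
#' @param ligand A `ligand_coordinates` object.
#' @param radius Labeling radius in Angstrom (default 5).
#' @return Integer vector (0/1), one entry per retained atom.
#' @export
label_binding_atoms <- function(structure, ligand, radius = 5.0) {
  if (!inherits(ligand, "ligand_coordinates")) {
    stop("'ligand' must be a ligand_coordinates object")
  }
  atoms <- retained_atoms(structure)
  p <- as.matrix(atoms[, c("x", "y", "z")])
  l <- ligand$atom_coords
  labels <- integer(nrow(p))
  if (nrow(p) == 0L) return(labels)

  # cell list over protein atoms, cell edge = radius
  cell <- floor(sweep(p, 2L, apply(p, 2L, min)) / radius)
  key <- paste(cell[, 1L], cell[, 2L], cell[, 3L])
  index <- split(seq_len(nrow(p)), key)
  origin <- apply(p, 2L, min)
  lcell <- floor(sweep(l, 2L, origin, "-") / radius)
  off <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  for (j in seq_len(nrow(l))) {
    for (k in seq_len(nrow(off))) {
      kk <- paste(lcell[j, 1L] + off[k, 1L], lcell[j, 2L] + off[k, 2L],
                  lcell[j, 3L] + off[k, 3L])
      idx <- index[[kk]]
      if (is.null(idx)) next
      d2 <- (p[idx, 1L] - l[j, 1L])^2 + (p[idx, 2L] - l[j, 2L])^2 +
        (p[idx, 3L] - l[j, 3L])^2
      labels[idx[d2 <= radius^2]] <- 1L
    }
  }
  labels
}

#' Quantize a featurized structure into a sparse protein tensor
#'
#' Grid coordinates are `floor((coord - origin) / resolution)` with the
#' per-structure minimum corner as origin. Atoms falling into the same cell
#' are merged: features are averaged, the label is the maximum, and
#' `atom_map` records which source atoms each row aggregates.
#'
#' @param structure A `protein_structure`.
#' @param features N x 9 feature matrix aligned with the retained atoms.
#' @param labels Length-N 0/1 vector (may be `NULL` for unlabeled inference
#'   input; labels are then all zero).
#' @param config A [tensorize_config()].
#' @param t Structure index stored in the 4th coordinate column.
#' @param b Batch index stored in the 5th coordinate column.
#' @return A `sparse_protein_tensor`: list with `coords` (M x 5 integer),
#'   `feats` (M x 9), `labels` (length M 0/1), `origin`, `resolution`,
#'   `atom_map` (list of source atom index vectors) and `structure_id`.
#' @export
quantize <- function(structure, features, labels = NULL,
                     config = tensorize_config(), t = 0L, b = 0L) {
  if (config$resolution <= 0) stop("resolution must be positive")
  atoms <- retained_atoms(structure)
  n <- nrow(atoms)
  stopifnot(nrow(features) == n)
  if (is.null(labels)) labels <- integer(n)
  stopifnot(length(labels) == n)

  p <- as.matrix(atoms[, c("x", "y", "z")])
  origin <- apply(p, 2L, min)
  grid <- floor(sweep(p, 2L, origin) / config$resolution)
  storage.mode(grid) <- "integer"
  key <- paste(grid[, 1L], grid[, 2L], grid[, 3L])
  groups <- split(seq_len(n), factor(key, levels = unique(key)))

  m <- length(groups)
  coords <- matrix(0L, m, 5L, dimnames = list(NULL, c("x", "y", "z", "t", "b")))
  feats <- matrix(0, m, ncol(features), dimnames = list(NULL, colnames(features)))
  lab <- integer(m)
  for (g in seq_len(m)) {
    idx <- groups[[g]]
    coords[g, 1:3] <- grid[idx[1L], ]
    feats[g, ] <- colMeans(features[idx, , drop = FALSE])
    lab[g] <- max(labels[idx])
  }
  coords[, 4L] <- as.integer(t)
  coords[, 5L] <- as.integer(b)

  structure(list(coords = coords, feats = feats, labels = lab,
                 origin = origin, resolution = config$resolution,
                 atom_map = unname(groups),
                 structure_id = structure$structure_id),
            class = "sparse_protein_tensor")
}

#' Full structure-to-tensor pipeline
#'
#' Convenience wrapper: featurize, (optionally) label against a ligand, and
#' quantize.
#'
#' @inheritParams quantize
#' @param ligand Optional `ligand_coordinates` for labeling.
#' @param config A [tensorize_config()].
#' @return A `sparse_protein_tensor`.
#' @export
tensorize_structure <- function(structure, ligand = NULL,
                                config = tensorize_config(), t = 0L, b = 0L) {
  feats <- featurize_atoms(structure, backend = config$perception_backend)
  labels <- if (is.null(ligand)) NULL else {
    label_binding_atoms(structure, ligand, radius = config$label_radius)
  }
  quantize(structure, feats, labels, config = config, t = t, b = b)
}

#' @export
print.sparse_protein_tensor <- function(x, ...) {
  cat("sparse_protein_tensor '", x$structure_id, "': ", nrow(x$coords),
      " occupied cells, ", sum(x$labels), " positive, resolution ",
      x$resolution, " A\n", sep = "")
  invisible(x)
}

#' Batch sparse protein tensors
#'
#' Row-concatenates tensors, keeping each tensor's structure index `t` and
#' assigning the batch index `b` by position (0-based). Overlapping spatial
#' coordinates across structures remain distinct rows because the (t, b)
#' columns disambiguate them.
#'
#' @param tensors List of `sparse_protein_tensor` objects sharing a
#'   resolution.
#' @return A combined `sparse_protein_tensor`; `atom_map` entries carry an
#'   attribute `tensor_of_row` giving the source tensor of every row.
#' @export
batch_tensors <- function(tensors) {
  stopifnot(length(tensors) >= 1L)
  res <- vapply(tensors, function(x) x$resolution, numeric(1L))
  if (length(unique(res)) != 1L) {
    stop("cannot batch tensors with mixed resolutions: ",
         paste(unique(res), collapse = ", "))
  }
  coords <- do.call(rbind, lapply(seq_along(tensors), function(i) {
    ci <- tensors[[i]]$coords
    ci[, 5L] <- i - 1L
    ci
  }))
  out <- structure(list(
    coords = coords,
    feats = do.call(rbind, lapply(tensors, function(x) x$feats)),
    labels = unlist(lapply(tensors, function(x) x$labels), use.names = FALSE),
    origin = NULL,
    resolution = res[1L],
    atom_map = do.call(c, lapply(tensors, function(x) x$atom_map)),
    structure_id = paste(vapply(tensors, function(x) x$structure_id,
                                character(1L)), collapse = "+")
  ), class = "sparse_protein_tensor")
  attr(out, "tensor_of_row") <- rep.int(seq_along(tensors),
                                        vapply(tensors, function(x)
                                          nrow(x$coords), integer(1L)))
  attr(out, "row_offsets") <- c(0L, cumsum(vapply(
    tensors, function(x) nrow(x$coords), integer(1L))))
  out
}

#' Save / load a sparse protein tensor archive
#'
#' Stores coords (integer), feats (double), labels (integer), origin,
#' resolution and atom_map in one compressed archive.
#'
#' @param tensor A `sparse_protein_tensor`.
#' @param path File path (`.rds`).
#' @return `save_tensor` returns `path` invisibly; `load_tensor` the tensor.
#' @export
save_tensor <- function(tensor, path) {
  saveRDS(tensor, path, compress = "gzip")
  invisible(path)
}

#' @rdname save_tensor
#' @export
load_tensor <- function(path) {
  x <- readRDS(path)
  stopifnot(inherits(x, "sparse_protein_tensor"))
  x
}
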