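# Pocket extraction: density-based clustering (DBSCAN) of predicted binding
# atoms, with neighbor queries served by an in-package k-d tree.

#' Postprocessing configuration
#'
#' @param probability_threshold Cells with predicted probability at or above
#'   this value feed the clustering (default 0.5).
#' @param eps DBSCAN neighborhood radius in Angstrom (default 5.5).
#' @param min_samples Minimum neighborhood size (point itself included) for
#'   a core point (default 5).
#' @param tree_leaf_size k-d tree leaf size (default 100).
#' @return A `postprocess_config` list.
#' @export
postprocess_config <- function(probability_threshold = 0.5, eps = 5.5,
                               min_samples = 5L, tree_leaf_size = 100L) {
  stopifnot(eps > 0, min_samples >= 1L, tree_leaf_size >= 1L)
  structure(list(probability_threshold = probability_threshold, eps = eps,
                 min_samples = as.integer(min_samples),
                 tree_leaf_size = as.integer(tree_leaf_size)),
            class = "postprocess_config")
}

#' Build a k-d tree over 3D points
#'
#' Recursive median splits on the widest coordinate, stopping at
#' `leaf_size` points per leaf.
#'
#' @param points N x 3 numeric matrix.
#' @param leaf_size Maximum points per leaf (default 100).
#' @return A `kd_tree` object for [kd_query_radius()].
#' @export
kd_tree <- function(points, leaf_size = 100L) {
  points <- as.matrix(points)
  build <- function(idx) {
    if (length(idx) <= leaf_size) {
      return(list(leaf = TRUE, idx = idx,
                  lo = apply(points[idx, , drop = FALSE], 2L, min),
                  hi = apply(points[idx, , drop = FALSE], 2L, max)))
    }
    p <- points[idx, , drop = FALSE]
    spread <- apply(p, 2L, function(v) diff(range(v)))
    ax <- which.max(spread)
    med <- stats::median(p[, ax])
    left <- idx[p[, ax] <= med]
    right <- idx[p[, ax] > med]
    if (length(left) == 0L || length(right) == 0L) {  # degenerate ties
      ord <- idx[order(p[, ax])]
      half <- length(ord) %/% 2L
      left <- ord[seq_len(half)]
      right <- ord[-seq_len(half)]
    }
    nl <- build(left); nr <- build(right)
    list(leaf = FALSE, left = nl, right = nr,
         lo = pmin(nl$lo, nr$lo), hi = pmax(nl$hi, nr$hi))
  }
  structure(list(root = build(seq_len(nrow(points))), points = points,
                 leaf_size = as.integer(leaf_size)),
            class = "kd_tree")
}

#' Radius query on a k-d tree
#'
#' @param tree A [kd_tree()].
#' @param q Query point (length 3).
#' @param radius Search radius.
#' @return Sorted integer indices of points within `radius` (inclusive).
#' @export
kd_query_radius <- function(tree, q, radius) {
  pts <- tree$points
  r2 <- radius^2
  out <- integer(0)
  visit <- function(node) {
    # prune: squared distance from q to the node's bounding box
    d <- pmax(node$lo - q, 0, q - node$hi)
    if (sum(d^2) > r2) return(invisible(NULL))
    if (node$leaf) {
      p <- pts[node$idx, , drop = FALSE]
      d2 <- (p[, 1L] - q[1L])^2 + (p[, 2L] - q[2L])^2 + (p[, 3L] - q[3L])^2
      out <<- c(out, node$idx[d2 <= r2])
    } else {
      visit(node$left); visit(node$right)
    }
    invisible(NULL)
  }
  visit(tree$root)
  sort(out)
}

#' Density-based clustering of 3D points (DBSCAN)
#'
#' Standard DBSCAN semantics: a core point has at least `min_samples`
#' points (itself included) within `eps`; clusters are the connected
#' components of core points, plus border points reachable from them.
#' Border points reachable from several clusters join the first-discovered
#' cluster under deterministic ascending-index iteration. Neighborhoods are
#' served by the package k-d tree.
#'
#' @param points N x 3 numeric matrix.
#' @param eps Neighborhood radius.
#' @param min_samples Core-point threshold (self included).
#' @param leaf_size k-d tree leaf size.
#' @return Integer vector of cluster labels (1, 2, ...), `-1` for noise;
#'   zero-length for empty input.
#' @export
density_cluster <- function(points, eps = 5.5, min_samples = 5L,
                            leaf_size = 100L) {
  points <- as.matrix(points)
  n <- nrow(points)
  if (n == 0L) return(integer(0))
  stopifnot(all(is.finite(points)))
  tree <- kd_tree(points, leaf_size)
  neighbors <- lapply(seq_len(n), function(i)
    kd_query_radius(tree, points[i, ], eps))
  is_core <- vapply(neighbors, length, integer(1L)) >= min_samples

  labels <- rep.int(-1L, n)
  cluster <- 0L
  for (i in seq_len(n)) {
    if (!is_core[i] || labels[i] != -1L) next
    cluster <- cluster + 1L
    labels[i] <- cluster
    queue <- i
    head <- 1L
    while (head <= length(queue)) {
      j <- queue[head]
      head <- head + 1L
      if (!is_core[j]) next
      nb <- neighbors[[j]]
      new <- nb[labels[nb] == -1L]
      if (length(new) > 0L) {
        labels[new] <- cluster
        queue <- c(queue, new)
      }
    }
  }
  labels
}

#' Extract binding pockets from network predictions
#'
#' Tensor rows with probability at or above the threshold are mapped back to
#' their source atoms (original Angstrom coordinates) through the tensor's
#' `atom_map` and clustered with [density_cluster()]. Every non-noise
#' cluster becomes a pocket with its member atoms, member residues and
#' centroid; pockets are ordered by member count (descending; ties by
#' smallest member atom index).
#'
#' @param tensor A `sparse_protein_tensor` of the structure.
#' @param probabilities Per-row probabilities aligned with `tensor$coords`.
#' @param structure The source `protein_structure`.
#' @param config A [postprocess_config()].
#' @return List of `pocket` objects: `pocket_id`, `member_atoms` (indices
#'   into `retained_atoms(structure)`), `member_residues` (data frame),
#'   `center` (xyz), `mean_probability`.
#' @export
extract_pockets <- function(tensor, probabilities, structure,
                            config = postprocess_config()) {
  stopifnot(length(probabilities) == nrow(tensor$coords))
  atoms <- retained_atoms(structure)
  rows <- which(probabilities >= config$probability_threshold)
  if (length(rows) == 0L) return(list())
  atom_idx <- sort(unique(unlist(tensor$atom_map[rows], use.names = FALSE)))
  row_prob <- numeric(nrow(atoms))
  for (r in rows) row_prob[tensor$atom_map[[r]]] <- probabilities[r]
  pts <- as.matrix(atoms[atom_idx, c("x", "y", "z")])
  labels <- density_cluster(pts, eps = config$eps,
                            min_samples = config$min_samples,
                            leaf_size = config$tree_leaf_size)
  ids <- setdiff(unique(labels), -1L)
  pockets <- lapply(ids, function(cl) {
    members <- atom_idx[labels == cl]
    a <- atoms[members, , drop = FALSE]
    res <- unique(a[, c("chain_id", "res_seq", "i_code", "res_name")])
    rownames(res) <- NULL
    structure(list(pocket_id = NA_integer_, member_atoms = members,
                   member_residues = res,
                   center = colMeans(as.matrix(a[, c("x", "y", "z")])),
                   mean_probability = mean(row_prob[members])),
              class = "pocket")
  })
  sizes <- vapply(pockets, function(p) length(p$member_atoms), integer(1L))
  firsts <- vapply(pockets, function(p) min(p$member_atoms), integer(1L))
  ord <- order(-sizes, firsts)
  pockets <- pockets[ord]
  for (i in seq_along(pockets)) pockets[[i]]$pocket_id <- i
  pockets
}

#' @export
print.pocket <- function(x, ...) {
  cat("pocket ", x$pocket_id, ": ", length(x$member_atoms), " atoms, ",
      nrow(x$member_residues), " residues, center (",
      paste(sprintf("%.2f", x$center), collapse = ", "), ")\n", sep = "")
  invisible(x)
}

#' Write pockets as a CSV table
#' @param pockets List of `pocket` objects.
#' @param path Destination file.
#' @return `path`, invisibly.
#' @export
write_pocket_csv <- function(pockets, path) {
  rows <- lapply(pockets, function(p) {
    data.frame(pocket_id = p$pocket_id,
               n_atoms = length(p$member_atoms),
               center_x = p$center[1L], center_y = p$center[2L],
               center_z = p$center[3L],
               mean_probability = p$mean_probability,
               residues = paste(p$member_residues$chain_id,
                                p$member_residues$res_seq,
                                p$member_residues$res_name,
                                sep = ":", collapse = ";"))
  })
  d <- if (length(rows) > 0L) do.call(rbind, rows) else {
    data.frame(pocket_id = integer(0), n_atoms = integer(0),
               center_x = numeric(0), center_y = numeric(0),
               center_z = numeric(0), mean_probability = numeric(0),
               residues = character(0))
  }
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}
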