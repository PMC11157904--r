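# Brute-force reference implementations used as independent oracles, plus
# small fixture builders. These deliberately avoid the package's spatial
# index / kernel-map machinery: direct loops and linear searches only.

# minimal PDB text builder
mini_pdb <- function(atoms, remarks = character(0), models = NULL) {
  fmt <- function(a) {
    sprintf("%-6s%5d %-4s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            ifelse(a$het, "HETATM", "ATOM"), a$serial,
            paste0(" ", a$name), " ", a$res, a$chain, a$seq, " ",
            a$x, a$y, a$z, 1, 0, a$el)
  }
  body <- vapply(atoms, fmt, character(1L))
  if (!is.null(models)) {
    lines <- remarks
    i <- 1L
    for (m in seq_along(models)) {
      lines <- c(lines, sprintf("MODEL     %4d", m),
                 body[i:(i + models[m] - 1L)], "ENDMDL")
      i <- i + models[m]
    }
    paste(c(lines, "END"), collapse = "\n")
  } else {
    paste(c(remarks, body, "END"), collapse = "\n")
  }
}

atom_spec <- function(serial, name, res, chain, seq, x, y, z,
                      el = substr(name, 1, 1), het = FALSE) {
  list(serial = serial, name = name, res = res, chain = chain, seq = seq,
       x = x, y = y, z = z, el = el, het = het)
}

# random sparse feature map on an n^3 grid (single structure, t = b = 0)
random_sparse_map <- function(n_sites, grid = 8L, channels = 3L, seed = 1L) {
  set.seed(seed)
  all_cells <- as.matrix(expand.grid(0:(grid - 1L), 0:(grid - 1L),
                                     0:(grid - 1L)))
  pick <- sample(nrow(all_cells), min(n_sites, nrow(all_cells)))
  coords <- cbind(all_cells[pick, , drop = FALSE], 0L, 0L)
  colnames(coords) <- c("x", "y", "z", "t", "b")
  sparse_feature_map(coords,
                     matrix(rnorm(length(pick) * channels), ncol = channels))
}

# brute-force generalized sparse convolution: for each output coordinate,
# linear-search the input for every offset tap
brute_sparse_conv <- function(in_coords, in_feats, out_coords, offsets, W,
                              offset_stride = 1L) {
  co <- dim(W)[3L]
  out <- matrix(0, nrow(out_coords), co)
  for (r in seq_len(nrow(out_coords))) {
    for (k in seq_len(nrow(offsets))) {
      tgt <- out_coords[r, ]
      tgt[1:3] <- tgt[1:3] + offsets[k, 1:3] * offset_stride
      tgt[4] <- tgt[4] + offsets[k, 4]
      hit <- which(in_coords[, 1] == tgt[1] & in_coords[, 2] == tgt[2] &
                     in_coords[, 3] == tgt[3] & in_coords[, 4] == tgt[4] &
                     in_coords[, 5] == tgt[5])
      if (length(hit) == 1L) {
        out[r, ] <- out[r, ] +
          as.numeric(in_feats[hit, ] %*% matrix(W[k, , ], dim(W)[2L], co))
      }
    }
  }
  out
}

# dense 3D convolution of a zero-padded dense array; evaluates
# out[u] = sum_i W_i x[u + i * offset_stride] at the requested coordinates
dense_conv_at <- function(dense, W, offsets, at_coords, offset_stride = 1L) {
  dims <- dim(dense)[1:3]
  co <- dim(W)[3L]
  out <- matrix(0, nrow(at_coords), co)
  for (r in seq_len(nrow(at_coords))) {
    for (k in seq_len(nrow(offsets))) {
      p <- at_coords[r, 1:3] + offsets[k, 1:3] * offset_stride + 1L
      if (all(p >= 1L) && all(p <= dims)) {
        out[r, ] <- out[r, ] +
          as.numeric(dense[p[1], p[2], p[3], ] %*%
                       matrix(W[k, , ], dim(W)[2L], co))
      }
    }
  }
  out
}

sparse_to_dense <- function(map, grid) {
  ch <- ncol(map$feats)
  dense <- array(0, dim = c(grid, grid, grid, ch))
  for (r in seq_len(nrow(map$coords))) {
    dense[map$coords[r, 1] + 1L, map$coords[r, 2] + 1L,
          map$coords[r, 3] + 1L, ] <- map$feats[r, ]
  }
  dense
}

# brute-force all-pairs binding-atom labeling
brute_labels <- function(structure, ligand, radius = 5.0) {
  atoms <- retained_atoms(structure)
  p <- as.matrix(atoms[, c("x", "y", "z")])
  l <- ligand$atom_coords
  out <- integer(nrow(p))
  for (i in seq_len(nrow(p))) {
    for (j in seq_len(nrow(l))) {
      if (sqrt(sum((p[i, ] - l[j, ])^2)) <= radius) { out[i] <- 1L; break }
    }
  }
  out
}

# brute-force DBSCAN (no spatial index), same deterministic iteration order
# as the package implementation
brute_dbscan <- function(points, eps, min_samples) {
  n <- nrow(points)
  if (n == 0L) return(integer(0))
  d <- as.matrix(dist(points))
  neighbors <- lapply(seq_len(n), function(i) which(d[i, ] <= eps))
  is_core <- vapply(neighbors, length, integer(1L)) >= min_samples
  labels <- rep.int(-1L, n)
  cl <- 0L
  for (i in seq_len(n)) {
    if (!is_core[i] || labels[i] != -1L) next
    cl <- cl + 1L
    labels[i] <- cl
    queue <- i
    head <- 1L
    while (head <= length(queue)) {
      j <- queue[head]; head <- head + 1L
      if (!is_core[j]) next
      new <- neighbors[[j]][labels[neighbors[[j]]] == -1L]
      if (length(new) > 0L) {
        labels[new] <- cl
        queue <- c(queue, new)
      }
    }
  }
  labels
}

# exhaustive threshold enumeration of the precision-recall curve area
brute_prc_auc <- function(probs, labels) {
  thr <- sort(unique(probs), decreasing = TRUE)
  pos <- sum(labels == 1)
  prev_r <- 0; auc <- 0
  for (t in thr) {
    sel <- probs >= t
    tp <- sum(sel & labels == 1)
    prec <- tp / sum(sel)
    rec <- tp / pos
    auc <- auc + (rec - prev_r) * prec
    prev_r <- rec
  }
  auc
}

# reduced network spec shared by the training tests
reduced_spec <- function() {
  network_spec(init_dim = 8L, encoder_planes = c(8L, 12L, 16L, 16L),
               decoder_planes = c(16L, 16L, 12L, 8L),
               encoder_blocks = rep(1L, 4L), decoder_blocks = rep(1L, 4L))
}

# small labeled synthetic tensors for training tests
small_training_set <- function(n = 5L, n_atoms = 300L, box = 30) {
  lapply(seq_len(n), function(s) {
    cx <- generate_complex(synthetic_spec(n_atoms = n_atoms, box_size = box,
                                          seed = s))
    tensorize_structure(cx$structure, cx$ligands[[1L]])
  })
}
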