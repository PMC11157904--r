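# Deterministic generator of protein-like complexes with planted binding
# pockets, so the full prepare/train/predict/evaluate cycle is exercisable
# without any external data.
#
# Geometry: residues are laid out along a self-avoiding-ish random walk
# (3.8 A C-alpha steps, reflected at the box walls) and decorated with
# backbone and side-chain atoms. Chemistry: residue types are drawn from an
# apolar pool by default; residues near a planted pseudo-ligand are drawn
# from a polar pool with elevated probability, so binding sites carry a
# donor/acceptor/charge feature signal on top of the geometric one.

.apolar_pool <- c("ALA", "LEU", "VAL", "PHE", "GLY")
.polar_pool <- c("SER", "THR", "ASN", "GLN", "LYS", "ASP")

.sidechain_templates <- list(
  ALA = c("CB"), GLY = character(0),
  LEU = c("CB", "CG", "CD1", "CD2"), VAL = c("CB", "CG1", "CG2"),
  PHE = c("CB", "CG", "CD1", "CD2"), SER = c("CB", "OG"),
  THR = c("CB", "OG1", "CG2"), ASN = c("CB", "CG", "OD1", "ND2"),
  GLN = c("CB", "CG", "CD", "OE1"), LYS = c("CB", "CG", "CD", "CE", "NZ"),
  ASP = c("CB", "CG", "OD1", "OD2")
)

#' Synthetic complex specification
#'
#' @param n_atoms Approximate protein atom count (default 1000).
#' @param n_pockets Number of planted binding pockets (default 1).
#' @param pocket_radius Spread of the pseudo-ligand atom blob in Angstrom
#'   (default 4).
#' @param ligand_atoms_per_pocket Pseudo-ligand atoms per pocket
#'   (default 8).
#' @param box_size Edge of the bounding box in Angstrom (default 44).
#' @param positive_feature_bias Added probability that a residue near a
#'   pseudo-ligand is polar (default 0.6, on a 0.25 baseline).
#' @param seed Seed making the complex fully reproducible.
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_atoms = 1000L, n_pockets = 1L, pocket_radius = 4,
                           ligand_atoms_per_pocket = 8L, box_size = 44,
                           positive_feature_bias = 0.6, seed = 1L) {
  stopifnot(n_atoms >= 20L * n_pockets, box_size > 4 * pocket_radius,
            ligand_atoms_per_pocket >= 1L, positive_feature_bias >= 0)
  structure(list(n_atoms = as.integer(n_atoms),
                 n_pockets = as.integer(n_pockets),
                 pocket_radius = pocket_radius,
                 ligand_atoms_per_pocket = as.integer(ligand_atoms_per_pocket),
                 box_size = box_size,
                 positive_feature_bias = positive_feature_bias,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

.unit_vec <- function() {
  v <- stats::rnorm(3L)
  v / sqrt(sum(v^2))
}

#' Generate a synthetic protein-ligand complex
#'
#' @param spec A [synthetic_spec()].
#' @param structure_id Identifier (default derived from the seed).
#' @return List with `structure` (a `protein_structure` whose HETATM
#'   records hold the pseudo-ligands as residues `LIG`) and `ligands`
#'   (list of `ligand_coordinates`, one per planted pocket).
#' @export
generate_complex <- function(spec = synthetic_spec(), structure_id = NULL) {
  if (is.null(structure_id)) structure_id <- sprintf("syn%05d", spec$seed)
  withr_seed(spec$seed, {
    margin <- 4
    lo <- margin; hi <- spec$box_size - margin

    # C-alpha random walk with direction persistence, reflected at walls
    n_res_max <- ceiling(spec$n_atoms / 3L)
    ca <- matrix(NA_real_, n_res_max, 3L)
    pos <- stats::runif(3L, lo + (hi - lo) / 4, hi - (hi - lo) / 4)
    dir <- .unit_vec()
    for (r in seq_len(n_res_max)) {
      ca[r, ] <- pos
      dir <- dir + 0.9 * .unit_vec()
      dir <- dir / sqrt(sum(dir^2))
      step <- pos + 3.8 * dir
      for (d in 1:3) {
        if (step[d] < lo) { step[d] <- 2 * lo - step[d]; dir[d] <- -dir[d] }
        if (step[d] > hi) { step[d] <- 2 * hi - step[d]; dir[d] <- -dir[d] }
      }
      pos <- step
    }

    # pocket centers on interior residues, mutually well separated
    min_sep <- max(4 * spec$pocket_radius, 20)
    # only residues certain to receive atoms (worst case 9 atoms/residue)
    # can host a pocket, so every planted site is surrounded by protein
    n_decorated_min <- max(spec$n_atoms %/% 9L, 3L)
    interior <- 2:max(n_decorated_min - 1L, 2L)
    centers <- matrix(NA_real_, spec$n_pockets, 3L)
    chosen <- integer(0)
    for (p in seq_len(spec$n_pockets)) {
      ok <- FALSE
      for (try in 1:200) {
        cand <- sample(interior, 1L)
        cpos <- ca[cand, ]
        if (length(chosen) == 0L ||
            min(sqrt(rowSums(sweep(centers[seq_along(chosen), , drop = FALSE],
                                   2L, cpos)^2))) >= min_sep) {
          centers[p, ] <- cpos
          chosen <- c(chosen, cand)
          ok <- TRUE
          break
        }
      }
      if (!ok) stop("could not place ", spec$n_pockets,
                    " pockets with separation ", min_sep,
                    " A inside a ", spec$box_size, " A box")
    }

    # pseudo-ligand blobs around the pocket centers
    ligands <- lapply(seq_len(spec$n_pockets), function(p) {
      pts <- t(vapply(seq_len(spec$ligand_atoms_per_pocket), function(i) {
        centers[p, ] + .unit_vec() * stats::runif(1L, 0, spec$pocket_radius / 2)
      }, numeric(3L)))
      ligand_coordinates(pts, ligand_id = sprintf("LIG_%d", p))
    })
    lig_all <- do.call(rbind, lapply(ligands, function(l) l$atom_coords))

    # residue types: polar bias near any ligand atom
    near_lig <- vapply(seq_len(n_res_max), function(r) {
      min(sqrt(rowSums(sweep(lig_all, 2L, ca[r, ])^2))) <= 7
    }, logical(1L))
    p_polar <- ifelse(near_lig, pmin(0.25 + spec$positive_feature_bias, 1), 0.25)
    polar <- stats::runif(n_res_max) < p_polar
    res_type <- ifelse(polar,
                       sample(.polar_pool, n_res_max, replace = TRUE),
                       sample(.apolar_pool, n_res_max, replace = TRUE))

    # decorate residues with atoms until the atom budget is spent
    rows <- list()
    serial <- 0L
    n_placed <- 0L
    for (r in seq_len(n_res_max)) {
      if (n_placed >= spec$n_atoms) break
      rt <- res_type[r]
      prev <- if (r > 1L) ca[r - 1L, ] else ca[r, ] + c(3.8, 0, 0)
      nxt <- if (r < n_res_max) ca[r + 1L, ] else ca[r, ] - c(3.8, 0, 0)
      to_prev <- (prev - ca[r, ]); to_prev <- to_prev / sqrt(sum(to_prev^2))
      to_next <- (nxt - ca[r, ]); to_next <- to_next / sqrt(sum(to_next^2))
      names_r <- c("N", "CA", "C", "O", .sidechain_templates[[rt]])
      coords_r <- rbind(
        ca[r, ] + 1.46 * to_prev,
        ca[r, ],
        ca[r, ] + 1.52 * to_next,
        ca[r, ] + 1.52 * to_next + 1.23 * .unit_vec()
      )
      base <- ca[r, ]
      for (s in seq_along(.sidechain_templates[[rt]])) {
        base <- base + 1.5 * .unit_vec()
        coords_r <- rbind(coords_r, base)
      }
      for (a in seq_along(names_r)) {
        serial <- serial + 1L
        rows[[length(rows) + 1L]] <- data.frame(
          serial = serial, atom_name = names_r[a], alt_loc = " ",
          res_name = rt, chain_id = "A", res_seq = r, i_code = " ",
          x = round(coords_r[a, 1L], 3L), y = round(coords_r[a, 2L], 3L),
          z = round(coords_r[a, 3L], 3L),
          element = substr(names_r[a], 1L, 1L), is_het = FALSE,
          stringsAsFactors = FALSE
        )
      }
      n_placed <- n_placed + length(names_r)
    }

    # pseudo-ligand HETATM records
    for (p in seq_len(spec$n_pockets)) {
      lc <- ligands[[p]]$atom_coords
      for (a in seq_len(nrow(lc))) {
        serial <- serial + 1L
        rows[[length(rows) + 1L]] <- data.frame(
          serial = serial, atom_name = sprintf("C%d", a), alt_loc = " ",
          res_name = "LIG", chain_id = "A", res_seq = 900L + p, i_code = " ",
          x = round(lc[a, 1L], 3L), y = round(lc[a, 2L], 3L),
          z = round(lc[a, 3L], 3L), element = "C", is_het = TRUE,
          stringsAsFactors = FALSE
        )
      }
    }

    atoms <- do.call(rbind, rows)
    st <- structure(
      list(structure_id = structure_id, atoms = atoms,
           model_atom_counts = nrow(atoms), resolution = 1.5,
           chain_ids = "A"),
      class = "protein_structure"
    )
    # ligand coordinates re-read at PDB precision so files round-trip
    ligands <- lapply(seq_len(spec$n_pockets), function(p) {
      sel <- atoms$is_het & atoms$res_seq == 900L + p
      ligand_coordinates(atoms[sel, c("x", "y", "z")],
                         ligand_id = sprintf("LIG_%d", p))
    })
    list(structure = st, ligands = ligands)
  })
}

#' Generate a serialized synthetic dataset with a manifest
#'
#' Writes one PDB file and one ligand CSV per structure plus a
#' `manifest.csv` (structure_id, pdb, ligand_csv, ligand_id, seed,
#' n_pockets). Ligand group labels are drawn from a small pool so a
#' ligand-grouped split is exercised; per-structure seeds derive
#' deterministically from the master seed, and regeneration from the
#' manifest reproduces the files byte for byte.
#'
#' @param n_structures Number of complexes.
#' @param template A [synthetic_spec()] used for every structure (its seed
#'   is replaced per structure).
#' @param seed Master seed.
#' @param dir Output directory (created if missing).
#' @return The manifest data frame, invisibly.
#' @export
generate_dataset <- function(n_structures, template = synthetic_spec(),
                             seed = 1L, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  lig_pool <- sprintf("LG%d", 1:4)
  manifest <- do.call(rbind, lapply(seq_len(n_structures), function(i) {
    si <- (as.integer(seed) * 7919L + i * 104729L) %% 2147483562L
    sp <- template
    sp$seed <- si
    id <- sprintf("syn%03d", i)
    cx <- generate_complex(sp, structure_id = id)
    pdb <- file.path(dir, paste0(id, ".pdb"))
    writeLines(write_pdb(cx$structure), pdb)
    lig_csv <- file.path(dir, paste0(id, "_ligand.csv"))
    utils::write.csv(do.call(rbind, lapply(cx$ligands, function(l)
      data.frame(ligand = l$ligand_id, l$atom_coords))),
      lig_csv, row.names = FALSE)
    lig_group <- withr_seed(si, sample(lig_pool, 1L))
    data.frame(structure_id = id, pdb = basename(pdb),
               ligand_csv = basename(lig_csv), ligand_id = lig_group,
               seed = si, n_pockets = sp$n_pockets,
               stringsAsFactors = FALSE)
  }))
  utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}

#' Read the sites of a synthetic complex back from its ligand CSV
#' @param path `*_ligand.csv` written by [generate_dataset()].
#' @return List of `ligand_coordinates`, one per pocket.
#' @export
read_sites_csv <- function(path) {
  d <- utils::read.csv(path)
  lapply(split(d, d$ligand), function(g)
    ligand_coordinates(g[, c("x", "y", "z")], ligand_id = g$ligand[1L]))
}
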