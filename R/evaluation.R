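# Pocket-centric (DCA/DCC success rates) and residue-centric
# (macro-averaged precision/recall/F1/MCC) evaluation.

#' Evaluation configuration
#'
#' @param dca_threshold,dcc_threshold Hit thresholds in Angstrom
#'   (default 4).
#' @param matching_rule `"any_pocket"`: a site is a hit when any predicted
#'   pocket is close enough; `"nearest_exclusive"`: greedy one-to-one
#'   matching by ascending distance.
#' @return An `eval_config` list.
#' @export
eval_config <- function(dca_threshold = 4.0, dcc_threshold = 4.0,
                        matching_rule = c("any_pocket", "nearest_exclusive")) {
  stopifnot(dca_threshold > 0, dcc_threshold > 0)
  structure(list(dca_threshold = dca_threshold,
                 dcc_threshold = dcc_threshold,
                 matching_rule = match.arg(matching_rule)),
            class = "eval_config")
}

#' Distance from a pocket center to the closest ligand atom (DCA)
#' @param pocket_center Length-3 numeric (Angstrom).
#' @param ligand A `ligand_coordinates` object.
#' @return Minimum Euclidean distance in Angstrom.
#' @export
dca <- function(pocket_center, ligand) {
  l <- ligand$atom_coords
  sqrt(min((l[, 1L] - pocket_center[1L])^2 +
             (l[, 2L] - pocket_center[2L])^2 +
             (l[, 3L] - pocket_center[3L])^2))
}

#' Distance from a pocket center to the ligand centroid (DCC)
#' @inheritParams dca
#' @return Euclidean distance to the mean of the ligand atom coordinates.
#' @export
dcc <- function(pocket_center, ligand) {
  sqrt(sum((colMeans(ligand$atom_coords) - pocket_center)^2))
}

#' DCA/DCC success rates over a set of structures
#'
#' Every annotated site counts in the denominator; predictions may be empty.
#' Under `any_pocket`, a site is a hit when any predicted pocket of its
#' structure lies within the threshold; under `nearest_exclusive` pockets
#' are matched one-to-one to sites greedily by ascending distance.
#'
#' @param pockets_per_structure List (one entry per structure) of pocket
#'   lists as returned by [extract_pockets()].
#' @param sites_per_structure List (one entry per structure) of lists of
#'   `ligand_coordinates` (the annotated sites).
#' @param config An [eval_config()].
#' @return List with `dca_rate` and `dcc_rate` (percent), `n_sites`,
#'   `dca_hits`, `dcc_hits`.
#' @export
success_rates <- function(pockets_per_structure, sites_per_structure,
                          config = eval_config()) {
  stopifnot(length(pockets_per_structure) == length(sites_per_structure))
  total <- sum(lengths(sites_per_structure))
  if (total == 0L) stop("no annotated sites: success rate undefined")
  hits <- c(dca = 0L, dcc = 0L)
  for (s in seq_along(sites_per_structure)) {
    sites <- sites_per_structure[[s]]
    pockets <- pockets_per_structure[[s]]
    if (length(sites) == 0L) next
    for (metric in c("dca", "dcc")) {
      fn <- if (metric == "dca") dca else dcc
      thr <- if (metric == "dca") config$dca_threshold else config$dcc_threshold
      if (length(pockets) == 0L) next
      d <- matrix(Inf, length(pockets), length(sites))
      for (i in seq_along(pockets)) for (j in seq_along(sites)) {
        d[i, j] <- fn(pockets[[i]]$center, sites[[j]])
      }
      if (config$matching_rule == "any_pocket") {
        hits[metric] <- hits[metric] + sum(apply(d, 2L, min) <= thr)
      } else {
        used_p <- logical(length(pockets)); used_s <- logical(length(sites))
        ord <- order(d)
        for (k in ord) {
          i <- (k - 1L) %% nrow(d) + 1L
          j <- (k - 1L) %/% nrow(d) + 1L
          if (used_p[i] || used_s[j]) next
          if (d[i, j] <= thr) hits[metric] <- hits[metric] + 1L
          used_p[i] <- TRUE; used_s[j] <- TRUE
        }
      }
    }
  }
  list(dca_rate = 100 * hits[["dca"]] / total,
       dcc_rate = 100 * hits[["dcc"]] / total,
       n_sites = total, dca_hits = hits[["dca"]], dcc_hits = hits[["dcc"]])
}

#' Residue-level confusion counts for one structure
#'
#' A residue is an actual binding residue when any of its atoms lies within
#' `label_radius` of a ligand atom (of any site); it is a predicted binding
#' residue when any of its atoms belongs to any predicted pocket.
#'
#' @param pockets Pocket list for the structure.
#' @param structure A `protein_structure`.
#' @param ligands List of `ligand_coordinates` (the structure's sites).
#' @param label_radius Angstrom radius defining actual binding residues
#'   (default 5, matching the training labels).
#' @return A `residue_confusion` list: `tp`, `fp`, `tn`, `fn`,
#'   `n_residues`.
#' @export
residue_confusion <- function(pockets, structure, ligands, label_radius = 5.0) {
  atoms <- retained_atoms(structure)
  res_key <- paste(atoms$chain_id, atoms$res_seq, atoms$i_code)
  residues <- unique(res_key)

  actual_atom <- rep(FALSE, nrow(atoms))
  for (lig in ligands) {
    actual_atom <- actual_atom |
      label_binding_atoms(structure, lig, radius = label_radius) == 1L
  }
  predicted_atom <- rep(FALSE, nrow(atoms))
  for (p in pockets) predicted_atom[p$member_atoms] <- TRUE

  actual_res <- vapply(split(actual_atom, res_key)[residues], any, logical(1L))
  pred_res <- vapply(split(predicted_atom, res_key)[residues], any, logical(1L))

  structure(list(tp = sum(actual_res & pred_res),
                 fp = sum(!actual_res & pred_res),
                 tn = sum(!actual_res & !pred_res),
                 fn = sum(actual_res & !pred_res),
                 n_residues = length(residues)),
            class = "residue_confusion")
}

#' Macro-averaged residue metrics
#'
#' Per-structure precision `TP/(TP+FP)`, recall `TP/(TP+FN)`,
#' `F1 = 2PR/(P+R)` and
#' `MCC = (TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`, each
#' averaged over structures. Terms with an undefined (zero) denominator
#' contribute 0 to the average, which penalizes empty predictions rather
#' than dropping the structure.
#'
#' @param confusions List of [residue_confusion()] results.
#' @return Named list `precision`, `recall`, `f1`, `mcc` (fractions in
#'   \[0, 1\], MCC in \[-1, 1\]).
#' @export
macro_metrics <- function(confusions) {
  if (length(confusions) == 0L) stop("no confusion tables supplied")
  safe <- function(num, den) if (den == 0) 0 else num / den
  per <- vapply(confusions, function(cf) {
    p <- safe(cf$tp, cf$tp + cf$fp)
    r <- safe(cf$tp, cf$tp + cf$fn)
    f1 <- safe(2 * p * r, p + r)
    den <- sqrt(cf$tp + cf$fp) * sqrt(cf$tp + cf$fn) *
      sqrt(cf$tn + cf$fp) * sqrt(cf$tn + cf$fn)
    mcc <- safe(as.numeric(cf$tp) * cf$tn - as.numeric(cf$fp) * cf$fn, den)
    c(p, r, f1, mcc)
  }, numeric(4L))
  list(precision = mean(per[1L, ]), recall = mean(per[2L, ]),
       f1 = mean(per[3L, ]), mcc = mean(per[4L, ]))
}

#' Full evaluation report
#'
#' Combines pocket-centric success rates and residue-centric macro metrics
#' over a set of structures.
#'
#' @param pockets_per_structure,sites_per_structure As in
#'   [success_rates()].
#' @param structures List of `protein_structure`s (for residue metrics).
#' @param config An [eval_config()].
#' @param label_radius Radius defining actual binding residues.
#' @return An `evaluation_report`: aggregate rates/metrics (percent) and a
#'   per-structure data frame.
#' @export
evaluation_report <- function(pockets_per_structure, sites_per_structure,
                              structures, config = eval_config(),
                              label_radius = 5.0) {
  rates <- success_rates(pockets_per_structure, sites_per_structure, config)
  confusions <- lapply(seq_along(structures), function(i) {
    residue_confusion(pockets_per_structure[[i]], structures[[i]],
                      sites_per_structure[[i]], label_radius)
  })
  mm <- macro_metrics(confusions)
  per <- do.call(rbind, lapply(seq_along(structures), function(i) {
    cf <- confusions[[i]]
    data.frame(structure_id = structures[[i]]$structure_id,
               n_pockets = length(pockets_per_structure[[i]]),
               n_sites = length(sites_per_structure[[i]]),
               tp = cf$tp, fp = cf$fp, tn = cf$tn, fn = cf$fn)
  }))
  structure(list(success_rate_dca = rates$dca_rate,
                 success_rate_dcc = rates$dcc_rate,
                 precision = 100 * mm$precision, recall = 100 * mm$recall,
                 f1 = 100 * mm$f1, mcc = 100 * mm$mcc,
                 n_structures = length(structures),
                 n_sites = rates$n_sites,
                 per_structure = per),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("evaluation over ", x$n_structures, " structure(s), ", x$n_sites,
      " site(s)\n", sep = "")
  cat(sprintf("  DCA success rate: %5.1f %%\n", x$success_rate_dca))
  cat(sprintf("  DCC success rate: %5.1f %%\n", x$success_rate_dcc))
  cat(sprintf("  precision %5.1f %%  recall %5.1f %%  F1 %5.1f %%  MCC %5.1f %%\n",
              x$precision, x$recall, x$f1, x$mcc))
  invisible(x)
}

#' Write an evaluation report (CSV per structure + JSON summary)
#' @param report An `evaluation_report`.
#' @param csv_path,json_path Output paths (either may be `NULL`).
#' @return The report, invisibly.
#' @export
write_evaluation_report <- function(report, csv_path = NULL, json_path = NULL) {
  if (!is.null(csv_path)) {
    utils::write.csv(report$per_structure, csv_path, row.names = FALSE)
  }
  if (!is.null(json_path)) {
    jsonlite::write_json(
      list(success_rate_dca = report$success_rate_dca,
           success_rate_dcc = report$success_rate_dcc,
           precision = report$precision, recall = report$recall,
           f1 = report$f1, mcc = report$mcc,
           n_structures = report$n_structures, n_sites = report$n_sites),
      json_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(report)
}
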