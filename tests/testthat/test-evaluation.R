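test_that("DCA and DCC follow their definitions", {
  lig <- ligand_coordinates(rbind(c(3, 0, 0), c(5, 0, 0)), "L")
  expect_equal(dca(c(0, 0, 0), lig), 3.0)
  expect_equal(dca(c(5, 0, 0), lig), 0.0)
  lig2 <- ligand_coordinates(rbind(c(2, 0, 0), c(-2, 0, 0)), "L")
  expect_equal(dcc(c(0, 3, 0), lig2), 3.0)
  expect_equal(dcc(c(0, 0, 0), lig2), 0.0)
  # brute-force check over random ligands
  set.seed(2)
  pts <- matrix(rnorm(300), ncol = 3)
  lig3 <- ligand_coordinates(pts, "L")
  ctr <- c(0.3, -0.2, 0.5)
  expect_equal(dca(ctr, lig3),
               min(apply(pts, 1, function(a) sqrt(sum((a - ctr)^2)))),
               tolerance = 1e-12)
  expect_equal(dcc(ctr, lig3), sqrt(sum((colMeans(pts) - ctr)^2)),
               tolerance = 1e-12)
})

test_that("success rates count hits over all annotated sites", {
  mk_pocket <- function(center) {
    structure(list(pocket_id = 1L, member_atoms = 1L,
                   member_residues = NULL, center = center,
                   mean_probability = 1), class = "pocket")
  }
  sites <- list(list(ligand_coordinates(matrix(c(0, 0, 0), 1), "a"),
                     ligand_coordinates(matrix(c(50, 0, 0), 1), "b")))
  pockets <- list(list(mk_pocket(c(1, 0, 0))))
  r <- success_rates(pockets, sites)
  expect_equal(r$dca_rate, 50)
  expect_equal(r$dcc_rate, 50)
  # no predictions anywhere: 0 %
  r0 <- success_rates(list(list()), sites)
  expect_equal(r0$dca_rate, 0)
  expect_error(success_rates(list(list()), list(list())), "no annotated")
  # tightening the threshold never increases the rate
  set.seed(5)
  pockets2 <- list(lapply(1:3, function(i) mk_pocket(runif(3, 0, 20))))
  sites2 <- list(lapply(1:4, function(i)
    ligand_coordinates(matrix(runif(3, 0, 20), 1), paste0("s", i))))
  rates <- vapply(c(8, 4, 2, 1), function(thr) {
    success_rates(pockets2, sites2,
                  eval_config(dca_threshold = thr,
                              dcc_threshold = thr))$dca_rate
  }, numeric(1))
  expect_true(all(diff(rates) <= 0))
  # rigid translation leaves rates unchanged
  shift <- c(11, -7, 3)
  pockets3 <- list(lapply(pockets2[[1]], function(p) {
    p$center <- p$center + shift; p
  }))
  sites3 <- list(lapply(sites2[[1]], function(s)
    ligand_coordinates(sweep(s$atom_coords, 2, -shift), s$ligand_id)))
  expect_equal(success_rates(pockets3, sites3)$dca_rate,
               success_rates(pockets2, sites2)$dca_rate)
})

test_that("nearest-exclusive matching is one-to-one", {
  mk_pocket <- function(center) {
    structure(list(pocket_id = 1L, member_atoms = 1L, member_residues = NULL,
                   center = center, mean_probability = 1), class = "pocket")
  }
  # one pocket near two sites: any_pocket credits both, exclusive only one
  sites <- list(list(ligand_coordinates(matrix(c(0, 0, 0), 1), "a"),
                     ligand_coordinates(matrix(c(2, 0, 0), 1), "b")))
  pockets <- list(list(mk_pocket(c(1, 0, 0))))
  expect_equal(success_rates(pockets, sites,
                             eval_config(matching_rule = "any_pocket"))$dca_rate,
               100)
  expect_equal(success_rates(pockets, sites,
                             eval_config(matching_rule = "nearest_exclusive"))$dca_rate,
               50)
})

test_that("residue confusion tallies conserve the residue count", {
  cx <- generate_complex(synthetic_spec(n_atoms = 300, box_size = 30,
                                        seed = 17))
  st <- cx$structure
  tz <- tensorize_structure(st, cx$ligands[[1]])
  # perfect prediction: pockets from the true labels
  pockets <- extract_pockets(tz, as.numeric(tz$labels), st)
  cf <- residue_confusion(pockets, st, cx$ligands)
  expect_equal(cf$tp + cf$fp + cf$tn + cf$fn, cf$n_residues)
  expect_equal(cf$fn, 0L)
  expect_equal(cf$fp, 0L)
  # empty prediction: no TP/FP, FN = actual positives
  cf0 <- residue_confusion(list(), st, cx$ligands)
  expect_equal(cf0$tp + cf0$fp, 0L)
  expect_gt(cf0$fn, 0L)
  expect_equal(cf0$fn + cf0$tn, cf0$n_residues)
})

test_that("macro metrics reproduce the worked confusion example", {
  cf <- structure(list(tp = 2, fp = 1, tn = 5, fn = 2, n_residues = 10),
                  class = "residue_confusion")
  m <- macro_metrics(list(cf))
  expect_equal(m$precision, 2 / 3, tolerance = 1e-12)
  expect_equal(m$recall, 1 / 2, tolerance = 1e-12)
  expect_equal(m$f1, 4 / 7, tolerance = 1e-12)
  expect_equal(m$mcc, 8 / sqrt(504), tolerance = 1e-12)
  # all-perfect structures: every metric is 1
  perfect <- structure(list(tp = 4, fp = 0, tn = 6, fn = 0, n_residues = 10),
                       class = "residue_confusion")
  mp <- macro_metrics(list(perfect, perfect))
  expect_equal(unlist(mp), c(precision = 1, recall = 1, f1 = 1, mcc = 1))
  # zero denominators contribute 0
  empty <- structure(list(tp = 0, fp = 0, tn = 8, fn = 2, n_residues = 10),
                     class = "residue_confusion")
  me <- macro_metrics(list(empty))
  expect_equal(me$precision, 0)
  expect_equal(me$mcc, 0)
  expect_error(macro_metrics(list()), "no confusion")
})

test_that("MCC of label-independent predictions centers on zero", {
  set.seed(31)
  mccs <- replicate(200, {
    n <- 60
    actual <- rbinom(n, 1, 0.3)
    pred <- rbinom(n, 1, 0.4)
    cf <- structure(list(tp = sum(actual & pred), fp = sum(!actual & pred),
                         tn = sum(!actual & !pred), fn = sum(actual & !pred),
                         n_residues = n), class = "residue_confusion")
    macro_metrics(list(cf))$mcc
  })
  expect_lt(abs(mean(mccs)), 0.03)
})

test_that("evaluation reports aggregate per-structure rows", {
  cxs <- lapply(1:3, function(s)
    generate_complex(synthetic_spec(n_atoms = 250, box_size = 30, seed = s)))
  pockets <- lapply(cxs, function(cx) {
    tz <- tensorize_structure(cx$structure, cx$ligands[[1]])
    extract_pockets(tz, as.numeric(tz$labels), cx$structure)
  })
  sites <- lapply(cxs, function(cx) cx$ligands)
  structures <- lapply(cxs, function(cx) cx$structure)
  rep <- evaluation_report(pockets, sites, structures)
  expect_equal(rep$n_structures, 3L)
  expect_equal(nrow(rep$per_structure), 3L)
  expect_equal(rep$success_rate_dca, 100)
  expect_equal(rep$recall, 100)
  expect_true(rep$mcc >= -100 - 1e-9 && rep$mcc <= 100 + 1e-9)
  tmp_csv <- tempfile(fileext = ".csv")
  tmp_json <- tempfile(fileext = ".json")
  write_evaluation_report(rep, tmp_csv, tmp_json)
  expect_equal(nrow(read.csv(tmp_csv)), 3L)
  js <- jsonlite::read_json(tmp_json)
  expect_equal(js$success_rate_dca, 100)
})
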