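test_that("dice loss matches the closed form and is symmetric", {
  expect_lt(dice_loss(rep(1, 10), rep(1, 10)), 0.05)
  # probs all 0, labels all 1, s = 1, n = 4: 1 - 1/5
  expect_equal(dice_loss(rep(0, 4), rep(1, 4)), 0.8)
  p <- runif(20); l <- rbinom(20, 1, 0.3)
  expect_equal(dice_loss(p, l), dice_loss(l, p))
  expect_error(dice_loss(1:3 / 3, c(0, 1)), "length")
})

test_that("focal loss reduces to half the cross-entropy at gamma 0, alpha 0.5", {
  set.seed(4)
  p <- runif(50, 0.02, 0.98)
  l <- rbinom(50, 1, 0.2)
  bce <- -mean(l * log(p) + (1 - l) * log(1 - p))
  expect_equal(focal_loss(p, l, gamma = 0, alpha = 0.5), 0.5 * bce,
               tolerance = 1e-9)
  # single-atom hand value: 0.25 * 0.1^2 * (-ln 0.9)
  expect_equal(focal_loss(0.9, 1, gamma = 2, alpha = 0.25),
               0.25 * 0.01 * (-log(0.9)), tolerance = 1e-12)
  expect_lt(focal_loss(c(1 - 1e-9, 1e-9), c(1, 0), 2, 0.25), 1e-8)
  expect_error(focal_loss(0.5, 1, gamma = -1), "gamma")
  expect_error(focal_loss(0.5, 1, alpha = 1.2), "alpha")
})

test_that("losses decrease when a wrong prediction moves toward its label", {
  l <- c(1, 0, 1, 0, 0)
  p <- c(0.2, 0.8, 0.6, 0.3, 0.1)
  for (i in c(1, 2)) {
    p2 <- p
    p2[i] <- if (l[i] == 1) p[i] + 0.1 else p[i] - 0.1
    expect_lt(focal_loss(p2, l, 1, 0.15), focal_loss(p, l, 1, 0.15))
    expect_lt(dice_loss(p2, l), dice_loss(p, l))
  }
})

test_that("ligand-grouped split keeps groups exclusive for every seed", {
  ids <- sprintf("s%02d", 1:12)
  ligs <- list("HEM", "HEM", "ADP", "ATP", "NAD", "HEM", "ADP", "FAD",
               "SAM", "GTP", "GDP", "PLP")
  for (seed in 1:10) {
    sp <- grouped_split(ids, ligs, fraction = 0.8, seed = seed)
    expect_setequal(c(sp$train, sp$validation), ids)
    expect_length(intersect(sp$train, sp$validation), 0)
    lig_of <- function(side) unlist(ligs[match(side, ids)])
    expect_length(intersect(lig_of(sp$train), lig_of(sp$validation)), 0)
    # HEM structures always travel together
    hem <- ids[vapply(ligs, function(x) "HEM" %in% x, logical(1))]
    expect_true(all(hem %in% sp$train) || all(hem %in% sp$validation))
  }
  # all-distinct ligands, n = 10, fraction 0.8 -> an 8/2 split
  sp <- grouped_split(sprintf("t%d", 1:10), as.list(letters[1:10]),
                      fraction = 0.8, seed = 3)
  expect_length(sp$train, 8)
  expect_length(sp$validation, 2)
  # determinism in the seed
  expect_identical(grouped_split(ids, ligs, seed = 5),
                   grouped_split(ids, ligs, seed = 5))
  expect_error(grouped_split(c("a", "b"), list("X", "X")), "impossible")
})

test_that("PRC-AUC matches exhaustive threshold enumeration", {
  # perfect separation
  expect_equal(prc_auc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1.0)
  # 4-point hand example
  p <- c(0.9, 0.6, 0.4, 0.2); l <- c(1, 0, 1, 0)
  expect_equal(prc_auc(p, l), brute_prc_auc(p, l), tolerance = 1e-12)
  # random cases up to n = 64, with ties
  for (seed in 1:20) {
    set.seed(seed)
    n <- sample(4:64, 1)
    p <- round(runif(n), 2)
    l <- rbinom(n, 1, 0.3)
    if (sum(l) == 0) l[1] <- 1
    expect_equal(prc_auc(p, l), brute_prc_auc(p, l), tolerance = 1e-12)
  }
  # label-independent scores approach the positive prevalence
  set.seed(99)
  n <- 20000
  p <- runif(n); l <- rbinom(n, 1, 0.07)
  expect_lt(abs(prc_auc(p, l) - 0.07), 0.015)
  expect_error(prc_auc(c(0.1, 0.2), c(0, 0)), "positive")
})

test_that("training overfits a small synthetic set and stops early on plateaus", {
  tens <- small_training_set(3, n_atoms = 200, box = 28)
  net <- build_network(reduced_spec(), seed = 11)
  cfg <- training_config(batch_size = 3, learning_rate = 3e-3,
                         loss = "focal", gamma = 1, alpha = 0.25,
                         max_epochs = 60, patience = 60, seed = 11)
  fit <- train_network(net, tens, tens, cfg)
  h <- fit$history
  expect_true(all(diff(h$train_loss[1:10]) < 0))
  expect_gte(max(h$val_f1), 0.9)
  expect_error(train_network(net, list(), NULL, cfg), "empty")
})

test_that("training histories are bit-identical across reruns of one seed", {
  tens <- small_training_set(2, n_atoms = 150, box = 26)
  cfg <- training_config(batch_size = 2, learning_rate = 2e-3,
                         max_epochs = 5, patience = 5, seed = 21)
  f1 <- train_network(build_network(reduced_spec(), seed = 21), tens, tens, cfg)
  f2 <- train_network(build_network(reduced_spec(), seed = 21), tens, tens, cfg)
  expect_identical(f1$history, f2$history)
  expect_equal(f1$net$params, f2$net$params)
})

test_that("early stopping halts exactly patience epochs after the last improvement", {
  tens <- small_training_set(2, n_atoms = 150, box = 26)
  # frozen weights: only batch-norm statistics drift, the validation loss
  # plateaus quickly and the patience rule must then fire
  cfg <- training_config(batch_size = 2, learning_rate = 0,
                         max_epochs = 50, patience = 3, seed = 5)
  fit <- train_network(build_network(reduced_spec(), seed = 5), tens, tens, cfg)
  expect_true(fit$stopped_early)
  vl <- fit$history$val_loss
  run_best <- cummin(vl)
  improved <- c(TRUE, diff(run_best) < -1e-12)
  expect_equal(nrow(fit$history), max(which(improved)) + cfg$patience)
})

test_that("the search driver returns the dominant configuration", {
  space <- search_space(lr = c(0.1, 0.9))
  objective <- function(cfg) if (cfg$lr < 0.5) 1.0 else 0.2
  res <- tune(space, trials = 6, objective,
              sampler = random_sampler(space, seed = 2))
  expect_equal(res$best_config$lr, 0.1)
  expect_equal(res$best_value, 1.0)
  expect_lte(nrow(res$trials), 6)
  # one trial returns that trial's configuration
  one <- tune(space, 1, objective, sampler = random_sampler(space, seed = 3))
  expect_true(one$best_config$lr %in% c(0.1, 0.9))
  expect_error(tune(space, 0, objective), "at least one")
  # ranges sample within bounds (log scale)
  sp2 <- search_space(lr = search_range(1e-4, 1e-2, log = TRUE))
  smp <- random_sampler(sp2, seed = 1)
  draws <- vapply(1:20, function(i) smp$suggest(i)$lr, numeric(1))
  expect_true(all(draws >= 1e-4 & draws <= 1e-2))
})
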