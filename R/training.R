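# Losses, ligand-grouped data splitting, PRC-AUC, the AdamW training loop
# with early stopping, and a pluggable hyperparameter search driver.

#' Soft Dice loss
#'
#' `1 - (2 * sum(p*l) + s) / (sum(p) + sum(l) + s)` with smoothing `s`;
#' symmetric in its arguments and bounded in \[0, 1\].
#'
#' @param probs Predicted probabilities.
#' @param labels 0/1 labels of the same length.
#' @param smooth Smoothing constant `s` (default 1).
#' @return Scalar loss.
#' @export
dice_loss <- function(probs, labels, smooth = 1) {
  if (length(probs) != length(labels)) {
    stop("probs and labels differ in length")
  }
  1 - (2 * sum(probs * labels) + smooth) /
    (sum(probs) + sum(labels) + smooth)
}

# gradient of dice_loss w.r.t. probs
.dice_grad <- function(probs, labels, smooth = 1) {
  num <- 2 * sum(probs * labels) + smooth
  den <- sum(probs) + sum(labels) + smooth
  -(2 * labels * den - num) / den^2
}

#' Focal loss for class-imbalanced binary segmentation
#'
#' Mean over atoms of `-alpha_t * (1 - p_t)^gamma * log(p_t)` with
#' `p_t = p` for positives and `1 - p` for negatives, `alpha_t = alpha` for
#' positives and `1 - alpha` for negatives. At `gamma = 0`, `alpha = 0.5` it
#' equals one half of the binary cross-entropy.
#'
#' @param probs Predicted probabilities.
#' @param labels 0/1 labels.
#' @param gamma Focusing exponent (>= 0); default 1.
#' @param alpha Positive-class weight in (0, 1); default 0.15.
#' @return Scalar loss (non-negative).
#' @export
focal_loss <- function(probs, labels, gamma = 1, alpha = 0.15) {
  if (gamma < 0) stop("gamma must be non-negative")
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  if (length(probs) != length(labels)) {
    stop("probs and labels differ in length")
  }
  p <- pmin(pmax(probs, 1e-12), 1 - 1e-12)
  pt <- ifelse(labels == 1, p, 1 - p)
  at <- ifelse(labels == 1, alpha, 1 - alpha)
  mean(-at * (1 - pt)^gamma * log(pt))
}

# gradient of focal_loss w.r.t. probs
.focal_grad <- function(probs, labels, gamma = 1, alpha = 0.15) {
  p <- pmin(pmax(probs, 1e-7), 1 - 1e-7)
  pt <- ifelse(labels == 1, p, 1 - p)
  at <- ifelse(labels == 1, alpha, 1 - alpha)
  # dL/dpt, then chain through dpt/dp = +1 (label 1) or -1 (label 0)
  dpt <- -at * ((1 - pt)^gamma / pt -
                  gamma * (1 - pt)^pmax(gamma - 1, 0) * log(pt) *
                  (if (gamma > 0) 1 else 0))
  sign <- ifelse(labels == 1, 1, -1)
  dpt * sign / length(probs)
}

# loss dispatcher: value and gradient w.r.t. logits
.loss_eval <- function(logits, labels, loss_cfg, want_grad = FALSE) {
  probs <- 1 / (1 + exp(-logits))
  if (loss_cfg$name == "focal") {
    value <- focal_loss(probs, labels, loss_cfg$gamma, loss_cfg$alpha)
    if (!want_grad) return(list(value = value))
    d_p <- .focal_grad(probs, labels, loss_cfg$gamma, loss_cfg$alpha)
  } else if (loss_cfg$name == "dice") {
    value <- dice_loss(probs, labels)
    if (!want_grad) return(list(value = value))
    d_p <- .dice_grad(probs, labels)
  } else {
    stop("unknown loss '", loss_cfg$name, "'")
  }
  list(value = value, d_logits = d_p * probs * (1 - probs))
}

#' Training configuration
#'
#' @param batch_size Structures per batch.
#' @param learning_rate AdamW step size.
#' @param loss Either `"dice"` or `"focal"`; focal parameters via `gamma`
#'   and `alpha`.
#' @param gamma,alpha Focal-loss parameters (defaults 1 and 0.15).
#' @param max_epochs Epoch budget.
#' @param patience Early-stopping patience in epochs (on validation loss).
#' @param seed Master seed for initialization and batch order.
#' @param beta1,beta2,weight_decay AdamW hyperparameters (defaults 0.9,
#'   0.999, 0.01); weight decay applies to convolution weights only.
#' @return A `training_config` list.
#' @export
training_config <- function(batch_size = 4L, learning_rate = 1e-3,
                            loss = c("focal", "dice"), gamma = 1, alpha = 0.15,
                            max_epochs = 50L, patience = 10L, seed = 1L,
                            beta1 = 0.9, beta2 = 0.999, weight_decay = 0.01) {
  loss <- match.arg(loss)
  stopifnot(gamma >= 0, patience >= 1L, batch_size >= 1L, max_epochs >= 1L)
  if (loss == "focal") stopifnot(alpha > 0, alpha < 1)
  structure(list(batch_size = as.integer(batch_size),
                 learning_rate = learning_rate,
                 loss = list(name = loss, gamma = gamma, alpha = alpha),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience), seed = as.integer(seed),
                 beta1 = beta1, beta2 = beta2, weight_decay = weight_decay),
            class = "training_config")
}

#' Ligand-grouped train/validation split
#'
#' Partitions structures so that no ligand identifier occurs on both sides
#' (structures sharing any ligand id form one indivisible group, computed as
#' connected components of ligand co-occurrence). Groups are assigned to the
#' training side in seeded random order until the training fraction is
#' reached.
#'
#' @param structure_ids Character vector of structure identifiers.
#' @param ligand_ids List (or vector) of ligand identifier(s) per structure.
#' @param fraction Target training fraction (default 0.8).
#' @param seed RNG seed; the split is deterministic given the seed.
#' @return List with `train` and `validation` character vectors.
#' @export
grouped_split <- function(structure_ids, ligand_ids, fraction = 0.8, seed = 1L) {
  n <- length(structure_ids)
  stopifnot(n == length(ligand_ids), fraction > 0, fraction < 1)
  if (!is.list(ligand_ids)) ligand_ids <- as.list(ligand_ids)

  # union-find over structures via shared ligand ids
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  lig_first <- new.env(parent = emptyenv())
  for (i in seq_len(n)) {
    for (lg in ligand_ids[[i]]) {
      j <- get0(lg, envir = lig_first)
      if (is.null(j)) assign(lg, i, envir = lig_first)
      else {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[ri] <- rj
      }
    }
  }
  root <- vapply(seq_len(n), find, integer(1L))
  groups <- split(seq_len(n), root)
  if (length(groups) < 2L) {
    stop("all structures share one ligand group; an exclusive split is impossible")
  }
  ord <- withr_seed(seed, sample.int(length(groups)))
  target <- fraction * n
  train_idx <- integer(0)
  for (g in ord) {
    if (length(train_idx) >= target) break
    train_idx <- c(train_idx, groups[[g]])
  }
  if (length(train_idx) == n) {  # keep at least one group for validation
    train_idx <- setdiff(train_idx, groups[[ord[length(ord)]]])
  }
  list(train = structure_ids[sort(train_idx)],
       validation = structure_ids[sort(setdiff(seq_len(n), train_idx))])
}

# evaluate expr with a temporary RNG seed, restoring the global stream
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  set.seed(seed)
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, globalenv())
  })
  expr
}

#' Area under the precision-recall curve
#'
#' Step-wise integration over all score thresholds (average precision):
#' thresholds at every distinct score, `AUC = sum (R_k - R_{k-1}) * P_k`.
#'
#' @param probs Prediction scores.
#' @param labels 0/1 labels (at least one positive).
#' @return Scalar in \[0, 1\].
#' @export
prc_auc <- function(probs, labels) {
  stopifnot(length(probs) == length(labels))
  pos <- sum(labels == 1)
  if (pos == 0L) stop("prc_auc needs at least one positive label")
  ord <- order(probs, decreasing = TRUE)
  lab <- labels[ord]
  sc <- probs[ord]
  tp <- cumsum(lab == 1)
  k <- seq_along(lab)
  last_of_threshold <- c(sc[-1] != sc[-length(sc)], TRUE)
  tp_t <- tp[last_of_threshold]
  k_t <- k[last_of_threshold]
  precision <- tp_t / k_t
  recall <- tp_t / pos
  sum(diff(c(0, recall)) * precision)
}

# ---- parameter-tree utilities for AdamW -----------------------------------

.tree_map <- function(f, a, b = NULL, path = character(0)) {
  if (is.list(a)) {
    nms <- names(a)
    out <- vector("list", length(a))
    for (i in seq_along(a)) {
      nm <- if (is.null(nms)) as.character(i) else nms[i]
      bi <- if (is.null(b)) NULL
            else if (!is.null(nms) && !is.null(names(b))) b[[nm]]
            else b[[i]]
      out[[i]] <- .tree_map(f, a[[i]], bi, c(path, nm))
    }
    names(out) <- nms
    out
  } else {
    f(a, b, path)
  }
}

.adamw_init <- function(params) {
  list(m = .tree_map(function(p, ...) p * 0, params),
       v = .tree_map(function(p, ...) p * 0, params),
       t = 0L)
}

.adamw_step <- function(params, grads, opt, cfg) {
  opt$t <- opt$t + 1L
  b1 <- cfg$beta1; b2 <- cfg$beta2; lr <- cfg$learning_rate
  bc1 <- 1 - b1^opt$t; bc2 <- 1 - b2^opt$t
  opt$m <- .tree_map(function(m, g, path) b1 * m + (1 - b1) * g,
                     opt$m, grads)
  opt$v <- .tree_map(function(v, g, path) b2 * v + (1 - b2) * g^2,
                     opt$v, grads)
  new_params <- params
  upd <- function(p, pair, path) {
    m <- pair$m; v <- pair$v
    leaf <- path[length(path)]
    decay <- if (leaf %in% c("W", "W1", "W2", "Wp")) cfg$weight_decay else 0
    p - lr * ((m / bc1) / (sqrt(v / bc2) + 1e-8) + decay * p)
  }
  zip <- function(a, b) {
    if (is.list(a)) {
      out <- vector("list", length(a)); names(out) <- names(a)
      for (i in seq_along(a)) out[[i]] <- zip(a[[i]], b[[i]])
      out
    } else list(m = a, v = b)
  }
  new_params <- .tree_map(upd, params, zip(opt$m, opt$v))
  list(params = new_params, opt = opt)
}

.tree_add <- function(a, b) {
  if (is.list(a)) {
    out <- vector("list", length(a)); names(out) <- names(a)
    for (i in seq_along(a)) out[[i]] <- .tree_add(a[[i]], b[[i]])
    out
  } else a + b
}

# F1 of thresholded probabilities
.f1_at <- function(probs, labels, threshold = 0.5) {
  pred <- probs >= threshold
  tp <- sum(pred & labels == 1)
  fp <- sum(pred & labels == 0)
  fn <- sum(!pred & labels == 1)
  if (2 * tp + fp + fn == 0) return(0)
  2 * tp / (2 * tp + fp + fn)
}

#' Train the segmentation network
#'
#' AdamW optimization with per-epoch validation. Early stopping halts
#' training after `patience` epochs without improvement in the validation
#' loss; the returned checkpoint is the epoch with the best validation
#' PRC-AUC (the optimization objective). Deterministic given
#' `config$seed` on a single thread.
#'
#' @param net A `sparse_unet` (its weights are the starting point).
#' @param train_tensors List of labeled `sparse_protein_tensor`s.
#' @param val_tensors Validation tensors (defaults to `train_tensors`).
#' @param config A [training_config()].
#' @param verbose Print per-epoch progress.
#' @return List with `net` (best-validation-PRC-AUC weights), `history`
#'   (data frame: epoch, train_loss, val_loss, val_prc_auc, val_f1),
#'   `best_epoch` and `stopped_early`.
#' @export
train_network <- function(net, train_tensors, val_tensors = NULL,
                          config = training_config(), verbose = FALSE) {
  if (length(train_tensors) == 0L) stop("empty training set")
  if (is.null(val_tensors)) val_tensors <- train_tensors

  batches <- withr_seed(config$seed, {
    ord <- sample.int(length(train_tensors))
    split(ord, ceiling(seq_along(ord) / config$batch_size))
  })
  batch_data <- lapply(batches, function(idx) {
    bt <- batch_tensors(train_tensors[idx])
    list(tensor = bt, geometry = build_geometry(net$spec, bt$coords),
         labels = bt$labels)
  })
  val_data <- lapply(val_tensors, function(v)
    list(tensor = v, geometry = build_geometry(net$spec, v$coords),
         labels = v$labels))

  opt <- .adamw_init(net$params)
  history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                        val_loss = numeric(0), val_prc_auc = numeric(0),
                        val_f1 = numeric(0))
  best_val_loss <- Inf; stall <- 0L
  best_auc <- -Inf; best_params <- net$params; best_state <- net$state
  best_epoch <- 0L; stopped_early <- FALSE

  for (epoch in seq_len(config$max_epochs)) {
    epoch_loss <- 0
    for (bd in batch_data) {
      fwd <- net_forward(net, bd$tensor, train = TRUE, geometry = bd$geometry)
      le <- .loss_eval(fwd$logits, bd$labels, config$loss, want_grad = TRUE)
      grads <- net_backward(net, fwd, le$d_logits)
      step <- .adamw_step(net$params, grads, opt, config)
      net$params <- step$params
      net$state <- fwd$state
      opt <- step$opt
      epoch_loss <- epoch_loss + le$value
    }
    epoch_loss <- epoch_loss / length(batch_data)

    vl <- 0; vprobs <- numeric(0); vlabs <- integer(0)
    for (vd in val_data) {
      f <- net_forward(net, vd$tensor, train = FALSE, geometry = vd$geometry,
                       keep_cache = FALSE)
      vl <- vl + .loss_eval(f$logits, vd$labels, config$loss)$value
      vprobs <- c(vprobs, f$probs)
      vlabs <- c(vlabs, vd$labels)
    }
    vl <- vl / length(val_data)
    auc <- if (sum(vlabs) > 0) prc_auc(vprobs, vlabs) else NA_real_
    f1 <- .f1_at(vprobs, vlabs)
    history <- rbind(history, data.frame(
      epoch = epoch, train_loss = epoch_loss, val_loss = vl,
      val_prc_auc = auc, val_f1 = f1))
    if (verbose) {
      message(sprintf("epoch %3d  train %.5f  val %.5f  prc-auc %.4f  f1 %.4f",
                      epoch, epoch_loss, vl, auc, f1))
    }
    if (!is.na(auc) && auc > best_auc) {
      best_auc <- auc; best_params <- net$params
      best_state <- net$state; best_epoch <- epoch
    }
    if (vl < best_val_loss - 1e-12) {
      best_val_loss <- vl; stall <- 0L
    } else {
      stall <- stall + 1L
      if (stall >= config$patience) { stopped_early <- TRUE; break }
    }
  }
  net$params <- best_params
  net$state <- best_state
  list(net = net, history = history, best_epoch = best_epoch,
       stopped_early = stopped_early)
}

#' Write a training history as CSV
#' @param history Data frame from [train_network()].
#' @param path Destination file.
#' @return `path`, invisibly.
#' @export
write_history_csv <- function(history, path) {
  utils::write.csv(history, path, row.names = FALSE)
  invisible(path)
}

# ---- hyperparameter search -------------------------------------------------

#' Hyperparameter search space
#'
#' Each entry is either a vector of discrete candidates or a length-2
#' numeric range `c(min, max)` tagged with `range = TRUE` via
#' [search_range()].
#'
#' @param ... Named entries (e.g. `batch_size = c(2, 4)`,
#'   `learning_rate = search_range(1e-4, 1e-2, log = TRUE)`).
#' @return A `search_space` object.
#' @export
search_space <- function(...) {
  sp <- list(...)
  stopifnot(length(sp) > 0, !is.null(names(sp)), all(nzchar(names(sp))))
  structure(sp, class = "search_space")
}

#' @rdname search_space
#' @param min,max Range bounds.
#' @param log Sample on a log scale.
#' @export
search_range <- function(min, max, log = FALSE) {
  structure(list(min = min, max = max, log = log), class = "search_range")
}

#' Seeded random sampler (default suggestion strategy)
#'
#' Implements the `suggest`/`report` contract: `suggest(trial)` draws one
#' configuration from the space, `report(config, value)` records the
#' outcome (unused by the random strategy, available to model-based
#' samplers).
#'
#' @param space A [search_space()].
#' @param seed RNG seed.
#' @return A sampler (list of functions).
#' @export
random_sampler <- function(space, seed = 1L) {
  draw_one <- function(entry) {
    if (inherits(entry, "search_range")) {
      u <- stats::runif(1)
      if (entry$log) exp(log(entry$min) + u * (log(entry$max) - log(entry$min)))
      else entry$min + u * (entry$max - entry$min)
    } else {
      entry[[sample.int(length(entry), 1L)]]
    }
  }
  counter <- new.env(parent = emptyenv()); counter$i <- 0L
  list(
    suggest = function(trial) {
      withr_seed(seed + trial * 1009L, lapply(space, draw_one))
    },
    report = function(config, value) invisible(NULL)
  )
}

#' Hyperparameter search over scaled-down train/eval cycles
#'
#' Runs up to `trials` evaluations of `objective` on sampler-suggested
#' configurations and returns the configuration with the best (maximal)
#' objective, typically the validation PRC-AUC.
#'
#' @param space A [search_space()].
#' @param trials Positive trial budget.
#' @param objective Function `config -> numeric` to maximize.
#' @param sampler A suggestion strategy (default [random_sampler()]).
#' @return List with `best_config`, `best_value` and `trials` (data frame
#'   log with one row per trial).
#' @export
tune <- function(space, trials, objective, sampler = random_sampler(space)) {
  if (trials < 1L) stop("at least one trial is required")
  log <- vector("list", trials)
  best_value <- -Inf; best_config <- NULL
  for (tr in seq_len(trials)) {
    cfg <- sampler$suggest(tr)
    value <- objective(cfg)
    sampler$report(cfg, value)
    log[[tr]] <- data.frame(trial = tr, value = value,
                            config = I(list(cfg)))
    if (value > best_value) { best_value <- value; best_config <- cfg }
  }
  list(best_config = best_config, best_value = best_value,
       trials = do.call(rbind, log))
}
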