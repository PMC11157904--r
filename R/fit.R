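# High-level modelling interface: one fitting function returning a classed
# object with the usual print/summary/predict/plot methods, wrapping the
# modular prepare/train/predict pipeline.

#' Fit a binding-site segmentation model
#'
#' Takes a list of protein-ligand complexes, tensorizes them (nine-channel
#' featurization, 5 Angstrom binding-atom labeling, grid quantization) and
#' trains the sparse-convolutional encoder-decoder with AdamW and early
#' stopping.
#'
#' @param complexes List of complexes, each a list with `structure` (a
#'   `protein_structure`) and `ligands` (list of `ligand_coordinates`), as
#'   produced by [generate_complex()] or assembled from [read_pdb()] and
#'   [extract_ligand()].
#' @param spec A [network_spec()]; the default is the full published
#'   configuration — for desk-scale work pass a reduced spec.
#' @param config A [training_config()].
#' @param tensor_config A [tensorize_config()].
#' @param validation Optional complexes held out for validation; by default
#'   training structures are also used for validation monitoring.
#' @return A `sparsepocket_model` with elements `net`, `history`,
#'   `best_epoch`, `config`, `tensor_config`.
#' @export
sparsepocket_fit <- function(complexes, spec = network_spec(),
                             config = training_config(),
                             tensor_config = tensorize_config(),
                             validation = NULL) {
  tensorize_all <- function(cs) lapply(seq_along(cs), function(i) {
    cx <- cs[[i]]
    labels <- NULL
    st <- cx$structure
    feats <- featurize_atoms(st, backend = tensor_config$perception_backend)
    for (lig in cx$ligands) {
      li <- label_binding_atoms(st, lig, radius = tensor_config$label_radius)
      labels <- if (is.null(labels)) li else pmax(labels, li)
    }
    quantize(st, feats, labels, config = tensor_config, t = i - 1L)
  })
  train_tensors <- tensorize_all(complexes)
  val_tensors <- if (is.null(validation)) NULL else tensorize_all(validation)
  net <- build_network(spec, seed = config$seed)
  fit <- train_network(net, train_tensors, val_tensors, config)
  structure(list(net = fit$net, history = fit$history,
                 best_epoch = fit$best_epoch,
                 stopped_early = fit$stopped_early,
                 config = config, tensor_config = tensor_config),
            class = "sparsepocket_model")
}

#' @export
print.sparsepocket_model <- function(x, ...) {
  pc <- count_parameters(x$net)
  h <- x$history
  cat("sparsepocket model: ", format(pc$total, big.mark = ","),
      " parameters, trained ", nrow(h), " epoch(s)",
      if (x$stopped_early) " (early stop)" else "", "\n", sep = "")
  if (nrow(h) > 0L) {
    best <- h[x$best_epoch, ]
    cat(sprintf("  best epoch %d: val loss %.5f, val PRC-AUC %.4f, val F1 %.4f\n",
                x$best_epoch, best$val_loss, best$val_prc_auc, best$val_f1))
  }
  invisible(x)
}

#' @export
summary.sparsepocket_model <- function(object, ...) {
  print(object)
  cat("\ntraining history (last 5 epochs):\n")
  print(utils::tail(object$history, 5L), row.names = FALSE)
  invisible(object)
}

#' Predict binding pockets for a new structure
#'
#' @param object A `sparsepocket_model`.
#' @param newdata A `protein_structure` (or a complex list with a
#'   `structure` element).
#' @param postprocess A [postprocess_config()].
#' @param ... Unused.
#' @return List of `pocket` objects (possibly empty).
#' @export
predict.sparsepocket_model <- function(object, newdata,
                                       postprocess = postprocess_config(),
                                       ...) {
  st <- if (inherits(newdata, "protein_structure")) newdata else newdata$structure
  tensor <- tensorize_structure(st, ligand = NULL,
                                config = object$tensor_config)
  probs <- predict_probabilities(object$net, tensor)
  extract_pockets(tensor, probs, st, config = postprocess)
}

#' Plot training and validation curves
#' @param x A `sparsepocket_model`.
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.sparsepocket_model <- function(x, ...) {
  h <- x$history
  graphics::matplot(h$epoch, cbind(h$train_loss, h$val_loss), type = "l",
                    lty = 1, col = c("black", "firebrick"),
                    xlab = "epoch", ylab = "loss", ...)
  graphics::legend("topright", c("train", "validation"),
                   lty = 1, col = c("black", "firebrick"), bty = "n")
  invisible(x)
}
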