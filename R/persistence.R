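# Plain-text persistence of trained model bundles (ANN ensembles only:
# weights, thresholds and confidence tables serialize to JSON; SVM bundles
# keep kernel state inside the LIBSVM fit and are session objects).

#' Write an ANN model bundle as JSON
#' @param bundle a `ppi_model_bundle` trained with `algorithm = "ann"`.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_model_bundle <- function(bundle, file) {
  if (bundle$config$algorithm != "ann")
    stop("only ANN bundles serialize to JSON; keep SVM bundles in-session")
  enc <- lapply(bundle$ensembles, function(e) list(
    type = e$type, threshold = e$threshold, seed = e$seed,
    confidence = as.list(e$confidence),
    models = lapply(e$models, function(m) list(
      W1 = m$weights$W1, b1 = m$weights$b1,
      W2 = as.numeric(m$weights$W2), b2 = m$weights$b2,
      best_iteration = m$best_iteration, best_val_mcc = m$best_val_mcc,
      n_hidden = m$n_hidden, seed = m$seed))))
  jsonlite::write_json(list(ensembles = enc, constants = bundle$constants,
                            config = unclass(bundle$config),
                            patch_params = bundle$patch_params),
                       file, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(file)
}

#' Read a model bundle written by [write_model_bundle()]
#' @param file path.
#' @return a `ppi_model_bundle`.
#' @export
read_model_bundle <- function(file) {
  x <- jsonlite::read_json(file, simplifyVector = TRUE)
  cfg <- do.call(ppi_config, x$config[setdiff(names(x$config), character())])
  ensembles <- lapply(x$ensembles, function(e) {
    models <- lapply(seq_len(length(e$models$b2)), function(k) {
      structure(list(
        weights = list(W1 = matrix(unlist(e$models$W1[[k]]), 32, 15,
                                   byrow = FALSE),
                       b1 = as.numeric(e$models$b1[[k]]),
                       W2 = matrix(as.numeric(e$models$W2[[k]]), ncol = 1),
                       b2 = e$models$b2[[k]]),
        best_iteration = e$models$best_iteration[[k]],
        best_val_mcc = e$models$best_val_mcc[[k]],
        n_hidden = e$models$n_hidden[[k]], seed = e$models$seed[[k]]),
        class = "ann_model")
    })
    conf <- as.data.frame(e$confidence)
    class(conf) <- c("confidence_table", "data.frame")
    structure(list(type = e$type, algorithm = "ann", models = models,
                   threshold = e$threshold, confidence = conf,
                   seed = e$seed),
              class = "atom_type_ensemble")
  })
  constants <- list(M_min = as.numeric(x$constants$M_min),
                    M_max = as.numeric(x$constants$M_max))
  structure(list(ensembles = ensembles, constants = constants,
                 config = cfg, report = NULL,
                 patch_params = x$patch_params),
            class = "ppi_model_bundle")
}
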