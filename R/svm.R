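# RBF-kernel support vector machine member models (LIBSVM via e1071), with
# cost/gamma selected by grid search on the bag's internal cross-validated
# MCC, and Platt-style probability outputs.

#' Train one SVM on a training bag with cost/gamma grid search
#'
#' Each (cost, gamma) candidate is scored by pooled MCC over a stratified
#' internal cross-validation of the bag; the maximiser wins, with ties
#' broken to the smallest cost, then the smallest gamma (the grid is
#' scanned in that order and only strict improvements replace the
#' incumbent).  The returned model is refit on the whole bag with
#' probability calibration.
#'
#' @param X bag feature matrix.
#' @param y bag labels (logical or 0/1).
#' @param cost_grid candidate costs (default 2^seq(-5, 15, 2)).
#' @param gamma_grid candidate gammas (default 2^seq(-15, 3, 2)).
#' @param inner_folds internal model-selection folds (default 3).
#' @param seed RNG seed for the internal folds.
#' @return an `svm_model` wrapping the fitted e1071 model plus the chosen
#'   parameters and their internal-CV MCC.
#' @export
train_svm_bag <- function(X, y, cost_grid = 2^seq(-5, 15, 2),
                          gamma_grid = 2^seq(-15, 3, 2),
                          inner_folds = 3, seed = 1) {
  stopifnot(length(cost_grid) >= 1, length(gamma_grid) >= 1)
  X <- as.matrix(X)
  y <- as.logical(y)
  if (length(unique(y)) < 2L) stop("single-class bag; cannot train SVM")
  set.seed(seed)
  fold <- integer(length(y))
  for (cl in c(TRUE, FALSE)) {
    idx <- sample(which(y == cl))
    fold[idx] <- rep_len(seq_len(inner_folds), length(idx))
  }
  yf <- factor(y, levels = c(FALSE, TRUE))
  best <- list(mcc = -Inf, cost = NA, gamma = NA)
  for (cost in sort(cost_grid)) {
    for (gamma in sort(gamma_grid)) {
      cc <- c(tp = 0, tn = 0, fp = 0, fn = 0)
      ok <- TRUE
      for (f in seq_len(inner_folds)) {
        tr <- fold != f
        if (length(unique(y[tr])) < 2L) { ok <- FALSE; break }
        m <- e1071::svm(X[tr, , drop = FALSE], yf[tr], kernel = "radial",
                        cost = cost, gamma = gamma, scale = FALSE)
        pr <- predict(m, X[!tr, , drop = FALSE]) == "TRUE"
        cc <- cc + c(tp = sum(pr & y[!tr]), tn = sum(!pr & !y[!tr]),
                     fp = sum(pr & !y[!tr]), fn = sum(!pr & y[!tr]))
      }
      if (!ok) next
      m <- mcc_from_counts(cc["tp"], cc["tn"], cc["fp"], cc["fn"])
      if (m > best$mcc) best <- list(mcc = m, cost = cost, gamma = gamma)
    }
  }
  fit <- e1071::svm(X, yf, kernel = "radial", cost = best$cost,
                    gamma = best$gamma, probability = TRUE, scale = FALSE)
  structure(list(fit = fit, cost = best$cost, gamma = best$gamma,
                 cv_mcc = best$mcc), class = "svm_model")
}

#' Predict positive-class probabilities with a trained SVM
#' @param model an `svm_model`.
#' @param X feature matrix.
#' @return probabilities in \[0, 1\].
#' @export
predict_svm <- function(model, X) {
  pr <- predict(model$fit, as.matrix(X), probability = TRUE)
  as.numeric(attr(pr, "probabilities")[, "TRUE"])
}
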