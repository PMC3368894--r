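# Bootstrap aggregation against class imbalance: every bag keeps all
# positives and draws negatives (without replacement) at 1.5x the positive
# count; member predictions are averaged with equal weight.

#' Compose training bags
#'
#' Each of `n_bags` bags contains every positive example plus
#' min(ceiling(ratio * n_pos), n_neg) negatives drawn without replacement;
#' a warning is emitted when the negatives run short.  Deterministic under
#' `seed` (each bag uses a derived sub-seed).
#'
#' @param positives indices (or ids) of positive examples.
#' @param negatives indices of negative examples.
#' @param n_bags number of bags (default 10).
#' @param ratio negatives per positive (default 1.5).
#' @param seed base RNG seed.
#' @return list of bags, each `list(positives, negatives)`.
#' @export
make_bags <- function(positives, negatives, n_bags = 10, ratio = 1.5,
                      seed = 1) {
  if (length(positives) < 1L)
    stop("no positive examples; no model trainable for this atom type")
  want <- ceiling(ratio * length(positives))
  if (length(negatives) < want)
    warning(sprintf("only %d negatives available for %d requested per bag",
                    length(negatives), want))
  take <- min(want, length(negatives))
  lapply(seq_len(n_bags), function(b) {
    set.seed(seed + b)
    list(positives = positives,
         negatives = sort(sample(negatives, take, replace = FALSE)))
  })
}

#' Train the bagged ensemble for one protein atom type
#'
#' Trains `n_bags` member models (all ANN or all SVM) on bags drawn from
#' the training examples; ANN members use the validation set for
#' best-iteration snapshots.  The decision threshold and confidence table
#' are attached later from validation-set activities (see
#' [run_training_pipeline()]).
#'
#' @param X,y training examples of this atom type.
#' @param X_val,y_val validation examples (disjoint from training).
#' @param type atom type ID (1-30).
#' @param algorithm "ann" or "svm".
#' @param n_bags,ratio bagging parameters.
#' @param seed base seed; member b uses seed * 1000 + b.
#' @param ann_iterations,ann_check_every ANN training schedule.
#' @param cost_grid,gamma_grid SVM search grids.
#' @return an `atom_type_ensemble`.
#' @export
train_atom_type_ensemble <- function(X, y, X_val, y_val, type,
                                     algorithm = c("ann", "svm"),
                                     n_bags = 10, ratio = 1.5, seed = 1,
                                     ann_iterations = 1000,
                                     ann_check_every = 10,
                                     cost_grid = 2^seq(-5, 15, 2),
                                     gamma_grid = 2^seq(-15, 3, 2)) {
  algorithm <- match.arg(algorithm)
  y <- as.logical(y)
  bags <- make_bags(which(y), which(!y), n_bags, ratio, seed)
  models <- lapply(seq_along(bags), function(b) {
    idx <- c(bags[[b]]$positives, bags[[b]]$negatives)
    if (algorithm == "ann") {
      train_ann_bag(X[idx, , drop = FALSE], y[idx], X_val, y_val,
                    iterations = ann_iterations,
                    check_every = ann_check_every,
                    seed = seed * 1000 + b)
    } else {
      train_svm_bag(X[idx, , drop = FALSE], y[idx], cost_grid, gamma_grid,
                    seed = seed * 1000 + b)
    }
  })
  structure(list(type = type, algorithm = algorithm, models = models,
                 threshold = 0.5, confidence = NULL, seed = seed),
            class = "atom_type_ensemble")
}

#' Ensemble activity: equal-weight average of member outputs
#'
#' @param ensemble an `atom_type_ensemble`.
#' @param X feature matrix (32 complete columns per atom).
#' @return activities in \[0, 1\], one per row of X.
#' @export
predict_activity <- function(ensemble, X) {
  X <- as.matrix(X)
  if (anyNA(X)) {
    bad <- which(apply(X, 1, anyNA))
    stop("missing feature component(s) for atom row(s): ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  outs <- vapply(ensemble$models, function(m) {
    if (inherits(m, "ann_model")) predict_ann(m, X) else predict_svm(m, X)
  }, numeric(nrow(X)))
  rowMeans(matrix(outs, nrow = nrow(X)))
}
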