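# Confusion-matrix benchmarking, threshold optimization, cross-validation
# planning, and the rank-sum attribute analysis.

#' Confusion counts
#' @param tp,tn,fp,fn non-negative integer counts.
#' @return a named list of class `ppi_confusion`.
#' @export
confusion_counts <- function(tp, tn, fp, fn) {
  stopifnot(tp >= 0, tn >= 0, fp >= 0, fn >= 0)
  structure(list(tp = tp, tn = tn, fp = fp, fn = fn),
            class = "ppi_confusion")
}

# raw MCC with the zero-denominator-is-zero convention; counts go through
# double precision so products cannot overflow integer range
mcc_from_counts <- function(tp, tn, fp, fn) {
  tp <- as.numeric(tp); tn <- as.numeric(tn)
  fp <- as.numeric(fp); fn <- as.numeric(fn)
  den <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  if (den == 0) return(0)
  (tp * tn - fp * fn) / sqrt(den)
}

#' Benchmark metrics from confusion counts
#'
#' Accuracy, precision, sensitivity (recall), specificity, F-score and the
#' Matthews correlation coefficient.  Any zero denominator yields 0 for the
#' affected ratio (and MCC = 0), the standard convention for degenerate
#' predictions.
#'
#' @param counts a `ppi_confusion` (or list with tp/tn/fp/fn).
#' @return named list: accuracy, precision, sensitivity, specificity,
#'   f_score, mcc.
#' @export
compute_metrics <- function(counts) {
  tp <- counts$tp; tn <- counts$tn; fp <- counts$fp; fn <- counts$fn
  tot <- tp + tn + fp + fn
  if (tot == 0) stop("all confusion counts are zero")
  safe <- function(num, den) if (den > 0) num / den else 0
  pre <- safe(tp, tp + fp)
  sen <- safe(tp, tp + fn)
  list(accuracy = (tp + tn) / tot,
       precision = pre,
       sensitivity = sen,
       specificity = safe(tn, tn + fp),
       f_score = safe(2 * pre * sen, pre + sen),
       mcc = mcc_from_counts(tp, tn, fp, fn))
}

# confusion from activities under threshold rule: positive <=> a >= thr
confusion_at_threshold <- function(activities, labels, threshold) {
  pred <- activities >= threshold
  confusion_counts(tp = sum(pred & labels), tn = sum(!pred & !labels),
                   fp = sum(pred & !labels), fn = sum(!pred & labels))
}

#' Optimal decision threshold on a validation set
#'
#' Scans the sorted unique activity values as candidate thresholds
#' (positive prediction = activity >= threshold) and returns the one
#' maximizing validation MCC; ties break to the lowest threshold.
#'
#' @param activities numeric vector in \[0, 1\].
#' @param labels logical (TRUE = PPI atom).
#' @return list(threshold, mcc).
#' @export
optimize_threshold <- function(activities, labels) {
  labels <- as.logical(labels)
  if (length(unique(labels)) < 2L)
    stop("validation set contains a single class; fall back to 0.5")
  cand <- sort(unique(activities))
  mccs <- vapply(cand, function(thr) {
    cc <- confusion_at_threshold(activities, labels, thr)
    mcc_from_counts(cc$tp, cc$tn, cc$fp, cc$fn)
  }, numeric(1))
  best <- which.max(mccs)   # which.max returns the first (lowest) maximiser
  list(threshold = cand[best], mcc = mccs[best])
}

#' Stratified five-fold cross-validation plan
#'
#' Random stratified partition into k folds of near-equal size and class
#' balance, with the rotation of roles: in rotation r, fold r is the test
#' set, the next fold the validation set, the remaining k-2 folds the
#' training set; each fold is tested exactly once.
#'
#' @param labels logical class labels of the examples.
#' @param k number of folds (default 5).
#' @param seed RNG seed.
#' @return list(fold = integer assignment per example, rotations = list of
#'   k lists with `test`, `validation`, `train` fold IDs).
#' @export
make_cv_folds <- function(labels, k = 5, seed = 1) {
  labels <- as.logical(labels)
  for (cl in c(TRUE, FALSE)) {
    if (sum(labels == cl) < k)
      stop("class ", cl, " has fewer than k = ", k, " members")
  }
  set.seed(seed)
  fold <- integer(length(labels))
  offset <- 0L
  for (cl in c(TRUE, FALSE)) {
    idx <- sample(which(labels == cl))
    # continue the round-robin across classes so fold totals stay within 1
    fold[idx] <- (seq_along(idx) - 1L + offset) %% k + 1L
    offset <- (offset + length(idx)) %% k
  }
  rotations <- lapply(seq_len(k), function(r)
    list(test = r, validation = r %% k + 1L,
         train = setdiff(seq_len(k), c(r, r %% k + 1L))))
  list(fold = fold, rotations = rotations)
}

#' Rank-sum discrimination matrix of the attributes
#'
#' For every (protein atom type, attribute) cell, a two-sided
#' Mann-Whitney/Wilcoxon rank-sum test compares the attribute values of
#' PPI-site atoms against non-PPI surface atoms of that type.  Small
#' samples without ties use the exact null distribution; otherwise the
#' normal approximation with tie correction and continuity correction is
#' used.  The sign records whether the PPI group mean is larger (+1),
#' smaller (-1) or equal (0).
#'
#' @param features scaled or raw attribute matrix (atoms x attributes).
#' @param labels logical PPI labels per atom.
#' @param types atom type per atom (1-30).
#' @return list of 30 x n_attr matrices `p` and `sign` (NA where a group
#'   is empty).
#' @export
utest_matrix <- function(features, labels, types) {
  labels <- as.logical(labels)
  na <- ncol(features)
  p <- matrix(NA_real_, 30, na, dimnames = list(1:30, colnames(features)))
  s <- matrix(NA_real_, 30, na, dimnames = dimnames(p))
  for (t in intersect(unique(types), 1:30)) {
    rows <- which(types == t)
    g1 <- labels[rows]
    if (!any(g1) || all(g1)) next
    for (j in seq_len(na)) {
      x <- features[rows[g1], j]
      y <- features[rows[!g1], j]
      exact <- max(length(x), length(y)) < 10 &&
        !anyDuplicated(c(x, y))
      wt <- suppressWarnings(
        stats::wilcox.test(x, y, exact = exact, correct = TRUE))
      p[t, j] <- wt$p.value
      s[t, j] <- sign(mean(x) - mean(y))
    }
  }
  list(p = p, sign = s)
}
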