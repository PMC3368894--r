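# Calibration of raw ensemble activities into prediction confidence levels:
# validation activities are sorted into ten bins of width 0.1, and each
# bin's confidence is the fraction of true positives among the predictions
# falling in it.

activity_bin <- function(activity) {
  if (any(activity < 0 | activity > 1))
    stop("activity outside [0, 1]")
  pmin(floor(activity * 10) + 1L, 10L)   # activity 1.0 maps to the last bin
}

#' Build the confidence lookup table for one atom type
#'
#' Empty bins receive a confidence interpolated linearly (by bin centre)
#' between the nearest non-empty bins, held constant beyond the ends.
#' The conservation identity sum(confidence * count) = number of positive
#' labels holds exactly over the non-empty bins.
#'
#' @param activities validation activities in \[0, 1\].
#' @param labels logical PPI labels of the same predictions.
#' @return a `confidence_table`: data.frame with bin edges, counts,
#'   positives and confidence.
#' @export
build_confidence_table <- function(activities, labels) {
  if (!length(activities)) stop("no validation predictions to calibrate")
  labels <- as.logical(labels)
  b <- activity_bin(activities)
  count <- tabulate(b, 10)
  pos <- vapply(1:10, function(k) sum(labels[b == k]), numeric(1))
  conf <- ifelse(count > 0, pos / count, NA_real_)
  if (anyNA(conf) && sum(!is.na(conf)) >= 1) {
    centers <- seq(0.05, 0.95, 0.1)
    known <- which(!is.na(conf))
    if (length(known) == 1L) {
      conf[is.na(conf)] <- conf[known]
    } else {
      # interior gaps: linear interpolation; edge gaps: linear
      # extrapolation from the two nearest populated bins, clipped
      conf <- stats::approx(centers[known], conf[known], xout = centers,
                            rule = 1)$y
      k1 <- known[1]; k2 <- known[2]
      kn <- known[length(known)]; km <- known[length(known) - 1]
      sl <- (conf[k2] - conf[k1]) / (centers[k2] - centers[k1])
      sr <- (conf[kn] - conf[km]) / (centers[kn] - centers[km])
      lo <- seq_len(k1 - 1)
      hi <- if (kn < 10) (kn + 1):10 else integer(0)
      conf[lo] <- conf[k1] + sl * (centers[lo] - centers[k1])
      conf[hi] <- conf[kn] + sr * (centers[hi] - centers[kn])
      conf <- pmin(1, pmax(0, conf))
    }
  }
  structure(data.frame(lower = seq(0, 0.9, 0.1), upper = seq(0.1, 1, 0.1),
                       count = count, positives = pos, confidence = conf),
            class = c("confidence_table", "data.frame"))
}

#' Convert activities to confidence levels
#'
#' @param activity numeric in \[0, 1\]; 1.0 maps to the last bin.
#' @param table a `confidence_table`.
#' @return confidence levels in \[0, 1\].
#' @export
to_confidence <- function(activity, table) {
  table$confidence[activity_bin(activity)]
}
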