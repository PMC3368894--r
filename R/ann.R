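# Feed-forward 32-15-1 neural network trained with resilient
# back-propagation (the iRprop- variant), minimizing the sum of squared
# error, full batch.  A snapshot of the weights at the iteration with the
# best validation MCC (checked every 10 iterations) is returned.

#' Numerically stable logistic sigmoid
#'
#' sf(x) = 1 / (1 + exp(-x)), stable for |x| well beyond 500.
#'
#' @param x numeric.
#' @return values in (0, 1).
#' @export
sigmoid <- function(x) {
  out <- x
  pos <- !is.na(x) & x >= 0
  out[pos] <- 1 / (1 + exp(-x[pos]))
  ex <- exp(x[!pos])
  out[!pos] <- ex / (1 + ex)
  out
}

ann_init <- function(n_in, n_hidden, seed) {
  set.seed(seed)
  list(W1 = matrix(stats::runif(n_in * n_hidden, -0.5, 0.5), n_in, n_hidden),
       b1 = stats::runif(n_hidden, -0.5, 0.5),
       W2 = matrix(stats::runif(n_hidden, -0.5, 0.5), n_hidden, 1),
       b2 = stats::runif(1, -0.5, 0.5))
}

ann_forward <- function(w, X) {
  H <- sigmoid(sweep(X %*% w$W1, 2, w$b1, "+"))
  y <- sigmoid(H %*% w$W2 + w$b2)
  list(H = H, y = as.numeric(y))
}

ann_gradient <- function(w, X, t) {
  f <- ann_forward(w, X)
  dy <- 2 * (f$y - t) * f$y * (1 - f$y)        # d SSE / d preactivation
  dH <- (dy %*% t(w$W2)) * f$H * (1 - f$H)
  list(W1 = crossprod(X, dH), b1 = colSums(dH),
       W2 = crossprod(f$H, matrix(dy)), b2 = sum(dy))
}

# one iRprop- update of a parameter block; state carries step sizes and the
# previous gradient sign
rprop_step <- function(par, g, st, eta_plus = 1.2, eta_minus = 0.5,
                       delta_max = 50, delta_min = 1e-9) {
  same <- st$g_prev * g
  st$delta <- ifelse(same > 0, pmin(st$delta * eta_plus, delta_max),
                     ifelse(same < 0, pmax(st$delta * eta_minus, delta_min),
                            st$delta))
  g[same < 0] <- 0                            # iRprop-: forget the sign flip
  par <- par - sign(g) * st$delta
  st$g_prev <- g
  list(par = par, state = st)
}

#' Train one ANN on a training bag
#'
#' Architecture 32-15-1 with sigmoid activations throughout; full-batch
#' iRprop- (eta+ = 1.2, eta- = 0.5, initial step 0.1, max step 50) on the
#' sum of squared error for `iterations` rounds.  Every `check_every`
#' iterations the model is scored on the validation set by MCC at the 0.5
#' activity threshold, and the best-scoring snapshot is returned.  If the
#' validation set has a single class, MCC is undefined and the final
#' iteration is returned with a warning.
#'
#' @param X training feature matrix (rows scaled to \[0, 1\]).
#' @param y training labels (logical or 0/1).
#' @param X_val,y_val validation set (disjoint from the bag).
#' @param iterations training iterations (default 1000).
#' @param check_every validation cadence (default 10).
#' @param n_hidden hidden-layer width (default 15).
#' @param seed weight-initialization seed.
#' @return an `ann_model`: weights, `best_iteration`, `best_val_mcc`.
#' @export
train_ann_bag <- function(X, y, X_val, y_val, iterations = 1000,
                          check_every = 10, n_hidden = 15, seed = 1) {
  X <- as.matrix(X); y <- as.numeric(y)
  X_val <- as.matrix(X_val); y_val <- as.logical(y_val)
  w <- ann_init(ncol(X), n_hidden, seed)
  st <- lapply(w, function(p) list(delta = p * 0 + 0.1, g_prev = p * 0))
  val_ok <- length(unique(y_val)) == 2L
  if (!val_ok)
    warning("single-class validation set: returning the final iteration")
  best <- list(w = w, mcc = -Inf, iter = 0L)
  for (it in seq_len(iterations)) {
    g <- ann_gradient(w, X, y)
    for (nm in names(w)) {
      up <- rprop_step(w[[nm]], g[[nm]], st[[nm]])
      w[[nm]] <- up$par
      st[[nm]] <- up$state
    }
    if (val_ok && it %% check_every == 0L) {
      yv <- ann_forward(w, X_val)$y
      cc <- confusion_at_threshold(yv, y_val, 0.5)
      m <- mcc_from_counts(cc$tp, cc$tn, cc$fp, cc$fn)
      if (m > best$mcc) best <- list(w = w, mcc = m, iter = it)
    }
  }
  if (!val_ok || best$iter == 0L)
    best <- list(w = w, mcc = NA_real_, iter = iterations)
  structure(list(weights = best$w, best_iteration = best$iter,
                 best_val_mcc = best$mcc, n_hidden = n_hidden, seed = seed),
            class = "ann_model")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Predict activities with a trained ANN
#' @param model an `ann_model`.
#' @param X feature matrix.
#' @return numeric activities in (0, 1).
#' @export
predict_ann <- function(model, X) {
  ann_forward(model$weights, as.matrix(X))$y
}
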