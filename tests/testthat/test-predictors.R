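# helper: an ann_model whose output is a given constant for any input
constant_ann <- function(p) {
  w <- list(W1 = matrix(0, 32, 15), b1 = rep(0, 15),
            W2 = matrix(0, 15, 1), b2 = log(p / (1 - p)))
  structure(list(weights = w, best_iteration = 0L, best_val_mcc = NA,
                 n_hidden = 15, seed = 0), class = "ann_model")
}

separable_blobs <- function(n = 120, seed = 1) {
  set.seed(seed)
  y <- rep(c(TRUE, FALSE), each = n / 2)
  X <- matrix(stats::runif(n * 32, 0, 0.35), n, 32)
  X[y, 1:8] <- X[y, 1:8] + 0.6
  list(X = X, y = y)
}

test_that("sigmoid is exact, symmetric and numerically stable", {
  expect_equal(sigmoid(0), 0.5)
  for (x in c(-10, -1, 3)) expect_equal(sigmoid(x) + sigmoid(-x), 1)
  expect_equal(sigmoid(1000), 1)
  expect_equal(sigmoid(-1000), 0)
  expect_false(any(is.nan(sigmoid(c(-800, 800)))))
})

test_that("bags keep all positives and draw 1.5x negatives without replacement", {
  bags <- make_bags(1:100, 101:1100, n_bags = 10, ratio = 1.5, seed = 3)
  expect_length(bags, 10)
  for (b in bags) {
    expect_identical(b$positives, 1:100)
    expect_length(b$negatives, 150)
    expect_false(anyDuplicated(b$negatives) > 0)
  }
  # not all bags draw the same negatives
  expect_gt(length(unique(lapply(bags, `[[`, "negatives"))), 1)

  expect_warning(short <- make_bags(1:100, 201:320, n_bags = 3, seed = 1),
                 "negatives")
  expect_true(all(lengths(lapply(short, `[[`, "negatives")) == 120))

  expect_identical(make_bags(1:10, 11:60, seed = 9),
                   make_bags(1:10, 11:60, seed = 9))
  expect_error(make_bags(integer(0), 1:10), "no positive")
})

test_that("RPROP training separates linearly separable blobs", {
  d <- separable_blobs(160, seed = 2)
  tr <- c(1:60, 81:140)   # both classes present on each side of the split
  m <- train_ann_bag(d$X[tr, ], d$y[tr], d$X[-tr, ], d$y[-tr],
                     iterations = 1000, seed = 4)
  expect_equal(m$best_val_mcc, 1)
  expect_lte(m$best_iteration, 1000)

  # bitwise-identical retraining under the same seed
  m2 <- train_ann_bag(d$X[tr, ], d$y[tr], d$X[-tr, ], d$y[-tr],
                      iterations = 200, seed = 4)
  m3 <- train_ann_bag(d$X[tr, ], d$y[tr], d$X[-tr, ], d$y[-tr],
                      iterations = 200, seed = 4)
  expect_identical(m2$weights, m3$weights)

  # constant features do not crash and outputs stay in (0, 1)
  Xc <- matrix(0.5, 60, 32)
  yc <- rep(c(TRUE, FALSE), 30)
  expect_warning(
    mc <- train_ann_bag(Xc, yc, Xc[1:10, ], rep(TRUE, 10),
                        iterations = 50, seed = 1),
    "single-class")
  pc <- predict_ann(mc, Xc)
  expect_true(all(pc > 0 & pc < 1))
})

test_that("SVM grid search separates blobs and breaks ties downward", {
  d <- separable_blobs(80, seed = 5)
  m <- train_svm_bag(d$X, d$y, cost_grid = c(1, 8), gamma_grid = c(0.1, 1),
                     seed = 2)
  expect_equal(m$cv_mcc, 1)
  # all grid points separate this toy perfectly, so the smallest wins
  expect_equal(m$cost, 1)
  expect_equal(m$gamma, 0.1)
  pr <- predict_svm(m, d$X)
  expect_true(all(pr >= 0 & pr <= 1))
})

test_that("ensemble activity is the equal-weight mean of member outputs", {
  ens <- structure(list(type = 8, algorithm = "ann",
                        models = lapply(c(0.2, 0.4, 0.6), constant_ann),
                        threshold = 0.5, confidence = NULL, seed = 1),
                   class = "atom_type_ensemble")
  X <- matrix(stats::runif(5 * 32), 5)
  expect_close(predict_activity(ens, X), rep(0.4, 5), 1e-12)

  one <- ens
  one$models <- ens$models[2]
  expect_close(predict_activity(one, X), rep(0.4, 5), 1e-12)

  # permutation invariance of the members and convexity of the mean
  d <- separable_blobs(60, seed = 7)
  real <- train_atom_type_ensemble(d$X, d$y, d$X, d$y, type = 8,
                                   n_bags = 3, seed = 2,
                                   ann_iterations = 100)
  a1 <- predict_activity(real, d$X)
  real2 <- real
  real2$models <- rev(real$models)
  expect_equal(predict_activity(real2, d$X), a1)
  expect_true(all(a1 >= 0 & a1 <= 1))

  expect_error(predict_activity(real, matrix(c(1, NA), 1, 32)), "missing")
})

test_that("a planted feature shift is recovered in cross-validation", {
  # positives carry a +0.3 shift on the hydrophobic-carbon attribute block
  set.seed(13)
  n <- 400
  y <- seq_len(n) <= 120
  X <- matrix(stats::runif(n * 32), n, 32)
  X[y, 6:9] <- pmin(1, X[y, 6:9] + 0.3)
  plan <- make_cv_folds(y, k = 5, seed = 3)
  cc <- c(tp = 0, tn = 0, fp = 0, fn = 0)
  for (rot in plan$rotations) {
    tr <- plan$fold %in% rot$train
    va <- plan$fold == rot$validation
    te <- plan$fold == rot$test
    ens <- train_atom_type_ensemble(X[tr, ], y[tr], X[va, ], y[va],
                                    type = 8, n_bags = 5, seed = 5,
                                    ann_iterations = 400)
    thr <- optimize_threshold(predict_activity(ens, X[va, ]), y[va])$threshold
    p <- predict_activity(ens, X[te, ]) >= thr
    cc <- cc + c(tp = sum(p & y[te]), tn = sum(!p & !y[te]),
                 fp = sum(p & !y[te]), fn = sum(!p & y[te]))
  }
  m <- compute_metrics(confusion_counts(cc["tp"], cc["tn"],
                                        cc["fp"], cc["fn"]))
  expect_gt(m$mcc, 0.5)
})
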