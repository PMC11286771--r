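# Small synthetic regression problems keep these tests fast; the full
# simulator-driven evaluation lives in test-acceptance.R.

synth_linear <- function(n = 200, p = 30, q = 5, seed = 21) {
  expansim:::with_seed(seed, {
    X <- matrix(stats::rnorm(n * p), n, p)
    A <- matrix(stats::rnorm(p * q), p, q)
    b <- stats::rnorm(q)
    list(X = X, Y = X %*% A + rep(b, each = n))
  })
}

fast_arch <- function(...) {
  args <- list(hidden = c(16, 16), max_epochs = 150, batch_size = 16,
               dct_k = 0, noise_sd = 0, swa_epochs = 0, patience = 40)
  do.call(arch_spec, utils::modifyList(args, list(...)))
}

test_that("column scalers z-score, flag constants and invert exactly", {
  set.seed(8)
  X <- cbind(matrix(stats::rnorm(200), 50), const = rep(3.5, 50))
  sc <- fit_scaler(X)
  expect_true(sc$constant[5])
  expect_false(any(sc$constant[1:4]))
  Z <- scaler_apply(sc, X)
  expect_equal(unname(colMeans(Z[, 1:4])), rep(0, 4), tolerance = 1e-9)
  expect_equal(unname(apply(Z[, 1:4], 2, stats::sd)), rep(1, 4),
               tolerance = 1e-9)
  expect_true(all(Z[, 5] == 0))
  expect_equal(scaler_invert(sc, Z), X, tolerance = 1e-12)
})

test_that("R-squared matches its definition, including the hand-computed case", {
  expect_equal(r_squared(c(1, 2, 3), c(1, 2, 3)), 1)
  y <- c(2, 4, 9, 1)
  expect_equal(r_squared(y, rep(mean(y), 4)), 0)
  expect_equal(r_squared(c(1, 2, 3), c(1, 2, 4)), 0.5)
  expect_lt(r_squared(c(1, 2, 3), c(3, 2, 1)), 0)
  expect_error(r_squared(c(1, 1, 1), c(1, 2, 3)), "constant")
  # invariant under a common affine transform of truth and prediction
  set.seed(1)
  yt <- stats::rnorm(30); yp <- yt + 0.3 * stats::rnorm(30)
  expect_equal(r_squared(yt, yp), r_squared(5 * yt - 2, 5 * yp - 2))
})

test_that("the network can overfit a tiny sample and is seed-deterministic", {
  d <- synth_linear(n = 64, p = 20, q = 3)
  Y <- d$Y + 0.3 * sin(d$X[, 1:3] * 2) # mild nonlinearity
  # ample epochs at constant lr, SWA-tail endpoint; no regularisation
  a <- fast_arch(hidden = c(32, 32), max_epochs = 1000, patience = 1000,
                 batch_size = 32, learning_rate = 3e-3, weight_decay = 0,
                 lr_decay = 1, swa_epochs = 100, swa_lr = 1e-4, seed = 2)
  m <- train_ann(d$X, Y, a)
  pred <- predict(m, d$X)
  sy <- fit_scaler(Y)
  fit_rows <- setdiff(seq_len(64), m$val_idx) # rows actually optimised on
  expect_lt(mean((scaler_apply(sy, pred[fit_rows, ]) -
                    scaler_apply(sy, Y[fit_rows, ]))^2), 1e-3)

  m2 <- train_ann(d$X, Y, a)
  expect_lt(max(abs(predict(m2, d$X) - pred)), 1e-6)
})

test_that("a linear map on a feature subset is recovered with near-perfect held-out accuracy", {
  # Y depends linearly on 10 of the 30 features; strong weight decay with a
  # deterministic lr schedule drives the network to the near-linear solution
  d <- expansim:::with_seed(21, {
    X <- matrix(stats::rnorm(200 * 30), 200)
    A <- matrix(stats::rnorm(10 * 5), 10, 5)
    b <- stats::rnorm(5)
    list(X = X, Y = X[, 1:10] %*% A + rep(b, each = 200))
  })
  tr <- 1:160; te <- 161:200
  m <- train_ann(d$X[tr, ], d$Y[tr, ],
                 fast_arch(hidden = 32, max_epochs = 2000, patience = 2000,
                           batch_size = 32, learning_rate = 1e-2,
                           lr_step_epochs = 150, lr_decay = 0.5,
                           min_lr = 1e-6, weight_decay = 3, seed = 5))
  p <- predict(m, d$X[te, ])
  for (j in 1:5)
    expect_gt(r_squared(d$Y[te, j], p[, j]), 0.99)
})

test_that("prediction enforces shape and is consistent between batch and single rows", {
  d <- synth_linear(n = 80)
  m <- train_ann(d$X, d$Y, fast_arch(max_epochs = 40, seed = 1))
  p <- predict(m, d$X[1:7, ])
  expect_equal(ncol(p), 5)
  expect_true(all(is.finite(p)))
  expect_equal(predict(m, d$X[3, ]), p[3, , drop = FALSE], ignore_attr = TRUE)
  expect_error(predict(m, d$X[, 1:10]), "width")
})

test_that("the DCT-basis reparameterisation stores an ordinary dense network", {
  d <- synth_linear(n = 80, p = 2 * 1001, q = 3)
  a <- arch_spec(hidden = c(8), max_epochs = 30, batch_size = 16,
                 dct_k = 40, swa_epochs = 0, patience = 30, seed = 3)
  m <- train_ann(d$X, d$Y, a)
  expect_equal(dim(m$par$W[[1]]), c(2 * 1001, 8))
  expect_true(all(is.finite(predict(m, d$X[1:4, ]))))
})

test_that("cross-validation partitions are exact, reproducible and leakage-free", {
  d <- synth_linear(n = 100, p = 12, q = 3, seed = 33)
  ds <- list(features = d$X,
             targets = cbind(d$Y, g = matrix(1 + abs(d$Y[, 1:2]) / 10,
                                             ncol = 2)))
  colnames(ds$targets) <- c("a", "b", "c", "g1", "g2")

  # partition bookkeeping via the internals used by cross_validate
  n <- 100; folds <- 10
  f1 <- expansim:::with_seed(1 + 1, sample(rep_len(seq_len(folds), n)))
  expect_equal(unname(table(f1)), rep(10L, 10), ignore_attr = TRUE)
  f2 <- expansim:::with_seed(1 + 2, sample(rep_len(seq_len(folds), n)))
  expect_false(identical(f1, f2)) # distinct partitions across repeats
  expect_identical(f1, expansim:::with_seed(2, sample(rep_len(1:10, n))))

  # leakage canary: a feature equal to the target on *test* rows only must
  # not inflate held-out accuracy
  set.seed(14)
  Xc <- matrix(stats::rnorm(100 * 10), 100)
  y <- stats::rnorm(100)
  fold_of <- expansim:::with_seed(2, sample(rep_len(1:5, 100)))
  test <- which(fold_of == 1)
  Xc[test, 10] <- y[test] # canary visible only on held-out rows
  m <- train_ann(Xc[-test, , drop = FALSE],
                 cbind(y = y[-test], z = y[-test]),
                 fast_arch(max_epochs = 120, seed = 4))
  r2 <- r_squared(y[test], predict(m, Xc[test, , drop = FALSE])[, 1])
  expect_lt(r2, 0.5)
})

test_that("cross_validate reports per-target R2 with the derived growth column", {
  # small but non-trivial learnable dataset
  d <- synth_linear(n = 90, p = 15, q = 26, seed = 55)
  colnames(d$Y) <- c(sprintf("g%02d", 1:25), "mu_mpa")
  Y <- cbind(d$Y[, 1:25, drop = FALSE] / 20 + 1.2,
             mu_mpa = d$Y[, 26], k_per_day = d$X[, 1], theta_nat = d$X[, 2])
  ds <- list(features = d$X, targets = Y)
  rep_ <- cross_validate(ds, fast_arch(max_epochs = 60, batch_size = 8, seed = 6),
                         folds = 5, repeats = 2, seed = 3)
  expect_equal(dim(rep_$r2), c(10, 29))
  expect_true("avg_growth" %in% colnames(rep_$r2))
  expect_equal(rep_$r2[, "avg_growth"],
               rowMeans(rep_$r2[, sprintf("g%02d", 1:25)]))
  expect_true(all(rep_$r2 <= 1))
  expect_gte(rep_$field_agreement, 0)
  expect_lte(rep_$field_agreement, 1)
  expect_equal(nrow(rep_$summary), 29)

  # report files round-trip
  dir <- withr::local_tempdir()
  files <- write_cv_report(rep_, dir)
  csv <- utils::read.csv(file.path(dir, "cv_r2.csv"))
  expect_equal(nrow(csv), 10)
  js <- jsonlite::read_json(file.path(dir, "cv_summary.json"))
  expect_equal(js$avg_growth$median,
               rep_$summary$median_r2[rep_$summary$target == "avg_growth"])
})

test_that("architecture search ranks by growth-field and shear-modulus medians", {
  d <- synth_linear(n = 80, p = 10, q = 26, seed = 77)
  Y <- cbind(d$Y[, 1:25] / 30 + 1.1, mu_mpa = d$Y[, 26],
             k_per_day = d$X[, 3], theta_nat = d$X[, 4])
  colnames(Y)[1:25] <- sprintf("g%02d", 1:25)
  ds <- list(features = d$X, targets = Y)
  base <- fast_arch(max_epochs = 40, batch_size = 8, seed = 2)

  single <- architecture_search(ds, candidates = list(c(8, 8)), arch = base,
                                folds = 4, repeats = 1, seed = 5)
  expect_equal(nrow(single$ranking), 1)
  expect_equal(single$ranking$hidden, "8x8")

  multi <- architecture_search(ds, candidates = list(4, c(8, 8)), arch = base,
                               folds = 4, repeats = 1, seed = 5)
  expect_length(multi$reports, 2)
  expect_true(all(diff(multi$ranking$score) <= 0)) # best first
  winner <- multi$ranking[1, ]
  expect_gte(winner$score, multi$ranking$score[2])
})
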