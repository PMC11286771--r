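# Neural-network inverse surrogate: a fully connected network mapping the
# 3003-dimensional waveform features to the 28 targets (25 coarsened growth
# values + mu, k, theta_nat), trained with minibatch Adam on standardized
# data under an MSE loss, evaluated by per-target R-squared under repeated
# k-fold cross-validation.

#' Network architecture and training hyperparameters
#'
#' @param hidden Ordered hidden-layer widths; default `c(32, 64, 32)`.
#' @param max_epochs Maximum training epochs.
#' @param batch_size Minibatch size.
#' @param learning_rate Adam step size.
#' @param patience Early-stopping patience (epochs without improvement of the
#'   inner-validation loss); the best weights are restored.
#' @param weight_decay Decoupled L2 weight decay applied with the Adam update
#'   (biases exempt); the main regulariser against overfitting the small
#'   noiseless training sets alongside early stopping.
#' @param val_fraction Fraction of the training rows held out as the inner
#'   validation split for early stopping.
#' @param activation Hidden-layer nonlinearity, `"relu"` or `"tanh"`.
#' @param lr_decay,lr_patience,min_lr Reduce-on-plateau schedule: multiply
#'   the learning rate by `lr_decay` after `lr_patience` epochs without
#'   validation improvement, down to `min_lr`.
#' @param lr_step_epochs If positive, replaces the plateau schedule with a
#'   deterministic one: the learning rate is multiplied by `lr_decay` every
#'   `lr_step_epochs` epochs (down to `min_lr`). Useful when the inner
#'   validation split is too small to drive the plateau schedule reliably.
#' @param dct_k Optimise the first layer in a fixed block-wise cosine basis:
#'   each 1001-sample waveform block of the (standardized) features is
#'   projected onto its leading `dct_k` orthonormal DCT-II modes, and the
#'   projected coordinates are re-standardized, before entering the first
#'   dense layer. Because projection and scaling are linear, they are folded
#'   back into the first weight matrix and bias after training, so the stored
#'   network has exactly the declared dense architecture. The basis imposes a
#'   time-smoothness prior on the first layer that conditions small-sample
#'   training of waveform inputs dramatically better than raw per-sample
#'   coordinates; `0` disables it. Only consulted when the feature width is a
#'   multiple of 1001.
#' @param sd_floor Passed to [fit_scaler()] for the feature scaler.
#' @param noise_sd Training-time augmentation: standard deviation of
#'   Gaussian noise added to the standardized features of each minibatch
#'   (fresh draw every step; the validation split stays clean). A standard
#'   small-sample regulariser for smooth, noiseless simulator features.
#' @param mixup_alpha If positive, minibatch rows are blended with randomly
#'   paired rows using Beta(`alpha`, `alpha`) convex weights (features and
#'   targets alike), encouraging locally linear behaviour between subjects.
#' @param log_growth If `TRUE`, growth-field targets (columns `g01`..`g25`)
#'   are re-expressed as `log(theta_g - 1)` before standardization and
#'   training, and back-transformed at prediction time. The held dome imposes
#'   a fixed spatial shape on the growth field, so in log space the 25
#'   targets differ mainly by additive spatial offsets, which makes the
#'   shared network head much easier to fit; accuracy is always reported in
#'   original units.
#' @param growth_weight Relative weight of the 25 growth-field targets
#'   (columns named `g01`..`g25`) in the training loss; the three material
#'   parameters keep weight 1. Values above 1 trade a little parameter
#'   accuracy for a more accurate field head.
#' @param swa_epochs If positive, the returned weights are the running
#'   average of the weights over the final `swa_epochs` training epochs
#'   (stochastic weight averaging) instead of the best-validation snapshot;
#'   early stopping is then disabled and the run length is `max_epochs`.
#' @param swa_lr Constant learning rate used during the averaging window
#'   (the usual SWA schedule); `0` keeps whatever the plateau schedule has
#'   reached.
#' @param seed Integer seed for weight initialisation, shuffling and the
#'   inner split.
#' @return An object of class `arch_spec`.
#' @export
arch_spec <- function(hidden = c(32, 64, 32), max_epochs = 500L,
                      batch_size = 32L, learning_rate = 1e-3,
                      patience = 100L, val_fraction = 0.05,
                      weight_decay = 1e-3, activation = c("tanh", "relu"),
                      lr_decay = 0.5, lr_patience = 30L, min_lr = 1e-5,
                      lr_step_epochs = 100L, dct_k = 450L, sd_floor = 0, noise_sd = 0.05,
                      log_growth = FALSE, growth_weight = 1, mixup_alpha = 0,
                      swa_epochs = 150L, swa_lr = 3e-4, seed = 1L) {
  activation <- match.arg(activation)
  stopifnot(length(hidden) >= 1, all(hidden >= 1), max_epochs >= 1,
            batch_size >= 1, learning_rate > 0, patience >= 1,
            val_fraction > 0, val_fraction < 0.5, weight_decay >= 0,
            lr_decay > 0, lr_decay <= 1, lr_patience >= 1, min_lr > 0,
            lr_step_epochs >= 0,
            dct_k >= 0, sd_floor >= 0, sd_floor < 1, noise_sd >= 0,
            growth_weight > 0, mixup_alpha >= 0, swa_epochs >= 0,
            swa_epochs <= max_epochs, swa_lr >= 0)
  structure(list(hidden = as.integer(hidden), max_epochs = as.integer(max_epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, patience = as.integer(patience),
                 val_fraction = val_fraction, weight_decay = weight_decay,
                 activation = activation, lr_decay = lr_decay,
                 lr_patience = as.integer(lr_patience), min_lr = min_lr,
                 lr_step_epochs = as.integer(lr_step_epochs),
                 dct_k = as.integer(dct_k), sd_floor = sd_floor,
                 noise_sd = noise_sd, log_growth = isTRUE(log_growth),
                 growth_weight = growth_weight,
                 mixup_alpha = mixup_alpha,
                 swa_epochs = as.integer(swa_epochs), swa_lr = swa_lr,
                 seed = as.integer(seed)),
            class = "arch_spec")
}

#' Column standardization scalers
#'
#' Fits per-column z-scoring on training data only. Zero-variance columns are
#' mapped to zero and flagged (their scale is set to 1 around the constant),
#' so applying and inverting round-trips all finite inputs.
#'
#' @param x Numeric matrix (training rows).
#' @param sd_floor Optional floor on the per-column scale, expressed as a
#'   fraction of the largest column standard deviation. Columns whose spread
#'   is tiny relative to the rest of the matrix (e.g. waveform samples before
#'   the first arrival) are then not inflated to unit variance, which would
#'   promote numerically silent inputs into dominant features.
#' @return An object of class `col_scaler` with `center`, `scale`,
#'   `constant` (logical flag per column).
#' @export
fit_scaler <- function(x, sd_floor = 0) {
  stopifnot(is.matrix(x), nrow(x) >= 2L, sd_floor >= 0, sd_floor < 1)
  ctr <- colMeans(x)
  sd_ <- apply(x, 2, stats::sd)
  constant <- !is.finite(sd_) | sd_ == 0
  sd_[constant] <- 1
  if (sd_floor > 0) sd_ <- pmax(sd_, sd_floor * max(sd_[!constant], 1e-300))
  structure(list(center = ctr, scale = sd_, constant = constant),
            class = "col_scaler")
}

#' @rdname fit_scaler
#' @param scaler A `col_scaler`.
#' @export
scaler_apply <- function(scaler, x) {
  sweep(sweep(x, 2, scaler$center, `-`), 2, scaler$scale, `/`)
}

#' @rdname fit_scaler
#' @export
scaler_invert <- function(scaler, x) {
  sweep(sweep(x, 2, scaler$scale, `*`), 2, scaler$center, `+`)
}

relu <- function(x) (x > 0) * x

act_fun <- function(name) switch(name, relu = relu, tanh = tanh)
act_grad <- function(name, h) switch(name, relu = (h > 0), tanh = 1 - h^2)

init_weights <- function(sizes, activation = "relu") {
  # He-uniform for rectifiers, Glorot-uniform for tanh
  W <- list(); b <- list()
  for (l in seq_len(length(sizes) - 1L)) {
    lim <- if (activation == "relu") sqrt(6 / sizes[l])
           else sqrt(6 / (sizes[l] + sizes[l + 1L]))
    W[[l]] <- matrix(stats::runif(sizes[l] * sizes[l + 1L], -lim, lim),
                     sizes[l], sizes[l + 1L])
    b[[l]] <- numeric(sizes[l + 1L])
  }
  list(W = W, b = b)
}

mlp_forward <- function(par, X, activation = "relu") {
  L <- length(par$W)
  f <- act_fun(activation)
  H <- X
  acts <- vector("list", L + 1L); acts[[1]] <- H
  for (l in seq_len(L)) {
    Z <- H %*% par$W[[l]]
    Z <- sweep(Z, 2, par$b[[l]], `+`)
    H <- if (l < L) f(Z) else Z # linear output layer
    acts[[l + 1L]] <- H
  }
  list(out = H, acts = acts)
}

mlp_backward <- function(par, acts, dOut, activation = "relu") {
  L <- length(par$W)
  gW <- vector("list", L); gb <- vector("list", L)
  delta <- dOut
  for (l in rev(seq_len(L))) {
    gW[[l]] <- crossprod(acts[[l]], delta)
    gb[[l]] <- colSums(delta)
    if (l > 1L) {
      delta <- delta %*% t(par$W[[l]])
      delta <- delta * act_grad(activation, acts[[l]])
    }
  }
  list(W = gW, b = gb)
}

mse_loss <- function(pred, truth) mean((pred - truth)^2)

# Orthonormal DCT-II basis (N samples x K modes).
dct_basis <- function(N, K) {
  B <- vapply(0:(K - 1L), function(k)
    cos(pi * (2 * (0:(N - 1L)) + 1) * k / (2 * N)), numeric(N))
  B[, 1] <- B[, 1] / sqrt(2)
  B * sqrt(2 / N)
}

# Block-diagonal cosine basis for features made of `blocks` waveform blocks.
blockwise_dct <- function(width, block_len, K) {
  blocks <- width %/% block_len
  B <- matrix(0, width, blocks * K)
  B1 <- dct_basis(block_len, K)
  for (b in seq_len(blocks) - 1L)
    B[b * block_len + seq_len(block_len), b * K + seq_len(K)] <- B1
  B
}

#' Train the inverse surrogate network
#'
#' Fits a fully connected network `3003 -> hidden -> 28` (ReLU hidden layers,
#' linear outputs) by minibatch Adam on the mean-squared-error loss. Features
#' and targets are z-scored with scalers fitted on the training rows (stored
#' in the model; predictions are returned in original units). An inner
#' validation split drives early stopping with best-weight restoration.
#' Fully deterministic for a fixed `arch$seed`.
#'
#' @param X Feature matrix, `n x 3003` (any width is accepted; the width is
#'   recorded and enforced at prediction time).
#' @param Y Target matrix, `n x 28` (likewise recorded).
#' @param arch [arch_spec()].
#' @param verbose Print the epoch log every 100 epochs.
#' @return An object of class `trained_ann` with the weights, scalers,
#'   architecture and training history.
#' @export
train_ann <- function(X, Y, arch = arch_spec(), verbose = FALSE) {
  stopifnot(is.matrix(X), is.matrix(Y), nrow(X) == nrow(Y))
  n <- nrow(X)
  if (n < 2L * arch$batch_size)
    stop("need at least 2 * batch_size training rows")
  growth_cols_idx <- if (!is.null(colnames(Y)))
    which(grepl("^g[0-9]+$", colnames(Y))) else integer(0)
  if (arch$log_growth && length(growth_cols_idx))
    Y[, growth_cols_idx] <- log(pmax(Y[, growth_cols_idx] - 1, 1e-10))
  with_seed(arch$seed, {
    sx <- fit_scaler(X, sd_floor = arch$sd_floor); sy <- fit_scaler(Y)
    Xs <- scaler_apply(sx, X); Ys <- scaler_apply(sy, Y)

    # optional fixed smooth basis for the first layer (folded back below)
    V <- NULL; b_shift <- NULL
    if (arch$dct_k > 0L && ncol(Xs) %% 1001L == 0L &&
        arch$dct_k < 1001L) {
      B <- blockwise_dct(ncol(Xs), 1001L, arch$dct_k)
      Xp <- Xs %*% B
      s2 <- fit_scaler(Xp)
      V <- sweep(B, 2, s2$scale, `/`)
      b_shift <- s2$center / s2$scale
      Xs <- sweep(Xp, 2, s2$scale, `/`)
      Xs <- sweep(Xs, 2, b_shift, `-`)
    }

    w_out <- rep(1, ncol(Y))
    if (arch$growth_weight != 1 && !is.null(colnames(Y)))
      w_out[grepl("^g[0-9]+$", colnames(Y))] <- arch$growth_weight
    w_out <- w_out / mean(w_out)

    n_val <- max(1L, round(arch$val_fraction * n))
    val_idx <- sample.int(n, n_val)
    tr_idx <- setdiff(seq_len(n), val_idx)
    Xtr <- Xs[tr_idx, , drop = FALSE]; Ytr <- Ys[tr_idx, , drop = FALSE]
    Xval <- Xs[val_idx, , drop = FALSE]; Yval <- Ys[val_idx, , drop = FALSE]

    sizes <- c(ncol(Xs), arch$hidden, ncol(Y))
    par <- init_weights(sizes, arch$activation)
    m <- rapply(par, function(x) x * 0, how = "replace")
    v <- m
    beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
    step <- 0L
    ntr <- nrow(Xtr)
    best <- list(loss = Inf, par = par, epoch = 0L)
    history <- data.frame(epoch = integer(), train_mse = numeric(),
                          val_mse = numeric())
    wait <- 0L
    lr <- arch$learning_rate
    lr_wait <- 0L
    swa <- NULL; swa_n <- 0L

    for (epoch in seq_len(arch$max_epochs)) {
      perm <- sample.int(ntr)
      starts <- seq(1L, ntr, by = arch$batch_size)
      for (s in starts) {
        idx <- perm[s:min(s + arch$batch_size - 1L, ntr)]
        Xb <- Xtr[idx, , drop = FALSE]; Yb <- Ytr[idx, , drop = FALSE]
        if (arch$mixup_alpha > 0) {
          lam <- stats::rbeta(length(idx), arch$mixup_alpha, arch$mixup_alpha)
          j <- sample.int(ntr, length(idx))
          Xb <- lam * Xb + (1 - lam) * Xtr[j, , drop = FALSE]
          Yb <- lam * Yb + (1 - lam) * Ytr[j, , drop = FALSE]
        }
        if (arch$noise_sd > 0)
          Xb <- Xb + stats::rnorm(length(Xb), sd = arch$noise_sd)
        fb <- mlp_forward(par, Xb, arch$activation)
        resid <- fb$out - Yb
        if (!all(is.finite(resid)))
          stop(sprintf("non-finite training loss at epoch %d; reduce the learning rate", epoch))
        dOut <- sweep(2 * resid / (length(idx) * ncol(resid)), 2, w_out, `*`)
        g <- mlp_backward(par, fb$acts, dOut, arch$activation)
        step <- step + 1L
        corr1 <- 1 - beta1^step; corr2 <- 1 - beta2^step
        for (l in seq_along(par$W)) {
          for (nm in c("W", "b")) {
            m[[nm]][[l]] <- beta1 * m[[nm]][[l]] + (1 - beta1) * g[[nm]][[l]]
            v[[nm]][[l]] <- beta2 * v[[nm]][[l]] + (1 - beta2) * g[[nm]][[l]]^2
            par[[nm]][[l]] <- par[[nm]][[l]] - lr *
              (m[[nm]][[l]] / corr1) / (sqrt(v[[nm]][[l]] / corr2) + eps)
            if (nm == "W" && arch$weight_decay > 0)
              par[[nm]][[l]] <- par[[nm]][[l]] * (1 - lr * arch$weight_decay)
          }
        }
      }
      val_mse <- mean(sweep((mlp_forward(par, Xval, arch$activation)$out -
                               Yval)^2, 2, w_out, `*`))
      if (epoch %% 20L == 0L || epoch == 1L) {
        tr_mse <- mse_loss(mlp_forward(par, Xtr, arch$activation)$out, Ytr)
        history <- rbind(history, data.frame(epoch = epoch, train_mse = tr_mse,
                                             val_mse = val_mse))
        if (verbose && epoch %% 100L == 0L)
          message(sprintf("epoch %4d  train %.3e  val %.3e", epoch, tr_mse, val_mse))
      }
      if (arch$lr_step_epochs > 0L && epoch %% arch$lr_step_epochs == 0L)
        lr <- max(arch$min_lr, lr * arch$lr_decay)
      if (arch$swa_epochs > 0L &&
          epoch > arch$max_epochs - arch$swa_epochs) {
        if (arch$swa_lr > 0) lr <- arch$swa_lr
        swa_n <- swa_n + 1L
        swa <- if (is.null(swa)) par else
          mapply(function(a, g) mapply(function(x, y)
            x + (y - x) / swa_n, a, g, SIMPLIFY = FALSE),
            swa, par, SIMPLIFY = FALSE)
      }
      if (val_mse < best$loss - 1e-12) {
        best <- list(loss = val_mse, par = par, epoch = epoch)
        wait <- 0L
        lr_wait <- 0L
      } else {
        wait <- wait + 1L
        lr_wait <- lr_wait + 1L
        if (wait >= arch$patience && arch$swa_epochs == 0L) break
        if (arch$lr_step_epochs == 0L && lr_wait >= arch$lr_patience &&
            lr > arch$min_lr) {
          lr <- max(arch$min_lr, lr * arch$lr_decay)
          lr_wait <- 0L
        }
      }
    }

    par <- if (arch$swa_epochs > 0L && !is.null(swa)) swa else best$par
    if (arch$swa_epochs > 0L)
      best <- list(loss = mse_loss(mlp_forward(par, Xval,
                     arch$activation)$out, Yval), par = par,
                   epoch = arch$max_epochs)
    if (!is.null(V)) { # fold the basis into the first dense layer
      if (!is.null(b_shift))
        par$b[[1]] <- par$b[[1]] - drop(b_shift %*% par$W[[1]])
      par$W[[1]] <- V %*% par$W[[1]]
      sizes[1] <- ncol(X)
    }
    structure(list(par = par, scaler_x = sx, scaler_y = sy,
                   arch = arch, sizes = sizes,
                   log_growth_cols = if (arch$log_growth) growth_cols_idx
                                     else integer(0),
                   val_idx = val_idx, history = history,
                   best_epoch = best$epoch, best_val_mse = best$loss),
              class = "trained_ann")
  })
}

#' @export
print.trained_ann <- function(x, ...) {
  cat(sprintf("Trained surrogate: %s (best epoch %d, val MSE %.3e)\n",
              paste(x$sizes, collapse = "-"), x$best_epoch, x$best_val_mse))
  invisible(x)
}

#' Predict targets from waveform features
#'
#' @param object `trained_ann`.
#' @param X Feature matrix (or single feature vector) with the width the
#'   model was trained on.
#' @param ... Unused.
#' @return Predictions in original units, `n x 28`.
#' @export
predict.trained_ann <- function(object, X, ...) {
  if (is.vector(X)) X <- matrix(X, nrow = 1L)
  if (ncol(X) != object$sizes[1])
    stop(sprintf("feature width mismatch: model expects %d columns, got %d",
                 object$sizes[1], ncol(X)))
  out <- mlp_forward(object$par, scaler_apply(object$scaler_x, X),
                     object$arch$activation)$out
  out <- scaler_invert(object$scaler_y, out)
  if (length(object$log_growth_cols))
    out[, object$log_growth_cols] <- 1 + exp(out[, object$log_growth_cols])
  out
}

#' Coefficient of determination
#'
#' `R^2 = 1 - SS_res / SS_tot` with `SS_tot` about the mean of `y_true`;
#' equals 1 only for a perfect prediction and can be negative.
#'
#' @param y_true,y_pred Numeric vectors of equal length (>= 2).
#' @return Scalar R^2.
#' @export
r_squared <- function(y_true, y_pred) {
  stopifnot(length(y_true) == length(y_pred), length(y_true) >= 2L)
  ss_tot <- sum((y_true - mean(y_true))^2)
  if (ss_tot == 0) stop("R^2 is undefined for constant y_true")
  1 - sum((y_true - y_pred)^2) / ss_tot
}

growth_cols <- function() 1:25

#' Repeated k-fold cross-validation of the surrogate
#'
#' For each repeat: a fresh random partition into `folds` near-equal folds
#' and fresh weight initialisation; for each fold the network is trained on
#' the remaining folds (scalers fitted inside [train_ann()] on training rows
#' only) and evaluated on the held-out fold by per-target R^2. The derived
#' column `avg_growth` is the mean R^2 over the 25 growth-field targets of
#' each evaluation.
#'
#' @param dataset `expansim_dataset` (or list with `features`, `targets`).
#' @param arch [arch_spec()].
#' @param folds Number of folds (default 10).
#' @param repeats Number of repeats with distinct seeds (default 5).
#' @param seed Base seed; repeat `r` uses `seed + r` for partitioning and
#'   `seed + 1000 r + fold` for weights.
#' @param agreement_tol Absolute tolerance used for the per-subject field
#'   agreement diagnostic (fraction of held-out subjects whose 25 growth
#'   values are all predicted within this tolerance).
#' @param verbose Print a line per fold.
#' @return An object of class `cv_report`: `r2` matrix
#'   (`folds*repeats x 29`), `summary` data frame (median and sd per
#'   target), `field_agreement` (overall fraction), and per-evaluation
#'   metadata.
#' @export
cross_validate <- function(dataset, arch = arch_spec(), folds = 10L,
                           repeats = 5L, seed = 1L, agreement_tol = 0.01,
                           verbose = FALSE) {
  X <- dataset$features; Y <- dataset$targets
  n <- nrow(X)
  stopifnot(n >= 2L * folds)
  cols <- c(colnames(Y), "avg_growth")
  r2 <- matrix(NA_real_, folds * repeats, length(cols),
               dimnames = list(NULL, cols))
  meta <- data.frame(repeat_ = rep(seq_len(repeats), each = folds),
                     fold = rep(seq_len(folds), repeats))
  agree_num <- 0L
  extra_area_err <- NULL
  row <- 0L
  for (r in seq_len(repeats)) {
    fold_of <- with_seed(seed + r, sample(rep_len(seq_len(folds), n)))
    for (f in seq_len(folds)) {
      row <- row + 1L
      test <- which(fold_of == f)
      a <- arch; a$seed <- seed + 1000L * r + f
      model <- train_ann(X[-test, , drop = FALSE], Y[-test, , drop = FALSE], a)
      pred <- predict(model, X[test, , drop = FALSE])
      r2[row, seq_len(ncol(Y))] <-
        vapply(seq_len(ncol(Y)),
               function(j) r_squared(Y[test, j], pred[, j]), numeric(1))
      r2[row, "avg_growth"] <- mean(r2[row, growth_cols()])
      gerr <- abs(pred[, growth_cols(), drop = FALSE] -
                    Y[test, growth_cols(), drop = FALSE])
      agree_num <- agree_num + sum(apply(gerr, 1, max) <= agreement_tol)
      if (verbose)
        message(sprintf("repeat %d fold %2d: avg growth R2 %.4f, mu %.4f, k %.4f, theta_nat %.4f",
                        r, f, r2[row, "avg_growth"], r2[row, "mu_mpa"],
                        r2[row, "k_per_day"], r2[row, "theta_nat"]))
    }
  }
  summary <- data.frame(target = cols,
                        median_r2 = apply(r2, 2, stats::median),
                        sd_r2 = apply(r2, 2, stats::sd))
  structure(list(r2 = r2, meta = meta, summary = summary,
                 folds = folds, repeats = repeats, seed = seed,
                 field_agreement = agree_num / (n * repeats),
                 agreement_tol = agreement_tol),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("Cross-validation report: %d folds x %d repeats\n",
              x$folds, x$repeats))
  key <- x$summary[x$summary$target %in%
                     c("avg_growth", "mu_mpa", "k_per_day", "theta_nat"), ]
  for (i in seq_len(nrow(key)))
    cat(sprintf("  %-10s median R2 = %.4f (sd %.4f)\n", key$target[i],
                key$median_r2[i], key$sd_r2[i]))
  cat(sprintf("  field agreement (all 25 growth values within %.2g): %.1f%% of held-out subjects\n",
              x$agreement_tol, 100 * x$field_agreement))
  invisible(x)
}

#' Write a CV report to CSV + JSON summary
#'
#' @param report `cv_report`.
#' @param dir Output directory.
#' @return Paths of the written files, invisibly.
#' @export
write_cv_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  csv <- file.path(dir, "cv_r2.csv")
  utils::write.csv(cbind(report$meta, as.data.frame(report$r2)), csv,
                   row.names = FALSE)
  js <- file.path(dir, "cv_summary.json")
  summ <- stats::setNames(
    lapply(seq_len(nrow(report$summary)), function(i)
      list(median = report$summary$median_r2[i],
           std = report$summary$sd_r2[i])),
    report$summary$target)
  jsonlite::write_json(summ, js, auto_unbox = TRUE, digits = NA)
  invisible(c(csv, js))
}

#' Architecture search by repeated cross-validation
#'
#' Runs [cross_validate()] for every candidate hidden-layer layout and ranks
#' the candidates by the selection criterion: maximising the median held-out
#' performance of the growth field and shear modulus (scored by the mean of
#' the two medians), ties broken by the growth-field median.
#'
#' @param dataset `expansim_dataset`.
#' @param candidates List of hidden-layer integer vectors; the default grid
#'   spans single- to three-layer layouts around the default `c(32, 64, 32)`.
#' @param arch Base [arch_spec()] providing the training hyperparameters.
#' @param folds,repeats,seed Passed to [cross_validate()].
#' @param verbose Print one line per candidate.
#' @return An object of class `arch_search`: `ranking` data frame (best
#'   first) and the per-candidate `cv_report`s.
#' @export
architecture_search <- function(dataset,
                                candidates = list(16, 32, 64, c(32, 32),
                                                  c(64, 64), c(32, 64, 32),
                                                  c(64, 128, 64), c(64, 64, 64)),
                                arch = arch_spec(), folds = 10L, repeats = 5L,
                                seed = 1L, verbose = FALSE) {
  stopifnot(length(candidates) >= 1L)
  reports <- vector("list", length(candidates))
  rows <- vector("list", length(candidates))
  for (i in seq_along(candidates)) {
    a <- arch; a$hidden <- as.integer(candidates[[i]])
    rep_i <- cross_validate(dataset, a, folds = folds, repeats = repeats,
                            seed = seed)
    reports[[i]] <- rep_i
    med <- function(t) rep_i$summary$median_r2[rep_i$summary$target == t]
    rows[[i]] <- data.frame(
      hidden = paste(candidates[[i]], collapse = "x"),
      median_growth = med("avg_growth"), median_mu = med("mu_mpa"),
      median_k = med("k_per_day"), median_theta_nat = med("theta_nat"),
      score = (med("avg_growth") + med("mu_mpa")) / 2)
    if (verbose)
      message(sprintf("candidate %-10s score %.4f", rows[[i]]$hidden,
                      rows[[i]]$score))
  }
  ranking <- do.call(rbind, rows)
  ord <- order(-ranking$score, -ranking$median_growth)
  structure(list(ranking = ranking[ord, ], reports = reports[ord],
                 candidates = candidates[ord]),
            class = "arch_search")
}
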