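# Turns raw protocol outputs into the fixed-shape learning dataset:
# waveforms interpolated onto a common 1001-point grid, concatenated into
# 3003-dimensional feature vectors; the day-7 growth field coarsened to a
# 5x5 grid and joined with the three material parameters into 28-dimensional
# targets; plus a lossless on-disk container.

#' Degree-4 spline interpolation of a waveform onto the common grid
#'
#' Fits an interpolating spline of degree 4 (order-5 B-splines, interior
#' knots at data midpoints, so the Schoenberg-Whitney conditions hold) through
#' the recorded samples and evaluates it on the regular grid of `n_out`
#' equally spaced times covering `[0, t_max]` seconds. The spline passes
#' through every original sample and reproduces quartic polynomials exactly.
#' No extrapolation: the record must cover the full window.
#'
#' @param wf A `waveform` (or any list with numeric `t`, `w`).
#' @param n_out Number of output samples (default 1001).
#' @param t_max End of the common time window, s (default 0.0125).
#' @return Numeric vector of `n_out` interpolated displacements.
#' @export
interpolate_waveform <- function(wf, n_out = 1001L, t_max = 0.0125) {
  t <- as.numeric(wf$t); w <- as.numeric(wf$w)
  stopifnot(length(t) == length(w), !is.unsorted(t, strictly = TRUE))
  if (t[1] > 0 || t[length(t)] < t_max)
    stop(sprintf("waveform covers [%g, %g] s but must cover [0, %g] s (no extrapolation)",
                 t[1], t[length(t)], t_max))
  m <- length(t)
  if (m < 6L) stop("need at least 6 samples for a degree-4 interpolating spline")
  ord <- 5L
  interior <- (t[3:(m - 3L)] + t[4:(m - 2L)]) / 2 # m - 5 interior knots
  knots <- c(rep(t[1], ord), interior, rep(t[m], ord))
  B <- splines::splineDesign(knots, t, ord = ord)
  coef <- solve(B, w)
  tout <- seq(0, t_max, length.out = n_out)
  Bout <- splines::splineDesign(knots, tout, ord = ord)
  drop(Bout %*% coef)
}

#' Assemble the 3003-dimensional feature vector
#'
#' Fixed-order concatenation of the three interpolated waveform blocks:
#' baseline, day 0, day 3.5 (1001 samples each).
#'
#' @param base,day0,day3p5 Numeric vectors of length 1001.
#' @return Numeric vector of length 3003.
#' @export
assemble_features <- function(base, day0, day3p5) {
  for (b in list(base, day0, day3p5))
    if (length(b) != 1001L)
      stop("each waveform block must have exactly 1001 samples, got ", length(b))
  c(base, day0, day3p5)
}

#' Coarsen a growth field to the 5x5 target grid
#'
#' Partitions the reference quarter domain into a 5x5 array of equal
#' rectangles (10 x 7.5 mm each at the default dimensions) and represents
#' each region by the field value of the cell whose centre is nearest to the
#' region's centre point (ties broken toward the origin). Values are returned
#' row-major from the symmetry corner: index `(j-1)*5 + i` holds region `i`
#' along x, `j` along y.
#'
#' @param field_values `nx x ny` matrix of cell-centre values (rows index x).
#' @param grid [build_patch()].
#' @return Numeric vector of length 25.
#' @export
coarsen_5x5 <- function(field_values, grid) {
  stopifnot(is.matrix(field_values),
            nrow(field_values) == grid$nx, ncol(field_values) == grid$ny)
  centres_x <- (seq_len(5) - 0.5) * grid$lx / 5
  centres_y <- (seq_len(5) - 0.5) * grid$ly / 5
  # nearest cell centre with ties toward the origin
  nearest <- function(c0, cells) {
    d <- abs(cells - c0)
    which(d <= min(d) + 1e-12)[1]
  }
  ix <- vapply(centres_x, nearest, integer(1), cells = grid$x_cells)
  iy <- vapply(centres_y, nearest, integer(1), cells = grid$y_cells)
  out <- numeric(25)
  for (j in 1:5) for (i in 1:5)
    out[(j - 1L) * 5L + i] <- field_values[ix[i], iy[j]]
  out
}

#' Extra skin area generated by growth
#'
#' Total new area over the quarter domain: `sum((theta_g - 1) * cell_area)`,
#' in mm^2; zero exactly when no growth has occurred.
#'
#' @param theta_g `nx x ny` matrix of growth stretches.
#' @param grid [build_patch()].
#' @return Extra area, mm^2.
#' @export
extra_area <- function(theta_g, grid) {
  stopifnot(is.matrix(theta_g),
            nrow(theta_g) == grid$nx, ncol(theta_g) == grid$ny)
  sum((theta_g - 1)) * grid$cell_area
}

target_names <- function() {
  c(sprintf("g%02d", 1:25), "mu_mpa", "k_per_day", "theta_nat")
}

feature_names <- function() {
  c(sprintf("base_%04d", 0:1000), sprintf("day0_%04d", 0:1000),
    sprintf("day35_%04d", 0:1000))
}

#' Build the learning dataset for a population of subjects
#'
#' Runs the full measurement protocol ([run_protocol()]) for every subject,
#' interpolates the three waveforms onto the common 1001-point grid,
#' assembles the `n x 3003` feature matrix, and builds the `n x 28` target
#' matrix: the 25 coarsened day-7 growth values followed by `mu` (MPa), `k`
#' (/day) and `theta_nat`.
#'
#' @param subjects `subjects` data frame from [sample_subjects()].
#' @param grid [build_patch()].
#' @param profile [expander_profile()].
#' @param impact [impact_config()].
#' @param config Optional configuration list stored with the dataset.
#' @param progress Print a progress line every 50 subjects.
#' @return An object of class `expansim_dataset`: list with `features`
#'   (`n x 3003`), `targets` (`n x 28`), `manifest` (the subjects table) and
#'   `config`.
#' @export
build_dataset <- function(subjects, grid = build_patch(),
                          profile = expander_profile(),
                          impact = impact_config(), config = list(),
                          progress = interactive()) {
  n <- nrow(subjects)
  X <- matrix(NA_real_, n, 3003L, dimnames = list(NULL, feature_names()))
  Y <- matrix(NA_real_, n, 28L, dimnames = list(NULL, target_names()))
  for (i in seq_len(n)) {
    mp <- subject_params(subjects, i)
    rec <- run_protocol(mp, grid, profile, impact)
    X[i, ] <- assemble_features(
      interpolate_waveform(rec$waveforms$baseline, t_max = impact$duration),
      interpolate_waveform(rec$waveforms$day0, t_max = impact$duration),
      interpolate_waveform(rec$waveforms$day3p5, t_max = impact$duration))
    Y[i, ] <- c(coarsen_5x5(rec$growth_day7, grid), mp$mu, mp$k, mp$theta_nat)
    if (progress && i %% 50L == 0L)
      message(sprintf("simulated %d / %d subjects", i, n))
  }
  structure(list(features = X, targets = Y, manifest = subjects,
                 config = config),
            class = "expansim_dataset")
}

#' @export
print.expansim_dataset <- function(x, ...) {
  cat(sprintf("Tissue-expansion dataset: %d subjects, %d features, %d targets\n",
              nrow(x$features), ncol(x$features), ncol(x$targets)))
  invisible(x)
}

#' Write / read the dataset container
#'
#' Stores a dataset losslessly in a portable directory container:
#' `features.feather` (n x 3003) and `targets.feather` (n x 28) in Arrow
#' Feather format (exact IEEE doubles, so `read_dataset(write_dataset(x))`
#' round-trips bit-exactly), `manifest.csv` (the subjects table) and
#' `config.json` (configuration snapshot).
#'
#' @param dataset `expansim_dataset`.
#' @param path Container directory (created if needed).
#' @return `write_dataset` returns `path` invisibly; `read_dataset` the
#'   dataset.
#' @export
write_dataset <- function(dataset, path) {
  stopifnot(inherits(dataset, "expansim_dataset"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  arrow::write_feather(as.data.frame(dataset$features),
                       file.path(path, "features.feather"))
  arrow::write_feather(as.data.frame(dataset$targets),
                       file.path(path, "targets.feather"))
  utils::write.csv(dataset$manifest, file.path(path, "manifest.csv"),
                   row.names = FALSE)
  jsonlite::write_json(dataset$config, file.path(path, "config.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(path) {
  need <- c("features.feather", "targets.feather", "manifest.csv", "config.json")
  for (f in need)
    if (!file.exists(file.path(path, f)))
      stop("dataset container is missing '", f, "'")
  X <- as.matrix(arrow::read_feather(file.path(path, "features.feather")))
  Y <- as.matrix(arrow::read_feather(file.path(path, "targets.feather")))
  if (ncol(X) != 3003L)
    stop("features: expected 3003 columns, found ", ncol(X))
  if (ncol(Y) != 28L)
    stop("targets: expected 28 columns, found ", ncol(Y))
  if (nrow(X) != nrow(Y))
    stop("features and targets disagree on the number of subjects")
  manifest <- read_subjects(file.path(path, "manifest.csv"))
  config <- jsonlite::read_json(file.path(path, "config.json"),
                                simplifyVector = TRUE)
  structure(list(features = X, targets = Y, manifest = manifest,
                 config = config),
            class = "expansim_dataset")
}
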