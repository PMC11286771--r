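# Virtual population: Latin hypercube sampling over the four-parameter
# material box (shear modulus, growth rate, natural pre-stretch, density).

#' Population specification
#'
#' Parameter box and size for the virtual population. Default ranges: shear
#' modulus `mu` in [0.01667, 0.1] MPa, growth rate `k` in [0.2, 1.92] /day,
#' natural pre-stretch `theta_nat` in [1.05, 1.2], density `rho` in
#' [1060.2, 1171.8] kg m^-3 (a nominal 1116 kg m^-3 +/- 5%).
#'
#' @param n Number of subjects.
#' @param ranges Named list of `c(lo, hi)` ranges for `mu`, `k`, `theta_nat`,
#'   `rho`.
#' @param seed Integer RNG seed recorded with the population.
#' @return An object of class `population_spec`.
#' @export
population_spec <- function(n = 1000,
                            ranges = list(mu = c(0.01667, 0.1),
                                          k = c(0.2, 1.92),
                                          theta_nat = c(1.05, 1.2),
                                          rho = c(1060.2, 1171.8)),
                            seed = 1L) {
  stopifnot(n >= 1, setequal(names(ranges), c("mu", "k", "theta_nat", "rho")))
  for (nm in names(ranges)) {
    r <- ranges[[nm]]
    if (length(r) != 2L || !(r[1] < r[2]))
      stop(sprintf("invalid range for '%s': need lo < hi", nm))
  }
  structure(list(n = as.integer(n), ranges = ranges, seed = as.integer(seed)),
            class = "population_spec")
}

# Evaluate expr with a private RNG stream seeded by `seed`, restoring the
# caller's RNG state afterwards.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Sample a virtual population by Latin hypercube
#'
#' Draws `spec$n` subjects by Latin hypercube sampling: each parameter's range
#' is divided into `n` equal-width bins, each bin receiving exactly one
#' sample (uniform within its bin), with independent random pairing across
#' dimensions. The first Lame parameter is tied to the shear modulus,
#' `lame1 = 40 mu`. Deterministic for a fixed seed.
#'
#' @param spec [population_spec()].
#' @return A data frame of class `subjects` with columns `subject_id`,
#'   `mu_mpa`, `lame1_mpa`, `k_per_day`, `theta_nat`, `rho_kg_m3`, `seed`.
#' @export
sample_subjects <- function(spec) {
  stopifnot(inherits(spec, "population_spec"))
  u <- with_seed(spec$seed, lhs::randomLHS(spec$n, 4L))
  scale1 <- function(u, r) r[1] + u * (r[2] - r[1])
  out <- data.frame(
    subject_id = seq_len(spec$n),
    mu_mpa = scale1(u[, 1], spec$ranges$mu),
    lame1_mpa = NA_real_,
    k_per_day = scale1(u[, 2], spec$ranges$k),
    theta_nat = scale1(u[, 3], spec$ranges$theta_nat),
    rho_kg_m3 = scale1(u[, 4], spec$ranges$rho),
    seed = spec$seed)
  out$lame1_mpa <- 40 * out$mu_mpa
  class(out) <- c("subjects", "data.frame")
  out
}

#' Convert one row of a subjects table to material parameters
#'
#' @param subjects A `subjects` data frame from [sample_subjects()].
#' @param i Row index.
#' @return [material_params()].
#' @export
subject_params <- function(subjects, i) {
  r <- subjects[i, ]
  material_params(mu = r$mu_mpa, k = r$k_per_day, theta_nat = r$theta_nat,
                  rho = r$rho_kg_m3, lame1 = r$lame1_mpa)
}

#' Write / read the subjects manifest CSV
#'
#' @param subjects `subjects` data frame.
#' @param path CSV path.
#' @return `write_subjects` returns `path` invisibly; `read_subjects` the
#'   `subjects` data frame.
#' @export
write_subjects <- function(subjects, path) {
  utils::write.csv(subjects, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_subjects
#' @export
read_subjects <- function(path) {
  out <- utils::read.csv(path)
  need <- c("subject_id", "mu_mpa", "lame1_mpa", "k_per_day", "theta_nat",
            "rho_kg_m3", "seed")
  missing <- setdiff(need, names(out))
  if (length(missing))
    stop("subjects manifest is missing columns: ",
         paste(missing, collapse = ", "))
  class(out) <- c("subjects", "data.frame")
  out
}
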