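# Shared fixtures: small grids and a tiny end-to-end dataset, built in code.

tiny_grid <- function() build_patch(nx = 10, ny = 8)

tiny_dataset <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      subs <- sample_subjects(population_spec(n = 5, seed = 42))
      cache <<- build_dataset(subs, grid = tiny_grid(), progress = FALSE)
    }
    cache
  }
})

# random rotation matrix via QR of a Gaussian matrix
random_rotation <- function() {
  qr_ <- qr(matrix(stats::rnorm(9), 3))
  Q <- qr.Q(qr_)
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

table2_corners <- function() {
  expand.grid(mu = c(0.01667, 0.1), k = c(0.2, 1.92),
              theta_nat = c(1.05, 1.2), rho = c(1060.2, 1171.8))
}
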