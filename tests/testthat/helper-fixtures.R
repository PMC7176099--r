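# Small deterministic study-pair table used across tests.
toy_pairs <- function() {
  tibble::tibble(
    study = c("a", "b", "c", "d", "e"),
    ro = c(0.45, 0.21, -0.33, 0.6, 0.12),
    no = c(28, 53, 40, 22, 80),
    rr = c(0.25, 0.05, -0.1, 0.48, 0.2),
    nr = c(53, 53, 60, 30, 80)
  )
}

# Per-column correlations of bivariate-normal samples, vectorized over
# replicates (columns).
simulate_correlations <- function(n, reps, rho) {
  x <- matrix(rnorm(n * reps), nrow = n)
  y <- rho * x + sqrt(1 - rho^2) * matrix(rnorm(n * reps), nrow = n)
  xc <- sweep(x, 2, colMeans(x))
  yc <- sweep(y, 2, colMeans(y))
  colSums(xc * yc) / sqrt(colSums(xc^2) * colSums(yc^2))
}
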