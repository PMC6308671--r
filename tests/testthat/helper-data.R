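# Fixtures built in code: small two-instrument datasets used across the
# suite.

# Desk-scale draw from the full generator.
tiny_spectra <- function(seed = 1, n = 40, bands = 20, ...) {
  generate_mean_spectra(synth_config(
    n_healthy = n / 2, n_bruised = n / 2, seed = seed,
    band_grid_pb = seq(480, 960, length.out = bands),
    band_grid_lctf = seq(965, 1655, length.out = bands), ...))
}

# Sparse-signal pair of tables: k informative bands per instrument (mean
# shift `delta`, recycled to length k, for bruised), the rest pure
# noise. Returns the tables plus the informative column indices.
sparse_tables <- function(seed, n = 240, p = 50, k = 5, delta = 1) {
  set.seed(seed)
  n_b <- n %/% 2; n_h <- n - n_b
  label <- c(rep("healthy", n_h), rep("bruised", n_b))
  delta <- rep_len(delta, k)
  make <- function(instrument, grid_lo, grid_hi) {
    X <- matrix(rnorm(n * p), n)
    info <- sort(sample.int(p, k))
    X[label == "bruised", info] <-
      sweep(X[label == "bruised", info, drop = FALSE], 2, delta, "+")
    list(table = spectrum_table(X, seq(grid_lo, grid_hi, length.out = p),
                                sprintf("S%03d", seq_len(n)), label,
                                instrument = instrument),
         informative = info)
  }
  a <- make("PB", 480, 960)
  set.seed(seed + 1000)
  b <- make("LCTF", 965, 1655)
  list(pb = a$table, info_pb = a$informative,
       lctf = b$table, info_lctf = b$informative, label = label)
}

# Well-separated two-class table (near-perfect classification).
separable_table <- function(seed = 1, n = 60, p = 8, delta = 6) {
  set.seed(seed)
  label <- rep(c("healthy", "bruised"), each = n / 2)
  X <- matrix(rnorm(n * p), n)
  X[label == "bruised", ] <- X[label == "bruised", ] - delta
  spectrum_table(X, seq(500, 900, length.out = p),
                 sprintf("S%03d", seq_len(n)), label)
}

# Random valid prob_output for n samples.
random_prob_output <- function(n, seed) {
  set.seed(seed)
  p_h <- runif(n)
  out <- data.frame(sample_id = sprintf("S%03d", seq_len(n)),
                    p_healthy = p_h, p_bruised = 1 - p_h,
                    score = qnorm(p_h),
                    label = ifelse(p_h > 0.5, "healthy", "bruised"),
                    stringsAsFactors = FALSE)
  class(out) <- c("prob_output", class(out))
  out
}
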