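# Internal helpers shared across modules.

#' @keywords internal
"_PACKAGE"

CLASS_LEVELS <- c("healthy", "bruised")

#' Derive a child seed from a master seed
#'
#' Deterministic integer mixing so that independent pseudo-random streams
#' (per instrument, per stage) can be split from one master seed. Result is
#' always a valid 32-bit R integer.
#'
#' @param seed master seed (integer).
#' @param offset stream index (integer).
#' @return an integer seed.
#' @export
derive_seed <- function(seed, offset) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.numeric(offset))
  as.integer((abs(seed) %% 1e6) * 1009 + (offset %% 1e5) * 9973 + 17) %% 2147483489L
}

# Nearest-band lookup; ties go to the lower (shorter-wavelength) band.
nearest_band <- function(wavelengths, nm) {
  d <- abs(wavelengths - nm)
  which(d == min(d))[1L]
}

# Stratified fold assignment: every fold gets a near-equal share of each
# class. Returns an integer vector of fold ids in 1..k.
stratified_folds <- function(labels, k, seed) {
  stopifnot(k >= 2L, length(labels) >= k)
  labels <- as.character(labels)
  fold <- integer(length(labels))
  set.seed(seed)
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    idx <- idx[sample.int(length(idx))]
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

# Hard label from healthy-class probability; tie (p == 0.5) -> bruised,
# the detection-positive class.
label_from_prob <- function(p_healthy) {
  ifelse(p_healthy > 0.5, "healthy", "bruised")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
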