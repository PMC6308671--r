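# Autoscaling: per-column standardization with training statistics,
# used both inside PLS-DA and to compensate instrument scale differences
# before data-level fusion.

SD_FLOOR <- 1e-8

#' Fit / apply an autoscaler
#'
#' `fit_scaler` learns per-column mean and standard deviation (n-1
#' denominator) on a training table; `apply_scaler` standardizes any table
#' on the same band grid with those statistics. Constant columns get
#' their sd clamped to a small floor (with a warning) so they transform
#' to zeros rather than NaN.
#'
#' @param train,table a [spectrum_table()] (`train` needs >= 2 rows).
#' @param scaler a fitted `scaler`.
#' @return `fit_scaler`: a `scaler`; `apply_scaler`: a transformed
#'   `spectrum_table`.
#' @export
fit_scaler <- function(train) {
  stopifnot(inherits(train, "spectrum_table"), nrow(train$values) >= 2L)
  mu <- colMeans(train$values)
  sd <- apply(train$values, 2, stats::sd)
  if (any(sd < SD_FLOOR)) {
    warning("fit_scaler: constant column(s); sd clamped to floor")
    sd <- pmax(sd, SD_FLOOR)
  }
  structure(list(mean = mu, sd = sd,
                 bands = colnames(train$values)),
            class = "scaler")
}

#' @rdname fit_scaler
#' @export
apply_scaler <- function(scaler, table) {
  stopifnot(inherits(scaler, "scaler"), inherits(table, "spectrum_table"))
  if (!identical(colnames(table$values), scaler$bands)) {
    stop("apply_scaler: table bands do not match the scaler's training bands")
  }
  vals <- sweep(sweep(table$values, 2, scaler$mean), 2, scaler$sd, "/")
  spectrum_table(vals, table$wavelengths, table$sample_id,
                 label = table$label, instrument = table$instrument)
}
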