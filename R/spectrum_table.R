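# SpectrumTable: the central container, a samples x wavelengths matrix of
# mean reflectance with sample ids, per-column wavelengths/instrument tags
# and an optional two-class label.

#' Construct a spectrum table
#'
#' A `spectrum_table` holds mean reflectance spectra: one row per sample,
#' one column per wavelength. Columns carry the wavelength in nm and the
#' instrument that measured them; fused tables may mix instruments, in
#' which case column names are namespaced as `"PB:850.8"` etc. Labels, when
#' present, are the two classes `"healthy"` and `"bruised"` (coded +1 / -1
#' for discriminant regression).
#'
#' @param values numeric matrix, samples x wavelengths, no missing values.
#' @param wavelengths numeric vector of band centres in nm, one per column.
#'   Must be strictly increasing within each instrument.
#' @param sample_id character vector of unique sample identifiers.
#' @param label optional character vector in `c("healthy","bruised")`.
#' @param instrument instrument tag, length 1 or one per column.
#' @return an object of class `spectrum_table`.
#' @export
spectrum_table <- function(values, wavelengths, sample_id,
                           label = NULL, instrument = "PB") {
  values <- as.matrix(values)
  if (anyNA(values) || !all(is.finite(values))) {
    stop("spectrum_table: values must be finite and non-missing")
  }
  if (length(wavelengths) != ncol(values)) {
    stop("spectrum_table: one wavelength per column required")
  }
  if (length(sample_id) != nrow(values)) {
    stop("spectrum_table: one sample_id per row required")
  }
  if (anyDuplicated(sample_id)) stop("spectrum_table: duplicate sample ids")
  instrument <- rep_len(as.character(instrument), ncol(values))
  for (ins in unique(instrument)) {
    w <- wavelengths[instrument == ins]
    if (length(w) > 1L && any(diff(w) <= 0)) {
      stop("spectrum_table: wavelengths must be strictly increasing per instrument")
    }
  }
  if (!is.null(label)) {
    label <- as.character(label)
    if (length(label) != nrow(values)) {
      stop("spectrum_table: one label per row required")
    }
    if (!all(label %in% CLASS_LEVELS)) {
      stop("spectrum_table: labels must be 'healthy' or 'bruised'")
    }
  }
  colnames(values) <- band_names(wavelengths, instrument)
  rownames(values) <- sample_id
  structure(
    list(values = values, wavelengths = as.numeric(wavelengths),
         sample_id = as.character(sample_id), label = label,
         instrument = instrument),
    class = "spectrum_table"
  )
}

band_names <- function(wavelengths, instrument) {
  paste0(instrument, ":", formatC(wavelengths, format = "f", digits = 1))
}

#' @export
print.spectrum_table <- function(x, ...) {
  cat(sprintf("<spectrum_table> %d samples x %d bands (%s)\n",
              nrow(x$values), ncol(x$values),
              paste(unique(x$instrument), collapse = "+")))
  rng <- range(x$wavelengths)
  cat(sprintf("  wavelengths %.1f-%.1f nm\n", rng[1], rng[2]))
  if (!is.null(x$label)) {
    tab <- table(factor(x$label, CLASS_LEVELS))
    cat(sprintf("  labels: %d healthy / %d bruised\n", tab[1], tab[2]))
  }
  invisible(x)
}

#' @export
dim.spectrum_table <- function(x) dim(x$values)

# Row subsetting that keeps ids and labels aligned.
st_rows <- function(table, idx) {
  spectrum_table(table$values[idx, , drop = FALSE],
                 table$wavelengths, table$sample_id[idx],
                 label = if (!is.null(table$label)) table$label[idx],
                 instrument = table$instrument)
}

# Column subsetting by index, preserving order given.
st_cols <- function(table, idx) {
  spectrum_table(table$values[, idx, drop = FALSE],
                 table$wavelengths[idx], table$sample_id,
                 label = table$label, instrument = table$instrument[idx])
}

#' Trim a spectrum table to a wavelength range
#'
#' Keeps columns with `lo <= wavelength <= hi`, preserving column order.
#' Used e.g. to discard the noisy edges of a push-broom acquisition and
#' keep only 480-960 nm.
#'
#' @param table a [spectrum_table()].
#' @param lo,hi range bounds in nm, `lo < hi`.
#' @return a `spectrum_table` with the surviving columns.
#' @export
trim_range <- function(table, lo, hi) {
  stopifnot(inherits(table, "spectrum_table"), lo < hi)
  keep <- which(table$wavelengths >= lo & table$wavelengths <= hi)
  if (length(keep) == 0L) {
    stop(sprintf("trim_range: no bands in [%g, %g] nm", lo, hi))
  }
  st_cols(table, keep)
}

#' Write / read a spectrum table as CSV
#'
#' Layout: first column `sample_id`, second `label` (empty string when
#' unlabeled), remaining columns named by wavelength in nm with one
#' decimal, namespaced by instrument.
#'
#' @param table a [spectrum_table()].
#' @param path file path.
#' @return `write_spectrum_csv` returns `path` invisibly;
#'   `read_spectrum_csv` returns a `spectrum_table`.
#' @export
write_spectrum_csv <- function(table, path) {
  stopifnot(inherits(table, "spectrum_table"))
  df <- data.frame(sample_id = table$sample_id,
                   label = table$label %||% rep("", nrow(table$values)),
                   table$values, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_spectrum_csv
#' @export
read_spectrum_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  stopifnot(all(c("sample_id", "label") %in% names(df)[1:2]))
  bands <- names(df)[-(1:2)]
  has_ns <- grepl(":", bands, fixed = TRUE)
  instrument <- ifelse(has_ns, sub(":.*$", "", bands), "PB")
  wl <- as.numeric(sub("^.*:", "", bands))
  lab <- as.character(df$label)
  if (all(lab == "" | is.na(lab))) lab <- NULL
  spectrum_table(as.matrix(df[, -(1:2), drop = FALSE]), wl,
                 as.character(df$sample_id), label = lab,
                 instrument = instrument)
}
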