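# Minimal ENVI cube I/O: ASCII .hdr plus BIL-interleaved float32 binary,
# the subset of the format used by the two imaging systems. Only
# interleave=bil, data type=4 (float32), byte order=0 is supported.

#' Write a hypercube in ENVI format
#'
#' Writes `<path>.hdr` (ASCII header with the wavelength list) and
#' `<path>.bil` (band-interleaved-by-line float32, little endian).
#'
#' @param cube a [hypercube()].
#' @param path output path stem (no extension).
#' @return `path`, invisibly.
#' @export
write_envi <- function(cube, path) {
  stopifnot(inherits(cube, "hypercube"))
  d <- dim(cube$values)  # rows(lines) x cols(samples) x bands
  hdr <- c(
    "ENVI",
    "description = {hsifuse synthetic cube}",
    sprintf("samples = %d", d[2]),
    sprintf("lines = %d", d[1]),
    sprintf("bands = %d", d[3]),
    "header offset = 0",
    "file type = ENVI Standard",
    "data type = 4",
    "interleave = bil",
    "byte order = 0",
    sprintf("instrument = %s", cube$instrument),
    sprintf("wavelength = {%s}",
            paste(formatC(cube$wavelengths, format = "f", digits = 1),
                  collapse = ", "))
  )
  writeLines(hdr, paste0(path, ".hdr"))
  con <- file(paste0(path, ".bil"), "wb")
  on.exit(close(con))
  # BIL layout: for each line, all bands of that line, samples fastest.
  for (line in seq_len(d[1])) {
    slab <- matrix(cube$values[line, , ], nrow = d[2])  # samples x bands
    writeBin(as.numeric(slab), con, size = 4, endian = "little")
  }
  invisible(path)
}

#' Read an ENVI cube written by [write_envi()]
#'
#' @param path path stem (no extension) or path to the `.hdr` file.
#' @return a [hypercube()].
#' @export
read_envi <- function(path) {
  path <- sub("\\.(hdr|bil)$", "", path)
  hdr_lines <- readLines(paste0(path, ".hdr"))
  hdr <- paste(hdr_lines, collapse = "\n")
  get_int <- function(key) {
    m <- regmatches(hdr, regexpr(sprintf("%s\\s*=\\s*[0-9]+", key), hdr))
    as.integer(sub(".*=\\s*", "", m))
  }
  samples <- get_int("samples"); lines <- get_int("lines")
  bands <- get_int("bands")
  interleave <- sub(".*=\\s*", "", regmatches(
    hdr, regexpr("interleave\\s*=\\s*\\w+", hdr)))
  dtype <- get_int("data type")
  if (!identical(tolower(interleave), "bil") || dtype != 4L) {
    stop("read_envi: only interleave=bil, data type=4 supported")
  }
  wl_block <- regmatches(hdr, regexpr("wavelength\\s*=\\s*\\{[^}]*\\}", hdr))
  wl <- as.numeric(strsplit(gsub(".*\\{|\\}", "", wl_block), ",")[[1]])
  ins_m <- regmatches(hdr, regexpr("instrument\\s*=\\s*\\S+", hdr))
  instrument <- if (length(ins_m)) sub(".*=\\s*", "", ins_m) else "PB"
  raw <- readBin(paste0(path, ".bil"), what = "numeric", size = 4,
                 n = samples * lines * bands, endian = "little")
  vals <- array(NA_real_, c(lines, samples, bands))
  i <- 1L
  for (line in seq_len(lines)) {
    for (b in seq_len(bands)) {
      vals[line, , b] <- raw[i:(i + samples - 1L)]
      i <- i + samples
    }
  }
  hypercube(vals, wl, instrument)
}
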