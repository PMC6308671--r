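# Hypercube container and cube-level preprocessing: reflectance
# calibration, band-threshold masking with small-object removal, sepal
# exclusion via the 1200/1075 nm band ratio, and mean-spectrum extraction.

#' Construct a hypercube
#'
#' @param values numeric array, rows x cols x bands, finite.
#' @param wavelengths strictly increasing band centres in nm.
#' @param instrument instrument tag (e.g. `"PB"` or `"LCTF"`).
#' @return an object of class `hypercube`.
#' @export
hypercube <- function(values, wavelengths, instrument = "PB") {
  values <- as.array(values)
  if (length(dim(values)) != 3L) stop("hypercube: values must be rows x cols x bands")
  if (!all(is.finite(values))) stop("hypercube: values must be finite")
  if (length(wavelengths) != dim(values)[3L]) {
    stop("hypercube: one wavelength per band required")
  }
  if (length(wavelengths) > 1L && any(diff(wavelengths) <= 0)) {
    stop("hypercube: wavelengths must be strictly increasing")
  }
  structure(list(values = values, wavelengths = as.numeric(wavelengths),
                 instrument = instrument),
            class = "hypercube")
}

#' @export
print.hypercube <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<hypercube> %d x %d pixels x %d bands (%s), %.1f-%.1f nm\n",
              d[1], d[2], d[3], x$instrument,
              min(x$wavelengths), max(x$wavelengths)))
  invisible(x)
}

# Single-band image at the nearest wavelength (ties to lower band).
cube_band <- function(cube, nm) {
  cube$values[, , nearest_band(cube$wavelengths, nm)]
}

#' Reflectance calibration from white and dark references
#'
#' Computes relative reflectance `(raw - dark) / (white - dark)` per pixel
#' and band, removing illumination non-uniformity and detector dark
#' current. All three cubes must share shape and wavelength axis.
#'
#' @param raw,white,dark [hypercube()]s of identical shape and wavelengths.
#' @param eps pixels with `white - dark < eps` are invalid (the ratio is
#'   undefined there) and raise an error naming band and pixel.
#' @return a calibrated `hypercube`.
#' @export
calibrate <- function(raw, white, dark, eps = 1e-12) {
  stopifnot(inherits(raw, "hypercube"), inherits(white, "hypercube"),
            inherits(dark, "hypercube"))
  if (!identical(dim(raw$values), dim(white$values)) ||
      !identical(dim(raw$values), dim(dark$values))) {
    stop("calibrate: cubes must share the same shape")
  }
  if (!isTRUE(all.equal(raw$wavelengths, white$wavelengths)) ||
      !isTRUE(all.equal(raw$wavelengths, dark$wavelengths))) {
    stop("calibrate: cubes must share the same wavelength axis")
  }
  denom <- white$values - dark$values
  bad <- which(denom < eps, arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    b <- bad[1L, ]
    stop(sprintf(
      "calibrate: white == dark at pixel (%d, %d), band %.1f nm",
      b[1], b[2], raw$wavelengths[b[3]]))
  }
  hypercube((raw$values - dark$values) / denom, raw$wavelengths,
            raw$instrument)
}

#' Build a pixel mask by band thresholding
#'
#' Thresholds the single-band image nearest `band_nm` (fruit is bright
#' against the dark background at 820 nm / 1075 nm), then removes
#' connected components (8-connectivity) smaller than `min_area` pixels --
#' the "erosion by removing small objects" cleanup -- and labels the
#' surviving components.
#'
#' @param cube a [hypercube()].
#' @param band_nm wavelength of the thresholding band, in nm; must lie
#'   within the cube's wavelength range.
#' @param threshold reflectance threshold; pixels strictly above it are
#'   foreground.
#' @param min_area components with fewer pixels are discarded (default 50).
#' @return a `pixel_mask`: logical matrix `mask` plus integer `labels`
#'   (0 = background, 1..K = objects).
#' @export
make_mask <- function(cube, band_nm, threshold, min_area = 50) {
  stopifnot(inherits(cube, "hypercube"))
  if (band_nm < min(cube$wavelengths) || band_nm > max(cube$wavelengths)) {
    stop("make_mask: band_nm outside the cube's wavelength range")
  }
  img <- cube_band(cube, band_nm)
  fg <- img > threshold
  lab <- label_components(fg)
  if (max(lab) > 0L) {
    sizes <- tabulate(lab[lab > 0L])
    drop <- which(sizes < min_area)
    if (length(drop) > 0L) lab[lab %in% drop] <- 0L
    # relabel compactly, preserving discovery order
    kept <- sort(unique(lab[lab > 0L]))
    lab <- match(lab, kept, nomatch = 0L)
    dim(lab) <- dim(fg)
  }
  if (!any(lab > 0L)) warning("make_mask: empty mask (no pixel survived)")
  pixel_mask(lab > 0L, lab)
}

pixel_mask <- function(mask, labels) {
  stopifnot(is.logical(mask), identical(dim(mask), dim(labels)))
  structure(list(mask = mask, labels = labels), class = "pixel_mask")
}

#' @export
print.pixel_mask <- function(x, ...) {
  cat(sprintf("<pixel_mask> %d x %d, %d objects, %d foreground pixels\n",
              nrow(x$mask), ncol(x$mask), max(x$labels), sum(x$mask)))
  invisible(x)
}

# Two-pass style connected-component labeling with 8-connectivity,
# implemented as iterative flood fill (cubes here are small).
label_components <- function(fg) {
  nr <- nrow(fg); nc <- ncol(fg)
  lab <- matrix(0L, nr, nc)
  cur <- 0L
  offs <- expand.grid(dr = -1:1, dc = -1:1)
  offs <- offs[!(offs$dr == 0 & offs$dc == 0), ]
  for (start in which(fg)) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    queue <- start
    lab[start] <- cur
    while (length(queue) > 0L) {
      px <- queue[length(queue)]
      queue <- queue[-length(queue)]
      r <- ((px - 1L) %% nr) + 1L
      c <- ((px - 1L) %/% nr) + 1L
      rr <- r + offs$dr; cc <- c + offs$dc
      ok <- rr >= 1L & rr <= nr & cc >= 1L & cc <= nc
      nb <- (cc[ok] - 1L) * nr + rr[ok]
      nb <- nb[fg[nb] & lab[nb] == 0L]
      if (length(nb) > 0L) {
        lab[nb] <- cur
        queue <- c(queue, nb)
      }
    }
  }
  lab
}

#' Remove sepal pixels from a mask by band ratio
#'
#' The vestigial sepals around the calyx end have a reflectance spectrum
#' resembling bruised tissue; they are identified by an elevated
#' 1200 nm / 1075 nm two-band ratio and removed from the mask so they do
#' not contaminate the mean spectrum.
#'
#' @param cube a [hypercube()] covering 1075 and 1200 nm.
#' @param mask a `pixel_mask` on the same spatial grid.
#' @param ratio_threshold pixels with ratio strictly above this are
#'   removed.
#' @return the filtered `pixel_mask` (labels preserved where kept).
#' @export
exclude_sepals <- function(cube, mask, ratio_threshold) {
  stopifnot(inherits(cube, "hypercube"), inherits(mask, "pixel_mask"))
  wl <- cube$wavelengths
  for (need in c(1075, 1200)) {
    if (min(abs(wl - need)) > 25) {
      stop(sprintf("exclude_sepals: cube does not cover %d nm", need))
    }
  }
  ratio <- cube_band(cube, 1200) / cube_band(cube, 1075)
  keep <- mask$mask & !(ratio > ratio_threshold)
  lab <- mask$labels
  lab[!keep] <- 0L
  pixel_mask(keep, lab)
}

#' Mean reflectance spectrum per masked object
#'
#' Averages the pixel spectra of each labeled object into one row of a
#' [spectrum_table()].
#'
#' @param cube a [hypercube()].
#' @param mask a `pixel_mask` with at least one labeled object.
#' @param ids optional character ids, one per object (default `obj1..K`).
#' @return a `spectrum_table` with one row per object.
#' @export
mean_spectrum <- function(cube, mask, ids = NULL) {
  stopifnot(inherits(cube, "hypercube"), inherits(mask, "pixel_mask"))
  K <- max(mask$labels)
  if (K < 1L) stop("mean_spectrum: mask has no labeled object")
  ids <- ids %||% paste0("obj", seq_len(K))
  stopifnot(length(ids) == K)
  nb <- length(cube$wavelengths)
  out <- matrix(NA_real_, K, nb)
  flat <- matrix(cube$values, ncol = nb)  # pixels x bands
  for (k in seq_len(K)) {
    px <- which(mask$labels == k)
    if (length(px) == 0L) stop(sprintf("mean_spectrum: object %d is empty", k))
    out[k, ] <- colMeans(flat[px, , drop = FALSE])
  }
  spectrum_table(out, cube$wavelengths, ids, instrument = cube$instrument)
}

#' Write a pixel mask as plain-text PGM plus a label CSV
#'
#' The mask goes to `<path>.pgm` (P2, 0/255) and component labels to
#' `<path>_labels.csv` (row, col, label).
#'
#' @param mask a `pixel_mask`.
#' @param path output path stem.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "pixel_mask"))
  img <- ifelse(t(mask$mask), 255L, 0L)  # PGM is row-major, width first
  con <- file(paste0(path, ".pgm"), "w")
  on.exit(close(con))
  writeLines(c("P2", paste(ncol(mask$mask), nrow(mask$mask)), "255"), con)
  utils::write.table(img, con, row.names = FALSE, col.names = FALSE)
  idx <- which(mask$labels > 0L, arr.ind = TRUE)
  utils::write.csv(
    data.frame(row = idx[, 1], col = idx[, 2],
               label = mask$labels[idx]),
    paste0(path, "_labels.csv"), row.names = FALSE)
  invisible(path)
}
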