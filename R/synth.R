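# Seeded synthetic data emulating the two imaging systems: a push-broom
# VIS/NIR instrument (480-960 nm) and an LCTF SWIR instrument
# (965-1655 nm). The generator produces paired mean-spectrum tables with
# the qualitative structure the analysis assumes: healthy reflectance
# above bruised everywhere >= 700 nm, no class difference below 700 nm,
# water-absorption dips near 980 / 1200 / 1460 nm, a hard "calyx-like"
# bruised subgroup with attenuated spectral effect, and complementary
# class information split between the instruments.

#' Synthetic-data configuration
#'
#' Bundles every knob of the generator with the defaults of the emulated
#' study design: 120 healthy + 120 bruise-treated calibration samples, a
#' 102-band push-broom grid over 480-960 nm, a 139-band LCTF grid at 5 nm
#' steps over 965-1655 nm, water dips at 980/1200/1460 nm, a 0.12
#' reflectance-unit drop for fully bruised tissue in the 700-1650 nm
#' window, and a 25% bruise-ratio labeling threshold.
#'
#' The two-instrument complementarity works through two per-sample latent
#' severity components `s_A = s + d`, `s_B = s - d`, where the overall
#' severity `s ~ Beta(5, 2)` drives the bruise-ratio ground truth and
#' `d ~ N(0, factor_sd)` (clipped so both components stay in `[0, 1]`) is
#' the part of the tissue signal seen differently by the two detectors.
#' Instrument X observes `(1 - rho) * s + rho * s_X = s +/- rho * d`. At
#' `rho = 0` both instruments see the label-determining severity exactly;
#' for `rho > 0` each single instrument sees a corrupted version while
#' the average of the two recovers `s` exactly, so fusing the
#' instruments is strictly better than either alone. With a fixed
#' severity, `d = 0` and the spectra are deterministic up to noise.
#'
#' @param n_healthy,n_bruised numbers of control and bruise-treated
#'   samples (> 0). Note treated samples whose bruise ratio falls below
#'   `ratio_threshold` are labeled healthy, as in the reference protocol.
#' @param seed master seed; all streams are derived from it.
#' @param band_grid_pb,band_grid_lctf wavelength grids (nm), strictly
#'   increasing, at least 2 bands each.
#' @param dip_centers,dip_widths,dip_depths water-absorption dip
#'   parameters (nm, nm, reflectance units).
#' @param effect_size reflectance drop for fully bruised tissue in the
#'   700-1650 nm window.
#' @param noise_sd_pb,noise_sd_lctf additive band noise sd per instrument.
#' @param edge_noise detector noise inflation at the ends of each band
#'   grid: the per-band noise sd is multiplied by
#'   `1 + edge_noise * exp(-distance_to_grid_edge / 30 nm)` (default 2,
#'   i.e. 3x noise at the extreme bands; 0 disables). Emulates the low
#'   signal-to-noise ratio at the edges of a detector's sensitive range.
#' @param scatter_sd sd of the per-sample flat multiplicative scatter
#'   factor.
#' @param bio_sd sd of each mode of the smooth per-sample multiplicative
#'   variability field (28 sine modes spanning 480-1655 nm, shared by the
#'   two instruments; default 0.03). Emulates sample-to-sample
#'   wavelength-dependent scattering differences -- the kind of
#'   structured nuisance that multiplicative scatter correction exists
#'   for -- and is what makes wavelength selection worthwhile relative
#'   to full-spectrum models.
#' @param rho complementarity in `[0, 1]`: fraction of the class signal
#'   carried by the instrument-specific severity components.
#' @param factor_sd sd of the latent factor split `d` between the two
#'   instruments' views of the severity (default 0.15).
#' @param calyx_fraction share of treated samples in the hard calyx-like
#'   subgroup; their spectral effect is attenuated by `gamma`.
#' @param gamma attenuation factor in `(0, 1)` for the calyx subgroup.
#' @param ratio_threshold bruise-ratio labeling threshold (default 0.25).
#' @param severity `NULL` for random Beta(5, 2) severity components, or a
#'   fixed value in `[0, 1]` applied to every treated sample.
#' @return a `synth_config` list.
#' @export
synth_config <- function(n_healthy = 120, n_bruised = 120, seed = 1,
                         band_grid_pb = seq(480, 960, length.out = 102),
                         band_grid_lctf = seq(965, 1655, by = 5),
                         dip_centers = c(980, 1200, 1460),
                         dip_widths = c(25, 35, 45),
                         dip_depths = c(0.08, 0.10, 0.16),
                         effect_size = 0.12,
                         noise_sd_pb = 0.01, noise_sd_lctf = 0.01,
                         edge_noise = 2,
                         scatter_sd = 0.05, bio_sd = 0.03,
                         rho = 0.5, factor_sd = 0.15,
                         calyx_fraction = 1 / 3, gamma = 0.4,
                         ratio_threshold = 0.25, severity = NULL) {
  stopifnot(n_healthy > 0, n_bruised > 0,
            noise_sd_pb >= 0, noise_sd_lctf >= 0, edge_noise >= 0,
            scatter_sd >= 0, bio_sd >= 0,
            rho >= 0, rho <= 1, factor_sd >= 0, gamma >= 0, gamma <= 1,
            calyx_fraction >= 0, calyx_fraction <= 1,
            effect_size >= 0, ratio_threshold > 0)
  for (g in list(band_grid_pb, band_grid_lctf)) {
    if (length(g) < 2L) stop("synth_config: band grid needs >= 2 bands")
    if (any(diff(g) <= 0)) stop("synth_config: band grid must be strictly increasing")
  }
  if (!is.null(severity)) stopifnot(severity >= 0, severity <= 1)
  structure(list(
    n_healthy = as.integer(n_healthy), n_bruised = as.integer(n_bruised),
    seed = as.integer(seed), band_grid_pb = band_grid_pb,
    band_grid_lctf = band_grid_lctf, dip_centers = dip_centers,
    dip_widths = dip_widths, dip_depths = dip_depths,
    effect_size = effect_size, noise_sd_pb = noise_sd_pb,
    noise_sd_lctf = noise_sd_lctf, edge_noise = edge_noise,
    scatter_sd = scatter_sd, bio_sd = bio_sd, rho = rho,
    factor_sd = factor_sd,
    calyx_fraction = calyx_fraction, gamma = gamma,
    ratio_threshold = ratio_threshold, severity = severity
  ), class = "synth_config")
}

#' Healthy baseline reflectance curve
#'
#' Smooth logistic rise through the red edge (480 -> 900 nm), a gently
#' declining SWIR plateau, minus Gaussian-shaped water-absorption dips.
#'
#' @param wavelengths nm vector.
#' @param config a [synth_config()].
#' @return reflectance vector.
#' @export
baseline_curve <- function(wavelengths, config = synth_config()) {
  r <- 0.12 + 0.42 * stats::plogis((wavelengths - 640) / 60) -
    0.06 * stats::plogis((wavelengths - 1300) / 150)
  for (k in seq_along(config$dip_centers)) {
    r <- r - config$dip_depths[k] *
      exp(-(wavelengths - config$dip_centers[k])^2 /
            (2 * config$dip_widths[k]^2))
  }
  r
}

#' Bruise spectral window
#'
#' The gating factor of the bruise effect: exactly 0 below 700 nm (no
#' class difference in the visible) rising smoothly to 1 in the
#' NIR/SWIR.
#'
#' @param wavelengths nm vector.
#' @return weights in `[0, 1]`.
#' @export
bruise_window <- function(wavelengths) {
  ifelse(wavelengths < 700, 0, 1 - exp(-((wavelengths - 700) / 60)^2))
}

# water-related absorption features where bruising expresses most
# strongly: NIR overtones (740, 840, 950 nm) and the SWIR water bands
# (980, 1200, 1460 nm)
WATER_BANDS <- data.frame(center = c(740, 840, 950, 980, 1200, 1460),
                          width = c(15, 20, 25, 20, 35, 45))

#' Bruise spectral effect profile
#'
#' The full wavelength weight of the bruise-induced reflectance drop:
#' zero in the visible, and in the NIR/SWIR strongest near the
#' water-related absorption features (bruising mainly redistributes
#' water), with a floor of 0.25 of the peak effect elsewhere in the
#' window (floor 0.05 of the peak effect). This concentration is what
#' makes a small number of selected wavelengths competitive with the
#' full spectrum.
#'
#' @param wavelengths nm vector.
#' @return weights in `[0, 1]`.
#' @export
bruise_profile <- function(wavelengths) {
  bump <- numeric(length(wavelengths))
  for (k in seq_len(nrow(WATER_BANDS))) {
    bump <- bump + exp(-(wavelengths - WATER_BANDS$center[k])^2 /
                         (2 * WATER_BANDS$width[k]^2))
  }
  bruise_window(wavelengths) * (0.05 + 0.95 * pmin(bump, 1))
}

#' Generate paired mean-spectrum tables for the two instruments
#'
#' Draws per-sample ground truth (severity components, bruise ratio,
#' subgroup, label), then renders one spectrum per sample per instrument:
#' `(baseline - amplitude * window) * scatter + noise`, with amplitude
#' `sev_X * gamma_j * effect_size` where `sev_X` is the instrument's view
#' of the severity (see [synth_config()]). Each instrument has its own
#' pseudo-random stream split from the master seed.
#'
#' @param config a [synth_config()].
#' @return a list with `pb` and `lctf` [spectrum_table()]s (identical
#'   sample ids and order) and `truth`, a data frame with `sample_id`,
#'   `severity`, `bruise_ratio`, `label`, `subgroup`.
#' @export
generate_mean_spectra <- function(config = synth_config()) {
  stopifnot(inherits(config, "synth_config"))
  n_h <- config$n_healthy; n_b <- config$n_bruised
  n <- n_h + n_b
  ids <- sprintf("S%04d", seq_len(n))
  treated <- c(rep(FALSE, n_h), rep(TRUE, n_b))

  set.seed(derive_seed(config$seed, 0L))  # truth stream
  if (is.null(config$severity)) {
    sev <- stats::rbeta(n, 5, 2)
    d <- stats::rnorm(n, 0, config$factor_sd)
    d <- sign(d) * pmin(abs(d), pmin(sev, 1 - sev))  # keep s +/- d in [0,1]
  } else {
    sev <- rep(config$severity, n)
    d <- rep(0, n)
  }
  sev[!treated] <- 0; d[!treated] <- 0
  s_a <- sev + d; s_b <- sev - d
  ratio <- sev * stats::runif(n, 0.6, 1.0)
  label <- ifelse(ratio >= config$ratio_threshold, "bruised", "healthy")
  subgroup <- rep("control", n)
  if (n_b > 0L) {
    pos <- sample(c("stem", "equator", "calyx"), n_b, replace = TRUE,
                  prob = c((1 - config$calyx_fraction) / 2,
                           (1 - config$calyx_fraction) / 2,
                           config$calyx_fraction))
    subgroup[treated] <- pos
  }
  atten <- ifelse(subgroup == "calyx", config$gamma, 1)

  sev_pb <- (1 - config$rho) * sev + config$rho * s_a
  sev_lctf <- (1 - config$rho) * sev + config$rho * s_b

  # smooth per-sample multiplicative variability, shared by both
  # instruments (same berry, same tissue): 28 sine modes over the full
  # 480-1655 nm span, drawn in the truth stream
  bio_coef <- matrix(stats::rnorm(n * 28, 0, config$bio_sd), n)
  bio_field <- function(grid) {
    phi <- sapply(1:28, function(m) sin(m * pi * (grid - 480) / (1655 - 480)))
    bio_coef %*% t(phi)  # n x length(grid)
  }

  render <- function(grid, sev_inst, noise_sd, stream) {
    base <- baseline_curve(grid, config)
    w <- bruise_profile(grid)
    amp <- sev_inst * atten * config$effect_size
    mu <- matrix(rep(base, each = n), n) - outer(amp, w)
    sd_band <- noise_sd * (1 + config$edge_noise *
                             (exp(-(grid - min(grid)) / 30) +
                                exp(-(max(grid) - grid) / 30)))
    mult <- 1 + bio_field(grid)
    set.seed(derive_seed(config$seed, stream))
    scatter <- 1 + stats::rnorm(n, 0, config$scatter_sd)
    mu * mult * scatter +
      matrix(stats::rnorm(n * length(grid), 0, rep(sd_band, each = n)), n)
  }

  pb <- spectrum_table(render(config$band_grid_pb, sev_pb,
                              config$noise_sd_pb, 1L),
                       config$band_grid_pb, ids, label, instrument = "PB")
  lctf <- spectrum_table(render(config$band_grid_lctf, sev_lctf,
                                config$noise_sd_lctf, 2L),
                         config$band_grid_lctf, ids, label,
                         instrument = "LCTF")
  truth <- data.frame(sample_id = ids, severity = sev, bruise_ratio = ratio,
                      label = label, subgroup = subgroup,
                      stringsAsFactors = FALSE)
  list(pb = pb, lctf = lctf, truth = truth)
}

#' Generate a raw/white/dark cube triplet with known ground truth
#'
#' Builds a small synthetic acquisition for exercising the cube
#' preprocessing chain: disk-shaped "fruit" objects of known true
#' reflectance on a dark background, a spatially non-uniform white
#' reference, a dark current image, and (optionally) a sepal-like ring on
#' the first object whose 1200/1075 nm band ratio is elevated. The raw
#' cube is constructed by inverting the reflectance calibration, so
#' calibrating the triplet recovers the truth exactly at zero noise.
#'
#' @param config a [synth_config()] (supplies the seed).
#' @param shape `c(rows, cols)`, each >= 8.
#' @param wavelengths band grid in nm (default covers 820/1075/1200 nm).
#' @param n_objects number of disks (may be 0).
#' @param radius disk radius in pixels.
#' @param object_reflectance true reflectance of object body pixels
#'   (scalar, applied at every band).
#' @param background_reflectance true background reflectance.
#' @param sepal if `TRUE`, the first object gets a one-pixel-wide outer
#'   ring with `sepal_ratio`-elevated 1200 nm reflectance.
#' @param sepal_ratio 1200/1075 band ratio of ring pixels (body pixels
#'   have ratio 1).
#' @param noise_sd additive noise on the raw cube (default 0).
#' @return a list with `raw`, `white`, `dark` [hypercube()]s, `truth_mask`
#'   (a `pixel_mask` of object bodies incl. ring), `sepal_mask` (logical
#'   matrix), and `reflectance` (the true reflectance array).
#' @export
generate_cube_triplet <- function(config = synth_config(), shape = c(32, 32),
                                  wavelengths = seq(700, 1400, by = 25),
                                  n_objects = 2, radius = 6,
                                  object_reflectance = 0.5,
                                  background_reflectance = 0.05,
                                  sepal = FALSE, sepal_ratio = 1.3,
                                  noise_sd = 0) {
  stopifnot(inherits(config, "synth_config"))
  if (length(shape) != 2L || any(shape < 8)) {
    stop("generate_cube_triplet: shape must be >= 8 x 8")
  }
  nr <- as.integer(shape[1]); nc <- as.integer(shape[2])
  nb <- length(wavelengths)
  set.seed(derive_seed(config$seed, 3L))

  labels <- matrix(0L, nr, nc)
  sepal_mask <- matrix(FALSE, nr, nc)
  refl <- array(background_reflectance, c(nr, nc, nb))
  if (n_objects > 0L) {
    # place disk centres on a jittered grid
    per_row <- ceiling(sqrt(n_objects))
    centres <- expand.grid(
      r = seq(radius + 2, nr - radius - 1, length.out = per_row),
      c = seq(radius + 2, nc - radius - 1, length.out = per_row))
    centres <- centres[seq_len(n_objects), , drop = FALSE]
    rr <- row(labels); cc <- col(labels)
    for (k in seq_len(n_objects)) {
      d2 <- (rr - centres$r[k])^2 + (cc - centres$c[k])^2
      disk <- d2 <= radius^2
      labels[disk] <- k
      for (b in seq_len(nb)) {
        slice <- refl[, , b]
        slice[disk] <- object_reflectance
        refl[, , b] <- slice
      }
      if (sepal && k == 1L) {
        ring <- d2 <= radius^2 & d2 > (radius - 1.5)^2
        sepal_mask <- sepal_mask | ring
      }
    }
    if (any(sepal_mask)) {
      b1200 <- nearest_band(wavelengths, 1200)
      slice <- refl[, , b1200]
      slice[sepal_mask] <- object_reflectance * sepal_ratio
      refl[, , b1200] <- slice
    }
  }

  # illumination field: smooth bump, brighter in the centre
  rr <- row(matrix(0, nr, nc)); cc <- col(matrix(0, nr, nc))
  illum <- 0.75 + 0.2 * exp(-(((rr - nr / 2)^2 + (cc - nc / 2)^2) /
                                (0.5 * (nr^2 + nc^2))))
  dark_img <- matrix(0.04, nr, nc) + 0.005 * (rr / nr)
  white <- array(rep(illum, nb), c(nr, nc, nb))
  dark <- array(rep(dark_img, nb), c(nr, nc, nb))
  raw <- dark + refl * (white - dark)
  if (noise_sd > 0) raw <- raw + array(stats::rnorm(length(raw), 0, noise_sd), dim(raw))

  list(raw = hypercube(raw, wavelengths, "LCTF"),
       white = hypercube(white, wavelengths, "LCTF"),
       dark = hypercube(dark, wavelengths, "LCTF"),
       truth_mask = pixel_mask(labels > 0L, labels),
       sepal_mask = sepal_mask,
       reflectance = refl)
}
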