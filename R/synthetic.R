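# Seeded generator of four-class peach-like NIR reflectance spectra with
# known (planted) class-discriminative bands, plus a toy hypercube builder
# for exercising the calibration and ROI operations.

gaussian_bump <- function(wl, center, width) {
  exp(-((wl - center)^2) / (2 * width^2))
}

#' Configuration for the synthetic spectra generator
#'
#' The defaults emulate the qualitative structure of near-infrared peach
#' reflectance: a smooth base curve with peaks near 1100 and 1290 nm,
#' water-absorption troughs near 1190 and 1450 nm, an overall decreasing
#' trend, and three defect classes that each perturb a disjoint pair of
#' planted wavelengths on top of per-sample severity variation,
#' multiplicative scatter, baseline drift and white noise.
#'
#' @param n_per_class samples per class (named or in canonical order).
#' @param n_bands bands on the 900--1700 nm grid.
#' @param base_peaks,base_troughs base-curve feature centers (nm).
#' @param bump_width Gaussian width (sd, nm) of the base-curve features.
#' @param planted data frame with columns `class`, `center_nm`, `effect`
#'   (reflectance units) defining the class-discriminative bumps.
#' @param planted_width Gaussian width (sd, nm) of the planted bumps.
#' @param class_offsets small global reflectance offset per class.
#' @param severity_sd sd of the per-sample multiplicative severity factor
#'   applied to a defect's planted bumps (truncated at 0); models
#'   defect-severity variability and keeps the classes overlapping.
#' @param scatter_sd sd of the multiplicative scatter term `1 + N(0, sd)`.
#' @param baseline_sd sd of the additive per-sample baseline offset.
#' @param noise_sd sd of the per-band white noise.
#' @param seed RNG seed; samples draw from per-sample substreams so one
#'   class's count can change without reshuffling the others.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(n_per_class = c(intact = 50L,
                                             internal_injury = 50L,
                                             scab = 50L, rotten = 50L),
                             n_bands = 254L,
                             base_peaks = c(1100, 1290),
                             base_troughs = c(1190, 1450),
                             bump_width = 40,
                             planted = default_planted_bands(),
                             planted_width = 12,
                             class_offsets = c(intact = 0,
                                               internal_injury = -0.008,
                                               scab = 0.010,
                                               rotten = -0.016),
                             severity_sd = 0.45,
                             scatter_sd = 0.035,
                             baseline_sd = 0.018,
                             noise_sd = 0.010,
                             seed = 2023L) {
  if (any(c(severity_sd, scatter_sd, baseline_sd, noise_sd) < 0)) {
    stop("all sd parameters must be >= 0")
  }
  if (is.null(names(n_per_class))) names(n_per_class) <- peach_classes()
  if (!all(peach_classes() %in% names(n_per_class)) ||
      any(n_per_class < 1L)) {
    stop("n_per_class must name all four classes with counts >= 1")
  }
  grid <- wavelength_grid(n_bands)
  if (any(planted$center_nm < min(grid)) ||
      any(planted$center_nm > max(grid))) {
    stop("planted band center outside the wavelength grid")
  }
  structure(list(n_per_class = n_per_class[peach_classes()],
                 wavelengths = grid,
                 base_peaks = base_peaks, base_troughs = base_troughs,
                 bump_width = bump_width, planted = planted,
                 planted_width = planted_width,
                 class_offsets = class_offsets[peach_classes()],
                 severity_sd = severity_sd, scatter_sd = scatter_sd,
                 baseline_sd = baseline_sd, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

#' Default planted class-discriminative bands
#'
#' Each defect class perturbs a disjoint pair of wavelengths; signs mix
#' increased and decreased reflectance (tissue browning lowers it, dried
#' scab tissue raises it).
#'
#' @return Data frame with columns `class`, `center_nm`, `effect`.
#' @export
default_planted_bands <- function() {
  data.frame(
    class = rep(c("internal_injury", "scab", "rotten"), each = 2L),
    center_nm = c(980, 1350, 1050, 1550, 1240, 1620),
    effect = c(-0.045, 0.0405, 0.0495, -0.045, -0.054, 0.0495),
    stringsAsFactors = FALSE
  )
}

base_curve <- function(config) {
  wl <- config$wavelengths
  curve <- 0.80 - 0.30 * (wl - 900) / 800
  peak_amp <- c(0.15, 0.12)
  trough_amp <- c(0.12, 0.18)
  for (i in seq_along(config$base_peaks)) {
    curve <- curve + peak_amp[pmin(i, 2L)] *
      gaussian_bump(wl, config$base_peaks[i], config$bump_width)
  }
  for (i in seq_along(config$base_troughs)) {
    curve <- curve - trough_amp[pmin(i, 2L)] *
      gaussian_bump(wl, config$base_troughs[i], config$bump_width)
  }
  curve
}

class_mean_curve <- function(config, cls) {
  curve <- base_curve(config) + config$class_offsets[[cls]]
  pl <- config$planted[config$planted$class == cls, , drop = FALSE]
  for (r in seq_len(nrow(pl))) {
    curve <- curve + pl$effect[r] *
      gaussian_bump(config$wavelengths, pl$center_nm[r],
                    config$planted_width)
  }
  curve
}

sample_seed <- function(seed, class_idx, i) {
  (as.numeric(seed) * 97L + class_idx * 1e6 + i) %% 2147483647
}

#' Generate a synthetic four-class spectral dataset
#'
#' Each spectrum is the class mean curve (base curve + class offset +
#' severity-scaled planted bumps) times a multiplicative scatter factor,
#' plus a baseline offset and per-band white noise. Fully reproducible
#' from the seed; per-sample RNG substreams mean per-class counts can be
#' changed independently.
#'
#' @param config a [synthetic_config()].
#' @return List with `dataset` (a [spectral_dataset()]) and `truth`
#'   (planted band grid indices, centers and effects per class).
#' @export
generate_dataset <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  wl <- config$wavelengths
  p <- length(wl)
  rows <- list(); labels <- character(0); ids <- character(0)
  for (ci in seq_along(peach_classes())) {
    cls <- peach_classes()[ci]
    curve <- base_curve(config) + config$class_offsets[[cls]]
    pl <- config$planted[config$planted$class == cls, , drop = FALSE]
    bump <- rep(0, p)
    for (r in seq_len(nrow(pl))) {
      bump <- bump + pl$effect[r] *
        gaussian_bump(wl, pl$center_nm[r], config$planted_width)
    }
    for (i in seq_len(config$n_per_class[[cls]])) {
      sp <- withr::with_seed(sample_seed(config$seed, ci, i), {
        severity <- max(0, stats::rnorm(1, 1, config$severity_sd))
        scatter <- 1 + stats::rnorm(1, 0, config$scatter_sd)
        offset <- stats::rnorm(1, 0, config$baseline_sd)
        noise <- stats::rnorm(p, 0, config$noise_sd)
        (curve + severity * bump) * scatter + offset + noise
      })
      rows[[length(rows) + 1L]] <- sp
      labels <- c(labels, cls)
      ids <- c(ids, sprintf("%s_%03d", cls, i))
    }
  }
  truth <- config$planted
  truth$band_index <- vapply(truth$center_nm,
                             function(cn) which.min(abs(wl - cn)),
                             integer(1))
  list(dataset = spectral_dataset(do.call(rbind, rows), labels, wl,
                                  ids = ids),
       truth = truth)
}

#' Generate a toy hypercube with dark/white references
#'
#' Builds a small pixels-x-bands scene whose defect-region pixels carry a
#' defect-class spectrum and the rest an intact-class spectrum, then mixes
#' the reflectance back through the inverse of the black/white correction
#' (`raw = ID + R * (IW - ID)`), so that [correct_reflectance()] recovers
#' the planted reflectance exactly (up to the configured noise).
#'
#' @param config a [synthetic_config()] (noise fields apply per pixel).
#' @param extent `c(rows, cols)` of the scene, each <= 64.
#' @param defect_rect `c(row0, row1, col0, col1)` rectangle of defect
#'   pixels (inclusive), within the extent.
#' @param defect_class which defect class the region carries.
#' @param dark_level,white_level per-band reference count levels.
#' @return List with `raw`, `ID`, `IW` (pixels x bands count matrices),
#'   `reflectance` (the planted truth), `defect_mask` and
#'   `background_mask` (pixel indices), and `wavelengths`.
#' @export
generate_hypercube <- function(config = synthetic_config(),
                               extent = c(16L, 16L),
                               defect_rect = c(5L, 10L, 5L, 10L),
                               defect_class = "scab",
                               dark_level = 120, white_level = 4000) {
  if (any(extent > 64L) || any(extent < 1L)) {
    stop("extent must be within 1..64 pixels per side")
  }
  if (defect_rect[1] < 1L || defect_rect[3] < 1L ||
      defect_rect[2] > extent[1] || defect_rect[4] > extent[2] ||
      defect_rect[1] > defect_rect[2] || defect_rect[3] > defect_rect[4]) {
    stop("defect_rect outside scene extent")
  }
  defect_class <- match.arg(defect_class, peach_classes()[-1L])
  wl <- config$wavelengths
  p <- length(wl)
  n_pix <- prod(extent)
  pix_row <- rep(seq_len(extent[1]), times = extent[2])
  pix_col <- rep(seq_len(extent[2]), each = extent[1])
  in_defect <- pix_row >= defect_rect[1] & pix_row <= defect_rect[2] &
    pix_col >= defect_rect[3] & pix_col <= defect_rect[4]
  intact_sp <- class_mean_curve(config, "intact")
  defect_sp <- class_mean_curve(config, defect_class)
  R <- matrix(0, n_pix, p)
  for (i in seq_len(n_pix)) {
    base_sp <- if (in_defect[i]) defect_sp else intact_sp
    R[i, ] <- withr::with_seed(sample_seed(config$seed, 9L, i), {
      base_sp + stats::rnorm(p, 0, config$noise_sd)
    })
  }
  ID <- matrix(dark_level, n_pix, p)
  IW <- matrix(white_level, n_pix, p)
  raw <- ID + R * (IW - ID)
  list(raw = raw, ID = ID, IW = IW, reflectance = R,
       defect_mask = which(in_defect), background_mask = which(!in_defect),
       wavelengths = wl)
}
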