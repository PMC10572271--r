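# Spectral pretreatments. All methods preserve matrix shape; filters keep
# length constant via reflect padding at the edges.

reflect_pad <- function(x, h) {
  n <- length(x)
  if (h >= n) stop("padding width exceeds spectrum length")
  if (h == 0L) return(x)
  c(x[(h + 1L):2L], x, x[(n - 1L):(n - h)])
}

#' Standard normal variate transform
#'
#' Centers and scales each spectrum (row) to zero mean and unit population
#' standard deviation, removing additive offsets and multiplicative scatter.
#'
#' @param X spectra matrix, samples in rows.
#' @return Transformed matrix of the same shape.
#' @export
snv <- function(X) {
  X <- as.matrix(X)
  mu <- rowMeans(X)
  Xc <- X - mu
  sd_pop <- sqrt(rowMeans(Xc^2))
  degenerate <- which(sd_pop < 1e-12)
  if (length(degenerate) > 0L) {
    stop("constant spectrum (zero variance) at sample row ",
         paste(utils::head(degenerate, 5L), collapse = ", "))
  }
  Xc / sd_pop
}

#' Savitzky--Golay derivative (D-SG)
#'
#' Per-spectrum Savitzky--Golay smoothing/derivative via local polynomial
#' least squares; filter coefficients come from [signal::sgolay()]. The
#' derivative is reported per band-index unit unless a grid is supplied for
#' per-nm scaling. Edges are reflect-padded so the band count is preserved.
#'
#' @param X spectra matrix, samples in rows.
#' @param window odd filter length (points), greater than `polyorder`.
#' @param polyorder polynomial order of the local fit.
#' @param deriv derivative order (0 = smoothing).
#' @param wavelengths optional grid; if given, derivatives are scaled to
#'   per-nm units using the mean band spacing.
#' @return Matrix of the same shape as `X`.
#' @export
sg_derivative <- function(X, window = 7L, polyorder = 2L, deriv = 1L,
                          wavelengths = NULL) {
  window <- as.integer(window)
  if (window %% 2L == 0L || window <= polyorder) {
    stop("window must be odd and greater than polyorder")
  }
  if (deriv > polyorder) stop("deriv must not exceed polyorder")
  h <- (window - 1L) %/% 2L
  filt <- signal::sgolay(p = polyorder, n = window, m = deriv)[h + 1L, ]
  X <- as.matrix(X)
  out <- t(apply(X, 1L, function(x) {
    xp <- reflect_pad(x, h)
    stats::filter(xp, rev(filt), sides = 2L)[(h + 1L):(h + length(x))]
  }))
  if (!is.null(wavelengths) && deriv > 0L) {
    out <- out / mean(diff(wavelengths))^deriv
  }
  out
}

#' Gap--segment derivative (D-GS)
#'
#' Norris-style derivative: the first derivative at band i is the difference
#' between the mean of a `segment`-point window to the right of a `gap` and
#' the mean of a matching window to the left, divided by `gap + segment`
#' (band-index units). The second derivative applies the rule twice.
#' Edges are reflect-padded.
#'
#' @param X spectra matrix, samples in rows.
#' @param gap gap size in points (>= 1).
#' @param segment averaging window length in points (>= 1).
#' @param deriv derivative order, 1 or 2.
#' @return Matrix of the same shape as `X`.
#' @export
gap_segment_derivative <- function(X, gap = 3L, segment = 3L, deriv = 1L) {
  gap <- as.integer(gap); segment <- as.integer(segment)
  if (gap < 1L || segment < 1L) stop("gap and segment must be >= 1")
  if (!deriv %in% c(1L, 2L)) stop("deriv must be 1 or 2")
  X <- as.matrix(X)
  if (ncol(X) < 2L * segment + gap) {
    stop("spectrum too short for gap = ", gap, ", segment = ", segment,
         " (need >= ", 2L * segment + gap, " bands)")
  }
  off <- as.integer(ceiling(gap / 2))
  h <- off + segment - 1L
  gs1 <- function(x) {
    xp <- reflect_pad(x, h)
    idx <- (h + 1L):(h + length(x))
    vapply(idx, function(i) {
      right <- mean(xp[(i + off):(i + off + segment - 1L)])
      left <- mean(xp[(i - off - segment + 1L):(i - off)])
      (right - left) / (gap + segment)
    }, numeric(1))
  }
  out <- t(apply(X, 1L, gs1))
  if (deriv == 2L) out <- t(apply(out, 1L, gs1))
  out
}

#' Baseline offset correction
#'
#' Subtracts each spectrum's own minimum so the row minimum becomes zero
#' (`method = "min"`, the default), or removes a least-squares straight line
#' fit to the spectrum (`method = "detrend"`).
#'
#' @param X spectra matrix, samples in rows.
#' @param method `"min"` or `"detrend"`.
#' @return Matrix of the same shape as `X`.
#' @export
baseline_correct <- function(X, method = c("min", "detrend")) {
  method <- match.arg(method)
  X <- as.matrix(X)
  if (ncol(X) == 0L) stop("empty spectra")
  if (method == "min") {
    return(X - apply(X, 1L, min))
  }
  b <- seq_len(ncol(X))
  t(apply(X, 1L, function(x) stats::lm.fit(cbind(1, b), x)$residuals))
}

#' Running-median smoothing (SMF)
#'
#' Per-spectrum running median with reflect-padded edges, built on
#' [stats::runmed()].
#'
#' @param X spectra matrix, samples in rows.
#' @param window odd window length >= 3.
#' @return Matrix of the same shape as `X`.
#' @export
median_smooth <- function(X, window = 5L) {
  window <- as.integer(window)
  if (window %% 2L == 0L || window < 3L) stop("window must be odd and >= 3")
  h <- (window - 1L) %/% 2L
  X <- as.matrix(X)
  t(apply(X, 1L, function(x) {
    xp <- reflect_pad(x, h)
    stats::runmed(xp, window, endrule = "keep")[(h + 1L):(h + length(x))]
  }))
}

#' Describe a pretreatment
#'
#' @param method one of `"none"`, `"SNV"`, `"baseline"`, `"SMF"`, `"D-SG"`,
#'   `"D-GS"`.
#' @param window filter window (D-SG, SMF).
#' @param polyorder polynomial order (D-SG).
#' @param deriv derivative order (D-SG, D-GS).
#' @param gap,segment gap--segment parameters (D-GS).
#' @return A `pretreatment_spec` object usable with [apply_pretreatment()].
#' @export
pretreatment_spec <- function(method = c("none", "SNV", "baseline", "SMF",
                                         "D-SG", "D-GS"),
                              window = 7L, polyorder = 2L, deriv = 1L,
                              gap = 3L, segment = 3L) {
  method <- match.arg(method)
  if (method == "D-SG" && (window %% 2L == 0L || window <= polyorder)) {
    stop("D-SG needs an odd window greater than polyorder")
  }
  if (method == "D-GS" && (gap < 1L || segment < 1L)) {
    stop("D-GS needs gap >= 1 and segment >= 1")
  }
  if (!deriv %in% c(0L, 1L, 2L)) stop("deriv must be 0, 1 or 2")
  structure(list(method = method, window = as.integer(window),
                 polyorder = as.integer(polyorder), deriv = as.integer(deriv),
                 gap = as.integer(gap), segment = as.integer(segment)),
            class = "pretreatment_spec")
}

#' Apply a pretreatment to a spectra matrix
#'
#' @param X spectra matrix, samples in rows.
#' @param spec a [pretreatment_spec()].
#' @return Transformed matrix of the same shape.
#' @export
apply_pretreatment <- function(X, spec) {
  stopifnot(inherits(spec, "pretreatment_spec"))
  switch(spec$method,
    none = as.matrix(X),
    SNV = snv(X),
    baseline = baseline_correct(X),
    SMF = median_smooth(X, spec$window),
    `D-SG` = sg_derivative(X, spec$window, spec$polyorder, max(spec$deriv, 1L)),
    `D-GS` = gap_segment_derivative(X, spec$gap, spec$segment,
                                    max(spec$deriv, 1L))
  )
}

#' Default pretreatment candidates
#'
#' The five pretreatments compared by the pipeline, with their default
#' parameters (window 7 / order 2 / first derivative for D-SG; gap 3 /
#' segment 3 for D-GS; window 5 for the median filter).
#'
#' @return Named list of [pretreatment_spec()] objects.
#' @export
default_pretreatments <- function() {
  list(
    `D-GS` = pretreatment_spec("D-GS", gap = 3L, segment = 3L, deriv = 1L),
    `D-SG` = pretreatment_spec("D-SG", window = 7L, polyorder = 2L, deriv = 1L),
    baseline = pretreatment_spec("baseline"),
    SMF = pretreatment_spec("SMF", window = 5L),
    SNV = pretreatment_spec("SNV")
  )
}

#' Rank pretreatments by PLS prediction performance
#'
#' Applies each candidate pretreatment to the spectra, fits a PLS1 model on
#' the calibration partition with the class codes as numeric response, and
#' tabulates calibration and prediction R-squared / RMSE for each method.
#' A raw-spectrum row is always included. The winner is the row with the
#' highest prediction R-squared, ties broken by lower RMSEP.
#'
#' @param dataset a [spectral_dataset()].
#' @param split a list with `calibration` and `prediction` index vectors,
#'   e.g. from [kennard_stone_split()].
#' @param specs named list of [pretreatment_spec()] candidates.
#' @param max_comp cap on the PLS component count; the count is chosen by
#'   minimum cross-validated RMSE per method.
#' @param cv_folds folds for that internal selection.
#' @param seed seed for the fold assignment.
#' @return Data frame with columns `method`, `n_comp`, `Rc2`, `RMSEC`,
#'   `Rp2`, `RMSEP`; attribute `"winner"` holds the winning method name.
#' @export
compare_pretreatments <- function(dataset, split,
                                  specs = default_pretreatments(),
                                  max_comp = 10L, cv_folds = 5L,
                                  seed = 2023L) {
  stopifnot(inherits(dataset, "spectral_dataset"))
  y <- class_code(dataset$labels)
  all_specs <- c(list(raw = pretreatment_spec("none")), specs)
  rows <- lapply(names(all_specs), function(nm) {
    Xp <- tryCatch(apply_pretreatment(dataset$X, all_specs[[nm]]),
                   error = function(e) {
                     stop("pretreatment '", nm, "' failed: ",
                          conditionMessage(e))
                   })
    Xc <- Xp[split$calibration, , drop = FALSE]
    yc <- y[split$calibration]
    Xv <- Xp[split$prediction, , drop = FALSE]
    yv <- y[split$prediction]
    a <- choose_ncomp(Xc, yc, max_comp = max_comp, folds = cv_folds,
                      seed = seed)
    fit <- fit_pls1(Xc, yc, a)
    sc <- score(fit, Xc, yc)
    sp <- score(fit, Xv, yv)
    data.frame(method = nm, n_comp = fit$n_components,
               Rc2 = sc$r2, RMSEC = sc$rmse,
               Rp2 = sp$r2, RMSEP = sp$rmse,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  ord <- order(-out$Rp2, out$RMSEP)
  attr(out, "winner") <- out$method[ord[1L]]
  out
}
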