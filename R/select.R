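# Wavelength selection: CARS, plus MIV / SPA / UVE as second-stage filters
# over a prior selection, and the chaining machinery composing them.

#' Selection result container
#'
#' @param method method name, e.g. `"CARS"` or `"CARS-MIV"`.
#' @param indices selected band indices (into the candidate matrix).
#' @param wavelengths optional band-center wavelengths of the candidates.
#' @param diagnostics method-specific diagnostics list.
#' @param seed seed used by any stochastic step.
#' @return An object of class `selection_result` with sorted unique indices.
#' @export
selection_result <- function(method, indices, wavelengths = NULL,
                             diagnostics = list(), seed = NULL) {
  indices <- sort(unique(as.integer(indices)))
  if (length(indices) == 0L) stop(method, ": empty selection")
  wl <- if (!is.null(wavelengths)) as.numeric(wavelengths)[indices] else NULL
  structure(list(method = method, indices = indices, wavelengths_nm = wl,
                 diagnostics = diagnostics, seed = seed),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(x$method, ": ", length(x$indices), " bands selected\n", sep = "")
  invisible(x)
}

#' Exponentially decreasing retention schedule for CARS
#'
#' Forced retention ratios `r_i = a * exp(-k * i)` with
#' `a = (p/2)^(1/(N-1))` and `k = log(p/2)/(N-1)`, so the retained count
#' decays from all `p` bands at the first run to 2 at the last.
#'
#' @param p number of candidate bands.
#' @param n_runs number of Monte-Carlo sampling runs.
#' @return List with `ratio` and the enforced counts `k` (`round(ratio * p)`).
#' @export
edf_schedule <- function(p, n_runs) {
  if (p < 2L) stop("need at least 2 candidate bands")
  if (n_runs < 2L) stop("n_runs must be >= 2")
  i <- seq_len(n_runs)
  a <- (p / 2)^(1 / (n_runs - 1))
  k <- log(p / 2) / (n_runs - 1)
  ratio <- a * exp(-k * i)
  list(ratio = ratio, k = as.integer(round(ratio * p)))
}

#' Competitive adaptive reweighted sampling (CARS)
#'
#' Iterative wavelength selection: at each of `n_runs` Monte-Carlo runs a
#' random sample-subset PLS model is fitted on the currently retained bands;
#' bands are weighted by their normalized absolute PLS coefficients; an
#' exponentially decreasing schedule forces the retained count down; and
#' adaptive reweighted sampling (weighted draws with replacement) picks the
#' working set for the next run. The subset with the smallest
#' cross-validated RMSE over the whole run is returned.
#'
#' @param X candidate spectra matrix (calibration samples x bands).
#' @param y numeric response (class codes).
#' @param n_runs Monte-Carlo sampling runs (default 50).
#' @param sample_ratio fraction of samples drawn per run.
#' @param cv_folds folds for the per-run RMSECV.
#' @param max_comp cap on PLS components (count chosen by minimum CV RMSE
#'   per retained subset).
#' @param ars if `TRUE` (default) apply adaptive reweighted sampling after
#'   the enforced top-k cut; if `FALSE` keep the deterministic top-k only.
#' @param seed RNG seed.
#' @param wavelengths optional grid for reporting.
#' @return A [selection_result()] whose `diagnostics$trace` records, per
#'   run, the retention ratio, retained count, RMSECV and component count,
#'   and `diagnostics$retained_sets` the retained index sets.
#' @export
cars_select <- function(X, y, n_runs = 50L, sample_ratio = 0.8,
                        cv_folds = 5L, max_comp = 10L, ars = TRUE,
                        seed = 2023L, wavelengths = NULL) {
  X <- as.matrix(X); y <- as.numeric(y)
  if (sample_ratio <= 0 || sample_ratio >= 1) {
    stop("sample_ratio must be in (0, 1)")
  }
  n <- nrow(X); p <- ncol(X)
  sched <- edf_schedule(p, n_runs)
  withr::with_seed(seed, {
    retained <- seq_len(p)
    trace <- vector("list", n_runs)
    sets <- vector("list", n_runs)
    for (i in seq_len(n_runs)) {
      if (length(retained) < 2L) break
      sets[[i]] <- retained
      # RMSECV of the entering subset (all calibration samples)
      folds_id <- make_folds(n, cv_folds)
      a_cap <- max(1L, min(max_comp, length(retained),
                           n - ceiling(n / cv_folds) - 1L))
      prof <- cv_rmse_profile(X[, retained, drop = FALSE], y, a_cap, folds_id)
      a_star <- which.min(prof)
      # Monte-Carlo subset fit gives the competing weights
      sub <- sample.int(n, ceiling(sample_ratio * n))
      a_fit <- min(a_star, length(sub) - 1L)
      fit <- suppressWarnings(
        fit_pls1(X[sub, retained, drop = FALSE], y[sub], a_fit))
      w <- abs(fit$b)
      if (sum(w) < 1e-300) w <- rep(1, length(w))
      w <- w / sum(w)
      trace[[i]] <- data.frame(run = i, ratio = sched$ratio[i],
                               n_retained = length(retained),
                               rmsecv = prof[a_star], n_comp = a_star)
      # enforced retention, then adaptive reweighted sampling
      k_i <- max(2L, min(sched$k[i], length(retained)))
      ord <- order(w, decreasing = TRUE)
      top <- ord[seq_len(k_i)]
      if (ars) {
        draws <- sample(top, k_i, replace = TRUE, prob = w[top])
        surv <- sort(unique(draws))
        if (length(surv) < 2L) surv <- sort(top[1:2])
      } else {
        surv <- sort(top)
      }
      retained <- retained[surv]
    }
    done <- !vapply(trace, is.null, logical(1))
    trace <- do.call(rbind, trace[done])
    sets <- sets[done]
  })
  best <- which.min(trace$rmsecv)
  selection_result(
    "CARS", sets[[best]], wavelengths,
    diagnostics = list(trace = trace, retained_sets = sets,
                       best_run = best, rmsecv_min = trace$rmsecv[best],
                       schedule = sched),
    seed = seed
  )
}

#' Mean-impact-value ranking of bands
#'
#' Perturbation importance for an arbitrary fitted model: each band column
#' is in turn scaled up by 10% and down by 10%, both perturbed matrices are
#' passed through the model, and the per-sample output difference
#' `y1 - y2` (the impact value, IV) is averaged into that band's MIV.
#' Bands are ranked by `|MIV|` descending (ties to the lower band index)
#' and annotated with contribution shares `|MIV|/sum|MIV|` and their
#' cumulative sum.
#'
#' @param model either a function `f(X) -> numeric` or a fitted object with
#'   a `predict` method.
#' @param X calibration matrix over the candidate bands.
#' @return Data frame (class `miv_records`) with one row per band:
#'   `band`, `miv`, `abs_miv`, `rank`, `share`, `cumulative` (in rank
#'   order), sorted by rank.
#' @export
miv_rank <- function(model, X) {
  X <- as.matrix(X)
  if (nrow(X) == 0L || ncol(X) == 0L) stop("X must be nonempty")
  f <- if (is.function(model)) model else function(M) {
    as.numeric(stats::predict(model, M))
  }
  miv <- vapply(seq_len(ncol(X)), function(j) {
    P1 <- X; P1[, j] <- X[, j] * 1.1
    P2 <- X; P2[, j] <- X[, j] * 0.9
    y1 <- tryCatch(f(P1), error = function(e) {
      stop("model failed on +10% perturbation of band ", j, ": ",
           conditionMessage(e))
    })
    y2 <- tryCatch(f(P2), error = function(e) {
      stop("model failed on -10% perturbation of band ", j, ": ",
           conditionMessage(e))
    })
    mean(y1 - y2)
  }, numeric(1))
  ord <- order(-abs(miv), seq_along(miv))
  total <- sum(abs(miv))
  share <- if (total > 0) abs(miv) / total else rep(0, length(miv))
  rec <- data.frame(band = ord, miv = miv[ord], abs_miv = abs(miv)[ord],
                    rank = seq_along(ord), share = share[ord],
                    cumulative = cumsum(share[ord]))
  class(rec) <- c("miv_records", "data.frame")
  rec
}

#' Select bands by cumulative MIV contribution
#'
#' Takes bands in descending `|MIV|` order until the cumulative
#' contribution share first reaches the cutoff (default 95%).
#'
#' @param records output of [miv_rank()].
#' @param cum_contrib cumulative-contribution cutoff in (0, 1].
#' @param wavelengths optional grid for reporting.
#' @return A [selection_result()] with `diagnostics$records`.
#' @export
miv_select <- function(records, cum_contrib = 0.95, wavelengths = NULL) {
  if (sum(records$abs_miv) <= 0) {
    stop("all MIV values are zero: no informative variables")
  }
  m <- which(records$cumulative >= cum_contrib - 1e-9)[1L]
  if (is.na(m)) m <- nrow(records)
  selection_result("MIV", records$band[seq_len(m)], wavelengths,
                   diagnostics = list(records = records,
                                      cum_contrib = cum_contrib))
}

#' Train the default MIV black-box model
#'
#' An RBF-kernel support-vector regressor (via [e1071::svm()]) on the
#' calibration class codes; the model family perturbed by [miv_rank()].
#'
#' @param X calibration matrix.
#' @param y numeric response.
#' @return Prediction function `f(X) -> numeric`.
#' @export
svm_regressor <- function(X, y) {
  fit <- e1071::svm(x = as.matrix(X), y = as.numeric(y),
                    type = "eps-regression", kernel = "radial")
  function(M) as.numeric(stats::predict(fit, as.matrix(M)))
}

#' Successive projections algorithm (SPA)
#'
#' Classic forward selection minimizing collinearity: from every starting
#' band a chain is grown by repeatedly adding the band whose column has the
#' largest norm after orthogonal projection onto the complement of the span
#' of the bands already chosen. Every (start, k) chain with
#' `k_min <= k <= k_max` is scored by the leave-one-out cross-validated
#' RMSE of an ordinary least-squares model on the chosen bands (computed
#' from the hat matrix), and the best-scoring chain is returned; ties
#' prefer fewer bands, then the lower starting band. Plain calibration
#' RMSE is available as `score_by = "calibration"`, but note it is
#' monotone non-increasing along a chain and therefore always favours
#' `k_max` bands.
#'
#' @param X candidate matrix (calibration samples x bands).
#' @param y numeric response.
#' @param k_min,k_max chain-length range (default 1--25).
#' @param score_by `"calibration"` (default) or `"cv"` (leave-one-out).
#' @param wavelengths optional grid for reporting.
#' @return A [selection_result()]; `diagnostics$rmse_by_k` holds the
#'   RMSE-versus-k curve of the winning start.
#' @export
spa_select <- function(X, y, k_min = 1L, k_max = 25L,
                       score_by = c("cv", "calibration"),
                       wavelengths = NULL) {
  score_by <- match.arg(score_by)
  X <- as.matrix(X); y <- as.numeric(y)
  n <- nrow(X); p <- ncol(X)
  if (k_max > p) stop("k_max (", k_max, ") exceeds candidate band count (",
                      p, ")")
  if (k_max > n - 2L) {
    warning("k_max capped at n - 2 = ", n - 2L, " for a determined fit")
    k_max <- n - 2L
  }
  k_min <- max(1L, as.integer(k_min)); k_max <- as.integer(k_max)
  chain_from <- function(s) {
    chain <- integer(k_max); chain[1L] <- s
    R <- X
    v <- R[, s]
    remaining <- setdiff(seq_len(p), s)
    for (step in seq_len(k_max - 1L)) {
      R <- R - v %*% (crossprod(v, R) / sum(v^2))
      norms <- sqrt(colSums(R[, remaining, drop = FALSE]^2))
      nxt <- remaining[which.max(norms)]
      if (max(norms) < 1e-12) { chain <- chain[seq_len(step)]; break }
      chain[step + 1L] <- nxt
      v <- R[, nxt]
      remaining <- setdiff(remaining, nxt)
    }
    chain[chain != 0L]
  }
  rmse_of <- function(subset) {
    M <- cbind(1, X[, subset, drop = FALSE])
    if (score_by == "calibration") {
      fit <- stats::lm.fit(M, y)
      return(sqrt(mean(fit$residuals^2)))
    }
    # leave-one-out via the hat matrix
    qr_m <- qr(M)
    h <- rowSums(qr.Q(qr_m)[, seq_len(qr_m$rank), drop = FALSE]^2)
    res <- y - M %*% qr.coef(qr_m, y)
    sqrt(mean((res / pmax(1 - h, 1e-8))^2))
  }
  best <- NULL
  for (s in seq_len(p)) {
    chain <- chain_from(s)
    ks <- seq(k_min, min(k_max, length(chain)))
    rmse_k <- vapply(ks, function(k) rmse_of(chain[seq_len(k)]), numeric(1))
    j <- which.min(rmse_k)
    cand <- list(start = s, k = ks[j], rmse = rmse_k[j],
                 subset = chain[seq_len(ks[j])],
                 curve = data.frame(k = ks, rmse = rmse_k))
    if (is.null(best) || cand$rmse < best$rmse - 1e-12 ||
        (abs(cand$rmse - best$rmse) <= 1e-12 && cand$k < best$k)) {
      best <- cand
    }
  }
  selection_result("SPA", best$subset, wavelengths,
                   diagnostics = list(start = best$start, k = best$k,
                                      rmse = best$rmse,
                                      rmse_by_k = best$curve))
}

#' Uninformative variable elimination (UVE)
#'
#' Appends seeded small-amplitude uniform noise columns to the candidate
#' matrix, fits a PLS1 model under leave-one-out resampling, and computes
#' each column's reliability `c = mean(b)/sd(b)` over the resampled
#' coefficient vectors. Real bands whose `|c|` does not exceed
#' `threshold_frac` times the largest noise-column `|c|` are eliminated.
#'
#' @param X candidate matrix (calibration samples x bands).
#' @param y numeric response.
#' @param n_noise number of appended noise columns (default: one per band).
#' @param n_components PLS components; `NULL` picks by CV RMSE once on the
#'   real bands.
#' @param threshold_frac fraction of the maximal noise reliability used as
#'   the cut (default 0.99).
#' @param noise_amplitude noise scale relative to `max(abs(X))`.
#' @param seed RNG seed for the noise matrix.
#' @param wavelengths optional grid for reporting.
#' @return A [selection_result()]; `diagnostics$records` tabulates every
#'   real and noise column's reliability, `diagnostics$threshold` the
#'   (lower, upper) cut.
#' @export
uve_select <- function(X, y, n_noise = ncol(X), n_components = NULL,
                       threshold_frac = 0.99, noise_amplitude = 1e-10,
                       seed = 2023L, wavelengths = NULL) {
  X <- as.matrix(X); y <- as.numeric(y)
  n <- nrow(X); p <- ncol(X)
  if (n < 3L) stop("UVE needs at least 3 samples")
  if (n_noise < p) stop("n_noise must be >= number of candidate bands")
  scale_x <- max(abs(X))
  noise <- withr::with_seed(seed,
    matrix(stats::runif(n * n_noise, -1, 1), n, n_noise)) *
    noise_amplitude * scale_x
  Xa <- cbind(X, noise)
  if (is.null(n_components)) {
    n_components <- choose_ncomp(X, y, max_comp = min(10L, p, n - 3L),
                                 seed = seed)
  }
  B <- matrix(NA_real_, n, p + n_noise)
  for (i in seq_len(n)) {
    a_i <- min(n_components, n - 2L)
    fit <- suppressWarnings(fit_pls1(Xa[-i, , drop = FALSE], y[-i], a_i))
    B[i, ] <- fit$b_all[, fit$n_components]
  }
  mu <- colMeans(B)
  sd_b <- apply(B, 2L, stats::sd)
  rel <- mu / sd_b
  zero_sd <- sd_b < 1e-300
  if (any(zero_sd)) {
    warning(sum(zero_sd), " column(s) with zero coefficient spread; ",
            "reliability set to +Inf")
    rel[zero_sd] <- Inf * sign(mu[zero_sd] + (mu[zero_sd] == 0))
  }
  cutoff <- threshold_frac * max(abs(rel[(p + 1L):(p + n_noise)]))
  keep <- which(abs(rel[seq_len(p)]) > cutoff)
  records <- data.frame(
    variable = seq_len(p + n_noise),
    type = rep(c("real", "noise"), c(p, n_noise)),
    mean_coef = mu, sd_coef = sd_b, reliability = rel)
  if (length(keep) == 0L) {
    stop("UVE eliminated every band: no reliability exceeds the noise ",
         "threshold ", signif(cutoff, 4))
  }
  selection_result("UVE", keep, wavelengths,
                   diagnostics = list(records = records,
                                      threshold = c(-cutoff, cutoff),
                                      n_components = n_components),
                   seed = seed)
}

#' Compose two selection stages
#'
#' Runs `first` on the full candidate matrix, then `second` on the columns
#' the first stage kept, and maps the result back to the original band
#' indices. The composed method name joins both stages ("CARS-MIV" etc.)
#' and both stages' diagnostics are retained, so chained selections are
#' nested subsets by construction.
#'
#' @param X candidate matrix (calibration samples x bands).
#' @param y numeric response.
#' @param first,second selector functions `f(X, y) -> selection_result`,
#'   e.g. from [stage_cars()] / [stage_miv()].
#' @param wavelengths optional grid for reporting.
#' @return A [selection_result()].
#' @export
chain_select <- function(X, y, first, second, wavelengths = NULL) {
  X <- as.matrix(X)
  res1 <- first(X, y)
  if (!inherits(res1, "selection_result") || length(res1$indices) == 0L) {
    stop("chain error: first stage produced an empty selection")
  }
  if (length(res1$indices) < 2L) {
    stop("chain error: first stage kept fewer than 2 bands")
  }
  res2 <- second(X[, res1$indices, drop = FALSE], y)
  final <- res1$indices[res2$indices]
  selection_result(paste(res1$method, res2$method, sep = "-"), final,
                   wavelengths,
                   diagnostics = list(first = res1, second = res2),
                   seed = res1$seed)
}

#' Selection-stage constructors
#'
#' Each returns a selector function `f(X, y) -> selection_result` with the
#' stated parameters bound, suitable for [chain_select()] and
#' [run_pipeline()]. `stage_miv()` trains its black-box model (default:
#' [svm_regressor()]) on the candidate matrix it receives; `stage_spa()`
#' caps `k_max` at the number of candidate bands it receives.
#'
#' @param n_runs,sample_ratio,cv_folds,max_comp,ars,seed see [cars_select()].
#' @param cum_contrib see [miv_select()].
#' @param model_fn trainer `f(X, y) -> prediction function` for MIV.
#' @param k_min,k_max,score_by see [spa_select()].
#' @param n_components,threshold_frac see [uve_select()].
#' @return A selector function.
#' @name stages
NULL

#' @rdname stages
#' @export
stage_cars <- function(n_runs = 50L, sample_ratio = 0.8, cv_folds = 5L,
                       max_comp = 10L, ars = TRUE, seed = 2023L) {
  function(X, y) cars_select(X, y, n_runs = n_runs,
                             sample_ratio = sample_ratio,
                             cv_folds = cv_folds, max_comp = max_comp,
                             ars = ars, seed = seed)
}

#' @rdname stages
#' @export
stage_miv <- function(cum_contrib = 0.95, model_fn = svm_regressor) {
  function(X, y) {
    model <- model_fn(X, y)
    miv_select(miv_rank(model, X), cum_contrib = cum_contrib)
  }
}

#' @rdname stages
#' @export
stage_spa <- function(k_min = 1L, k_max = 25L,
                      score_by = c("cv", "calibration")) {
  score_by <- match.arg(score_by)
  function(X, y) spa_select(X, y, k_min = k_min,
                            k_max = min(k_max, ncol(X)),
                            score_by = score_by)
}

#' @rdname stages
#' @export
stage_uve <- function(n_components = NULL, threshold_frac = 0.99,
                      seed = 2023L) {
  function(X, y) uve_select(X, y, n_components = n_components,
                            threshold_frac = threshold_frac, seed = seed)
}

#' @rdname stages
#' @export
stage_identity <- function() {
  function(X, y) selection_result("identity", seq_len(ncol(X)))
}
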