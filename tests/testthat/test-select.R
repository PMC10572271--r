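test_that("EDF schedule decays from all bands to two", {
  s <- edf_schedule(24, 50)
  expect_equal(s$k[1], 24L)
  expect_equal(s$k[50], 2L)
  expect_equal(s$ratio[1], 1, tolerance = 1e-12)
  expect_true(all(diff(s$ratio) < 0))
})

test_that("CARS trace bookkeeping is consistent and retention is monotone", {
  sim <- generate_dataset(small_sim_config(seed = 2))
  ds <- sim$dataset
  y <- class_code(ds$labels)
  sel <- cars_select(ds$X, y, n_runs = 20, seed = 5,
                     wavelengths = ds$wavelengths)
  tr <- sel$diagnostics$trace
  expect_equal(nrow(tr), length(sel$diagnostics$retained_sets))
  expect_true(all(diff(tr$n_retained) <= 0))
  expect_equal(sel$diagnostics$rmsecv_min, min(tr$rmsecv))
  expect_setequal(sel$indices,
                  sel$diagnostics$retained_sets[[sel$diagnostics$best_run]])
  expect_equal(sel$wavelengths_nm, ds$wavelengths[sel$indices])
  # same seed reproduces the selection exactly
  sel2 <- cars_select(ds$X, y, n_runs = 20, seed = 5)
  expect_identical(sel2$indices, sel$indices)
})

test_that("MIV matches the linear closed form and ignores unused bands", {
  withr::with_seed(3, X <- matrix(runif(40, 0.5, 2), 10, 4))
  beta <- c(3, 0, -1.5, 0.25)
  lin <- function(M) drop(M %*% beta) + 2
  rec <- miv_rank(lin, X)
  expected <- 0.2 * beta * colMeans(X)
  expect_equal(rec$miv[order(rec$band)], expected, tolerance = 1e-10)
  expect_equal(rec$miv[rec$band == 2], 0)
  # scaling a column by c scales its MIV by c for a linear model
  X2 <- X; X2[, 3] <- 3 * X[, 3]
  rec2 <- miv_rank(lin, X2)
  expect_equal(rec2$miv[rec2$band == 3], 3 * expected[3], tolerance = 1e-10)
})

test_that("MIV record invariants hold: shares sum to 1, cumulative is monotone", {
  withr::with_seed(4, X <- matrix(runif(60, 0.5, 2), 15, 4))
  rec <- miv_rank(function(M) drop(M %*% c(1, -2, 0.5, 0.1)), X)
  expect_equal(sum(rec$share), 1)
  expect_true(all(diff(rec$cumulative) >= -1e-15))
  expect_identical(rec$rank, 1:4)
})

test_that("cumulative-contribution cut selects the documented counts", {
  mk <- function(shares) {
    data.frame(band = seq_along(shares), miv = shares, abs_miv = shares,
               rank = seq_along(shares), share = shares,
               cumulative = cumsum(shares))
  }
  expect_length(miv_select(mk(c(0.5, 0.3, 0.15, 0.05)))$indices, 3L)
  expect_length(miv_select(mk(1))$indices, 1L)
  expect_length(miv_select(mk(c(0.94, 0.03, 0.02, 0.01)))$indices, 2L)
  expect_error(miv_select(mk(c(0, 0, 0, 0))), "no informative")
})

test_that("SPA keeps the large orthogonal columns and never reuses a duplicate", {
  Q <- qr.Q(qr(matrix(rnorm(36), 6)))[, 1:3]
  X <- Q %*% diag(c(3, 2, 1))
  y <- X[, 1] + X[, 2]
  sel <- spa_select(X, y, k_min = 2, k_max = 2, score_by = "calibration")
  expect_setequal(sel$indices, c(1L, 2L))
  # duplicated column: projection of the twin is zero, so never chosen twice
  Xd <- cbind(X, X[, 1])
  sel_d <- spa_select(Xd, y, k_min = 3, k_max = 3, score_by = "calibration")
  expect_false(all(c(1L, 4L) %in% sel_d$indices))
})

test_that("SPA chains equal an exhaustive Gram-Schmidt oracle on small instances", {
  oracle_chain <- function(X, s, k) {
    chain <- s
    for (step in seq_len(k - 1)) {
      rem <- setdiff(seq_len(ncol(X)), chain)
      norms <- vapply(rem, function(j) {
        fit <- lm.fit(X[, chain, drop = FALSE], X[, j])
        sqrt(sum(fit$residuals^2))
      }, numeric(1))
      chain <- c(chain, rem[which.max(norms)])
    }
    chain
  }
  oracle_spa <- function(X, y, k_max) {
    best <- NULL
    for (s in seq_len(ncol(X))) {
      for (k in seq_len(k_max)) {
        sub <- oracle_chain(X, s, k)
        M <- cbind(1, X[, sub, drop = FALSE])
        rmse <- sqrt(mean(lm.fit(M, y)$residuals^2))
        if (is.null(best) || rmse < best$rmse - 1e-12 ||
            (abs(rmse - best$rmse) <= 1e-12 && k < best$k)) {
          best <- list(subset = sub, rmse = rmse, k = k)
        }
      }
    }
    best
  }
  for (s_data in 1:3) {
    withr::with_seed(s_data, {
      X <- matrix(rnorm(48), 8, 6)
      y <- rnorm(8)
    })
    sel <- spa_select(X, y, k_min = 1, k_max = 4, score_by = "calibration")
    ora <- oracle_spa(X, y, 4L)
    expect_setequal(sel$indices, ora$subset)
    expect_equal(sel$diagnostics$rmse, ora$rmse, tolerance = 1e-10)
  }
})

test_that("UVE keeps a perfect predictor and eliminates pure noise bands", {
  withr::with_seed(7, {
    X <- matrix(rnorm(30 * 10), 30, 10)
    y <- X[, 4] # band 4 is the response itself
  })
  sel <- uve_select(X, y, n_noise = 10, n_components = 3, seed = 7)
  expect_true(4L %in% sel$indices)
  rec <- sel$diagnostics$records
  expect_equal(nrow(rec), 20L)
  thr <- sel$diagnostics$threshold
  expect_equal(thr[2], -thr[1])
  # the maximal-|c| noise column sits exactly on the threshold boundary
  noise_rel <- abs(rec$reliability[rec$type == "noise"])
  expect_equal(max(noise_rel) * 0.99, thr[2], tolerance = 1e-12)
  # eliminated = reliability inside the threshold band
  real_rel <- abs(rec$reliability[rec$type == "real"])
  expect_setequal(sel$indices, which(real_rel > thr[2]))
})

test_that("pure-noise predictors rarely survive UVE", {
  survivors <- vapply(1:20, function(s) {
    withr::with_seed(s, {
      X <- matrix(rnorm(25 * 8), 25, 8)
      y <- rnorm(25)
    })
    # enough noise columns that the null survival rate ~ 1/(n_noise + 1)
    # sits well under the asserted bound
    n <- tryCatch(
      length(suppressWarnings(
        uve_select(X, y, n_noise = 40, n_components = 2, seed = s))$indices),
      error = function(e) 0L)
    n
  }, integer(1))
  # expected survivor rate at threshold_frac 0.99 stays low under the null
  expect_lte(mean(survivors / 8), 0.10)
})

test_that("chained selection composes names and is nested in the first stage", {
  sim <- generate_dataset(small_sim_config(seed = 3))
  ds <- sim$dataset
  y <- class_code(ds$labels)
  # identity o identity leaves the band set unchanged
  sel_id <- chain_select(ds$X, y, stage_identity(), stage_identity())
  expect_identical(sel_id$indices, seq_len(ncol(ds$X)))
  expect_identical(sel_id$method, "identity-identity")
  # second stage selecting everything reproduces the first stage
  cars1 <- stage_cars(n_runs = 15, seed = 4)
  sel_cars <- cars1(ds$X, y)
  sel_all <- chain_select(ds$X, y, cars1, stage_identity())
  expect_identical(sel_all$indices, sel_cars$indices)
  # CARS-MIV is a subset of CARS
  sel_miv <- chain_select(ds$X, y, cars1, stage_miv())
  expect_true(all(sel_miv$indices %in% sel_cars$indices))
  expect_identical(sel_miv$method, "CARS-MIV")
  expect_error(chain_select(ds$X, y,
                            function(X, y) stop("nothing"),
                            stage_identity()),
               "nothing")
})
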