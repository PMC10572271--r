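test_that("SNV centers and scales each spectrum to zero mean, unit pop sd", {
  out <- snv(matrix(c(1, 2, 3), 1))
  expect_equal(out[1, ], c(-1, 0, 1) / sqrt(2 / 3), tolerance = 1e-6)
  withr::with_seed(2, X <- matrix(rnorm(60), 5, 12))
  Z <- snv(X)
  expect_lt(max(abs(rowMeans(Z))), 1e-12)
  expect_equal(sqrt(rowMeans(Z^2)), rep(1, 5))
  expect_error(snv(rbind(c(5, 5, 5))), "constant")
})

test_that("SNV is invariant to per-row positive affine transforms", {
  withr::with_seed(3, x <- rnorm(20))
  expect_equal(snv(matrix(3.7 * x + 1.2, 1)), snv(matrix(x, 1)))
})

test_that("Savitzky-Golay derivative is exact on low-order polynomials", {
  b <- 1:21
  X <- rbind(b^2)
  d <- sg_derivative(X, window = 5, polyorder = 2, deriv = 1)
  expect_equal(d[1, 3:19], 2 * b[3:19], tolerance = 1e-8)
  ramp <- rbind(3 * b)
  expect_equal(sg_derivative(ramp, 5, 2, 1)[1, 3:19], rep(3, 17),
               tolerance = 1e-8)
  # deriv 0 reproduces smoothing: identity on polynomials <= polyorder
  expect_equal(sg_derivative(X, 7, 2, 0)[1, 4:18], X[1, 4:18],
               tolerance = 1e-8)
  expect_error(sg_derivative(X, window = 6, polyorder = 2), "odd")
})

test_that("Savitzky-Golay matches a per-point local polynomial fit oracle", {
  withr::with_seed(5, x <- rnorm(21))
  w <- 7L; po <- 3L; h <- 3L
  got <- sg_derivative(rbind(x), w, po, 1)[1, ]
  for (i in (h + 1):(21 - h)) {
    z <- (-h):h
    fit <- lm(x[(i - h):(i + h)] ~ poly(z, po, raw = TRUE))
    expect_equal(got[i], unname(coef(fit)[2]), tolerance = 1e-8)
  }
})

test_that("gap-segment derivative matches its defining window means", {
  # interior of a unit ramp has slope 1; reflected edges flatten to 0
  expect_equal(gap_segment_derivative(rbind(c(0, 1, 2, 3)), 1, 1, 1)[1, 2:3],
               c(1, 1))
  expect_equal(gap_segment_derivative(matrix(2, 3, 10), 2, 3, 1),
               matrix(0, 3, 10))
  withr::with_seed(6, x <- rnorm(30))
  got <- gap_segment_derivative(rbind(x), gap = 3, segment = 2, deriv = 1)[1, ]
  off <- 2L # ceiling(3/2)
  for (i in 4:27) {
    right <- mean(x[(i + off):(i + off + 1)])
    left <- mean(x[(i - off - 1):(i - off)])
    expect_equal(got[i], (right - left) / 5, tolerance = 1e-12)
  }
  expect_error(gap_segment_derivative(rbind(1:4), 3, 3, 1), "short")
})

test_that("baseline correction subtracts the row minimum and is offset-invariant", {
  expect_equal(baseline_correct(rbind(c(2, 3, 4))), rbind(c(0, 1, 2)))
  x <- rbind(c(0, 2, 1))
  expect_equal(baseline_correct(x), x)
  expect_equal(baseline_correct(x + 5), baseline_correct(x))
})

test_that("median smoothing removes spikes and matches a naive sliding median", {
  expect_equal(median_smooth(rbind(c(0, 0, 9, 0, 0)), 3),
               rbind(rep(0, 5)))
  mono <- rbind(sort(rnorm(12)))
  expect_equal(median_smooth(mono, 3)[1, 2:11], mono[1, 2:11])
  withr::with_seed(8, x <- rnorm(25))
  got <- median_smooth(rbind(x), 5)[1, ]
  for (i in 3:23) {
    expect_equal(got[i], median(x[(i - 2):(i + 2)]))
  }
  expect_error(median_smooth(rbind(x), 4), "odd")
})

test_that("all pretreatments preserve the matrix shape", {
  withr::with_seed(9, X <- matrix(runif(8 * 40, 0.2, 0.9), 8, 40))
  for (spec in default_pretreatments()) {
    expect_identical(dim(apply_pretreatment(X, spec)), dim(X),
                     info = spec$method)
  }
})

test_that("pretreatment comparison table is complete, exact on perfect data, and reproducible", {
  sim <- generate_dataset(small_sim_config(seed = 1))
  ds <- sim$dataset
  split <- kennard_stone_split(ds$X, 45)
  tab1 <- compare_pretreatments(ds, split, max_comp = 5L)
  expect_equal(nrow(tab1), length(default_pretreatments()) + 1L)
  expect_identical(tab1$method[1L], "raw")
  expect_true(all(c(attr(tab1, "winner")) %in% tab1$method))
  tab2 <- compare_pretreatments(ds, split, max_comp = 5L)
  expect_identical(tab1, tab2)

  # perfectly linear response, identical train/test: R2 = 1, RMSE = 0
  withr::with_seed(10, Xl <- matrix(runif(30 * 6, 0.1, 1), 30, 6))
  yl <- 1 + drop(Xl %*% c(3, -2, 1, 0, 0, 0))
  fit <- fit_pls1(Xl, yl, 6)
  sc <- score(fit, Xl, yl)
  expect_equal(sc$r2, 1, tolerance = 1e-10)
  expect_lt(sc$rmse, 1e-8)
})
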