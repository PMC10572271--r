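test_that("Kennard-Stone picks extreme points first and is deterministic", {
  X <- matrix(c(0, 1, 2, 10), 4, 1)
  sp <- kennard_stone_split(X, 2)
  expect_setequal(sp$calibration, c(1L, 4L))
  expect_identical(sp$prediction, c(2L, 3L))
  withr::with_seed(1, Xr <- matrix(rnorm(60 * 5), 60, 5))
  s1 <- kennard_stone_split(Xr, 45)
  s2 <- kennard_stone_split(Xr, 45)
  expect_identical(s1, s2)
  expect_length(s1$calibration, 45L)
  expect_length(intersect(s1$calibration, s1$prediction), 0L)
})

test_that("a 347-sample matrix splits into 259 + 88", {
  withr::with_seed(2, X <- matrix(rnorm(347 * 8), 347, 8))
  sp <- kennard_stone_split(X, 259)
  expect_length(sp$calibration, 259L)
  expect_length(sp$prediction, 88L)
})

test_that("every held-out point is at least as close to the calibration set as the last pick was", {
  withr::with_seed(3, X <- matrix(rnorm(40 * 3), 40, 3))
  sp <- kennard_stone_split(X, 25)
  D <- as.matrix(dist(X))
  cal <- sp$calibration
  last <- cal[length(cal)]
  last_sel_dist <- min(D[last, cal[-length(cal)]])
  for (j in sp$prediction) {
    expect_lte(min(D[j, cal]), last_sel_dist + 1e-12)
  }
})

test_that("confusion tallies counts in canonical order", {
  y <- rep(peach_classes(), times = c(3, 2, 2, 1))
  cm <- confusion(y, y)
  expect_equal(unname(diag(cm)), c(3L, 2L, 2L, 1L))
  expect_equal(sum(cm) - sum(diag(cm)), 0L)
  cm0 <- confusion(character(0), character(0))
  expect_equal(sum(cm0), 0L)
  expect_equal(dim(cm0), c(4L, 4L))
  expect_error(confusion(y, rep("mystery", 8)), "unknown")
  # tallying a printed prediction list reproduces its matrix
  y_true <- rep(peach_classes(), times = c(49, 9, 17, 13))
  y_pred <- c(rep("intact", 49),
              rep(c("internal_injury", "scab", "rotten"), c(7, 1, 1)),
              rep(c("scab", "rotten"), c(16, 1)),
              rep(c("scab", "rotten"), c(2, 11)))
  cm2 <- confusion(y_true, y_pred)
  expect_equal(unname(cm2),
               rbind(c(49L, 0L, 0L, 0L), c(0L, 7L, 1L, 1L),
                     c(0L, 0L, 16L, 1L), c(0L, 0L, 2L, 11L)))
})

test_that("discriminant rates are per-class diagonals and their unweighted mean", {
  cm <- rbind(c(49, 0, 0, 0), c(0, 4, 5, 0), c(0, 6, 11, 0),
              c(0, 0, 3, 10))
  r <- discriminant_rates(cm)
  expect_equal(round_half_up(unname(r$per_class), 2),
               c(100, 44.44, 64.71, 76.92))
  expect_equal(round_half_up(r$total, 2), 71.52)
  # identity predictions give 100 everywhere
  r100 <- discriminant_rates(diag(c(5, 2, 9, 4)))
  expect_equal(unname(r100$per_class), rep(100, 4))
  expect_equal(r100$total, 100)
  expect_error(discriminant_rates(rbind(c(1, 0), c(0, 0))), "no true samples")
})

test_that("total rate is invariant to a consistent class permutation", {
  cm <- rbind(c(10, 1, 0, 2), c(0, 7, 1, 1), c(2, 0, 12, 1),
              c(0, 1, 0, 9))
  perm <- c(3, 1, 4, 2)
  expect_equal(discriminant_rates(cm[perm, perm])$total,
               discriminant_rates(cm)$total)
})

test_that("macro total equals micro accuracy only for equal class sizes or equal rates", {
  # equal class sizes: macro == micro
  cm_eq <- rbind(c(8, 2, 0, 0), c(1, 9, 0, 0), c(0, 0, 10, 0),
                 c(0, 3, 0, 7))
  macro <- discriminant_rates(cm_eq)$total
  micro <- 100 * sum(diag(cm_eq)) / sum(cm_eq)
  expect_equal(macro, micro)
  # unequal sizes with unequal rates: they differ
  cm_ne <- rbind(c(49, 0, 0, 0), c(0, 4, 5, 0), c(0, 6, 11, 0),
                 c(0, 0, 3, 10))
  expect_gt(abs(discriminant_rates(cm_ne)$total -
                100 * sum(diag(cm_ne)) / sum(cm_ne)), 1)
})

test_that("reports assemble, hash configs, and round-trip through JSON", {
  d_y <- rep(peach_classes(), each = 5)
  sel <- selection_result("CARS", c(2L, 5L), wavelengths = NULL, seed = 1L)
  cls <- structure(list(kind = "ga_svm",
                        hyperparams = list(C = 2, gamma = 0.5),
                        cv_fitness = 0.9),
                   class = "peach_classifier")
  rep1 <- build_report(sel, cls, d_y, d_y, config = list(a = 1), seed = 1L)
  expect_equal(rep1$total_rate, 100)
  expect_equal(sum(rep1$confusion) - sum(diag(rep1$confusion)), 0L)
  rep2 <- build_report(sel, cls, d_y, d_y, config = list(a = 2), seed = 1L)
  expect_false(identical(rep1$config_hash, rep2$config_hash))
  rep3 <- build_report(sel, cls, d_y, d_y, config = list(a = 1), seed = 1L)
  expect_identical(rep1$config_hash, rep3$config_hash)
  path <- withr::local_tempfile(fileext = ".json")
  write_report(rep1, path)
  back <- jsonlite::fromJSON(path)
  expect_equal(back$total_rate, rep1$total_rate)
  expect_equal(unname(back$confusion), unname(unclass(rep1$confusion)))
  expect_error(build_report(NULL, cls, d_y, d_y), "missing")
})

test_that("presentation rounding is half away from zero", {
  expect_equal(round_half_up(c(0.5, 1.5, 2.5), 0), c(1, 2, 3))
  expect_equal(round_half_up(-2.5, 0), -3)
  expect_equal(round_half_up(100 * 8 / 9, 2), 88.89)
  expect_equal(round_half_up(100 * 11 / 17, 2), 64.71)
})
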