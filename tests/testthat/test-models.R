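# two well-separated Gaussian blobs per class in 2-D
blob_data <- function(n_per = 12L, sep = 6, seed = 1L, classes = 4L) {
  withr::with_seed(seed, {
    centers <- cbind(c(0, sep, 0, sep), c(0, 0, sep, sep))[seq_len(classes), ,
                                                           drop = FALSE]
    X <- do.call(rbind, lapply(seq_len(classes), function(k) {
      cbind(rnorm(n_per, centers[k, 1], 0.4), rnorm(n_per, centers[k, 2], 0.4))
    }))
    list(X = X, y = rep(peach_classes()[seq_len(classes)], each = n_per))
  })
}

test_that("GA best-so-far fitness is monotone non-decreasing with elitism", {
  d <- blob_data(seed = 2)
  cls <- ga_svm_train(d$X, d$y, tiny_ga(seed = 2, gens = 6))
  expect_true(all(diff(cls$trace$best_fitness) >= 0))
  expect_equal(nrow(cls$trace), 6L)
})

test_that("GA-SVM separates well-separated classes and is reproducible", {
  d <- blob_data(seed = 3)
  c1 <- ga_svm_train(d$X, d$y, tiny_ga(seed = 3))
  expect_gte(c1$cv_fitness, 0.95)
  expect_identical(predict(c1, d$X), d$y)
  c2 <- ga_svm_train(d$X, d$y, tiny_ga(seed = 3))
  expect_identical(c1$hyperparams, c2$hyperparams)
  expect_identical(c1$trace, c2$trace)
})

test_that("a degenerate single-chromosome search keeps a constant best fitness", {
  d <- blob_data(seed = 4, classes = 2L)
  cfg <- ga_config(population_size = 2L, max_generations = 4L,
                   bits_per_parameter = 1L, log2_c_range = c(0, 0),
                   log2_gamma_range = c(0, 0), mutation_prob = 0,
                   crossover_prob = 0, seed = 4L, cv_folds = 3L)
  cls <- ga_svm_train(d$X, d$y, cfg)
  expect_equal(length(unique(cls$trace$best_fitness)), 1L)
  expect_equal(cls$hyperparams$C, 1)
  expect_equal(cls$hyperparams$gamma, 1)
})

test_that("training rejects single-class input and tiny classes", {
  d <- blob_data(seed = 5, classes = 2L)
  expect_error(ga_svm_train(d$X[1:12, ], d$y[1:12], tiny_ga()), "2 classes")
  Xs <- d$X[c(1:10, 13), ]; ys <- d$y[c(1:10, 13)]
  expect_error(ga_svm_train(Xs, ys, tiny_ga()), "fewer than 2")
})

test_that("LS-SVM binary subproblem equals the dense augmented-system oracle", {
  withr::with_seed(6, X <- matrix(rnorm(12), 6, 2))
  y_pm <- c(1, 1, 1, -1, -1, -1)
  gam <- 4; sig2 <- 2
  K <- exp(-as.matrix(dist(X))^2 / sig2)
  M <- rbind(c(0, rep(1, 6)), cbind(1, K + diag(6) / gam))
  oracle <- solve(M, c(0, y_pm))
  got <- peachspec:::lssvm_solve(K, y_pm, gam)
  expect_equal(got$b, oracle[1], tolerance = 1e-10)
  expect_equal(got$alpha, oracle[-1], tolerance = 1e-10)
})

test_that("LS-SVM classifies separated data and records the full grid trace", {
  d <- blob_data(seed = 7)
  grid <- tiny_ls(seed = 7)
  cls <- ls_svm_train(d$X, d$y, grid)
  expect_identical(predict(cls, d$X), d$y)
  expect_equal(nrow(cls$trace), length(grid$gam) * length(grid$sig2))
  expect_gte(cls$cv_fitness, 0.9)
})

test_that("predictions are deterministic and survive serialization", {
  d <- blob_data(seed = 8)
  cls <- ls_svm_train(d$X, d$y, tiny_ls(seed = 8))
  Xdup <- d$X[c(1, 1, 5, 5), ]
  p <- predict(cls, Xdup)
  expect_identical(p[1], p[2])
  expect_identical(p[3], p[4])
  path <- withr::local_tempfile(fileext = ".rds")
  saveRDS(cls, path)
  expect_identical(predict(readRDS(path), d$X), predict(cls, d$X))
  expect_error(predict(cls, d$X[, 1, drop = FALSE]), "bands")
})

test_that("GA search is no worse than random search at equal budget", {
  sim <- generate_dataset(small_sim_config(seed = 9))
  ds <- sim$dataset
  X <- ds$X[, seq(1, 60, by = 6)] # a small band subset keeps this quick
  wins <- 0L
  for (s in 1:5) {
    cfg <- ga_config(population_size = 10L, max_generations = 15L,
                     bits_per_parameter = 10L, seed = s)
    ga <- ga_svm_train(X, ds$labels, cfg)
    scaler <- peachspec:::minmax_fit(X)
    Xn <- peachspec:::minmax_apply(X, scaler)
    folds <- peachspec:::stratified_folds(ds$labels, cfg$cv_folds, cfg$seed)
    # random search gets exactly the number of distinct evaluations the GA
    # actually performed
    rand_best <- withr::with_seed(1000 + s, {
      max(vapply(seq_len(ga$n_evaluations), function(i) {
        C <- 2^runif(1, -5, 15); g <- 2^runif(1, -15, 3)
        peachspec:::svm_cv_accuracy(Xn, ds$labels, C, g, folds)
      }, numeric(1)))
    })
    if (ga$cv_fitness >= rand_best - 1e-12) wins <- wins + 1L
  }
  expect_gte(wins, 3L)
})
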