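# Classifiers: GA-tuned RBF C-SVM (via e1071) and a grid-searched LS-SVM.
# Both min-max normalize features on the calibration data and store the
# scaling so prediction re-applies it.

minmax_fit <- function(X) {
  lo <- apply(X, 2L, min)
  hi <- apply(X, 2L, max)
  rng <- hi - lo
  rng[rng < 1e-300] <- 1
  list(lo = lo, rng = rng)
}

minmax_apply <- function(X, scaler) {
  sweep(sweep(X, 2L, scaler$lo), 2L, scaler$rng, "/")
}

stratified_folds <- function(y, k, seed) {
  y <- as.character(y)
  counts <- table(y)
  if (any(counts < 2L)) {
    stop("stratified ", k, "-fold CV impossible: class '",
         names(counts)[counts < 2L][1L], "' has fewer than 2 samples")
  }
  folds <- integer(length(y))
  withr::with_seed(seed, {
    for (cl in names(counts)) {
      idx <- which(y == cl)
      idx <- idx[sample.int(length(idx))]
      folds[idx] <- rep(seq_len(k), length.out = length(idx))
    }
  })
  folds
}

#' Genetic-algorithm configuration for SVM tuning
#'
#' Defaults follow common SVM-tuning practice: 20-bit binary encoding of
#' each hyperparameter on a log2 grid, C in [2^-5, 2^15] and the RBF gamma
#' in [2^-15, 2^3], population 20, 100 generations, crossover 0.7,
#' per-bit mutation 0.01, elitism, and five-fold cross-validated accuracy
#' as the fitness.
#'
#' @param population_size individuals per generation (>= 2).
#' @param max_generations generations to run.
#' @param bits_per_parameter bits encoding each of C and gamma.
#' @param log2_c_range,log2_gamma_range search ranges in log2 units.
#' @param crossover_prob,mutation_prob genetic-operator probabilities.
#' @param cv_folds folds for the fitness (stratified).
#' @param elitism carry the best individual unchanged into each generation.
#' @param seed RNG seed for the whole search.
#' @return A `ga_config` list.
#' @export
ga_config <- function(population_size = 20L, max_generations = 100L,
                      bits_per_parameter = 20L,
                      log2_c_range = c(-5, 15), log2_gamma_range = c(-15, 3),
                      crossover_prob = 0.7, mutation_prob = 0.01,
                      cv_folds = 5L, elitism = TRUE, seed = 2023L) {
  if (population_size < 2L) stop("population_size must be >= 2")
  if (cv_folds < 2L) stop("cv_folds must be >= 2")
  if (crossover_prob < 0 || crossover_prob > 1 ||
      mutation_prob < 0 || mutation_prob > 1) {
    stop("probabilities must lie in [0, 1]")
  }
  structure(list(population_size = as.integer(population_size),
                 max_generations = as.integer(max_generations),
                 bits_per_parameter = as.integer(bits_per_parameter),
                 log2_c_range = log2_c_range,
                 log2_gamma_range = log2_gamma_range,
                 crossover_prob = crossover_prob,
                 mutation_prob = mutation_prob,
                 cv_folds = as.integer(cv_folds),
                 elitism = isTRUE(elitism), seed = as.integer(seed)),
            class = "ga_config")
}

decode_chromosome <- function(bits, config) {
  nb <- config$bits_per_parameter
  to_val <- function(b, range) {
    ival <- sum(b * 2^(rev(seq_along(b)) - 1L))
    range[1L] + ival / (2^length(b) - 1) * (range[2L] - range[1L])
  }
  c(C = 2^to_val(bits[seq_len(nb)], config$log2_c_range),
    gamma = 2^to_val(bits[nb + seq_len(nb)], config$log2_gamma_range))
}

svm_cv_accuracy <- function(X, y, C, gamma, folds) {
  y <- factor(y)
  correct <- 0L
  for (f in seq_len(max(folds))) {
    tr <- folds != f
    fit <- e1071::svm(x = X[tr, , drop = FALSE], y = y[tr],
                      type = "C-classification", kernel = "radial",
                      cost = C, gamma = gamma, scale = FALSE)
    pred <- stats::predict(fit, X[!tr, , drop = FALSE])
    correct <- correct + sum(pred == y[!tr])
  }
  correct / length(y)
}

#' Train a GA-optimized RBF support-vector classifier
#'
#' Binary chromosomes encode (C, gamma) on log2 grids; fitness is the
#' stratified cross-validated accuracy of the corresponding RBF C-SVM on
#' min-max-normalized calibration data. Generations apply roulette-wheel
#' selection, single-point crossover, bitwise mutation, and (by default)
#' elitism; the returned classifier is refit on all calibration samples at
#' the best hyperparameters found (fitness ties broken toward smaller C,
#' then smaller gamma). Identical chromosomes are evaluated once (cached).
#'
#' @param X calibration matrix (samples x selected bands).
#' @param y class labels (character, see [peach_classes()]).
#' @param config a [ga_config()].
#' @return A `peach_classifier` with the fitted SVM, chosen
#'   hyperparameters, the per-generation tuning `trace`
#'   (`generation`, `best_fitness`, `mean_fitness`) and the stored
#'   normalization.
#' @export
ga_svm_train <- function(X, y, config = ga_config()) {
  X <- as.matrix(X)
  y <- as.character(y)
  if (length(unique(y)) < 2L) stop("need at least 2 classes to train")
  scaler <- minmax_fit(X)
  Xn <- minmax_apply(X, scaler)
  folds <- stratified_folds(y, config$cv_folds, config$seed)
  nbits <- 2L * config$bits_per_parameter
  cache <- new.env(parent = emptyenv())
  fitness <- function(bits) {
    key <- paste(bits, collapse = "")
    if (!is.null(cache[[key]])) return(cache[[key]])
    hp <- decode_chromosome(bits, config)
    val <- svm_cv_accuracy(Xn, y, hp[["C"]], hp[["gamma"]], folds)
    cache[[key]] <- val
    val
  }
  better <- function(fa, hpa, fb, hpb) {
    # strictly better fitness, or equal fitness with a simpler model
    if (fa > fb + 1e-12) return(TRUE)
    if (fa < fb - 1e-12) return(FALSE)
    if (hpa[["C"]] != hpb[["C"]]) return(hpa[["C"]] < hpb[["C"]])
    hpa[["gamma"]] < hpb[["gamma"]]
  }
  trace <- data.frame(generation = integer(), best_fitness = numeric(),
                      mean_fitness = numeric())
  withr::with_seed(config$seed + 1L, {
    pop <- lapply(seq_len(config$population_size), function(i) {
      stats::rbinom(nbits, 1L, 0.5)
    })
    best_bits <- NULL; best_fit <- -Inf; best_hp <- NULL
    for (g in seq_len(config$max_generations)) {
      fits <- vapply(pop, fitness, numeric(1))
      for (i in seq_along(pop)) {
        hp_i <- decode_chromosome(pop[[i]], config)
        if (is.null(best_bits) ||
            better(fits[i], hp_i, best_fit, best_hp)) {
          best_bits <- pop[[i]]; best_fit <- fits[i]; best_hp <- hp_i
        }
      }
      trace <- rbind(trace, data.frame(generation = g,
                                       best_fitness = best_fit,
                                       mean_fitness = mean(fits)))
      if (g == config$max_generations) break
      # roulette selection on fitness (accuracies are nonnegative)
      probs <- fits + 1e-9
      parents <- sample.int(length(pop), length(pop), replace = TRUE,
                            prob = probs)
      nextpop <- pop[parents]
      # single-point crossover on consecutive pairs
      for (i in seq(1L, length(nextpop) - 1L, by = 2L)) {
        if (stats::runif(1) < config$crossover_prob) {
          cut <- sample.int(nbits - 1L, 1L)
          a <- nextpop[[i]]; b <- nextpop[[i + 1L]]
          nextpop[[i]] <- c(a[seq_len(cut)], b[(cut + 1L):nbits])
          nextpop[[i + 1L]] <- c(b[seq_len(cut)], a[(cut + 1L):nbits])
        }
      }
      # bitwise mutation
      nextpop <- lapply(nextpop, function(bits) {
        flip <- stats::runif(nbits) < config$mutation_prob
        bits[flip] <- 1L - bits[flip]
        bits
      })
      if (config$elitism) nextpop[[1L]] <- best_bits
      pop <- nextpop
    }
  })
  fit <- e1071::svm(x = Xn, y = factor(y, levels = sort(unique(y))),
                    type = "C-classification", kernel = "radial",
                    cost = best_hp[["C"]], gamma = best_hp[["gamma"]],
                    scale = FALSE)
  structure(list(kind = "ga_svm", model = fit,
                 hyperparams = list(C = unname(best_hp[["C"]]),
                                    gamma = unname(best_hp[["gamma"]])),
                 cv_fitness = best_fit, trace = trace, scaler = scaler,
                 n_evaluations = length(ls(cache)),
                 n_bands = ncol(X), config = config),
            class = "peach_classifier")
}

rbf_kernel <- function(X1, X2, sig2) {
  d2 <- outer(rowSums(X1^2), rowSums(X2^2), "+") - 2 * tcrossprod(X1, X2)
  exp(-pmax(d2, 0) / sig2)
}

# solve the LS-SVM dual: [0 1'; 1 K + I/gam] [b; alpha] = [0; y]
lssvm_solve <- function(K, y_pm, gam) {
  n <- nrow(K)
  M <- rbind(c(0, rep(1, n)), cbind(1, K + diag(n) / gam))
  sol <- tryCatch(solve(M, c(0, y_pm)), error = function(e) NULL)
  if (is.null(sol)) {
    sol <- tryCatch(solve(M + diag(1e-8, n + 1L), c(0, y_pm)),
                    error = function(e) {
                      stop("LS-SVM system is singular even after jitter")
                    })
  }
  list(b = sol[1L], alpha = sol[-1L])
}

lssvm_ovo_fit <- function(Xn, y, gam, sig2) {
  classes <- sort(unique(y))
  pairs <- utils::combn(classes, 2L, simplify = FALSE)
  fits <- lapply(pairs, function(pr) {
    idx <- which(y %in% pr)
    y_pm <- ifelse(y[idx] == pr[1L], 1, -1)
    Xp <- Xn[idx, , drop = FALSE]
    sol <- lssvm_solve(rbf_kernel(Xp, Xp, sig2), y_pm, gam)
    list(pair = pr, X = Xp, alpha = sol$alpha, b = sol$b)
  })
  list(fits = fits, classes = classes, gam = gam, sig2 = sig2)
}

lssvm_ovo_predict <- function(machine, Xn) {
  classes <- machine$classes
  votes <- matrix(0L, nrow(Xn), length(classes),
                  dimnames = list(NULL, classes))
  margin <- matrix(0, nrow(Xn), length(classes),
                   dimnames = list(NULL, classes))
  for (f in machine$fits) {
    dec <- rbf_kernel(Xn, f$X, machine$sig2) %*% f$alpha + f$b
    win <- ifelse(dec >= 0, f$pair[1L], f$pair[2L])
    for (cl in f$pair) {
      votes[, cl] <- votes[, cl] + (win == cl)
      margin[, cl] <- margin[, cl] + abs(dec) * (win == cl)
    }
  }
  vapply(seq_len(nrow(Xn)), function(i) {
    top <- which(votes[i, ] == max(votes[i, ]))
    if (length(top) > 1L) top <- top[which.max(margin[i, top])]
    classes[top]
  }, character(1))
}

#' Default LS-SVM tuning grid
#'
#' @param gam regularization values (log-spaced).
#' @param sig2 squared RBF bandwidth values (log-spaced).
#' @param cv_folds folds for the grid search (stratified).
#' @param seed RNG seed for the fold assignment.
#' @return An `ls_grid` list.
#' @export
ls_grid <- function(gam = 2^seq(-2, 10, by = 2),
                    sig2 = 2^seq(-2, 12, by = 2),
                    cv_folds = 5L, seed = 2023L) {
  structure(list(gam = gam, sig2 = sig2, cv_folds = as.integer(cv_folds),
                 seed = as.integer(seed)),
            class = "ls_grid")
}

#' Train a grid-searched least-squares SVM classifier
#'
#' Least-squares SVM with RBF kernel: each one-vs-one binary subproblem is
#' the solution of the equality-constrained dual linear system
#' `[0 1'; 1 K + I/gam][b; alpha] = [0; y]`, and four-class prediction uses
#' majority voting (ties broken by the larger aggregate decision margin).
#' (gam, sig2) is chosen from a log-spaced grid by stratified
#' cross-validated accuracy (ties toward smaller gam, then smaller sig2);
#' the full grid of CV scores is kept as the tuning trace.
#'
#' @param X calibration matrix (samples x selected bands).
#' @param y class labels.
#' @param grid an [ls_grid()].
#' @return A `peach_classifier` with the fitted one-vs-one machinery,
#'   chosen hyperparameters, and the grid `trace`
#'   (`gam`, `sig2`, `cv_accuracy`).
#' @export
ls_svm_train <- function(X, y, grid = ls_grid()) {
  X <- as.matrix(X)
  y <- as.character(y)
  if (length(unique(y)) < 2L) stop("need at least 2 classes to train")
  scaler <- minmax_fit(X)
  Xn <- minmax_apply(X, scaler)
  folds <- stratified_folds(y, grid$cv_folds, grid$seed)
  combos <- expand.grid(gam = grid$gam, sig2 = grid$sig2,
                        KEEP.OUT.ATTRS = FALSE)
  acc <- vapply(seq_len(nrow(combos)), function(r) {
    correct <- 0L
    for (f in seq_len(grid$cv_folds)) {
      tr <- folds != f
      machine <- lssvm_ovo_fit(Xn[tr, , drop = FALSE], y[tr],
                               combos$gam[r], combos$sig2[r])
      pred <- lssvm_ovo_predict(machine, Xn[!tr, , drop = FALSE])
      correct <- correct + sum(pred == y[!tr])
    }
    correct / length(y)
  }, numeric(1))
  ord <- order(-acc, combos$gam, combos$sig2)
  best <- ord[1L]
  machine <- lssvm_ovo_fit(Xn, y, combos$gam[best], combos$sig2[best])
  structure(list(kind = "ls_svm", model = machine,
                 hyperparams = list(gam = combos$gam[best],
                                    sig2 = combos$sig2[best]),
                 cv_fitness = acc[best],
                 trace = cbind(combos, cv_accuracy = acc),
                 scaler = scaler, n_bands = ncol(X), config = grid),
            class = "peach_classifier")
}

#' Predict class labels
#'
#' @param object a `peach_classifier` from [ga_svm_train()] or
#'   [ls_svm_train()].
#' @param newdata matrix with the classifier's band count; the stored
#'   min-max normalization is re-applied.
#' @param ... unused.
#' @return Character vector of class labels.
#' @export
predict.peach_classifier <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  if (ncol(X) != object$n_bands) {
    stop("newdata has ", ncol(X), " bands; classifier expects ",
         object$n_bands)
  }
  Xn <- minmax_apply(X, object$scaler)
  if (object$kind == "ga_svm") {
    as.character(stats::predict(object$model, Xn))
  } else {
    lssvm_ovo_predict(object$model, Xn)
  }
}

#' @export
print.peach_classifier <- function(x, ...) {
  cat(toupper(gsub("_", "-", x$kind)), "classifier;",
      x$n_bands, "bands; CV fitness", round(x$cv_fitness, 4), "\n")
  cat("hyperparameters:",
      paste(names(x$hyperparams), signif(unlist(x$hyperparams), 4),
            sep = " = ", collapse = ", "), "\n")
  invisible(x)
}
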