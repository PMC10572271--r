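# PLS1 regression on mean-centered data (NIPALS deflation). For a single
# response the NIPALS weight vector is available in closed form per
# component, so each component costs one pass over the matrix; coefficient
# vectors for every nested component count are kept because the selection
# engines (CARS weights, UVE reliabilities) introspect them.

#' Fit a single-response PLS regression
#'
#' NIPALS-style PLS1 on mean-centered data. Components whose weight or
#' score norm falls below 1e-12 indicate exhausted rank; the model is then
#' truncated with a warning.
#'
#' @param X predictor matrix (samples x bands).
#' @param y numeric response (class codes in this package's pipeline).
#' @param n_components number of latent variables; at most
#'   `min(nrow(X) - 1, ncol(X))`.
#' @return A `pls1_model`: coefficients `b` (for centered X), centering
#'   vectors, latent structure (`W`, `P`, `q`), the per-component
#'   coefficient matrix `b_all`, and the achieved `n_components`.
#' @export
fit_pls1 <- function(X, y, n_components) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  n <- nrow(X); p <- ncol(X)
  if (length(y) != n) stop("length(y) must equal nrow(X)")
  if (stats::var(y) < 1e-24) stop("response y has zero variance")
  n_components <- as.integer(n_components)
  if (n_components < 1L || n_components > min(n - 1L, p)) {
    stop("n_components must be in 1..min(n_samples - 1, n_bands) = ",
         min(n - 1L, p))
  }
  x_mean <- colMeans(X)
  y_mean <- mean(y)
  Xc <- sweep(X, 2L, x_mean)
  yc <- y - y_mean
  W <- matrix(0, p, n_components)
  P <- matrix(0, p, n_components)
  q <- numeric(n_components)
  a_done <- 0L
  for (a in seq_len(n_components)) {
    w <- crossprod(Xc, yc)[, 1L]
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) break
    w <- w / nw
    t_sc <- Xc %*% w
    tt <- sum(t_sc^2)
    if (tt < 1e-12) break
    p_load <- crossprod(Xc, t_sc)[, 1L] / tt
    q_a <- sum(yc * t_sc) / tt
    Xc <- Xc - t_sc %*% t(p_load)
    yc <- yc - q_a * t_sc
    W[, a] <- w; P[, a] <- p_load; q[a] <- q_a
    a_done <- a
  }
  if (a_done == 0L) stop("X has no covariance with y; cannot fit PLS")
  if (a_done < n_components) {
    warning("rank exhausted after ", a_done, " components (requested ",
            n_components, ")")
    W <- W[, seq_len(a_done), drop = FALSE]
    P <- P[, seq_len(a_done), drop = FALSE]
    q <- q[seq_len(a_done)]
  }
  # nested coefficient vectors b^(a) = W_a (P_a' W_a)^{-1} q_a for a = 1..A
  b_all <- matrix(0, p, a_done)
  for (a in seq_len(a_done)) {
    Wa <- W[, seq_len(a), drop = FALSE]
    Pa <- P[, seq_len(a), drop = FALSE]
    b_all[, a] <- Wa %*% solve(crossprod(Pa, Wa), q[seq_len(a)])
  }
  structure(list(b = b_all[, a_done], b_all = b_all, x_mean = x_mean,
                 y_mean = y_mean, W = W, P = P, q = q,
                 n_components = a_done),
            class = "pls1_model")
}

#' @export
predict.pls1_model <- function(object, newdata, n_components = NULL, ...) {
  X <- as.matrix(newdata)
  if (ncol(X) != length(object$x_mean)) {
    stop("newdata has ", ncol(X), " bands; model expects ",
         length(object$x_mean))
  }
  b <- if (is.null(n_components)) object$b else {
    n_components <- as.integer(n_components)
    if (n_components < 1L || n_components > object$n_components) {
      stop("n_components out of fitted range 1..", object$n_components)
    }
    object$b_all[, n_components]
  }
  drop(sweep(X, 2L, object$x_mean) %*% b) + object$y_mean
}

r2_rmse <- function(obs, pred) {
  res <- obs - pred
  rmse <- sqrt(mean(res^2))
  sstot <- sum((obs - mean(obs))^2)
  if (sstot < 1e-24) {
    warning("zero-variance response: R^2 undefined (NaN)")
    return(list(r2 = NaN, rmse = rmse))
  }
  list(r2 = 1 - sum(res^2) / sstot, rmse = rmse)
}

#' Score a fitted PLS model
#'
#' @param model a `pls1_model`.
#' @param X predictor matrix with the model's band count.
#' @param y observed numeric response.
#' @return List with `r2` (`1 - SS_res/SS_tot`) and `rmse`.
#' @export
score <- function(model, X, y) {
  r2_rmse(as.numeric(y), predict(model, X))
}

make_folds <- function(n, k, seed = NULL) {
  if (k > n) stop("fold count (", k, ") exceeds sample count (", n, ")")
  if (!is.null(seed)) {
    perm <- withr::with_seed(seed, sample.int(n))
  } else {
    perm <- sample.int(n)
  }
  folds <- rep(seq_len(k), length.out = n)
  out <- integer(n)
  out[perm] <- folds
  out
}

# out-of-fold RMSE for each component count 1..max_comp (one nested fit per
# fold), used by CARS and by the component-count chooser
cv_rmse_profile <- function(X, y, max_comp, folds_id) {
  X <- as.matrix(X); y <- as.numeric(y)
  k <- max(folds_id)
  pred <- matrix(NA_real_, length(y), max_comp)
  amin <- max_comp
  for (f in seq_len(k)) {
    tr <- folds_id != f
    a_f <- min(max_comp, sum(tr) - 1L, ncol(X))
    fit <- suppressWarnings(fit_pls1(X[tr, , drop = FALSE], y[tr], a_f))
    amin <- min(amin, fit$n_components)
    for (a in seq_len(fit$n_components)) {
      pred[!tr, a] <- predict(fit, X[!tr, , drop = FALSE], n_components = a)
    }
  }
  vapply(seq_len(amin), function(a) sqrt(mean((y - pred[, a])^2)),
         numeric(1))
}

#' Cross-validated RMSE of a PLS1 model
#'
#' @param X predictor matrix.
#' @param y numeric response.
#' @param n_components latent-variable count.
#' @param scheme `"loo"` (leave-one-out, deterministic) or `"kfold"`.
#' @param k fold count for `"kfold"`.
#' @param seed seed for the fold assignment (`"kfold"` only).
#' @return Root-mean-square error of the out-of-fold predictions.
#' @export
cv_rmse <- function(X, y, n_components, scheme = c("loo", "kfold"), k = 5L,
                    seed = 2023L) {
  scheme <- match.arg(scheme)
  X <- as.matrix(X)
  n <- nrow(X)
  folds_id <- if (scheme == "loo") seq_len(n) else make_folds(n, k, seed)
  prof <- cv_rmse_profile(X, y, n_components, folds_id)
  if (length(prof) < n_components) {
    warning("rank supported only ", length(prof), " components in CV")
  }
  prof[length(prof)]
}

#' Choose a PLS component count by minimum cross-validated RMSE
#'
#' @inheritParams cv_rmse
#' @param max_comp largest component count considered (capped by rank).
#' @param folds fold count.
#' @return Integer component count with the smallest CV RMSE.
#' @export
choose_ncomp <- function(X, y, max_comp = 10L, folds = 5L, seed = 2023L) {
  X <- as.matrix(X)
  a_cap <- max(1L, min(max_comp, nrow(X) - 1L - ceiling(nrow(X) / folds),
                       ncol(X)))
  folds_id <- make_folds(nrow(X), folds, seed)
  prof <- cv_rmse_profile(X, y, a_cap, folds_id)
  which.min(prof)
}
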