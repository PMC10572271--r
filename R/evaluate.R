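# Kennard-Stone partitioning, confusion matrices, discriminant rates and
# report assembly.

#' Kennard--Stone calibration/prediction split
#'
#' Deterministic max-min partitioning: the first two calibration picks are
#' the sample pair at maximal Euclidean distance; each subsequent pick is
#' the sample whose minimal distance to the already-chosen calibration set
#' is largest. Distance ties are broken toward the lower sample index.
#'
#' @param X sample matrix (rows are compared in Euclidean metric).
#' @param n_cal calibration-set size, `2 <= n_cal < nrow(X)`.
#' @return List with `calibration` (indices, in selection order) and
#'   `prediction` (remaining indices, ascending).
#' @export
kennard_stone_split <- function(X, n_cal) {
  X <- as.matrix(X)
  n <- nrow(X)
  n_cal <- as.integer(n_cal)
  if (n_cal < 2L || n_cal >= n) stop("n_cal must satisfy 2 <= n_cal < ", n)
  D <- as.matrix(stats::dist(X))
  # max-distance pair, first occurrence scanning rows then columns
  first <- arrayInd(which.max(t(D)), dim(D))
  sel <- sort(c(first[1, 2], first[1, 1]))
  mind <- pmin(D[, sel[1L]], D[, sel[2L]])
  mind[sel] <- -Inf
  while (length(sel) < n_cal) {
    nxt <- which.max(mind) # which.max takes the first (lowest index) on ties
    sel <- c(sel, nxt)
    mind <- pmin(mind, D[, nxt])
    mind[nxt] <- -Inf
  }
  list(calibration = sel, prediction = setdiff(seq_len(n), sel))
}

#' Confusion matrix in canonical class order
#'
#' @param y_true,y_pred equal-length label vectors (see [peach_classes()]).
#' @param classes class order; defaults to the canonical four.
#' @return Integer matrix, rows = true class, columns = predicted class.
#' @export
confusion <- function(y_true, y_pred, classes = peach_classes()) {
  if (length(y_true) != length(y_pred)) {
    stop("y_true and y_pred must have equal length")
  }
  bad <- setdiff(unique(c(as.character(y_true), as.character(y_pred))),
                 classes)
  if (length(bad) > 0L) {
    stop("unknown label(s): ", paste(bad, collapse = ", "))
  }
  ft <- factor(as.character(y_true), levels = classes)
  fp <- factor(as.character(y_pred), levels = classes)
  cm <- unclass(table(ft, fp))
  dimnames(cm) <- list(true = classes, predicted = classes)
  storage.mode(cm) <- "integer"
  cm
}

#' Per-class and macro-averaged discriminant rates
#'
#' The per-class discriminant rate is the percentage of that class's
#' samples on the matrix diagonal (`100 * cm[i,i] / rowsum(i)`); the total
#' discriminant rate is the unweighted arithmetic mean of the per-class
#' rates. Values are kept at full precision; round only for presentation.
#'
#' @param cm square confusion matrix, rows = true class.
#' @return List with `per_class` (named numeric, %) and `total` (%).
#' @export
discriminant_rates <- function(cm) {
  cm <- as.matrix(cm)
  if (nrow(cm) != ncol(cm)) stop("confusion matrix must be square")
  rs <- rowSums(cm)
  if (any(rs == 0)) {
    nm <- rownames(cm)
    if (is.null(nm)) nm <- as.character(seq_len(nrow(cm)))
    stop("class '", nm[rs == 0][1L],
         "' has no true samples; its rate is undefined")
  }
  per <- 100 * diag(cm) / rs
  names(per) <- rownames(cm)
  list(per_class = per, total = mean(per))
}

#' Round half away from zero
#'
#' Presentation rounding used for reported percentages (base R's `round()`
#' rounds half to even).
#'
#' @param x numeric vector.
#' @param digits decimal places.
#' @return Rounded vector.
#' @export
round_half_up <- function(x, digits = 2L) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

config_hash <- function(obj) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA,
                              force = TRUE), tmp)
  unname(tools::md5sum(tmp))
}

#' Assemble an evaluation report
#'
#' Bundles the confusion matrix, per-class and total discriminant rates,
#' the selection, classifier metadata, optional PLS metrics, and
#' provenance (method chain, seed, config hash) into one serializable
#' structure.
#'
#' @param selection a [selection_result()].
#' @param classifier a `peach_classifier`.
#' @param y_true,y_pred prediction-set labels (true and predicted).
#' @param pls_metrics optional named list of PLS diagnostics.
#' @param config optional configuration list; hashed into the provenance.
#' @param seed pipeline seed.
#' @return An `evaluation_report` list.
#' @export
build_report <- function(selection, classifier, y_true, y_pred,
                         pls_metrics = NULL, config = NULL, seed = NULL) {
  missing_bits <- c(selection = is.null(selection),
                    classifier = is.null(classifier),
                    y_true = is.null(y_true), y_pred = is.null(y_pred))
  if (any(missing_bits)) {
    stop("cannot assemble report; missing: ",
         paste(names(missing_bits)[missing_bits], collapse = ", "))
  }
  cm <- confusion(y_true, y_pred)
  rates <- discriminant_rates(cm)
  structure(list(
    method = paste(selection$method,
                   toupper(gsub("_", "-", classifier$kind)), sep = "-"),
    selection = list(method = selection$method,
                     indices = selection$indices,
                     wavelengths_nm = selection$wavelengths_nm,
                     n_bands = length(selection$indices),
                     seed = selection$seed),
    model = list(kind = classifier$kind,
                 hyperparams = classifier$hyperparams,
                 cv_fitness = classifier$cv_fitness),
    confusion = cm,
    per_class_rates = rates$per_class,
    total_rate = rates$total,
    pls_metrics = pls_metrics,
    seed = seed,
    config_hash = if (!is.null(config)) config_hash(config) else NULL
  ), class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("evaluation_report:", x$method, "\n")
  cat("selected bands:", x$selection$n_bands, "\n")
  print(x$confusion)
  cat("per-class rates (%):",
      paste(names(x$per_class_rates),
            round_half_up(x$per_class_rates, 2), sep = " = ",
            collapse = ", "), "\n")
  cat("total discriminant rate (%):", round_half_up(x$total_rate, 2), "\n")
  invisible(x)
}

#' Serialize a report to JSON
#'
#' Deterministic serialization: identical reports produce byte-identical
#' files.
#'
#' @param report an `evaluation_report`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  out <- unclass(report)
  out$confusion <- unname(apply(report$confusion, 1L, identity,
                                simplify = FALSE))
  out$per_class_rates <- as.list(report$per_class_rates)
  writeLines(jsonlite::toJSON(out, auto_unbox = TRUE, digits = 10,
                              pretty = TRUE, force = TRUE, null = "null"),
             path)
  invisible(path)
}
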