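#' Canonical peach defect classes
#'
#' The four sample classes handled throughout the package, in canonical
#' order. The integer code of a class is its position in this vector, and
#' those codes (1--4) are what the PLS regression stages use as the numeric
#' response.
#'
#' @return Character vector `c("intact", "internal_injury", "scab", "rotten")`.
#' @export
peach_classes <- function() {
  c("intact", "internal_injury", "scab", "rotten")
}

#' Convert class labels to integer codes and back
#'
#' @param labels character vector of class labels.
#' @param codes integer vector of class codes (1--4).
#' @return `class_code()` returns integer codes; `class_label()` returns
#'   character labels.
#' @export
class_code <- function(labels) {
  codes <- match(as.character(labels), peach_classes())
  if (anyNA(codes)) {
    bad <- unique(as.character(labels)[is.na(codes)])
    stop("unknown class label(s): ", paste(bad, collapse = ", "),
         "; allowed: ", paste(peach_classes(), collapse = ", "))
  }
  codes
}

#' @rdname class_code
#' @export
class_label <- function(codes) {
  codes <- as.integer(codes)
  if (any(is.na(codes)) || any(codes < 1L) || any(codes > 4L)) {
    stop("class codes must be integers in 1..4")
  }
  peach_classes()[codes]
}

#' Construct an evenly spaced wavelength grid
#'
#' @param n_bands number of band centers (default 254, a typical band count
#'   for a 900--1700 nm InGaAs line-scan camera).
#' @param from,to wavelength range in nm.
#' @return Numeric vector of band-center wavelengths.
#' @export
wavelength_grid <- function(n_bands = 254L, from = 900, to = 1700) {
  grid <- seq(from, to, length.out = n_bands)
  validate_grid(grid)
  grid
}

validate_grid <- function(wavelengths) {
  if (length(wavelengths) < 2L) stop("wavelength grid needs at least 2 bands")
  if (any(!is.finite(wavelengths))) stop("wavelength grid must be finite")
  if (any(diff(wavelengths) <= 0)) {
    stop("wavelengths must be strictly increasing")
  }
  if (min(wavelengths) < 900 || max(wavelengths) > 1700) {
    stop("wavelengths must lie within [900, 1700] nm")
  }
  invisible(wavelengths)
}

#' Bundle spectra, labels and a wavelength grid into a dataset
#'
#' The container passed between every pipeline stage: an n_samples x n_bands
#' reflectance matrix, one class label per row, sample identifiers, and the
#' band-center wavelengths.
#'
#' @param X numeric matrix, samples in rows, bands in columns.
#' @param labels character vector of class labels (see [peach_classes()]).
#' @param wavelengths numeric vector of band centers (nm).
#' @param ids optional sample identifiers; defaults to `s001, s002, ...`.
#' @return An object of class `spectral_dataset`.
#' @export
spectral_dataset <- function(X, labels, wavelengths, ids = NULL) {
  X <- as.matrix(X)
  if (!is.numeric(X)) stop("X must be numeric")
  if (any(!is.finite(X))) stop("X must contain only finite values")
  validate_grid(wavelengths)
  if (ncol(X) != length(wavelengths)) {
    stop("ncol(X) (", ncol(X), ") must equal length(wavelengths) (",
         length(wavelengths), ")")
  }
  labels <- as.character(labels)
  class_code(labels) # validates
  if (nrow(X) != length(labels)) {
    stop("nrow(X) must equal length(labels)")
  }
  if (is.null(ids)) ids <- sprintf("s%03d", seq_len(nrow(X)))
  if (length(ids) != nrow(X)) stop("length(ids) must equal nrow(X)")
  structure(
    list(X = unname(X), labels = labels, ids = as.character(ids),
         wavelengths = as.numeric(wavelengths)),
    class = "spectral_dataset"
  )
}

#' @export
print.spectral_dataset <- function(x, ...) {
  cat("spectral_dataset: ", nrow(x$X), " samples x ", ncol(x$X), " bands (",
      format(min(x$wavelengths)), "-", format(max(x$wavelengths)), " nm)\n",
      sep = "")
  print(table(factor(x$labels, levels = peach_classes())))
  invisible(x)
}

#' Black/white reflectance correction
#'
#' Converts raw intensity counts to relative reflectance using dark-current
#' and white-reference frames: `R = (IR - ID) / (IW - ID)`, elementwise.
#' Values outside `[-0.5, 1.5]` after correction are retained but reported
#' via a message, since they usually indicate a reference problem.
#'
#' @param IR raw intensity frame (matrix or vector of counts).
#' @param ID dark (blackboard) reference, same shape as `IR`.
#' @param IW white reference, same shape as `IR`.
#' @param eps guard on `|IW - ID|`; any element at or below it aborts.
#' @return Reflectance, same shape as the inputs.
#' @export
correct_reflectance <- function(IR, ID, IW, eps = 1e-12) {
  if (!identical(dim(IR), dim(ID)) || !identical(dim(IR), dim(IW)) ||
      length(IR) != length(ID) || length(IR) != length(IW)) {
    stop("IR, ID and IW must have identical shapes")
  }
  denom <- IW - ID
  bad <- which(abs(denom) <= eps)
  if (length(bad) > 0L) {
    stop("white minus dark reference is ~0 at element(s) ",
         paste(utils::head(bad, 5L), collapse = ", "),
         if (length(bad) > 5L) " ..." else "",
         "; cannot calibrate")
  }
  R <- (IR - ID) / denom
  n_out <- sum(R < -0.5 | R > 1.5)
  if (n_out > 0L) {
    message(n_out, " corrected value(s) outside [-0.5, 1.5]; retained unclipped")
  }
  R
}

#' Mean spectrum of a region of interest
#'
#' @param cube reflectance matrix, pixels in rows, bands in columns.
#' @param mask integer pixel indices (rows of `cube`) or a logical vector.
#' @return Numeric vector: per-band mean over the masked pixels.
#' @export
extract_roi_mean <- function(cube, mask) {
  cube <- as.matrix(cube)
  if (is.logical(mask)) {
    if (length(mask) != nrow(cube)) stop("logical mask length must equal pixel count")
    mask <- which(mask)
  }
  mask <- as.integer(mask)
  if (length(mask) == 0L) stop("ROI mask is empty")
  if (any(mask < 1L) || any(mask > nrow(cube))) {
    stop("ROI mask indices outside cube extent (1..", nrow(cube), ")")
  }
  colMeans(cube[mask, , drop = FALSE])
}

#' Read and write spectral datasets as CSV
#'
#' The exchange format is a plain CSV: first column `sample_id`, second
#' `label`, remaining columns headed by band-center wavelengths in nm.
#' A write/read round trip reproduces the data to text precision.
#'
#' @param path file path.
#' @param dataset a [spectral_dataset()].
#' @return `read_dataset()` returns a `spectral_dataset`;
#'   `write_dataset()` returns `path` invisibly.
#' @export
read_dataset <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 4L) stop("dataset CSV needs sample_id, label and >= 2 bands")
  if (!identical(names(df)[1:2], c("sample_id", "label"))) {
    stop("first two columns must be 'sample_id' and 'label', got: ",
         paste(names(df)[1:2], collapse = ", "))
  }
  wl <- suppressWarnings(as.numeric(names(df)[-(1:2)]))
  if (anyNA(wl)) {
    stop("non-numeric wavelength header at column ",
         which(is.na(wl))[1L] + 2L)
  }
  if (any(diff(wl) <= 0)) {
    stop("wavelength headers must be strictly increasing (violated at column ",
         which(diff(wl) <= 0)[1L] + 2L, ")")
  }
  X <- as.matrix(df[, -(1:2), drop = FALSE])
  if (!is.numeric(X) || any(!is.finite(X))) {
    bad <- which(!is.finite(X), arr.ind = TRUE)
    stop("non-finite/non-numeric value at row ", bad[1, 1], ", band column ",
         bad[1, 2])
  }
  ok <- df$label %in% peach_classes()
  if (!all(ok)) {
    stop("unknown label '", df$label[!ok][1L], "' at row ", which(!ok)[1L],
         "; allowed: ", paste(peach_classes(), collapse = ", "))
  }
  spectral_dataset(X, df$label, wl, ids = df$sample_id)
}

#' @rdname read_dataset
#' @export
write_dataset <- function(dataset, path) {
  stopifnot(inherits(dataset, "spectral_dataset"))
  df <- data.frame(sample_id = dataset$ids, label = dataset$labels,
                   check.names = FALSE, stringsAsFactors = FALSE)
  mat <- as.data.frame(dataset$X)
  names(mat) <- format(dataset$wavelengths, trim = TRUE, digits = 10)
  utils::write.csv(cbind(df, mat), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
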