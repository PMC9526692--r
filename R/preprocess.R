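#' Per-gene mean of the T0 reference replicates
#'
#' First preprocessing step: the intensities of each protein group in the
#' T0 replicates are averaged (arithmetic mean over non-missing values) to
#' form the reference every later sample is ratioed against.
#'
#' @param im an [intensity_matrix()] on the linear scale containing at
#'   least one `T0` column.
#' @return Named numeric vector, one reference value per gene; `NA` where
#'   all T0 replicates are missing.
#' @export
average_reference <- function(im) {
  stopifnot(inherits(im, "intensity_matrix"))
  t0 <- class_columns(im, "T0")
  if (!length(t0)) stop("no T0 samples: a reference class is required")
  rowMeans(im$values[, t0, drop = FALSE], na.rm = TRUE) |>
    (\(r) { r[is.nan(r)] <- NA_real_; r })()
}

#' Ratio all non-reference samples to the T0 mean
#'
#' Divides every non-T0 intensity by the per-gene reference and drops the
#' T0 columns; the result carries the four time x gravity classes only.
#' Missing values stay missing; a gene whose reference is missing, zero or
#' negative becomes all-missing (with a warning for the degenerate
#' references), so it is removed later by [filter_valid()].
#'
#' @param im an [intensity_matrix()] with T0 columns.
#' @param ref reference vector from [average_reference()], same gene order.
#' @return An [intensity_matrix()] of ratios without T0 columns.
#' @export
ratio_to_reference <- function(im, ref) {
  stopifnot(inherits(im, "intensity_matrix"))
  if (length(ref) != nrow(im$values))
    stop("reference length does not match gene count")
  bad_ref <- !is.na(ref) & ref <= 0
  if (any(bad_ref)) {
    warning(sum(bad_ref), " gene(s) with non-positive T0 reference set to missing")
    ref[bad_ref] <- NA_real_
  }
  keep <- im$classes != "T0"
  vals <- im$values[, keep, drop = FALSE] / ref
  intensity_matrix(vals, im$classes[keep], im$replicates[keep],
                   log2 = im$log2, imputed = im$imputed[, keep, drop = FALSE])
}

#' Filter protein groups for valid values
#'
#' Keeps a gene iff at least one class has a fraction of non-missing
#' replicates >= `min_fraction` (default 70%). The fraction is computed on
#' the exact class size, so 2 valid of 3 (0.667) fails at the default while
#' 2 of 2 passes. Row order is preserved.
#'
#' @param im an [intensity_matrix()].
#' @param min_fraction required valid fraction within at least one class.
#' @return The filtered [intensity_matrix()].
#' @export
filter_valid <- function(im, min_fraction = 0.7) {
  stopifnot(inherits(im, "intensity_matrix"))
  cls <- unique(im$classes)
  frac <- sapply(cls, function(k) {
    j <- class_columns(im, k)
    rowMeans(!is.na(im$values[, j, drop = FALSE]))
  })
  frac <- matrix(frac, nrow = nrow(im$values))
  keep <- apply(frac, 1, max) >= min_fraction
  im[keep]
}

#' Log2-transform an intensity matrix
#'
#' @param im an [intensity_matrix()] on the linear scale with strictly
#'   positive non-missing values.
#' @return The matrix on the log2 scale.
#' @export
log2_transform <- function(im) {
  stopifnot(inherits(im, "intensity_matrix"))
  if (im$log2) stop("matrix is already on the log2 scale")
  if (any(im$values <= 0, na.rm = TRUE))
    stop("non-positive intensities cannot be log2-transformed")
  intensity_matrix(log2(im$values), im$classes, im$replicates,
                   log2 = TRUE, imputed = im$imputed)
}

#' Impute missing values from a downshifted Gaussian
#'
#' Replaces each missing entry by a draw from a normal distribution whose
#' mean is the sample column's observed mean shifted down by
#' `downshift` column sds and whose sd is `width` times the column sd —
#' the standard left-censoring model for label-free proteomics, where
#' missing values arise from low-abundance dropout. Non-missing values are
#' untouched and the `imputed` mask records what was filled in.
#'
#' @param im an [intensity_matrix()] on the log2 scale; every column needs
#'   >= 2 observed values.
#' @param width imputation sd as a multiple of the column sd (default 0.3).
#' @param downshift mean downshift in column sds (default 1.8).
#' @param seed integer RNG seed.
#' @return The completed [intensity_matrix()].
#' @export
impute_gaussian <- function(im, width = 0.3, downshift = 1.8, seed = 1L) {
  stopifnot(inherits(im, "intensity_matrix"))
  if (!im$log2) stop("impute on the log2 scale")
  vals <- im$values
  imputed <- im$imputed
  withr::with_seed(seed, {
    for (j in seq_len(ncol(vals))) {
      obs <- vals[, j][!is.na(vals[, j])]
      miss <- which(is.na(vals[, j]))
      if (length(obs) < 2)
        stop("column ", colnames(vals)[j],
             " has fewer than 2 observed values")
      if (!length(miss)) next
      mu <- mean(obs); sdev <- stats::sd(obs)
      vals[miss, j] <- stats::rnorm(length(miss),
                                    mu - downshift * sdev, width * sdev)
      imputed[miss, j] <- TRUE
    }
  })
  intensity_matrix(vals, im$classes, im$replicates, log2 = TRUE,
                   imputed = imputed)
}
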