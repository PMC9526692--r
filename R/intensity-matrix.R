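#' Protein-group intensity matrix
#'
#' Container for a protein-group x sample abundance matrix with class labels.
#' Rows are protein groups keyed by official gene symbol; columns are samples
#' belonging to one of the five experimental classes (`T0`, `T8_GC`, `T8_RPM`,
#' `T28_GC`, `T28_RPM`): three differentiation time points crossed with the
#' culturing condition (gravity control GC vs the random positioning machine
#' RPM). Missing values are stored as `NA` and interpreted as
#' missing-not-at-random (low-abundance censoring); the `imputed` mask records
#' entries filled in later by [impute_gaussian()].
#'
#' @param values numeric matrix (genes x samples) with `NA` for missing
#'   entries; rownames are gene symbols.
#' @param classes character vector, one class label per column.
#' @param replicates optional integer vector of replicate indices per column;
#'   defaults to 1..n within each class.
#' @param log2 logical flag: are `values` on the log2 scale?
#' @param imputed optional logical matrix marking imputed entries.
#' @return An object of class `"intensity_matrix"`: a list with elements
#'   `values`, `classes`, `replicates`, `log2`, `imputed`.
#' @examples
#' m <- matrix(2^rnorm(12, 20), 3, 4,
#'             dimnames = list(c("ALPL", "COL1A1", "SPP1"), NULL))
#' im <- intensity_matrix(m, c("T0", "T0", "T8_GC", "T8_GC"))
#' im
#' @export
intensity_matrix <- function(values, classes, replicates = NULL,
                             log2 = FALSE, imputed = NULL) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (length(classes) != ncol(values))
    stop("`classes` must have one label per column")
  classes <- as.character(classes)
  bad <- setdiff(unique(classes), smg_classes())
  if (length(bad))
    stop("unknown class label(s): ", paste(bad, collapse = ", "))
  if (is.null(replicates)) {
    replicates <- stats::ave(seq_along(classes), classes, FUN = seq_along)
  }
  replicates <- as.integer(replicates)
  if (anyDuplicated(paste(classes, replicates)))
    stop("duplicate (class, replicate) pairs")
  if (is.null(rownames(values)))
    rownames(values) <- paste0("PG", seq_len(nrow(values)))
  if (anyDuplicated(rownames(values)))
    stop("duplicate gene identifiers in rownames")
  colnames(values) <- paste(classes, replicates, sep = "_")
  if (is.null(imputed)) {
    imputed <- matrix(FALSE, nrow(values), ncol(values),
                      dimnames = dimnames(values))
  }
  stopifnot(identical(dim(imputed), dim(values)))
  structure(list(values = values, classes = classes,
                 replicates = replicates, log2 = isTRUE(log2),
                 imputed = imputed),
            class = "intensity_matrix")
}

#' Valid experimental class labels
#'
#' @return Character vector of the five time x gravity classes.
#' @export
smg_classes <- function() c("T0", "T8_GC", "T8_RPM", "T28_GC", "T28_RPM")

#' The four post-reference classes compared by the differential analysis
#' @return Character vector of the four classes retained after T0 ratioing.
#' @export
smg_test_classes <- function() c("T8_GC", "T8_RPM", "T28_GC", "T28_RPM")

#' @export
print.intensity_matrix <- function(x, ...) {
  cat(sprintf("intensity_matrix: %d protein groups x %d samples (%s scale)\n",
              nrow(x$values), ncol(x$values),
              if (x$log2) "log2" else "linear"))
  tab <- table(factor(x$classes, levels = smg_classes()))
  tab <- tab[tab > 0]
  cat("  classes:", paste(sprintf("%s(%d)", names(tab), tab), collapse = " "),
      "\n")
  cat(sprintf("  missing: %d (%.1f%%), imputed: %d\n",
              sum(is.na(x$values)),
              100 * mean(is.na(x$values)),
              sum(x$imputed)))
  invisible(x)
}

#' @export
dim.intensity_matrix <- function(x) dim(x$values)

#' Subset an intensity matrix by gene (row)
#'
#' @param x an `intensity_matrix`.
#' @param i row index (numeric, logical or gene names).
#' @param ... ignored.
#' @return An `intensity_matrix` with the selected rows.
#' @export
`[.intensity_matrix` <- function(x, i, ...) {
  intensity_matrix(x$values[i, , drop = FALSE], x$classes, x$replicates,
                   log2 = x$log2, imputed = x$imputed[i, , drop = FALSE])
}

#' @export
as.matrix.intensity_matrix <- function(x, ...) x$values

genes_of <- function(im) rownames(im$values)

class_columns <- function(im, cls) which(im$classes == cls)
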