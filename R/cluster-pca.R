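#' Row z-scoring and hierarchical clustering
#'
#' Z-scores each row to mean 0, sd 1 (the scale used for the heatmaps of
#' the top regulated protein groups) and clusters rows and columns by
#' agglomerative hierarchical clustering (Euclidean distance, average
#' linkage by default). Leaf orders are deterministic for fixed input.
#'
#' @param x numeric matrix (genes x samples); every row needs sd > 0.
#' @param linkage agglomeration method passed to [stats::hclust()]
#'   (default `"average"`).
#' @return A list with `z` (the z-scored matrix), `row_hclust`,
#'   `col_hclust`, `row_order`, `col_order`.
#' @export
zscore_and_cluster <- function(x, linkage = "average") {
  sds <- apply(x, 1, stats::sd)
  if (any(sds == 0))
    stop("zero-variance row(s): ",
         paste(rownames(x)[sds == 0], collapse = ", "))
  z <- (x - rowMeans(x)) / sds
  rh <- stats::hclust(stats::dist(z), method = linkage)
  ch <- stats::hclust(stats::dist(t(z)), method = linkage)
  list(z = z, row_hclust = rh, col_hclust = ch,
       row_order = rh$order, col_order = ch$order)
}

#' PCA variance fractions of the sample replicates
#'
#' Principal component analysis with samples as observations and genes as
#' variables, on the mean-centered log2 ratio matrix. Variance fractions
#' sum to 1 and are also returned as percentages, the form in which they
#' are reported on PCA score plots.
#'
#' @param x complete numeric matrix (genes x samples).
#' @return A list with `fractions` (per-component variance fractions),
#'   `percent` (`100 * fractions`), and `scores` (samples x components).
#' @export
pca_variance <- function(x) {
  if (nrow(x) < 2 || ncol(x) < 2) stop("need >= 2 genes and >= 2 samples")
  if (all(apply(x, 1, stats::sd) == 0)) stop("constant matrix has no principal components")
  pc <- stats::prcomp(t(x), center = TRUE, scale. = FALSE)
  v <- pc$sdev^2
  fr <- v / sum(v)
  list(fractions = fr, percent = 100 * fr, scores = pc$x)
}
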