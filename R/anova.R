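#' Row-wise one-way ANOVA across sample classes
#'
#' Computes the classical between/within mean-square F statistic for every
#' row of a complete (imputed) matrix in one vectorized pass, with p values
#' from the F distribution on (k - 1, N - k) degrees of freedom. Rows with
#' zero within-group and zero between-group variance (constant rows) are
#' defined as F = 0, p = 1; rows with zero within-group but positive
#' between-group variance get p = 0.
#'
#' @param x numeric matrix (genes x samples) with no missing values.
#' @param classes class label per column (>= 2 classes, each >= 2 samples).
#' @return A data.frame with columns `F` and `p`, one row per gene.
#' @export
row_anova <- function(x, classes) {
  if (anyNA(x)) stop("row_anova requires a complete matrix (impute first)")
  f <- factor(classes)
  k <- nlevels(f)
  if (k < 2) stop("need >= 2 classes")
  n_j <- tabulate(f)
  if (any(n_j < 2)) stop("every class needs >= 2 samples")
  N <- ncol(x)
  G <- stats::model.matrix(~ f - 1)
  M <- sweep(x %*% G, 2, n_j, "/")          # group means, genes x k
  gm <- rowMeans(x)
  ssb <- rowSums(sweep((M - gm)^2, 2, n_j, "*"))
  sst <- rowSums((x - gm)^2)
  ssw <- pmax(sst - ssb, 0)
  tol <- .Machine$double.eps^0.75 * pmax(sst, 1)
  Fstat <- (ssb / (k - 1)) / (ssw / (N - k))
  p <- stats::pf(Fstat, k - 1, N - k, lower.tail = FALSE)
  const <- ssw <= tol
  null_row <- const & ssb <= tol
  Fstat[null_row] <- 0; p[null_row] <- 1
  p[const & !null_row] <- 0
  data.frame(F = Fstat, p = p, row.names = rownames(x))
}

#' One-way ANOVA for a single protein group
#'
#' Convenience scalar interface over [row_anova()].
#'
#' @param values numeric vector of (log2-ratio) abundances.
#' @param classes class label per value.
#' @return A list with `F` and `p`.
#' @examples
#' anova_oneway(c(1, 2, 2, 3, 5, 6, 8, 9, 10),
#'              rep(c("T8_GC", "T8_RPM", "T28_GC"), each = 3))
#' @export
anova_oneway <- function(values, classes) {
  res <- row_anova(matrix(values, 1), classes)
  list(F = res$F, p = res$p)
}

#' Permutation-based FDR control for the row-wise ANOVA
#'
#' Recomputes all row ANOVA p values under `n_perm` random permutations of
#' the sample class labels (class sizes preserved). The estimated FDR at an
#' observed p value cutoff c is the mean, over permutations, of the number
#' of permuted p values <= c, divided by the observed count at c. The
#' significance cutoff is the largest observed p value whose estimated FDR
#' is <= `fdr`; when no cutoff qualifies the significant set is empty.
#'
#' @param x complete numeric matrix (genes x samples), log2 ratios after
#'   imputation.
#' @param classes class label per column (the four time x gravity classes).
#' @param n_perm number of label permutations (default 250).
#' @param fdr accepted false-discovery rate (default 0.05).
#' @param seed integer RNG seed for the permutations.
#' @return A list with `p` (observed per-gene ANOVA p), `significant`
#'   (logical per gene), `cutoff` (p value cutoff, `NA` if the set is
#'   empty), `n_significant`, and `fdr_at_cutoff`.
#' @export
permutation_fdr <- function(x, classes, n_perm = 250L, fdr = 0.05,
                            seed = 1L) {
  if (n_perm < 1) stop("n_perm must be >= 1")
  obs <- row_anova(x, classes)$p
  N <- length(classes)
  perm_pool <- withr::with_seed(seed, {
    unlist(lapply(seq_len(n_perm), function(b) {
      row_anova(x, classes[sample.int(N)])$p
    }), use.names = FALSE)
  })
  ord <- order(obs)
  obs_sorted <- obs[ord]
  perm_sorted <- sort(perm_pool)
  # counts of permuted / observed p values <= each candidate cutoff
  n_perm_le <- findInterval(obs_sorted, perm_sorted)
  n_obs_le <- seq_along(obs_sorted)
  fdr_hat <- (n_perm_le / n_perm) / pmax(1, n_obs_le)
  ok <- which(fdr_hat <= fdr)
  if (!length(ok)) {
    return(list(p = obs, significant = rep(FALSE, length(obs)),
                cutoff = NA_real_, n_significant = 0L,
                fdr_at_cutoff = NA_real_))
  }
  cut_idx <- max(ok)
  cutoff <- obs_sorted[cut_idx]
  sig <- obs <= cutoff
  list(p = obs, significant = sig, cutoff = cutoff,
       n_significant = sum(sig), fdr_at_cutoff = fdr_hat[cut_idx])
}
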