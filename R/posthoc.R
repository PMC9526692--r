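#' Tukey HSD post-hoc calls for one protein group
#'
#' Runs the Tukey-Kramer honestly-significant-difference test (studentized
#' range, valid for unequal group sizes — the `T8_GC` class has only two
#' replicates) on all 6 pairs of the four classes and records, per pair,
#' which class mean is higher and whether the difference is significant at
#' `alpha`.
#'
#' @param values numeric vector of log2-ratio abundances for one gene.
#' @param classes class label per value (4 classes, each >= 2 values).
#' @param alpha significance level (default 0.05).
#' @return A data.frame with one row per pair: `class_a`, `class_b`,
#'   `diff` (mean of `class_b` minus mean of `class_a`), `p_adj`,
#'   `higher`, `significant`.
#' @examples
#' cls <- rep(smg_test_classes(), times = c(2, 3, 3, 3))
#' tukey_hsd(c(0, 0.1, -2, -2.1, -1.9, 0.05, -0.05, 0, 0.1, 0, -0.1), cls)
#' @export
tukey_hsd <- function(values, classes, alpha = 0.05) {
  f <- factor(classes)
  if (any(tabulate(f) < 2)) stop("every class needs >= 2 values")
  fit <- stats::aov(values ~ f, data = data.frame(values = values, f = f))
  th <- stats::TukeyHSD(fit)$f
  nm <- strsplit(rownames(th), "-", fixed = TRUE)
  out <- data.frame(
    class_a = vapply(nm, `[`, "", 2L),
    class_b = vapply(nm, `[`, "", 1L),
    diff = th[, "diff"],
    p_adj = th[, "p adj"],
    stringsAsFactors = FALSE
  )
  out$higher <- ifelse(out$diff >= 0, out$class_b, out$class_a)
  out$significant <- !is.na(out$p_adj) & out$p_adj < alpha
  rownames(out) <- NULL
  out
}

pair_direction <- function(pairs, gc, rpm) {
  hit <- (pairs$class_a == gc & pairs$class_b == rpm) |
    (pairs$class_a == rpm & pairs$class_b == gc)
  if (!any(hit)) stop("missing pair call: ", gc, " vs ", rpm)
  row <- pairs[which(hit)[1], ]
  if (!row$significant) return(NA_character_)
  if (row$higher == rpm) "up" else "down"
}

pair_significant <- function(pairs, a, b) {
  hit <- (pairs$class_a == a & pairs$class_b == b) |
    (pairs$class_a == b & pairs$class_b == a)
  if (!any(hit)) stop("missing pair call: ", a, " vs ", b)
  pairs$significant[which(hit)[1]]
}

#' The trend-category vocabulary
#'
#' @return Character vector of the 8 mutually exclusive trend categories a
#'   significant protein group can fall in.
#' @export
trend_categories <- function() {
  c("down_T8_only", "up_T8_only", "down_T28_only", "up_T28_only",
    "down_both", "up_both", "time_only", "mixed")
}

#' Classify the microgravity trend of a significant protein group
#'
#' Maps the Tukey pair calls to one of eight categories describing the
#' regulation in simulated microgravity (RPM) relative to gravity control
#' (GC): down/up at 8 days only, at 28 days only, or at both time points;
#' `mixed` when the two time points disagree in direction; `time_only` when
#' no RPM-vs-GC pair is significant (the difference is attributed to
#' maturation over time — at least one of the `T8_GC` vs `T28_GC` or
#' `T8_RPM` vs `T28_RPM` contrasts is usually significant in that case, and
#' the rare residual with only cross pairs significant is binned here too).
#'
#' @param pairs data.frame of 6 pair calls from [tukey_hsd()].
#' @return One of [trend_categories()].
#' @export
classify_trend <- function(pairs) {
  if (nrow(pairs) != 6) stop("expected exactly 6 pair calls, got ", nrow(pairs))
  d8 <- pair_direction(pairs, "T8_GC", "T8_RPM")
  d28 <- pair_direction(pairs, "T28_GC", "T28_RPM")
  if (!is.na(d8) && !is.na(d28)) {
    if (d8 == d28) return(paste0(d8, "_both"))
    return("mixed")
  }
  if (!is.na(d8)) return(paste0(d8, "_T8_only"))
  if (!is.na(d28)) return(paste0(d28, "_T28_only"))
  "time_only"
}

#' Reduce redundant isoform entries to one record per base gene
#'
#' Protein groups labelled with the same base gene symbol plus an isoform
#' suffix (e.g. `GENE1` and `GENE1-2`) are collapsed to the single record
#' with the smallest ANOVA p value; ties break by gene name (stable sort).
#'
#' @param records data.frame with at least `gene` and `anova_p` columns.
#' @return The reduced data.frame, original order preserved among the kept
#'   records; the number of dropped records is reported via `message()`.
#' @export
dedupe_isoforms <- function(records) {
  if (!nrow(records)) return(records)
  base <- sub("-[0-9]+$", "", records$gene)
  ord <- order(base, records$anova_p, records$gene)
  keep_first <- !duplicated(base[ord])
  keep <- sort(ord[keep_first])
  dropped <- nrow(records) - length(keep)
  if (dropped > 0)
    message(dropped, " redundant isoform record(s) removed, ",
            length(keep), " retained")
  records[keep, , drop = FALSE]
}

#' Summarize trend categories as counts and percentages
#'
#' @param categories character vector of per-gene trend categories, or a
#'   named integer vector of counts (then `total` must be given).
#' @param total total number of differentially abundant protein groups the
#'   percentages refer to; defaults to `length(categories)` /
#'   `sum(categories)`.
#' @param digits decimal places for the percentage (default 1, as commonly
#'   reported).
#' @return A data.frame with `category`, `n`, `pct`.
#' @examples
#' trend_summary(c(down_T8_only = 73, down_T28_only = 17,
#'                 down_both = 28, up_both = 16), total = 481)
#' @export
trend_summary <- function(categories, total = NULL, digits = 1) {
  if (is.numeric(categories)) {
    counts <- categories
    if (is.null(total)) total <- sum(counts)
  } else {
    counts <- table(factor(categories, levels = trend_categories()))
    counts <- stats::setNames(as.integer(counts), names(counts))
    if (is.null(total)) total <- length(categories)
  }
  pct <- if (total > 0) round(100 * as.integer(counts) / total, digits)
         else rep(0, length(counts))
  data.frame(category = names(counts),
             n = as.integer(counts),
             pct = pct,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Top regulated protein groups in simulated microgravity
#'
#' Ranks genes by the mean RPM-minus-GC log2 difference averaged over the
#' two time points and returns the `k` most downregulated and `k` most
#' upregulated gene lists; ties break by gene name.
#'
#' @param x complete numeric matrix of log2 ratios (genes x samples).
#' @param classes class label per column.
#' @param k list length per direction (default 10).
#' @return A list with `down`, `up` (gene name vectors) and `score`
#'   (named vector of the ranking score for all genes).
#' @export
top_regulated <- function(x, classes, k = 10) {
  score <- smg_score(x, classes)
  if (length(score) < k) {
    warning("fewer than k = ", k, " genes; returning all")
    k <- length(score)
  }
  ord_dn <- order(score, names(score))
  ord_up <- order(-score, names(score))
  list(down = names(score)[ord_dn[seq_len(k)]],
       up = names(score)[ord_up[seq_len(k)]],
       score = score)
}

# mean over the two time points of (mean RPM - mean GC) log2 difference
smg_score <- function(x, classes) {
  mcls <- function(k) rowMeans(x[, classes == k, drop = FALSE])
  s <- ((mcls("T8_RPM") - mcls("T8_GC")) +
          (mcls("T28_RPM") - mcls("T28_GC"))) / 2
  stats::setNames(as.numeric(s), rownames(x))
}
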