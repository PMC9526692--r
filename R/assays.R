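#' Two-sided Student's t test (pooled variance)
#'
#' The shared two-sample test of the study's assays. Pooled-variance
#' Student's t by default (Welch available via `var_equal = FALSE`).
#' Degenerate inputs are defined explicitly: zero pooled variance with
#' equal means gives t = 0, p = 1; zero pooled variance with unequal means
#' gives p = 0 and is flagged degenerate.
#'
#' @param a,b numeric samples, each with >= 2 values.
#' @param var_equal pool the variances (default `TRUE`).
#' @return A list with `t`, `df`, `p`, `degenerate`.
#' @examples
#' student_t(c(1, 2, 3), c(4, 5, 6))
#' @export
student_t <- function(a, b, var_equal = TRUE) {
  if (length(a) < 2 || length(b) < 2) stop("each sample needs >= 2 values")
  pooled0 <- stats::var(a) == 0 && stats::var(b) == 0
  if (pooled0) {
    if (mean(a) == mean(b))
      return(list(t = 0, df = length(a) + length(b) - 2, p = 1,
                  degenerate = FALSE))
    return(list(t = Inf * sign(mean(a) - mean(b)),
                df = length(a) + length(b) - 2, p = 0, degenerate = TRUE))
  }
  tt <- stats::t.test(a, b, var.equal = var_equal)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, degenerate = FALSE)
}

#' Relative gene expression by the 2^-ddCt method
#'
#' For every target condition: dCt is the mean target Ct minus the mean
#' reference-gene Ct, ddCt is the dCt minus the calibrator condition's
#' dCt, and the fold change is `2^-ddCt`. Uncertainty is propagated from
#' the sd of the replicate-wise dCt values to the range
#' `2^-(ddCt +/- sd)`.
#'
#' @param ct data.frame with columns `gene`, `condition`, `replicate`,
#'   `ct` (as produced by [simulate_ct_table()]; extra columns such as
#'   `timepoint` are ignored, filter beforehand for per-timepoint results).
#' @param target target gene symbol.
#' @param reference reference gene symbol (default `"RNA18S"`, the 18S
#'   rRNA endogenous control).
#' @param calibrator calibrator condition the fold changes are relative to
#'   (default `"GC"`).
#' @return A data.frame with one row per condition: `condition`, `dct`,
#'   `ddct`, `fold_change`, `fold_lo`, `fold_hi`, `sd_dct`.
#' @examples
#' fc <- matrix(c(1, 0.5), 1, 2, dimnames = list("ALPL", c("GC", "RPM")))
#' ddct_fold_change(simulate_ct_table(fc), "ALPL")
#' @export
ddct_fold_change <- function(ct, target, reference = "RNA18S",
                             calibrator = "GC") {
  need <- c("gene", "condition", "replicate", "ct")
  if (!all(need %in% names(ct)))
    stop("ct table needs columns: ", paste(need, collapse = ", "))
  if (!reference %in% ct$gene)
    stop("reference gene ", reference, " absent from the Ct table")
  if (!target %in% ct$gene) stop("target gene ", target, " absent")
  conds <- unique(ct$condition)
  if (!calibrator %in% conds)
    stop("calibrator condition ", calibrator, " absent")
  per_cond <- lapply(conds, function(cc) {
    tgt <- ct[ct$gene == target & ct$condition == cc, ]
    ref <- ct[ct$gene == reference & ct$condition == cc, ]
    if (!nrow(tgt) || !nrow(ref))
      stop("missing Ct values for condition ", cc)
    # replicate-wise dCt for the sd; mean dCt equals diff of means
    reps <- intersect(tgt$replicate, ref$replicate)
    dct_rep <- vapply(reps, function(r) {
      mean(tgt$ct[tgt$replicate == r]) - mean(ref$ct[ref$replicate == r])
    }, 0)
    list(dct = mean(tgt$ct) - mean(ref$ct),
         sd = if (length(dct_rep) > 1) stats::sd(dct_rep) else 0)
  })
  names(per_cond) <- conds
  dct_cal <- per_cond[[calibrator]]$dct
  out <- do.call(rbind, lapply(conds, function(cc) {
    ddct <- per_cond[[cc]]$dct - dct_cal
    sdv <- per_cond[[cc]]$sd
    data.frame(condition = cc, dct = per_cond[[cc]]$dct, ddct = ddct,
               fold_change = 2^(-ddct),
               fold_lo = 2^(-(ddct + sdv)), fold_hi = 2^(-(ddct - sdv)),
               sd_dct = sdv, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Fit a linear standard curve
#'
#' Ordinary least-squares line `absorbance = slope * concentration +
#' intercept` fitted on the calibration standards, as used for the
#' alkaline-phosphatase activity assay and the indirect ELISAs (both run
#' in their linear range).
#'
#' @param concentration numeric vector of standard concentrations (>= 2
#'   distinct values).
#' @param absorbance numeric vector of measured absorbances (same length).
#' @return A list of class `"standard_curve"`: `slope`, `intercept`,
#'   `r_squared`, `range` (min/max standard concentration).
#' @examples
#' fit_standard_curve(0:5, 2 * (0:5) + 1)
#' @export
fit_standard_curve <- function(concentration, absorbance) {
  if (length(concentration) != length(absorbance))
    stop("concentration and absorbance lengths differ")
  if (length(unique(concentration)) < 2)
    stop("need >= 2 distinct standard concentrations")
  fit <- stats::lm(absorbance ~ concentration)
  # summary.lm warns on an exact fit; noiseless round trips are legitimate
  r2 <- suppressWarnings(summary(fit)$r.squared)
  if (is.nan(r2)) r2 <- 1  # two points: exact fit
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = r2,
                 range = range(concentration)),
            class = "standard_curve")
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf(
    "standard_curve: absorbance = %.4g * conc + %.4g (r^2 = %.4f, range %g-%g)\n",
    x$slope, x$intercept, x$r_squared, x$range[1], x$range[2]))
  invisible(x)
}

#' Back-calculate concentrations from a standard curve
#'
#' @param curve a `"standard_curve"` from [fit_standard_curve()].
#' @param absorbance numeric vector of unknown-sample absorbances.
#' @return A data.frame with `absorbance`, `concentration`, and
#'   `extrapolated` (TRUE where the back-calculated concentration lies
#'   outside the standard range).
#' @export
calibrate <- function(curve, absorbance) {
  stopifnot(inherits(curve, "standard_curve"))
  if (curve$slope == 0) stop("cannot invert a flat standard curve")
  conc <- (absorbance - curve$intercept) / curve$slope
  data.frame(absorbance = absorbance, concentration = conc,
             extrapolated = conc < curve$range[1] | conc > curve$range[2])
}

#' Crystal-size statistics for two growth conditions
#'
#' Summarizes hydroxyapatite crystal areas per group (min, max, mean, n),
#' computes a frequency distribution over bins shared by the two groups
#' (fractions summing to 1 per group), and compares the groups with a
#' pooled-variance Student's t test.
#'
#' @param areas_1,areas_2 positive crystal areas for the two groups
#'   (e.g. GC and RPM).
#' @param bins number of shared histogram bins (default 10) or an explicit
#'   vector of break points.
#' @param labels group labels (default `c("GC", "RPM")`).
#' @return A list with `summary` (per-group data.frame), `freq`
#'   (data.frame `bin_lo`, `bin_hi`, one fraction column per group, and
#'   per-group counts), and `test` (the [student_t()] result).
#' @export
crystal_stats <- function(areas_1, areas_2, bins = 10,
                          labels = c("GC", "RPM")) {
  if (!length(areas_1) || !length(areas_2)) stop("both groups must be non-empty")
  if (any(c(areas_1, areas_2) <= 0)) stop("crystal areas must be > 0")
  breaks <- if (length(bins) > 1) bins else
    seq(min(areas_1, areas_2), max(areas_1, areas_2), length.out = bins + 1)
  h1 <- graphics::hist(areas_1, breaks = breaks, plot = FALSE)
  h2 <- graphics::hist(areas_2, breaks = breaks, plot = FALSE)
  summ <- data.frame(group = labels,
                     n = c(length(areas_1), length(areas_2)),
                     min = c(min(areas_1), min(areas_2)),
                     max = c(max(areas_1), max(areas_2)),
                     mean = c(mean(areas_1), mean(areas_2)))
  freq <- data.frame(bin_lo = breaks[-length(breaks)], bin_hi = breaks[-1],
                     count_1 = h1$counts, count_2 = h2$counts,
                     frac_1 = h1$counts / length(areas_1),
                     frac_2 = h2$counts / length(areas_2))
  names(freq)[3:6] <- c(paste0("count_", labels), paste0("frac_", labels))
  list(summary = summ, freq = freq, test = student_t(areas_1, areas_2))
}

#' Pooled-variance t test from summary statistics
#'
#' Reconstructs the two-sample Student's t test from group means, standard
#' deviations and sizes (useful when only summary tables are available).
#'
#' @param mean1,sd1,n1,mean2,sd2,n2 group summary statistics.
#' @return A list with `t`, `df`, `p`.
#' @export
t_from_summary <- function(mean1, sd1, n1, mean2, sd2, n2) {
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / df
  t <- (mean1 - mean2) / sqrt(sp2 * (1 / n1 + 1 / n2))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}
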