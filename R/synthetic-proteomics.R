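#' Specification for a synthetic proteomics experiment
#'
#' Describes a label-free quantification experiment with the study's replicate
#' design: five classes (T0 reference plus the four time x gravity classes),
#' three biological replicates per class except `T8_GC` with two. A fraction
#' `frac_dapg` of proteins receives a spiked log2 effect in the RPM classes
#' relative to GC, with the trend (down/up at T8 only, at T28 only, or both)
#' drawn uniformly; the remaining proteins are null. Missingness is
#' missing-not-at-random: in every sample, linear-scale intensities below
#' that sample's empirical `mnar_quantile` are censored, emulating
#' detection-limit dropout of low-abundance peptides.
#'
#' @param n_proteins number of protein groups.
#' @param class_sizes named integer vector of replicate counts per class;
#'   must include `T0`.
#' @param frac_dapg fraction of proteins with a spiked effect, in \[0, 1\].
#' @param effect_log2 absolute log2 shift applied to spiked proteins in the
#'   affected RPM classes.
#' @param base_log2_mean,base_log2_sd baseline per-protein log2 abundance
#'   distribution (typical LFQ intensities are around 2^20).
#' @param noise_sd replicate noise sd on the log2 scale.
#' @param mnar_quantile per-sample censoring quantile in \[0, 1); 0 disables
#'   missingness.
#' @param seed integer RNG seed.
#' @return A list of class `"proteomics_sim_spec"`.
#' @export
proteomics_sim_spec <- function(n_proteins,
                                class_sizes = c(T0 = 3L, T8_GC = 2L,
                                                T8_RPM = 3L, T28_GC = 3L,
                                                T28_RPM = 3L),
                                frac_dapg = 0,
                                effect_log2 = 2,
                                base_log2_mean = 20,
                                base_log2_sd = 2,
                                noise_sd = 0.25,
                                mnar_quantile = 0.05,
                                seed = 1L) {
  if (!"T0" %in% names(class_sizes))
    stop("class_sizes must include the T0 reference class")
  bad <- setdiff(names(class_sizes), smg_classes())
  if (length(bad)) stop("unknown class(es): ", paste(bad, collapse = ", "))
  if (any(class_sizes < 2)) stop("every class needs >= 2 replicates")
  if (frac_dapg < 0 || frac_dapg > 1) stop("frac_dapg must be in [0, 1]")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (mnar_quantile < 0 || mnar_quantile >= 1)
    stop("mnar_quantile must be in [0, 1)")
  structure(list(n_proteins = as.integer(n_proteins),
                 class_sizes = class_sizes, frac_dapg = frac_dapg,
                 effect_log2 = effect_log2,
                 base_log2_mean = base_log2_mean,
                 base_log2_sd = base_log2_sd, noise_sd = noise_sd,
                 mnar_quantile = mnar_quantile, seed = as.integer(seed)),
            class = "proteomics_sim_spec")
}

# the six ground-truth trend labels a spiked protein can carry
spike_categories <- function() {
  c("down_T8_only", "up_T8_only", "down_T28_only", "up_T28_only",
    "down_both", "up_both")
}

# per-category signed multipliers of effect_log2 in (T8_RPM, T28_RPM)
spike_signs <- function(category) {
  switch(category,
         down_T8_only  = c(-1,  0), up_T8_only   = c( 1,  0),
         down_T28_only = c( 0, -1), up_T28_only  = c( 0,  1),
         down_both     = c(-1, -1), up_both      = c( 1,  1),
         c(0, 0))
}

#' Generate a synthetic protein-group intensity matrix with ground truth
#'
#' Linear-scale intensities are `2^(base + class effect + noise)`; spiked
#' effects shift the RPM classes relative to GC at the affected time points,
#' so after T0 ratioing the log2 difference between RPM and GC equals the
#' spiked effect in expectation. Values below the per-sample
#' `mnar_quantile` of that sample's own draw are set missing.
#'
#' @param spec a [proteomics_sim_spec()].
#' @return A list with `matrix` (an [intensity_matrix()], linear scale) and
#'   `truth`, a data.frame with per-protein columns `gene`, `dapg` (logical),
#'   `category` (trend label or `"null"`), `effect_t8`, `effect_t28`
#'   (signed log2 shifts of RPM vs GC).
#' @examples
#' sim <- simulate_proteomics(proteomics_sim_spec(50, frac_dapg = 0.1, seed = 7))
#' sim$matrix
#' table(sim$truth$category)
#' @export
simulate_proteomics <- function(spec) {
  stopifnot(inherits(spec, "proteomics_sim_spec"))
  withr::with_seed(spec$seed, {
    n <- spec$n_proteins
    cls <- rep(names(spec$class_sizes), spec$class_sizes)
    genes <- sprintf("GENE%04d", seq_len(n))

    n_dapg <- round(spec$frac_dapg * n)
    dapg <- logical(n)
    dapg[sample.int(n, n_dapg)] <- TRUE
    category <- rep("null", n)
    category[dapg] <- sample(spike_categories(), n_dapg, replace = TRUE)
    signs <- t(vapply(category, spike_signs, numeric(2)))
    eff_t8 <- signs[, 1] * spec$effect_log2
    eff_t28 <- signs[, 2] * spec$effect_log2

    effect <- matrix(0, n, length(cls))
    effect[, cls == "T8_RPM"] <- eff_t8
    effect[, cls == "T28_RPM"] <- eff_t28

    base <- stats::rnorm(n, spec$base_log2_mean, spec$base_log2_sd)
    noise <- matrix(stats::rnorm(n * length(cls), 0, spec$noise_sd),
                    n, length(cls))
    lin <- 2^(base + effect + noise)
    rownames(lin) <- genes

    if (spec$mnar_quantile > 0) {
      for (j in seq_len(ncol(lin))) {
        limit <- stats::quantile(lin[, j], spec$mnar_quantile, names = FALSE)
        lin[lin[, j] < limit, j] <- NA_real_
      }
    }

    truth <- data.frame(gene = genes, dapg = dapg, category = category,
                        effect_t8 = eff_t8, effect_t28 = eff_t28,
                        stringsAsFactors = FALSE)
    list(matrix = intensity_matrix(lin, cls), truth = truth)
  })
}
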