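#' Generate a synthetic qPCR Ct table
#'
#' Emulates a relative-quantification experiment: each target gene's
#' threshold cycle is the reference-gene Ct plus a baseline offset, minus
#' log2 of the true fold change in that condition (one PCR cycle = one
#' doubling of transcript), plus well noise. Each assay is run in triplicate
#' wells, and the reference gene is measured in every condition.
#'
#' @param fold_changes numeric matrix of true fold changes, genes x
#'   conditions (all > 0); rownames are gene symbols, colnames are
#'   conditions (the first, conventionally `GC`, is the calibrator and
#'   usually all 1).
#' @param ct_ref reference-gene threshold cycle (default 15, typical for
#'   abundant 18S rRNA).
#' @param ct_baseline offset of the target genes above the reference Ct.
#' @param noise_sd per-well Ct noise sd.
#' @param n_replicates wells per assay (default 3, triplicate reactions).
#' @param reference_gene reference gene symbol (default `"RNA18S"`).
#' @param timepoint timepoint label attached to every row.
#' @param seed integer RNG seed.
#' @return A data.frame with columns `gene`, `condition`, `timepoint`,
#'   `replicate`, `ct`, including rows for the reference gene.
#' @examples
#' fc <- matrix(c(1, 0.5), 1, 2, dimnames = list("ALPL", c("GC", "RPM")))
#' head(simulate_ct_table(fc))
#' @export
simulate_ct_table <- function(fold_changes, ct_ref = 15, ct_baseline = 8,
                              noise_sd = 0, n_replicates = 3L,
                              reference_gene = "RNA18S",
                              timepoint = "T8", seed = 1L) {
  fold_changes <- as.matrix(fold_changes)
  if (any(fold_changes <= 0)) stop("fold changes must be > 0")
  if (is.null(rownames(fold_changes)))
    rownames(fold_changes) <- sprintf("GENE%d", seq_len(nrow(fold_changes)))
  if (is.null(colnames(fold_changes)))
    colnames(fold_changes) <- c("GC", "RPM")[seq_len(ncol(fold_changes))]
  withr::with_seed(seed, {
    rows <- expand.grid(gene = c(reference_gene, rownames(fold_changes)),
                        condition = colnames(fold_changes),
                        replicate = seq_len(n_replicates),
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    ct <- ifelse(rows$gene == reference_gene,
                 ct_ref,
                 ct_ref + ct_baseline -
                   log2(fold_changes[cbind(match(rows$gene,
                                                 rownames(fold_changes)),
                                           match(rows$condition,
                                                 colnames(fold_changes)))]))
    ct[is.na(ct)] <- ct_ref  # reference rows
    ct <- ct + stats::rnorm(nrow(rows), 0, noise_sd)
    data.frame(gene = rows$gene, condition = rows$condition,
               timepoint = timepoint, replicate = rows$replicate,
               ct = ct, stringsAsFactors = FALSE)
  })
}

#' Generate a synthetic plate-reader absorbance table
#'
#' Absorbance follows the linear calibration `slope * concentration +
#' intercept` with additive noise; every well (standards and unknowns) is
#' read in triplicate.
#'
#' @param slope,intercept true calibration line.
#' @param standards strictly increasing vector of >= 2 standard
#'   concentrations.
#' @param unknowns vector of true concentrations of the unknown samples.
#' @param noise_sd absorbance noise sd per read.
#' @param n_reads reads per well (default 3).
#' @param seed integer RNG seed.
#' @return A list with `plate`, a data.frame (`sample`, `role`,
#'   `concentration` — `NA` for unknowns —, `read`, `absorbance`), and
#'   `truth`, a data.frame of the unknowns' true concentrations.
#' @export
simulate_plate <- function(slope, intercept, standards, unknowns = numeric(),
                           noise_sd = 0, n_reads = 3L, seed = 1L) {
  if (length(standards) < 2) stop("need >= 2 standard concentrations")
  if (any(diff(standards) <= 0))
    stop("standards must be strictly increasing")
  withr::with_seed(seed, {
    conc <- c(standards, unknowns)
    role <- rep(c("standard", "unknown"),
                c(length(standards), length(unknowns)))
    sample_id <- c(sprintf("std%d", seq_along(standards)),
                   if (length(unknowns)) sprintf("unk%d", seq_along(unknowns)))
    df <- expand.grid(i = seq_along(conc), read = seq_len(n_reads),
                      KEEP.OUT.ATTRS = FALSE)
    absorbance <- slope * conc[df$i] + intercept +
      stats::rnorm(nrow(df), 0, noise_sd)
    plate <- data.frame(sample = sample_id[df$i], role = role[df$i],
                        concentration = ifelse(role[df$i] == "standard",
                                               conc[df$i], NA_real_),
                        read = df$read, absorbance = absorbance,
                        stringsAsFactors = FALSE)
    truth <- data.frame(sample = sprintf("unk%d", seq_along(unknowns)),
                        concentration = unknowns)
    list(plate = plate, truth = truth)
  })
}
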