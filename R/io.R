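#' Read a wide protein-group intensity TSV
#'
#' Expects a header line `gene<TAB>CLASS_rep ...` where each sample token is a
#' class label (`T0`, `T8_GC`, `T8_RPM`, `T28_GC`, `T28_RPM`) followed by an
#' underscore and a replicate index, e.g. `T8_GC_2`. Blank cells and `NA` are
#' read as missing values. Duplicate gene rows are rejected.
#'
#' @param path path to a tab-separated file.
#' @return An [intensity_matrix()] on the linear scale.
#' @export
read_intensity_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, na.strings = c("", "NA"),
                          colClasses = "character")
  if (ncol(df) < 2 || tolower(names(df)[1]) != "gene")
    stop("first column must be named 'gene'")
  toks <- parse_sample_tokens(names(df)[-1])
  vals <- as.matrix(df[, -1, drop = FALSE])
  suppressWarnings(storage.mode(vals) <- "double")
  rownames(vals) <- df[[1]]
  intensity_matrix(vals, toks$class, toks$replicate)
}

parse_sample_tokens <- function(tokens) {
  m <- regmatches(tokens, regexec("^(.*)_([0-9]+)$", tokens))
  bad <- tokens[lengths(m) != 3]
  if (length(bad))
    stop("unparseable sample token(s): ", paste(bad, collapse = ", "))
  cls <- vapply(m, `[`, "", 2L)
  rep <- as.integer(vapply(m, `[`, "", 3L))
  unknown <- setdiff(unique(cls), smg_classes())
  if (length(unknown))
    stop("unknown class token(s): ", paste(unknown, collapse = ", "))
  list(class = cls, replicate = rep)
}

#' Write an intensity matrix as wide TSV
#'
#' Inverse of [read_intensity_tsv()]; missing entries are written as `NA`.
#'
#' @param im an [intensity_matrix()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_intensity_tsv <- function(im, path) {
  df <- data.frame(gene = genes_of(im), im$values, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write differential-abundance results as TSV
#'
#' Columns mirror the supplementary-table layout of the study: gene, the
#' ANOVA p value and its -log10, the permutation-FDR significance call, the
#' significant Tukey pairs, and the trend category.
#'
#' @param records data.frame of per-gene results (see [run_dapg_pipeline()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_dapg_tsv <- function(records, path) {
  utils::write.table(records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read gene sets in GMT format
#'
#' Each line is `term_id<TAB>term_name<TAB>gene1<TAB>gene2...`.
#'
#' @param path path to a GMT file.
#' @return Named list of character vectors of member genes; names are term
#'   ids, the `"term_name"` attribute on each element carries the
#'   description field.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  sets <- lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(f) < 3) stop("malformed GMT line: ", substr(l, 1, 40))
    structure(unique(f[-(1:2)]), term_name = f[2])
  })
  names(sets) <- vapply(lines, function(l)
    strsplit(l, "\t", fixed = TRUE)[[1]][1], "")
  sets
}

#' Pipeline configuration
#'
#' Builds a validated configuration list holding every tunable of the
#' pipeline. Unknown keys are rejected so that typos in YAML files fail
#' loudly; a seed is mandatory because imputation and the permutation FDR
#' are stochastic.
#'
#' @param ... named overrides of the defaults.
#' @param seed integer RNG seed (mandatory).
#' @return A named list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(..., seed) {
  if (missing(seed)) stop("`seed` is mandatory: every stochastic step draws from it")
  defaults <- list(
    min_fraction = 0.7,      # valid-value filter threshold per class
    n_perm = 250L,           # label permutations for FDR estimation
    fdr = 0.05,              # accepted false-discovery rate
    alpha = 0.05,            # Tukey HSD significance level
    impute_width = 0.3,      # imputation sd as multiple of the column sd
    impute_downshift = 1.8,  # imputation mean downshift in column sds
    n_belts = 11L,           # concentric belts, 0 = centrosome .. 10 = edge
    threshold_method = "otsu"
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(defaults))
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(defaults, over)
  cfg$seed <- as.integer(seed)
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file with a subset of the keys of [pipeline_config()]
#'   plus a mandatory `seed`.
#' @return A `"pipeline_config"` list.
#' @export
read_config_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y$seed)) stop("config must provide `seed`")
  seed <- y$seed
  y$seed <- NULL
  do.call(pipeline_config, c(y, list(seed = seed)))
}
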