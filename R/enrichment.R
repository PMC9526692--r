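#' Over-representation analysis by the hypergeometric test
#'
#' Tests each annotation set for over-representation in a gene list against
#' a background universe: the upper-tail hypergeometric probability
#' `P(X >= k)` of drawing `k` or more set members in a list of size `n`
#' from a background of `N` genes containing `K` set members. The
#' enrichment ratio is `(k/n) / (K/N)`. This replaces external web-service
#' enrichment with a hermetic, user-supplied-annotation operation.
#'
#' @param genes character vector of query genes (must all be in
#'   `background`).
#' @param sets named list of character vectors (e.g. from [read_gmt()]);
#'   members outside the background are ignored.
#' @param background character vector: the gene universe, by default all
#'   genes of the quantified matrix the list came from.
#' @param alpha keep terms with p <= `alpha` (default 0.05; use 1 to keep
#'   all).
#' @param adjust apply Benjamini-Hochberg correction before filtering
#'   (default `FALSE`, matching a raw p-value threshold).
#' @return A data.frame sorted by p (ties by term id) with columns
#'   `term`, `term_name`, `k`, `n`, `K`, `N`, `ratio`, `p`
#'   (and `p_adj` when `adjust = TRUE`).
#' @examples
#' ora(c("A", "B"), list(S1 = c("A", "B", "C")), background = LETTERS[1:10],
#'     alpha = 1)
#' @export
ora <- function(genes, sets, background, alpha = 0.05, adjust = FALSE) {
  genes <- unique(genes)
  background <- unique(background)
  missing_bg <- setdiff(genes, background)
  if (length(missing_bg))
    stop("gene(s) absent from background: ",
         paste(utils::head(missing_bg, 10), collapse = ", "))
  if (!length(sets)) stop("no annotation sets supplied")
  N <- length(background)
  n <- length(genes)
  rows <- lapply(names(sets), function(id) {
    members <- intersect(unique(sets[[id]]), background)
    K <- length(members)
    k <- length(intersect(genes, members))
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    ratio <- if (K > 0) (k / n) / (K / N) else 0
    nm <- attr(sets[[id]], "term_name")
    data.frame(term = id, term_name = if (is.null(nm)) id else nm,
               k = k, n = n, K = K, N = N, ratio = ratio, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$p, out$term), , drop = FALSE]
  if (adjust) {
    out$p_adj <- stats::p.adjust(out$p, method = "BH")
    out <- out[out$p_adj <= alpha, , drop = FALSE]
  } else {
    out <- out[out$p <= alpha, , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

#' Split classified protein groups into four regulation lists
#'
#' Divides trend-classified protein groups into the four lists used for
#' functional enrichment: down- and upregulated by simulated microgravity
#' at 8 or at 28 days. Groups regulated at both time points appear in both
#' lists of their direction.
#'
#' @param records data.frame with `gene` and `category` columns (see
#'   [run_dapg_pipeline()]).
#' @return A list of four character vectors: `down_T8`, `up_T8`,
#'   `down_T28`, `up_T28`.
#' @export
split_lists <- function(records) {
  pick <- function(cats) records$gene[records$category %in% cats]
  list(down_T8 = pick(c("down_T8_only", "down_both")),
       up_T8 = pick(c("up_T8_only", "up_both")),
       down_T28 = pick(c("down_T28_only", "down_both")),
       up_T28 = pick(c("up_T28_only", "up_both")))
}
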