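#' Gene-set over-representation of screen candidates
#'
#' For every supplied gene set, tests whether the candidate genes overlap it
#' more than expected by chance in the gene universe, via Fisher's exact test
#' on the 2x2 table (overlap, candidates outside the set, set members that
#' are not candidates, everything else), with Benjamini-Hochberg adjustment
#' across sets.  Sets are intersected with the universe first; the default
#' one-sided (`greater`) test targets over-representation, the two-sided
#' variant is also exposed.
#'
#' @param candidates character vector of candidate gene ids (subset of
#'   `universe`).
#' @param universe character vector: the post-filter gene universe.
#' @param gene_sets named list of character vectors (e.g. from
#'   [read_gmt()]).
#' @param sided `"greater"` (default) or `"two.sided"`.
#' @return data frame with one row per set: `set_name`, `overlap` (k),
#'   `set_size` (K, after intersection), `n_candidates` (n), `universe` (N),
#'   `odds_ratio`, `p_value`, `q_value`, ordered as supplied.
#' @export
fisher_enrichment <- function(candidates, universe, gene_sets,
                              sided = c("greater", "two.sided")) {
  sided <- match.arg(sided)
  universe <- unique(universe)
  if (length(universe) == 0L) stop("empty gene universe")
  candidates <- unique(candidates)
  stray <- setdiff(candidates, universe)
  if (length(stray))
    stop("candidates outside the universe: ",
         paste(utils::head(stray, 5), collapse = ", "))
  if (length(gene_sets) == 0L) stop("no gene sets supplied")
  N <- length(universe)
  n <- length(candidates)
  rows <- lapply(names(gene_sets), function(nm) {
    set <- intersect(unique(gene_sets[[nm]]), universe)
    K <- length(set)
    k <- length(intersect(set, candidates))
    tbl <- matrix(c(k, n - k, K - k, N - n - K + k), nrow = 2L)
    ft <- stats::fisher.test(tbl, alternative = sided)
    data.frame(set_name = nm, overlap = k, set_size = K, n_candidates = n,
               universe = N, odds_ratio = unname(ft$estimate),
               p_value = ft$p.value, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q_value <- bh_adjust(out$p_value)
  rownames(out) <- NULL
  out
}
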