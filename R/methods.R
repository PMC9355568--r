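#' @export
print.forward_screen <- function(x, ...) {
  cat("Forward-genomics screen for convergent gene loss\n")
  cat(sprintf("  genes: %d supplied, %d retained after filtering, %d tested\n",
              x$n_genes_input, nrow(x$results), x$n_genes_tested))
  cat(sprintf("  foreground lineages: %d\n", length(x$lineages)))
  cat(sprintf("  candidates (q < %g, lost in >= %d lineage(s)): %d\n",
              x$params$fdr, x$params$min_lineages, sum(x$results$candidate)))
  invisible(x)
}

#' Summarize a forward-genomics screen
#'
#' @param object a `forward_screen` object.
#' @param n number of top-ranked genes to display (default 10).
#' @param ... unused.
#' @return invisibly, the ranked results data frame (ties broken by
#'   `(q_value, p_value, gene_id)` for reproducible order).
#' @export
summary.forward_screen <- function(object, n = 10, ...) {
  res <- ranked_results(object)
  print(object)
  cat("\nTop-ranked genes:\n")
  top <- utils::head(res, n)
  top$slope <- signif(top$slope, 4)
  top$t_stat <- signif(top$t_stat, 4)
  top$p_value <- signif(top$p_value, 4)
  top$q_value <- signif(top$q_value, 4)
  print(top, row.names = FALSE)
  invisible(res)
}

#' Screen results ranked by significance
#'
#' @param x a `forward_screen` object.
#' @return the results data frame ordered by `(q_value, p_value, gene_id)`.
#' @export
ranked_results <- function(x) {
  stopifnot(inherits(x, "forward_screen"))
  res <- x$results
  res[order(res$q_value, res$p_value, res$gene_id,
            method = "radix", na.last = TRUE), , drop = FALSE]
}

#' Candidate genes of a screen
#' @param x a `forward_screen` object.
#' @return character vector of candidate gene ids, ranked.
#' @export
candidate_genes <- function(x) {
  res <- ranked_results(x)
  res$gene_id[res$candidate]
}

#' @export
as.data.frame.forward_screen <- function(x, ...) x$results

#' @export
coef.forward_screen <- function(object, ...) {
  stats::setNames(object$results$slope, object$results$gene_id)
}

#' Plot a forward-genomics screen
#'
#' Ranked gene significance: `-log10(q)` against rank, with the FDR cutoff as
#' a dashed line; candidates (passing both the FDR and the convergence
#' filter) are filled.
#'
#' @param x a `forward_screen` object.
#' @param ... passed to [plot.default()].
#' @export
plot.forward_screen <- function(x, ...) {
  res <- ranked_results(x)
  res <- res[!is.na(res$q_value), , drop = FALSE]
  q <- pmax(res$q_value, 1e-300)
  plot(seq_along(q), -log10(q), xlab = "gene rank",
       ylab = expression(-log[10](q)),
       pch = ifelse(res$candidate, 19, 1),
       col = ifelse(res$candidate, "firebrick", "grey40"), ...)
  graphics::abline(h = -log10(x$params$fdr), lty = 2)
  invisible(x)
}
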