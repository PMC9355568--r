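#' Normalize species names
#'
#' Spaces become underscores; case is preserved.  Applied identically to all
#' inputs so that labels match the tree byte-for-byte; residual mismatches
#' are reported as errors by [check_species_labels()], never dropped
#' silently.
#'
#' @param x character vector.
#' @return normalized character vector.
#' @export
normalize_species_names <- function(x) gsub(" ", "_", x, fixed = TRUE)

#' Read a rooted species tree from a Newick file
#'
#' @param path Newick file.
#' @param epsilon replacement for zero-length branches (default `1e-8`, with a
#'   warning); negative lengths and duplicate or missing leaf labels are
#'   rejected.
#' @return a `phylo` object with strictly positive branch lengths.
#' @export
read_newick <- function(path, epsilon = 1e-8) {
  txt <- paste(readLines(path, warn = FALSE), collapse = "")
  bal <- cumsum(ifelse(strsplit(txt, "")[[1]] == "(", 1L,
                       ifelse(strsplit(txt, "")[[1]] == ")", -1L, 0L)))
  if (length(bal) && (any(bal < 0) || utils::tail(bal, 1) != 0)) {
    pos <- if (any(bal < 0)) which(bal < 0)[1L] else length(bal)
    stop(sprintf("unbalanced parentheses in '%s' at character %d", path, pos))
  }
  tree <- tryCatch(ape::read.tree(path),
                   error = function(e) stop(sprintf("cannot parse '%s': %s",
                                                    path, conditionMessage(e))))
  if (is.null(tree)) stop(sprintf("cannot parse '%s' as Newick", path))
  if (anyDuplicated(tree$tip.label))
    stop("duplicate leaf labels: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]), collapse = ", "))
  if (is.null(tree$edge.length))
    stop(sprintf("tree in '%s' has no branch lengths", path))
  if (any(tree$edge.length < 0))
    stop(sprintf("tree in '%s' has negative branch lengths", path))
  if (any(tree$edge.length == 0)) {
    warning(sprintf("%d zero-length branch(es) replaced by epsilon = %g",
                    sum(tree$edge.length == 0), epsilon))
    tree$edge.length[tree$edge.length == 0] <- epsilon
  }
  tree$tip.label <- normalize_species_names(tree$tip.label)
  tree
}

#' Write a tree to Newick
#' @param tree `phylo` object.
#' @param path output file.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Read a gene x species \%intact matrix from TSV
#'
#' First column `gene_id`, remaining columns one species each; `NA` encodes
#' missing.  Values outside `[0, 100]` or non-numeric cells are rejected with
#' their row and column.
#'
#' @param path TSV file with a header row.
#' @return numeric matrix, rownames = genes, colnames = normalized species.
#' @export
read_intactness_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop(sprintf("'%s': need gene_id plus species columns", path))
  genes <- as.character(df[[1L]])
  if (anyDuplicated(genes)) stop(sprintf("'%s': duplicate gene ids", path))
  vals <- df[, -1L, drop = FALSE]
  for (j in seq_along(vals)) {
    v <- suppressWarnings(as.numeric(vals[[j]]))
    bad <- which(!is.na(vals[[j]]) & vals[[j]] != "NA" & is.na(v))
    if (length(bad))
      stop(sprintf("'%s': non-numeric value at row %d, column '%s'",
                   path, bad[1L], names(vals)[j]))
    out <- which(!is.na(v) & (v < 0 | v > 100))
    if (length(out))
      stop(sprintf("'%s': value %g out of [0, 100] at row %d, column '%s'",
                   path, v[out[1L]], out[1L], names(vals)[j]))
    vals[[j]] <- v
  }
  m <- as.matrix(vals)
  rownames(m) <- genes
  colnames(m) <- normalize_species_names(colnames(m))
  m
}

#' Write a \%intact matrix to TSV (deterministic formatting)
#' @param matrix numeric genes x species matrix.
#' @param path output TSV.
#' @export
write_intactness_matrix <- function(matrix, path) {
  df <- data.frame(gene_id = rownames(matrix),
                   apply(matrix, 2L, .fmt_num),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.fmt_num <- function(v) ifelse(is.na(v), "NA", formatC(signif(v, 6),
                                                       format = "g", digits = 6))

#' Read a species acuity table from TSV
#'
#' Columns `species_id`, `va`, and optionally `source` (default
#' `behavioral`).
#'
#' @param path TSV file.
#' @return an [acuity_table()].
#' @export
read_acuity <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("species_id", "va")
  if (!all(need %in% names(df)))
    stop(sprintf("'%s': columns species_id and va required", path))
  src <- if ("source" %in% names(df)) df$source else
    rep("behavioral", nrow(df))
  acuity_table(normalize_species_names(df$species_id),
               suppressWarnings(as.numeric(df$va)), src)
}

#' Read gene sets in GMT format
#'
#' One set per line: name, description, then tab-separated gene ids.
#'
#' @param path GMT file.
#' @return named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) < 3L) stop(sprintf("'%s': GMT line with fewer than 3 fields", path))
    out[[f[1L]]] <- unique(f[-(1:2)])
  }
  out
}

#' Cross-validate species labels against a tree
#'
#' @param species character vector of labels (e.g. matrix columns).
#' @param tree `phylo` object.
#' @param what label used in the error message.
#' @return invisibly `TRUE`; mismatches raise an error listing every
#'   offending label on each side.
#' @export
check_species_labels <- function(species, tree, what = "input") {
  only_in <- setdiff(species, tree$tip.label)
  if (length(only_in))
    stop(sprintf("%s species absent from tree: %s", what,
                 paste(sort(only_in), collapse = ", ")))
  invisible(TRUE)
}

#' Write screen results to TSV (deterministic formatting)
#'
#' Fixed column order `gene_id, n_species_used, slope, t_stat, p_value,
#' q_value, n_lost_lineages, candidate`; numbers at 6 significant digits; no
#' timestamps — identical inputs give byte-identical files.
#'
#' @param x a `forward_screen` object or its `$results` data frame.
#' @param path output TSV.
#' @export
write_screen_results <- function(x, path) {
  res <- if (inherits(x, "forward_screen")) x$results else x
  cols <- c("gene_id", "n_species_used", "slope", "t_stat", "p_value",
            "q_value", "n_lost_lineages", "candidate")
  stopifnot(all(cols %in% names(res)))
  out <- res[, cols]
  for (cc in c("slope", "t_stat", "p_value", "q_value"))
    out[[cc]] <- .fmt_num(out[[cc]])
  out$candidate <- ifelse(out$candidate, "TRUE", "FALSE")
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a mutation table to TSV
#' @param mutations data frame with columns `gene_id`, `species_id`, `kind`,
#'   `codon_start`, `codon_end` (extra columns kept).
#' @param path output TSV.
#' @export
write_mutations <- function(mutations, path) {
  utils::write.table(mutations, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write an acuity table to TSV
#' @param table an [acuity_table()].
#' @param path output TSV.
#' @export
write_acuity <- function(table, path) {
  df <- as.data.frame(table)
  df$va <- .fmt_num(df$va)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
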