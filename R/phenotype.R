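#' Construct a species visual-acuity table
#'
#' @param species_id character vector of species labels (must match tree tips
#'   byte-for-byte after [normalize_species_names()]).
#' @param va visual acuity in cycles per degree; `NA` allowed only when the
#'   species is not flagged `assumed_zero`.
#' @param source provenance of each value: `behavioral`, `anatomical`,
#'   `proxy_relative`, or `assumed_zero` (functionally blind species without a
#'   measurement; their `va` must be 0).
#' @return a data frame of class `acuity_table`.
#' @export
acuity_table <- function(species_id, va,
                         source = rep("behavioral", length(species_id))) {
  stopifnot(length(species_id) == length(va), length(va) == length(source))
  src_levels <- c("behavioral", "anatomical", "proxy_relative", "assumed_zero")
  if (!all(source %in% src_levels))
    stop("unknown acuity source: ", paste(setdiff(source, src_levels), collapse = ", "))
  if (any(!is.na(va) & va < 0)) stop("visual acuity must be non-negative")
  if (any(source == "assumed_zero" & (is.na(va) | va != 0)))
    stop("assumed_zero species must carry va = 0")
  if (anyDuplicated(species_id)) stop("duplicate species in acuity table")
  structure(data.frame(species_id = as.character(species_id), va = va,
                       source = source, stringsAsFactors = FALSE),
            class = c("acuity_table", "data.frame"))
}

#' Construct a phenotype assignment
#'
#' @param labels named character vector over `foreground`, `background`,
#'   `excluded`, named by species.
#' @param lineages optional list of character vectors partitioning the
#'   foreground species into independent lineages (see
#'   [partition_lineages()]).
#' @param provenance free-form list recording how the labels were derived.
#' @return an object of class `phenotype_assignment`.
#' @export
phenotype_assignment <- function(labels, lineages = NULL, provenance = list()) {
  stopifnot(!is.null(names(labels)),
            all(labels %in% c("foreground", "background", "excluded")))
  fg <- names(labels)[labels == "foreground"]
  if (!is.null(lineages)) {
    flat <- unlist(lineages)
    if (anyDuplicated(flat) || !setequal(flat, fg))
      stop("lineages must partition exactly the foreground species")
  }
  structure(list(labels = labels, lineages = lineages,
                 provenance = provenance),
            class = "phenotype_assignment")
}

#' @export
print.phenotype_assignment <- function(x, ...) {
  n <- table(factor(x$labels, c("foreground", "background", "excluded")))
  cat(sprintf("<phenotype_assignment> %d foreground, %d background, %d excluded",
              n[1], n[2], n[3]))
  if (!is.null(x$lineages))
    cat(sprintf("; %d independent foreground lineage(s)", length(x$lineages)))
  cat("\n")
  invisible(x)
}

#' Foreground species of an assignment
#' @param x a `phenotype_assignment`.
#' @return character vector of foreground species.
#' @export
foreground_species <- function(x) {
  stopifnot(inherits(x, "phenotype_assignment"))
  names(x$labels)[x$labels == "foreground"]
}

#' Label species as low- or high-acuity by an acuity threshold
#'
#' Species with visual acuity strictly below `threshold` cycles/degree become
#' foreground (trait-loss) species; the rest background.  Species without a
#' value and without the `assumed_zero` flag are excluded.  When a tree is
#' supplied, the foreground is additionally partitioned into independent
#' lineages.
#'
#' @param table an [acuity_table()].
#' @param threshold acuity cutoff in cycles/degree (default 1).
#' @param tree optional rooted `phylo` tree used to partition lineages.
#' @return a [phenotype_assignment()].
#' @export
classify_by_acuity <- function(table, threshold = 1, tree = NULL) {
  stopifnot(inherits(table, "acuity_table") || is.data.frame(table))
  stopifnot(threshold > 0)
  if (any(!is.na(table$va) & table$va < 0)) stop("visual acuity must be non-negative")
  lab <- ifelse(is.na(table$va), "excluded",
                ifelse(table$va < threshold, "foreground", "background"))
  names(lab) <- table$species_id
  lin <- NULL
  if (!is.null(tree))
    lin <- partition_lineages(tree, names(lab)[lab == "foreground"])
  phenotype_assignment(lab, lin,
                       provenance = list(method = "acuity_threshold",
                                         threshold = threshold))
}

#' Label species by a molecular loss signature
#'
#' A species joins the foreground when it has lost at least `min_lost` of the
#' marker genes (status `lost` in the status matrix), emulating a phenotype
#' definition from the molecular decay of a known gene set rather than from a
#' measured trait.
#'
#' @param status_matrix character matrix (genes x species) of statuses as
#'   produced by [classify_status()].
#' @param marker_genes character vector of marker gene ids (must be rows of
#'   the matrix).
#' @param min_lost minimum number of lost marker genes (default 5).
#' @param tree optional tree for lineage partitioning.
#' @return a [phenotype_assignment()].
#' @export
classify_by_signature <- function(status_matrix, marker_genes, min_lost = 5,
                                  tree = NULL) {
  if (length(marker_genes) == 0L) stop("marker gene set is empty")
  missing_markers <- setdiff(marker_genes, rownames(status_matrix))
  if (length(missing_markers))
    stop("marker genes absent from matrix: ",
         paste(utils::head(missing_markers, 5), collapse = ", "))
  sub <- status_matrix[marker_genes, , drop = FALSE]
  n_lost <- colSums(sub == "lost", na.rm = TRUE)
  lab <- ifelse(n_lost >= min_lost, "foreground", "background")
  names(lab) <- colnames(status_matrix)
  lin <- if (!is.null(tree))
    partition_lineages(tree, names(lab)[lab == "foreground"]) else NULL
  phenotype_assignment(lab, lin,
                       provenance = list(method = "loss_signature",
                                         min_lost = min_lost,
                                         n_markers = length(marker_genes)))
}

#' Partition foreground species into independent lineages
#'
#' An independent lineage is a maximal monophyletic clade whose leaves are all
#' foreground: two foreground species belong to the same lineage exactly when
#' every species on the path between them is also foreground.  The returned
#' sets are pairwise disjoint and their union is the foreground.
#'
#' @param tree rooted `phylo` object.
#' @param foreground character vector of foreground species (subset of tree
#'   tips).
#' @return list of character vectors, ordered by their first tip's position in
#'   `tree$tip.label`.
#' @export
partition_lineages <- function(tree, foreground) {
  stopifnot(inherits(tree, "phylo"))
  bad <- setdiff(foreground, tree$tip.label)
  if (length(bad))
    stop("species not in tree: ", paste(bad, collapse = ", "))
  ntip <- length(tree$tip.label)
  if (length(foreground) == 0L) return(list())
  nnode <- ntip + tree$Nnode
  all_fg <- logical(nnode)
  all_fg[seq_len(ntip)] <- tree$tip.label %in% foreground
  # postorder accumulation: a node is all-foreground iff all children are
  po <- ape::reorder.phylo(tree, "postorder")
  has_bg <- logical(nnode)
  has_bg[seq_len(ntip)] <- !all_fg[seq_len(ntip)]
  for (i in seq_len(nrow(po$edge))) {
    par <- po$edge[i, 1L]; ch <- po$edge[i, 2L]
    if (has_bg[ch]) has_bg[par] <- TRUE
  }
  all_fg <- !has_bg
  parent <- integer(nnode)
  parent[tree$edge[, 2L]] <- tree$edge[, 1L]
  root <- ntip + 1L
  parent[root] <- root
  maximal <- which(all_fg & (seq_len(nnode) == root | !all_fg[parent]))
  tips_below <- function(node) {
    if (node <= ntip) return(tree$tip.label[node])
    ape::extract.clade(tree, node)$tip.label
  }
  out <- lapply(maximal, tips_below)
  out[order(vapply(out, function(s) match(s[1L], tree$tip.label), integer(1)))]
}
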