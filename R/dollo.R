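# internal: per-node flags over {has intact leaf below, has lost leaf below},
# missing leaves uninformative; returns maximal all-lost clades
.maximal_lost_clades <- function(tree, lost, intact) {
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  has_intact <- logical(nnode)
  has_lost <- logical(nnode)
  has_intact[seq_len(ntip)] <- tree$tip.label %in% intact
  has_lost[seq_len(ntip)] <- tree$tip.label %in% lost
  po <- ape::reorder.phylo(tree, "postorder")
  for (i in seq_len(nrow(po$edge))) {
    par <- po$edge[i, 1L]; ch <- po$edge[i, 2L]
    has_intact[par] <- has_intact[par] || has_intact[ch]
    has_lost[par] <- has_lost[par] || has_lost[ch]
  }
  qualifies <- has_lost & !has_intact
  parent <- integer(nnode)
  parent[tree$edge[, 2L]] <- tree$edge[, 1L]
  root <- ntip + 1L
  parent[root] <- root
  is_root <- seq_len(nnode) == root
  which(qualifies & (is_root | !qualifies[parent]))
}

.clade_tips <- function(tree, node) {
  ntip <- length(tree$tip.label)
  if (node <= ntip) tree$tip.label[node]
  else ape::extract.clade(tree, node)$tip.label
}

# child-node label for an edge above `node`: tip label for tips, otherwise the
# internal node label when present, else "node_<id>"
.branch_label <- function(tree, node) {
  ntip <- length(tree$tip.label)
  if (node <= ntip) return(tree$tip.label[node])
  if (!is.null(tree$node.label) &&
      !is.na(tree$node.label[node - ntip]) &&
      nzchar(tree$node.label[node - ntip]))
    return(tree$node.label[node - ntip])
  paste0("node_", node)
}

#' Count independent gene-loss events by Dollo parsimony
#'
#' Under Dollo parsimony an intact gene can be lost on any branch but never
#' regained, and the gene is presumed intact at the root.  The minimum number
#' of loss events explaining the leaf statuses is then the number of maximal
#' clades whose non-missing leaves are all `lost` (with at least one such
#' leaf); each event is placed on the stem branch of its clade — the deepest
#' placement consistent with the minimum.  Leaves with status `missing` are
#' uninformative: they neither create nor destroy events.
#'
#' @param tree rooted `phylo`.
#' @param statuses named character vector over `lost`, `intact`, `missing`,
#'   keyed by tree tips.  Tips absent from `statuses` are treated as missing.
#' @return list with `count` (minimum number of loss events) and `events`, a
#'   data frame with one row per event: `branch` (child-node label of the stem
#'   edge), `n_descendant_lost`, and `descendant_lost` (comma-joined lost
#'   species below the branch).
#' @export
dollo_count <- function(tree, statuses) {
  stopifnot(inherits(tree, "phylo"), !is.null(names(statuses)))
  bad_val <- setdiff(unique(statuses), c("lost", "intact", "missing"))
  if (length(bad_val))
    stop("unknown status value(s): ", paste(bad_val, collapse = ", "))
  bad_sp <- setdiff(names(statuses), tree$tip.label)
  if (length(bad_sp))
    stop("status species not in tree: ", paste(bad_sp, collapse = ", "))
  lost <- names(statuses)[statuses == "lost"]
  intact <- names(statuses)[statuses == "intact"]
  if (length(lost) == 0L && length(intact) == 0L)
    stop("all leaves missing: loss history undefined")
  nodes <- .maximal_lost_clades(tree, lost, intact)
  events <- do.call(rbind, lapply(nodes, function(nd) {
    tips <- .clade_tips(tree, nd)
    lost_tips <- intersect(tips, lost)
    data.frame(branch = .branch_label(tree, nd),
               n_descendant_lost = length(lost_tips),
               descendant_lost = paste(sort(lost_tips), collapse = ","),
               stringsAsFactors = FALSE)
  }))
  if (is.null(events))
    events <- data.frame(branch = character(), n_descendant_lost = integer(),
                         descendant_lost = character())
  list(count = length(nodes), events = events)
}

#' Assign shared inactivating mutations to ancestral branches
#'
#' A mutation with identical kind and codon position observed in every
#' non-missing leaf of a clade most parsimoniously arose once on that clade's
#' stem branch.  For each distinct `(kind, codon_start)` key the deepest such
#' clades are found; keys carried by a single species stay leaf-private.
#' Pairs of keys of the same kind whose codon positions differ by exactly one
#' are additionally reported as possibly shared (alignment wobble can shift a
#' lesion by one codon) but are never merged.
#'
#' @param mutations data frame with columns `species_id`, `kind`,
#'   `codon_start` (one gene; extra columns ignored).
#' @param tree rooted `phylo`.
#' @param missing_species species whose locus is missing data; they do not
#'   veto an ancestral assignment.
#' @return list with `assignments` (one row per `(kind, codon_start, branch)`:
#'   `shared` is `TRUE` for ancestral placements covering >= 2 species) and
#'   `possibly_shared` (near-matching key pairs).
#' @export
shared_mutations <- function(mutations, tree, missing_species = character()) {
  stopifnot(inherits(tree, "phylo"),
            all(c("species_id", "kind", "codon_start") %in% names(mutations)))
  bad <- setdiff(mutations$species_id, tree$tip.label)
  if (length(bad))
    stop("mutation species not in tree: ", paste(bad, collapse = ", "))
  keys <- unique(mutations[, c("kind", "codon_start")])
  non_missing <- setdiff(tree$tip.label, missing_species)
  rows <- lapply(seq_len(nrow(keys)), function(i) {
    kk <- keys$kind[i]; cc <- keys$codon_start[i]
    carriers <- unique(mutations$species_id[mutations$kind == kk &
                                            mutations$codon_start == cc])
    nodes <- .maximal_lost_clades(tree, carriers,
                                  setdiff(non_missing, carriers))
    do.call(rbind, lapply(nodes, function(nd) {
      tips <- intersect(.clade_tips(tree, nd), carriers)
      data.frame(kind = kk, codon_start = cc,
                 branch = .branch_label(tree, nd),
                 n_species = length(tips),
                 species = paste(sort(tips), collapse = ","),
                 shared = length(tips) >= 2L,
                 stringsAsFactors = FALSE)
    }))
  })
  assignments <- do.call(rbind, rows)
  if (is.null(assignments))
    assignments <- data.frame(kind = character(), codon_start = integer(),
                              branch = character(), n_species = integer(),
                              species = character(), shared = logical())
  possibly <- NULL
  if (nrow(keys) > 1L) {
    for (i in seq_len(nrow(keys) - 1L)) for (j in (i + 1L):nrow(keys)) {
      if (keys$kind[i] == keys$kind[j] &&
          abs(keys$codon_start[i] - keys$codon_start[j]) == 1L) {
        possibly <- rbind(possibly, data.frame(
          kind = keys$kind[i],
          codon_a = min(keys$codon_start[i], keys$codon_start[j]),
          codon_b = max(keys$codon_start[i], keys$codon_start[j]),
          stringsAsFactors = FALSE))
      }
    }
  }
  if (is.null(possibly))
    possibly <- data.frame(kind = character(), codon_a = integer(),
                           codon_b = integer())
  list(assignments = assignments, possibly_shared = possibly)
}

#' Annotate a tree with loss events
#'
#' Writes a Newick string in which every branch carrying a loss event is
#' tagged with a `[&loss]` comment on its child node label.
#'
#' @param tree rooted `phylo`.
#' @param events event table from [dollo_count()].
#' @return a single Newick character string.
#' @export
annotate_loss_tree <- function(tree, events) {
  tr <- tree
  ntip <- length(tr$tip.label)
  if (is.null(tr$node.label))
    tr$node.label <- paste0("node_", ntip + seq_len(tr$Nnode))
  hit_tips <- tr$tip.label %in% events$branch
  hit_nodes <- tr$node.label %in% events$branch
  tr$tip.label[hit_tips] <- paste0(tr$tip.label[hit_tips], "[&loss]")
  tr$node.label[hit_nodes] <- paste0(tr$node.label[hit_nodes], "[&loss]")
  ape::write.tree(tr)
}
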