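#' Configuration for the synthetic phylogenomic benchmark
#'
#' Bundles the study conditions the generator emulates: an ultrametric
#' species tree, a minority of low-acuity foreground lineages, associated
#' genes accruing inactivating mutations preferentially on foreground
#' branches (relaxed selection), background genes with rare noise mutations,
#' and a continuous acuity covariate separating the groups.
#'
#' @param n_species number of species (default 49).
#' @param birth_rate pure-birth speciation rate (default 1); trees are
#'   rescaled to unit height so rates are per total tree depth.
#' @param n_fg_lineages number of independent foreground lineages (default 7).
#' @param n_genes number of genes (default 2000).
#' @param n_associated number of genes whose loss follows the phenotype
#'   (default 20).
#' @param lambda_fg inactivating-mutation rate per unit branch length on
#'   foreground branches of associated genes; `NULL` (default) calibrates it
#'   so each foreground species is lost with probability `fg_loss_prob`.
#' @param fg_loss_prob target per-species loss probability used for the
#'   calibration (default 0.8).
#' @param lambda_bg background noise rate on all branches of all genes
#'   (default 0.02).
#' @param cds_len coding length in codons (default 500).
#' @param n_exons exons per gene (default 8).
#' @param kind_mix named probabilities over mutation kinds (must sum to 1).
#' @param va_fg,va_bg acuity sampling intervals (cycles/degree) for
#'   foreground and background species.
#' @param max_lineage_size largest clade eligible as a foreground lineage
#'   (default 3).
#' @param min_stem_frac minimum stem-origin-to-tip path of an eligible
#'   foreground lineage as a fraction of tree height (default 0.1).
#' @param miss_rate per-cell probability that a \%intact value is missing
#'   (assembly incompleteness; default 0.02).
#' @param loss_thr \%intact loss threshold used by the calibration
#'   (default 60).
#' @param seed integer master seed; all randomness flows from it through
#'   named substreams (tree, phenotype, per-gene).
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(n_species = 49, birth_rate = 1, n_fg_lineages = 7,
                       n_genes = 2000, n_associated = 20,
                       lambda_fg = NULL, fg_loss_prob = 0.8,
                       lambda_bg = 0.02, cds_len = 500, n_exons = 8,
                       kind_mix = c(frameshift_deletion = 0.3,
                                    frameshift_insertion = 0.2,
                                    premature_stop = 0.35,
                                    splice_site = 0.1,
                                    exon_deletion = 0.05),
                       va_fg = c(0, 0.9), va_bg = c(1.1, 60),
                       max_lineage_size = 3, min_stem_frac = 0.1,
                       miss_rate = 0.02, loss_thr = 60, seed = 1) {
  stopifnot(n_species >= 2, n_genes >= 1, n_associated <= n_genes,
            n_fg_lineages >= 1, cds_len >= 3 * n_exons,
            abs(sum(kind_mix) - 1) < 1e-8,
            all(names(kind_mix) %in% MUTATION_KINDS),
            miss_rate >= 0, miss_rate < 1,
            fg_loss_prob > 0, fg_loss_prob < 1)
  if (!is.null(lambda_fg)) stopifnot(lambda_bg <= lambda_fg)
  structure(list(n_species = n_species, birth_rate = birth_rate,
                 n_fg_lineages = n_fg_lineages, n_genes = n_genes,
                 n_associated = n_associated, lambda_fg = lambda_fg,
                 fg_loss_prob = fg_loss_prob, lambda_bg = lambda_bg,
                 cds_len = cds_len, n_exons = n_exons, kind_mix = kind_mix,
                 va_fg = va_fg, va_bg = va_bg,
                 max_lineage_size = max_lineage_size,
                 min_stem_frac = min_stem_frac, miss_rate = miss_rate,
                 loss_thr = loss_thr, seed = as.integer(seed)),
            class = "sim_config")
}

# deterministic substream seeds below 2^31 (double arithmetic: exact here)
.substream <- function(seed, offset)
  as.integer((as.numeric(seed) * 1013 + as.numeric(offset)) %% 2147483629)

#' Simulate an ultrametric pure-birth species tree
#'
#' @param n_species number of extant species.
#' @param birth_rate speciation rate of the pure-birth process.
#' @param seed integer seed.
#' @return a rooted ultrametric `phylo` rescaled to unit height, tips
#'   `s01, s02, ...`.
#' @export
simulate_tree <- function(n_species, birth_rate = 1, seed = 1) {
  stopifnot(n_species >= 2)
  set.seed(.substream(seed, 1L))
  tr <- ape::rphylo(n_species, birth = birth_rate, death = 0)
  h <- max(ape::node.depth.edgelength(tr))
  tr$edge.length <- tr$edge.length / h
  tr$tip.label <- sprintf("s%02d", seq_len(n_species))
  tr
}

#' Select foreground lineages and sample visual acuities
#'
#' Chooses `n_fg_lineages` disjoint clades of at most `max_lineage_size`
#' species as trait-loss lineages (rejecting draws in which two chosen clades
#' merge into a larger all-foreground clade), then samples acuities:
#' foreground uniform on `va_fg`, background log-uniform on `va_bg`.  By
#' construction [classify_by_acuity()] at threshold 1 recovers the intended
#' labels and [partition_lineages()] recovers exactly the chosen lineages.
#'
#' @param tree rooted `phylo`.
#' @param n_fg_lineages number of independent foreground lineages.
#' @param va_fg,va_bg acuity intervals (cycles/degree).
#' @param max_lineage_size largest eligible clade.
#' @param min_stem_frac minimum stem-origin-to-tip path of an eligible
#'   lineage, as a fraction of tree height (default 0.1): trait-loss lineages
#'   must be old enough for molecular decay to have accumulated.
#' @param seed integer seed.
#' @return list with `assignment` (a [phenotype_assignment()] with lineages)
#'   and `acuity` (an [acuity_table()]).
#' @export
assign_phenotype <- function(tree, n_fg_lineages, va_fg = c(0, 0.9),
                             va_bg = c(1.1, 60), max_lineage_size = 3,
                             min_stem_frac = 0.1, seed = 1) {
  set.seed(.substream(seed, 2L))
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  clade_tips <- lapply(seq_len(nnode), function(nd) .clade_tips(tree, nd))
  sizes <- lengths(clade_tips)
  # trait loss needs evolutionary time: a lineage qualifies only when the
  # path from its stem origin to its tips spans at least min_stem_frac of the
  # tree height (a species that split off yesterday cannot have decayed)
  depths <- ape::node.depth.edgelength(tree)
  height <- max(depths)
  parent <- integer(nnode)
  parent[tree$edge[, 2L]] <- tree$edge[, 1L]
  parent[ntip + 1L] <- ntip + 1L
  stem_path <- vapply(seq_len(nnode), function(nd) {
    tips <- if (nd <= ntip) nd else match(clade_tips[[nd]], tree$tip.label)
    max(depths[tips]) - depths[parent[nd]]
  }, numeric(1))
  eligible <- which(sizes <= max_lineage_size & sizes <= ntip %/% 2L &
                    stem_path >= min_stem_frac * height)
  if (length(eligible) < n_fg_lineages)
    stop("tree offers too few clades of size <= ", max_lineage_size)
  for (attempt in 1:200) {
    picked <- integer(0)
    taken <- character(0)
    for (nd in sample(eligible)) {
      if (length(picked) == n_fg_lineages) break
      if (length(intersect(clade_tips[[nd]], taken))) next
      picked <- c(picked, nd)
      taken <- c(taken, clade_tips[[nd]])
    }
    if (length(picked) < n_fg_lineages) next
    if (length(taken) >= ntip) next
    if (length(partition_lineages(tree, taken)) == n_fg_lineages) {
      lineages <- lapply(picked, function(nd) clade_tips[[nd]])
      fg <- taken
      lab <- stats::setNames(ifelse(tree$tip.label %in% fg,
                                    "foreground", "background"),
                             tree$tip.label)
      va <- numeric(ntip)
      is_fg <- tree$tip.label %in% fg
      va[is_fg] <- stats::runif(sum(is_fg), va_fg[1], va_fg[2])
      va[!is_fg] <- 10^stats::runif(sum(!is_fg), log10(va_bg[1]), log10(va_bg[2]))
      acuity <- acuity_table(tree$tip.label, va)
      lineages <- lineages[order(vapply(lineages, function(s)
        match(s[1L], tree$tip.label), integer(1)))]
      asg <- phenotype_assignment(lab, lineages,
                                  provenance = list(method = "simulated",
                                                    seed = seed))
      return(list(assignment = asg, acuity = acuity))
    }
  }
  stop("could not place ", n_fg_lineages, " disjoint independent lineages")
}

# P(max spacing of k uniform points on [0,1] < s): the gene is lost when no
# clean stretch reaches the loss threshold fraction s
.p_lost_given_k <- function(k, s) {
  if (k == 0L) return(0)
  j <- seq_len(floor(1 / s))
  tail <- sum((-1)^(j + 1) * choose(k + 1, j) * pmax(1 - j * s, 0)^k)
  1 - min(max(tail, 0), 1)
}

#' Calibrate the foreground mutation rate to a target loss probability
#'
#' Solves for the Poisson mutation rate such that a foreground species whose
#' lineage accrues mutations along its stem-to-tip path is lost
#' (\%intact below `loss_thr`) with probability `target`, using the exact
#' distribution of the maximum spacing of uniformly placed breakpoints.
#'
#' @param tree `phylo` tree.
#' @param lineages foreground lineage partition.
#' @param target per-species loss probability.
#' @param loss_thr \%intact loss threshold.
#' @return rate per unit branch length.
#' @export
calibrate_lambda_fg <- function(tree, lineages, target = 0.8, loss_thr = 60) {
  s <- loss_thr / 100
  depths <- ape::node.depth.edgelength(tree)
  ntip <- length(tree$tip.label)
  # mean stem-to-tip path over foreground species: tip depth minus depth of
  # the lineage MRCA's parent (the stem origin)
  parent <- integer(ntip + tree$Nnode)
  parent[tree$edge[, 2L]] <- tree$edge[, 1L]
  root <- ntip + 1L
  parent[root] <- root
  path_len <- unlist(lapply(lineages, function(sp) {
    tips <- match(sp, tree$tip.label)
    mrca <- if (length(tips) == 1L) tips else ape::getMRCA(tree, tips)
    depths[tips] - depths[parent[mrca]]
  }))
  p_lost <- function(m) {
    ks <- 0:ceiling(m + 10 * sqrt(m) + 20)
    sum(stats::dpois(ks, m) * vapply(ks, .p_lost_given_k, numeric(1), s = s))
  }
  # paths differ across species, so solve for the rate at which the mean
  # per-species loss probability reaches the target
  mean_p <- function(lambda) mean(vapply(path_len, function(l) p_lost(lambda * l),
                                         numeric(1)))
  stats::uniroot(function(lambda) mean_p(lambda) - target,
                 lower = 1e-6, upper = 50 / min(path_len),
                 extendInt = "upX", tol = 1e-6)$root
}

#' Simulate the gene-inactivation history of one gene
#'
#' Mutations accrue as a Poisson process along every branch: at rate
#' `lambda_bg` everywhere and additionally `lambda_fg` on branches within
#' foreground lineages (stem included) when the gene is associated with the
#' phenotype.  Mutations on internal branches are inherited by all descendant
#' species.  Point-mutation codons are drawn without replacement over the
#' codons not covered by a deleted exon and never hit the terminal codon, so
#' an implanted set round-trips exactly through [emit_alignments()] and
#' [detect_mutations()].
#'
#' @param tree rooted `phylo`.
#' @param assignment [phenotype_assignment()] with lineages.
#' @param associated is this gene phenotype-associated?
#' @param cfg a [sim_config()]; `lambda_fg` must be resolved (numeric).
#' @param seed integer seed.
#' @return data frame with columns `species_id`, `kind`, `codon_start`,
#'   `codon_end`, `branch`, `detail` (splice boundary/side or exon index).
#' @export
simulate_gene <- function(tree, assignment, associated, cfg, seed) {
  stopifnot(is.numeric(cfg$lambda_fg))
  set.seed(.substream(seed, 17L))
  L <- cfg$cds_len
  eb <- .default_exon_bounds(L, cfg$n_exons)
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode

  # edges inside foreground lineages, stem edge included
  fg_node <- logical(nnode)
  for (sp in assignment$lineages) {
    tips <- match(sp, tree$tip.label)
    mrca <- if (length(tips) == 1L) tips else ape::getMRCA(tree, tips)
    fg_node[mrca] <- TRUE
  }
  pre <- ape::reorder.phylo(tree, "cladewise")
  in_fg <- logical(nnode)
  for (i in seq_len(nrow(pre$edge))) {
    par <- pre$edge[i, 1L]; ch <- pre$edge[i, 2L]
    in_fg[ch] <- in_fg[par] || fg_node[ch]
  }
  edge_rate <- cfg$lambda_bg +
    ifelse(associated & in_fg[tree$edge[, 2L]], cfg$lambda_fg, 0)
  n_mut <- stats::rpois(nrow(tree$edge), edge_rate * tree$edge.length)
  total <- sum(n_mut)
  if (total == 0L)
    return(data.frame(species_id = character(), kind = character(),
                      codon_start = integer(), codon_end = integer(),
                      branch = character(), detail = character()))

  kinds <- sample(names(cfg$kind_mix), total, replace = TRUE,
                  prob = cfg$kind_mix)
  # whole-exon deletions first: they mask their codons for point mutations
  del_exons <- integer(0)
  rows <- vector("list", total)
  edge_of <- rep(seq_len(nrow(tree$edge)), n_mut)
  is_exdel <- kinds == "exon_deletion"
  for (i in which(is_exdel)) {
    avail <- setdiff(seq_len(nrow(eb)), del_exons)
    if (!length(avail)) { kinds[i] <- "premature_stop"; next }
    ex <- if (length(avail) == 1L) avail else sample(avail, 1L)
    del_exons <- c(del_exons, ex)
    rows[[i]] <- list(kind = "exon_deletion", codon_start = eb$codon_start[ex],
                      codon_end = eb$codon_end[ex], detail = paste0("exon:", ex))
  }
  blocked <- unique(unlist(lapply(del_exons, function(ex)
    eb$codon_start[ex]:(eb$codon_end[ex] - 1L))))
  free_codons <- setdiff(0:(L - 2L), blocked)
  n_bound <- nrow(eb) - 1L
  used_splice <- character(0)
  fallback <- integer(0)                 # splice draws with no boundary left
  for (i in which(kinds == "splice_site")) {
    cand <- character(0)
    if (n_bound >= 1L) {
      cand <- setdiff(as.vector(outer(seq_len(n_bound), c("donor", "acceptor"),
                                      paste, sep = ":")), used_splice)
      cand <- Filter(function(x) {
        b <- as.integer(strsplit(x, ":")[[1]][1])
        !(b %in% del_exons) && !((b + 1L) %in% del_exons)
      }, cand)
    }
    if (!length(cand)) { fallback <- c(fallback, i); next }
    pickv <- if (length(cand) == 1L) cand else sample(cand, 1L)
    used_splice <- c(used_splice, pickv)
    parts <- strsplit(pickv, ":")[[1]]
    b <- as.integer(parts[1]); side <- parts[2]
    c0 <- if (side == "donor") eb$codon_end[b] - 1L else eb$codon_start[b + 1L]
    free_codons <- setdiff(free_codons, c0)
    rows[[i]] <- list(kind = "splice_site", codon_start = c0,
                      codon_end = c0 + 1L, detail = pickv)
  }
  point <- c(which(!is_exdel & kinds != "splice_site"), fallback)
  open_codons <- setdiff(0:(L - 2L), blocked)
  if (!length(open_codons)) open_codons <- 0:(L - 2L)
  for (i in point) {
    k <- if (i %in% fallback) "premature_stop" else kinds[i]
    if (length(free_codons)) {
      # unique codons while the pool lasts, so implanted sets round-trip
      c0 <- if (length(free_codons) == 1L) free_codons else sample(free_codons, 1L)
      free_codons <- setdiff(free_codons, c0)
    } else {
      c0 <- if (length(open_codons) == 1L) open_codons else sample(open_codons, 1L)
    }
    rows[[i]] <- list(kind = k, codon_start = c0, codon_end = c0 + 1L,
                      detail = NA_character_)
  }

  # propagate each mutation to all species below its edge
  out <- list()
  for (i in seq_len(total)) {
    if (is.null(rows[[i]])) next
    ch <- tree$edge[edge_of[i], 2L]
    sp <- .clade_tips(tree, ch)
    out[[length(out) + 1L]] <- data.frame(
      species_id = sp, kind = rows[[i]]$kind,
      codon_start = rows[[i]]$codon_start, codon_end = rows[[i]]$codon_end,
      branch = .branch_label(tree, ch), detail = rows[[i]]$detail,
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  res <- res[order(res$species_id, res$codon_start), , drop = FALSE]
  rownames(res) <- NULL
  res
}

.default_exon_bounds <- function(L, n_exons) {
  cuts <- round(seq(0, L, length.out = n_exons + 1L))
  data.frame(exon = seq_len(n_exons),
             codon_start = as.integer(cuts[-(n_exons + 1L)]),
             codon_end = as.integer(cuts[-1L]))
}

NON_STOP_CODONS <- setdiff(apply(expand.grid(c("A", "C", "G", "T"),
                                             c("A", "C", "G", "T"),
                                             c("A", "C", "G", "T")),
                                 1L, paste, collapse = ""),
                           c("TAA", "TAG", "TGA"))

#' Render codon alignments carrying an implanted mutation set
#'
#' Generates a random reference CDS (no internal stop, terminal `TAA`) and,
#' for each species in the mutation table, a query alignment carrying exactly
#' the listed lesions: premature stops substitute the codon, frameshifts
#' insert or delete a single base within the codon, splice-site mutations
#' corrupt the recorded donor/acceptor dinucleotide, and exon deletions gap
#' the whole exon.  The output round-trips through [detect_mutations()].
#'
#' @param mutations data frame as from [simulate_gene()] (one gene);
#'   `detail` is required for splice-site lesions.
#' @param cds_len codons.
#' @param n_exons exons (bounds as in the generator).
#' @param gene_id identifier stamped on the fixtures.
#' @param species character vector of species to render; defaults to those in
#'   `mutations` (species without mutations get an identity alignment).
#' @param seed integer seed.
#' @return named list of [coding_alignment()] objects, one per species.
#' @export
emit_alignments <- function(mutations, cds_len, n_exons = 8,
                            gene_id = "g1", species = NULL, seed = 1) {
  set.seed(.substream(seed, 23L))
  L <- cds_len
  eb <- .default_exon_bounds(L, n_exons)
  ref_codons <- c(sample(NON_STOP_CODONS, L - 1L, replace = TRUE), "TAA")
  ref <- paste(ref_codons, collapse = "")
  if (is.null(species)) species <- sort(unique(mutations$species_id))
  lapply(stats::setNames(species, species), function(s) {
    mu <- mutations[mutations$species_id == s, , drop = FALSE]
    if (anyDuplicated(mu$codon_start)) {
      # overlapping lesions cannot coexist in one alignment: re-draw colliding
      # point mutations onto unused codons (structural lesions keep their
      # anchors; a structural duplicate is dropped)
      point_kind <- mu$kind %in% c("frameshift_insertion", "frameshift_deletion",
                                   "premature_stop")
      pool <- setdiff(0:(cds_len - 2L), mu$codon_start)
      dup <- which(duplicated(mu$codon_start))
      moved <- 0L; dropped <- integer(0)
      for (d in dup) {
        if (point_kind[d] && length(pool)) {
          c0 <- if (length(pool) == 1L) pool else sample(pool, 1L)
          pool <- setdiff(pool, c0)
          mu$codon_start[d] <- c0
          mu$codon_end[d] <- c0 + 1L
          moved <- moved + 1L
        } else dropped <- c(dropped, d)
      }
      if (length(dropped)) mu <- mu[-dropped, , drop = FALSE]
      message(sprintf("species %s: re-drew %d and dropped %d overlapping lesion(s)",
                      s, moved, length(dropped)))
    }
    rc <- strsplit(ref, "")[[1]]
    qc <- rc
    ss <- data.frame(boundary = seq_len(n_exons - 1L),
                     donor = rep("GT", n_exons - 1L),
                     acceptor = rep("AG", n_exons - 1L))
    ins_after <- rep("", length(rc))   # query bases inserted after column i
    for (i in seq_len(nrow(mu))) {
      k <- mu$kind[i]; c0 <- mu$codon_start[i]
      cols <- (3L * c0 + 1L):(3L * c0 + 3L)
      if (k == "premature_stop") {
        qc[cols] <- c("T", "G", "A")
      } else if (k == "frameshift_deletion") {
        qc[cols[1L]] <- "-"
      } else if (k == "frameshift_insertion") {
        ins_after[cols[1L]] <- "A"
      } else if (k == "splice_site") {
        parts <- strsplit(mu$detail[i], ":")[[1]]
        b <- as.integer(parts[1])
        if (parts[2] == "donor") ss$donor[b] <- "CT" else ss$acceptor[b] <- "AA"
      } else if (k == "exon_deletion") {
        ex <- which(eb$codon_start == c0)
        dcols <- (3L * eb$codon_start[ex] + 1L):(3L * eb$codon_end[ex])
        qc[dcols] <- "-"
      } else if (k == "gene_deletion") {
        qc[] <- "-"
      }
    }
    ref_out <- character(0); qry_out <- character(0)
    for (j in seq_along(rc)) {
      ref_out <- c(ref_out, rc[j])
      qry_out <- c(qry_out, qc[j])
      if (nzchar(ins_after[j])) {
        ref_out <- c(ref_out, "-")
        qry_out <- c(qry_out, ins_after[j])
      }
    }
    aln <- coding_alignment(gene_id, s, paste(ref_out, collapse = ""),
                            paste(qry_out, collapse = ""),
                            exon_bounds = eb, splice_sites = ss)
    attr(aln, "mutations") <- mu      # realized set after collision re-draws
    aln
  })
}

#' Simulate a complete forward-genomics benchmark data set
#'
#' Orchestrates the generator: species tree, foreground lineages and
#' acuities, per-gene mutation histories (the first `n_associated` gene ids
#' are the associated ones), the \%intact matrix derived from the implanted
#' lesions, and random missingness.
#'
#' @param cfg a [sim_config()].
#' @return list of class `sim_truth` with elements `tree`, `assignment`,
#'   `acuity`, `matrix` (\%intact, `NA` = missing), `mutations` (per-gene
#'   list), `associated_genes`, `lambda_fg` (realized rate), `config`.
#' @export
simulate_screen_data <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  tree <- simulate_tree(cfg$n_species, cfg$birth_rate, cfg$seed)
  ph <- assign_phenotype(tree, cfg$n_fg_lineages, cfg$va_fg, cfg$va_bg,
                         cfg$max_lineage_size, cfg$min_stem_frac, cfg$seed)
  lambda_fg <- cfg$lambda_fg
  if (is.null(lambda_fg))
    lambda_fg <- calibrate_lambda_fg(tree, ph$assignment$lineages,
                                     cfg$fg_loss_prob, cfg$loss_thr)
  cfg2 <- cfg; cfg2$lambda_fg <- lambda_fg
  genes <- sprintf("g%04d", seq_len(cfg$n_genes))
  associated <- genes[seq_len(cfg$n_associated)]
  L <- cfg$cds_len
  set.seed(.substream(cfg$seed, 99L))
  miss <- matrix(stats::runif(cfg$n_genes * cfg$n_species) < cfg$miss_rate,
                 nrow = cfg$n_genes,
                 dimnames = list(genes, tree$tip.label))
  mutations <- vector("list", cfg$n_genes)
  names(mutations) <- genes
  mat <- matrix(NA_real_, cfg$n_genes, cfg$n_species,
                dimnames = list(genes, tree$tip.label))
  for (gi in seq_len(cfg$n_genes)) {
    mu <- simulate_gene(tree, ph$assignment, genes[gi] %in% associated,
                        cfg2, seed = .substream(cfg$seed, 1000L + gi))
    mutations[[gi]] <- mu
    vals <- stats::setNames(rep(100, cfg$n_species), tree$tip.label)
    if (nrow(mu)) {
      for (s in unique(mu$species_id))
        vals[s] <- percent_intact(mu[mu$species_id == s, , drop = FALSE], L)
    }
    vals[miss[gi, ]] <- NA_real_
    mat[gi, ] <- vals
  }
  structure(list(tree = tree, assignment = ph$assignment, acuity = ph$acuity,
                 matrix = mat, mutations = mutations,
                 associated_genes = associated, lambda_fg = lambda_fg,
                 config = cfg),
            class = "sim_truth")
}

#' @export
print.sim_truth <- function(x, ...) {
  cat(sprintf("<sim_truth> %d species, %d foreground lineage(s), %d genes (%d associated), lambda_fg = %.3g\n",
              length(x$tree$tip.label), length(x$assignment$lineages),
              nrow(x$matrix), length(x$associated_genes), x$lambda_fg))
  invisible(x)
}
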