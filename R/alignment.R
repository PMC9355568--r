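#' Construct a codon-aware pairwise coding alignment
#'
#' Bundles a reference coding sequence and a query sequence aligned to it
#' codon-wise, together with the exon structure of the reference, the splice
#' dinucleotides observed in the query, and an assembly-presence mask.  This is
#' the unit of input for [detect_mutations()].
#'
#' The two aligned strings must have equal length; `-` in the reference marks
#' an insertion in the query, `-` in the query marks a deletion.  The ungapped
#' reference must be a whole number of codons, contain exactly one stop codon,
#' and that stop must be the terminal codon.
#'
#' @param gene_id,species_id identifiers.
#' @param ref_aln,qry_aln aligned nucleotide strings (single character values)
#'   over `A,C,G,T,-`.
#' @param exon_bounds data frame with columns `codon_start`, `codon_end`
#'   (0-based, half-open, codon units); intervals must be disjoint, sorted and
#'   tile `[0, L)` where `L` is the reference codon count.
#' @param splice_sites optional data frame with columns `boundary` (1-based
#'   index of the internal exon boundary, i.e. boundary `i` sits between exon
#'   `i` and exon `i+1`), `donor`, `acceptor` (dinucleotides observed in the
#'   query; `NA` when the intron is not sequenced).  Defaults to all-canonical
#'   sites.
#' @param present_mask logical vector of length `L`; `FALSE` marks codons not
#'   covered by assembly sequence.  Defaults to all present.
#' @return an object of class `coding_alignment`.
#' @seealso [detect_mutations()], [percent_intact()], [emit_alignments()]
#' @export
coding_alignment <- function(gene_id, species_id, ref_aln, qry_aln,
                             exon_bounds, splice_sites = NULL,
                             present_mask = NULL) {
  stopifnot(is.character(ref_aln), length(ref_aln) == 1L,
            is.character(qry_aln), length(qry_aln) == 1L)
  rc <- strsplit(toupper(ref_aln), "")[[1]]
  qc <- strsplit(toupper(qry_aln), "")[[1]]
  if (length(rc) != length(qc))
    stop(sprintf("malformed alignment for gene '%s', species '%s': aligned lengths differ (%d vs %d)",
                 gene_id, species_id, length(rc), length(qc)))
  n_ref <- sum(rc != "-")
  if (n_ref == 0L || n_ref %% 3L != 0L)
    stop(sprintf("malformed alignment for gene '%s', species '%s': reference length %d is not a whole codon count",
                 gene_id, species_id, n_ref))
  L <- n_ref %/% 3L
  ref_cds <- paste(rc[rc != "-"], collapse = "")
  cod <- substring(ref_cds, seq(1L, n_ref, 3L), seq(3L, n_ref, 3L))
  stops <- cod %in% c("TAA", "TAG", "TGA")
  if (sum(stops) != 1L || !stops[L])
    stop(sprintf("reference for gene '%s' must contain exactly one stop codon, at the terminal position",
                 gene_id))
  exon_bounds <- as.data.frame(exon_bounds)
  stopifnot(all(c("codon_start", "codon_end") %in% names(exon_bounds)))
  eb <- exon_bounds[order(exon_bounds$codon_start), , drop = FALSE]
  if (eb$codon_start[1L] != 0L || eb$codon_end[nrow(eb)] != L ||
      (nrow(eb) > 1L && any(eb$codon_start[-1L] != eb$codon_end[-nrow(eb)])))
    stop(sprintf("exon bounds for gene '%s' must tile [0, %d)", gene_id, L))
  if (is.null(present_mask)) present_mask <- rep(TRUE, L)
  stopifnot(is.logical(present_mask), length(present_mask) == L)
  if (is.null(splice_sites)) {
    nb <- nrow(eb) - 1L
    splice_sites <- data.frame(boundary = seq_len(nb),
                               donor = rep("GT", nb),
                               acceptor = rep("AG", nb))
  }
  structure(list(gene_id = gene_id, species_id = species_id,
                 ref = rc, qry = qc, L = L,
                 exon_bounds = eb, splice_sites = as.data.frame(splice_sites),
                 present_mask = present_mask),
            class = "coding_alignment")
}

#' @export
print.coding_alignment <- function(x, ...) {
  cat(sprintf("<coding_alignment> gene %s, species %s: %d codons, %d exon(s), %.0f%% present\n",
              x$gene_id, x$species_id, x$L, nrow(x$exon_bounds),
              100 * mean(x$present_mask)))
  invisible(x)
}

STOP_CODONS <- c("TAA", "TAG", "TGA")
MUTATION_KINDS <- c("frameshift_insertion", "frameshift_deletion",
                    "premature_stop", "splice_site", "exon_deletion",
                    "gene_deletion")

# codon index (0-based) of each alignment column: columns with a reference
# base get that base's codon; insertion columns inherit the codon of the next
# reference base (or the last codon at the alignment's 3' end).
.column_codons <- function(ref_chars) {
  pos <- cumsum(ref_chars != "-")           # 1-based ref coordinate, 0 before first base
  cod <- (pos - 1L) %/% 3L
  gap <- ref_chars == "-"
  if (any(gap)) {
    L <- max(pos) %/% 3L
    cod[gap] <- pmin(pos[gap] %/% 3L, L - 1L)
  }
  cod
}

#' Detect gene-inactivating mutations in a coding alignment
#'
#' Scans a codon-aware pairwise alignment for the lesion classes that
#' inactivate a reading frame: frameshifting insertions and deletions
#' (net indel length within a contiguous gap run not a multiple of 3),
#' premature in-frame stop codons, non-canonical splice-site dinucleotides,
#' and deletions of whole exons or of the entire gene.  Codons flagged as
#' absent from the assembly (`present_mask`) are never called.
#'
#' @param aln a [coding_alignment()].
#' @param gc_donor tolerate `GC` as a donor dinucleotide (default `TRUE`);
#'   `GT` donors and `AG` acceptors are always canonical.
#' @return a data frame with columns `gene_id`, `species_id`, `kind`,
#'   `codon_start`, `codon_end` (0-based, half-open, codon units), sorted by
#'   `codon_start`.  Zero rows when the query frame is clean.
#' @export
detect_mutations <- function(aln, gc_donor = TRUE) {
  stopifnot(inherits(aln, "coding_alignment"))
  rc <- aln$ref; qc <- aln$qry; L <- aln$L
  col_cod <- .column_codons(rc)
  absent <- !aln$present_mask

  ev <- list()
  add <- function(kind, s, e) {
    ev[[length(ev) + 1L]] <<- data.frame(kind = kind, codon_start = s,
                                         codon_end = e)
  }

  eb <- aln$exon_bounds
  n_ex <- nrow(eb)
  exon_cols <- lapply(seq_len(n_ex), function(i)
    which(col_cod >= eb$codon_start[i] & col_cod < eb$codon_end[i] & rc != "-"))
  exon_present <- vapply(seq_len(n_ex), function(i)
    all(aln$present_mask[(eb$codon_start[i] + 1L):eb$codon_end[i]]), logical(1))
  exon_deleted <- vapply(seq_len(n_ex), function(i)
    exon_present[i] && all(qc[exon_cols[[i]]] == "-"), logical(1))

  if (all(exon_deleted)) {
    add("gene_deletion", 0L, L)
  } else {
    for (i in which(exon_deleted))
      add("exon_deletion", eb$codon_start[i], eb$codon_end[i])
  }

  deleted_codons <- rep(FALSE, L)
  for (i in which(exon_deleted))
    deleted_codons[(eb$codon_start[i] + 1L):eb$codon_end[i]] <- TRUE

  # --- indels: maximal runs of columns gapped in either sequence ------------
  is_gap <- rc == "-" | qc == "-"
  # ignore gap columns that sit in deleted exons or absent codons
  is_gap[is_gap & (deleted_codons[col_cod + 1L] | absent[col_cod + 1L])] <- FALSE
  if (any(is_gap)) {
    r <- rle(is_gap)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (j in which(r$values)) {
      idx <- starts[j]:ends[j]
      ins <- sum(rc[idx] == "-")
      del <- sum(qc[idx] == "-" & rc[idx] != "-")
      net <- ins - del
      if (net %% 3L != 0L) {
        kind <- if (net > 0L) "frameshift_insertion" else "frameshift_deletion"
        c0 <- col_cod[idx[1L]]
        add(kind, c0, c0 + 1L)
      }
    }
  }

  # --- premature stops (codon-aligned triplets) -----------------------------
  base_cols <- which(rc != "-")
  for (c0 in 0:(L - 2L)) {
    if (absent[c0 + 1L] || deleted_codons[c0 + 1L]) next
    cols <- base_cols[(3L * c0 + 1L):(3L * c0 + 3L)]
    q3 <- qc[cols]
    if (any(q3 == "-")) next
    if (paste(q3, collapse = "") %in% STOP_CODONS)
      add("premature_stop", c0, c0 + 1L)
  }

  # --- splice sites ---------------------------------------------------------
  ss <- aln$splice_sites
  donors <- if (gc_donor) c("GT", "GC") else "GT"
  if (!is.null(ss) && nrow(ss)) {
    for (j in seq_len(nrow(ss))) {
      b <- ss$boundary[j]
      up <- b; down <- b + 1L          # exon indices flanking boundary b
      if (exon_deleted[up] || exon_deleted[down]) next
      don <- toupper(ss$donor[j]); acc <- toupper(ss$acceptor[j])
      if (!is.na(don) && !(don %in% donors)) {
        c0 <- eb$codon_end[up] - 1L
        if (!absent[c0 + 1L]) add("splice_site", c0, c0 + 1L)
      }
      if (!is.na(acc) && acc != "AG") {
        c0 <- eb$codon_start[down]
        if (!absent[c0 + 1L]) add("splice_site", c0, c0 + 1L)
      }
    }
  }

  out <- if (length(ev)) do.call(rbind, ev) else
    data.frame(kind = character(), codon_start = integer(),
               codon_end = integer())
  out <- data.frame(gene_id = rep(aln$gene_id, nrow(out)),
                    species_id = rep(aln$species_id, nrow(out)),
                    out, stringsAsFactors = FALSE)
  out <- out[order(out$codon_start, out$kind), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Maximum percent of the reading frame that remains intact
#'
#' The per-gene, per-species statistic of the screen.  Every mutation span and
#' every maximal run of assembly-absent codons breaks the reading frame; the
#' statistic is 100 times the longest remaining contiguous stretch of clean,
#' present codons divided by the total codon count.  A mutation-free, fully
#' present gene scores 100; a whole-gene deletion scores 0.
#'
#' @param muts data frame of mutations for one (gene, species) as returned by
#'   [detect_mutations()] (columns `codon_start`, `codon_end` used).
#' @param L reference codon count (> 0).
#' @param present_mask logical vector of length `L`, or `NULL` for all present.
#' @return a single value in `[0, 100]`.
#' @export
percent_intact <- function(muts, L, present_mask = NULL) {
  stopifnot(L > 0)
  if (is.null(present_mask)) present_mask <- rep(TRUE, L)
  stopifnot(length(present_mask) == L)
  broken <- !present_mask
  if (!is.null(muts) && nrow(muts)) {
    if (any(muts$codon_start < 0 | muts$codon_end > L |
            muts$codon_start >= muts$codon_end))
      stop("mutation coordinates outside [0, L)")
    for (i in seq_len(nrow(muts)))
      broken[(muts$codon_start[i] + 1L):muts$codon_end[i]] <- TRUE
  }
  if (!any(broken)) return(100)
  if (all(broken)) return(0)
  r <- rle(broken)
  100 * max(r$lengths[!r$values]) / L
}

#' Classify per-species gene status from intactness and assembly presence
#'
#' A gene is `missing` when less than `missing_thr` of its coding sequence is
#' present in the assembly; otherwise `lost` when \%intact falls below
#' `loss_thr`, `intact` when it reaches `intact_thr`, and `uncertain` in
#' between.
#'
#' @param percent_intact numeric vector in `[0, 100]`.
#' @param present_fraction numeric vector in `[0, 1]`.
#' @param loss_thr,intact_thr \%intact thresholds (defaults 60 and 90).
#' @param missing_thr present-fraction threshold (default 0.5).
#' @return character vector over `intact`, `lost`, `uncertain`, `missing`.
#' @export
classify_status <- function(percent_intact, present_fraction,
                            loss_thr = 60, intact_thr = 90,
                            missing_thr = 0.5) {
  stopifnot(loss_thr >= 0, loss_thr <= intact_thr, intact_thr <= 100,
            missing_thr >= 0, missing_thr <= 1)
  stopifnot(all(is.na(percent_intact) | (percent_intact >= 0 & percent_intact <= 100)),
            all(is.na(present_fraction) | (present_fraction >= 0 & present_fraction <= 1)))
  out <- ifelse(present_fraction < missing_thr, "missing",
         ifelse(percent_intact < loss_thr, "lost",
         ifelse(percent_intact >= intact_thr, "intact", "uncertain")))
  out[is.na(percent_intact) | is.na(present_fraction)] <- "missing"
  out
}

#' Transcript-level classification on the central 80\% of the CDS
#'
#' Mirrors orthology-annotation practice: a transcript is `missing` when less
#' than half of its coding sequence is present in the assembly,
#' `potentially_lost` when at least one inactivating mutation overlaps the
#' central 80\% of the codons, and `intact` otherwise.  Mutations confined to
#' the outer 10\% at either terminus do not condemn a transcript.
#'
#' @param aln a [coding_alignment()].
#' @param gc_donor passed to [detect_mutations()].
#' @return one of `"intact"`, `"potentially_lost"`, `"missing"`.
#' @export
classify_transcript_central80 <- function(aln, gc_donor = TRUE) {
  stopifnot(inherits(aln, "coding_alignment"))
  if (mean(aln$present_mask) < 0.5) return("missing")
  muts <- detect_mutations(aln, gc_donor = gc_donor)
  lo <- ceiling(0.1 * aln$L)
  hi <- floor(0.9 * aln$L)
  if (nrow(muts) && any(muts$codon_start < hi & muts$codon_end > lo))
    "potentially_lost" else "intact"
}
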