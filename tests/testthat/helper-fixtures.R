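# shared fixture builders and independent oracles

# build a coding_alignment from explicit codon vectors (one string per codon,
# "-" gaps allowed); splice sites default canonical
make_aln <- function(ref_codons, qry_codons = ref_codons, n_exons = 1,
                     splice = NULL, present = NULL, gene = "g", sp = "s") {
  L <- length(ref_codons)
  cuts <- round(seq(0, L, length.out = n_exons + 1))
  eb <- data.frame(codon_start = cuts[-(n_exons + 1)], codon_end = cuts[-1])
  coding_alignment(gene, sp, paste(ref_codons, collapse = ""),
                   paste(qry_codons, collapse = ""),
                   exon_bounds = eb, splice_sites = splice,
                   present_mask = present)
}

# random non-stop codons with terminal TAA
random_cds <- function(L) {
  pool <- apply(expand.grid(c("A","C","G","T"), c("A","C","G","T"),
                            c("A","C","G","T")), 1, paste, collapse = "")
  pool <- setdiff(pool, c("TAA", "TAG", "TGA"))
  c(sample(pool, L - 1, replace = TRUE), "TAA")
}

# brute-force Dollo oracle: minimum loss events over all internal labelings
# (root state free, +1 charged when the root itself starts lost); missing
# leaves may take either state; no lost -> intact edge allowed
dollo_brute <- function(tree, statuses) {
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  st <- rep(NA_integer_, nnode)            # 1 = lost, 0 = intact
  lv <- statuses[tree$tip.label]
  st[seq_len(ntip)][lv == "lost"] <- 1L
  st[seq_len(ntip)][lv == "intact"] <- 0L
  free <- which(is.na(st))                 # internals + missing leaves
  best <- Inf
  for (mask in 0:(2^length(free) - 1)) {
    s <- st
    s[free] <- bitwAnd(mask %/% 2^(seq_along(free) - 1L), 1L)
    ok <- TRUE; cost <- s[ntip + 1L]       # root lost costs the stem event
    for (e in seq_len(nrow(tree$edge))) {
      a <- s[tree$edge[e, 1L]]; b <- s[tree$edge[e, 2L]]
      if (a == 1L && b == 0L) { ok <- FALSE; break }
      if (a == 0L && b == 1L) cost <- cost + 1L
    }
    if (ok && cost < best) best <- cost
  }
  best
}

# direct step-up BH oracle
bh_direct <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  pmin(q, 1)[order(o)]
}

# hypergeometric upper-tail oracle by direct summation of choose() terms
hyper_tail <- function(k, K, n, N) {
  i <- k:min(K, n)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}
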