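set.seed(421)

test_that("an identical query yields no mutations and full intactness", {
  ref <- random_cds(100)
  aln <- make_aln(ref, n_exons = 4)
  muts <- detect_mutations(aln)
  expect_equal(nrow(muts), 0)
  expect_equal(percent_intact(muts, 100), 100)
  expect_equal(classify_status(100, 1), "intact")
  expect_equal(classify_transcript_central80(aln), "intact")
})

test_that("frameshift and premature stop are detected at their codons", {
  ref <- random_cds(300)
  qry <- ref
  # 2-nt deletion inside codon 50 (0-based)
  qry[51] <- paste0(substr(qry[51], 1, 1), "--")
  qry[121] <- "TGA"
  aln <- make_aln(ref, qry)
  muts <- detect_mutations(aln)
  expect_equal(muts$kind, c("frameshift_deletion", "premature_stop"))
  expect_equal(muts$codon_start, c(50L, 120L))
  expect_equal(muts$codon_end, c(51L, 121L))
})

test_that("in-frame indels are not frameshifts; net length decides", {
  ref <- random_cds(60)
  qry <- ref
  qry[11] <- "---"                       # whole-codon deletion: net -3
  aln <- make_aln(ref, qry)
  expect_equal(nrow(detect_mutations(aln)), 0)
  qry2 <- ref
  qry2[11] <- "---"; qry2[12] <- paste0("-", substr(ref[12], 2, 3))  # net -4
  muts <- detect_mutations(make_aln(ref, qry2))
  expect_equal(muts$kind, "frameshift_deletion")
  expect_equal(muts$codon_start, 10L)
})

test_that("splice-site dinucleotides follow the configured dialect", {
  ref <- random_cds(80)
  sp <- data.frame(boundary = 1:3, donor = c("GT", "GC", "CT"),
                   acceptor = c("AG", "AG", "AG"))
  aln <- make_aln(ref, n_exons = 4, splice = sp)
  muts <- detect_mutations(aln)                    # GC tolerated by default
  expect_equal(muts$kind, "splice_site")
  expect_equal(muts$codon_start, 59L)              # last codon of exon 3
  muts2 <- detect_mutations(aln, gc_donor = FALSE)
  expect_equal(sort(muts2$codon_start), c(39L, 59L))
  # acceptor mutation anchors at the downstream exon's first codon
  sp3 <- data.frame(boundary = 1:3, donor = "GT", acceptor = c("AA", "AG", "AG"))
  muts3 <- detect_mutations(make_aln(ref, n_exons = 4, splice = sp3))
  expect_equal(muts3$codon_start, 20L)
})

test_that("exon and gene deletions are distinguished", {
  ref <- random_cds(80)
  qry <- ref
  qry[1:20] <- "---"                     # exon 1 of 4 gone
  muts <- detect_mutations(make_aln(ref, qry, n_exons = 4))
  expect_true("exon_deletion" %in% muts$kind)
  ed <- muts[muts$kind == "exon_deletion", ]
  expect_equal(c(ed$codon_start, ed$codon_end), c(0L, 20L))
  qry2 <- rep("---", 80)
  muts2 <- detect_mutations(make_aln(ref, qry2, n_exons = 4))
  expect_equal(muts2$kind, "gene_deletion")
  expect_equal(percent_intact(muts2, 80), 0)
})

test_that("assembly-absent codons are never called and reduce intact runs", {
  ref <- random_cds(100)
  qry <- ref
  qry[31] <- "TGA"                       # inside absent region: must not call
  present <- rep(TRUE, 100); present[21:40] <- FALSE
  aln <- make_aln(ref, qry, present = present)
  muts <- detect_mutations(aln)
  expect_equal(nrow(muts), 0)
  # absent run still breaks the intact stretch
  expect_equal(percent_intact(muts, 100, present), 60)
  expect_equal(classify_status(60, 0.8), "uncertain")
  expect_equal(classify_status(60, 0.4), "missing")
})

test_that("percent_intact follows the longest-clean-stretch convention", {
  two <- data.frame(codon_start = c(200L, 700L), codon_end = c(201L, 701L))
  expect_equal(percent_intact(two, 1000), 49.9)
  one_mid <- data.frame(codon_start = 500L, codon_end = 501L)
  expect_equal(percent_intact(one_mid, 1000), 50)
  expect_equal(percent_intact(NULL, 100), 100)
  expect_error(percent_intact(data.frame(codon_start = 90L, codon_end = 120L),
                              100), "outside")
})

test_that("percent_intact is monotone non-increasing under lesion addition", {
  for (rep in 1:40) {
    L <- sample(50:400, 1)
    k <- sample(0:6, 1)
    pos <- sort(sample(0:(L - 1), k))
    muts <- data.frame(codon_start = pos, codon_end = pos + 1L)
    pi0 <- percent_intact(muts, L)
    expect_gte(pi0, 0); expect_lte(pi0, 100)
    extra <- sample(0:(L - 1), 1)
    muts2 <- rbind(muts, data.frame(codon_start = extra, codon_end = extra + 1L))
    expect_lte(percent_intact(muts2, L), pi0)
  }
})

test_that("status thresholds use the documented boundary semantics", {
  expect_equal(classify_status(95, 1.0), "intact")
  expect_equal(classify_status(90, 1.0), "intact")     # >= 90
  expect_equal(classify_status(89.9, 1.0), "uncertain")
  expect_equal(classify_status(60, 1.0), "uncertain")
  expect_equal(classify_status(59.9, 1.0), "lost")     # < 60
  expect_equal(classify_status(99, 0.4), "missing")    # < 0.5 present
  expect_equal(classify_status(99, 0.5), "intact")
  expect_equal(classify_status(c(95, 10), c(1, 1)), c("intact", "lost"))
  expect_error(classify_status(101, 1))
  expect_error(classify_status(50, 1, loss_thr = 95, intact_thr = 90))
})

test_that("central-80% transcript classification ignores terminal lesions", {
  ref <- random_cds(300)
  qry <- ref; qry[151] <- "TGA"
  expect_equal(classify_transcript_central80(make_aln(ref, qry)),
               "potentially_lost")
  qry2 <- ref; qry2[3] <- "TGA"          # codon 2 < 0.1 * 300
  expect_equal(classify_transcript_central80(make_aln(ref, qry2)), "intact")
  qry3 <- ref; qry3[300 - 5] <- "TGA"    # codon 294 >= 0.9 * 300 = 270
  expect_equal(classify_transcript_central80(make_aln(ref, qry3)), "intact")
  present <- c(rep(FALSE, 160), rep(TRUE, 140))
  expect_equal(classify_transcript_central80(make_aln(ref, present = present)),
               "missing")
})

test_that("malformed alignments are rejected with gene and species named", {
  expect_error(coding_alignment("gX", "spY", "ATGTAA", "ATG"), "gX")
  expect_error(coding_alignment("gX", "spY", "ATGC", "ATGC"),
               "whole codon count")
  ref <- random_cds(10); ref[5] <- "TAA"     # internal stop
  expect_error(make_aln(ref), "exactly one stop")
})

test_that("implanted mutation sets round-trip through emission and detection", {
  cfg <- sim_config(n_species = 8, n_fg_lineages = 2, n_genes = 1,
                    n_associated = 1, lambda_fg = 6, lambda_bg = 0.5,
                    cds_len = 150, n_exons = 4, seed = 5)
  tree <- simulate_tree(8, 1, 5)
  ph <- assign_phenotype(tree, 2, seed = 5)
  for (s in 1:20) {
    mu <- simulate_gene(tree, ph$assignment, TRUE, cfg, seed = 7000 + s)
    if (!nrow(mu)) next
    alns <- emit_alignments(mu, cds_len = 150, n_exons = 4, seed = 7000 + s)
    for (sp in names(alns)) {
      implanted <- attr(alns[[sp]], "mutations")
      got <- detect_mutations(alns[[sp]])
      expect_equal(got$kind[order(got$codon_start)],
                   implanted$kind[order(implanted$codon_start)])
      expect_equal(sort(got$codon_start), sort(implanted$codon_start))
    }
  }
})
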