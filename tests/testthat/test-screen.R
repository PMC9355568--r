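set.seed(77)

make_assignment <- function(species, fg, tree = NULL) {
  lab <- stats::setNames(ifelse(species %in% fg, "foreground", "background"),
                         species)
  lin <- if (!is.null(tree)) partition_lineages(tree, fg) else NULL
  phenotype_assignment(lab, lin)
}

test_that("gene filtering drops untestable and constant genes, keeps order", {
  sp <- sprintf("s%d", 1:10)
  fg <- sp[1:4]
  m <- matrix(runif(50, 0, 100), 5, 10, dimnames = list(sprintf("g%d", 1:5), sp))
  m["g2", sp[1:3]] <- NA                # missing in 3 of 4 foreground
  m["g4", ] <- 100                      # constant
  m["g5", ] <- c(NA, 77, NA, 77, 77, NA, 77, 77, NA, 77)  # constant after NA
  out <- filter_genes(m, make_assignment(sp, fg))
  expect_equal(rownames(out), c("g1", "g3"))
  m2 <- m[c("g4", "g5"), ]
  expect_warning(out2 <- filter_genes(m2, make_assignment(sp, fg)), "no genes")
  expect_equal(nrow(out2), 0)
  expect_error(filter_genes(m[, 1:9], make_assignment(sp[1:8], fg)), "s9")
})

test_that("PGLS matches the closed-form GLS solution on small trees", {
  for (nw in c("((A:1,B:1):1,(C:1,D:1):1);",
               "(((A:1,B:2):1,(C:1.5,D:0.5):2):1,(E:3,F:1):1);")) {
    tr <- ape::read.tree(text = nw)
    sp <- tr$tip.label
    set.seed(nchar(nw))
    y <- stats::setNames(rnorm(length(sp), 50, 20), sp)
    x <- stats::setNames(as.numeric(seq_along(sp) <= 2), sp)
    fit <- pgls_fit(y, x, tr)
    V <- ape::vcv(tr)[sp, sp]
    X <- cbind(1, x)
    Vi <- solve(V)
    beta <- solve(t(X) %*% Vi %*% X) %*% t(X) %*% Vi %*% y
    expect_equal(fit$slope, unname(beta[2]), tolerance = 1e-10)
    r <- y - X %*% beta
    s2 <- as.numeric(t(r) %*% Vi %*% r) / (length(sp) - 2)
    se <- sqrt(s2 * solve(t(X) %*% Vi %*% X)[2, 2])
    expect_equal(fit$t_stat, unname(beta[2] / se), tolerance = 1e-10)
    expect_equal(fit$p_value, stats::pt(fit$t_stat, length(sp) - 2),
                 tolerance = 1e-12)
  }
})

test_that("PGLS agrees with an independent GLS implementation", {
  skip_if_not_installed("nlme")
  # ultrametric tree: corBrownian models the correlation only, so tip
  # variances must be equal for the two formulations to coincide
  tr <- ape::read.tree(text = "(((A:1,B:1):1,(C:1.5,D:1.5):0.5):1,(E:2,F:2):1);")
  sp <- tr$tip.label
  set.seed(5)
  dat <- data.frame(y = rnorm(6, 50, 15), x = c(1, 1, 0, 0, 0, 0),
                    species = sp)
  g <- nlme::gls(y ~ x, data = dat,
                 correlation = ape::corBrownian(phy = tr, form = ~species))
  fit <- pgls_fit(stats::setNames(dat$y, sp), stats::setNames(dat$x, sp), tr)
  expect_equal(fit$slope, unname(coef(g)["x"]), tolerance = 1e-8)
  expect_equal(fit$t_stat, unname(summary(g)$tTable["x", "t-value"]),
               tolerance = 1e-6)
})

test_that("on a star tree PGLS collapses to ordinary least squares", {
  star <- ape::read.tree(text = "(A:2,B:2,C:2,D:2,E:2,F:2,G:2,H:2);")
  sp <- star$tip.label
  set.seed(9)
  y <- stats::setNames(rnorm(8, 60, 25), sp)
  x <- stats::setNames(rep(c(1, 0), each = 4), sp)
  fit <- pgls_fit(y, x, star)
  ols <- summary(stats::lm(y ~ x))
  expect_equal(fit$slope, unname(coef(ols)[2, 1]), tolerance = 1e-10)
  expect_equal(fit$t_stat, unname(coef(ols)[2, 3]), tolerance = 1e-10)
  expect_equal(fit$p_value, stats::pt(unname(coef(ols)[2, 3]), 6),
               tolerance = 1e-12)
})

test_that("degenerate responses yield p = 1, not an exception", {
  tr <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
  y <- stats::setNames(rep(100, 4), tr$tip.label)
  x <- stats::setNames(c(1, 1, 0, 0), tr$tip.label)
  fit <- pgls_fit(y, x, tr)
  expect_true(fit$degenerate)
  expect_equal(fit$p_value, 1)
  expect_error(pgls_fit(y[1:2], x, tr), "at least 3")
  expect_error(pgls_fit(y, stats::setNames(rep(1, 4), names(x)), tr),
               "single class")
})

test_that("BH adjustment matches the direct step-up formula", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.04)), c(0.03, 0.03, 0.04))
  expect_equal(bh_adjust(0.37), 0.37)
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(31)
  for (i in 1:20) {
    p <- runif(sample(1:50, 1))
    q <- bh_adjust(p)
    expect_equal(q, bh_direct(p), tolerance = 1e-12)
    o <- order(p)
    expect_true(all(diff(q[o]) >= -1e-12))
  }
})

test_that("convergent losses are counted per lineage, not per species", {
  lin <- list(c("a", "b"), "c", c("d", "e"))
  st <- c(a = "lost", b = "lost", c = "intact", d = "intact", e = "intact")
  expect_equal(convergent_loss_count(st, lin), 1)
  st2 <- c(a = "lost", b = "intact", c = "lost", d = "missing", e = "lost")
  expect_equal(convergent_loss_count(st2, lin), 3)
  st3 <- c(a = "intact", b = "intact", c = "intact", d = "intact", e = "intact")
  expect_equal(convergent_loss_count(st3, lin), 0)
})

test_that("the screen is invariant to gene order and leaf order", {
  sim <- simulate_screen_data(sim_config(n_species = 16, n_fg_lineages = 3,
                                         n_genes = 40, n_associated = 4,
                                         seed = 21))
  scr <- forward_screen(sim$matrix, sim$tree, sim$assignment)
  perm_g <- sample(nrow(sim$matrix))
  perm_s <- sample(ncol(sim$matrix))
  tr2 <- ape::read.tree(text = ape::write.tree(ape::rotateConstr(
    sim$tree, rev(sim$tree$tip.label))))
  scr2 <- forward_screen(sim$matrix[perm_g, perm_s], tr2, sim$assignment)
  a <- scr$results[order(scr$results$gene_id), ]
  b <- scr2$results[order(scr2$results$gene_id), ]
  expect_equal(a$p_value, b$p_value, tolerance = 1e-9)
  expect_equal(a$candidate, b$candidate)
  expect_equal(a$n_lost_lineages, b$n_lost_lineages)
})

test_that("candidate set shrinks as fdr tightens or min_lineages rises", {
  sim <- simulate_screen_data(sim_config(n_species = 20, n_fg_lineages = 4,
                                         n_genes = 80, n_associated = 8,
                                         seed = 13))
  base <- forward_screen(sim$matrix, sim$tree, sim$assignment,
                         fdr = 0.1, min_lineages = 2)
  tight_q <- forward_screen(sim$matrix, sim$tree, sim$assignment,
                            fdr = 0.01, min_lineages = 2)
  tight_l <- forward_screen(sim$matrix, sim$tree, sim$assignment,
                            fdr = 0.1, min_lineages = 4)
  expect_true(all(candidate_genes(tight_q) %in% candidate_genes(base)))
  expect_true(all(candidate_genes(tight_l) %in% candidate_genes(base)))
})

test_that("swapping foreground and background flips the slope sign", {
  star <- ape::read.tree(text = "(A:1,B:1,C:1,D:1,E:1,F:1);")
  sp <- star$tip.label
  m <- matrix(c(20, 25, 30, 95, 90, 100), 1, 6,
              dimnames = list("g1", sp))
  fg <- sp[1:3]
  s1 <- forward_screen(m, star, make_assignment(sp, fg, star), filter = FALSE)
  s2 <- control_screen(m, star, sp[4:6], filter = FALSE)
  expect_equal(s1$results$slope, -s2$results$slope, tolerance = 1e-10)
  expect_lt(s1$results$slope, 0)
})

test_that("continuous phenotype mode accepts a numeric predictor", {
  sim <- simulate_screen_data(sim_config(n_species = 16, n_fg_lineages = 3,
                                         n_genes = 30, n_associated = 3,
                                         seed = 3))
  va <- stats::setNames(log10(pmax(sim$acuity$va, 0.01)), sim$acuity$species_id)
  scr <- forward_screen(sim$matrix, sim$tree, sim$assignment,
                        alternative = "greater", phenotype = va)
  expect_true(scr$params$continuous)
  expect_true(all(scr$results$p_value >= 0 & scr$results$p_value <= 1,
                  na.rm = TRUE))
  # associated genes: low acuity goes with low %intact => positive slope on va
  a <- scr$results[scr$results$gene_id %in% sim$associated_genes, ]
  expect_true(mean(a$slope > 0, na.rm = TRUE) > 0.5)
})

test_that("screen q-values never fall below their p-values", {
  sim <- simulate_screen_data(sim_config(n_species = 12, n_fg_lineages = 2,
                                         n_genes = 40, n_associated = 4,
                                         seed = 8))
  scr <- forward_screen(sim$matrix, sim$tree, sim$assignment)
  ok <- !is.na(scr$results$p_value)
  expect_true(all(scr$results$q_value[ok] >= scr$results$p_value[ok] - 1e-12))
})
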