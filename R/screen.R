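#' Filter the gene universe before association testing
#'
#' Drops genes whose \%intact value is missing for more than half of the
#' foreground species or more than half of the background species (assembly
#' incompleteness makes them untestable), and genes whose non-missing values
#' are all identical (they cannot associate with any phenotype).  Gene order
#' is preserved.
#'
#' @param matrix numeric genes x species matrix of \%intact values in
#'   `[0, 100]` with `NA` for missing.
#' @param assignment a [phenotype_assignment()] whose labels cover the matrix
#'   species.
#' @return the filtered matrix (possibly zero rows, with a warning).
#' @export
filter_genes <- function(matrix, assignment) {
  stopifnot(is.matrix(matrix), inherits(assignment, "phenotype_assignment"))
  sp <- colnames(matrix)
  uncovered <- setdiff(sp, names(assignment$labels))
  if (length(uncovered))
    stop("species without phenotype label: ", paste(uncovered, collapse = ", "))
  fg <- intersect(sp, foreground_species(assignment))
  bg <- intersect(sp, names(assignment$labels)[assignment$labels == "background"])
  miss_fg <- rowSums(is.na(matrix[, fg, drop = FALSE]))
  miss_bg <- rowSums(is.na(matrix[, bg, drop = FALSE]))
  too_missing <- miss_fg > 0.5 * length(fg) | miss_bg > 0.5 * length(bg)
  constant <- apply(matrix, 1L, function(v) {
    v <- v[!is.na(v)]
    length(v) == 0L || all(v == v[1L])
  })
  keep <- !too_missing & !constant
  out <- matrix[keep, , drop = FALSE]
  if (nrow(out) == 0L) warning("no genes survive filtering")
  out
}

#' Phylogenetic generalized least squares fit for one gene
#'
#' Regresses a per-species response on a predictor under a Brownian-motion
#' error covariance: `V[i, j]` is the shared root-to-tip path length of
#' species `i` and `j` on the tree pruned to the species with data.  Solved by
#' Cholesky whitening followed by ordinary least squares on the transformed
#' variables.  The reported p-value tests the slope with `n - 2` degrees of
#' freedom; the default alternative is `less` (losses depress \%intact in the
#' foreground).
#'
#' @param y named numeric response (e.g. \%intact), `NA` dropped.
#' @param x named numeric predictor (e.g. 1 = foreground, 0 = background).
#' @param tree rooted `phylo` with branch lengths; pruned to the species used.
#' @param alternative `"less"` (default), `"greater"`, or `"two.sided"`.
#' @return list with `slope`, `t_stat`, `p_value`, `n`, `df`, `degenerate`.
#'   A constant response or a singular covariance yields `p_value = 1` with
#'   `degenerate = TRUE`; fewer than 3 usable species or a single-class
#'   predictor is an error (the screen skips such genes upstream).
#' @export
pgls_fit <- function(y, x, tree,
                     alternative = c("less", "greater", "two.sided")) {
  alternative <- match.arg(alternative)
  stopifnot(!is.null(names(y)), !is.null(names(x)))
  sp <- intersect(names(y)[!is.na(y)], names(x)[!is.na(x)])
  sp <- intersect(sp, tree$tip.label)
  if (length(sp) < 3L) stop("need at least 3 species with data")
  y <- y[sp]; x <- x[sp]
  if (length(unique(x)) < 2L)
    stop("predictor has a single class among species with data")
  pruned <- if (length(sp) < length(tree$tip.label))
    ape::keep.tip(tree, sp) else tree
  V <- ape::vcv(pruned)[sp, sp]
  .pgls_core(y, x, V, alternative)
}

.pgls_core <- function(y, x, V, alternative) {
  n <- length(y)
  degen <- function() list(slope = 0, t_stat = 0, p_value = 1, n = n,
                           df = n - 2L, degenerate = TRUE)
  if (stats::var(y) == 0) return(degen())
  R <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(R)) return(degen())
  X <- cbind(intercept = 1, slope = x)
  ty <- backsolve(R, y, transpose = TRUE)
  tX <- backsolve(R, X, transpose = TRUE)
  colnames(tX) <- colnames(X)
  fit <- stats::lm.fit(tX, ty)
  if (fit$rank < 2L) return(degen())
  beta <- fit$coefficients["slope"]
  df <- n - 2L
  sigma2 <- sum(fit$residuals^2) / df
  XtX_inv <- chol2inv(fit$qr$qr[1:2, 1:2, drop = FALSE])
  se <- sqrt(sigma2 * XtX_inv[2L, 2L])
  t_stat <- unname(beta / se)
  p <- switch(alternative,
              less = stats::pt(t_stat, df),
              greater = stats::pt(t_stat, df, lower.tail = FALSE),
              two.sided = 2 * stats::pt(abs(t_stat), df, lower.tail = FALSE))
  list(slope = unname(beta), t_stat = t_stat, p_value = p, n = n, df = df,
       degenerate = FALSE)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment, order-preserving with the input.
#'
#' @param p numeric vector of p-values in `[0, 1]` (`NA` passed through).
#' @return numeric vector of q-values.
#' @export
bh_adjust <- function(p) {
  if (any(!is.na(p) & (p < 0 | p > 1))) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Count foreground lineages with at least one lost species
#'
#' @param statuses named character vector of per-species statuses for one gene
#'   (values from [classify_status()]).
#' @param lineages list of species sets from [partition_lineages()].
#' @return integer count of lineages containing a `lost` species.
#' @export
convergent_loss_count <- function(statuses, lineages) {
  sum(vapply(lineages, function(sp) {
    s <- statuses[intersect(sp, names(statuses))]
    any(s == "lost", na.rm = TRUE)
  }, logical(1)))
}

#' Forward-genomics screen for convergent gene loss
#'
#' The central fit of the package: for every gene in the (filtered) \%intact
#' matrix it regresses \%intact on the foreground indicator by phylogenetic
#' generalized least squares under a Brownian-motion covariance, adjusts the
#' per-gene p-values by Benjamini-Hochberg over the post-filter universe, and
#' flags as candidates the genes with `q < fdr` that are lost (\%intact <
#' `loss_thr`) in at least `min_lineages` independent foreground lineages.
#'
#' Species whose \%intact is missing are dropped gene-wise (the tree is pruned
#' per gene); genes for which only one phenotype class remains are skipped and
#' recorded with `NA` statistics.  A constant response after pruning yields a
#' degenerate fit with `p = 1`.
#'
#' @param matrix numeric genes x species \%intact matrix (`NA` = missing).
#' @param tree rooted `phylo`; matrix species must be tree tips.
#' @param assignment a [phenotype_assignment()]; lineages are derived from the
#'   tree when absent.
#' @param fdr candidate false-discovery-rate cutoff (default 0.05).
#' @param min_lineages minimum number of foreground lineages with a loss
#'   (default 3).
#' @param loss_thr \%intact threshold below which a species counts as lost
#'   (default 60).
#' @param alternative sidedness of the slope test, default `"less"`.
#' @param phenotype optional named numeric vector overriding the binary
#'   indicator (e.g. `log10` visual acuity for a continuous-phenotype screen);
#'   default `NULL` uses foreground = 1, background = 0, excluded dropped.
#' @param filter apply [filter_genes()] first (default `TRUE`).
#' @return an object of class `forward_screen`; see [summary.forward_screen()].
#'   Its `$results` data frame has one row per retained gene with columns
#'   `gene_id`, `n_species_used`, `slope`, `t_stat`, `p_value`, `q_value`,
#'   `n_lost_lineages`, `candidate`.
#' @examples
#' sim <- simulate_screen_data(sim_config(n_species = 20, n_fg_lineages = 3,
#'                                        n_genes = 60, n_associated = 5,
#'                                        seed = 7))
#' scr <- forward_screen(sim$matrix, sim$tree, sim$assignment)
#' summary(scr)
#' @export
forward_screen <- function(matrix, tree, assignment, fdr = 0.05,
                           min_lineages = 3, loss_thr = 60,
                           alternative = c("less", "greater", "two.sided"),
                           phenotype = NULL, filter = TRUE) {
  alternative <- match.arg(alternative)
  stopifnot(is.matrix(matrix), inherits(tree, "phylo"),
            inherits(assignment, "phenotype_assignment"),
            fdr > 0, fdr <= 1, min_lineages >= 0)
  bad <- setdiff(colnames(matrix), tree$tip.label)
  if (length(bad))
    stop("matrix species not in tree: ", paste(bad, collapse = ", "))
  n_input <- nrow(matrix)
  if (filter) matrix <- filter_genes(matrix, assignment)

  lab <- assignment$labels[colnames(matrix)]
  use_sp <- colnames(matrix)[lab %in% c("foreground", "background")]
  matrix <- matrix[, use_sp, drop = FALSE]
  x_all <- if (is.null(phenotype)) {
    stats::setNames(as.numeric(assignment$labels[use_sp] == "foreground"),
                    use_sp)
  } else {
    stopifnot(!is.null(names(phenotype)))
    phenotype[use_sp]
  }
  lineages <- assignment$lineages
  if (is.null(lineages))
    lineages <- partition_lineages(tree, intersect(foreground_species(assignment),
                                                   tree$tip.label))

  genes <- rownames(matrix)
  res <- data.frame(gene_id = genes, n_species_used = NA_integer_,
                    slope = NA_real_, t_stat = NA_real_, p_value = NA_real_,
                    q_value = NA_real_, n_lost_lineages = NA_integer_,
                    candidate = FALSE, stringsAsFactors = FALSE)
  skipped <- character(0)

  if (length(genes)) {
    # genes sharing a missingness pattern share a pruned covariance; factor
    # the Cholesky once per pattern and fit all its genes in one pass
    patt <- apply(!is.na(matrix), 1L, function(m) paste(which(m), collapse = ","))
    V_full <- ape::vcv(ape::keep.tip(tree, use_sp))[use_sp, use_sp]
    for (pt in unique(patt)) {
      idx <- which(patt == pt)
      cols <- as.integer(strsplit(pt, ",")[[1]])
      sp <- use_sp[cols]
      x <- x_all[sp]
      if (length(sp) < 3L || length(unique(x)) < 2L) {
        skipped <- c(skipped, genes[idx])
        next
      }
      V <- V_full[sp, sp]
      R <- tryCatch(chol(V), error = function(e) NULL)
      Y <- t(matrix[idx, sp, drop = FALSE])      # species x genes
      n <- length(sp); df <- n - 2L
      if (is.null(R) || df < 1L) {
        const <- rep(TRUE, length(idx))
      } else {
        tX <- backsolve(R, cbind(1, x), transpose = TRUE)
        tY <- backsolve(R, Y, transpose = TRUE)
        qrX <- qr(tX)
        coefs <- qr.coef(qrX, tY)                # 2 x genes
        resid <- tY - tX %*% coefs
        sigma2 <- colSums(resid^2) / df
        C <- chol2inv(qr.R(qrX))
        se <- sqrt(sigma2 * C[2L, 2L])
        tval <- coefs[2L, ] / se
        const <- apply(Y, 2L, function(v) stats::var(v) == 0) | !is.finite(tval)
        pval <- switch(alternative,
                       less = stats::pt(tval, df),
                       greater = stats::pt(tval, df, lower.tail = FALSE),
                       two.sided = 2 * stats::pt(abs(tval), df, lower.tail = FALSE))
        res$slope[idx] <- ifelse(const, 0, coefs[2L, ])
        res$t_stat[idx] <- ifelse(const, 0, tval)
        res$p_value[idx] <- ifelse(const, 1, pval)
      }
      if (is.null(R) || df < 1L) {
        res$slope[idx] <- 0; res$t_stat[idx] <- 0; res$p_value[idx] <- 1
      }
      res$n_species_used[idx] <- n
    }
    res$q_value <- bh_adjust(res$p_value)
    status <- classify_status(matrix,
                              present_fraction = ifelse(is.na(matrix), 0, 1),
                              loss_thr = loss_thr)
    dim(status) <- dim(matrix); dimnames(status) <- dimnames(matrix)
    res$n_lost_lineages <- vapply(genes, function(g)
      convergent_loss_count(status[g, ], lineages), integer(1))
    res$candidate <- !is.na(res$q_value) & res$q_value < fdr &
      res$n_lost_lineages >= min_lineages
  }
  if (length(skipped))
    message(length(skipped), " gene(s) skipped (single phenotype class or <3 species after pruning)")

  structure(list(results = res,
                 params = list(fdr = fdr, min_lineages = min_lineages,
                               loss_thr = loss_thr, alternative = alternative,
                               continuous = !is.null(phenotype)),
                 lineages = lineages,
                 n_genes_input = n_input,
                 n_genes_tested = sum(!is.na(res$p_value)),
                 skipped = skipped,
                 assignment = assignment,
                 call = match.call()),
            class = "forward_screen")
}

#' Control screen on an alternative foreground
#'
#' Re-runs [forward_screen()] with a user-supplied foreground — typically the
#' high-acuity sister species of the original trait-loss lineages — to check
#' that the association machinery does not flag genes regardless of phenotype.
#' All other labelled species become background.
#'
#' @param matrix,tree,... as in [forward_screen()].
#' @param sister_foreground character vector of species to treat as
#'   foreground.
#' @return a `forward_screen` object.
#' @export
control_screen <- function(matrix, tree, sister_foreground, ...) {
  sp <- colnames(matrix)
  bad <- setdiff(sister_foreground, sp)
  if (length(bad))
    stop("sister species not in matrix: ", paste(bad, collapse = ", "))
  lab <- stats::setNames(ifelse(sp %in% sister_foreground,
                                "foreground", "background"), sp)
  asg <- phenotype_assignment(lab,
                              lineages = partition_lineages(tree,
                                intersect(sp[lab == "foreground"], tree$tip.label)),
                              provenance = list(method = "control_sisters"))
  forward_screen(matrix, tree, asg, ...)
}
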