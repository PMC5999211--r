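# Descriptive and inferential population genetics on the adult sample:
# diversity, Hardy-Weinberg exact tests, F-statistics, linkage
# disequilibrium, null alleles and exclusion probabilities.

#' Second-parent exclusion probability for one locus
#'
#' Probability that a randomly chosen non-father is Mendelian-excluded as the
#' sire of an offspring when the mother's genotype is known. Computed exactly
#' by summing over mother genotypes (Hardy-Weinberg weights), the maternally
#' transmitted allele, and the paternal allele drawn from the population
#' frequencies: given the resulting mother-offspring pair, the set of
#' possible paternal alleles is determined, and a random male is excluded
#' when neither of his alleles belongs to that set.
#'
#' @param freqs numeric vector of allele frequencies (sums to 1).
#' @return Exclusion probability in \code{[0, 1]}; 0 for a monomorphic locus.
#' @export
#' @examples
#' exclusion_prob_known_parent(c(0.5, 0.5))
exclusion_prob_known_parent <- function(freqs) {
  p <- as.numeric(freqs)
  if (any(p < 0) || abs(sum(p) - 1) > 1e-9)
    stop("frequencies must be non-negative and sum to 1")
  k <- length(p)
  if (k < 2) return(0)
  tot <- 0
  for (i in seq_len(k)) for (j in seq_len(k)) {     # ordered mother genotype
    w_m <- p[i] * p[j]
    if (w_m == 0) next
    for (m in c(i, j)) {                            # maternal transmitted allele
      for (f in seq_len(k)) {                       # paternal allele ~ freqs
        w <- w_m * 0.5 * p[f]
        if (w == 0) next
        # offspring genotype {m, f}; possible paternal alleles given mother {i,j}
        S <- paternal_allele_set(c(m, f), c(i, j))
        pS <- sum(p[S])
        tot <- tot + w * (1 - pS)^2
      }
    }
  }
  tot
}

# alleles of offspring {x,y} that could have come from the father, given the
# mother carries alleles in M; integer indices/labels, possibly length 0
paternal_allele_set <- function(off, mother) {
  x <- off[1]; y <- off[2]
  S <- integer(0)
  if (y %in% mother) S <- c(S, x)
  if (x %in% mother) S <- c(S, y)
  unique(S)
}

#' Combine per-locus exclusion probabilities
#'
#' Multi-locus exclusion probability \eqn{1 - \prod_l (1 - EXP_l)}: a random
#' non-father escapes exclusion only by being compatible at every locus.
#'
#' @param exps numeric vector of per-locus exclusion probabilities in
#'   \code{[0, 1]}.
#' @return Combined exclusion probability.
#' @export
#' @examples
#' combined_exclusion(c(0.370, 0.494, 0.405, 0.669, 0.745,
#'                      0.529, 0.661, 0.399, 0.646, 0.582))
combined_exclusion <- function(exps) {
  if (any(exps < 0 | exps > 1)) stop("exclusion probabilities must lie in [0, 1]")
  1 - prod(1 - exps)
}

#' Exact test of Hardy-Weinberg equilibrium
#'
#' Conditional exact test on the genotype counts of one locus. All genotype
#' arrays consistent with the observed allele counts are enumerated when
#' their number does not exceed \code{max_enum}; the p-value is the summed
#' conditional probability (Levene's distribution) of arrays no more probable
#' than the observed one. For larger tables a Monte-Carlo version shuffles
#' the allele vector into random genotype arrays.
#'
#' @param geno two-column matrix (or 2-column slice of a genotype matrix) of
#'   allele labels, one row per individual; rows with missing alleles are
#'   dropped.
#' @param mc_reps Monte-Carlo replicates used when enumeration is infeasible.
#' @param max_enum maximum number of genotype arrays to enumerate exactly.
#' @return List with \code{p} (p-value), \code{method} ("enumeration" or
#'   "monte-carlo"), and \code{n_arrays} (arrays enumerated, or \code{NA}).
#' @export
hwe_exact_test <- function(geno, mc_reps = 10000, max_enum = 1e6) {
  geno <- as.matrix(geno)
  keep <- stats::complete.cases(geno)
  geno <- geno[keep, , drop = FALSE]
  n <- nrow(geno)
  if (n < 1) stop("at least one genotype is required")
  alleles <- sort(unique(as.vector(geno)))
  k <- length(alleles)
  if (k < 2) return(list(p = 1, method = "degenerate", n_arrays = 1L))
  a1 <- match(geno[, 1], alleles)
  a2 <- match(geno[, 2], alleles)
  ac <- tabulate(c(a1, a2), nbins = k)
  # genotype-array log-probabilities are compared through their varying
  # part only: het * log(2) - sum(lfactorial(n_ij))
  code_of <- function(x, y) (pmin(x, y) - 1L) * k + pmax(x, y)
  obs_codes <- code_of(a1, a2)
  het_obs <- sum(a1 != a2)
  cnt_obs <- tabulate(obs_codes, nbins = k * k)
  logp_obs <- het_obs * log(2) - sum(lfactorial(cnt_obs[cnt_obs > 0L]))

  # cheap upper bound on the number of arrays: one degree of freedom per
  # heterozygote cell, each at most min(a_i, a_j) + 1 values
  log_bound <- 0
  for (i in seq_len(k - 1)) for (j in (i + 1):k)
    log_bound <- log_bound + log1p(min(ac[i], ac[j]))
  if (log_bound <= log(max_enum)) {
    res <- hwe_enum_p(ac, logp_obs, max_enum)
    if (!is.null(res))
      return(list(p = min(res$p, 1), method = "enumeration",
                  n_arrays = res$n_arrays))
  }
  # Monte Carlo: shuffle alleles into random pairings
  pool <- c(a1, a2)
  hits <- 0L
  for (r in seq_len(mc_reps)) {
    perm <- sample(pool)
    g1 <- perm[seq_len(n)]; g2 <- perm[n + seq_len(n)]
    codes <- code_of(g1, g2)
    cnt <- tabulate(codes, nbins = k * k)
    lp <- sum(g1 != g2) * log(2) - sum(lfactorial(cnt[cnt > 0L]))
    if (lp <= logp_obs + 1e-9) hits <- hits + 1L
  }
  list(p = (hits + 1) / (mc_reps + 1), method = "monte-carlo", n_arrays = NA_integer_)
}

# exact enumeration of genotype arrays consistent with the allele counts,
# accumulating the conditional p-value in place; NULL when more than
# max_enum arrays exist
hwe_enum_p <- function(ac, logp_obs, max_enum) {
  k <- length(ac)
  cells <- which(upper.tri(diag(k), diag = TRUE), arr.ind = TRUE)
  cells <- cells[order(cells[, 1], cells[, 2]), , drop = FALSE]
  ncell <- nrow(cells)
  n_arrays <- 0L
  num <- 0; den <- 0
  aborted <- FALSE
  rec <- function(cell, rem, lp, het) {
    if (aborted) return(invisible(NULL))
    if (cell > ncell) {
      if (all(rem == 0L)) {
        n_arrays <<- n_arrays + 1L
        if (n_arrays > max_enum) { aborted <<- TRUE; return(invisible(NULL)) }
        w <- exp(het * log(2) - lp)
        den <<- den + w
        if (het * log(2) - lp <= logp_obs + 1e-9) num <<- num + w
      }
      return(invisible(NULL))
    }
    i <- cells[cell, 1]; j <- cells[cell, 2]
    max_n <- if (i == j) rem[i] %/% 2L else min(rem[i], rem[j])
    for (nij in 0:max_n) {
      rem2 <- rem
      if (i == j) rem2[i] <- rem2[i] - 2L * nij
      else { rem2[i] <- rem2[i] - nij; rem2[j] <- rem2[j] - nij }
      # after allele i's last cell its count must be exhausted
      if (j == k && rem2[i] != 0L) next
      rec(cell + 1L, rem2,
          lp + lfactorial(nij), het + if (i == j) 0L else nij)
      if (aborted) return(invisible(NULL))
    }
    invisible(NULL)
  }
  rec(1L, as.integer(ac), 0, 0L)
  if (aborted) return(NULL)
  list(p = num / den, n_arrays = n_arrays)
}

#' Unbiased expected heterozygosity
#'
#' Nei's small-sample-corrected gene diversity
#' \eqn{\frac{2n}{2n-1}(1 - \sum \hat p_i^2)}.
#'
#' @param geno two-column matrix of allele labels (missing rows dropped).
#' @return Expected heterozygosity in \code{[0, 1]}.
#' @export
unbiased_he <- function(geno) {
  geno <- as.matrix(geno)
  geno <- geno[stats::complete.cases(geno), , drop = FALSE]
  n <- nrow(geno)
  if (n == 0) return(NA_real_)
  p <- as.vector(table(as.vector(geno))) / (2 * n)
  (2 * n / (2 * n - 1)) * (1 - sum(p^2))
}

#' Per-locus summary statistics
#'
#' Computes, for each panel locus: allele count, observed and unbiased
#' expected heterozygosity, exact-test Hardy-Weinberg p-value, inbreeding
#' coefficient \eqn{F_{IS} = 1 - H_O/H_E}, the Chakraborty moment estimator
#' of null-allele frequency \eqn{(H_E - H_O)/(H_E + H_O)}, and the
#' second-parent exclusion probability computed from the sample allele
#' frequencies.
#'
#' @param genotypes genotype matrix (two columns per locus, allele labels,
#'   \code{NA} = missing).
#' @param panel the \code{locus_panel} naming the loci.
#' @param mc_reps Monte-Carlo replicates for the HWE test on large tables.
#' @return data.frame with one row per locus: \code{locus}, \code{n},
#'   \code{n_alleles}, \code{ho}, \code{he}, \code{hwe_p}, \code{fis},
#'   \code{f_null}, \code{exp}. \code{fis} and \code{f_null} are \code{NA}
#'   for monomorphic loci.
#' @export
locus_summaries <- function(genotypes, panel, mc_reps = 2000) {
  L <- n_loci(panel)
  out <- vector("list", L)
  for (l in seq_len(L)) {
    g <- genotypes[, locus_cols(l), drop = FALSE]
    g <- g[stats::complete.cases(g), , drop = FALSE]
    n <- nrow(g)
    if (n < 2) stop("locus ", panel[[l]]$name, ": fewer than 2 typed individuals")
    alleles <- sort(unique(as.vector(g)))
    k <- length(alleles)
    ho <- mean(g[, 1] != g[, 2])
    he <- unbiased_he(g)
    p <- as.vector(table(factor(as.vector(g), levels = alleles))) / (2 * n)
    if (k > 1) {
      hwe <- hwe_exact_test(g, mc_reps = mc_reps)$p
      fis <- 1 - ho / he
      fnull <- (he - ho) / (he + ho)
      exp_l <- exclusion_prob_known_parent(p)
    } else {
      hwe <- 1; fis <- NA_real_; fnull <- NA_real_; exp_l <- 0
    }
    out[[l]] <- data.frame(locus = panel[[l]]$name, n = n, n_alleles = k,
                           ho = ho, he = he, hwe_p = hwe, fis = fis,
                           f_null = fnull, exp = exp_l,
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' One-sample t-test of mean inbreeding coefficient across loci
#'
#' @param summaries output of [locus_summaries()].
#' @return \code{htest} object testing mean \eqn{F_{IS} = 0} across loci.
#' @export
fis_t_test <- function(summaries) {
  stats::t.test(summaries$fis[!is.na(summaries$fis)], mu = 0)
}

# Weir-Cockerham variance components (a, b, c) summed over alleles of one
# locus for r >= 2 samples; geno = two-column matrix, grp = factor
wc_components <- function(geno, grp) {
  keep <- stats::complete.cases(geno)
  geno <- geno[keep, , drop = FALSE]
  grp <- factor(grp[keep])
  r <- nlevels(grp)
  ni <- as.vector(table(grp))
  if (any(ni < 1)) stop("each group needs at least one typed individual")
  nbar <- mean(ni)
  nc <- (r * nbar - sum(ni^2) / (r * nbar)) / (r - 1)
  alleles <- sort(unique(as.vector(geno)))
  A <- 0; B <- 0; C <- 0
  for (al in alleles) {
    pi_ <- vapply(levels(grp), function(g) {
      rows <- grp == g
      mean(geno[rows, ] == al)
    }, numeric(1))
    hi <- vapply(levels(grp), function(g) {
      rows <- grp == g
      mean((geno[rows, 1] == al) != (geno[rows, 2] == al))
    }, numeric(1))
    pbar <- sum(ni * pi_) / (r * nbar)
    s2 <- sum(ni * (pi_ - pbar)^2) / ((r - 1) * nbar)
    hbar <- sum(ni * hi) / (r * nbar)
    a <- (nbar / nc) * (s2 - (1 / (nbar - 1)) *
           (pbar * (1 - pbar) - ((r - 1) / r) * s2 - hbar / 4))
    b <- (nbar / (nbar - 1)) * (pbar * (1 - pbar) - ((r - 1) / r) * s2 -
           ((2 * nbar - 1) / (4 * nbar)) * hbar)
    cc <- hbar / 2
    A <- A + a; B <- B + b; C <- C + cc
  }
  c(a = A, b = B, c = C)
}

#' Pairwise F_ST (Weir-Cockerham theta) with permutation test
#'
#' Multilocus \eqn{\theta} as the ratio of summed variance components
#' \eqn{\sum_l a_l / \sum_l (a_l + b_l + c_l)} over loci, with a p-value from
#' permuting group labels across individuals.
#'
#' @param genotypes genotype matrix (two columns per locus).
#' @param groups group label per individual (two groups).
#' @param panel the \code{locus_panel}.
#' @param permutations number of label permutations (>= 1).
#' @return List with \code{theta}, \code{p} (permutation p-value, one-sided
#'   on theta), and \code{n_perm}.
#' @export
pairwise_fst <- function(genotypes, groups, panel, permutations = 1000) {
  groups <- factor(groups)
  if (nlevels(groups) != 2) stop("exactly two groups are required")
  if (any(table(groups) < 2)) stop("each group needs at least 2 individuals")
  theta_of <- function(grp) {
    comp <- rowSums(vapply(seq_len(n_loci(panel)), function(l)
      wc_components(genotypes[, locus_cols(l), drop = FALSE], grp),
      numeric(3)))
    comp[["a"]] / (comp[["a"]] + comp[["b"]] + comp[["c"]])
  }
  obs <- theta_of(groups)
  hits <- 0L
  for (i in seq_len(permutations)) {
    if (theta_of(sample(groups)) >= obs - 1e-12) hits <- hits + 1L
  }
  list(theta = obs, p = (hits + 1) / (permutations + 1), n_perm = permutations)
}

#' Genotypic linkage-disequilibrium test for a locus pair
#'
#' Log-likelihood-ratio G statistic for association between the genotype
#' classifications at two loci, with the null distribution obtained by
#' permuting one locus's genotypes across individuals.
#'
#' @param genotypes genotype matrix.
#' @param l1,l2 locus indices in the panel.
#' @param panel the \code{locus_panel}.
#' @param permutations number of permutations (must be >= 1).
#' @return List with \code{G}, \code{p}, \code{n} (individuals used).
#' @export
ld_test <- function(genotypes, l1, l2, panel, permutations = 1000) {
  if (permutations < 1) stop("permutations must be >= 1")
  g1 <- genotypes[, locus_cols(l1), drop = FALSE]
  g2 <- genotypes[, locus_cols(l2), drop = FALSE]
  keep <- stats::complete.cases(g1) & stats::complete.cases(g2)
  g1 <- g1[keep, , drop = FALSE]; g2 <- g2[keep, , drop = FALSE]
  n <- nrow(g1)
  if (n < 10) stop("at least 10 individuals typed at both loci are required")
  f1 <- factor(paste(pmin(g1[, 1], g1[, 2]), pmax(g1[, 1], g1[, 2])))
  f2 <- factor(paste(pmin(g2[, 1], g2[, 2]), pmax(g2[, 1], g2[, 2])))
  if (nlevels(f1) < 2 || nlevels(f2) < 2)
    return(list(G = 0, p = 1, n = n))
  g_stat <- function(x, y) {
    tab <- table(x, y)
    e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    idx <- tab > 0
    2 * sum(tab[idx] * log(tab[idx] / e[idx]))
  }
  obs <- g_stat(f1, f2)
  hits <- 0L
  for (i in seq_len(permutations))
    if (g_stat(f1, sample(f2)) >= obs - 1e-12) hits <- hits + 1L
  list(G = obs, p = (hits + 1) / (permutations + 1), n = n)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment of a vector of p-values
#' (delegates to [stats::p.adjust()]).
#'
#' @param p numeric vector of p-values in \code{[0, 1]}.
#' @return Adjusted p-values, same length and order as the input.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}
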