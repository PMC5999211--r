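test_that("exclusion probability equals brute-force enumeration", {
  # independent oracle: enumerate mother x true father x transmission x
  # random male over all ordered genotype combinations
  brute_exp <- function(p) {
    k <- length(p); tot <- 0
    for (mi in 1:k) for (mj in 1:k) for (fi in 1:k) for (fj in 1:k) {
      w0 <- p[mi] * p[mj] * p[fi] * p[fj]
      for (ma in c(mi, mj)) for (fa in c(fi, fj)) {
        w <- w0 * 0.25
        S <- unique(c(if (fa %in% c(mi, mj)) ma, if (ma %in% c(mi, mj)) fa))
        excl <- 0
        for (ri in 1:k) for (rj in 1:k)
          if (!(ri %in% S) && !(rj %in% S)) excl <- excl + p[ri] * p[rj]
        tot <- tot + w * excl
      }
    }
    tot
  }
  for (k in c(2, 4, 8)) {
    p <- rep(1 / k, k)
    expect_equal(exclusion_prob_known_parent(p), brute_exp(p),
                 tolerance = 1e-12)
  }
  # a skewed case too
  p <- c(0.5, 0.3, 0.2)
  expect_equal(exclusion_prob_known_parent(p), brute_exp(p), tolerance = 1e-12)
})

test_that("exclusion probability grows with allele count", {
  exps <- vapply(2:10, function(k)
    exclusion_prob_known_parent(rep(1 / k, k)), numeric(1))
  expect_true(all(diff(exps) > 0))
  expect_equal(exclusion_prob_known_parent(1), 0)
})

test_that("combined exclusion behaves as one minus product of complements", {
  exps <- c(0.370, 0.494, 0.405, 0.669, 0.745, 0.529, 0.661, 0.399, 0.646, 0.582)
  expect_equal(combined_exclusion(exps), combined_exclusion(rev(exps)))
  expect_equal(combined_exclusion(0.4), 0.4)
  expect_equal(combined_exclusion(c(0.3, 1)), 1)
  expect_error(combined_exclusion(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("two-allele HWE enumeration matches the closed-form Levene sum", {
  set.seed(20)
  n11 <- 6L; n12 <- 5L; n22 <- 9L
  g <- rbind(matrix(1L, n11, 2), matrix(c(1L, 2L), n12, 2, byrow = TRUE),
             matrix(2L, n22, 2))
  n <- n11 + n12 + n22
  a1 <- 2 * n11 + n12
  # closed form: P(n12) over all arrays with the allele-count parity
  levene <- function(h) {
    x11 <- (a1 - h) / 2; x22 <- n - x11 - h
    exp(lfactorial(n) - lfactorial(x11) - lfactorial(h) - lfactorial(x22) +
          h * log(2) + lfactorial(a1) + lfactorial(2 * n - a1) -
          lfactorial(2 * n))
  }
  hs <- seq(a1 %% 2, min(a1, 2 * n - a1), by = 2)
  probs <- vapply(hs, levene, numeric(1))
  p_closed <- sum(probs[probs <= levene(n12) + 1e-12])
  res <- hwe_exact_test(g)
  expect_equal(res$method, "enumeration")
  expect_equal(res$p, p_closed, tolerance = 1e-9)
})

test_that("HWE test calls extreme heterozygote excess significant", {
  g <- matrix(c(1L, 2L), 20, 2, byrow = TRUE)
  expect_lt(hwe_exact_test(g)$p, 0.05)
  # counts at exact HW proportions sit at the distribution's mode
  g2 <- rbind(matrix(1L, 4, 2), matrix(c(1L, 2L), 8, 2, byrow = TRUE),
              matrix(2L, 4, 2))
  expect_gte(hwe_exact_test(g2)$p, 0.5)
})

test_that("Monte-Carlo HWE agrees with enumeration on a multiallelic locus", {
  set.seed(21)
  g <- cbind(sample(1:3, 60, TRUE), sample(1:3, 60, TRUE))
  e <- hwe_exact_test(g)
  m <- hwe_exact_test(g, max_enum = 0, mc_reps = 20000)
  expect_equal(e$method, "enumeration")
  expect_equal(m$method, "monte-carlo")
  expect_lt(abs(e$p - m$p), 0.02)
})

test_that("locus summaries reproduce textbook cases", {
  pan <- locus_panel(c("HW", "MONO"),
                     alleles = list(c(1L, 2L), c(7L, 8L)),
                     freqs = list(c(0.5, 0.5), c(1, 0)))
  # locus HW exactly at Hardy-Weinberg proportions, n = 16
  g <- cbind(c(rep(1L, 4), rep(1L, 8), rep(2L, 4)),
             c(rep(1L, 4), rep(2L, 8), rep(2L, 4)),
             rep(7L, 16), rep(7L, 16))
  colnames(g) <- c("HW.1", "HW.2", "MONO.1", "MONO.2")
  rownames(g) <- sprintf("i%02d", 1:16)
  s <- locus_summaries(g, pan)
  expect_equal(s$ho[1], 0.5)
  expect_equal(s$n_alleles, c(2L, 1L))
  expect_equal(s$fis[1], 1 - 0.5 / s$he[1])
  # monomorphic locus: no exclusion power, undefined F_IS
  expect_equal(s$exp[2], 0)
  expect_equal(s$ho[2], 0)
  expect_equal(s$he[2], 0)
  expect_true(is.na(s$fis[2]))
  expect_equal(s$hwe_p[2], 1)
})

test_that("Weir-Cockerham theta matches hand-computed variance components", {
  # two samples, one biallelic locus; the oracle transcribes the
  # variance-component formulas directly on scalars
  g <- rbind(c(1L, 1L), c(1L, 2L), c(1L, 2L), c(2L, 2L),  # sample 1
             c(1L, 2L), c(2L, 2L), c(2L, 2L), c(2L, 2L), c(1L, 2L)) # sample 2
  grp <- rep(c("A", "B"), c(4, 5))
  pan <- locus_panel("L", list(c(1L, 2L)), list(c(0.5, 0.5)))
  colnames(g) <- c("L.1", "L.2")
  hand_theta <- function() {
    ni <- c(4, 5); r <- 2
    nbar <- mean(ni)
    nc <- (sum(ni) - sum(ni^2) / sum(ni)) / (r - 1)
    tot_a <- tot_b <- tot_c <- 0
    for (al in 1:2) {
      p1 <- mean(g[1:4, ] == al); p2 <- mean(g[5:9, ] == al)
      h1 <- mean((g[1:4, 1] == al) != (g[1:4, 2] == al))
      h2 <- mean((g[5:9, 1] == al) != (g[5:9, 2] == al))
      pbar <- (ni[1] * p1 + ni[2] * p2) / sum(ni)
      s2 <- (ni[1] * (p1 - pbar)^2 + ni[2] * (p2 - pbar)^2) / ((r - 1) * nbar)
      hbar <- (ni[1] * h1 + ni[2] * h2) / sum(ni)
      a <- (nbar / nc) * (s2 - (pbar * (1 - pbar) - s2 / 2 - hbar / 4) / (nbar - 1))
      b <- (nbar / (nbar - 1)) *
        (pbar * (1 - pbar) - s2 / 2 - hbar * (2 * nbar - 1) / (4 * nbar))
      cc <- hbar / 2
      tot_a <- tot_a + a; tot_b <- tot_b + b; tot_c <- tot_c + cc
    }
    tot_a / (tot_a + tot_b + tot_c)
  }
  res <- pairwise_fst(g, grp, pan, permutations = 50)
  expect_equal(res$theta, hand_theta(), tolerance = 1e-12)
})

test_that("theta is 1 for fixed differences and near 0 without differentiation", {
  pan <- locus_panel("L", list(c(1L, 2L)), list(c(0.5, 0.5)))
  g <- rbind(matrix(1L, 10, 2), matrix(2L, 10, 2))
  colnames(g) <- c("L.1", "L.2")
  grp <- rep(c("A", "B"), each = 10)
  expect_equal(pairwise_fst(g, grp, pan, permutations = 20)$theta, 1)

  set.seed(22)
  pan10 <- lobster_panel(with_errors = FALSE)
  gg <- sample_genotypes(pan10, 1000)
  grp2 <- rep(c("reserve", "fished"), each = 500)
  res <- pairwise_fst(gg, grp2, pan10, permutations = 99)
  expect_lt(abs(res$theta), 0.005)
  expect_gt(res$p, 0.01)
})

test_that("LD test flags perfect association and errors on zero permutations", {
  set.seed(23)
  pan <- locus_panel(c("L1", "L2"),
                     alleles = list(c(1L, 2L, 3L), c(11L, 12L, 13L)),
                     freqs = list(rep(1/3, 3), rep(1/3, 3)))
  g1 <- cbind(sample(1:3, 80, TRUE), sample(1:3, 80, TRUE))
  g <- cbind(g1, g1 + 10L)  # second locus duplicates the first
  colnames(g) <- c("L1.1", "L1.2", "L2.1", "L2.2")
  expect_lt(ld_test(g, 1, 2, pan, permutations = 200)$p, 0.01)
  expect_error(ld_test(g, 1, 2, pan, permutations = 0), "permutations")
})

test_that("independent loci give uniform LD p-values", {
  set.seed(24)
  pan <- lobster_panel(with_errors = FALSE)
  g <- sample_genotypes(pan, 150)
  ps <- numeric(0)
  for (i in 1:9) for (j in (i + 1):10)
    ps <- c(ps, ld_test(g, i, j, pan, permutations = 199)$p)
  expect_length(ps, 45)
  expect_gt(suppressWarnings(stats::ks.test(ps, "punif"))$p.value, 0.01)
})

test_that("Benjamini-Hochberg adjustment follows the step-up rule", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_error(bh_adjust(c(0.5, 1.5)), "\\[0, 1\\]")
})
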