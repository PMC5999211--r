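test_that("paternal alleles are deduced per the mother-offspring combination", {
  pan <- locus_panel("L", list(c(1L, 2L, 3L)), list(c(0.4, 0.4, 0.2)))
  mom <- c(L.1 = 1L, L.2 = 2L)
  eggs <- rbind(c(1L, 3L),   # paternal allele must be 3
                c(1L, 2L),   # ambiguous: 1 or 2
                c(3L, 3L))   # incompatible with the mother
  colnames(eggs) <- c("L.1", "L.2")
  ped <- deduce_paternal_alleles(eggs, mom, pan)
  expect_equal(ped[[1]]$L$alleles, 3L)
  expect_setequal(ped[[2]]$L$alleles, c(1L, 2L))
  expect_true(ped[[3]]$L$mismatch)
  expect_false(ped[[1]]$L$mismatch)
})

test_that("trio likelihood matches hand enumeration and excludes at zero error", {
  # single locus, freq(C) = 0.1; mother A/B, egg A/C, candidate C/C:
  # P(egg | M, C/C) = 1/2, P(egg | M, random) = 1/2 * 0.1 -> LR = 10
  pan <- locus_panel("L", list(c(1L, 2L, 3L)), list(c(0.5, 0.4, 0.1)))
  mom <- c(L.1 = 1L, L.2 = 2L)
  egg <- c(L.1 = 1L, L.2 = 3L)
  cand_cc <- c(L.1 = 3L, L.2 = 3L)
  expect_equal(paternity_loglik(egg, mom, cand_cc, pan), log(10),
               tolerance = 1e-12)
  cand_bad <- c(L.1 = 2L, L.2 = 2L)  # cannot have transmitted C
  expect_equal(paternity_loglik(egg, mom, cand_bad, pan), -Inf)
})

test_that("likelihood ratio is invariant to allele relabeling", {
  set.seed(30)
  pan1 <- locus_panel("L", list(c(1L, 2L, 3L)), list(c(0.5, 0.3, 0.2)),
                      eps1 = 0.05, eps2 = 0.01)
  pan2 <- locus_panel("L", list(c(901L, 902L, 903L)), list(c(0.5, 0.3, 0.2)),
                      eps1 = 0.05, eps2 = 0.01)
  relab <- function(x) x + 900L
  for (i in 1:20) {
    mom <- sample(1:3, 2, TRUE, prob = c(0.5, 0.3, 0.2))
    egg <- c(sample(mom, 1), sample(1:3, 1, prob = c(0.5, 0.3, 0.2)))
    cand <- sample(1:3, 2, TRUE, prob = c(0.5, 0.3, 0.2))
    nm <- c("L.1", "L.2")
    l1 <- paternity_loglik(stats::setNames(egg, nm), stats::setNames(mom, nm),
                           stats::setNames(cand, nm), pan1)
    l2 <- paternity_loglik(stats::setNames(relab(egg), nm),
                           stats::setNames(relab(mom), nm),
                           stats::setNames(relab(cand), nm), pan2)
    expect_equal(l1, l2, tolerance = 1e-12)
  }
})

test_that("true fathers outscore unrelated males on average", {
  set.seed(31)
  pan <- lobster_panel()  # with the published error rates
  n <- 300
  moms <- sample_genotypes(pan, n)
  dads <- sample_genotypes(pan, n)
  unrel <- sample_genotypes(pan, n)
  d_true <- d_un <- numeric(n)
  for (i in 1:n) {
    egg <- matesel:::mendelian_offspring(moms[i, ], dads[i, ], pan)
    egg <- matesel:::observe_genotypes(matrix(egg, 1,
                     dimnames = list(NULL, colnames(moms))), pan, 0)[1, ]
    d_true[i] <- paternity_loglik(egg, moms[i, ], dads[i, ], pan)
    d_un[i] <- paternity_loglik(egg, moms[i, ], unrel[i, ], pan)
  }
  expect_gt(mean(d_true), mean(d_un))
  expect_gt(mean(d_true), 0)
})

test_that("confidence calibration meets its precision contract", {
  pan <- informative_panel(6)
  # perfectly informative loci, all fathers sampled: zero error rate and a
  # small positive threshold
  cal <- calibrate_confidence(pan, pool_size = 50, sampled_fraction = 1,
                              reps = 200, seed = 32)
  expect_true(is.finite(cal$threshold))
  expect_gte(cal$precision_at, 0.95)
  expect_equal(mean(cal$deltas$correct), 1)
  # nobody sampled: no admissible threshold
  cal0 <- calibrate_confidence(pan, pool_size = 50, sampled_fraction = 0,
                               reps = 10, seed = 33)
  expect_identical(cal0$threshold, Inf)
})

test_that("calibrated threshold keeps the false-positive rate near target", {
  set.seed(34)
  pan <- lobster_panel(with_errors = FALSE)
  cal <- calibrate_confidence(pan, pool_size = 150, sampled_fraction = 0.5,
                              reps = 600, seed = 35)
  # fresh simulation at the returned threshold
  pool <- sample_genotypes(pan, 150, ids = sprintf("P%03d", 1:150))
  wrong <- 0; accepted <- 0
  for (r in 1:300) {
    mom <- sample_genotypes(pan, 1)[1, ]
    inside <- r %% 2 == 0
    truth <- if (inside) sample(150, 1) else NA
    dad <- if (inside) pool[truth, ] else sample_genotypes(pan, 1)[1, ]
    egg <- matesel:::mendelian_offspring(mom, dad, pan)
    eggs_df <- data.frame(egg_id = "e", mother_id = "m")
    momg <- matrix(mom, 1, dimnames = list("m", names(mom)))
    ass <- assign_fathers(matrix(egg, 1, dimnames = list("e", names(egg))),
                          eggs_df, momg, pool, pan, threshold = cal$threshold)
    if (ass$assigned) {
      accepted <- accepted + 1
      if (!inside || ass$father_id != sprintf("P%03d", truth))
        wrong <- wrong + 1
    }
  }
  expect_gt(accepted, 50)
  expect_lte(wrong / accepted, 0.10)  # 5% target with Monte-Carlo slack
})

test_that("error-free assignment with complete sampling recovers the truth", {
  set.seed(36)
  pan <- lobster_panel(with_errors = FALSE)
  cfg <- small_config(p_multiple = 0)
  ds <- simulate_dataset(cfg, pan, seed = 36)
  g <- ds$genotypes
  males <- ds$adults$id[ds$adults$sex == "M"]
  ass <- assign_fathers(g$egg_obs, g$eggs, g$adult_obs,
                        g$adult_obs[males, ], pan, threshold = 0)
  correct <- ass$father_id == g$eggs$father_id
  expect_gt(mean(correct & ass$assigned), 0.98)
  expect_true(all(ass$mother_mismatch == 0))
  # every brood's most-assigned sire is the true one
  for (m in unique(g$eggs$mother_id)) {
    idx <- g$eggs$mother_id == m
    tab <- table(ass$father_id[idx & ass$assigned])
    expect_equal(names(tab)[which.max(tab)],
                 unique(g$eggs$father_id[idx])[1])
  }
})

test_that("eggs of unsampled fathers stay unassigned at the calibrated threshold", {
  set.seed(37)
  pan <- lobster_panel(with_errors = FALSE)
  cfg <- small_config(p_multiple = 0)
  ds <- simulate_dataset(cfg, pan, seed = 37)
  g <- ds$genotypes
  males <- ds$adults$id[ds$adults$sex == "M"]
  sires <- unique(g$eggs$father_id)
  removed <- sires[1:5]
  pool <- setdiff(males, removed)
  cal <- calibrate_confidence(pan, length(pool), sampled_fraction = 0.8,
                              reps = 400, seed = 38)
  ass <- assign_fathers(g$egg_obs, g$eggs, g$adult_obs,
                        g$adult_obs[pool, ], pan, threshold = cal$threshold)
  orphan <- g$eggs$father_id %in% removed
  expect_gte(mean(!ass$assigned[orphan]), 0.95)
})

test_that("brood classification applies the five-locus acceptance rule", {
  pan <- informative_panel(10)
  set.seed(39)
  momg <- sample_genotypes(pan, 1, ids = "mom")
  dadA <- sample_genotypes(pan, 1, ids = "A")
  dadB <- sample_genotypes(pan, 1, ids = "B")
  cand <- rbind(dadA, dadB)
  make_brood <- function(n_from_B) {
    eggs <- matrix(NA_integer_, 10, ncol(momg),
                   dimnames = list(sprintf("mom_e%02d", 1:10),
                                   colnames(momg)))
    for (e in 1:10) {
      dad <- if (e <= 10 - n_from_B) dadA[1, ] else dadB[1, ]
      eggs[e, ] <- matesel:::mendelian_offspring(momg[1, ], dad, pan)
    }
    eggs
  }
  eggs_meta <- data.frame(egg_id = sprintf("mom_e%02d", 1:10),
                          mother_id = "mom", stringsAsFactors = FALSE)
  run <- function(eggs) {
    ass <- assign_fathers(eggs, eggs_meta, momg, cand, pan, threshold = 0)
    classify_broods(eggs_meta, eggs, momg, ass, cand, pan)
  }
  # all ten eggs from one sire
  single <- run(make_brood(0))
  expect_equal(single$classification, "single")
  expect_equal(single$n_primary, 10)
  # 9:1 split with near-perfectly informative loci: accepted as multiple
  multi <- run(make_brood(1))
  expect_equal(multi$classification, "multiple")
  expect_equal(c(multi$n_primary, multi$n_secondary), c(9, 1))
  expect_equal(multi$primary, "A")
})

test_that("few mismatching loci make a brood ambiguous, not multiple", {
  # second sire shares dad A's genotype except at 3 loci: below the
  # five-locus rule
  pan <- informative_panel(10)
  set.seed(40)
  momg <- sample_genotypes(pan, 1, ids = "mom")
  dadA <- sample_genotypes(pan, 1, ids = "A")
  dadB <- dadA; rownames(dadB) <- "B"
  for (l in 1:3) {
    used <- c(momg[1, c(2*l-1, 2*l)], dadA[1, c(2*l-1, 2*l)])
    free <- setdiff(pan[[l]]$alleles, used)
    dadB[1, c(2*l-1, 2*l)] <- free[1:2]
  }
  eggs <- matrix(NA_integer_, 10, ncol(momg),
                 dimnames = list(sprintf("mom_e%02d", 1:10), colnames(momg)))
  for (e in 1:9)
    eggs[e, ] <- matesel:::mendelian_offspring(momg[1, ], dadA[1, ], pan)
  eggs[10, ] <- matesel:::mendelian_offspring(momg[1, ], dadB[1, ], pan)
  eggs_meta <- data.frame(egg_id = sprintf("mom_e%02d", 1:10),
                          mother_id = "mom", stringsAsFactors = FALSE)
  ass <- assign_fathers(eggs, eggs_meta, momg, dadA, pan, threshold = 0)
  cls <- classify_broods(eggs_meta, eggs, momg, ass, dadA, pan)
  expect_true(cls$classification %in% c("ambiguous", "single"))
  expect_false(cls$classification == "multiple")
})
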