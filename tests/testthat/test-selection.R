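test_that("standardization is exact per group and location-invariant", {
  expect_equal(standardize(c(1, 2, 3)), c(-1, 0, 1))
  x <- c(5, 9, 14, 2, 8)
  expect_equal(standardize(x), standardize(x + 100))
  g <- rep(c("a", "b"), c(3, 2))
  z <- standardize(c(1, 2, 3, 10, 30), g)
  expect_equal(as.vector(tapply(z, g, mean)), c(0, 0))
  expect_equal(as.vector(tapply(z, g, stats::sd)), c(1, 1))
  expect_error(standardize(c(2, 2, 2)), "variance")
})

test_that("selection differentials are the successful-minus-all mean shift", {
  z <- c(-1, 0, 1)
  s <- selection_differential(z, c(FALSE, FALSE, TRUE))
  expect_equal(s$S, 1)
  expect_true(is.na(selection_differential(z, rep(FALSE, 3))$S))
  # random success gives a near-zero differential
  set.seed(70)
  diffs <- replicate(1000, {
    z <- stats::rnorm(100)
    succ <- sample(c(rep(TRUE, 20), rep(FALSE, 80)))
    selection_differential(z, succ)$S
  })
  expect_lt(abs(mean(diffs)), 0.1)
})

test_that("residual claw size has the OLS properties", {
  set.seed(71)
  cl <- runif(100, 80, 130)
  cw <- -27 + 0.82 * cl
  expect_equal(residual_claw(cw, cl), rep(0, 100), tolerance = 1e-10)
  cw2 <- cw + rnorm(100, 0, 6)
  r <- residual_claw(cw2, cl)
  expect_lt(abs(mean(r)), 1e-10)
  expect_lt(abs(stats::cor(r, cl)), 1e-10)
  expect_lt(abs(stats::sd(r) - 6) / 6, 0.25)
  expect_error(residual_claw(cw[1:2], cl[1:2]), "3")
})

test_that("null-model AICc matches the closed form", {
  set.seed(72)
  n <- 80; k <- 17
  y <- sample(c(rep(1, k), rep(0, n - k)))
  d <- data.frame(success = y, z_cl = rnorm(n), z_cw = rnorm(n),
                  z_cwres = rnorm(n), area = "one")
  ms <- fit_selection_models(d, include_area = FALSE)
  phat <- k / n
  ll <- k * log(phat) + (n - k) * log(1 - phat)
  aicc_null <- -2 * ll + 2 * 1 + 2 * 1 * 2 / (n - 2)
  expect_equal(ms$table$aicc[ms$table$model == "Null"], aicc_null,
               tolerance = 1e-9)
})

test_that("the generating trait is identified by AICc model ranking", {
  set.seed(73)
  wins <- 0
  for (r in 1:30) {
    n <- 150
    z_cl <- rnorm(n); z_cw <- rnorm(n); z_cwres <- rnorm(n)
    p <- stats::plogis(-1.4 + 1.2 * z_cwres)
    d <- data.frame(success = rbinom(n, 1, p), z_cl = z_cl, z_cw = z_cw,
                    z_cwres = z_cwres, area = "one")
    ms <- fit_selection_models(d, include_area = FALSE)
    if (ms$table$model[1] %in% c("CWres", "CL + CWres")) wins <- wins + 1
  }
  expect_gte(wins / 30, 0.8)
})

test_that("an inert squared term does not beat the null decisively", {
  set.seed(74)
  deltas <- replicate(30, {
    n <- 150
    d <- data.frame(success = rbinom(n, 1, 0.25), z_cl = rnorm(n),
                    z_cw = rnorm(n), z_cwres = rnorm(n), area = "one")
    ms <- fit_selection_models(d, include_area = FALSE)
    t <- ms$table
    t$aicc[t$model == "Null"] - t$aicc[t$model == "CL + CL2"]
  })
  expect_lt(stats::median(deltas), 2)
})

test_that("Janzen-Stern gradients behave across the selection-strength range", {
  set.seed(75)
  # null coefficient maps to a zero gradient
  n <- 500
  d <- data.frame(success = rbinom(n, 1, 0.3), z = rnorm(n))
  f0 <- stats::glm(success ~ z, binomial, data = d)
  g0 <- janzen_stern_gradient(f0)
  expect_lt(abs(g0[["z"]]), 0.15)
  f00 <- f0; f00$coefficients["z"] <- 0
  expect_equal(unname(janzen_stern_gradient(f00)[["z"]]), 0)
  # weak-selection limit agrees with the OLS gradient of relative fitness
  n <- 2000
  z <- rnorm(n)
  y <- rbinom(n, 1, stats::plogis(-0.5 + 0.2 * z))
  fit <- stats::glm(y ~ z, binomial)
  bjs <- janzen_stern_gradient(fit)[["z"]]
  bols <- stats::coef(stats::lm(y / mean(y) ~ z))[["z"]]
  expect_lt(abs(bjs - bols), 0.05)
  # strong selection: gradient positive but attenuated below b
  y2 <- rbinom(n, 1, stats::plogis(-1 + 2 * z))
  fit2 <- stats::glm(y2 ~ z, binomial)
  b2 <- stats::coef(fit2)[["z"]]
  bjs2 <- janzen_stern_gradient(fit2)[["z"]]
  expect_gt(bjs2, 0)
  expect_lt(bjs2, b2)
})

test_that("mean-standardized gradients are arithmetic and refuse relative traits", {
  expect_equal(mean_standardized_gradient(0, 99, 14), 0)
  expect_equal(mean_standardized_gradient(0.5, 99, 14), 0.5 * 99 / 14)
  expect_error(mean_standardized_gradient(0.5, 0, 1, trait = "CW_res"),
               "relative claw")
})

test_that("assortative model recovers slope, supports additivity, flags area", {
  set.seed(76)
  recovered <- 0; additive <- 0
  for (r in 1:20) {
    nf <- 40
    fcl <- c(runif(nf, 80, 120), runif(nf, 80, 110))
    area <- rep(c("reserve", "fished"), each = nf)
    mcl <- 20 + 0.8 * fcl + ifelse(area == "reserve", 12, 0) + rnorm(2 * nf, 0, 8)
    pairs <- data.frame(female_cl = fcl, male_cl = mcl, area = area)
    am <- assortative_model(pairs)
    if (am$slope_ci[1] <= 0.8 && 0.8 <= am$slope_ci[2]) recovered <- recovered + 1
    if (am$lrt_p > 0.05) additive <- additive + 1
    if (r == 1) {
      expect_gt(am$area_coef, 0)  # reserve males larger at a given female size
      expect_equal(am$lrt_chisq,
                   as.numeric(2 * (stats::logLik(am$interaction_fit) -
                                   stats::logLik(am$additive_fit))))
    }
  }
  expect_gte(recovered, 17)
  expect_gte(additive, 16)
})

test_that("random pairing yields a null assortative slope", {
  set.seed(77)
  pairs <- data.frame(female_cl = runif(60, 80, 120),
                      male_cl = runif(60, 80, 130),
                      area = rep(c("reserve", "fished"), 30))
  am <- assortative_model(pairs)
  expect_true(am$slope_ci[1] <= 0 && 0 <= am$slope_ci[2])
})

test_that("pair size gaps are exact arithmetic with a Welch test", {
  pairs <- data.frame(female_cl = rep(100, 10), male_cl = rep(120, 10))
  g <- pair_size_gap(pairs)
  expect_equal(g$mean_gap_pct, 20)
  expect_true(is.na(g$p))  # zero-variance sizes: the Welch test degenerates
  set.seed(79)
  pairs1 <- data.frame(female_cl = rnorm(20, 100, 3),
                       male_cl = rnorm(20, 120, 3))
  expect_lt(pair_size_gap(pairs1)$p, 0.001)
  pairs2 <- data.frame(female_cl = c(90, 100), male_cl = c(90, 100))
  expect_equal(pair_size_gap(pairs2)$mean_gap_pct, 0)
})

test_that("estimates are invariant to trait units", {
  set.seed(78)
  n <- 200
  cl_mm <- runif(n, 80, 130)
  succ <- rbinom(n, 1, stats::plogis(-2 + 0.03 * cl_mm)) == 1
  S_mm <- selection_differential(standardize(cl_mm), succ)$S
  S_cm <- selection_differential(standardize(cl_mm / 10), succ)$S
  expect_equal(S_mm, S_cm, tolerance = 1e-12)
})
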