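# Synthetic population generator: adults, size-biased matings with
# occasional skewed multiple paternity, Mendelian broods with a
# dropout/false-allele observation layer, and mark-recapture growth records.

#' Configuration for the synthetic lobster population
#'
#' Defaults reproduce the structure of the study population: per-area and
#' per-sex sample sizes and carapace-length distributions (means and CVs as
#' published for the pooled years), a claw-width allometry for males,
#' log-linear size-biased female preference with a Gaussian assortative
#' kernel on the male/female size ratio, a small probability of multiple
#' paternity with a 9:1 paternal skew, ten eggs sampled per brood, and a
#' moult-probability/growth-increment model for the mark-recapture series.
#'
#' @param n list of group sizes: \code{reserve_m}, \code{fished_m},
#'   \code{reserve_f}, \code{fished_f}.
#' @param mean_cl,cv_cl lists of carapace-length means (mm) and coefficients
#'   of variation per group (same names as \code{n}).
#' @param claw_slope,claw_intercept,claw_sd male claw-width allometry
#'   CW = intercept + slope * CL + N(0, sd), in mm.
#' @param b_size,b_claw_res female-preference log-odds per SD of male CL and
#'   residual claw width.
#' @param delta_assort preferred male/female CL ratio (assortative kernel
#'   centre); \code{sigma_assort} is the kernel SD on the ratio scale.
#' @param p_multiple probability a brood receives a second sire.
#' @param skew paternal contribution vector (sums to 1).
#' @param eggs_per_brood eggs sampled per female.
#' @param harvest_threshold CL (mm) above which fished-area individuals are
#'   removed with probability \code{harvest_prob} (0 disables truncation; the
#'   default group means already describe the harvested population, so
#'   truncation is an explicit scenario knob).
#' @param moult_intercept,moult_slope logistic moult-probability curve on CL
#'   (defaults give p near 1 below 90 mm, below 0.75 beyond 113 mm).
#' @param growth_intercept,growth_slope,growth_sd moult-increment line
#'   (mm/yr) on CL.
#' @param missing_rate per-genotype missingness in the observation layer.
#' @param year the mating year; females are captured in it.
#' @param male_year_offsets,male_year_probs capture-year offsets of males
#'   relative to the mating year and their probabilities (default: 70\% of
#'   males measured one year off the mating year, mirroring the fraction of
#'   pairs that need growth adjustment).
#' @return A list of class \code{population_config}.
#' @export
population_config <- function(
    n = list(reserve_m = 274, fished_m = 287, reserve_f = 51, fished_f = 46),
    mean_cl = list(reserve_m = 99, fished_m = 88, reserve_f = 97, fished_f = 92),
    cv_cl = list(reserve_m = 0.18, fished_m = 0.15, reserve_f = 0.12, fished_f = 0.11),
    claw_slope = 0.82, claw_intercept = -27, claw_sd = 6,
    b_size = 0.8, b_claw_res = 0.5,
    delta_assort = 1.2, sigma_assort = 0.15,
    p_multiple = 0.02, skew = c(0.9, 0.1), eggs_per_brood = 10,
    harvest_threshold = 90, harvest_prob = 0,
    moult_intercept = 12.36, moult_slope = -0.0996,
    growth_intercept = 18, growth_slope = -0.07, growth_sd = 1.2,
    missing_rate = 0, year = 2010,
    male_year_offsets = c(-1L, 0L, 1L),
    male_year_probs = c(0.35, 0.30, 0.35)) {
  cfg <- list(n = n, mean_cl = mean_cl, cv_cl = cv_cl,
              claw_slope = claw_slope, claw_intercept = claw_intercept,
              claw_sd = claw_sd, b_size = b_size, b_claw_res = b_claw_res,
              delta_assort = delta_assort, sigma_assort = sigma_assort,
              p_multiple = p_multiple, skew = skew,
              eggs_per_brood = eggs_per_brood,
              harvest_threshold = harvest_threshold, harvest_prob = harvest_prob,
              moult_intercept = moult_intercept, moult_slope = moult_slope,
              growth_intercept = growth_intercept, growth_slope = growth_slope,
              growth_sd = growth_sd, missing_rate = missing_rate, year = year,
              male_year_offsets = male_year_offsets,
              male_year_probs = male_year_probs)
  validate_population_config(cfg)
  structure(cfg, class = "population_config")
}

validate_population_config <- function(cfg) {
  if (any(unlist(cfg$n) <= 0)) stop("group counts must be positive")
  if (any(unlist(cfg$cv_cl) <= 0)) stop("CVs must be positive")
  if (abs(sum(cfg$skew) - 1) > 1e-9) stop("paternal skew must sum to 1")
  if (cfg$eggs_per_brood < 1) stop("eggs per brood must be >= 1")
  if (cfg$p_multiple < 0 || cfg$p_multiple > 1) stop("p_multiple must lie in [0, 1]")
  if (cfg$missing_rate < 0 || cfg$missing_rate >= 1) stop("missing_rate must lie in [0, 1)")
  if (length(cfg$male_year_offsets) != length(cfg$male_year_probs) ||
      abs(sum(cfg$male_year_probs) - 1) > 1e-9)
    stop("male capture-year probabilities must match the offsets and sum to 1")
  invisible(cfg)
}

#' Simulate the adult population
#'
#' Carapace lengths are drawn per group from a normal distribution with the
#' configured mean and CV, truncated at zero by redrawing. Fished-area
#' individuals above the harvest threshold are removed with the configured
#' probability. Male claw width follows the linear allometry with normal
#' residuals.
#'
#' @param config a [population_config()].
#' @return data.frame with columns \code{id}, \code{sex} ("M"/"F"),
#'   \code{area} ("reserve"/"fished"), \code{year} (capture year), \code{cl}
#'   (measured at capture), \code{cw} (males; \code{NA} for females) and
#'   \code{cl_mating} (true size in the mating year).
#' @export
simulate_adults <- function(config) {
  validate_population_config(config)
  groups <- list(
    c("reserve", "M", "reserve_m"), c("fished", "M", "fished_m"),
    c("reserve", "F", "reserve_f"), c("fished", "F", "fished_f"))
  out <- lapply(groups, function(g) {
    area <- g[1]; sex <- g[2]; key <- g[3]
    n <- config$n[[key]]
    mu <- config$mean_cl[[key]]
    sd <- config$cv_cl[[key]] * mu
    cl <- stats::rnorm(n, mu, sd)
    while (any(cl <= 0)) cl[cl <= 0] <- stats::rnorm(sum(cl <= 0), mu, sd)
    data.frame(sex = sex, area = area, year = config$year, cl = cl,
               stringsAsFactors = FALSE)
  })
  adults <- do.call(rbind, out)
  if (config$harvest_prob > 0) {
    drop <- adults$area == "fished" & adults$cl > config$harvest_threshold &
      stats::runif(nrow(adults)) < config$harvest_prob
    adults <- adults[!drop, , drop = FALSE]
  }
  adults$cw <- NA_real_
  m <- adults$sex == "M"
  adults$cw[m] <- config$claw_intercept + config$claw_slope * adults$cl[m] +
    stats::rnorm(sum(m), 0, config$claw_sd)
  # males are captured up to a year off the mating year; their size in the
  # mating year follows the true moult/increment process from the measured
  # size (females are captured in the mating year itself)
  adults$cl_mating <- adults$cl
  offs <- sample(config$male_year_offsets, sum(m), replace = TRUE,
                 prob = config$male_year_probs)
  adults$year[m] <- adults$year[m] + offs
  diff <- config$year - adults$year[m]   # mating year minus capture year
  p_moult <- stats::plogis(config$moult_intercept +
                             config$moult_slope * adults$cl[m])
  moulted <- stats::runif(sum(m)) < p_moult
  inc <- config$growth_intercept + config$growth_slope * adults$cl[m] +
    stats::rnorm(sum(m), 0, config$growth_sd)
  adults$cl_mating[m] <- adults$cl[m] + diff * ifelse(moulted, pmax(inc, 0), 0)
  adults$id <- sprintf("%s%04d", ifelse(adults$sex == "M", "M", "F"),
                       seq_len(nrow(adults)))
  rownames(adults) <- NULL
  adults[, c("id", "sex", "area", "year", "cl", "cw", "cl_mating")]
}

# z-scores that degrade to zeros when the group is too small or constant
zsafe <- function(x) {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) return(rep(0, length(x)))
  (x - mean(x)) / s
}

# preference weight of each male for one female: log-linear in standardized
# CL and residual claw width plus a Gaussian kernel on the size ratio
mating_weights <- function(female_cl, male_z_cl, male_z_cwres, male_cl, config) {
  lw <- config$b_size * male_z_cl + config$b_claw_res * male_z_cwres
  if (is.finite(config$sigma_assort) && config$sigma_assort > 0) {
    ratio <- male_cl / female_cl
    lw <- lw - (ratio - config$delta_assort)^2 / (2 * config$sigma_assort^2)
  }
  w <- exp(lw - max(lw))
  w / sum(w)
}

#' Simulate matings
#'
#' Each female chooses a sire among the males of her own area with
#' probability proportional to
#' \eqn{\exp(b_{size} z_{CL} + b_{claw} z_{CWres})} times a Gaussian
#' assortative kernel centred at \code{delta_assort} on the male/female CL
#' ratio. With probability \code{p_multiple} a second (distinct) sire is
#' drawn from the same weights and the brood contributions follow the
#' configured skew.
#'
#' @param adults output of [simulate_adults()].
#' @param config a [population_config()].
#' @return data.frame with one row per (mother, sire): \code{mother_id},
#'   \code{father_id}, \code{contribution}, \code{rank} (1 = primary sire).
#' @export
simulate_matings <- function(adults, config) {
  males <- adults[adults$sex == "M", , drop = FALSE]
  females <- adults[adults$sex == "F", , drop = FALSE]
  if (nrow(males) == 0) stop("male pool is empty")
  if (nrow(females) == 0) stop("no females to mate")
  rows <- list()
  for (area in unique(females$area)) {
    ma <- males[males$area == area, , drop = FALSE]
    if (nrow(ma) == 0) stop("male pool is empty in area ", area)
    fa <- females[females$area == area, , drop = FALSE]
    mcl <- if ("cl_mating" %in% names(ma)) ma$cl_mating else ma$cl
    z_cl <- zsafe(mcl)
    z_res <- if (nrow(ma) >= 3)
      zsafe(stats::resid(stats::lm(cw ~ cl, data = ma))) else rep(0, nrow(ma))
    for (i in seq_len(nrow(fa))) {
      w <- mating_weights(fa$cl[i], z_cl, z_res, mcl, config)
      n_sires <- if (stats::runif(1) < config$p_multiple &&
                     nrow(ma) >= length(config$skew)) length(config$skew) else 1L
      sires <- sample(seq_len(nrow(ma)), n_sires, replace = FALSE, prob = w)
      contrib <- if (n_sires == 1L) 1 else config$skew[seq_len(n_sires)] /
        sum(config$skew[seq_len(n_sires)])
      rows[[length(rows) + 1L]] <- data.frame(
        mother_id = fa$id[i], father_id = ma$id[sires],
        contribution = contrib, rank = seq_len(n_sires),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# apply the observation layer (dropout, false allele, missingness) to a
# true genotype matrix
observe_genotypes <- function(true, panel, missing_rate = 0) {
  obs <- true
  n <- nrow(true)
  for (l in seq_len(n_loci(panel))) {
    loc <- panel[[l]]
    cols <- locus_cols(l)
    a1 <- obs[, cols[1]]; a2 <- obs[, cols[2]]
    # allelic dropout: heterozygote observed as homozygote for one allele
    het <- a1 != a2
    drop <- het & stats::runif(n) < loc$eps1
    pick1 <- stats::runif(n) < 0.5
    a2[drop & pick1] <- a1[drop & pick1]
    a1[drop & !pick1] <- a2[drop & !pick1]
    # false allele: each allele independently replaced by a random panel allele
    for (v in 1:2) {
      a <- if (v == 1) a1 else a2
      fa <- stats::runif(n) < loc$eps2
      if (any(fa)) a[fa] <- sample(loc$alleles, sum(fa), replace = TRUE)
      if (v == 1) a1 <- a else a2 <- a
    }
    miss <- stats::runif(n) < missing_rate
    a1[miss] <- NA_integer_; a2[miss] <- NA_integer_
    obs[, cols[1]] <- a1; obs[, cols[2]] <- a2
  }
  obs
}

#' Simulate genotypes for a pedigree
#'
#' Parents receive Hardy-Weinberg genotypes from the panel; each egg inherits
#' one allele per locus from its mother and its sire uniformly at random. The
#' observation layer then applies allelic dropout (rate \code{eps1} per
#' heterozygous genotype), false alleles (rate \code{eps2} per allele,
#' replacement uniform over the panel's alleles) and missingness. True and
#' observed genotypes are both returned.
#'
#' @param adults adult table ([simulate_adults()]).
#' @param matings mating table ([simulate_matings()]).
#' @param panel a \code{locus_panel}.
#' @param config a [population_config()] (eggs per brood, missing rate).
#' @return List with \code{adult_true}, \code{adult_obs} (genotype matrices,
#'   rownames = adult ids), \code{egg_true}, \code{egg_obs} (one row per
#'   egg) and \code{eggs}: data.frame \code{egg_id}, \code{mother_id},
#'   \code{father_id} (true sire of each egg).
#' @export
simulate_genotypes <- function(adults, matings, panel, config) {
  adult_true <- sample_genotypes(panel, nrow(adults), ids = adults$id)
  mothers <- unique(matings$mother_id)
  egg_rows <- list()
  for (m in mothers) {
    sires <- matings[matings$mother_id == m, , drop = FALSE]
    counts <- as.vector(stats::rmultinom(1, config$eggs_per_brood,
                                         sires$contribution))
    fathers <- rep(sires$father_id, counts)
    egg_rows[[m]] <- data.frame(
      egg_id = sprintf("%s_e%02d", m, seq_along(fathers)),
      mother_id = m, father_id = fathers, stringsAsFactors = FALSE)
  }
  eggs <- do.call(rbind, egg_rows)
  rownames(eggs) <- NULL
  ne <- nrow(eggs)
  L <- n_loci(panel)
  egg_true <- matrix(NA_integer_, ne, 2L * L,
                     dimnames = list(eggs$egg_id, colnames(adult_true)))
  mi <- match(eggs$mother_id, adults$id)
  fi <- match(eggs$father_id, adults$id)
  if (anyNA(mi) || anyNA(fi)) stop("pedigree refers to unknown adults")
  for (l in seq_len(L)) {
    cols <- locus_cols(l)
    mpick <- stats::runif(ne) < 0.5
    fpick <- stats::runif(ne) < 0.5
    egg_true[, cols[1]] <- ifelse(mpick, adult_true[mi, cols[1]],
                                  adult_true[mi, cols[2]])
    egg_true[, cols[2]] <- ifelse(fpick, adult_true[fi, cols[1]],
                                  adult_true[fi, cols[2]])
  }
  list(adult_true = adult_true,
       adult_obs = observe_genotypes(adult_true, panel, config$missing_rate),
       egg_true = egg_true,
       egg_obs = observe_genotypes(egg_true, panel, config$missing_rate),
       eggs = eggs)
}

#' Simulate mark-recapture growth records
#'
#' Males captured in two consecutive years: the second-year carapace length
#' adds the moult increment when a Bernoulli draw from the logistic
#' moult-probability curve succeeds, and small measurement noise (truncated
#' below the moult-detection threshold) otherwise.
#'
#' @param config a [population_config()].
#' @param n number of records.
#' @param cl_range range (mm) from which first-capture CL is drawn uniformly.
#' @return data.frame with \code{id}, \code{cl1}, \code{cl2}.
#' @export
simulate_growth_records <- function(config, n = 400, cl_range = c(60, 140)) {
  cl1 <- stats::runif(n, cl_range[1], cl_range[2])
  p <- stats::plogis(config$moult_intercept + config$moult_slope * cl1)
  moulted <- stats::runif(n) < p
  inc <- config$growth_intercept + config$growth_slope * cl1 +
    stats::rnorm(n, 0, config$growth_sd)
  noise <- pmin(pmax(stats::rnorm(n, 0, 1.2), -4.5), 4.5)
  cl2 <- ifelse(moulted, cl1 + inc, cl1 + noise)
  data.frame(id = sprintf("G%04d", seq_len(n)), cl1 = cl1, cl2 = cl2)
}

#' Simulate a complete dataset
#'
#' Runs [simulate_adults()], [simulate_matings()], [simulate_genotypes()] and
#' [simulate_growth_records()] under one seed and bundles the results.
#'
#' @param config a [population_config()].
#' @param panel a \code{locus_panel} (default [lobster_panel()]).
#' @param seed integer seed; all randomness flows from it.
#' @param n_growth number of mark-recapture growth records.
#' @return A list of class \code{mating_dataset} with components
#'   \code{adults}, \code{matings}, \code{genotypes} (see
#'   [simulate_genotypes()]), \code{growth}, \code{panel}, \code{config},
#'   \code{seed}.
#' @export
simulate_dataset <- function(config = population_config(),
                             panel = lobster_panel(), seed = 1,
                             n_growth = 400) {
  set.seed(seed)
  adults <- simulate_adults(config)
  matings <- simulate_matings(adults, config)
  genotypes <- simulate_genotypes(adults, matings, panel, config)
  growth <- simulate_growth_records(config, n = n_growth)
  structure(list(adults = adults, matings = matings, genotypes = genotypes,
                 growth = growth, panel = panel, config = config,
                 seed = seed),
            class = "mating_dataset")
}

#' @export
print.mating_dataset <- function(x, ...) {
  cat("Synthetic mating dataset (seed ", x$seed, ")\n", sep = "")
  cat("  adults:", nrow(x$adults), " matings:", nrow(x$matings),
      " eggs:", nrow(x$genotypes$eggs), " growth records:",
      nrow(x$growth), "\n")
  invisible(x)
}

#' Recover mating-preference coefficients from simulated matings
#'
#' Maximum-likelihood fit of the generating choice model: each female's
#' primary sire is modelled as a draw from her area's males with probability
#' proportional to \eqn{\exp(b_{size} z_{CL} + b_{claw} z_{CWres})} times the
#' Gaussian assortative kernel. Standard errors come from the numerically
#' differentiated Hessian. Used for parameter-recovery validation of the
#' generator.
#'
#' @param adults adult table.
#' @param matings mating table (only \code{rank == 1} sires are used).
#' @param sigma_assort kernel SD, fixed at its generating value.
#' @param fit_delta logical; also estimate the kernel centre.
#' @return data.frame with \code{parameter}, \code{estimate}, \code{se},
#'   \code{lo}, \code{hi} (Wald 95\% CI).
#' @export
estimate_preference <- function(adults, matings, sigma_assort = 0.15,
                                fit_delta = TRUE) {
  males <- adults[adults$sex == "M", , drop = FALSE]
  prim <- matings[matings$rank == 1, , drop = FALSE]
  females <- adults[match(prim$mother_id, adults$id), , drop = FALSE]
  choice <- list()
  for (area in unique(females$area)) {
    ma <- males[males$area == area, , drop = FALSE]
    mcl <- if ("cl_mating" %in% names(ma)) ma$cl_mating else ma$cl
    z_cl <- zsafe(mcl)
    z_res <- zsafe(stats::resid(stats::lm(cw ~ cl, data = ma)))
    idx <- which(females$area == area)
    choice[[area]] <- list(z_cl = z_cl, z_res = z_res,
                           ratio = outer(mcl, females$cl[idx], "/"),
                           chosen = match(prim$father_id[idx], ma$id))
  }
  nll <- function(par) {
    b1 <- par[1]; b2 <- par[2]
    delta <- if (fit_delta) par[3] else NA
    tot <- 0
    for (ch in choice) {
      nf <- length(ch$chosen)
      M <- matrix(b1 * ch$z_cl + b2 * ch$z_res, length(ch$z_cl), nf)
      if (fit_delta)
        M <- M - (ch$ratio - delta)^2 / (2 * sigma_assort^2)
      cm <- apply(M, 2, max)
      lse <- cm + log(colSums(exp(sweep(M, 2, cm))))
      tot <- tot - sum(M[cbind(ch$chosen, seq_len(nf))] - lse)
    }
    tot
  }
  par0 <- if (fit_delta) c(0, 0, 1.1) else c(0, 0)
  fit <- stats::optim(par0, nll, method = "BFGS", hessian = TRUE)
  se <- sqrt(diag(solve(fit$hessian)))
  nm <- c("b_size", "b_claw_res", if (fit_delta) "delta_assort")
  data.frame(parameter = nm, estimate = fit$par, se = se,
             lo = fit$par - 1.96 * se, hi = fit$par + 1.96 * se,
             stringsAsFactors = FALSE)
}
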