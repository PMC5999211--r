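# Paternity assignment with known mothers: error-aware trio likelihoods,
# simulation-calibrated confidence thresholds, and the acceptance rules for
# multiple paternity. Mothers are known in this design, so independent
# per-egg trio likelihoods stand in for full-pedigree reconstruction.

# per-allele observation channel: P(observe x | true s) under the
# false-allele model (replacement uniform over the k panel alleles)
channel_prob <- function(s, x, eps2, k) {
  (1 - eps2) * (s == x) + eps2 / k
}

# P(observed unordered pair {x, y} | intermediate ordered pair (s, t))
pair_obs_prob <- function(s, t, x, y, eps2, k) {
  if (x != y) {
    channel_prob(s, x, eps2, k) * channel_prob(t, y, eps2, k) +
      channel_prob(s, y, eps2, k) * channel_prob(t, x, eps2, k)
  } else {
    channel_prob(s, x, eps2, k) * channel_prob(t, x, eps2, k)
  }
}

# P(observed egg pair | true genotype {u, v}) integrating dropout and
# false alleles; vectorized over v
true_to_obs_prob <- function(u, v, x, y, eps1, eps2, k) {
  pp <- function(s, t) {
    if (x != y) {
      channel_prob(s, x, eps2, k) * channel_prob(t, y, eps2, k) +
        channel_prob(s, y, eps2, k) * channel_prob(t, x, eps2, k)
    } else {
      channel_prob(s, x, eps2, k) * channel_prob(t, x, eps2, k)
    }
  }
  het <- v != u
  p_mm <- pp(u, u)
  p_uv <- pp(rep(u, length(v)), v)
  p_vv <- pp(v, v)
  ifelse(het, (1 - eps1) * p_uv + (eps1 / 2) * (p_mm + p_vv), p_mm)
}

# t-vector for one egg at one locus: t[a] = P(obs egg | mother, paternal
# allele a), averaging over the maternally transmitted allele
egg_tvec <- function(egg_pair, mother_pair, loc) {
  k <- length(loc$alleles)
  x <- egg_pair[1]; y <- egg_pair[2]
  0.5 * (true_to_obs_prob(mother_pair[1], loc$alleles, x, y,
                          loc$eps1, loc$eps2, k) +
         true_to_obs_prob(mother_pair[2], loc$alleles, x, y,
                          loc$eps1, loc$eps2, k))
}

#' Deduce paternal alleles for a brood
#'
#' For each egg and locus, returns the allele(s) of the egg not attributable
#' to the mother: if only one egg allele can be maternal, the other must be
#' paternal; if the egg shares both alleles with the mother, the paternal
#' allele is ambiguous (both retained); if neither egg allele occurs in the
#' mother, the locus is flagged as a mother mismatch.
#'
#' @param egg_geno genotype matrix of the brood's eggs (rows = eggs).
#' @param mother_geno the mother's genotype (one row of a genotype matrix).
#' @param panel the \code{locus_panel}.
#' @return List per egg of lists per locus with components \code{alleles}
#'   (integer vector, possibly empty) and \code{mismatch} (logical).
#' @export
deduce_paternal_alleles <- function(egg_geno, mother_geno, panel) {
  L <- n_loci(panel)
  lapply(seq_len(nrow(egg_geno)), function(e) {
    per_locus <- vector("list", L)
    for (l in seq_len(L)) {
      cols <- locus_cols(l)
      off <- egg_geno[e, cols]
      mom <- mother_geno[cols]
      if (anyNA(off) || anyNA(mom)) {
        per_locus[[l]] <- list(alleles = integer(0), mismatch = FALSE,
                               missing = TRUE)
        next
      }
      S <- paternal_allele_set(off, mom)
      per_locus[[l]] <- list(alleles = S, mismatch = length(S) == 0,
                             missing = FALSE)
    }
    names(per_locus) <- locus_names(panel)
    per_locus
  })
}

#' Trio log-likelihood ratio for one candidate father
#'
#' Log of P(egg | mother, candidate) over P(egg | mother, father drawn from
#' the population allele frequencies), summed over loci. The egg observation
#' model integrates allelic dropout (\code{eps1}) and false alleles
#' (\code{eps2}) over possible true genotypes; mother and candidate
#' genotypes are taken as observed. Missing loci (in the egg or both) and
#' candidate-missing loci contribute 0.
#'
#' @param egg_obs observed egg genotype (vector of 2L allele labels).
#' @param mother_obs mother genotype.
#' @param candidate_obs candidate father genotype.
#' @param panel the \code{locus_panel}.
#' @return Log-likelihood ratio (\code{-Inf} if the candidate is excluded
#'   under a zero-error model).
#' @export
paternity_loglik <- function(egg_obs, mother_obs, candidate_obs, panel) {
  tot <- 0
  for (l in seq_len(n_loci(panel))) {
    loc <- panel[[l]]
    cols <- locus_cols(l)
    if (anyNA(egg_obs[cols]) || anyNA(mother_obs[cols])) next
    tv <- egg_tvec(egg_obs[cols], mother_obs[cols], loc)
    denom <- sum(loc$freqs * tv)
    if (anyNA(candidate_obs[cols])) next
    idx <- match(candidate_obs[cols], loc$alleles)
    if (anyNA(idx)) stop("candidate allele absent from panel at ", loc$name)
    num <- 0.5 * (tv[idx[1]] + tv[idx[2]])
    tot <- tot + log(num) - log(denom)
  }
  tot
}

# log-likelihood of every candidate for one egg; candidates given as a list
# of per-locus index matrices (precomputed by candidate_index)
candidate_loglik <- function(egg_obs, mother_obs, cand_idx, panel) {
  nc <- nrow(cand_idx[[1]])
  ll <- numeric(nc)
  ll0 <- 0
  for (l in seq_len(n_loci(panel))) {
    loc <- panel[[l]]
    cols <- locus_cols(l)
    if (anyNA(egg_obs[cols]) || anyNA(mother_obs[cols])) next
    tv <- egg_tvec(egg_obs[cols], mother_obs[cols], loc)
    denom <- sum(loc$freqs * tv)
    ll0 <- ll0 + log(denom)
    i1 <- cand_idx[[l]][, 1]; i2 <- cand_idx[[l]][, 2]
    contrib <- log(0.5 * (tv[i1] + tv[i2])) # NA indices give NA -> random-father
    contrib[is.na(contrib)] <- log(denom)
    ll <- ll + contrib
  }
  list(ll = ll, ll0 = ll0)
}

# per-locus allele-index matrices for a candidate genotype matrix
candidate_index <- function(cand_geno, panel) {
  lapply(seq_len(n_loci(panel)), function(l) {
    a <- cand_geno[, locus_cols(l), drop = FALSE]
    cbind(match(a[, 1], panel[[l]]$alleles), match(a[, 2], panel[[l]]$alleles))
  })
}

# count Mendelian-mismatch loci of a candidate as father of an egg
mendel_mismatches <- function(egg_obs, mother_obs, candidate_obs, panel) {
  mm <- 0L
  for (l in seq_len(n_loci(panel))) {
    cols <- locus_cols(l)
    if (anyNA(egg_obs[cols]) || anyNA(mother_obs[cols]) ||
        anyNA(candidate_obs[cols])) next
    S <- paternal_allele_set(egg_obs[cols], mother_obs[cols])
    if (length(S) == 0) next  # mother mismatch, flagged elsewhere
    if (!any(candidate_obs[cols] %in% S)) mm <- mm + 1L
  }
  mm
}

#' Calibrate the assignment confidence threshold
#'
#' Simulates offspring whose true fathers are inside the candidate pool with
#' probability \code{sampled_fraction} (and unsampled otherwise), runs the
#' trio-likelihood assignment against a Hardy-Weinberg candidate pool of the
#' given size, and returns the smallest value of the Delta statistic (best
#' minus second-best candidate log-likelihood) at which at least
#' \code{confidence} of the assignments exceeding it are correct.
#'
#' @param panel the \code{locus_panel}.
#' @param pool_size number of candidate males.
#' @param sampled_fraction probability the true father is in the pool.
#' @param reps simulated offspring (>= 100 recommended; the calibration
#'   contract assumes >= 1000).
#' @param seed integer seed.
#' @param confidence target precision among accepted assignments
#'   (default 0.95).
#' @return List with \code{threshold} (\code{Inf} when no threshold attains
#'   the target, e.g. \code{sampled_fraction = 0}), \code{precision_at}
#'   (achieved precision), and \code{deltas} (simulated Delta/correctness
#'   table).
#' @export
calibrate_confidence <- function(panel, pool_size, sampled_fraction, reps,
                                 seed = 1, confidence = 0.95) {
  set.seed(seed)
  if (sampled_fraction <= 0)
    return(list(threshold = Inf, precision_at = NA_real_,
                deltas = data.frame(delta = numeric(0), correct = logical(0))))
  pool <- sample_genotypes(panel, pool_size,
                           ids = sprintf("P%04d", seq_len(pool_size)))
  cidx <- candidate_index(pool, panel)
  delta <- numeric(reps); correct <- logical(reps); made <- logical(reps)
  for (r in seq_len(reps)) {
    mother <- sample_genotypes(panel, 1)[1, ]
    inside <- stats::runif(1) < sampled_fraction
    father <- if (inside) {
      truth <- sample.int(pool_size, 1)
      pool[truth, ]
    } else {
      truth <- NA_integer_
      sample_genotypes(panel, 1)[1, ]
    }
    egg_true <- mendelian_offspring(mother, father, panel)
    egg_obs <- observe_genotypes(matrix(egg_true, 1), panel, 0)[1, ]
    sc <- candidate_loglik(egg_obs, mother, cidx, panel)
    o <- order(sc$ll, decreasing = TRUE)
    if (!is.finite(sc$ll[o[1]])) next
    d <- sc$ll[o[1]] - if (pool_size > 1) sc$ll[o[2]] else -Inf
    if (!is.finite(d)) d <- .Machine$double.xmax
    made[r] <- d > 0 && (sc$ll[o[1]] - sc$ll0) > 0
    delta[r] <- d
    correct[r] <- inside && !is.na(truth) && o[1] == truth
  }
  tab <- data.frame(delta = delta[made], correct = correct[made])
  if (!nrow(tab))
    return(list(threshold = Inf, precision_at = NA_real_, deltas = tab))
  tab <- tab[order(-tab$delta), , drop = FALSE]
  prec <- cumsum(tab$correct) / seq_len(nrow(tab))
  ok <- which(prec >= confidence)
  if (!length(ok))
    return(list(threshold = Inf, precision_at = max(prec), deltas = tab))
  cut <- max(ok)
  list(threshold = tab$delta[cut], precision_at = prec[cut], deltas = tab)
}

# draw one Mendelian offspring genotype from two parent genotype vectors
mendelian_offspring <- function(mother, father, panel) {
  L <- n_loci(panel)
  out <- integer(2L * L)
  for (l in seq_len(L)) {
    cols <- locus_cols(l)
    out[cols[1]] <- mother[cols][sample.int(2, 1)]
    out[cols[2]] <- father[cols][sample.int(2, 1)]
  }
  names(out) <- names(mother)
  out
}

#' Assign fathers to eggs
#'
#' For each egg, computes the trio log-likelihood of every candidate male
#' and assigns the best candidate when (i) the Delta statistic (best minus
#' second-best) reaches the calibrated threshold, (ii) the best candidate
#' beats the population-frequency (unsampled) father, and (iii) the egg
#' carries no mother-mismatch flag. Ties (Delta = 0) are never assigned.
#'
#' @param egg_obs observed egg genotype matrix.
#' @param eggs egg metadata (\code{egg_id}, \code{mother_id}).
#' @param mother_obs genotype matrix holding the mothers (rownames = ids).
#' @param cand_obs genotype matrix of candidate males (rownames = ids).
#' @param panel the \code{locus_panel}.
#' @param threshold Delta acceptance threshold from
#'   [calibrate_confidence()] (default 0 accepts any strict best).
#' @return data.frame per egg: \code{egg_id}, \code{mother_id},
#'   \code{father_id} (\code{NA} = unsampled), \code{delta}, \code{llr}
#'   (best candidate vs population father), \code{mismatches} (Mendelian
#'   mismatch loci vs the best candidate), \code{mother_mismatch} (count of
#'   mother-incompatible loci), \code{assigned}.
#' @export
assign_fathers <- function(egg_obs, eggs, mother_obs, cand_obs, panel,
                           threshold = 0) {
  cidx <- candidate_index(cand_obs, panel)
  cand_ids <- rownames(cand_obs)
  n <- nrow(eggs)
  out <- data.frame(egg_id = eggs$egg_id, mother_id = eggs$mother_id,
                    father_id = NA_character_, delta = NA_real_,
                    llr = NA_real_, mismatches = NA_integer_,
                    mother_mismatch = 0L, assigned = FALSE,
                    stringsAsFactors = FALSE)
  for (e in seq_len(n)) {
    mom <- mother_obs[eggs$mother_id[e], ]
    egg <- egg_obs[e, ]
    ped <- deduce_paternal_alleles(matrix(egg, 1), mom, panel)[[1]]
    mmm <- sum(vapply(ped, `[[`, logical(1), "mismatch"))
    out$mother_mismatch[e] <- mmm
    sc <- candidate_loglik(egg, mom, cidx, panel)
    o <- order(sc$ll, decreasing = TRUE)
    best <- o[1]
    if (!is.finite(sc$ll[best])) next
    d <- if (length(o) > 1) sc$ll[best] - sc$ll[o[2]] else Inf
    llr <- sc$ll[best] - sc$ll0
    out$delta[e] <- d
    out$llr[e] <- llr
    out$mismatches[e] <- mendel_mismatches(egg, mom, cand_obs[best, ], panel)
    if (d >= threshold && d > 0 && llr > 0 && mmm == 0) {
      out$father_id[e] <- cand_ids[best]
      out$assigned[e] <- TRUE
    }
  }
  out
}

#' Aggregate assignments into a mating list
#'
#' @param assignments output of [assign_fathers()].
#' @param adults adult table (for areas of mothers and fathers).
#' @return data.frame of distinct (mother, father) pairs with per-pair
#'   offspring counts and an \code{interarea} flag.
#' @export
mating_list <- function(assignments, adults) {
  a <- assignments[assignments$assigned, , drop = FALSE]
  if (!nrow(a))
    return(data.frame(mother_id = character(0), father_id = character(0),
                      n_offspring = integer(0), interarea = logical(0),
                      stringsAsFactors = FALSE))
  key <- paste(a$mother_id, a$father_id)
  agg <- stats::aggregate(list(n_offspring = key), by = list(key = key), FUN = length)
  parts <- do.call(rbind, strsplit(agg$key, " "))
  area <- function(id) adults$area[match(id, adults$id)]
  out <- data.frame(mother_id = parts[, 1], father_id = parts[, 2],
                    n_offspring = agg$n_offspring,
                    interarea = area(parts[, 1]) != area(parts[, 2]),
                    stringsAsFactors = FALSE)
  out[order(out$mother_id, out$father_id), , drop = FALSE]
}

#' Classify a brood as single- or multiply-sired
#'
#' The primary sire is the candidate compatible with (assigned to) most
#' eggs. The brood is accepted as multiply sired only when at least one egg
#' (i) mismatches the primary sire at \code{min_mismatch_loci} or more loci,
#' (ii) carries no mother-mismatch flag, and (iii) has the mismatching loci
#' fully observed (no missing alleles in egg or primary sire). Eggs
#' mismatching at 1 to \code{min_mismatch_loci - 1} loci make the brood
#' ambiguous rather than multiple.
#'
#' @param brood_eggs egg metadata rows of one brood.
#' @param egg_obs observed genotypes of those eggs (same order).
#' @param mother_obs the mother's genotype vector.
#' @param assignments assignment rows for those eggs.
#' @param cand_obs candidate genotype matrix.
#' @param panel the \code{locus_panel}.
#' @param min_mismatch_loci acceptance rule threshold (default 5).
#' @return List with \code{brood_id}, \code{primary}, \code{secondary}
#'   (id or \code{NA}), \code{counts} (named vector summing to brood size),
#'   \code{classification} ("single", "multiple" or "ambiguous").
#' @export
classify_brood <- function(brood_eggs, egg_obs, mother_obs, assignments,
                           cand_obs, panel, min_mismatch_loci = 5) {
  n <- nrow(brood_eggs)
  ass <- assignments[match(brood_eggs$egg_id, assignments$egg_id), ,
                     drop = FALSE]
  fathers <- ass$father_id[ass$assigned]
  if (!length(fathers)) {
    return(list(brood_id = brood_eggs$mother_id[1], primary = NA_character_,
                secondary = NA_character_,
                counts = c(primary = n, secondary = 0L),
                classification = "single"))
  }
  primary <- names(sort(table(fathers), decreasing = TRUE))[1]
  pg <- cand_obs[primary, ]
  n_evidence <- 0L; n_ambig <- 0L
  secondary <- NA_character_
  for (e in seq_len(n)) {
    if (identical(ass$father_id[e], primary)) next
    egg <- egg_obs[e, ]
    mm <- mendel_mismatches(egg, mother_obs, pg, panel)
    if (mm == 0) next
    mom_mm <- ass$mother_mismatch[e] > 0
    loci_observed <- mismatch_loci_observed(egg, mother_obs, pg, panel)
    if (mm >= min_mismatch_loci && !mom_mm && loci_observed) {
      n_evidence <- n_evidence + 1L
      if (ass$assigned[e]) secondary <- ass$father_id[e]
    } else {
      n_ambig <- n_ambig + 1L
    }
  }
  classification <- if (n_evidence >= 1) "multiple"
    else if (n_ambig >= 1) "ambiguous" else "single"
  list(brood_id = brood_eggs$mother_id[1], primary = primary,
       secondary = secondary,
       counts = c(primary = n - n_evidence, secondary = n_evidence),
       classification = classification)
}

# TRUE when every locus mismatching the primary sire is fully observed in
# the egg (no imputed/missing alleles back the evidence)
mismatch_loci_observed <- function(egg, mother, primary, panel) {
  for (l in seq_len(n_loci(panel))) {
    cols <- locus_cols(l)
    if (anyNA(mother[cols]) || anyNA(primary[cols])) next
    if (anyNA(egg[cols])) return(FALSE)
  }
  TRUE
}

#' Classify all broods
#'
#' @param eggs egg metadata table.
#' @param egg_obs observed egg genotypes (rows aligned with \code{eggs}).
#' @param mother_obs mothers' genotype matrix.
#' @param assignments output of [assign_fathers()].
#' @param cand_obs candidate genotype matrix.
#' @param panel the \code{locus_panel}.
#' @param min_mismatch_loci acceptance-rule threshold (default 5).
#' @return data.frame per brood with \code{brood_id}, \code{primary},
#'   \code{secondary}, \code{n_primary}, \code{n_secondary},
#'   \code{classification}.
#' @export
classify_broods <- function(eggs, egg_obs, mother_obs, assignments, cand_obs,
                            panel, min_mismatch_loci = 5) {
  mothers <- unique(eggs$mother_id)
  rows <- lapply(mothers, function(m) {
    idx <- which(eggs$mother_id == m)
    cl <- classify_brood(eggs[idx, , drop = FALSE],
                         egg_obs[idx, , drop = FALSE],
                         mother_obs[m, ], assignments, cand_obs, panel,
                         min_mismatch_loci)
    data.frame(brood_id = cl$brood_id, primary = cl$primary,
               secondary = cl$secondary,
               n_primary = cl$counts[["primary"]],
               n_secondary = cl$counts[["secondary"]],
               classification = cl$classification, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
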