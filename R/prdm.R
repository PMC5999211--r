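# Monte-Carlo power to detect multiple paternity (prDM) for a locus panel,
# brood size and sire-contribution skew. Detection is error-free Mendelian
# incompatibility with any single father, which keeps the brute-force
# oracle exact.

# can the per-egg paternal allele sets at one locus be covered by some
# father genotype (at most 2 alleles)? sets: list of integer vectors
cover_by_two <- function(sets) {
  sets <- sets[lengths(sets) > 0]
  if (!length(sets)) return(TRUE)
  singles <- unique(unlist(sets[lengths(sets) == 1]))
  if (length(singles) > 2) return(FALSE)
  if (length(singles) == 2) {
    for (s in sets) if (!any(s %in% singles)) return(FALSE)
    return(TRUE)
  }
  cand <- unique(unlist(sets))
  if (length(cand) <= 2) return(TRUE)
  # try all unordered pairs of candidate alleles
  for (i in seq_along(cand)) for (j in i:length(cand)) {
    pair <- c(cand[i], cand[j])
    ok <- TRUE
    for (s in sets) if (!any(s %in% pair)) { ok <- FALSE; break }
    if (ok) return(TRUE)
  }
  FALSE
}

#' Detect multiple paternity in a brood
#'
#' TRUE when no single father genotype is Mendelian-compatible with all
#' eggs: i.e. at some locus the per-egg deduced paternal allele sets cannot
#' be jointly covered by any two alleles. Because a father's genotypes at
#' different loci are independent, the joint single-father check decomposes
#' into a per-locus two-allele covering problem.
#'
#' @param egg_geno genotype matrix of the brood's eggs.
#' @param mother_geno the mother's genotype vector.
#' @param panel the \code{locus_panel}.
#' @return Logical.
#' @export
detect_multiple <- function(egg_geno, mother_geno, panel) {
  ped <- deduce_paternal_alleles(egg_geno, mother_geno, panel)
  for (l in seq_len(n_loci(panel))) {
    sets <- lapply(ped, function(e) e[[l]]$alleles)
    # mother-mismatching or missing loci carry no usable paternal set
    usable <- vapply(ped, function(e)
      !e[[l]]$mismatch && !e[[l]]$missing, logical(1))
    if (!cover_by_two(sets[usable])) return(TRUE)
  }
  FALSE
}

#' Monte-Carlo probability of detecting multiple paternity
#'
#' Simulates a mother and the given number of sires from the panel's allele
#' frequencies (Hardy-Weinberg), draws \code{n_eggs} eggs with sires chosen
#' multinomially by the contribution vector, and applies [detect_multiple()].
#' The sampling bound \eqn{1 - \sum_k c_k^n} (all eggs from one sire are
#' undetectable) dominates the genetic detectability for any panel.
#'
#' @param panel the \code{locus_panel}.
#' @param n_eggs brood size.
#' @param contributions sire contribution vector (sums to 1); a single sire
#'   short-circuits to 0.
#' @param reps Monte-Carlo replicates.
#' @param seed integer seed; results are deterministic given the seed.
#' @return List of class \code{power_result}: \code{prdm} (detection
#'   probability), \code{se} (binomial Monte-Carlo standard error),
#'   \code{reps}, \code{n_eggs}, \code{contributions},
#'   \code{sampling_bound}.
#' @export
prdm <- function(panel, n_eggs = 10, contributions = c(0.5, 0.5),
                 reps = 10000, seed = 1) {
  if (n_eggs < 1) stop("brood size must be >= 1")
  if (reps < 1) stop("replicates must be >= 1")
  if (any(contributions < 0) || abs(sum(contributions) - 1) > 1e-9)
    stop("contributions must be non-negative and sum to 1")
  bound <- 1 - sum(contributions^n_eggs)
  if (length(contributions) == 1)
    return(structure(list(prdm = 0, se = 0, reps = reps, n_eggs = n_eggs,
                          contributions = contributions, sampling_bound = 0),
                     class = "power_result"))
  set.seed(seed)
  L <- n_loci(panel)
  ns <- length(contributions)
  hits <- 0L
  for (r in seq_len(reps)) {
    sire_of_egg <- sample.int(ns, n_eggs, replace = TRUE,
                              prob = contributions)
    if (length(unique(sire_of_egg)) < 2) next  # sampling bound: undetectable
    detected <- FALSE
    for (l in seq_len(L)) {
      loc <- panel[[l]]
      mom <- sample(loc$alleles, 2, replace = TRUE, prob = loc$freqs)
      sires <- matrix(sample(loc$alleles, 2 * ns, replace = TRUE,
                             prob = loc$freqs), ns, 2)
      mat <- mom[sample.int(2, n_eggs, replace = TRUE)]
      pat <- sires[cbind(sire_of_egg, sample.int(2, n_eggs, replace = TRUE))]
      sets <- lapply(seq_len(n_eggs), function(e)
        paternal_allele_set(c(mat[e], pat[e]), mom))
      if (!cover_by_two(sets)) { detected <- TRUE; break }
    }
    if (detected) hits <- hits + 1L
  }
  p <- hits / reps
  structure(list(prdm = p, se = sqrt(p * (1 - p) / reps), reps = reps,
                 n_eggs = n_eggs, contributions = contributions,
                 sampling_bound = bound),
            class = "power_result")
}

#' @export
print.power_result <- function(x, ...) {
  cat(sprintf("prDM = %.4f (SE %.4f, %d reps; n = %d, skew %s; bound %.4f)\n",
              x$prdm, x$se, x$reps, x$n_eggs,
              paste(round(x$contributions, 3), collapse = ":"),
              x$sampling_bound))
  invisible(x)
}

#' Detection-power table over brood sizes and skews
#'
#' @param panel the \code{locus_panel}.
#' @param n_values integer vector of brood sizes.
#' @param skews list of contribution vectors.
#' @param reps Monte-Carlo replicates per cell.
#' @param seed integer seed (each cell uses a sub-seed derived from it).
#' @return data.frame with one row per (n, skew): \code{n_eggs},
#'   \code{skew}, \code{prdm}, \code{se}, \code{sampling_bound}.
#' @export
skew_table <- function(panel, n_values, skews, reps = 2000, seed = 1) {
  rows <- list()
  cell <- 0L
  for (n in n_values) for (s in skews) {
    cell <- cell + 1L
    r <- prdm(panel, n_eggs = n, contributions = s, reps = reps,
              seed = seed + cell)
    rows[[cell]] <- data.frame(
      n_eggs = n, skew = paste(round(s, 3), collapse = ":"),
      prdm = r$prdm, se = r$se, sampling_bound = r$sampling_bound,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
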