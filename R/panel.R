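#' Construct a microsatellite locus panel
#'
#' A locus panel bundles, for each microsatellite locus, the allele labels
#' (integer fragment lengths), their population frequencies, and the two
#' genotyping-error rates used throughout the package: the allelic-dropout
#' rate \code{eps1} (a heterozygote observed as a homozygote) and the
#' false-allele rate \code{eps2} (an allele replaced by a random panel
#' allele).
#'
#' @param names character vector of locus names.
#' @param alleles list of integer vectors, one per locus, giving allele labels.
#' @param freqs list of numeric vectors, one per locus; each must sum to 1.
#' @param eps1 numeric vector of allelic-dropout rates, recycled to the
#'   number of loci. Must lie in \code{[0, 0.5)}.
#' @param eps2 numeric vector of false-allele rates, recycled likewise.
#'
#' @return An object of class \code{locus_panel}: a list with one element per
#'   locus, each a list with components \code{name}, \code{alleles},
#'   \code{freqs}, \code{eps1}, \code{eps2}.
#' @export
#' @examples
#' locus_panel("L1", list(c(100L, 102L)), list(c(0.5, 0.5)))
locus_panel <- function(names, alleles, freqs, eps1 = 0, eps2 = 0) {
  L <- length(names)
  stopifnot(length(alleles) == L, length(freqs) == L)
  eps1 <- rep_len(eps1, L)
  eps2 <- rep_len(eps2, L)
  loci <- vector("list", L)
  for (l in seq_len(L)) {
    a <- as.integer(alleles[[l]])
    f <- as.numeric(freqs[[l]])
    if (length(a) != length(f))
      stop("locus ", names[l], ": allele and frequency vectors differ in length")
    if (anyDuplicated(a))
      stop("locus ", names[l], ": duplicated allele labels")
    if (any(f < 0) || abs(sum(f) - 1) > 1e-9)
      stop("locus ", names[l], ": frequencies must be non-negative and sum to 1")
    if (eps1[l] < 0 || eps1[l] >= 0.5 || eps2[l] < 0 || eps2[l] >= 0.5)
      stop("locus ", names[l], ": error rates must lie in [0, 0.5)")
    loci[[l]] <- list(name = names[l], alleles = a, freqs = f,
                      eps1 = eps1[l], eps2 = eps2[l])
  }
  names(loci) <- names
  structure(loci, class = "locus_panel")
}

#' @export
print.locus_panel <- function(x, ...) {
  cat("Locus panel with", length(x), "loci\n")
  for (l in x) {
    he <- 1 - sum(l$freqs^2)
    cat(sprintf("  %-8s k=%2d  He=%.3f  eps1=%.3f eps2=%.3f\n",
                l$name, length(l$alleles), he, l$eps1, l$eps2))
  }
  invisible(x)
}

#' Number and names of panel loci
#' @param panel a \code{locus_panel}.
#' @return \code{n_loci}: integer count; \code{locus_names}: character vector.
#' @export
n_loci <- function(panel) length(panel)

#' @rdname n_loci
#' @export
locus_names <- function(panel)
  unname(vapply(panel, `[[`, character(1), "name"))

#' Build a panel matching target allele counts and heterozygosities
#'
#' For each locus, allele frequencies are taken as a geometric series over
#' \code{n_alleles} alleles, with the series ratio tuned by bisection so that
#' the expected heterozygosity \eqn{1 - \sum p_i^2} matches the target
#' \code{he} (within \code{tol}). A ratio of 1 gives equifrequent alleles and
#' the maximum attainable heterozygosity \eqn{1 - 1/k}; smaller ratios give
#' more skewed frequencies and lower heterozygosity. The tuning is
#' deterministic.
#'
#' @param n_alleles integer vector of allele counts per locus.
#' @param he numeric vector of target expected heterozygosities.
#' @param names optional locus names (default \code{L1, L2, ...}).
#' @param eps1,eps2 genotyping-error rates passed to [locus_panel()].
#' @param tol bisection tolerance on heterozygosity (default 1e-4,
#'   comfortably below the 0.005 matching requirement).
#' @return A \code{locus_panel}.
#' @export
panel_from_summary <- function(n_alleles, he, names = NULL,
                               eps1 = 0, eps2 = 0, tol = 1e-4) {
  L <- length(n_alleles)
  stopifnot(length(he) == L)
  if (is.null(names)) names <- paste0("L", seq_len(L))
  alleles <- freqs <- vector("list", L)
  for (l in seq_len(L)) {
    k <- n_alleles[l]
    if (he[l] >= 1 - 1/k)
      stop("locus ", names[l], ": target He ", he[l],
           " unattainable with ", k, " alleles (max ", 1 - 1/k, ")")
    f <- geometric_freqs(k, he[l], tol)
    alleles[[l]] <- 100L + 2L * seq_len(k)  # dinucleotide-style fragment lengths
    freqs[[l]] <- f
  }
  locus_panel(names, alleles, freqs, eps1, eps2)
}

# geometric frequency series p_i proportional to r^(i-1), ratio r found by
# bisection so expected heterozygosity matches the target
geometric_freqs <- function(k, he_target, tol = 1e-4) {
  he_of <- function(r) {
    p <- r^(0:(k - 1))
    p <- p / sum(p)
    1 - sum(p^2)
  }
  lo <- 1e-6; hi <- 1
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (he_of(mid) < he_target) lo <- mid else hi <- mid
    if (abs(he_of(mid) - he_target) < tol) break
  }
  r <- (lo + hi) / 2
  p <- r^(0:(k - 1))
  p / sum(p)
}

#' Reference locus summary for the study panel
#'
#' Published per-locus summary statistics for the ten microsatellite loci
#' used in the lobster parentage study: allele counts, observed and expected
#' heterozygosity, second-parent exclusion probability, inbreeding
#' coefficient, null-allele frequency and genotyping-error rates. These
#' printed values parameterize the default synthetic panel and serve as
#' reference inputs for power and exclusion calculations.
#'
#' @return A data.frame with one row per locus and columns \code{locus},
#'   \code{n_alleles}, \code{ho}, \code{he}, \code{exp} (second-parent
#'   exclusion probability), \code{fis}, \code{f_null}, \code{eps1},
#'   \code{eps2}.
#' @export
lobster_locus_table <- function() {
  data.frame(
    locus = c("C118", "D106", "D111", "C131", "C120",
              "C111", "A8", "B4", "B6", "C129"),
    n_alleles = c(9L, 9L, 12L, 13L, 19L, 9L, 14L, 9L, 11L, 14L),
    ho   = c(0.619, 0.703, 0.645, 0.806, 0.844, 0.725, 0.712, 0.606, 0.738, 0.706),
    he   = c(0.587, 0.709, 0.631, 0.830, 0.870, 0.735, 0.818, 0.606, 0.818, 0.779),
    exp  = c(0.370, 0.494, 0.405, 0.669, 0.745, 0.529, 0.661, 0.399, 0.646, 0.582),
    fis  = c(-0.060, 0.013, -0.024, 0.025, 0.009, 0.021, 0.116, -0.004, 0.001, 0.096),
    f_null = c(-0.031, 0.012, -0.012, 0.012, 0.008, 0.001, 0.062, 0.001, 0.044, 0.040),
    eps1 = c(0.013, 0.012, 0.000, 0.012, 0.023, 0.001, 0.062, 0.006, 0.044, 0.040),
    eps2 = c(0.010, 0.010, 0.010, 0.023, 0.013, 0.018, 0.010, 0.010, 0.010, 0.010),
    stringsAsFactors = FALSE
  )
}

#' Default ten-locus lobster panel
#'
#' Builds a \code{locus_panel} whose allele counts, expected heterozygosities
#' and error rates match the published summary of the study loci (see
#' [lobster_locus_table()]). Allele frequencies are a deterministic geometric
#' series per locus tuned to the target heterozygosity.
#'
#' @param with_errors logical; if \code{FALSE}, error rates are set to zero.
#' @return A \code{locus_panel} with ten loci.
#' @export
lobster_panel <- function(with_errors = TRUE) {
  tab <- lobster_locus_table()
  panel_from_summary(tab$n_alleles, tab$he, names = tab$locus,
                     eps1 = if (with_errors) tab$eps1 else 0,
                     eps2 = if (with_errors) tab$eps2 else 0)
}

#' Draw Hardy-Weinberg genotypes from a panel
#'
#' @param panel a \code{locus_panel}.
#' @param n number of individuals.
#' @param ids optional row names.
#' @return Integer matrix, \code{n} rows and two columns per locus named
#'   \code{<locus>.1}, \code{<locus>.2}, holding allele labels.
#' @export
sample_genotypes <- function(panel, n, ids = NULL) {
  L <- length(panel)
  g <- matrix(NA_integer_, n, 2L * L)
  cn <- character(2L * L)
  for (l in seq_len(L)) {
    loc <- panel[[l]]
    g[, 2L * l - 1L] <- sample(loc$alleles, n, replace = TRUE, prob = loc$freqs)
    g[, 2L * l]      <- sample(loc$alleles, n, replace = TRUE, prob = loc$freqs)
    cn[c(2L * l - 1L, 2L * l)] <- paste0(loc$name, c(".1", ".2"))
  }
  colnames(g) <- cn
  if (!is.null(ids)) rownames(g) <- ids
  g
}

# column indices of one locus in a genotype matrix
locus_cols <- function(l) c(2L * l - 1L, 2L * l)
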