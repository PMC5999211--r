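# shared fixtures: tiny panels and small simulated datasets built in code

# two-locus panel with simple frequencies, no genotyping error
tiny_panel <- function(eps1 = 0, eps2 = 0) {
  locus_panel(c("LA", "LB"),
              alleles = list(c(100L, 102L, 104L), c(200L, 202L)),
              freqs = list(c(0.5, 0.3, 0.2), c(0.6, 0.4)),
              eps1 = eps1, eps2 = eps2)
}

# k equifrequent alleles at a single locus
equi_panel <- function(k, eps1 = 0, eps2 = 0) {
  locus_panel("EQ", alleles = list(100L + 2L * seq_len(k)),
              freqs = list(rep(1 / k, k)), eps1 = eps1, eps2 = eps2)
}

# ten nearly perfectly informative loci (32 near-equifrequent alleles each):
# parental genotypes are almost surely four distinct alleles per locus
informative_panel <- function(n_loci = 10) {
  k <- 32L
  locus_panel(paste0("I", seq_len(n_loci)),
              alleles = rep(list(100L + 2L * seq_len(k)), n_loci),
              freqs = rep(list(rep(1 / k, k)), n_loci))
}

# small population configuration for fast end-to-end runs
small_config <- function(...) {
  population_config(
    n = list(reserve_m = 60, fished_m = 60, reserve_f = 15, fished_f = 15),
    ...)
}

# brute-force single-father compatibility: for every locus, search all
# father genotypes over the panel's alleles; independent of the package's
# covering logic
brute_single_father_ok <- function(egg_geno, mother_geno, panel) {
  for (l in seq_len(n_loci(panel))) {
    loc <- panel[[l]]
    cols <- c(2 * l - 1, 2 * l)
    k <- length(loc$alleles)
    found <- FALSE
    for (i in seq_len(k)) for (j in i:k) {
      fa <- c(loc$alleles[i], loc$alleles[j])
      ok <- TRUE
      for (e in seq_len(nrow(egg_geno))) {
        off <- egg_geno[e, cols]
        mom <- mother_geno[cols]
        # offspring explained if one allele is maternal and the other paternal
        expl <- (off[1] %in% mom && off[2] %in% fa) ||
                (off[2] %in% mom && off[1] %in% fa)
        if (!expl) { ok <- FALSE; break }
      }
      if (ok) { found <- TRUE; break }
    }
    if (!found) return(FALSE)
  }
  TRUE
}

# builds a per-egg assignment fixture carrying prescribed bookkeeping
# counts: offspring and assignments per area, distinct fathers, matings
# split by father area
bookkeeping_fixture <- function() {
  # 51 reserve + 46 fished mothers, 10 eggs each: 510 + 457 offspring
  # (three fished broods hold 9 eggs to land on 457)
  mothers <- c(sprintf("RF%02d", 1:51), sprintf("FF%02d", 1:46))
  m_area <- rep(c("reserve", "fished"), c(51, 46))
  brood_n <- c(rep(10, 51), rep(10, 43), rep(9, 3))
  # 54 mated mothers, 43 distinct fathers: 36 reserve matings by 27 males
  # (3 with three mates, 3 with two), 18 fished matings by 16 males (2 with
  # two mates) - the study's polygamy structure
  res_fathers <- sprintf("RM%02d", 1:27)
  res_seq <- c(rep(res_fathers[1:3], 3), rep(res_fathers[4:6], 2),
               res_fathers[7:27])                             # 36 matings
  fis_fathers <- sprintf("FM%02d", 1:16)
  fis_seq <- c(rep(fis_fathers[1:2], 2), fis_fathers[3:16])   # 18 matings
  father_of <- c(res_seq, rep(NA, 15), fis_seq, rep(NA, 28))
  # assigned eggs per area: 353 reserve, 158 fished
  eggs_assigned_res <- c(rep(10, 35), 3)            # 36 broods -> 353
  eggs_assigned_fis <- c(rep(9, 17), 5)             # 18 broods -> 158
  rows <- list()
  k <- 0
  for (i in seq_along(mothers)) {
    n <- brood_n[i]
    fa <- father_of[i]
    n_ass <- if (is.na(fa)) 0 else if (m_area[i] == "reserve")
      eggs_assigned_res[sum(!is.na(father_of[1:i][m_area[1:i] == "reserve"]))]
      else eggs_assigned_fis[sum(!is.na(father_of[1:i][m_area[1:i] == "fished"]))]
    for (e in seq_len(n)) {
      k <- k + 1
      rows[[k]] <- data.frame(
        egg_id = sprintf("%s_e%02d", mothers[i], e), mother_id = mothers[i],
        father_id = if (e <= n_ass) fa else NA_character_,
        assigned = e <= n_ass, stringsAsFactors = FALSE)
    }
  }
  assignments <- do.call(rbind, rows)
  adults <- data.frame(
    id = c(mothers, res_fathers, fis_fathers),
    area = c(m_area, rep("reserve", 27), rep("fished", 16)),
    stringsAsFactors = FALSE)
  candidates <- c(res_fathers, fis_fathers,
                  sprintf("XM%03d", seq_len(561 - 43)))
  brood_class <- data.frame(
    brood_id = mothers,
    classification = c(rep("multiple", 2), rep("single", 95)),
    stringsAsFactors = FALSE)
  list(assignments = assignments, adults = adults, candidates = candidates,
       brood_class = brood_class)
}
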