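# Orchestration: simulate -> QC -> assign -> power -> adjust -> select,
# as one reproducible run with a consolidated report.

#' Pipeline run configuration
#'
#' Bundles the simulation configuration, the locus panel, the analysis
#' thresholds (all defaulting to the study's rules: exclusion at >= 5
#' missing loci, 5 mm moult detection, 80 mm candidate maturity cut, 95\%
#' assignment confidence, >= 5 mismatching loci to accept multiple
#' paternity) and the replicate counts of the stochastic stages.
#'
#' @param sim a [population_config()].
#' @param panel a \code{locus_panel}.
#' @param seed integer seed for the whole run.
#' @param max_missing missing-loci exclusion threshold.
#' @param moult_mm moult-detection threshold (mm).
#' @param candidate_min_cl minimum candidate male carapace length (mm).
#' @param confidence assignment confidence level.
#' @param min_mismatch_loci multiple-paternity acceptance rule (loci).
#' @param calib_reps,calib_fraction replicates and assumed sampled-father
#'   fraction for the confidence calibration.
#' @param prdm_reps Monte-Carlo replicates for the power stage.
#' @param fst_permutations permutations for the differentiation test.
#' @param mating_year_only restrict gradient models to males captured in
#'   the mating year.
#' @param out_dir optional directory; when set, every stage writes its
#'   table as tab-separated text.
#' @return List of class \code{run_config}.
#' @export
run_config <- function(sim = population_config(), panel = lobster_panel(),
                       seed = 1, max_missing = 5, moult_mm = 5,
                       candidate_min_cl = 80, confidence = 0.95,
                       min_mismatch_loci = 5, calib_reps = 500,
                       calib_fraction = 0.5, prdm_reps = 2000,
                       fst_permutations = 200, mating_year_only = TRUE,
                       out_dir = NULL) {
  structure(list(sim = sim, panel = panel, seed = seed,
                 max_missing = max_missing, moult_mm = moult_mm,
                 candidate_min_cl = candidate_min_cl,
                 confidence = confidence,
                 min_mismatch_loci = min_mismatch_loci,
                 calib_reps = calib_reps, calib_fraction = calib_fraction,
                 prdm_reps = prdm_reps, fst_permutations = fst_permutations,
                 mating_year_only = mating_year_only, out_dir = out_dir),
            class = "run_config")
}

write_stage <- function(tab, name, out_dir) {
  if (is.null(out_dir)) return(invisible(NULL))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  utils::write.table(tab, file.path(out_dir, paste0(name, ".tsv")),
                     sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Build the mated-pair table
#'
#' Joins the mating list with female sizes and growth-adjusted male sizes:
#' each male's measured carapace length is adjusted to the female's mating
#' year with [adjust_cl()]. Males mated to several females appear once per
#' pair. Interarea pairs are flagged (and excluded downstream).
#'
#' @param matings mating list ([mating_list()] output or the true mating
#'   table).
#' @param adults adult table.
#' @param model fitted \code{growth_model}.
#' @param mating_year the year females mated.
#' @return data.frame with \code{mother_id}, \code{father_id},
#'   \code{female_cl}, \code{male_cl_measured}, \code{male_cl} (adjusted),
#'   \code{year_diff}, \code{area} (female's), \code{interarea}.
#' @export
make_pairs <- function(matings, adults, model, mating_year) {
  fi <- match(matings$father_id, adults$id)
  mi <- match(matings$mother_id, adults$id)
  year_diff <- mating_year - adults$year[fi]
  data.frame(
    mother_id = matings$mother_id, father_id = matings$father_id,
    female_cl = adults$cl[mi],
    male_cl_measured = adults$cl[fi],
    male_cl = adjust_cl(adults$cl[fi], year_diff, model),
    year_diff = year_diff,
    area = adults$area[mi],
    interarea = adults$area[mi] != adults$area[fi],
    stringsAsFactors = FALSE)
}

#' Summarize assignments into the bookkeeping table
#'
#' Per-area and pooled counts with percentages: offspring assigned a known
#' father, distinct fathers among the candidates, known matings and their
#' area split (by the father's area), polygamous males, multiply-sired
#' broods, interarea pairs, and mean mates per female (sampled fathers
#' only, and including one inferred unsampled father for any brood whose
#' eggs are all unassigned).
#'
#' @param assignments per-egg assignment table with at least
#'   \code{mother_id}, \code{assigned}, \code{father_id}.
#' @param adults adult table (areas for mothers and fathers).
#' @param candidates character vector of candidate male ids.
#' @param brood_class optional [classify_broods()] output.
#' @return List of class \code{mating_summary}; numeric entries are
#'   percentages where named \code{*_pct} (rounded to 1 decimal).
#' @export
summarize_matings <- function(assignments, adults, candidates,
                              brood_class = NULL) {
  area_of <- function(id) adults$area[match(id, adults$id)]
  m_area <- area_of(assignments$mother_id)
  n_off <- c(table(factor(m_area, levels = c("reserve", "fished"))))
  ass <- assignments$assigned
  n_ass <- c(table(factor(m_area[ass], levels = c("reserve", "fished"))))
  pairs <- unique(assignments[ass, c("mother_id", "father_id")])
  fathers <- unique(pairs$father_id)
  f_area <- area_of(pairs$father_id)
  reserve_matings <- sum(f_area == "reserve")
  poly <- table(pairs$father_id)
  poly_ids <- names(poly)[poly > 1]
  interarea <- sum(area_of(pairs$mother_id) != f_area)
  mates_per_female <- if (nrow(pairs)) mean(table(pairs$mother_id)) else 0
  # alternative definition: every brood has at least one (possibly
  # unsampled) father
  mothers <- unique(assignments$mother_id)
  n_per_mother <- vapply(mothers, function(m)
    max(1, length(unique(pairs$father_id[pairs$mother_id == m]))), numeric(1))
  n_multiple <- if (!is.null(brood_class))
    sum(brood_class$classification == "multiple") else NA_integer_
  n_broods <- if (!is.null(brood_class)) nrow(brood_class)
    else length(mothers)
  pct <- function(a, b) round(100 * a / b, 1)
  structure(list(
    n_offspring = sum(n_off), n_offspring_by_area = n_off,
    n_assigned = sum(n_ass), n_assigned_by_area = n_ass,
    assigned_pct = pct(sum(n_ass), sum(n_off)),
    assigned_pct_by_area = pct(n_ass, n_off),
    n_candidates = length(candidates),
    n_fathers = length(fathers),
    fathers_pct = pct(length(fathers), length(candidates)),
    n_matings = nrow(pairs),
    n_matings_reserve = reserve_matings,
    reserve_matings_pct = pct(reserve_matings, nrow(pairs)),
    n_polygamous = length(poly_ids),
    polygamous_by_area = c(table(factor(area_of(poly_ids),
                                        levels = c("reserve", "fished")))),
    n_interarea = interarea,
    n_broods = n_broods, n_multiple = n_multiple,
    multiple_pct = if (is.na(n_multiple)) NA_real_ else pct(n_multiple, n_broods),
    mates_per_female_sampled = mates_per_female,
    mates_per_female_all = mean(n_per_mother)),
    class = "mating_summary")
}

#' @export
print.mating_summary <- function(x, ...) {
  cat("Assignment summary\n")
  cat(sprintf("  offspring assigned: %d / %d (%.1f%%)\n",
              x$n_assigned, x$n_offspring, x$assigned_pct))
  cat(sprintf("  fathers: %d / %d candidates (%.1f%%)\n",
              x$n_fathers, x$n_candidates, x$fathers_pct))
  cat(sprintf("  known matings: %d (reserve share %.1f%%)\n",
              x$n_matings, x$reserve_matings_pct))
  if (!is.na(x$n_multiple))
    cat(sprintf("  multiply-sired broods: %d / %d (%.1f%%)\n",
                x$n_multiple, x$n_broods, x$multiple_pct))
  invisible(x)
}

#' Selection tables for one run
#'
#' Standardized selection differentials per area (candidates filtered to
#' the maturity cut before standardization), the AICc-ranked logistic
#' model set, and Janzen-Stern gradients (with mean-standardized values
#' for the absolute traits) from the top-ranked converged model and the
#' univariate fits.
#'
#' @param adults adult table.
#' @param assignments per-egg assignment table.
#' @param config a [run_config()].
#' @return List with \code{differentials} (data.frame), \code{model_table},
#'   \code{gradients} (data.frame), \code{fits}.
#' @export
selection_tables <- function(adults, assignments, config) {
  males <- adults[adults$sex == "M" & adults$cl >= config$candidate_min_cl, ,
                  drop = FALSE]
  sires <- unique(assignments$father_id[assignments$assigned])
  males$success <- males$id %in% sires
  # differentials per area and pooled, on CL and CW
  rows <- list()
  for (ar in c("reserve", "fished", "pooled")) {
    sub <- if (ar == "pooled") males else males[males$area == ar, , drop = FALSE]
    if (nrow(sub) < 3 || !any(sub$success)) next
    for (trait in c("cl", "cw")) {
      z <- standardize(sub[[trait]],
                       if (ar == "pooled") sub$area else rep(1, nrow(sub)))
      sd_ <- selection_differential(z, sub$success)
      rows[[paste(ar, trait)]] <- data.frame(
        area = ar, trait = toupper(trait), S = sd_$S, p = sd_$p,
        n = sd_$n, n_success = sd_$n_success, stringsAsFactors = FALSE)
    }
  }
  differentials <- do.call(rbind, rows)
  rownames(differentials) <- NULL
  # gradient models on the mating-year cohort
  grad_males <- if (config$mating_year_only)
    males[adults$year[match(males$id, adults$id)] == config$sim$year, ,
          drop = FALSE] else males
  # area groups too small to standardize within are dropped
  keep_area <- names(which(table(grad_males$area) >= 5))
  grad_males <- grad_males[grad_males$area %in% keep_area, , drop = FALSE]
  gradients <- NULL; model_table <- NULL; fits <- NULL
  if (nrow(grad_males) >= 20 && any(grad_males$success) &&
      !all(grad_males$success)) {
    grad_males$z_cl <- standardize(grad_males$cl, grad_males$area)
    grad_males$z_cw <- standardize(grad_males$cw, grad_males$area)
    grad_males$z_cwres <- standardize(residual_claw(grad_males$cw,
                                                    grad_males$cl),
                                      grad_males$area)
    ms <- fit_selection_models(grad_males)
    model_table <- ms$table
    fits <- ms$fits
    grads <- list()
    top <- ms$table$model[ms$table$converged][1]
    for (nm in unique(c(top, "CL", "CW", "CWres"))) {
      f <- ms$fits[[nm]]
      if (is.null(f) || !f$converged) next
      bg <- janzen_stern_gradient(f)
      for (term in names(bg)) {
        trait <- switch(term, z_cl = "CL", z_cw = "CW", z_cwres = "CW_res",
                        NA_character_)
        if (is.na(trait)) next
        raw <- switch(trait, CL = grad_males$cl, CW = grad_males$cw,
                      CW_res = NULL)
        bmu <- if (is.null(raw)) NA_real_ else
          mean_standardized_gradient(bg[[term]], mean(raw),
                                     stats::sd(raw), trait)
        sm <- summary(f)$coefficients
        grads[[paste(nm, term)]] <- data.frame(
          model = nm, trait = trait, b = sm[term, 1], se = sm[term, 2],
          z = sm[term, 3], p = sm[term, 4],
          beta_avggrad = unname(bg[[term]]), beta_mu = bmu,
          stringsAsFactors = FALSE)
      }
    }
    gradients <- do.call(rbind, grads)
    rownames(gradients) <- NULL
  }
  list(differentials = differentials, model_table = model_table,
       gradients = gradients, fits = fits)
}

#' Run the full pipeline
#'
#' Executes simulate, QC, assignment, multiple-paternity power, growth
#' adjustment and selection analysis in order under one seed, returning a
#' consolidated report. Re-running with the same configuration reproduces
#' the report exactly.
#'
#' @param config a [run_config()].
#' @return List of class \code{pipeline_report} with components
#'   \code{dataset}, \code{qc} (locus summaries, FST, filter/duplicate
#'   logs), \code{assignment} (threshold, per-egg table, mating list, brood
#'   classes, summary), \code{power}, \code{growth} (fitted model, pair
#'   table), \code{selection}, \code{seed}.
#' @export
run_pipeline <- function(config = run_config()) {
  stage <- "simulate"
  report <- list(seed = config$seed)
  tryCatch({
    ds <- simulate_dataset(config$sim, config$panel, seed = config$seed)
    report$dataset <- ds

    stage <- "qc"
    adults <- ds$adults
    geno <- ds$genotypes$adult_obs
    flt <- filter_missing(geno, config$max_missing)
    geno <- flt$genotypes
    adults <- adults[adults$id %in% rownames(geno), , drop = FALSE]
    dup <- find_duplicates(geno)
    drop <- resolve_duplicates(dup, geno, adults)
    if (length(drop)) {
      geno <- geno[!rownames(geno) %in% drop, , drop = FALSE]
      adults <- adults[!adults$id %in% drop, , drop = FALSE]
    }
    qc <- list(locus_summaries = locus_summaries(geno, config$panel),
               fst = pairwise_fst(geno, adults$area, config$panel,
                                  config$fst_permutations),
               removed_missing = flt$removed, duplicates = dup,
               removed_duplicates = drop)
    report$qc <- qc
    write_stage(qc$locus_summaries, "locus_summaries", config$out_dir)

    stage <- "assign"
    mothers <- unique(ds$genotypes$eggs$mother_id)
    mothers <- mothers[mothers %in% rownames(geno)]
    eggs <- ds$genotypes$eggs[ds$genotypes$eggs$mother_id %in% mothers, ,
                              drop = FALSE]
    egg_obs <- ds$genotypes$egg_obs[match(eggs$egg_id,
                                          ds$genotypes$eggs$egg_id), ,
                                    drop = FALSE]
    cand_ids <- adults$id[adults$sex == "M"]
    cand_obs <- geno[cand_ids, , drop = FALSE]
    calib <- calibrate_confidence(config$panel, length(cand_ids),
                                  config$calib_fraction, config$calib_reps,
                                  seed = config$seed + 1,
                                  confidence = config$confidence)
    assignments <- assign_fathers(egg_obs, eggs, geno, cand_obs,
                                  config$panel, threshold = calib$threshold)
    matings <- mating_list(assignments, adults)
    brood_class <- classify_broods(eggs, egg_obs, geno, assignments,
                                   cand_obs, config$panel,
                                   config$min_mismatch_loci)
    summary_tab <- summarize_matings(assignments, adults, cand_ids,
                                     brood_class)
    report$assignment <- list(threshold = calib$threshold,
                              assignments = assignments, matings = matings,
                              brood_class = brood_class,
                              summary = summary_tab)
    write_stage(assignments, "assignments", config$out_dir)

    stage <- "power"
    report$power <- skew_table(config$panel, n_values = config$sim$eggs_per_brood,
                               skews = list(c(0.5, 0.5), config$sim$skew),
                               reps = config$prdm_reps,
                               seed = config$seed + 2)
    write_stage(report$power, "power", config$out_dir)

    stage <- "adjust"
    model <- fit_growth_model(ds$growth, config$moult_mm)
    pairs <- make_pairs(matings, adults, model, config$sim$year)
    report$growth <- list(model = model, pairs = pairs)
    write_stage(pairs, "pairs", config$out_dir)

    stage <- "select"
    sel <- selection_tables(adults, assignments, config)
    intra <- pairs[!pairs$interarea, , drop = FALSE]
    if (length(unique(intra$area)) >= 1 && nrow(intra) >= 6) {
      sel$assortative <- assortative_model(intra)
      sel$gap <- lapply(split(intra, intra$area), pair_size_gap)
    }
    report$selection <- sel
    if (!is.null(sel$differentials))
      write_stage(sel$differentials, "differentials", config$out_dir)

    structure(report, class = "pipeline_report")
  }, error = function(e) {
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("Pipeline report (seed ", x$seed, ")\n", sep = "")
  print(x$assignment$summary)
  if (!is.null(x$selection$differentials)) {
    cat("Selection differentials:\n")
    print(x$selection$differentials, digits = 3)
  }
  invisible(x)
}
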