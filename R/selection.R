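# Assortative-mating models, standardized selection differentials, and
# sexual-selection gradients from logistic regressions of mating success on
# standardized male traits.

#' Standardize trait values within groups
#'
#' Mean-centres and scales to unit sample standard deviation within each
#' group (area-year combination).
#'
#' @param x numeric trait values.
#' @param group grouping factor (default: a single group).
#' @return Numeric vector of z-scores.
#' @export
#' @examples
#' standardize(c(1, 2, 3))  # -1 0 1
standardize <- function(x, group = rep(1, length(x))) {
  group <- factor(group)
  out <- numeric(length(x))
  for (g in levels(group)) {
    idx <- group == g
    s <- stats::sd(x[idx])
    if (!is.finite(s) || s == 0)
      stop("group ", g, " has zero trait variance; cannot standardize")
    out[idx] <- (x[idx] - mean(x[idx])) / s
  }
  out
}

#' Standardized selection differential
#'
#' Difference between the mean standardized trait of successful males and
#' the mean over all candidate males, with a two-tailed Welch t-test
#' comparing successful against unsuccessful males.
#'
#' @param z standardized trait values of the candidate males.
#' @param success logical mating-success flags.
#' @return List with \code{S}, \code{p}, \code{n_success}, \code{n}.
#'   \code{S} is \code{NA} when no male was successful.
#' @export
selection_differential <- function(z, success) {
  stopifnot(length(z) == length(success))
  if (!any(success))
    return(list(S = NA_real_, p = NA_real_, n_success = 0L, n = length(z)))
  S <- mean(z[success]) - mean(z)
  p <- if (any(!success) && sum(success) >= 2)
    stats::t.test(z[success], z[!success])$p.value else NA_real_
  list(S = S, p = p, n_success = sum(success), n = length(z))
}

#' Residual claw size
#'
#' Residuals from the ordinary least-squares regression of claw width on
#' carapace length; a measure of relative claw size uncorrelated with body
#' size by construction.
#'
#' @param cw claw width (mm).
#' @param cl carapace length (mm).
#' @return Numeric vector of residuals (mean 0).
#' @export
residual_claw <- function(cw, cl) {
  if (length(cw) < 3) stop("at least 3 males with both traits are required")
  unname(stats::resid(stats::lm(cw ~ cl)))
}

# small-sample-corrected Akaike information criterion
aicc <- function(fit) {
  k <- attr(stats::logLik(fit), "df")
  n <- stats::nobs(fit)
  stats::AIC(fit) + 2 * k * (k + 1) / (n - k - 1)
}

#' Fit the candidate set of mating-success models
#'
#' Fits, by maximum likelihood, the standard set of logistic regressions of
#' mating success on standardized male traits: additive and area-interaction
#' forms for carapace length (CL), claw width (CW) and residual claw size
#' (CWres), the CL + CWres combination, and the null model; ranks them by
#' small-sample-corrected AIC. Non-converging fits are flagged and ranked
#' last.
#'
#' @param data data.frame with logical/0-1 \code{success}, standardized
#'   \code{z_cl}, \code{z_cw}, \code{z_cwres}, and \code{area}.
#' @param include_area logical; set \code{FALSE} (or pass a single-area
#'   table) to drop the area terms.
#' @return List with \code{table} (data.frame: model, formula, p
#'   (parameters), aicc, delta_aicc, converged, ranked) and \code{fits}
#'   (named list of \code{glm} objects).
#' @export
fit_selection_models <- function(data, include_area = length(unique(data$area)) > 1) {
  forms <- if (include_area) list(
    "CL + CWres"      = success ~ z_cl + z_cwres,
    "CWres"           = success ~ z_cwres,
    "CL + CWres x Area" = success ~ z_cl + z_cwres * area,
    "CWres x Area"    = success ~ z_cwres * area,
    "CW"              = success ~ z_cw,
    "CW x Area"       = success ~ z_cw * area,
    "CL"              = success ~ z_cl,
    "CL x Area"       = success ~ z_cl * area,
    "Null"            = success ~ 1
  ) else list(
    "CL + CWres"      = success ~ z_cl + z_cwres,
    "CWres"           = success ~ z_cwres,
    "CW"              = success ~ z_cw,
    "CL"              = success ~ z_cl,
    "CL + CL2"        = success ~ z_cl + I(z_cl^2),
    "CW + CW2"        = success ~ z_cw + I(z_cw^2),
    "Null"            = success ~ 1
  )
  fits <- lapply(forms, function(f)
    suppressWarnings(stats::glm(f, family = stats::binomial(), data = data)))
  conv <- vapply(fits, function(f) f$converged, logical(1))
  ic <- vapply(fits, aicc, numeric(1))
  ic[!conv] <- Inf
  tab <- data.frame(model = names(forms),
                    p = vapply(fits, function(f)
                      attr(stats::logLik(f), "df"), numeric(1)),
                    aicc = vapply(fits, aicc, numeric(1)),
                    converged = conv, stringsAsFactors = FALSE)
  tab <- tab[order(ic), , drop = FALSE]
  tab$delta_aicc <- tab$aicc - tab$aicc[1]
  rownames(tab) <- NULL
  list(table = tab, fits = fits)
}

#' Janzen-Stern approximate selection gradients
#'
#' Transforms logistic-regression coefficients on standardized traits into
#' approximate selection gradients:
#' \deqn{\beta_{avggrad,j} = b_j \cdot \overline{\hat w (1 - \hat w)} / \bar w}
#' where \eqn{\hat w} are the fitted success probabilities and \eqn{\bar w}
#' the mean observed success. In the weak-selection limit this equals the
#' ordinary least-squares regression slope of relative fitness on the
#' standardized trait.
#'
#' @param fit a converged binomial \code{glm} on standardized traits.
#' @param terms coefficient names to transform (default: all but the
#'   intercept).
#' @return Named numeric vector of gradients.
#' @export
janzen_stern_gradient <- function(fit, terms = NULL) {
  w_hat <- stats::fitted(fit)
  w_obs <- fit$y
  wbar <- mean(w_obs)
  if (wbar == 0) stop("mean mating success is zero; gradient undefined")
  scale_fac <- mean(w_hat * (1 - w_hat)) / wbar
  b <- stats::coef(fit)
  if (is.null(terms)) terms <- setdiff(names(b), "(Intercept)")
  b[terms] * scale_fac
}

#' Mean-standardized selection gradient
#'
#' Multiplies an approximate gradient by the unstandardized trait mean and
#' divides by its standard deviation. Only meaningful for absolute traits
#' (carapace length, claw width) with a natural zero; refuse residual claw
#' size.
#'
#' @param beta_avggrad approximate gradient on the standardized trait.
#' @param trait_mean,trait_sd mean and SD of the raw (unstandardized) trait.
#' @param trait trait label; \code{"CW_res"} errors.
#' @return Mean-standardized gradient.
#' @export
mean_standardized_gradient <- function(beta_avggrad, trait_mean, trait_sd,
                                       trait = "CL") {
  if (trait %in% c("CW_res", "CWres", "cwres"))
    stop("mean-standardized gradients are undefined for relative claw size")
  if (trait_sd <= 0) stop("trait SD must be positive")
  beta_avggrad * trait_mean / trait_sd
}

#' Size-assortative mating model
#'
#' Linear models of male adjusted carapace length on female carapace length
#' and area: the interaction form (female size x area) is compared against
#' the additive form with a 1-df likelihood-ratio test. Interarea pairs
#' must be removed beforehand.
#'
#' @param pairs data.frame with \code{female_cl}, \code{male_cl} (adjusted)
#'   and \code{area}.
#' @return List with \code{slope} (additive-model coefficient on female
#'   size), \code{slope_se}, \code{slope_ci}, \code{area_coef},
#'   \code{r_squared} (additive model), \code{lrt_chisq}, \code{lrt_p},
#'   \code{additive_fit}, \code{interaction_fit}.
#' @export
assortative_model <- function(pairs) {
  single_area <- length(unique(pairs$area)) < 2
  if (single_area) {
    warning("single area present; area terms dropped")
    add <- stats::lm(male_cl ~ female_cl, data = pairs)
    s <- summary(add)$coefficients
    ci <- stats::confint(add)["female_cl", ]
    return(list(slope = s["female_cl", 1], slope_se = s["female_cl", 2],
                slope_ci = unname(ci), area_coef = NA_real_,
                r_squared = summary(add)$r.squared,
                lrt_chisq = NA_real_, lrt_p = NA_real_,
                additive_fit = add, interaction_fit = NULL))
  }
  add <- stats::lm(male_cl ~ female_cl + area, data = pairs)
  int <- stats::lm(male_cl ~ female_cl * area, data = pairs)
  lrt <- as.numeric(2 * (stats::logLik(int) - stats::logLik(add)))
  s <- summary(add)$coefficients
  area_row <- grep("^area", rownames(s), value = TRUE)
  list(slope = s["female_cl", 1], slope_se = s["female_cl", 2],
       slope_ci = unname(stats::confint(add)["female_cl", ]),
       area_coef = unname(s[area_row, 1]),
       r_squared = summary(add)$r.squared,
       lrt_chisq = lrt, lrt_p = stats::pchisq(lrt, df = 1, lower.tail = FALSE),
       additive_fit = add, interaction_fit = int)
}

#' Within-pair relative size gap
#'
#' Per-pair relative size difference
#' \eqn{(CL_{male} - CL_{female}) / CL_{female} \times 100} (per cent), with
#' a two-tailed Welch t-test of male versus female sizes.
#'
#' @param pairs data.frame with \code{female_cl} and \code{male_cl}.
#' @return List with \code{mean_gap_pct}, \code{gaps}, \code{t}, \code{df},
#'   \code{p}, \code{n}.
#' @export
pair_size_gap <- function(pairs) {
  if (nrow(pairs) < 2) stop("at least 2 pairs are required")
  gaps <- (pairs$male_cl - pairs$female_cl) / pairs$female_cl * 100
  tt <- tryCatch(stats::t.test(pairs$male_cl, pairs$female_cl),
                 error = function(e) NULL)  # degenerate: constant sizes
  list(mean_gap_pct = mean(gaps), gaps = gaps,
       t = if (is.null(tt)) NA_real_ else unname(tt$statistic),
       df = if (is.null(tt)) NA_real_ else unname(tt$parameter),
       p = if (is.null(tt)) NA_real_ else tt$p.value, n = nrow(pairs))
}
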