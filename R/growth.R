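# Back/forward-adjustment of male carapace length to the mating year:
# moult-probability (logistic) and growth-increment (linear) sub-models
# fitted from mark-recapture records captured in consecutive years.

#' Infer whether a moult occurred between two captures
#'
#' A male is taken to have moulted when the size difference between
#' consecutive years is at least \code{threshold} mm; smaller differences
#' are treated as measurement error. Shrinkage beyond the threshold is
#' flagged as a suspect measurement (\code{NA}) and excluded from fits.
#'
#' @param cl1,cl2 carapace length (mm) at first capture and one year later.
#' @param threshold moult-detection threshold in mm (default 5).
#' @return Logical vector (\code{NA} = suspect record).
#' @export
#' @examples
#' infer_moult(c(90, 90, 90), c(95, 94, 84))  # TRUE FALSE NA
infer_moult <- function(cl1, cl2, threshold = 5) {
  if (threshold <= 0) stop("threshold must be positive")
  d <- cl2 - cl1
  out <- d >= threshold
  out[d <= -threshold] <- NA
  out
}

#' Fit the growth model from mark-recapture records
#'
#' Logistic regression of the moult indicator on carapace length at first
#' capture (all usable records), and linear regression of the yearly growth
#' increment on carapace length (moulted records only). Complete separation
#' in the logistic fit is flagged and refitted with a small ridge penalty on
#' the coefficients.
#'
#' @param records data.frame with columns \code{cl1}, \code{cl2}.
#' @param threshold moult-detection threshold (mm).
#' @return Object of class \code{growth_model}: list with \code{moult_coef}
#'   (intercept, slope), \code{moult_se}, \code{growth_coef},
#'   \code{growth_se}, \code{sigma} (increment residual SD), \code{n},
#'   \code{separation} flag and \code{threshold}.
#' @export
fit_growth_model <- function(records, threshold = 5) {
  moult <- infer_moult(records$cl1, records$cl2, threshold)
  ok <- !is.na(moult)
  if (sum(ok) < 20) stop("at least 20 usable records are required")
  if (diff(range(records$cl1[ok])) < 20)
    stop("records must span at least 20 mm of carapace length")
  cl <- records$cl1[ok]
  y <- moult[ok]
  separation <- FALSE
  fit <- withCallingHandlers(
    stats::glm(y ~ cl, family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        separation <<- TRUE
      invokeRestart("muffleWarning")
    })
  if (separation || !fit$converged) {
    # ridge-penalized logistic fallback for separated data
    pen_nll <- function(b)
      -sum(stats::dbinom(y, 1, stats::plogis(b[1] + b[2] * cl), log = TRUE)) +
        1e-3 * sum(b^2)
    opt <- stats::optim(c(0, 0), pen_nll, method = "BFGS", hessian = TRUE)
    mc <- opt$par
    mse <- sqrt(diag(solve(opt$hessian)))
    separation <- TRUE
  } else {
    mc <- stats::coef(fit)
    mse <- summary(fit)$coefficients[, "Std. Error"]
  }
  grow <- y & !is.na(y)
  inc <- (records$cl2 - records$cl1)[ok][grow]
  clg <- cl[grow]
  if (length(inc) < 3) stop("too few moulted records to fit the increment line")
  lfit <- stats::lm(inc ~ clg)
  lsum <- suppressWarnings(summary(lfit))
  structure(list(moult_coef = unname(mc), moult_se = unname(mse),
                 growth_coef = unname(stats::coef(lfit)),
                 growth_se = unname(lsum$coefficients[, "Std. Error"]),
                 sigma = lsum$sigma,
                 n = sum(ok), n_moulted = sum(grow),
                 separation = separation, threshold = threshold),
            class = "growth_model")
}

#' @export
print.growth_model <- function(x, ...) {
  cat("Growth model (", x$n, " records, ", x$n_moulted, " moulted)\n", sep = "")
  cat(sprintf("  p(moult): logit^-1(%.3f %+.4f CL)%s\n", x$moult_coef[1],
              x$moult_coef[2], if (x$separation) "  [separation: penalized]" else ""))
  cat(sprintf("  increment: %.2f %+.4f CL mm/yr (sigma %.2f)\n",
              x$growth_coef[1], x$growth_coef[2], x$sigma))
  invisible(x)
}

#' Predicted moult probability and growth increment
#'
#' @param model a fitted \code{growth_model}.
#' @param cl carapace length (mm).
#' @return Numeric vector of predictions.
#' @export
predict_moult_prob <- function(model, cl) {
  stats::plogis(model$moult_coef[1] + model$moult_coef[2] * cl)
}

#' @rdname predict_moult_prob
#' @export
predict_increment <- function(model, cl) {
  model$growth_coef[1] + model$growth_coef[2] * cl
}

#' Adjust male carapace length to the mating year
#'
#' Single-step linear extrapolation: measured length plus the year
#' difference times the expected annual growth, the latter being the
#' predicted increment times the predicted moult probability, both
#' evaluated at the measured length. Negative year differences (male
#' sampled after the mating year) subtract growth.
#'
#' @param cl measured carapace length (mm).
#' @param year_diff mating year minus measurement year (any integer).
#' @param model a fitted \code{growth_model}.
#' @return Adjusted carapace length (mm).
#' @export
adjust_cl <- function(cl, year_diff, model) {
  if (!inherits(model, "growth_model")) stop("model must be a fitted growth_model")
  cl + year_diff * predict_increment(model, cl) * predict_moult_prob(model, cl)
}
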