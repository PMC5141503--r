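#' Construct a pooled MR result
#'
#' Container for a pooled causal estimate: the method, the estimate on the
#' per-exposure-SD scale, its standard error and confidence interval, the
#' number of instruments, and (for MR-Egger) the intercept test. Results are
#' convertible between per-SD and per-100-gram scales with
#' [convert_scale()] and, for binary outcomes, to odds ratios with
#' [or_with_ci()].
#'
#' @param method `"ivw"`, `"egger_slope"` or `"weighted_median"`.
#' @param beta,se,ci_low,ci_high Estimate, SE and CI bounds.
#' @param n_snps Number of instruments used.
#' @param outcome_type `"log_odds"` (binary outcome) or `"sd_units"`.
#' @param scale `"per_sd"` or `"per_100g"`.
#' @param available `FALSE` only for the weighted median under the
#'   dominant-instrument rule.
#' @param egger_intercept,egger_intercept_se,egger_intercept_p Intercept
#'   test, present for `egger_slope` only.
#' @return List of class `mr_result`.
#' @keywords internal
mr_result <- function(method, beta, se, ci_low, ci_high, n_snps,
                      outcome_type = "log_odds", scale = "per_sd",
                      available = TRUE,
                      egger_intercept = NULL, egger_intercept_se = NULL,
                      egger_intercept_p = NULL) {
  structure(
    list(method = method, beta = beta, se = se, ci_low = ci_low,
         ci_high = ci_high, n_snps = n_snps, outcome_type = outcome_type,
         scale = scale, available = available,
         egger_intercept = egger_intercept,
         egger_intercept_se = egger_intercept_se,
         egger_intercept_p = egger_intercept_p),
    class = "mr_result"
  )
}

#' @export
print.mr_result <- function(x, ...) {
  label <- c(ivw = "Inverse-variance weighted (fixed effects)",
             egger_slope = "MR-Egger slope",
             weighted_median = "Weighted median")[x$method]
  cat(label, sprintf("[J = %d, scale = %s, outcome = %s]\n",
                     x$n_snps, x$scale, x$outcome_type))
  if (!x$available) {
    cat("  not available: one SNP contributes more than the allowed",
        "share of the information\n")
    return(invisible(x))
  }
  cat(sprintf("  estimate %.4f (SE %.4f), CI [%.4f, %.4f]\n",
              x$beta, x$se, x$ci_low, x$ci_high))
  if (identical(x$outcome_type, "log_odds")) {
    or <- or_with_ci(x)
    cat(sprintf("  OR %.3f (%.3f to %.3f)\n", or[1], or[2], or[3]))
  }
  if (!is.null(x$egger_intercept)) {
    cat(sprintf("  intercept %.4f (SE %.4f), p = %.3g\n",
                x$egger_intercept, x$egger_intercept_se, x$egger_intercept_p))
  }
  invisible(x)
}

#' Fixed-effect inverse-variance-weighted pooling of Wald ratios
#'
#' Combines per-SNP Wald ratio estimates into a single causal estimate with
#' weights equal to the reciprocal of each ratio's variance: the pooled
#' estimate is the weighted mean of the ratios and its standard error is
#' `(sum of weights)^(-1/2)` (fixed effects; a common causal effect across
#' instruments is assumed). Under the default `"fieller"` weight scheme the
#' per-SNP variance is derived from the bounded Fieller interval; under
#' `"first_order_delta"` it is `se_y^2 / beta_x^2`.
#'
#' @param estimates Data frame from [wald_ratios()]. For the delta weight
#'   scheme the columns `beta_x`/`se_y` of an `mr_instruments` data frame
#'   may be supplied instead, or in addition (columns are taken from
#'   `instruments` when given).
#' @param config [mr_config()] settings.
#' @param instruments Optional harmonized instruments, required for the
#'   `first_order_delta` scheme when `estimates` lacks `beta_x`/`se_y`.
#' @param outcome_type Passed through to the result.
#' @return An `mr_result` with method `"ivw"`.
#' @export
ivw_pool <- function(estimates, config = mr_config(), instruments = NULL,
                     outcome_type = "log_odds") {
  stopifnot(nrow(estimates) >= 1)
  if (config$weight_scheme == "fieller") {
    bad <- estimates$fieller_case != "bounded"
    if (any(bad)) {
      stop("Fieller interval not bounded for ",
           paste(estimates$rsid[bad], collapse = ", "),
           "; use weight_scheme = 'first_order_delta' or exclude these ",
           "weak instruments", call. = FALSE)
    }
    variance <- estimates$variance
  } else {
    src <- if (!is.null(instruments)) {
      usable <- if ("status" %in% names(instruments)) {
        usable_instruments(instruments)
      } else instruments
      usable[match(estimates$rsid, usable$rsid), ]
    } else {
      estimates
    }
    if (!all(c("beta_x", "se_y") %in% names(src))) {
      stop("first_order_delta weights need beta_x and se_y; pass the ",
           "harmonized instruments", call. = FALSE)
    }
    variance <- delta_variance(src$beta_x, src$se_y)
  }
  stopifnot(all(is.finite(variance)), all(variance > 0))

  w <- 1 / variance
  beta <- sum(w * estimates$ratio) / sum(w)
  se <- sqrt(1 / sum(w))
  z <- stats::qnorm(1 - config$alpha / 2)
  mr_result("ivw", beta = beta, se = se,
            ci_low = beta - z * se, ci_high = beta + z * se,
            n_snps = nrow(estimates), outcome_type = outcome_type)
}

#' MR-Egger regression with the directional-pleiotropy intercept test
#'
#' Weighted least-squares regression of the SNP-outcome effects on the
#' SNP-exposure effects with a free intercept and weights `1/se_y^2`.
#' Instruments are first oriented so every exposure effect is positive
#' (negating both betas where needed), which makes the fit invariant to the
#' arbitrary choice of effect allele. The slope is a pleiotropy-adjusted
#' causal estimate; the intercept estimates the average directional
#' pleiotropic effect, and its two-sided test (Student t with J - 2 df by
#' default) is the screen for directional horizontal pleiotropy.
#'
#' @param instruments Harmonized instruments (usable rows are selected).
#' @param config [mr_config()] settings (`alpha`, `egger_df`).
#' @param outcome_type Passed through to the result.
#' @return An `mr_result` with method `"egger_slope"` and the intercept
#'   fields populated.
#' @export
egger_regression <- function(instruments, config = mr_config(),
                             outcome_type = "log_odds") {
  if ("status" %in% names(instruments)) {
    instruments <- usable_instruments(instruments)
  }
  J <- nrow(instruments)
  if (J < 3) {
    stop("MR-Egger needs at least 3 instruments (intercept and slope are ",
         "not jointly identifiable with J = ", J, ")", call. = FALSE)
  }
  sign_x <- ifelse(instruments$beta_x < 0, -1, 1)
  bx <- instruments$beta_x * sign_x
  by <- instruments$beta_y * sign_x
  w <- 1 / instruments$se_y^2

  fit <- stats::lm(by ~ bx, weights = w)
  coefs <- summary(fit)$coefficients
  slope <- coefs["bx", "Estimate"]
  slope_se <- coefs["bx", "Std. Error"]
  inter <- coefs["(Intercept)", "Estimate"]
  inter_se <- coefs["(Intercept)", "Std. Error"]

  if (config$egger_df == "t") {
    q <- stats::qt(1 - config$alpha / 2, df = J - 2)
    inter_p <- 2 * stats::pt(abs(inter / inter_se), df = J - 2,
                             lower.tail = FALSE)
  } else {
    q <- stats::qnorm(1 - config$alpha / 2)
    inter_p <- 2 * stats::pnorm(abs(inter / inter_se), lower.tail = FALSE)
  }

  mr_result("egger_slope", beta = slope, se = slope_se,
            ci_low = slope - q * slope_se, ci_high = slope + q * slope_se,
            n_snps = J, outcome_type = outcome_type,
            egger_intercept = inter, egger_intercept_se = inter_se,
            egger_intercept_p = inter_p)
}

# Interpolated weighted median of `values` with normalized weights `w`
# (cumulative-midpoint convention). Stable sort by (value, id) keeps results
# deterministic under ties.
weighted_median_point <- function(values, w, ids = NULL) {
  if (is.null(ids)) ids <- as.character(seq_along(values))
  ord <- order(values, ids)
  v <- values[ord]
  wn <- w[ord] / sum(w)
  s <- cumsum(wn) - wn / 2
  if (0.5 <= s[1]) return(v[1])
  if (0.5 >= s[length(s)]) return(v[length(v)])
  j <- max(which(s <= 0.5))
  v[j] + (v[j + 1] - v[j]) * (0.5 - s[j]) / (s[j + 1] - s[j])
}

#' Weighted median causal estimate
#'
#' The weighted median of the per-SNP Wald ratios is a consistent causal
#' estimate as long as valid instruments contribute more than 50% of the
#' information. Each SNP's information weight is `beta_x^2 / se_y^2`
#' (the first-order precision of its Wald ratio), normalized to sum to one.
#' When a single SNP's normalized weight exceeds `dominance_threshold`
#' (default 0.5) the estimator's defining guarantee cannot hold and the
#' result is reported as *not available* rather than as a number.
#'
#' The point estimate interpolates the inverse of the cumulative weight
#' function at 1/2 over the ratio-ordered instruments. The standard error is
#' a parametric bootstrap: exposure and outcome effects are resampled from
#' normal distributions centred at the observed values with the observed
#' standard errors, the weighted median is recomputed for each replicate,
#' and the SD across replicates (fixed seed, fixed rep count) is the SE.
#'
#' @param instruments Harmonized instruments (usable rows are selected);
#'   J >= 2 required.
#' @param config [mr_config()] settings (`bootstrap_reps`, `seed`,
#'   `dominance_threshold`, `alpha`).
#' @param outcome_type Passed through to the result.
#' @param bootstrap Set `FALSE` to skip the bootstrap (point estimate only,
#'   SE and CI `NA`); used by large simulation studies.
#' @return An `mr_result` with method `"weighted_median"`; `available` is
#'   `FALSE` (and the numeric fields `NA`) under the dominance rule.
#' @export
weighted_median_mr <- function(instruments, config = mr_config(),
                               outcome_type = "log_odds", bootstrap = TRUE) {
  if ("status" %in% names(instruments)) {
    instruments <- usable_instruments(instruments)
  }
  J <- nrow(instruments)
  stopifnot(J >= 2)
  w <- instruments$beta_x^2 / instruments$se_y^2
  wn <- w / sum(w)
  if (max(wn) > config$dominance_threshold) {
    return(mr_result("weighted_median", beta = NA_real_, se = NA_real_,
                     ci_low = NA_real_, ci_high = NA_real_, n_snps = J,
                     outcome_type = outcome_type, available = FALSE))
  }
  ratios <- instruments$beta_y / instruments$beta_x
  est <- weighted_median_point(ratios, wn, instruments$rsid)

  se <- ci_low <- ci_high <- NA_real_
  if (bootstrap) {
    B <- config$bootstrap_reps
    boot <- local({
      old <- if (exists(".Random.seed", globalenv())) {
        get(".Random.seed", globalenv())
      }
      on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
      set.seed(config$seed)
      bx <- matrix(stats::rnorm(J * B, instruments$beta_x, instruments$se_x),
                   nrow = J)
      by <- matrix(stats::rnorm(J * B, instruments$beta_y, instruments$se_y),
                   nrow = J)
      vapply(seq_len(B), function(b) {
        wb <- bx[, b]^2 / instruments$se_y^2
        weighted_median_point(by[, b] / bx[, b], wb, instruments$rsid)
      }, numeric(1))
    })
    se <- stats::sd(boot)
    z <- stats::qnorm(1 - config$alpha / 2)
    ci_low <- est - z * se
    ci_high <- est + z * se
  }
  mr_result("weighted_median", beta = est, se = se,
            ci_low = ci_low, ci_high = ci_high, n_snps = J,
            outcome_type = outcome_type)
}
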