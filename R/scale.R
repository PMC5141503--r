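#' Standard deviation of the birth-weight z-score, in grams
#'
#' Exposure effects are estimated on the z-score scale; for interpretability
#' results are rescaled to 100-gram units of birth weight assuming one SD of
#' birth weight is 484 grams.
#' @export
BIRTHWEIGHT_SD_GRAMS <- 484

#' Convert a pooled result from per-SD to per-100-gram units
#'
#' Multiplies the estimate, its standard error and both confidence bounds by
#' `100 / 484` (100 grams as a fraction of one birth-weight SD). For binary
#' outcomes the per-100-g odds ratio is `exp(beta_per_sd * 100/484)`.
#'
#' @param result An `mr_result` on the `per_sd` scale.
#' @param sd_grams SD of the exposure in grams (default 484).
#' @return The result on the `per_100g` scale.
#' @export
#' @examples
#' r <- bwmr:::mr_result("ivw", beta = 0.484, se = 0.1,
#'                       ci_low = 0.288, ci_high = 0.68, n_snps = 7)
#' convert_scale(r)$beta  # 0.1
convert_scale <- function(result, sd_grams = BIRTHWEIGHT_SD_GRAMS) {
  stopifnot(inherits(result, "mr_result"))
  if (!identical(result$scale, "per_sd")) {
    stop("result is already on the ", result$scale,
         " scale; conversion applies to per_sd results only", call. = FALSE)
  }
  f <- 100 / sd_grams
  # the Egger intercept is in outcome units per allele, not per exposure
  # SD, so it is untouched by exposure rescaling
  for (field in c("beta", "se", "ci_low", "ci_high")) {
    result[[field]] <- result[[field]] * f
  }
  result$scale <- "per_100g"
  result
}

#' Odds ratio with confidence interval from a log-odds result
#'
#' @param result An `mr_result` with `outcome_type = "log_odds"`.
#' @return Named numeric vector `c(or, or_low, or_high)`. Exponentiation is
#'   monotone, so the bound ordering is preserved.
#' @export
#' @examples
#' r <- bwmr:::mr_result("ivw", beta = log(2), se = 0.1,
#'                       ci_low = log(1.5), ci_high = log(3), n_snps = 7)
#' or_with_ci(r)
or_with_ci <- function(result) {
  stopifnot(inherits(result, "mr_result"))
  if (!identical(result$outcome_type, "log_odds")) {
    stop("odds ratios apply to log_odds outcomes; this result is in ",
         result$outcome_type, call. = FALSE)
  }
  c(or = exp(result$beta), or_low = exp(result$ci_low),
    or_high = exp(result$ci_high))
}
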