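#' Estimation settings shared by all estimators
#'
#' Collects the tunable settings used across the estimators: the confidence
#' level, the per-SNP weighting scheme for inverse-variance pooling, the
#' parametric-bootstrap size and seed for the weighted-median standard error,
#' the information-share threshold above which the weighted median is declared
#' unavailable, and the reference distribution for the MR-Egger intercept test.
#'
#' @param alpha Two-sided significance level for confidence intervals
#'   (default 0.05, i.e. 95% CIs).
#' @param weight_scheme How the per-SNP variance entering inverse-variance
#'   weights is derived: `"fieller"` uses the squared half-width of the
#'   bounded Fieller interval divided by the squared normal quantile;
#'   `"first_order_delta"` uses the leading-order delta-method variance
#'   `se_y^2 / beta_x^2`.
#' @param bootstrap_reps Number of parametric bootstrap replicates for the
#'   weighted-median standard error (>= 100).
#' @param seed Integer seed for the bootstrap resampling.
#' @param dominance_threshold Maximum normalized information share any single
#'   SNP may contribute before the weighted median is reported unavailable
#'   (default 0.5: one SNP holding more than half the information).
#' @param egger_df Reference distribution for the MR-Egger intercept and slope
#'   tests: `"t"` (Student t with J - 2 degrees of freedom) or `"normal"`.
#'
#' @return A list of class `mr_config`.
#' @export
#' @examples
#' cfg <- mr_config(alpha = 0.05, bootstrap_reps = 1000)
#' cfg$dominance_threshold
mr_config <- function(alpha = 0.05,
                      weight_scheme = c("fieller", "first_order_delta"),
                      bootstrap_reps = 10000,
                      seed = 20161207,
                      dominance_threshold = 0.5,
                      egger_df = c("t", "normal")) {
  weight_scheme <- match.arg(weight_scheme)
  egger_df <- match.arg(egger_df)
  stopifnot(is.numeric(alpha), length(alpha) == 1, alpha > 0, alpha < 1)
  if (!is.numeric(bootstrap_reps) || bootstrap_reps < 100) {
    stop("`bootstrap_reps` must be at least 100", call. = FALSE)
  }
  stopifnot(dominance_threshold > 0, dominance_threshold <= 1)
  structure(
    list(
      alpha = alpha,
      weight_scheme = weight_scheme,
      bootstrap_reps = as.integer(bootstrap_reps),
      seed = as.integer(seed),
      dominance_threshold = dominance_threshold,
      egger_df = egger_df
    ),
    class = "mr_config"
  )
}
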