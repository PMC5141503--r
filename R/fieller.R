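#' Per-SNP Wald ratio with Fieller's-theorem confidence interval
#'
#' The Wald ratio `beta_y / beta_x` is the per-SNP causal estimate of the
#' outcome per unit of exposure. Its confidence set by Fieller's theorem is
#' the set of candidate ratios g satisfying
#' \deqn{(\beta_y - g\,\beta_x)^2 \le z^2 (se_y^2 + g^2 se_x^2)}
#' with z the standard-normal 1 - alpha/2 quantile and zero covariance
#' between numerator and denominator (the two-sample design draws them from
#' separate studies). Solving the quadratic in g yields three cases:
#' a bounded interval when the instrument is strong
#' (`|beta_x| > z * se_x`), the complement of an interval (`exclusive`)
#' or the whole real line (`unbounded`) when it is weak.
#'
#' For a bounded interval a per-SNP variance is derived as
#' `((upper - lower) / (2 z))^2`; this is the weight denominator used for
#' fixed-effect inverse-variance pooling under the `"fieller"` weight scheme.
#' Unbounded and exclusive cases carry no variance and are surfaced as
#' weak-instrument diagnostics.
#'
#' @param beta_x,se_x SNP-exposure effect and standard error (`se_x > 0`).
#' @param beta_y,se_y SNP-outcome effect and standard error (`se_y > 0`).
#' @param alpha Two-sided significance level (default 0.05).
#' @param rsid Optional identifier carried through to the result.
#'
#' @return A one-row data frame: `rsid`, `ratio`, `ci_low`, `ci_high`,
#'   `variance`, `fieller_case` (one of `"bounded"`, `"exclusive"`,
#'   `"unbounded"`). For `exclusive` the reported pair (`ci_low`, `ci_high`)
#'   delimits the *excluded* interval; for `unbounded` the bounds are
#'   `-Inf`/`Inf`. `ratio` is `NA` when `beta_x = 0`.
#' @export
#' @examples
#' wald_ratio(beta_x = 0.10, se_x = 0.01, beta_y = 0.05, se_y = 0.02)
wald_ratio <- function(beta_x, se_x, beta_y, se_y, alpha = 0.05,
                       rsid = NA_character_) {
  stopifnot(se_x > 0, se_y > 0, alpha > 0, alpha < 1)
  z <- stats::qnorm(1 - alpha / 2)
  ratio <- if (beta_x == 0) NA_real_ else beta_y / beta_x

  # quadratic A g^2 + B g + C <= 0 from the Fieller inequality
  A <- beta_x^2 - z^2 * se_x^2
  B <- -2 * beta_x * beta_y
  C <- beta_y^2 - z^2 * se_y^2
  disc <- B^2 - 4 * A * C

  if (A > 0) {
    # disc > 0 is guaranteed when A > 0 (see the expanded discriminant)
    r1 <- (-B - sqrt(disc)) / (2 * A)
    r2 <- (-B + sqrt(disc)) / (2 * A)
    ci <- sort(c(r1, r2))
    fieller_case <- "bounded"
    variance <- ((ci[2] - ci[1]) / (2 * z))^2
  } else if (A < 0 && disc > 0) {
    r1 <- (-B - sqrt(disc)) / (2 * A)
    r2 <- (-B + sqrt(disc)) / (2 * A)
    ci <- sort(c(r1, r2))
    fieller_case <- "exclusive"
    variance <- NA_real_
  } else {
    ci <- c(-Inf, Inf)
    fieller_case <- "unbounded"
    variance <- NA_real_
  }

  data.frame(rsid = rsid, ratio = ratio, ci_low = ci[1], ci_high = ci[2],
             variance = variance, fieller_case = fieller_case,
             stringsAsFactors = FALSE)
}

#' Wald ratios for a harmonized instrument set
#'
#' Applies [wald_ratio()] to each usable row (status `aligned` or
#' `flipped`) of a harmonized instrument table.
#'
#' @param instruments `mr_instruments` data frame (see [harmonize()]), or
#'   any data frame with columns `rsid`, `beta_x`, `se_x`, `beta_y`, `se_y`.
#' @param alpha Two-sided significance level.
#' @return Data frame with one row per instrument (see [wald_ratio()]).
#' @export
wald_ratios <- function(instruments, alpha = 0.05) {
  if ("status" %in% names(instruments)) {
    instruments <- usable_instruments(instruments)
  }
  out <- do.call(rbind, lapply(seq_len(nrow(instruments)), function(i) {
    wald_ratio(instruments$beta_x[i], instruments$se_x[i],
               instruments$beta_y[i], instruments$se_y[i],
               alpha = alpha, rsid = instruments$rsid[i])
  }))
  rownames(out) <- NULL
  out
}

# First-order delta-method variance of the Wald ratio; the configurable
# fallback weight when Fieller intervals are unbounded.
delta_variance <- function(beta_x, se_y) {
  se_y^2 / beta_x^2
}
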