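# Build a minimal harmonized instrument table in code.
make_instruments <- function(beta_x, se_x, beta_y, se_y,
                             rsid = paste0("snp", seq_along(beta_x))) {
  j <- length(beta_x)
  out <- data.frame(
    rsid = rsid,
    effect_allele = "A", other_allele = "G",
    beta_x = beta_x, se_x = rep_len(se_x, j),
    eaf_x = NA_real_,
    beta_y = beta_y, se_y = rep_len(se_y, j),
    eaf_y = NA_real_,
    status = "aligned", annotations = "",
    stringsAsFactors = FALSE
  )
  class(out) <- c("mr_instruments", "data.frame")
  out
}

# Write a GWAS summary table to a temp file and return the path.
write_temp_gwas <- function(df, sep = "\t", ext = ".tsv") {
  path <- tempfile(fileext = ext)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  path
}

make_gwas_records <- function(rsid, ea, oa, beta, se, eaf = NA_real_) {
  data.frame(rsid = rsid, effect_allele = ea, other_allele = oa,
             eaf = eaf, beta = beta, se = se,
             pvalue = NA_real_, n = NA_real_, stringsAsFactors = FALSE)
}

# Independent grid-membership oracle for the Fieller confidence set: scans a
# fine grid of candidate ratios g and keeps those satisfying the defining
# inequality (beta_y - g beta_x)^2 <= z^2 (se_y^2 + g^2 se_x^2).
fieller_grid_oracle <- function(beta_x, se_x, beta_y, se_y, alpha = 0.05,
                                lo, hi, step = 1e-4) {
  z <- qnorm(1 - alpha / 2)
  g <- seq(lo, hi, by = step)
  inside <- (beta_y - g * beta_x)^2 <= z^2 * (se_y^2 + g^2 * se_x^2)
  list(grid = g, inside = inside,
       lo = if (any(inside)) min(g[inside]) else NA_real_,
       hi = if (any(inside)) max(g[inside]) else NA_real_)
}

# Independent weighted-median oracle: scans the piecewise-linear interpolated
# cumulative-weight function on a fine grid and returns the g where it
# crosses one half.
weighted_median_scan_oracle <- function(ratios, weights, step = 1e-6) {
  ord <- order(ratios)
  r <- ratios[ord]
  w <- weights[ord] / sum(weights)
  s <- cumsum(w) - w / 2
  g <- seq(min(r), max(r), by = step)
  cdf <- approx(r, s, xout = g, rule = 2, ties = "ordered")$y
  g[which.min(abs(cdf - 0.5))]
}

# Independent weighted-least-squares oracle via the normal equations.
wls_normal_equations <- function(x, y, w) {
  X <- cbind(1, x)
  XtWX <- t(X) %*% (w * X)
  XtWy <- t(X) %*% (w * y)
  coef <- solve(XtWX, XtWy)
  resid <- y - X %*% coef
  sigma2 <- sum(w * resid^2) / (length(y) - 2)
  se <- sqrt(diag(sigma2 * solve(XtWX)))
  list(intercept = unname(coef[1]), slope = unname(coef[2]),
       se_intercept = unname(se[1]), se_slope = unname(se[2]))
}
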