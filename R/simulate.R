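#' Define a two-sample summary-statistics simulation scenario
#'
#' Describes the generative model behind a two-sample MR dataset: J
#' instruments with true per-allele exposure effects gamma_j, a true causal
#' effect theta, independent sampling noise on the exposure and outcome
#' effects (the two samples are separate studies), and an optional direct
#' (pleiotropic) path alpha_j from instrument to outcome:
#' \deqn{\hat\beta_{Xj} \sim N(\gamma_j, se_{Xj}^2), \quad
#'       \hat\beta_{Yj} \sim N(\theta\gamma_j + \alpha_j, se_{Yj}^2).}
#'
#' Pleiotropy regimes: `"none"` (all alpha_j = 0, valid instruments),
#' `"balanced"` (alpha_j ~ N(0, tau^2): pleiotropy present but averaging to
#' zero), `"directional"` (alpha_j ~ N(mu_alpha, tau^2): systematic bias),
#' `"inside_violating"` (alpha_j correlated with gamma_j at correlation
#' `rho`, breaking the Instrument Strength Independent of Direct Effect
#' assumption that MR-Egger needs). Only a fraction `invalid_fraction` of
#' instruments (chosen at random) receives a pleiotropic effect.
#'
#' @param j Number of instruments (>= 2).
#' @param theta True causal effect, outcome units per exposure SD.
#' @param gamma Per-SNP true exposure effects: a length-`j` vector, or
#'   `NULL` to draw uniformly from `gamma_range`.
#' @param gamma_range Range for drawn gamma (default 0.03-0.09, per-allele
#'   z-score effects typical of large birth-weight GWAS loci).
#' @param se_x,se_y Standard errors, scalar or length-`j` (defaults 0.006
#'   and 0.012: magnitudes typical of consortium-scale exposure and
#'   case-control outcome GWAS).
#' @param pleiotropy Regime, see above.
#' @param tau SD of the pleiotropic effects (>= 0).
#' @param mu_alpha Mean pleiotropic effect (directional regime).
#' @param rho Correlation of alpha with gamma (inside_violating regime).
#' @param invalid_fraction Share of SNPs receiving pleiotropy, in [0, 1].
#' @param seed Integer seed; generation is fully deterministic given it.
#' @return List of class `sim_scenario`.
#' @export
sim_scenario <- function(j = 7, theta = 0, gamma = NULL,
                         gamma_range = c(0.03, 0.09),
                         se_x = 0.006, se_y = 0.012,
                         pleiotropy = c("none", "balanced", "directional",
                                        "inside_violating"),
                         tau = 0, mu_alpha = 0, rho = 0,
                         invalid_fraction = 0, seed = 1L) {
  pleiotropy <- match.arg(pleiotropy)
  stopifnot(j >= 2, tau >= 0,
            invalid_fraction >= 0, invalid_fraction <= 1,
            all(se_x > 0), all(se_y > 0))
  if (!is.null(gamma)) stopifnot(length(gamma) == j)
  structure(
    list(j = as.integer(j), theta = theta, gamma = gamma,
         gamma_range = gamma_range,
         se_x = rep_len(se_x, j), se_y = rep_len(se_y, j),
         pleiotropy = pleiotropy, tau = tau, mu_alpha = mu_alpha, rho = rho,
         invalid_fraction = invalid_fraction, seed = as.integer(seed)),
    class = "sim_scenario"
  )
}

#' Generate a two-sample summary dataset from a scenario
#'
#' @param scenario A [sim_scenario()].
#' @return List of class `sim_dataset`: `instruments` (an `mr_instruments`
#'   data frame, already harmonized, rsids `snp1..snpJ` with placeholder
#'   alleles) and `truth` (theta, and the drawn `gamma`, `alpha`,
#'   `invalid` indicator per SNP, for scoring estimates against the truth).
#' @export
#' @examples
#' d <- sim_generate(sim_scenario(j = 5, theta = 0.4, seed = 7))
#' d$truth$theta
sim_generate <- function(scenario) {
  stopifnot(inherits(scenario, "sim_scenario"))
  set.seed(scenario$seed)
  j <- scenario$j

  gamma <- scenario$gamma
  if (is.null(gamma)) {
    gamma <- stats::runif(j, scenario$gamma_range[1], scenario$gamma_range[2])
  }

  n_invalid <- round(scenario$invalid_fraction * j)
  invalid <- rep(FALSE, j)
  if (n_invalid > 0) invalid[sample.int(j, n_invalid)] <- TRUE

  alpha <- rep(0, j)
  if (any(invalid) && scenario$pleiotropy != "none") {
    k <- sum(invalid)
    alpha[invalid] <- switch(
      scenario$pleiotropy,
      balanced = stats::rnorm(k, 0, scenario$tau),
      directional = stats::rnorm(k, scenario$mu_alpha, scenario$tau),
      inside_violating = {
        g <- gamma[invalid]
        gs <- if (stats::sd(g) > 0) (g - mean(g)) / stats::sd(g) else rep(0, k)
        scenario$mu_alpha +
          scenario$tau * (scenario$rho * gs +
                            sqrt(1 - scenario$rho^2) * stats::rnorm(k))
      }
    )
  }

  beta_x <- stats::rnorm(j, gamma, scenario$se_x)
  beta_y <- stats::rnorm(j, scenario$theta * gamma + alpha, scenario$se_y)

  instruments <- data.frame(
    rsid = paste0("snp", seq_len(j)),
    effect_allele = "A", other_allele = "G",
    beta_x = beta_x, se_x = scenario$se_x,
    eaf_x = NA_real_,
    beta_y = beta_y, se_y = scenario$se_y,
    eaf_y = NA_real_,
    status = "aligned", annotations = "",
    stringsAsFactors = FALSE
  )
  class(instruments) <- c("mr_instruments", "data.frame")

  structure(
    list(instruments = instruments,
         truth = list(theta = scenario$theta, gamma = gamma, alpha = alpha,
                      invalid = invalid),
         scenario = scenario),
    class = "sim_dataset"
  )
}

#' Operating characteristics of the estimators under a scenario
#'
#' Repeatedly generates datasets from `scenario` (seeds `seed + 1 ... seed +
#' n_reps`), applies the requested estimators, and summarizes bias, spread,
#' confidence-interval coverage and rejection rate against the known truth.
#'
#' @param scenario A [sim_scenario()]; its `seed` anchors the replicate
#'   seeds.
#' @param n_reps Number of replicates (>= 100).
#' @param estimators Subset of `c("ivw", "egger", "weighted_median")`.
#' @param config [mr_config()] used for every fit. The default uses
#'   first-order-delta IVW weights (robust to weak draws) and a reduced
#'   bootstrap for the weighted-median SE, sized for simulation studies.
#' @return Data frame, one row per estimator: `mean_bias`, `mc_se_bias`
#'   (Monte-Carlo SE of the mean bias), `empirical_se`, `coverage`,
#'   `mc_se_coverage`, `rejection_rate` (type-I error when theta = 0,
#'   power otherwise), `mc_se_rejection`, `n_reps`.
#' @export
evaluate_estimators <- function(scenario, n_reps = 1000,
                                estimators = c("ivw", "egger",
                                               "weighted_median"),
                                config = mr_config(
                                  weight_scheme = "first_order_delta",
                                  bootstrap_reps = 200)) {
  stopifnot(n_reps >= 100)
  estimators <- match.arg(estimators, several.ok = TRUE)
  theta <- scenario$theta

  draws <- lapply(estimators, function(e) {
    matrix(NA_real_, nrow = n_reps, ncol = 3,
           dimnames = list(NULL, c("est", "lo", "hi")))
  })
  names(draws) <- estimators

  for (r in seq_len(n_reps)) {
    sc <- scenario
    sc$seed <- scenario$seed + r
    dat <- sim_generate(sc)
    inst <- dat$instruments
    wr <- wald_ratios(inst, alpha = config$alpha)
    for (e in estimators) {
      fit <- switch(e,
        ivw = ivw_pool(wr, config, instruments = inst),
        egger = egger_regression(inst, config),
        weighted_median = {
          cfg <- config
          cfg$seed <- scenario$seed + r # independent bootstrap per replicate
          weighted_median_mr(inst, cfg)
        })
      if (isTRUE(fit$available)) {
        draws[[e]][r, ] <- c(fit$beta, fit$ci_low, fit$ci_high)
      }
    }
  }

  summarize <- function(m) {
    ok <- stats::complete.cases(m)
    est <- m[ok, "est"]; lo <- m[ok, "lo"]; hi <- m[ok, "hi"]
    n <- length(est)
    cover <- mean(lo <= theta & theta <= hi)
    reject <- mean(lo > 0 | hi < 0)
    data.frame(
      mean_bias = mean(est) - theta,
      mc_se_bias = stats::sd(est) / sqrt(n),
      empirical_se = stats::sd(est),
      coverage = cover,
      mc_se_coverage = sqrt(cover * (1 - cover) / n),
      rejection_rate = reject,
      mc_se_rejection = sqrt(reject * (1 - reject) / n),
      n_reps = n
    )
  }
  out <- do.call(rbind, lapply(draws, summarize))
  cbind(data.frame(estimator = estimators, stringsAsFactors = FALSE), out)
}
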