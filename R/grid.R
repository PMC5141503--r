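#' Assemble an analysis plan
#'
#' A plan is the full analysis matrix: outcomes (each with a display name, a
#' source label, an outcome type and its summary table), the named
#' instrument subsets to run, and the estimation methods.
#'
#' @param exposure Exposure summary table (data frame from
#'   [read_gwas_table()]) or a file path.
#' @param outcomes Named list; each element a list with `name` (display
#'   name), `source` (data-source label), `outcome_type` (`"log_odds"` or
#'   `"sd_units"`) and `data` (summary table data frame) or `path`.
#' @param sets Character vector of instrument-set names
#'   (see [builtin_instrument_sets()]) or a named list of rsid vectors.
#' @param methods Subset of `c("ivw", "weighted_median", "egger")`.
#' @param config [mr_config()] settings.
#' @return List of class `analysis_plan`.
#' @export
analysis_plan <- function(exposure, outcomes,
                          sets = c("7snp", "5snp", "4snp", "2snp", "10snp"),
                          methods = c("ivw", "weighted_median"),
                          config = mr_config()) {
  stopifnot(length(outcomes) >= 1, length(sets) >= 1, length(methods) >= 1)
  methods <- match.arg(methods, c("ivw", "weighted_median", "egger"),
                       several.ok = TRUE)
  if (is.character(exposure)) exposure <- read_gwas_table(exposure)
  outcomes <- lapply(outcomes, function(o) {
    stopifnot(!is.null(o$name), !is.null(o$outcome_type))
    if (is.null(o$data)) o$data <- read_gwas_table(o$path)
    if (is.null(o$source)) o$source <- "unspecified"
    o
  })
  if (is.character(sets)) {
    known <- builtin_instrument_sets()
    stopifnot(all(sets %in% names(known)))
    sets <- known[sets]
  }
  structure(list(exposure = exposure, outcomes = outcomes, sets = sets,
                 methods = methods, config = config),
            class = "analysis_plan")
}

fit_one_method <- function(method, inst, config, outcome_type) {
  switch(method,
    ivw = ivw_pool(wald_ratios(inst, alpha = config$alpha), config,
                   instruments = inst, outcome_type = outcome_type),
    weighted_median = weighted_median_mr(inst, config,
                                         outcome_type = outcome_type),
    egger = egger_regression(inst, config, outcome_type = outcome_type))
}

#' Run the full sensitivity grid
#'
#' Executes every (outcome, instrument set, method) cell of a plan:
#' harmonizes the exposure against each outcome table, restricts to each
#' named subset, fits each method, and collects one row per cell on the
#' per-exposure-SD scale. Weighted-median cells hitting the
#' dominant-instrument rule are emitted with `available = FALSE` (rendered
#' "N/A"), never as errors; cell-level failures (e.g. an empty set after
#' harmonization) are recorded in `note` and the grid continues.
#'
#' @param plan An [analysis_plan()].
#' @return Data frame, one row per cell: `outcome`, `source`, `set`,
#'   `method`, `n_snps` (effective J), `available`, `beta`, `se`,
#'   `ci_low`, `ci_high` (per exposure SD), `outcome_type`, `note`.
#' @export
run_grid <- function(plan) {
  stopifnot(inherits(plan, "analysis_plan"))
  rows <- list()
  for (oc in plan$outcomes) {
    harm <- suppressMessages(harmonize(plan$exposure, oc$data))
    harm <- annotate_instruments(harm)
    for (set_name in names(plan$sets)) {
      inst <- tryCatch({
        s <- select_set(harm, plan$sets[[set_name]])
        usable_instruments(s)
      }, error = function(e) e)
      for (method in plan$methods) {
        row <- data.frame(
          outcome = oc$name, source = oc$source, set = set_name,
          method = method, n_snps = NA_integer_, available = FALSE,
          beta = NA_real_, se = NA_real_, ci_low = NA_real_,
          ci_high = NA_real_, outcome_type = oc$outcome_type,
          note = "", stringsAsFactors = FALSE
        )
        if (inherits(inst, "error")) {
          row$note <- conditionMessage(inst)
        } else if (nrow(inst) == 0) {
          row$note <- "no usable instruments after harmonization"
        } else {
          fit <- tryCatch(
            fit_one_method(method, inst, plan$config, oc$outcome_type),
            error = function(e) e)
          if (inherits(fit, "error")) {
            row$note <- conditionMessage(fit)
            row$n_snps <- nrow(inst)
          } else {
            row$n_snps <- fit$n_snps
            row$available <- fit$available
            if (fit$available) {
              row$beta <- fit$beta; row$se <- fit$se
              row$ci_low <- fit$ci_low; row$ci_high <- fit$ci_high
            } else {
              row$note <- "one SNP contributed more than 50% of the information"
            }
          }
        }
        rows[[length(rows) + 1]] <- row
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Render a grid on the reporting scale
#'
#' Converts a [run_grid()] result from per-SD to per-100-gram units and, for
#' binary outcomes, to odds ratios; adds display columns rounded the way the
#' published tables print (ORs to 2 decimals, mean differences to 2
#' significant figures). Unavailable cells render "N/A". Full-precision
#' per-SD columns are retained.
#'
#' @param grid Result of [run_grid()].
#' @param sd_grams Exposure SD in grams (default 484).
#' @return The grid with added columns `est_per_100g`, `lo_per_100g`,
#'   `hi_per_100g` (OR scale for log-odds outcomes) and a formatted
#'   `display` column.
#' @export
render_grid <- function(grid, sd_grams = BIRTHWEIGHT_SD_GRAMS) {
  f <- 100 / sd_grams
  is_or <- grid$outcome_type == "log_odds"
  est <- grid$beta * f
  lo <- grid$ci_low * f
  hi <- grid$ci_high * f
  grid$est_per_100g <- ifelse(is_or, exp(est), est)
  grid$lo_per_100g <- ifelse(is_or, exp(lo), lo)
  grid$hi_per_100g <- ifelse(is_or, exp(hi), hi)
  fmt <- function(x, or) {
    ifelse(is.na(x), NA_character_,
           ifelse(or, sprintf("%.2f", x), as.character(signif(x, 2))))
  }
  grid$display <- ifelse(
    !grid$available, "N/A",
    paste0(fmt(grid$est_per_100g, is_or), " (",
           fmt(grid$lo_per_100g, is_or), " to ",
           fmt(grid$hi_per_100g, is_or), ")"))
  grid
}

#' MR-Egger intercept screen for one instrument set
#'
#' @param instruments Harmonized instruments (J >= 3 usable rows).
#' @param config [mr_config()] settings.
#' @return One-row data frame: `n_snps`, `intercept`, `intercept_se`,
#'   `intercept_p`, `flagged` (p below `config$alpha`).
#' @export
egger_screen <- function(instruments, config = mr_config()) {
  fit <- egger_regression(instruments, config)
  data.frame(n_snps = fit$n_snps,
             intercept = fit$egger_intercept,
             intercept_se = fit$egger_intercept_se,
             intercept_p = fit$egger_intercept_p,
             flagged = fit$egger_intercept_p < config$alpha)
}

#' Funnel-plot data: per-SNP ratio vs precision
#'
#' One point per SNP with the Wald ratio on x and its precision (1 / SE of
#' the ratio) on y. The SE comes from the bounded Fieller interval when it
#' exists, otherwise from the first-order delta approximation; SNPs with an
#' undefined ratio are omitted with a message.
#'
#' @param instruments Harmonized instruments.
#' @param alpha Level for the Fieller intervals behind the SE.
#' @return Data frame: `rsid`, `ratio`, `precision`.
#' @export
funnel_data <- function(instruments, alpha = 0.05) {
  wr <- wald_ratios(instruments, alpha = alpha)
  if ("status" %in% names(instruments)) {
    instruments <- usable_instruments(instruments)
  }
  undefined <- is.na(wr$ratio)
  if (any(undefined)) {
    message("funnel_data: omitting SNP(s) with undefined ratio: ",
            paste(wr$rsid[undefined], collapse = ", "))
  }
  se_ratio <- ifelse(is.na(wr$variance),
                     sqrt(delta_variance(instruments$beta_x,
                                         instruments$se_y)),
                     sqrt(wr$variance))
  out <- data.frame(rsid = wr$rsid, ratio = wr$ratio,
                    precision = 1 / se_ratio,
                    stringsAsFactors = FALSE)
  out[!undefined, , drop = FALSE]
}

#' Forest-plot data: per-SNP estimates plus the pooled summary
#'
#' @param estimates Per-SNP Wald estimates from [wald_ratios()].
#' @param pooled An `mr_result` summary row.
#' @return Data frame of `label`, `estimate`, `ci_low`, `ci_high`, `kind`
#'   (`"snp"` or `"pooled"`); CI widths are the Fieller widths.
#' @export
forest_data <- function(estimates, pooled) {
  rows <- data.frame(label = estimates$rsid, estimate = estimates$ratio,
                     ci_low = estimates$ci_low, ci_high = estimates$ci_high,
                     kind = "snp", stringsAsFactors = FALSE)
  summary_row <- data.frame(
    label = paste0("pooled (", pooled$method, ")"),
    estimate = pooled$beta, ci_low = pooled$ci_low, ci_high = pooled$ci_high,
    kind = "pooled", stringsAsFactors = FALSE)
  out <- rbind(rows, summary_row)
  rownames(out) <- NULL
  out
}

#' Basic funnel plot
#'
#' @param points Data frame from [funnel_data()].
#' @param ivw_estimate Optional pooled IVW estimate drawn as a vertical line.
#' @return A ggplot object.
#' @export
plot_funnel <- function(points, ivw_estimate = NULL) {
  p <- ggplot2::ggplot(points,
                       ggplot2::aes(x = ratio, y = precision)) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "per-SNP causal estimate (Wald ratio)",
                  y = "precision (1/SE)") +
    ggplot2::theme_minimal()
  if (!is.null(ivw_estimate)) {
    p <- p + ggplot2::geom_vline(xintercept = ivw_estimate, linetype = 2)
  }
  p
}

#' Basic forest plot
#'
#' @param rows Data frame from [forest_data()].
#' @return A ggplot object.
#' @export
plot_forest <- function(rows) {
  rows$label <- factor(rows$label, levels = rev(rows$label))
  ggplot2::ggplot(rows, ggplot2::aes(x = estimate, y = label,
                                     shape = kind)) +
    ggplot2::geom_point() +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = ci_low,
                                         xmax = ci_high),
                            height = 0.2) +
    ggplot2::geom_vline(xintercept = 0, linetype = 3) +
    ggplot2::labs(x = "causal estimate per exposure SD", y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "none")
}

#' Write a results table as TSV
#'
#' @param df Data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_results_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}
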