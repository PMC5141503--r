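#' Read a GWAS summary-statistics table
#'
#' Reads a delimited text table of per-SNP association statistics (one row per
#' SNP) into a validated data frame. Consortium files differ in column naming,
#' so columns are selected through an explicit logical-to-physical mapping
#' rather than by position.
#'
#' @param path Path to a TSV or CSV file with a header row.
#' @param column_map Named character vector mapping the logical column names
#'   `rsid`, `effect_allele`, `other_allele`, `beta`, `se` (required) and
#'   `eaf`, `pvalue`, `n` (optional) to the column names in the file.
#'   Defaults to identity naming.
#' @param sep Field separator; `"auto"` (default) detects tab vs comma from
#'   the header line.
#'
#' @return A data frame with columns `rsid`, `effect_allele`, `other_allele`,
#'   `eaf`, `beta`, `se`, `pvalue`, `n` (missing optional columns are `NA`).
#'   Allele strings are upper-cased. Malformed rows abort with their line
#'   numbers.
#' @export
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("snp\tea\toa\tbeta\tse",
#'              "rs900400\tT\tC\t0.086\t0.006"), tf)
#' read_gwas_table(tf, c(rsid = "snp", effect_allele = "ea",
#'                       other_allele = "oa", beta = "beta", se = "se"))
read_gwas_table <- function(path, column_map = NULL, sep = "auto") {
  if (!file.exists(path)) {
    stop("summary-statistics file not found: ", path, call. = FALSE)
  }
  if (identical(sep, "auto")) {
    header <- readLines(path, n = 1L)
    sep <- if (grepl("\t", header)) "\t" else ","
  }
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE,
                           comment.char = "", quote = "\"")

  defaults <- c(rsid = "rsid", effect_allele = "effect_allele",
                other_allele = "other_allele", beta = "beta", se = "se",
                eaf = "eaf", pvalue = "pvalue", n = "n")
  map <- defaults
  if (!is.null(column_map)) {
    unknown <- setdiff(names(column_map), names(defaults))
    if (length(unknown)) {
      stop("unknown logical column(s) in column_map: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    map[names(column_map)] <- column_map
  }

  required <- c("rsid", "effect_allele", "other_allele", "beta", "se")
  missing_cols <- required[!map[required] %in% names(raw)]
  if (length(missing_cols)) {
    stop("required column(s) not found in ", path, ": ",
         paste(sprintf("%s (mapped to '%s')", missing_cols, map[missing_cols]),
               collapse = ", "), call. = FALSE)
  }

  get_col <- function(logical_name, as_num = FALSE) {
    physical <- map[[logical_name]]
    if (physical %in% names(raw)) {
      x <- raw[[physical]]
      if (as_num) suppressWarnings(as.numeric(x)) else as.character(x)
    } else {
      rep(NA_real_, nrow(raw))
    }
  }

  out <- data.frame(
    rsid = get_col("rsid"),
    effect_allele = toupper(get_col("effect_allele")),
    other_allele = toupper(get_col("other_allele")),
    eaf = get_col("eaf", as_num = TRUE),
    beta = get_col("beta", as_num = TRUE),
    se = get_col("se", as_num = TRUE),
    pvalue = get_col("pvalue", as_num = TRUE),
    n = get_col("n", as_num = TRUE),
    stringsAsFactors = FALSE
  )
  validate_gwas_records(out, source = path)
  out
}

# Validation shared by file input and in-memory tables. Line numbers are
# header-offset so they match the text file.
validate_gwas_records <- function(records, source = "input") {
  line_of <- function(i) i + 1L
  bad_allele <- which(!records$effect_allele %in% c("A", "C", "G", "T") |
                        !records$other_allele %in% c("A", "C", "G", "T"))
  if (length(bad_allele)) {
    stop(sprintf("invalid allele code(s) in %s at line(s) %s (rsid %s)",
                 source, paste(line_of(bad_allele), collapse = ", "),
                 paste(records$rsid[bad_allele], collapse = ", ")),
         call. = FALSE)
  }
  same <- which(records$effect_allele == records$other_allele)
  if (length(same)) {
    stop(sprintf("effect and other allele identical in %s for rsid %s (line %s)",
                 source, paste(records$rsid[same], collapse = ", "),
                 paste(line_of(same), collapse = ", ")), call. = FALSE)
  }
  bad_se <- which(!is.finite(records$se) | records$se <= 0)
  if (length(bad_se)) {
    stop(sprintf("standard error must be > 0 in %s: rsid %s (line %s)",
                 source, paste(records$rsid[bad_se], collapse = ", "),
                 paste(line_of(bad_se), collapse = ", ")), call. = FALSE)
  }
  bad_beta <- which(!is.finite(records$beta))
  if (length(bad_beta)) {
    stop(sprintf("missing or non-numeric beta in %s: line(s) %s",
                 source, paste(line_of(bad_beta), collapse = ", ")),
         call. = FALSE)
  }
  bad_eaf <- which(!is.na(records$eaf) & (records$eaf < 0 | records$eaf > 1))
  if (length(bad_eaf)) {
    stop(sprintf("effect-allele frequency outside [0, 1] in %s: rsid %s",
                 source, paste(records$rsid[bad_eaf], collapse = ", ")),
         call. = FALSE)
  }
  invisible(records)
}

#' Write a GWAS summary table in the dialect `read_gwas_table()` reads
#'
#' @param records Data frame as returned by [read_gwas_table()].
#' @param path Output path; tab-separated with header.
#' @return `path`, invisibly.
#' @export
write_gwas_table <- function(records, path) {
  utils::write.table(records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

dna_complement <- function(x) {
  chartr("ACGT", "TGCA", x)
}

is_palindromic <- function(a1, a2) {
  a1 == dna_complement(a2)
}

#' Harmonize exposure and outcome summary statistics to a shared effect allele
#'
#' Aligns each SNP's outcome association to the exposure's effect allele so
#' that the per-SNP effect pairs (beta_x, beta_y) refer to the same allele.
#' Matching alleles in order are kept as-is (`aligned`); swapped
#' effect/other alleles have the outcome beta negated (`flipped`); strand
#' complements are resolved by complementing the outcome alleles first.
#' Palindromic variants (A/T or G/C), whose strand cannot be inferred from the
#' alleles alone, are resolved from allele-frequency concordance when both
#' frequencies are informative, and otherwise flagged
#' `palindromic_ambiguous`. Anything else is `allele_mismatch`. Only
#' `aligned`/`flipped` rows enter estimation; nothing is silently dropped.
#'
#' @param exposure,outcome Data frames of per-SNP records (see
#'   [read_gwas_table()]), keyed by `rsid`.
#' @param palindromic_eaf_window Half-width around 0.5 within which an
#'   effect-allele frequency is considered uninformative for strand
#'   inference (default 0.08). Must lie in [0, 0.5).
#'
#' @return A data frame of class `mr_instruments` with one row per exposure
#'   rsid found in the outcome: `rsid`, `effect_allele`, `other_allele`,
#'   `beta_x`, `se_x`, `eaf_x`, `beta_y`, `se_y`, `eaf_y`, `status`,
#'   `annotations` (empty; see [annotate_instruments()]). Exposure rsids
#'   absent from the outcome are recorded in the `missing_rsids` attribute
#'   and reported with a message.
#' @export
harmonize <- function(exposure, outcome, palindromic_eaf_window = 0.08) {
  stopifnot(palindromic_eaf_window >= 0, palindromic_eaf_window < 0.5)
  validate_gwas_records(exposure, "exposure")
  validate_gwas_records(outcome, "outcome")
  if (anyDuplicated(exposure$rsid)) {
    stop("duplicated rsid in exposure table", call. = FALSE)
  }

  idx <- match(exposure$rsid, outcome$rsid)
  missing_rsids <- exposure$rsid[is.na(idx)]
  if (length(missing_rsids)) {
    message("harmonize: ", length(missing_rsids),
            " exposure SNP(s) absent from outcome table: ",
            paste(missing_rsids, collapse = ", "))
  }
  keep <- !is.na(idx)
  exp <- exposure[keep, , drop = FALSE]
  out <- outcome[idx[keep], , drop = FALSE]

  n <- nrow(exp)
  status <- character(n)
  beta_y <- out$beta
  eaf_y <- out$eaf

  eaf_informative <- function(f) {
    !is.na(f) & abs(f - 0.5) > palindromic_eaf_window
  }

  for (i in seq_len(n)) {
    ea_x <- exp$effect_allele[i]; oa_x <- exp$other_allele[i]
    ea_y <- out$effect_allele[i]; oa_y <- out$other_allele[i]

    if (is_palindromic(ea_x, oa_x)) {
      # alleles match under both strand readings; orientation only decidable
      # from allele frequencies
      if (!setequal(c(ea_y, oa_y), c(ea_x, oa_x))) {
        status[i] <- "allele_mismatch"
        next
      }
      if (!eaf_informative(exp$eaf[i]) || !eaf_informative(out$eaf[i])) {
        status[i] <- "palindromic_ambiguous"
        next
      }
      # the allele letter is uninformative for a palindrome (strand
      # complement maps each allele to the other); frequency concordance
      # alone decides the orientation
      same_side <- (exp$eaf[i] > 0.5) == (out$eaf[i] > 0.5)
      if (same_side) {
        status[i] <- "aligned"
      } else {
        status[i] <- "flipped"
        beta_y[i] <- -out$beta[i]
        eaf_y[i] <- 1 - out$eaf[i]
      }
      next
    }

    if (ea_y == ea_x && oa_y == oa_x) {
      status[i] <- "aligned"
    } else if (ea_y == oa_x && oa_y == ea_x) {
      status[i] <- "flipped"
      beta_y[i] <- -out$beta[i]
      eaf_y[i] <- if (is.na(out$eaf[i])) NA_real_ else 1 - out$eaf[i]
    } else if (dna_complement(ea_y) == ea_x && dna_complement(oa_y) == oa_x) {
      status[i] <- "aligned"
    } else if (dna_complement(ea_y) == oa_x && dna_complement(oa_y) == ea_x) {
      status[i] <- "flipped"
      beta_y[i] <- -out$beta[i]
      eaf_y[i] <- if (is.na(out$eaf[i])) NA_real_ else 1 - out$eaf[i]
    } else {
      status[i] <- "allele_mismatch"
    }
  }

  res <- data.frame(
    rsid = exp$rsid,
    effect_allele = exp$effect_allele,
    other_allele = exp$other_allele,
    beta_x = exp$beta,
    se_x = exp$se,
    eaf_x = exp$eaf,
    beta_y = beta_y,
    se_y = out$se,
    eaf_y = eaf_y,
    status = status,
    annotations = "",
    stringsAsFactors = FALSE
  )
  attr(res, "missing_rsids") <- missing_rsids
  class(res) <- c("mr_instruments", "data.frame")
  res
}

#' Rows of a harmonized set usable for estimation
#'
#' @param instruments `mr_instruments` data frame from [harmonize()].
#' @return The subset with status `aligned` or `flipped`.
#' @export
usable_instruments <- function(instruments) {
  instruments[instruments$status %in% c("aligned", "flipped"), , drop = FALSE]
}

#' Harmonization report
#'
#' One row per exposure SNP (including those missing from the outcome) with
#' the harmonization status and the action taken; writable as TSV.
#'
#' @param instruments Result of [harmonize()].
#' @param path Optional output path for a TSV copy.
#' @return Data frame with columns `rsid`, `status`, `action`.
#' @export
harmonization_report <- function(instruments, path = NULL) {
  action <- c(aligned = "kept as reported",
              flipped = "outcome beta negated (effect/other swapped)",
              palindromic_ambiguous = "excluded (strand not inferable)",
              allele_mismatch = "excluded (alleles incompatible)")
  rep_df <- data.frame(
    rsid = instruments$rsid,
    status = instruments$status,
    action = unname(action[instruments$status]),
    stringsAsFactors = FALSE
  )
  miss <- attr(instruments, "missing_rsids")
  if (length(miss)) {
    rep_df <- rbind(rep_df, data.frame(
      rsid = miss, status = "missing_in_outcome",
      action = "excluded (not found in outcome table)",
      stringsAsFactors = FALSE
    ))
  }
  if (!is.null(path)) {
    utils::write.table(rep_df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  rep_df
}

#' The named instrument subsets of the birth-weight analysis
#'
#' The sensitivity analyses run over nested subsets of the 7 genome-wide
#' significant birth-weight SNPs: dropping the two height-associated SNPs
#' (LCORL, HMGA2), then the blood-pressure SNP (ADRB1), then the two type-2
#' diabetes SNPs (CDKAL1, ADCY5), plus an extended set adding three SNPs
#' below genome-wide significance (p < 1e-5).
#'
#' @return Named list of five character vectors: `7snp`, `5snp`, `4snp`,
#'   `2snp`, `10snp`.
#' @export
#' @examples
#' builtin_instrument_sets()[["2snp"]]
builtin_instrument_sets <- function() {
  snp7 <- c("rs724577", "rs900400", "rs1042725", "rs1801253", "rs4432842",
            "rs6931514", "rs9883204")
  snp5 <- setdiff(snp7, c("rs724577", "rs1042725"))
  snp4 <- setdiff(snp5, "rs1801253")
  snp2 <- setdiff(snp4, c("rs6931514", "rs9883204"))
  snp10 <- c(snp7, "rs5415", "rs5758511", "rs7780752")
  list(`7snp` = snp7, `5snp` = snp5, `4snp` = snp4, `2snp` = snp2,
       `10snp` = snp10)
}

#' Subset harmonized instruments to a named set
#'
#' @param instruments `mr_instruments` data frame.
#' @param set Character vector of rsIDs, or the name of a built-in set
#'   (see [builtin_instrument_sets()]).
#' @return The member rows, in set order.
#' @export
select_set <- function(instruments, set) {
  if (is.character(set) && length(set) == 1 &&
      set %in% names(builtin_instrument_sets())) {
    set <- builtin_instrument_sets()[[set]]
  }
  stopifnot(length(set) >= 1, !anyDuplicated(set))
  absent <- setdiff(set, instruments$rsid)
  if (length(absent)) {
    stop("instrument set member(s) not present: ",
         paste(absent, collapse = ", "), call. = FALSE)
  }
  out <- instruments[match(set, instruments$rsid), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- class(instruments)
  out
}

#' Curated pleiotropy annotations for the birth-weight instruments
#'
#' Trait tags for the instruments with known associations beyond birth
#' weight: height (LCORL, HMGA2), blood pressure (ADRB1) and type 2 diabetes
#' (CDKAL1, ADCY5). Shipped as a TSV of (rsid, trait_tag) pairs under
#' `extdata`; user-supplied files in the same two-column format are accepted.
#'
#' @param path Optional path to a custom annotation TSV.
#' @return Data frame with columns `rsid`, `trait_tag`.
#' @export
default_pleiotropy_annotations <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "pleiotropy_annotations.tsv",
                        package = "bwmr")
  }
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
}

#' Attach curated trait annotations to harmonized instruments
#'
#' @param instruments `mr_instruments` data frame.
#' @param annotations Data frame of (rsid, trait_tag) pairs; defaults to the
#'   packaged curation.
#' @return `instruments` with the `annotations` column filled with
#'   comma-separated trait tags.
#' @export
annotate_instruments <- function(instruments,
                                 annotations = default_pleiotropy_annotations()) {
  tags <- vapply(instruments$rsid, function(id) {
    paste(annotations$trait_tag[annotations$rsid == id], collapse = ",")
  }, character(1))
  instruments$annotations <- unname(tags)
  instruments
}

#' Warn about correlated instruments
#'
#' Instruments are assumed uncorrelated (independent loci). When a
#' user-supplied pairwise r-squared table is available, flag pairs above a
#' threshold; the analysis itself does not adjust for LD.
#'
#' @param ld Data frame with columns `rsid1`, `rsid2`, `r2`.
#' @param threshold Warn when `r2` exceeds this (default 0.05).
#' @return Invisibly, the offending rows.
#' @export
check_ld_independence <- function(ld, threshold = 0.05) {
  stopifnot(all(c("rsid1", "rsid2", "r2") %in% names(ld)))
  bad <- ld[ld$r2 > threshold, , drop = FALSE]
  if (nrow(bad)) {
    warning(sprintf("instrument pair(s) with r2 > %g: %s", threshold,
                    paste(sprintf("%s-%s (%.3f)", bad$rsid1, bad$rsid2,
                                  bad$r2), collapse = "; ")),
            call. = FALSE)
  }
  invisible(bad)
}
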