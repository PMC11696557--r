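# Panel tumor mutational burden and actionability stratification.

# Targeted territory (Mb) per panel version. The published record states the
# gene counts (341/410/468/505) but not the captured megabases, so these are
# documented estimates supplied as overridable defaults, not authoritative
# values; always pass target_mb explicitly for clinical-grade numbers.
PANEL_TARGET_MB <- c(`341` = 0.98, `410` = 1.06, `468` = 1.14, `505` = 1.25)

#' Describe a panel version
#'
#' The assay grew from 341 genes (2014) through 410 (2015-2016) and 468
#' (2017-2020) to 505 genes (2021-2022). The targeted territory in megabases
#' is the TMB denominator; it is not derivable from the gene count, so a
#' built-in estimate is used unless `target_mb` is given.
#'
#' @param n_genes One of 341, 410, 468, 505.
#' @param target_mb Targeted megabases; overrides the built-in estimate.
#' @return An object of class `panel_version` with `name`, `n_genes`,
#'   `target_mb`, `years_active`.
#' @examples
#' panel_version(505, target_mb = 1.3)
#' @export
panel_version <- function(n_genes, target_mb = NULL) {
  years <- c(`341` = "2014", `410` = "2015-2016", `468` = "2017-2020",
             `505` = "2021-2022")
  key <- as.character(n_genes)
  if (!key %in% names(PANEL_TARGET_MB)) {
    stop_invalid("`n_genes` must be one of %s",
                 paste(names(PANEL_TARGET_MB), collapse = ", "))
  }
  if (is.null(target_mb)) target_mb <- unname(PANEL_TARGET_MB[key])
  if (!is_scalar_number(target_mb) || target_mb <= 0) {
    stop_invalid("`target_mb` must be > 0")
  }
  structure(list(name = sprintf("panel-%s", key), n_genes = as.integer(n_genes),
                 target_mb = target_mb, years_active = unname(years[key])),
            class = "panel_version")
}

#' Compute panel tumor mutational burden
#'
#' TMB is the number of nonsynonymous somatic mutations (driver mutations in
#' oncogenes included) divided by the panel's targeted genomic territory in
#' megabases. Synonymous variants never contribute.
#'
#' @param variants MAF-like data frame with a logical `nonsynonymous` column
#'   (zero rows allowed).
#' @param panel A [panel_version()] or a positive number of targeted
#'   megabases.
#' @return TMB in mutations per megabase.
#' @examples
#' v <- data.frame(nonsynonymous = rep(c(TRUE, FALSE), c(16, 4)))
#' compute_tmb(v, 1.6)  # 10
#' @export
compute_tmb <- function(variants, panel) {
  target_mb <- if (inherits(panel, "panel_version")) panel$target_mb else panel
  if (!is_scalar_number(target_mb) || target_mb <= 0) {
    stop_invalid("`target_mb` must be > 0")
  }
  check_columns(variants, "nonsynonymous", "variants")
  sum(variants$nonsynonymous) / target_mb
}

#' Classify a sample as TMB-high
#'
#' Samples with strictly more than `threshold` mutations per megabase
#' (default 10) are TMB-high; exactly 10 is not.
#'
#' @param tmb Mutations per megabase (>= 0); vectorized.
#' @param threshold TMB-high threshold (default 10 mutations/Mb).
#' @return Logical vector.
#' @examples
#' classify_tmb_high(c(10, 10.7))  # FALSE TRUE
#' @export
classify_tmb_high <- function(tmb, threshold = 10) {
  if (any(tmb < 0, na.rm = TRUE)) stop_invalid("`tmb` must be >= 0")
  tmb > threshold
}

ACTIONABILITY_ORDER <- c("L1", "L2", "L3A", "L3B", "L4",
                         "oncogenic_no_level", "vus")
ONCOKB_LEVELS <- c(ACTIONABILITY_ORDER, "R1", "R2")
TARGETABLE_LEVELS <- c("L1", "L2", "L3A", "L3B")

#' Highest actionability level of a variant set
#'
#' Ranks therapeutic levels L1 > L2 > L3A > L3B > L4 > oncogenic-no-level >
#' variant of unknown significance and reports the best one. A sample is
#' targetable when it carries at least one L1/L2/L3A/L3B alteration.
#' Resistance (R1) annotations form an independent axis and are reported as
#' a separate flag, not ranked against the therapeutic levels.
#'
#' @param variants MAF-like data frame with an `oncokb_level` column, or a
#'   character vector of levels.
#' @return A list: `best_level` (`NA` if no therapeutic-axis level present),
#'   `targetable`, `has_resistance` (any R1).
#' @examples
#' highest_actionability(c("L3B", "vus", "L1"))
#' highest_actionability(c("R1", "L2"))
#' @export
highest_actionability <- function(variants) {
  levels <- if (is.data.frame(variants)) {
    check_columns(variants, "oncokb_level", "variants")$oncokb_level
  } else {
    as.character(variants)
  }
  bad <- setdiff(levels, ONCOKB_LEVELS)
  if (length(bad)) {
    stop_invalid("unknown actionability level(s): %s",
                 paste(unique(bad), collapse = ", "))
  }
  ranks <- match(levels, ACTIONABILITY_ORDER)   # NA for R1/R2
  best <- if (all(is.na(ranks))) NA_character_ else {
    ACTIONABILITY_ORDER[min(ranks, na.rm = TRUE)]
  }
  list(best_level = best,
       targetable = !is.na(best) && best %in% TARGETABLE_LEVELS,
       has_resistance = any(levels == "R1"))
}
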