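# Internal helpers shared across modules.

#' Round half away from zero
#'
#' Presentation rounding used when comparing recomputed rates against printed
#' values: ties go up (49.5 -> 50), unlike base [round()]'s round-half-even.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places to keep.
#' @return `x` rounded half-up to `digits` decimals.
#' @examples
#' round_half_up(49.5)        # 50
#' round_half_up(80.55)       # 81
#' round_half_up(5.206, 1)    # 5.2
#' @export
round_half_up <- function(x, digits = 0) {
  s <- 10^digits
  # nudge by a relative eps so values that are exactly representable ties
  # (e.g. 29.7 * 55 arithmetic) are not knocked below .5 by FP error
  floor(x * s + 0.5 + sign(x) * .Machine$double.eps * abs(x) * s) / s
}

# invalid-argument / invalid-input conditions
stop_invalid <- function(fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c("cytoqc_invalid_input", "cytoqc_error")))
}

# not-estimable: distinct from a zero estimate
stop_not_estimable <- function(fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c("cytoqc_not_estimable", "cytoqc_error")))
}

# scalar checks ---------------------------------------------------------

is_scalar_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}

check_fraction <- function(x, name, lo = 0, hi = 1,
                           lo_open = FALSE, hi_open = FALSE) {
  if (!is_scalar_number(x)) stop_invalid("`%s` must be a finite number", name)
  ok_lo <- if (lo_open) x > lo else x >= lo
  ok_hi <- if (hi_open) x < hi else x <= hi
  if (!ok_lo || !ok_hi) {
    stop_invalid("`%s` = %g is outside %s%g, %g%s", name, x,
                 if (lo_open) "(" else "[", lo, hi, if (hi_open) ")" else "]")
  }
  invisible(x)
}

check_count <- function(x, name, min = 1) {
  if (!is_scalar_number(x) || x != trunc(x) || x < min) {
    stop_invalid("`%s` must be an integer >= %d", name, min)
  }
  invisible(as.integer(x))
}

# data-frame column checks ----------------------------------------------

check_columns <- function(df, cols, what) {
  if (!is.data.frame(df)) stop_invalid("`%s` must be a data frame", what)
  miss <- setdiff(cols, names(df))
  if (length(miss)) {
    stop_invalid("`%s` is missing column(s): %s", what,
                 paste(miss, collapse = ", "))
  }
  invisible(df)
}

check_allele_counts <- function(counts, what = "counts") {
  check_columns(counts, c("site_id", "depth", "ref_count", "alt_count",
                          "other_count"), what)
  num <- counts[c("depth", "ref_count", "alt_count", "other_count")]
  if (any(vapply(num, function(x) any(!is.finite(x) | x < 0), logical(1)))) {
    stop_invalid("`%s` contains negative or non-finite counts", what)
  }
  tot <- counts$ref_count + counts$alt_count + counts$other_count
  if (any(tot != counts$depth)) {
    stop_invalid("`%s`: ref + alt + other must equal depth at every site", what)
  }
  invisible(counts)
}

check_snp_panel <- function(panel, what = "panel") {
  check_columns(panel, c("site_id", "chrom", "pos", "ref_allele",
                         "alt_allele", "pop_alt_freq"), what)
  if (anyDuplicated(panel$site_id)) {
    stop_invalid("`%s`: site_id values must be unique", what)
  }
  if (any(panel$pop_alt_freq <= 0 | panel$pop_alt_freq >= 1)) {
    stop_invalid("`%s`: pop_alt_freq must lie strictly in (0, 1)", what)
  }
  if (any(panel$ref_allele == panel$alt_allele)) {
    stop_invalid("`%s`: ref and alt alleles must differ", what)
  }
  invisible(panel)
}

check_genotype_profile <- function(profile, what = "profile") {
  check_columns(profile, c("site_id", "genotype", "alt_dosage"), what)
  bad <- !profile$genotype %in% c("hom_ref", "het", "hom_alt", "no_call")
  if (any(bad)) stop_invalid("`%s`: unknown genotype labels", what)
  invisible(profile)
}

GENOTYPE_LEVELS <- c("hom_ref", "het", "hom_alt", "no_call")
dosage_to_genotype <- function(d) c("hom_ref", "het", "hom_alt")[d + 1L]
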