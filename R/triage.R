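# End-to-end sample qualification: pre-analytic gates, sequencing gates and
# the contamination gate with a VAF-filter rescue, yielding exactly one
# outcome category per sample. Gate precedence mirrors the physical
# laboratory workflow: tumor-content review happens before extraction
# metrics, which precede sequencing metrics, which precede the
# contamination check.

#' Era-dependent DNA-input acceptance policy
#'
#' Minimum DNA concentration thresholds for cell-block extractions: 0.9
#' ng/uL until September 2021, 0.54 ng/uL thereafter, which with the assay's
#' 55 uL maximum input volume translate to minimum total inputs of 50 ng and
#' 30 ng respectively (0.9 * 55 = 49.5 -> 50; 0.54 * 55 = 29.7 -> 30, round
#' half up).
#'
#' @param cutoff_date Date the lower threshold took effect.
#' @param conc_threshold_before,conc_threshold_after Minimum DNA
#'   concentrations (ng/uL) before/after `cutoff_date`.
#' @param max_volume Maximum assay input volume (uL).
#' @return An object of class `era_policy`.
#' @examples
#' era_policy()$min_input_after   # 30
#' @export
era_policy <- function(cutoff_date = as.Date("2021-09-01"),
                       conc_threshold_before = 0.9,
                       conc_threshold_after = 0.54,
                       max_volume = 55) {
  structure(list(
    cutoff_date = as.Date(cutoff_date),
    conc_threshold_before = conc_threshold_before,
    conc_threshold_after = conc_threshold_after,
    max_volume = max_volume,
    min_input_before = round_half_up(conc_threshold_before * max_volume),
    min_input_after = round_half_up(conc_threshold_after * max_volume)
  ), class = "era_policy")
}

#' DNA-input gate
#'
#' A cell-block sample fails if its DNA concentration is strictly below the
#' threshold in force on its collection date. Supernatant cfDNA samples are
#' sequenced below these thresholds (to spare the patient a repeat biopsy)
#' and bypass the gate.
#'
#' @param dna_conc DNA concentration in ng/uL (>= 0); vectorized.
#' @param date Collection date(s), coercible with [as.Date()].
#' @param policy An [era_policy()].
#' @param prep_type `"CB"`, `"ScfDNA"` or `"surgical"`; ScfDNA always passes.
#' @return `"pass"`/`"fail"` per sample.
#' @examples
#' evaluate_dna_input(0.6, "2020-05-01")  # fail (0.9 threshold era)
#' evaluate_dna_input(0.6, "2022-01-01")  # pass (0.54 threshold era)
#' @export
evaluate_dna_input <- function(dna_conc, date, policy = era_policy(),
                               prep_type = "CB") {
  if (any(dna_conc < 0, na.rm = TRUE)) stop_invalid("`dna_conc` must be >= 0")
  date <- as.Date(date)
  thr <- ifelse(date < policy$cutoff_date,
                policy$conc_threshold_before, policy$conc_threshold_after)
  ifelse(prep_type == "ScfDNA" | dna_conc >= thr, "pass", "fail")
}

#' Tumor-content gate
#'
#' Samples are rejected when the tumor proportion is below 10% and manual
#' enrichment (macro-dissection) is not feasible; the 10% boundary itself
#' passes.
#'
#' @param tumor_purity Tumor cell percentage in `[0, 100]`; vectorized.
#' @param enrichable Whether manual enrichment is possible.
#' @return `"pass"`/`"fail"` per sample.
#' @export
evaluate_tumor_content <- function(tumor_purity, enrichable) {
  if (any(tumor_purity < 0 | tumor_purity > 100, na.rm = TRUE)) {
    stop_invalid("`tumor_purity` must be a percentage in [0, 100]")
  }
  ifelse(tumor_purity < 10 & !enrichable, "fail", "pass")
}

#' Coverage gate
#'
#' Samples below 50x fold-coverage fail outright; coverage in `[50, 200)` is
#' flagged low (sensitivity concerns for variant calling at 2% allele
#' fraction, and contamination estimates become unreliable) but does not by
#' itself fail the sample; 200x and above is adequate.
#'
#' @param sample_coverage Fold coverage (>= 0); vectorized.
#' @return `"fail"`, `"low_coverage_flag"` or `"adequate"` per sample.
#' @examples
#' evaluate_coverage(c(40, 150, 600))
#' @export
evaluate_coverage <- function(sample_coverage) {
  if (any(sample_coverage < 0, na.rm = TRUE)) {
    stop_invalid("`sample_coverage` must be >= 0")
  }
  ifelse(sample_coverage < 50, "fail",
         ifelse(sample_coverage < 200, "low_coverage_flag", "adequate"))
}

#' Contamination gate with VAF-filter rescue
#'
#' A sample with clinically significant contamination (`alpha_hat >= cutoff`)
#' but very high tumor content remains partially evaluable: variants with
#' VAF at or below the contamination level are filtered out, since they
#' could originate from the contaminant, while higher-VAF calls are
#' retained. "Very high tumor content" is quantified as the expected clonal
#' driver VAF (`purity/2`, as a fraction) exceeding `margin * alpha_hat`.
#' Below that, contamination and real signal are not separable and the whole
#' sample fails.
#'
#' @param variants MAF-like data frame with a `vaf` column.
#' @param alpha_hat Estimated contamination fraction in `[0, 1]`.
#' @param tumor_purity Tumor percentage in `[0, 100]`.
#' @param cutoff Clinical contamination cutoff (default 0.02).
#' @param margin Separation factor between expected driver VAF and
#'   contamination level required for the rescue (default 2).
#' @return A list: `variants` (retained rows), `partially_evaluable`,
#'   `evaluable` (FALSE means whole-sample contamination failure),
#'   `vaf_filter_threshold` (`NA` unless filtering was applied).
#' @examples
#' v <- data.frame(vaf = c(0.01, 0.02, 0.28))
#' contamination_vaf_filter(v, alpha_hat = 0.03, tumor_purity = 60)
#' @export
contamination_vaf_filter <- function(variants, alpha_hat, tumor_purity,
                                     cutoff = 0.02, margin = 2) {
  check_fraction(alpha_hat, "alpha_hat")
  check_columns(variants, "vaf", "variants")
  if (alpha_hat < cutoff) {
    return(list(variants = variants, partially_evaluable = FALSE,
                evaluable = TRUE, vaf_filter_threshold = NA_real_))
  }
  expected_driver_vaf <- (tumor_purity / 100) / 2
  if (expected_driver_vaf > margin * alpha_hat) {
    keep <- variants$vaf > alpha_hat
    list(variants = variants[keep, , drop = FALSE],
         partially_evaluable = TRUE, evaluable = TRUE,
         vaf_filter_threshold = alpha_hat)
  } else {
    list(variants = variants[0, , drop = FALSE],
         partially_evaluable = FALSE, evaluable = FALSE,
         vaf_filter_threshold = NA_real_)
  }
}

# vectorized gate engine shared by triage_sample() and triage_cohort()
triage_engine <- function(prep_type, collection_date, tumor_purity,
                          enrichable, dna_conc, sample_coverage,
                          base_quality_ok, alpha, policy, cutoff, margin) {
  n <- length(tumor_purity)
  need <- list(prep_type = prep_type, tumor_purity = tumor_purity,
               enrichable = enrichable, dna_conc = dna_conc,
               sample_coverage = sample_coverage,
               base_quality_ok = base_quality_ok)
  for (nm in names(need)) {
    if (length(need[[nm]]) != n || anyNA(need[[nm]])) {
      stop_invalid("missing or malformed required QC field `%s`", nm)
    }
  }
  alpha <- if (is.null(alpha)) rep(NA_real_, n) else alpha

  tumor_fail <- evaluate_tumor_content(tumor_purity, enrichable) == "fail"
  dna_fail <- evaluate_dna_input(dna_conc, collection_date, policy,
                                 prep_type) == "fail"
  cov_fail <- evaluate_coverage(sample_coverage) == "fail"
  qual_fail <- !base_quality_ok
  contam_sig <- !is.na(alpha) & alpha >= cutoff
  rescue <- contam_sig & (tumor_purity / 100) / 2 > margin * alpha
  contam_fail <- contam_sig & !rescue

  outcome <- rep("pass", n)
  # assign in reverse precedence so earlier gates overwrite later ones
  outcome[contam_fail] <- "fail_contamination"
  outcome[qual_fail] <- "fail_low_quality"
  outcome[cov_fail] <- "fail_low_coverage"
  outcome[dna_fail] <- "fail_low_dna"
  outcome[tumor_fail] <- "fail_scant_tumor"

  pe <- outcome == "pass" & rescue
  data.frame(
    outcome = outcome,
    partially_evaluable = pe,
    vaf_filter_threshold = ifelse(pe, alpha, NA_real_),
    stringsAsFactors = FALSE
  )
}

#' Triage one sample through the qualification gates
#'
#' Applies the gates in pipeline order — tumor content, DNA input (era
#' policy, skipped for ScfDNA), coverage, base quality, contamination — and
#' the first failing gate fixes the outcome. A sample with significant
#' contamination but high tumor content passes as partially evaluable with a
#' VAF filter threshold attached (see [contamination_vaf_filter()]).
#'
#' @param qc A list or one-row data frame with fields `prep_type`,
#'   `tumor_purity`, `enrichable`, `dna_conc`, `sample_coverage`,
#'   `base_quality_ok`, and `collection_date` (or `year`).
#' @param contamination A `contam_fit`, a numeric contamination fraction, or
#'   `NULL` when no contamination assessment is available.
#' @param policy An [era_policy()].
#' @param cutoff,margin Contamination-gate parameters, see
#'   [contamination_vaf_filter()].
#' @return An object of class `triage_decision`: `outcome` (one of `pass`,
#'   `fail_scant_tumor`, `fail_low_dna`, `fail_low_coverage`,
#'   `fail_low_quality`, `fail_contamination`), `partially_evaluable`,
#'   `vaf_filter_threshold`.
#' @examples
#' qc <- list(prep_type = "CB", tumor_purity = 30, enrichable = TRUE,
#'            dna_conc = 2.0, sample_coverage = 600, base_quality_ok = TRUE,
#'            collection_date = "2020-01-01")
#' triage_sample(qc, contamination = 0.004)$outcome  # pass
#' @export
triage_sample <- function(qc, contamination = NULL, policy = era_policy(),
                          cutoff = 0.02, margin = 2) {
  if (is.data.frame(qc)) {
    if (nrow(qc) != 1L) stop_invalid("`qc` must describe a single sample")
    qc <- as.list(qc)
  }
  date <- qc$collection_date
  if (is.null(date)) {
    if (is.null(qc$year)) stop_invalid("`qc` needs `collection_date` or `year`")
    date <- as.Date(sprintf("%d-06-15", qc$year))
  }
  alpha <- if (inherits(contamination, "contam_fit")) {
    contamination$alpha_hat
  } else contamination
  res <- triage_engine(qc$prep_type, as.Date(date), qc$tumor_purity,
                       qc$enrichable, qc$dna_conc, qc$sample_coverage,
                       qc$base_quality_ok, alpha, policy, cutoff, margin)
  structure(list(sample_id = qc$sample_id,
                 outcome = res$outcome,
                 partially_evaluable = res$partially_evaluable,
                 vaf_filter_threshold = res$vaf_filter_threshold),
            class = "triage_decision")
}

#' @export
print.triage_decision <- function(x, ...) {
  cat(sprintf("Triage: %s%s\n", x$outcome,
              if (x$partially_evaluable) {
                sprintf(" (partially evaluable, VAF filter at %.3f)",
                        x$vaf_filter_threshold)
              } else ""))
  invisible(x)
}

#' Triage every sample in a manifest
#'
#' Vectorized application of [triage_sample()] over a manifest such as the
#' one produced by [simulate_cohort()]; the `contamination_rate` column (if
#' present) feeds the contamination gate.
#'
#' @param manifest Manifest data frame; see [simulate_cohort()] for the
#'   column contract.
#' @param policy An [era_policy()].
#' @param cutoff,margin Contamination-gate parameters.
#' @return Data frame `sample_id`, `outcome`, `partially_evaluable`,
#'   `vaf_filter_threshold`.
#' @export
triage_cohort <- function(manifest, policy = era_policy(), cutoff = 0.02,
                          margin = 2) {
  check_columns(manifest, c("sample_id", "prep_type", "tumor_purity",
                            "enrichable", "dna_conc", "sample_coverage",
                            "base_quality_ok"), "manifest")
  date <- if ("collection_date" %in% names(manifest)) {
    as.Date(manifest$collection_date)
  } else if ("year" %in% names(manifest)) {
    as.Date(sprintf("%d-06-15", manifest$year))
  } else {
    stop_invalid("`manifest` needs `collection_date` or `year`")
  }
  alpha <- if ("contamination_rate" %in% names(manifest)) {
    manifest$contamination_rate
  } else NULL
  res <- triage_engine(manifest$prep_type, date, manifest$tumor_purity,
                       manifest$enrichable, manifest$dna_conc,
                       manifest$sample_coverage, manifest$base_quality_ok,
                       alpha, policy, cutoff, margin)
  cbind(data.frame(sample_id = manifest$sample_id,
                   stringsAsFactors = FALSE), res)
}

#' Expected number of queryable target DNA molecules
#'
#' Targeted assays quantify, by digital droplet PCR, how many amplifiable
#' target copies a nanogram of FFPE-derived DNA contributes; multiplying by
#' the DNA input mass gives the number of target molecules the assay can
#' query. At the assay's minimum accepted input of 30 ng and the lower 95%
#' confidence bound of 220.5 copies/ng, at least 6615 target molecules are
#' expected in 95% of cases.
#'
#' @param input_ng DNA input mass in nanograms (>= 0).
#' @param copies_per_ng Amplifiable target copies per nanogram (>= 0).
#' @return Expected molecule count, rounded half-up to the nearest integer.
#' @examples
#' expected_target_copies(30, 220.5)  # 6615
#' @export
expected_target_copies <- function(input_ng, copies_per_ng) {
  if (any(input_ng < 0) || any(copies_per_ng < 0)) {
    stop_invalid("inputs must be >= 0")
  }
  round_half_up(input_ng * copies_per_ng)
}
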