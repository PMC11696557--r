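# Synthetic-cohort simulator: SNP panels, germline genotypes and two-person
# read mixtures with known contamination fraction. The protected clinical
# data cannot be shipped, so every pipeline input is generated here with
# ground truth attached for parameter-recovery testing.

#' Simulate a panel of common SNP sites
#'
#' Large tumor panels tile intergenic/intronic probes centered on common SNPs
#' specifically so that germline genotypes can be used for identity and
#' contamination QC. This generates such a panel with population alternate
#' allele frequencies drawn uniformly on `[af_low, af_high]`; the default
#' spectrum Uniform(0.05, 0.5) reflects that panel SNPs are chosen to be
#' common (minor allele frequency well above rare-variant territory).
#'
#' @param n_sites Number of SNP sites (positive integer).
#' @param af_low,af_high Bounds of the population alternate-allele frequency
#'   spectrum, `0 < af_low <= af_high < 1`.
#' @param seed Optional integer seed; the panel is deterministic given it.
#' @return A data frame with columns `site_id`, `chrom`, `pos`, `ref_allele`,
#'   `alt_allele`, `pop_alt_freq`.
#' @examples
#' panel <- simulate_snp_panel(100, seed = 1)
#' range(panel$pop_alt_freq)
#' @export
simulate_snp_panel <- function(n_sites, af_low = 0.05, af_high = 0.5,
                               seed = NULL) {
  n_sites <- check_count(n_sites, "n_sites")
  check_fraction(af_low, "af_low", lo_open = TRUE, hi_open = TRUE)
  check_fraction(af_high, "af_high", lo_open = TRUE, hi_open = TRUE)
  if (af_low > af_high) stop_invalid("`af_low` must be <= `af_high`")
  if (!is.null(seed)) set.seed(seed)

  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n_sites, replace = TRUE)
  # alt drawn from the three non-ref bases
  alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1L), character(1))
  data.frame(
    site_id = sprintf("snp%05d", seq_len(n_sites)),
    chrom = sample(paste0("chr", 1:22), n_sites, replace = TRUE),
    pos = sample.int(2.4e8, n_sites),
    ref_allele = ref,
    alt_allele = unname(alt),
    pop_alt_freq = stats::runif(n_sites, af_low, af_high),
    stringsAsFactors = FALSE
  )
}

#' Simulate diploid germline genotypes under Hardy-Weinberg equilibrium
#'
#' At a site with population alternate-allele frequency p, the alt-allele
#' dosage is Binomial(2, p), i.e. genotype probabilities (1-p)^2, 2p(1-p),
#' p^2 for hom_ref / het / hom_alt. Patient and contaminant individuals are
#' drawn independently from the same population.
#'
#' @param panel SNP panel as returned by [simulate_snp_panel()].
#' @param seed Optional integer seed.
#' @return A genotype profile: data frame with `site_id`, `genotype`
#'   (`hom_ref`/`het`/`hom_alt`), `alt_dosage` (0/1/2).
#' @examples
#' panel <- simulate_snp_panel(50, seed = 1)
#' gt <- simulate_genotypes(panel, seed = 2)
#' table(gt$genotype)
#' @export
simulate_genotypes <- function(panel, seed = NULL) {
  check_snp_panel(panel)
  if (nrow(panel) == 0L) stop_invalid("`panel` must contain at least one site")
  if (!is.null(seed)) set.seed(seed)
  d <- stats::rbinom(nrow(panel), 2L, panel$pop_alt_freq)
  data.frame(
    site_id = panel$site_id,
    genotype = dosage_to_genotype(d),
    alt_dosage = d,
    stringsAsFactors = FALSE
  )
}

#' Specify a two-person DNA mixture
#'
#' Bundles the parameters of a simulated tumor library: the contaminant read
#' fraction `alpha` (the quantity the contamination estimator recovers; the
#' patient contributes fraction `1 - alpha`), tumor cell fraction `purity`,
#' mean per-site depth, a symmetric ref<->alt per-base miscall rate, and an
#' optional negative-binomial overdispersion for depth (real panel coverage
#' is overdispersed; the Poisson default is the idealized case).
#'
#' @param alpha Contaminant read fraction in `[0, 1)`.
#' @param purity Tumor cell fraction in `[0, 1]`.
#' @param mean_depth Mean reads per site (> 0).
#' @param error_rate Per-base miscall fraction in `[0, 0.01]`; default 0.001.
#' @param seed Optional integer seed used by [simulate_allele_counts()].
#' @param overdispersion Optional negative-binomial `size`; `NULL` keeps
#'   Poisson depths.
#' @return An object of class `mixture_spec`.
#' @export
mixture_spec <- function(alpha = 0, purity = 1, mean_depth = 500,
                         error_rate = 0.001, seed = NULL,
                         overdispersion = NULL) {
  check_fraction(alpha, "alpha", hi_open = TRUE)
  check_fraction(purity, "purity")
  if (!is_scalar_number(mean_depth) || mean_depth <= 0) {
    stop_invalid("`mean_depth` must be > 0")
  }
  check_fraction(error_rate, "error_rate", hi = 0.01)
  if (!is.null(overdispersion) &&
      (!is_scalar_number(overdispersion) || overdispersion <= 0)) {
    stop_invalid("`overdispersion` must be NULL or > 0")
  }
  structure(list(alpha = alpha, purity = purity, mean_depth = mean_depth,
                 error_rate = error_rate, seed = seed,
                 overdispersion = overdispersion),
            class = "mixture_spec")
}

#' Simulate tumor-sample allele counts from a two-person mixture
#'
#' Per site the depth is Poisson(`mean_depth`) (negative binomial if the spec
#' sets `overdispersion`), and the expected alt-read fraction is
#' `f = (1 - alpha) * d_p / 2 + alpha * d_c / 2` where `d_p`, `d_c` are the
#' patient and contaminant alt dosages. Sequencing error perturbs `f`
#' symmetrically toward the other allele (`f' = f(1 - e) + (1 - f)e`), and
#' the alt count is Binomial(depth, f'). At sites where the patient is
#' homozygous, any unexpected-allele reads are therefore contamination (or
#' error) by construction — exactly the discrepancies the estimator measures.
#'
#' @param patient,contaminant Genotype profiles on the same panel.
#' @param spec A [mixture_spec()].
#' @param panel The SNP panel both profiles were drawn on.
#' @return Allele-count data frame: `site_id`, `depth`, `ref_count`,
#'   `alt_count`, `other_count` (always summing to `depth`).
#' @examples
#' panel <- simulate_snp_panel(200, seed = 1)
#' pat <- simulate_genotypes(panel, seed = 2)
#' con <- simulate_genotypes(panel, seed = 3)
#' cnt <- simulate_allele_counts(pat, con, mixture_spec(alpha = 0.05, seed = 4),
#'                               panel)
#' @export
simulate_allele_counts <- function(patient, contaminant, spec, panel) {
  check_snp_panel(panel)
  check_genotype_profile(patient, "patient")
  check_genotype_profile(contaminant, "contaminant")
  if (!inherits(spec, "mixture_spec")) {
    stop_invalid("`spec` must be created by mixture_spec()")
  }
  if (!identical(sort(patient$site_id), sort(panel$site_id)) ||
      !identical(sort(contaminant$site_id), sort(panel$site_id))) {
    stop_invalid("patient/contaminant profiles must cover the same panel")
  }
  if (!is.null(spec$seed)) set.seed(spec$seed)

  n <- nrow(panel)
  dp <- patient$alt_dosage[match(panel$site_id, patient$site_id)]
  dc <- contaminant$alt_dosage[match(panel$site_id, contaminant$site_id)]
  depth <- if (is.null(spec$overdispersion)) {
    stats::rpois(n, spec$mean_depth)
  } else {
    stats::rnbinom(n, size = spec$overdispersion, mu = spec$mean_depth)
  }
  f <- (1 - spec$alpha) * dp / 2 + spec$alpha * dc / 2
  f <- f * (1 - spec$error_rate) + (1 - f) * spec$error_rate
  alt <- stats::rbinom(n, depth, f)
  data.frame(
    site_id = panel$site_id,
    depth = depth,
    ref_count = depth - alt,
    alt_count = alt,
    other_count = 0L,
    stringsAsFactors = FALSE
  )
}

#' Simulate purity-scaled somatic variants
#'
#' Somatic variants are modeled as diploid heterozygous events with cancer
#' cell fraction (CCF) 1 for clonal mutations and Uniform(0.1, 1) for
#' subclonal ones, giving `VAF = purity * CCF / 2`, so all VAFs lie in
#' `(0, purity/2]`. Nonsynonymous status and actionability level are drawn
#' from configurable categorical distributions; the default level weights are
#' dominated by variants of unknown significance, as in clinical panels.
#' Variants are placed at positions distinct from any QC SNP panel.
#'
#' @param n_variants Number of variants (positive integer).
#' @param purity Tumor cell fraction in `(0, 1]`.
#' @param seed Optional integer seed.
#' @param clonal_fraction Probability a variant is clonal (CCF = 1).
#' @param nonsyn_prob Probability a variant is nonsynonymous.
#' @param level_probs Named probability vector over actionability levels.
#' @return MAF-like data frame: `gene`, `chrom`, `pos`, `ref`, `alt`, `vaf`,
#'   `nonsynonymous`, `oncokb_level`.
#' @examples
#' v <- simulate_tumor_variants(20, purity = 0.4, seed = 1)
#' max(v$vaf) <= 0.2
#' @export
simulate_tumor_variants <- function(n_variants, purity, seed = NULL,
                                    clonal_fraction = 0.7,
                                    nonsyn_prob = 0.75,
                                    level_probs = c(
                                      L1 = 0.12, L2 = 0.03, L3A = 0.05,
                                      L3B = 0.05, L4 = 0.05, R1 = 0.02,
                                      oncogenic_no_level = 0.06, vus = 0.62)) {
  n_variants <- check_count(n_variants, "n_variants")
  check_fraction(purity, "purity", lo_open = TRUE)
  check_fraction(clonal_fraction, "clonal_fraction")
  check_fraction(nonsyn_prob, "nonsyn_prob")
  if (is.null(names(level_probs)) || any(level_probs < 0)) {
    stop_invalid("`level_probs` must be a named non-negative vector")
  }
  if (!is.null(seed)) set.seed(seed)

  genes <- c("EGFR", "KRAS", "PIK3CA", "ERBB2", "TP53", "ALK", "BRAF",
             "RET", "ROS1", "STK11", "KEAP1", "FGFR3", "ESR1", "CDKN2A")
  bases <- c("A", "C", "G", "T")
  ccf <- ifelse(stats::runif(n_variants) < clonal_fraction, 1,
                stats::runif(n_variants, 0.1, 1))
  ref <- sample(bases, n_variants, replace = TRUE)
  alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1L), character(1))
  data.frame(
    gene = sample(genes, n_variants, replace = TRUE),
    chrom = sample(paste0("chr", 1:22), n_variants, replace = TRUE),
    pos = sample.int(2.4e8, n_variants),   # unique -> unique identity keys
    ref = ref,
    alt = unname(alt),
    vaf = purity * ccf / 2,
    nonsynonymous = stats::runif(n_variants) < nonsyn_prob,
    oncokb_level = sample(names(level_probs), n_variants, replace = TRUE,
                          prob = level_probs),
    stringsAsFactors = FALSE
  )
}

# outcome categories in triage-gate order (pass last for readability)
TRIAGE_OUTCOMES <- c("pass", "fail_low_dna", "fail_scant_tumor",
                     "fail_low_coverage", "fail_contamination",
                     "fail_low_quality")

#' Simulate a sample manifest with known triage outcomes
#'
#' Each sample is assigned a target outcome category by multinomial sampling
#' from `outcome_probs`, then given pre-analytic and sequencing metrics that
#' the triage procedure maps back to exactly that category: the intended gate
#' fails while every other gate passes. Default probabilities are the
#' published cohort's outcome frequencies (80.6% success; failures 11.3% low
#' DNA, 4.6% scant tumor, 1.8% low coverage, 1.6% contamination, 0.1% low
#' quality). Samples destined to fail the DNA-input gate are forced to cell
#' block preparation since supernatant cfDNA bypasses that gate.
#'
#' @param n_samples Number of samples (positive integer).
#' @param outcome_probs Named probabilities over
#'   `pass`, `fail_low_dna`, `fail_scant_tumor`, `fail_low_coverage`,
#'   `fail_contamination`, `fail_low_quality`; must sum to 1 (tol 1e-9).
#' @param seed Optional integer seed.
#' @param years Calendar years to sample collection dates from.
#' @return Manifest data frame with one row per sample: identifiers,
#'   `prep_type` (CB/ScfDNA), `source`, `year`, `collection_date`,
#'   `tumor_purity` (percent), `enrichable`, `dna_conc` (ng/uL), `dna_yield`
#'   (ng), `sample_coverage` (fold), `base_quality_ok`, `contamination_rate`
#'   and the generating `true_outcome`.
#' @examples
#' m <- simulate_cohort(500, seed = 1)
#' table(m$true_outcome)
#' @export
simulate_cohort <- function(n_samples,
                            outcome_probs = c(
                              pass = 0.806, fail_low_dna = 0.113,
                              fail_scant_tumor = 0.046,
                              fail_low_coverage = 0.018,
                              fail_contamination = 0.016,
                              fail_low_quality = 0.001),
                            seed = NULL, years = 2014:2022) {
  n_samples <- check_count(n_samples, "n_samples")
  if (is.null(names(outcome_probs)) ||
      !all(names(outcome_probs) %in% TRIAGE_OUTCOMES)) {
    stop_invalid("`outcome_probs` must be named with triage outcome categories")
  }
  if (any(outcome_probs < 0) || abs(sum(outcome_probs) - 1) > 1e-9) {
    stop_invalid("`outcome_probs` must be non-negative and sum to 1")
  }
  if (!is.null(seed)) set.seed(seed)

  n <- n_samples
  cat_ <- sample(names(outcome_probs), n, replace = TRUE,
                 prob = outcome_probs)

  year <- sample(years, n, replace = TRUE)
  month <- sample.int(12, n, replace = TRUE)
  prep <- sample(c("CB", "ScfDNA"), n, replace = TRUE, prob = c(0.942, 0.058))
  src <- sample(c("internal", "external"), n, replace = TRUE,
                prob = c(0.63, 0.37))

  # metrics that clear every gate, then per-category overrides
  purity <- stats::runif(n, 15, 90)
  enrich <- rep(TRUE, n)
  conc <- stats::runif(n, 1.5, 10)
  coverage <- stats::runif(n, 250, 900)
  bq <- rep(TRUE, n)
  contam <- stats::runif(n, 0, 0.015)

  i <- cat_ == "fail_low_dna"
  prep[i] <- "CB"                           # ScfDNA bypasses the input gate
  conc[i] <- stats::runif(sum(i), 0.05, 0.50)  # below both era thresholds

  i <- cat_ == "fail_scant_tumor"
  purity[i] <- stats::runif(sum(i), 0, 9.9)
  enrich[i] <- FALSE

  i <- cat_ == "fail_low_coverage"
  coverage[i] <- stats::runif(sum(i), 5, 49)

  i <- cat_ == "fail_contamination"
  # purity low enough that the VAF-filter rescue cannot apply:
  # rescue needs purity/200 > 2 * alpha, so draw alpha above purity/400
  purity[i] <- stats::runif(sum(i), 10, 30)
  contam[i] <- stats::runif(sum(i), pmax(0.025, purity[i] / 400 + 0.005), 0.32)

  i <- cat_ == "fail_low_quality"
  bq[i] <- FALSE

  data.frame(
    sample_id = sprintf("S%05d", seq_len(n)),
    prep_type = prep,
    source = src,
    year = year,
    collection_date = as.Date(sprintf("%d-%02d-15", year, month)),
    tumor_purity = purity,
    enrichable = enrich,
    dna_conc = conc,
    dna_yield = conc * 55,
    sample_coverage = coverage,
    base_quality_ok = bq,
    contamination_rate = contam,
    true_outcome = cat_,
    stringsAsFactors = FALSE
  )
}
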