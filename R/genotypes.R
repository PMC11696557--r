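# Genotype calling from allele counts and pairwise genotype concordance.
# Genotypes are defined from the matched normal sample; the tumor is then
# interrogated at patient-homozygous sites for contamination and compared
# genotype-to-genotype for identity (sample-swap) checking.

#' Call diploid genotypes from allele counts
#'
#' Hard-threshold caller on the alt-read fraction: sites below `min_depth`
#' are `no_call`; alt fraction `<= hom_band` is `hom_ref`, `>= 1 - hom_band`
#' is `hom_alt`, inside `het_band` is `het`, anything else (ambiguous zone)
#' is `no_call`. The defaults (`min_depth = 20`, `hom_band = 0.05`,
#' `het_band = c(0.30, 0.70)`) keep homozygote misclassification — which
#' would inflate apparent contamination — negligible at typical panel depths
#' of several hundred fold.
#'
#' @param counts Allele-count data frame (`site_id`, `depth`, `ref_count`,
#'   `alt_count`, `other_count`).
#' @param min_depth Minimum depth for a call (>= 1).
#' @param hom_band Maximum alt fraction for a homozygous call.
#' @param het_band Length-2 alt-fraction interval for a heterozygous call.
#' @return Genotype profile data frame (`site_id`, `genotype`, `alt_dosage`;
#'   dosage is `NA` for `no_call`).
#' @examples
#' cnt <- data.frame(site_id = c("a", "b"), depth = c(100L, 100L),
#'                   ref_count = c(100L, 50L), alt_count = c(0L, 50L),
#'                   other_count = 0L)
#' call_genotypes(cnt)$genotype
#' @export
call_genotypes <- function(counts, min_depth = 20, hom_band = 0.05,
                           het_band = c(0.30, 0.70)) {
  check_allele_counts(counts)
  min_depth <- check_count(min_depth, "min_depth")
  check_fraction(hom_band, "hom_band", lo_open = TRUE, hi_open = TRUE)
  if (length(het_band) != 2L || het_band[1] >= het_band[2]) {
    stop_invalid("`het_band` must be an increasing pair of fractions")
  }
  if (hom_band >= het_band[1]) {
    stop_invalid("`hom_band` must be below the lower het band")
  }

  af <- ifelse(counts$depth > 0, counts$alt_count / counts$depth, NA_real_)
  geno <- rep("no_call", nrow(counts))
  callable <- counts$depth >= min_depth
  geno[callable & af <= hom_band] <- "hom_ref"
  geno[callable & af >= 1 - hom_band] <- "hom_alt"
  geno[callable & af >= het_band[1] & af <= het_band[2]] <- "het"
  dosage <- c(hom_ref = 0L, het = 1L, hom_alt = 2L,
              no_call = NA_integer_)[geno]
  data.frame(site_id = counts$site_id, genotype = geno,
             alt_dosage = unname(dosage), stringsAsFactors = FALSE)
}

#' Pairwise genotype concordance between two samples
#'
#' Identity check for sample-swap detection: the fraction of SNP sites,
#' called in both profiles, with identical diploid calls. Same-patient pairs
#' sit near 1; unrelated individuals sit near the Hardy-Weinberg match
#' expectation (for a site with alt frequency p this is
#' `sum over genotypes g of P(g)^2`, e.g. 0.375 at p = 0.5), far below the
#' default swap threshold of 0.80.
#'
#' @param profile_a,profile_b Genotype profiles sharing site ids.
#' @param swap_threshold Concordance below which a swap is suspected.
#' @return An object of class `concordance_report`: `fraction_concordant`,
#'   `n_compared_sites`, `swap_suspected`, `swap_threshold`.
#' @examples
#' panel <- simulate_snp_panel(300, seed = 1)
#' a <- simulate_genotypes(panel, seed = 2)
#' genotype_concordance(a, a)$fraction_concordant   # 1
#' @export
genotype_concordance <- function(profile_a, profile_b, swap_threshold = 0.80) {
  check_genotype_profile(profile_a, "profile_a")
  check_genotype_profile(profile_b, "profile_b")
  check_fraction(swap_threshold, "swap_threshold")

  idx <- match(profile_a$site_id, profile_b$site_id)
  ga <- profile_a$genotype[!is.na(idx)]
  gb <- profile_b$genotype[idx[!is.na(idx)]]
  keep <- ga != "no_call" & gb != "no_call"
  if (!any(keep)) {
    stop_not_estimable("no sites called in both profiles; concordance not estimable")
  }
  frac <- mean(ga[keep] == gb[keep])
  structure(list(
    fraction_concordant = frac,
    n_compared_sites = sum(keep),
    swap_suspected = frac < swap_threshold,
    swap_threshold = swap_threshold
  ), class = "concordance_report")
}

#' @export
print.concordance_report <- function(x, ...) {
  cat(sprintf("Genotype concordance: %.4f over %d co-called sites\n",
              x$fraction_concordant, x$n_compared_sites))
  cat(if (x$swap_suspected) {
    sprintf("SAMPLE SWAP SUSPECTED (below threshold %.2f)\n", x$swap_threshold)
  } else {
    "consistent with a same-patient pair\n"
  })
  invisible(x)
}
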