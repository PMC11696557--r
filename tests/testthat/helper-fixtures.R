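# Shared fixture builders. Everything is generated in code; seeds are fixed
# per call site so individual tests are reproducible in isolation.

# A tumor-normal replicate with exactly n_hom patient-homozygous sites,
# contaminated at `alpha`. Returns the pieces estimate_contamination() needs
# plus the truth.
make_mixture_replicate <- function(alpha, n_hom = 1000, mean_depth = 500,
                                   error_rate = 0.001, seed = 1,
                                   af_low = 0.05, af_high = 0.5) {
  set.seed(seed)
  # oversample sites, then keep the first n_hom at which the patient is
  # homozygous (~63.5% of sites under the default spectrum)
  n_panel <- ceiling(n_hom / 0.55)
  panel <- simulate_snp_panel(n_panel, af_low, af_high)
  patient <- simulate_genotypes(panel)
  hom <- which(patient$genotype != "het")
  stopifnot(length(hom) >= n_hom)
  keep <- hom[seq_len(n_hom)]
  panel <- panel[keep, ]
  patient <- patient[keep, ]
  contaminant <- simulate_genotypes(panel)
  counts <- simulate_allele_counts(
    patient, contaminant,
    mixture_spec(alpha = alpha, mean_depth = mean_depth,
                 error_rate = error_rate),
    panel)
  list(panel = panel, patient = patient, contaminant = contaminant,
       counts = counts, alpha = alpha)
}

# Hand-constructable allele-count table
make_counts <- function(site_id, depth, alt, other = 0L) {
  data.frame(site_id = site_id, depth = as.integer(depth),
             ref_count = as.integer(depth - alt - other),
             alt_count = as.integer(alt), other_count = as.integer(other),
             stringsAsFactors = FALSE)
}

# The three-site hand-worked contamination example: two hom-ref sites and
# one hom-alt site; alpha_hat(moment, depth-weighted) =
# (1 + 4 + 3) / (100*0.2 + 200*0.4 + 100*0.3) = 8/130.
make_hand_example <- function() {
  panel <- data.frame(
    site_id = c("s1", "s2", "s3"), chrom = "chr1", pos = 1:3,
    ref_allele = "A", alt_allele = "G",
    pop_alt_freq = c(0.2, 0.4, 0.7), stringsAsFactors = FALSE)
  normal <- data.frame(
    site_id = c("s1", "s2", "s3"),
    genotype = c("hom_ref", "hom_ref", "hom_alt"),
    alt_dosage = c(0L, 0L, 2L), stringsAsFactors = FALSE)
  counts <- data.frame(
    site_id = c("s1", "s2", "s3"), depth = c(100L, 200L, 100L),
    ref_count = c(99L, 196L, 3L), alt_count = c(1L, 4L, 97L),
    other_count = 0L, stringsAsFactors = FALSE)
  list(panel = panel, normal = normal, counts = counts,
       alpha_expected = 8 / 130)
}

# A passing single-sample QC record; override fields to hit specific gates.
make_qc <- function(...) {
  qc <- list(sample_id = "S1", prep_type = "CB", tumor_purity = 30,
             enrichable = TRUE, dna_conc = 2.0, sample_coverage = 600,
             base_quality_ok = TRUE, collection_date = "2020-01-01")
  utils::modifyList(qc, list(...))
}

# MAF-like variant table from explicit fields
make_variants <- function(pos, vaf = 0.2, level = "vus", nonsyn = TRUE,
                          chrom = "chr1", gene = "TP53") {
  n <- length(pos)
  data.frame(gene = rep_len(gene, n), chrom = rep_len(chrom, n), pos = pos,
             ref = rep_len("A", n), alt = rep_len("T", n),
             vaf = rep_len(vaf, n), nonsynonymous = rep_len(nonsyn, n),
             oncokb_level = rep_len(level, n), stringsAsFactors = FALSE)
}

fig1c_probs <- c(pass = 0.806, fail_low_dna = 0.113, fail_scant_tumor = 0.046,
                 fail_low_coverage = 0.018, fail_contamination = 0.016,
                 fail_low_quality = 0.001)
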