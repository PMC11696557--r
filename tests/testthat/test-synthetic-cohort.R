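test_that("SNP panel simulation respects the frequency spectrum and seeds", {
  expect_error(simulate_snp_panel(0), class = "cytoqc_invalid_input")

  panel <- simulate_snp_panel(1000, 0.05, 0.5, seed = 7)
  expect_equal(nrow(panel), 1000)
  expect_true(all(panel$pop_alt_freq >= 0.05 & panel$pop_alt_freq <= 0.5))
  expect_false(anyDuplicated(panel$site_id) > 0)
  expect_true(all(panel$ref_allele != panel$alt_allele))

  degen <- simulate_snp_panel(1000, 0.25, 0.25, seed = 1)
  expect_true(all(degen$pop_alt_freq == 0.25))

  expect_identical(simulate_snp_panel(200, seed = 3),
                   simulate_snp_panel(200, seed = 3))
  expect_false(identical(simulate_snp_panel(200, seed = 3)$pop_alt_freq,
                         simulate_snp_panel(200, seed = 4)$pop_alt_freq))
})

test_that("genotype simulation follows Hardy-Weinberg proportions", {
  # near-zero allele frequency: essentially all hom_ref
  lo <- simulate_genotypes(simulate_snp_panel(2000, 0.001, 0.001, seed = 1),
                           seed = 2)
  expect_gt(mean(lo$genotype == "hom_ref"), 0.99)

  # p = 0.5: het fraction 2p(1-p) = 0.5 within 3 binomial SE at 10,000 sites
  panel <- simulate_snp_panel(10000, 0.5, 0.5, seed = 1)
  gt <- simulate_genotypes(panel, seed = 5)
  se <- sqrt(0.5 * 0.5 / 10000)
  expect_lt(abs(mean(gt$genotype == "het") - 0.5), 3 * se)

  # full HWE category check at p = 0.3, 4 SE band
  panel <- simulate_snp_panel(20000, 0.3, 0.3, seed = 2)
  gt <- simulate_genotypes(panel, seed = 6)
  for (g in c("hom_ref", "het", "hom_alt")) {
    expected <- c(hom_ref = 0.49, het = 0.42, hom_alt = 0.09)[[g]]
    se <- sqrt(expected * (1 - expected) / 20000)
    expect_lt(abs(mean(gt$genotype == g) - expected), 4 * se)
  }

  expect_identical(simulate_genotypes(panel, seed = 9),
                   simulate_genotypes(panel, seed = 9))
})

test_that("allele-count mixtures conserve reads and have the right mean", {
  panel <- simulate_snp_panel(500, seed = 1)
  pat <- simulate_genotypes(panel, seed = 2)
  con <- simulate_genotypes(panel, seed = 3)

  cnt <- simulate_allele_counts(pat, con,
                                mixture_spec(alpha = 0.1, seed = 4), panel)
  expect_true(all(cnt$ref_count + cnt$alt_count + cnt$other_count ==
                    cnt$depth))

  # pure sample, no error: zero alt reads wherever the patient is hom_ref
  pure <- simulate_allele_counts(
    pat, con, mixture_spec(alpha = 0, error_rate = 0, seed = 5), panel)
  expect_true(all(pure$alt_count[pat$genotype == "hom_ref"] == 0))

  # mixture mean: at hom_ref patient sites with contaminant HWE at p = 0.3,
  # mean alt fraction converges to alpha * p = 0.03
  panel2 <- simulate_snp_panel(4800, 0.3, 0.3, seed = 11)
  pat2 <- simulate_genotypes(panel2, seed = 12)
  keep <- which(pat2$genotype == "hom_ref")[1:2000]
  panel2 <- panel2[keep, ]; pat2 <- pat2[keep, ]
  con2 <- simulate_genotypes(panel2, seed = 13)
  cnt2 <- simulate_allele_counts(
    pat2, con2,
    mixture_spec(alpha = 0.10, mean_depth = 1000, error_rate = 0, seed = 14),
    panel2)
  frac <- cnt2$alt_count / cnt2$depth
  expect_lt(abs(mean(frac) - 0.03), 3 * stats::sd(frac) / sqrt(length(frac)))

  # determinism and panel mismatch
  expect_identical(
    simulate_allele_counts(pat, con, mixture_spec(alpha = 0.1, seed = 4),
                           panel),
    cnt)
  expect_error(
    simulate_allele_counts(pat[-1, ], con, mixture_spec(seed = 1), panel),
    class = "cytoqc_invalid_input")
})

test_that("simulated somatic VAFs are bounded by purity/2", {
  expect_error(simulate_tumor_variants(0, 0.5), class = "cytoqc_invalid_input")
  expect_error(simulate_tumor_variants(10, 0), class = "cytoqc_invalid_input")

  clonal <- simulate_tumor_variants(50, purity = 1, seed = 1,
                                    clonal_fraction = 1)
  expect_true(all(clonal$vaf == 0.5))

  low <- simulate_tumor_variants(200, purity = 0.10, seed = 2)
  expect_true(all(low$vaf > 0 & low$vaf <= 0.05))
  expect_true(all(low$oncokb_level %in% c("L1", "L2", "L3A", "L3B", "L4",
                                          "R1", "oncogenic_no_level", "vus")))
})

test_that("cohort simulation reproduces requested outcome frequencies", {
  expect_error(simulate_cohort(100, c(pass = 0.5)),
               class = "cytoqc_invalid_input")
  expect_error(simulate_cohort(100, c(nonsense = 1)),
               class = "cytoqc_invalid_input")

  # single-category round trip
  all_pass <- simulate_cohort(200, c(pass = 1), seed = 1)
  expect_true(all(triage_cohort(all_pass)$outcome == "pass"))

  m <- simulate_cohort(5000, fig1c_probs, seed = 2)
  freq <- table(factor(m$true_outcome, names(fig1c_probs))) / 5000
  se <- sqrt(fig1c_probs * (1 - fig1c_probs) / 5000)
  expect_true(all(abs(freq - fig1c_probs) <= 3 * pmax(se, 1e-4)))

  expect_identical(simulate_cohort(500, seed = 7),
                   simulate_cohort(500, seed = 7))
  expect_false(identical(simulate_cohort(500, seed = 7)$dna_conc,
                         simulate_cohort(500, seed = 8)$dna_conc))
})
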