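test_that("DNA-input gate follows the era policy and the ScfDNA bypass", {
  expect_equal(evaluate_dna_input(0.6, "2020-05-01"), "fail")
  expect_equal(evaluate_dna_input(0.6, "2022-01-01"), "pass")
  expect_equal(evaluate_dna_input(0.0, "2020-05-01"), "fail")
  expect_equal(evaluate_dna_input(0.0, "2022-01-01"), "fail")
  # boundary: the threshold value itself passes (failure is strictly below)
  expect_equal(evaluate_dna_input(0.9, "2020-05-01"), "pass")
  expect_equal(evaluate_dna_input(0.54, "2021-09-01"), "pass")
  # supernatant cfDNA is sequenced below the thresholds
  expect_equal(evaluate_dna_input(0.1, "2020-05-01", prep_type = "ScfDNA"),
               "pass")
  expect_error(evaluate_dna_input(-1, "2020-05-01"),
               class = "cytoqc_invalid_input")
})

test_that("era thresholds reproduce the printed minimum inputs", {
  pol <- era_policy()
  expect_equal(round_half_up(pol$conc_threshold_before * pol$max_volume), 50)
  expect_equal(round_half_up(pol$conc_threshold_after * pol$max_volume), 30)
  expect_equal(pol$min_input_before, 50)
  expect_equal(pol$min_input_after, 30)
})

test_that("tumor-content gate fails only scant non-enrichable samples", {
  expect_equal(evaluate_tumor_content(5, FALSE), "fail")
  expect_equal(evaluate_tumor_content(5, TRUE), "pass")
  expect_equal(evaluate_tumor_content(10, FALSE), "pass")  # boundary
  expect_error(evaluate_tumor_content(150, TRUE),
               class = "cytoqc_invalid_input")
})

test_that("coverage gate distinguishes failure, low flag and adequate", {
  expect_equal(evaluate_coverage(c(40, 150, 600)),
               c("fail", "low_coverage_flag", "adequate"))
  expect_equal(evaluate_coverage(c(50, 200)),
               c("low_coverage_flag", "adequate"))  # boundaries
})

test_that("VAF filter rescues high-purity samples and fails low-purity ones", {
  v <- make_variants(1:3, vaf = c(0.01, 0.02, 0.28))

  clean <- contamination_vaf_filter(v, alpha_hat = 0, tumor_purity = 60)
  expect_equal(nrow(clean$variants), 3)
  expect_false(clean$partially_evaluable)

  rescued <- contamination_vaf_filter(v, alpha_hat = 0.03, tumor_purity = 60)
  expect_equal(rescued$variants$vaf, 0.28)
  expect_true(rescued$partially_evaluable)
  expect_equal(rescued$vaf_filter_threshold, 0.03)

  failed <- contamination_vaf_filter(v, alpha_hat = 0.03, tumor_purity = 8)
  expect_false(failed$evaluable)
  expect_equal(nrow(failed$variants), 0)
})

test_that("triage applies gates in pipeline order and is total", {
  expect_equal(triage_sample(make_qc(), contamination = 0.004)$outcome,
               "pass")
  expect_equal(triage_sample(make_qc(tumor_purity = 5, enrichable = FALSE)
                             )$outcome, "fail_scant_tumor")
  expect_equal(triage_sample(make_qc(tumor_purity = 40, sample_coverage = 30)
                             )$outcome, "fail_low_coverage")
  expect_equal(triage_sample(make_qc(dna_conc = 0.6))$outcome,
               "fail_low_dna")
  expect_equal(triage_sample(make_qc(base_quality_ok = FALSE))$outcome,
               "fail_low_quality")
  expect_equal(triage_sample(make_qc(tumor_purity = 15),
                             contamination = 0.10)$outcome,
               "fail_contamination")

  # a multi-failure sample takes the earliest gate in pipeline order
  multi <- make_qc(tumor_purity = 5, enrichable = FALSE, dna_conc = 0.1,
                   sample_coverage = 10, base_quality_ok = FALSE)
  expect_equal(triage_sample(multi, contamination = 0.2)$outcome,
               "fail_scant_tumor")

  # contaminated but high purity: pass, partially evaluable with threshold
  pe <- triage_sample(make_qc(tumor_purity = 80), contamination = 0.03)
  expect_equal(pe$outcome, "pass")
  expect_true(pe$partially_evaluable)
  expect_equal(pe$vaf_filter_threshold, 0.03)

  # determinism and missing-field rejection
  expect_identical(triage_sample(make_qc(), contamination = 0.004),
                   triage_sample(make_qc(), contamination = 0.004))
  expect_error(triage_sample(make_qc(dna_conc = NULL)),
               class = "cytoqc_invalid_input")
})

test_that("raising any single metric never converts a pass into a fail", {
  set.seed(7)
  for (i in 1:60) {
    qc <- make_qc(tumor_purity = runif(1, 0, 100),
                  enrichable = runif(1) < 0.5,
                  dna_conc = runif(1, 0, 3),
                  sample_coverage = runif(1, 0, 800),
                  base_quality_ok = runif(1) < 0.9,
                  collection_date = sample(c("2019-03-01", "2022-03-01"), 1))
    alpha <- runif(1, 0, 0.1)
    base <- triage_sample(qc, contamination = alpha)$outcome
    if (base != "pass") next
    for (field in c("tumor_purity", "dna_conc", "sample_coverage")) {
      up <- qc
      up[[field]] <- qc[[field]] * 1.5 + 1
      if (field == "tumor_purity") up[[field]] <- min(up[[field]], 100)
      expect_equal(triage_sample(up, contamination = alpha)$outcome, "pass")
    }
  }
})

test_that("a simulated cohort re-triages to its generating categories", {
  m <- simulate_cohort(4000, fig1c_probs, seed = 17)
  tr <- triage_cohort(m)
  expect_equal(tr$outcome, m$true_outcome)
  # contamination-rescued samples never appear here by construction
  expect_false(any(tr$partially_evaluable))
})

test_that("expected queryable target molecules scale linearly with input", {
  expect_equal(expected_target_copies(30, 220.5), 6615)
  expect_equal(expected_target_copies(0, 238), 0)
  expect_equal(expected_target_copies(50, 238), 11900)
  expect_error(expected_target_copies(-1, 238),
               class = "cytoqc_invalid_input")
})
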