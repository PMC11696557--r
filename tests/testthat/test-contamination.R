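test_that("genotype calling applies depth and allele-fraction bands", {
  cnt <- make_counts(c("a", "b", "c", "d", "e"),
                     depth = c(100, 100, 200, 10, 100),
                     alt = c(0, 50, 24, 5, 96))
  gt <- call_genotypes(cnt)
  # af 0.12 with hom_band 0.05 / het_band [0.30, 0.70] is ambiguous
  expect_equal(gt$genotype, c("hom_ref", "het", "no_call", "no_call",
                              "hom_alt"))
  expect_equal(gt$alt_dosage, c(0L, 1L, NA, NA, 2L))

  bad <- make_counts("a", 100, 10)
  bad$ref_count <- 5L
  expect_error(call_genotypes(bad), class = "cytoqc_invalid_input")
  expect_error(call_genotypes(cnt, hom_band = 0.4),
               class = "cytoqc_invalid_input")
})

test_that("moment estimator equals the hand-computed closed-form ratio", {
  h <- make_hand_example()
  fit <- estimate_contamination(h$counts, h$normal, h$panel,
                                method = "moment")
  expect_identical(fit$alpha_hat, h$alpha_expected)
  expect_equal(fit$n_hom_sites, 3)

  # unweighted variant: mean(d)/mean(q) = ((0.01 + 0.02 + 0.03)/3)/(0.9/3)
  unw <- estimate_contamination(h$counts, h$normal, h$panel,
                                method = "moment", weighted = FALSE)
  expect_equal(unw$alpha_hat, 0.06 / 0.9)
})

test_that("a pure sample estimates zero and is not flagged", {
  r <- make_mixture_replicate(alpha = 0, error_rate = 0, n_hom = 300,
                              seed = 21)
  fit <- estimate_contamination(r$counts, r$patient, r$panel,
                                method = "moment")
  expect_identical(fit$alpha_hat, 0)
  expect_false(fit$clinically_significant)
  mle <- estimate_contamination(r$counts, r$patient, r$panel, method = "mle",
                                error_rate = 0)
  expect_identical(mle$alpha_hat, 0)
})

test_that("both estimators recover a 5% mixture at depth 500", {
  r <- make_mixture_replicate(alpha = 0.05, n_hom = 1000, mean_depth = 500,
                              error_rate = 0, seed = 42)
  for (m in c("moment", "mle")) {
    fit <- estimate_contamination(r$counts, r$patient, r$panel, method = m,
                                  error_rate = 0)
    expect_gt(fit$alpha_hat, 0.04)
    expect_lt(fit$alpha_hat, 0.06)
    expect_true(fit$clinically_significant)
  }
})

test_that("clinical significance follows the 2% cutoff inclusively", {
  # calibrated counts: every hom_ref site carries exactly the unexpected
  # fraction that makes the weighted moment ratio land on the target alpha
  panel <- data.frame(site_id = "a", chrom = "chr1", pos = 1L,
                      ref_allele = "A", alt_allele = "G",
                      pop_alt_freq = 0.5, stringsAsFactors = FALSE)
  normal <- data.frame(site_id = "a", genotype = "hom_ref",
                       alt_dosage = 0L, stringsAsFactors = FALSE)
  counts_at <- function(u) make_counts("a", 2000, u)
  # alpha_hat = u / (2000 * 0.5) = u / 1000
  at_cutoff <- estimate_contamination(counts_at(21), normal, panel,
                                      method = "moment")
  expect_equal(at_cutoff$alpha_hat, 0.021)
  expect_true(at_cutoff$clinically_significant)
  below <- estimate_contamination(counts_at(18), normal, panel,
                                  method = "moment")
  expect_equal(below$alpha_hat, 0.018)
  expect_false(below$clinically_significant)
  exactly <- estimate_contamination(counts_at(20), normal, panel,
                                    method = "moment")
  expect_true(exactly$clinically_significant)   # >= 2% is significant
})

test_that("estimation fails distinctly when no informative sites exist", {
  h <- make_hand_example()
  all_het <- h$normal
  all_het$genotype <- "het"
  all_het$alt_dosage <- 1L
  expect_error(estimate_contamination(h$counts, all_het, h$panel),
               class = "cytoqc_not_estimable")
  # depth filter can also exhaust the informative set
  shallow <- h$counts
  shallow$depth <- 5L; shallow$ref_count <- 5L; shallow$alt_count <- 0L
  expect_error(estimate_contamination(shallow, h$normal, h$panel),
               class = "cytoqc_not_estimable")
})

test_that("mean estimate increases strictly across the contamination grid", {
  grid <- c(0, 0.02, 0.05, 0.10, 0.20)
  means <- vapply(grid, function(a) {
    reps <- vapply(1:20, function(i) {
      r <- make_mixture_replicate(a, n_hom = 400, mean_depth = 300,
                                  seed = 1000 * i + round(1e4 * a))
      estimate_contamination(r$counts, r$patient, r$panel,
                             method = "moment")$alpha_hat
    }, numeric(1))
    mean(reps)
  }, numeric(1))
  expect_true(all(diff(means) > 0))
})

test_that("sites with elevated third-allele fractions are excluded", {
  h <- make_hand_example()
  dirty <- h$counts
  dirty$other_count[1] <- 10L
  dirty$ref_count[1] <- 89L
  fit <- estimate_contamination(dirty, h$normal, h$panel, method = "moment")
  expect_equal(fit$n_hom_sites, 2)
  # explicit exclusion list behaves the same way
  fit2 <- estimate_contamination(h$counts, h$normal, h$panel,
                                 method = "moment", exclude_sites = "s1")
  expect_equal(fit2$n_hom_sites, 2)
})

test_that("contam_fit methods are coherent", {
  r <- make_mixture_replicate(alpha = 0.05, n_hom = 500, seed = 31)
  fit <- estimate_contamination(r$counts, r$patient, r$panel)
  expect_s3_class(fit, "contam_fit")
  expect_named(coef(fit), "alpha")
  expect_length(residuals(fit), fit$n_hom_sites)
  expect_equal(residuals(fit),
               fit$sites$unexpected_count / fit$sites$depth - fitted(fit))
  ci <- confint(fit)
  expect_lt(ci["lower"], fit$alpha_hat)
  expect_gt(ci["upper"], fit$alpha_hat)
  expect_output(print(summary(fit)), "Contamination estimate")

  sims <- simulate(fit, nsim = 2, seed = 1)
  expect_length(sims, 2)
  expect_true(all(sims[[1]]$unexpected_count <= sims[[1]]$depth))

  pdf(NULL)
  on.exit(dev.off())
  expect_invisible(plot(fit))
})

test_that("contamination labels respect the coverage context", {
  expect_equal(classify_contamination(0.005, 600), "clean")
  expect_equal(classify_contamination(0.04, 400),
               "significant_contamination")
  expect_equal(classify_contamination(0.10, 30),
               "low_coverage_artifact_possible")
  # boundary: 50x counts as adequate for interpretation
  expect_equal(classify_contamination(0.03, 50), "significant_contamination")
})

test_that("genotype concordance detects identity and unrelatedness", {
  panel <- simulate_snp_panel(10000, 0.5, 0.5, seed = 1)
  a <- simulate_genotypes(panel, seed = 2)
  b <- simulate_genotypes(panel, seed = 3)

  expect_equal(genotype_concordance(a, a)$fraction_concordant, 1.0)

  # unrelated pair at p = 0.5: match probability sum(P(g)^2) = 0.375
  rep <- genotype_concordance(a, b)
  se <- sqrt(0.375 * 0.625 / rep$n_compared_sites)
  expect_lt(abs(rep$fraction_concordant - 0.375), 4 * se)
  expect_true(rep$swap_suspected)

  # symmetry
  expect_equal(genotype_concordance(b, a)$fraction_concordant,
               rep$fraction_concordant)

  # no co-called sites
  nc <- a
  nc$genotype <- "no_call"
  expect_error(genotype_concordance(a, nc), class = "cytoqc_not_estimable")
})

test_that("deliberate tumor-normal swaps are always flagged", {
  panel <- simulate_snp_panel(1000, seed = 99)
  flags <- vapply(1:50, function(i) {
    p1 <- simulate_genotypes(panel, seed = 2 * i)
    p2 <- simulate_genotypes(panel, seed = 2 * i + 1)
    genotype_concordance(p1, p2)$swap_suspected
  }, logical(1))
  expect_true(all(flags))
})
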