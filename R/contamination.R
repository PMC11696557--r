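# Contamination estimation from patient-homozygous SNP sites.
#
# At a SNP site where the matched normal is homozygous, both patient alleles
# are identical, so reads carrying the other allele in the tumor library are
# unexpected: they arise from sequencing error or from DNA of another
# individual. For an unrelated contaminant in Hardy-Weinberg equilibrium
# with unexpected-allele population frequency q_i, the expected
# unexpected-read fraction at site i is E[d_i] = alpha * q_i, where alpha is
# the contaminant read fraction. Two estimators invert this signal:
#
#   moment: alpha_hat = sum(w_i d_i) / sum(w_i q_i), w_i = depth_i
#           (depth weighting is variance-motivated; switchable), clipped to
#           [0, 1];
#   mle:    maximize over alpha in [0, 0.5] the product over sites of
#           binomial likelihoods of the unexpected count, marginalized over
#           the contaminant genotype g in {0,1,2} under HWE at q_i, with
#           success probability alpha * g/2 + error_rate.
#
# A contaminant fraction >= 2% is flagged as clinically significant (the
# variant-calling threshold); estimates from samples with very low coverage
# are interpreted cautiously because sparse counts inflate them.

hom_site_table <- function(tumor_counts, normal_profile, panel,
                           min_depth, max_other_frac, exclude_sites) {
  m <- merge(merge(panel[c("site_id", "pop_alt_freq")],
                   normal_profile[c("site_id", "genotype")], by = "site_id"),
             tumor_counts, by = "site_id")
  m <- m[m$genotype %in% c("hom_ref", "hom_alt"), , drop = FALSE]
  if (!is.null(exclude_sites)) {
    m <- m[!m$site_id %in% exclude_sites, , drop = FALSE]
  }
  m <- m[m$depth >= min_depth, , drop = FALSE]
  # sites with an elevated third-allele fraction can reflect somatic events
  # or artifacts that mimic contamination
  m <- m[m$other_count <= max_other_frac * m$depth, , drop = FALSE]
  if (nrow(m) == 0L) return(m)
  hom_ref <- m$genotype == "hom_ref"
  data.frame(
    site_id = m$site_id,
    depth = m$depth,
    unexpected_count = ifelse(hom_ref, m$alt_count, m$ref_count),
    q = ifelse(hom_ref, m$pop_alt_freq, 1 - m$pop_alt_freq),
    stringsAsFactors = FALSE
  )
}

contam_loglik_factory <- function(u, n, q, error_rate) {
  w0 <- (1 - q)^2; w1 <- 2 * q * (1 - q); w2 <- q^2
  function(alpha) {
    p0 <- min(max(error_rate, 0), 1)
    p1 <- min(alpha / 2 + error_rate, 1)
    p2 <- min(alpha + error_rate, 1)
    lik <- w0 * stats::dbinom(u, n, p0) +
           w1 * stats::dbinom(u, n, p1) +
           w2 * stats::dbinom(u, n, p2)
    sum(log(pmax(lik, 1e-300)))
  }
}

#' Estimate non-patient DNA contamination from homozygous SNP sites
#'
#' Fits the contaminant read fraction alpha of a tumor sample using the
#' unexpected-allele read counts at panel SNP sites where the matched
#' normal's genotype is homozygous. See the package vignette for the model:
#' briefly, with an unrelated Hardy-Weinberg contaminant, the expected
#' unexpected-read fraction at a site with unexpected-allele population
#' frequency `q_i` is `alpha * q_i`; hom-alt sites contribute symmetrically
#' with `q_i = 1 - pop_alt_freq`. The method-of-moments estimator is the
#' depth-weighted ratio `sum(d_i w_i) / sum(q_i w_i)`; the default
#' maximum-likelihood estimator maximizes the binomial likelihood of the
#' unexpected counts marginalized over the contaminant genotype, which also
#' absorbs the sequencing error rate.
#'
#' @param tumor_counts Allele-count data frame for the tumor sample.
#' @param normal_profile Genotype profile of the matched normal (e.g. from
#'   [call_genotypes()]).
#' @param panel SNP panel with population alt frequencies.
#' @param method `"mle"` (default, reported estimate) or `"moment"`.
#' @param error_rate Assumed symmetric per-base miscall rate (default 0.001);
#'   enters the MLE success probability.
#' @param min_depth Minimum tumor depth for a site to be informative.
#' @param max_other_frac Sites with `other_count/depth` above this are
#'   excluded (possible somatic events or artifacts mimicking contamination).
#' @param exclude_sites Optional site ids to drop (e.g. sites overlapping
#'   known somatic variants).
#' @param weighted Depth-weight the moment estimator (default TRUE).
#' @param clinical_cutoff Contamination fraction at or above which the sample
#'   is flagged clinically significant (default 0.02).
#' @return An object of class `contam_fit` with components `alpha_hat`,
#'   `method`, `alpha_moment`, `n_hom_sites`, `median_site_depth`,
#'   `clinically_significant` (`alpha_hat >= clinical_cutoff`),
#'   `low_coverage_caveat` (median informative-site depth < 200),
#'   per-site table `sites`, and for the MLE the maximized `loglik`.
#' @seealso [classify_contamination()], [genotype_concordance()]
#' @examples
#' panel <- simulate_snp_panel(400, seed = 1)
#' pat <- simulate_genotypes(panel, seed = 2)
#' con <- simulate_genotypes(panel, seed = 3)
#' cnt <- simulate_allele_counts(pat, con,
#'   mixture_spec(alpha = 0.05, mean_depth = 500, seed = 4), panel)
#' fit <- estimate_contamination(cnt, pat, panel)
#' coef(fit)
#' @export
estimate_contamination <- function(tumor_counts, normal_profile, panel,
                                   method = c("mle", "moment"),
                                   error_rate = 0.001, min_depth = 20,
                                   max_other_frac = 0.02,
                                   exclude_sites = NULL, weighted = TRUE,
                                   clinical_cutoff = 0.02) {
  method <- match.arg(method)
  check_allele_counts(tumor_counts, "tumor_counts")
  check_genotype_profile(normal_profile, "normal_profile")
  check_snp_panel(panel)
  check_fraction(error_rate, "error_rate", hi = 0.01)

  sites <- hom_site_table(tumor_counts, normal_profile, panel,
                          min_depth, max_other_frac, exclude_sites)
  if (nrow(sites) == 0L) {
    stop_not_estimable(
      "no informative homozygous sites; contamination not estimable")
  }

  d <- sites$unexpected_count / sites$depth
  w <- if (weighted) sites$depth else rep(1, nrow(sites))
  alpha_moment <- min(max(sum(w * d) / sum(w * sites$q), 0), 1)

  ll <- NULL
  loglik <- NA_real_
  alpha_mle <- NA_real_
  if (method == "mle") {
    ll <- contam_loglik_factory(sites$unexpected_count, sites$depth,
                                sites$q, error_rate)
    opt <- stats::optimize(ll, c(0, 0.5), maximum = TRUE, tol = 1e-6)
    # optimize never probes the endpoints; pick the best of interior and 0
    if (ll(0) >= opt$objective) {
      alpha_mle <- 0
      loglik <- ll(0)
    } else {
      alpha_mle <- opt$maximum
      loglik <- opt$objective
    }
  }
  alpha_hat <- if (method == "mle") alpha_mle else alpha_moment

  med_depth <- stats::median(sites$depth)
  structure(list(
    alpha_hat = alpha_hat,
    method = method,
    alpha_moment = alpha_moment,
    alpha_mle = alpha_mle,
    n_hom_sites = nrow(sites),
    median_site_depth = med_depth,
    clinically_significant = alpha_hat >= clinical_cutoff,
    low_coverage_caveat = med_depth < 200,
    clinical_cutoff = clinical_cutoff,
    error_rate = error_rate,
    weighted = weighted,
    sites = sites,
    loglik = loglik,
    loglik_fn = ll,
    call = match.call()
  ), class = "contam_fit")
}

#' @export
print.contam_fit <- function(x, ...) {
  cat(sprintf("Contamination estimate (%s): alpha = %.4f\n",
              x$method, x$alpha_hat))
  cat(sprintf("  %d informative homozygous sites, median depth %.0fx\n",
              x$n_hom_sites, x$median_site_depth))
  if (x$clinically_significant) {
    cat(sprintf("  CLINICALLY SIGNIFICANT (>= %.0f%% cutoff)\n",
                100 * x$clinical_cutoff))
  }
  if (x$low_coverage_caveat) {
    cat("  caveat: low coverage may inflate the estimate\n")
  }
  invisible(x)
}

#' @export
coef.contam_fit <- function(object, ...) c(alpha = object$alpha_hat)

#' Expected unexpected-read fractions under the fitted contamination model
#' @param object A `contam_fit`.
#' @param ... Unused.
#' @return Fitted per-site unexpected-read fractions
#'   `alpha_hat * q_i + error_rate`.
#' @export
fitted.contam_fit <- function(object, ...) {
  object$alpha_hat * object$sites$q + object$error_rate
}

#' Residual unexpected-read fractions of a contamination fit
#' @param object A `contam_fit`.
#' @param type `"response"` (observed minus fitted fraction) or `"pearson"`
#'   (scaled by the binomial standard error at the fitted fraction).
#' @param ... Unused.
#' @return Numeric vector, one residual per informative site.
#' @export
residuals.contam_fit <- function(object, type = c("response", "pearson"),
                                 ...) {
  type <- match.arg(type)
  d <- object$sites$unexpected_count / object$sites$depth
  p <- fitted(object)
  r <- d - p
  if (type == "pearson") {
    r <- r / sqrt(pmax(p * (1 - p), 1e-12) / object$sites$depth)
  }
  r
}

#' @export
summary.contam_fit <- function(object, ...) {
  s <- object$sites
  structure(list(
    fit = object,
    depth_quartiles = stats::quantile(s$depth, c(0.25, 0.5, 0.75)),
    mean_unexpected_fraction = mean(s$unexpected_count / s$depth),
    mean_q = mean(s$q),
    n_hom_ref = sum(s$q <= 0.5),   # hom-alt sites carry q = 1 - p > 0.5
    n_sites_with_unexpected = sum(s$unexpected_count > 0)
  ), class = "summary.contam_fit")
}

#' @export
print.summary.contam_fit <- function(x, ...) {
  print(x$fit)
  cat(sprintf("  mean unexpected-read fraction: %.5f (mean q = %.3f)\n",
              x$mean_unexpected_fraction, x$mean_q))
  cat(sprintf("  sites with any unexpected reads: %d / %d\n",
              x$n_sites_with_unexpected, x$fit$n_hom_sites))
  cat(sprintf("  depth quartiles: %.0f / %.0f / %.0f\n",
              x$depth_quartiles[1], x$depth_quartiles[2],
              x$depth_quartiles[3]))
  if (!is.na(x$fit$alpha_mle) && x$fit$method == "mle") {
    cat(sprintf("  moment-estimator cross-check: %.4f\n",
                x$fit$alpha_moment))
  }
  invisible(x)
}

#' Profile-likelihood confidence interval for the contamination fraction
#'
#' Inverts the likelihood-ratio statistic of the marginal binomial model;
#' available for MLE fits only. Bounds are clamped to the search interval
#' `[0, 0.5]`.
#'
#' @param object A `contam_fit` fitted with `method = "mle"`.
#' @param parm Ignored (single-parameter model).
#' @param level Confidence level.
#' @param ... Unused.
#' @return Length-2 vector `c(lower, upper)`.
#' @export
confint.contam_fit <- function(object, parm, level = 0.95, ...) {
  if (object$method != "mle" || is.null(object$loglik_fn)) {
    stop_invalid("confidence intervals require method = \"mle\"")
  }
  ll <- object$loglik_fn
  target <- object$loglik - stats::qchisq(level, df = 1) / 2
  f <- function(a) ll(a) - target
  ahat <- object$alpha_hat
  lower <- if (ahat <= 1e-8 || f(0) >= 0) 0 else {
    stats::uniroot(f, c(0, ahat), tol = 1e-7)$root
  }
  upper <- if (f(0.5) >= 0) 0.5 else {
    stats::uniroot(f, c(ahat, 0.5), tol = 1e-7)$root
  }
  c(lower = lower, upper = upper)
}

#' Simulate unexpected-allele counts from a fitted contamination model
#'
#' Parametric-bootstrap style draws: at each informative site the marginal
#' unexpected-read probability is `alpha_hat * q_i + error_rate` and counts
#' are Binomial(depth_i, p_i).
#'
#' @param object A `contam_fit`.
#' @param nsim Number of simulated count tables.
#' @param seed Optional integer seed.
#' @param ... Unused.
#' @return A list of `nsim` data frames (`site_id`, `depth`,
#'   `unexpected_count`).
#' @export
simulate.contam_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  s <- object$sites
  p <- pmin(object$alpha_hat * s$q + object$error_rate, 1)
  lapply(seq_len(nsim), function(i) {
    data.frame(site_id = s$site_id, depth = s$depth,
               unexpected_count = stats::rbinom(nrow(s), s$depth, p),
               stringsAsFactors = FALSE)
  })
}

#' Diagnostic plot of a contamination fit
#'
#' Observed unexpected-read fraction against the unexpected-allele population
#' frequency, with the fitted line `error_rate + alpha_hat * q`. A cloud
#' scattered around a positively sloped line is the signature of genuine
#' cross-individual contamination; pure samples scatter around the error
#' floor.
#'
#' @param x A `contam_fit`.
#' @param ... Further arguments to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.contam_fit <- function(x, ...) {
  s <- x$sites
  graphics::plot(s$q, s$unexpected_count / s$depth,
                 xlab = "unexpected-allele population frequency (q)",
                 ylab = "unexpected-read fraction",
                 main = sprintf("alpha_hat = %.4f (%s)", x$alpha_hat,
                                x$method), ...)
  graphics::abline(a = x$error_rate, b = x$alpha_hat, col = "red")
  invisible(x)
}

#' Interpret a contamination estimate in its coverage context
#'
#' Applies the clinical cutoff together with the coverage caveat: estimates
#' at or above the cutoff from samples sequenced below `min_coverage` (50x
#' by default) are labeled as possible low-coverage artifacts rather than
#' confirmed contamination, since sparse counts can falsely elevate the
#' rate; such samples are excluded from headline contamination rates.
#'
#' @param result A `contam_fit` or a numeric contamination fraction.
#' @param sample_coverage Sample-level fold coverage.
#' @param cutoff Clinical significance cutoff (default 0.02).
#' @param min_coverage Coverage below which a significant estimate is treated
#'   as a possible artifact (default 50).
#' @return One of `"clean"`, `"significant_contamination"`,
#'   `"low_coverage_artifact_possible"`.
#' @examples
#' classify_contamination(0.005, 600)  # clean
#' classify_contamination(0.04, 400)   # significant_contamination
#' classify_contamination(0.10, 30)    # low_coverage_artifact_possible
#' @export
classify_contamination <- function(result, sample_coverage, cutoff = 0.02,
                                   min_coverage = 50) {
  alpha <- if (inherits(result, "contam_fit")) result$alpha_hat else result
  if (!is_scalar_number(alpha)) stop_invalid("`result` must be estimable")
  if (alpha < cutoff) return("clean")
  if (sample_coverage < min_coverage) return("low_coverage_artifact_possible")
  "significant_contamination"
}
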