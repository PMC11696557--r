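# Cohort-level aggregation: success rates, failure breakdowns, the standard
# group-comparison tests, and reproduction of published headline rates from
# a packaged fixture of cohort counts.

#' Load the packaged cohort-count fixture
#'
#' A table of integer counts and printed aggregate values transcribed from
#' the published clinical-experience cohort (4871 cytology samples profiled
#' on a paired tumor-normal hybridization-capture panel), with one citation
#' string per entry. Row kinds: `rate` (numerator/denominator pairs whose
#' printed percentage is recomputable), `product` (derived molecule counts),
#' and `metadata` (printed per-sample summaries such as median coverage that
#' depend on the protected raw data and are carried for reference only,
#' never recomputed). The `check` column marks how each recomputable row is
#' compared: `exact` at the printed precision, `tolerance` within the
#' stated `tolerance`, or `flag_only` for entries whose printed value is
#' internally inconsistent with the printed counts and is reported but not
#' required to match.
#'
#' @return Data frame of class `cohort_fixture`.
#' @examples
#' fx <- cohort_fixture()
#' fx[fx$key == "overall_success", ]
#' @export
cohort_fixture <- function() {
  path <- system.file("extdata", "cohort_counts.tsv", package = "cytoqc",
                      mustWork = TRUE)
  fx <- utils::read.delim(path, stringsAsFactors = FALSE)
  class(fx) <- c("cohort_fixture", class(fx))
  fx
}

fixture_value <- function(fixture, key, field = "printed") {
  i <- match(key, fixture$key)
  if (is.na(i)) stop_invalid("missing fixture key `%s`", key)
  fixture[[field]][i]
}

#' Check the internal consistency of the cohort fixture
#'
#' Sub-cohort counts must sum to the totals the source implies: sequenced
#' cell block + supernatant samples equal all sequenced samples
#' (4457 + 268 = 4725), successes by preparation sum to overall successes
#' (3616 + 190 = 3806), and preparation/source splits of received samples
#' sum to the cohort total (4871). All counts must be non-negative.
#'
#' @param fixture A [cohort_fixture()].
#' @return `TRUE` invisibly; errors on inconsistency.
#' @export
validate_fixture <- function(fixture = cohort_fixture()) {
  num <- function(key) fixture_value(fixture, key, "numerator")
  den <- function(key) fixture_value(fixture, key, "denominator")
  cnt <- fixture$numerator[fixture$kind == "rate"]
  if (any(cnt < 0, na.rm = TRUE)) stop_invalid("fixture counts must be >= 0")
  checks <- list(
    c(num("cb_success") + num("scfdna_success"), num("overall_success")),
    c(den("cb_success") + den("scfdna_success"), den("overall_success")),
    c(num("cb_share_of_cohort") + num("scfdna_share_of_cohort"),
      den("cb_share_of_cohort")),
    c(num("internal_share") + num("external_share"), den("internal_share"))
  )
  for (ch in checks) {
    if (ch[1] != ch[2]) {
      stop_invalid("fixture inconsistency: %s != %s", ch[1], ch[2])
    }
  }
  invisible(TRUE)
}

#' Success rates by grouping keys
#'
#' Rate = 100 * successes / processed per group, where success means a
#' `pass` triage outcome. Raw numerators and denominators are always
#' returned alongside the rate; rounding to a reporting precision is a
#' presentation choice left to the caller.
#'
#' @param manifest Data frame with an outcome column and any grouping
#'   columns (e.g. the result of merging a manifest with [triage_cohort()]).
#' @param group_by Character vector of grouping column names (empty for the
#'   overall rate).
#' @param outcome_col Name of the outcome column (default `"outcome"`).
#' @return Data frame with the grouping keys, `n_success`, `n_total`,
#'   `rate` (percent). Empty groups do not appear.
#' @examples
#' m <- data.frame(outcome = c("pass", "pass", "fail_low_dna"),
#'                 prep_type = c("CB", "ScfDNA", "CB"))
#' success_rates(m, "prep_type")
#' @export
success_rates <- function(manifest, group_by = character(),
                          outcome_col = "outcome") {
  check_columns(manifest, c(group_by, outcome_col), "manifest")
  if (nrow(manifest) == 0L) stop_invalid("`manifest` is empty")
  succ <- manifest[[outcome_col]] == "pass"
  if (length(group_by) == 0L) {
    return(data.frame(n_success = sum(succ), n_total = length(succ),
                      rate = 100 * mean(succ)))
  }
  key <- interaction(manifest[group_by], drop = TRUE, sep = "\r")
  n_total <- tapply(succ, key, length)
  n_success <- tapply(succ, key, sum)
  keys <- do.call(rbind, strsplit(names(n_total), "\r", fixed = TRUE))
  out <- as.data.frame(keys, stringsAsFactors = FALSE)
  names(out) <- group_by
  out$n_success <- as.integer(n_success)
  out$n_total <- as.integer(n_total)
  out$rate <- 100 * out$n_success / out$n_total
  rownames(out) <- NULL
  out
}

#' Failure-category breakdown of a triaged cohort
#'
#' Percentages of each outcome category over the processed denominator;
#' together with the success percentage they sum to 100 (up to rounding
#' when presented).
#'
#' @param outcomes Character vector of triage outcomes, or a data frame with
#'   an `outcome` column.
#' @return Named numeric vector of percentages over all outcome categories.
#' @export
failure_breakdown <- function(outcomes) {
  if (is.data.frame(outcomes)) {
    outcomes <- check_columns(outcomes, "outcome", "outcomes")$outcome
  }
  if (length(outcomes) == 0L) stop_invalid("no outcomes supplied")
  bad <- setdiff(outcomes, TRIAGE_OUTCOMES)
  if (length(bad)) {
    stop_invalid("unknown outcome(s): %s", paste(unique(bad), collapse = ", "))
  }
  tab <- table(factor(outcomes, levels = TRIAGE_OUTCOMES))
  pct <- 100 * as.vector(tab) / length(outcomes)
  names(pct) <- names(tab)
  pct
}

#' Compare two groups of continuous measurements
#'
#' Two-sided Mann-Whitney (Wilcoxon rank-sum) test, the standard choice for
#' skewed sequencing metrics such as coverage, DNA yield or VAF.
#'
#' @param values_a,values_b Non-empty numeric vectors.
#' @return The two-sided p-value.
#' @export
compare_groups_continuous <- function(values_a, values_b) {
  if (length(values_a) == 0L || length(values_b) == 0L) {
    stop_invalid("both groups must be non-empty")
  }
  stats::wilcox.test(values_a, values_b, exact = FALSE)$p.value
}

#' Compare categorical groups in an r x c contingency table
#'
#' Pearson's chi-squared test for r x c tables with adequate expected
#' counts; 2 x 2 tables with any expected count below 5 fall back to
#' Fisher's exact test.
#'
#' @param table An r x c matrix of non-negative counts (at least 2 x 2).
#' @return The p-value, with the test used in `attr(, "method")`
#'   (`"chisq"` or `"fisher"`).
#' @examples
#' compare_groups_categorical(matrix(c(90, 50, 10, 50), 2))
#' @export
compare_groups_categorical <- function(table) {
  tab <- as.matrix(table)
  if (nrow(tab) < 2L || ncol(tab) < 2L) {
    stop_invalid("`table` must be at least 2 x 2")
  }
  if (any(tab < 0) || sum(tab) == 0) {
    stop_invalid("`table` must hold non-negative counts with a positive total")
  }
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (all(dim(tab) == 2L) && any(expected < 5)) {
    p <- stats::fisher.test(tab)$p.value
    method <- "fisher"
  } else {
    p <- suppressWarnings(stats::chisq.test(tab)$p.value)
    method <- "chisq"
  }
  structure(p, method = method)
}

#' Recompute the published headline aggregates from the count fixture
#'
#' For every recomputable fixture row the aggregate is recomputed from its
#' counts — percentages as `100 * numerator / denominator` rounded half-up
#' to the printed precision, molecule counts via
#' [expected_target_copies()] — and compared with the printed value.
#' Mismatches are listed rather than silently dropped; rows marked
#' `flag_only` record printed values that are internally inconsistent with
#' the printed counts and are not required to match.
#'
#' @param fixture A [cohort_fixture()].
#' @return Data frame of class `aggregate_report`: `key`, `kind`,
#'   `recomputed`, `printed`, `matched`, `check`, `note`, `citation`. The
#'   attribute `all_required_match` is `TRUE` when every `exact` and
#'   `tolerance` row matches.
#' @examples
#' rep <- reproduce_printed_aggregates()
#' attr(rep, "all_required_match")
#' @export
reproduce_printed_aggregates <- function(fixture = cohort_fixture()) {
  validate_fixture(fixture)
  rows <- fixture[fixture$kind %in% c("rate", "product"), , drop = FALSE]
  recomputed <- numeric(nrow(rows))
  for (i in seq_len(nrow(rows))) {
    recomputed[i] <- if (rows$kind[i] == "rate") {
      round_half_up(100 * rows$numerator[i] / rows$denominator[i],
                    rows$digits[i])
    } else {
      expected_target_copies(rows$numerator[i], rows$denominator[i])
    }
  }
  tol <- ifelse(rows$check == "tolerance", rows$tolerance, 0)
  matched <- abs(recomputed - rows$printed) <= tol + 1e-9
  out <- data.frame(
    key = rows$key,
    kind = rows$kind,
    recomputed = recomputed,
    printed = rows$printed,
    matched = matched,
    check = rows$check,
    note = rows$note,
    citation = rows$citation,
    stringsAsFactors = FALSE
  )
  class(out) <- c("aggregate_report", class(out))
  attr(out, "all_required_match") <-
    all(out$matched[out$check != "flag_only"])
  out
}

#' @export
print.aggregate_report <- function(x, ...) {
  x <- as.data.frame(x)   # column subsets of the report print as plain frames
  if (!all(c("matched", "check") %in% names(x))) {
    print(x, row.names = FALSE)
    return(invisible(x))
  }
  cat(sprintf("Printed-aggregate reproduction: %d/%d required entries match\n",
              sum(x$matched[x$check != "flag_only"]),
              sum(x$check != "flag_only")))
  print(x[c("key", "recomputed", "printed", "matched", "check")],
        row.names = FALSE)
  mism <- x[!x$matched, , drop = FALSE]
  if (nrow(mism)) {
    cat("mismatches:\n")
    for (i in seq_len(nrow(mism))) {
      cat(sprintf("  %s: recomputed %g vs printed %g — %s\n", mism$key[i],
                  mism$recomputed[i], mism$printed[i], mism$note[i]))
    }
  }
  invisible(x)
}
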