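# Matched cytology vs surgical mutation concordance: shared/exclusive
# accounting, per-level stratification and VAF-shift testing. Variant
# identity is genomic (chrom, pos, ref, alt), not gene-level, so distinct
# events in the same gene are never merged.

variant_key <- function(v) {
  paste(v$chrom, v$pos, v$ref, v$alt, sep = ":")
}

#' Partition two variant lists into shared and exclusive calls
#'
#' Variants are matched on the identity key (chrom, pos, ref, alt). The
#' partition is disjoint and exhaustive over the union of both lists.
#'
#' @param a,b MAF-like data frames with columns `chrom`, `pos`, `ref`, `alt`
#'   (and typically `vaf`, `oncokb_level`).
#' @return A list of class `variant_match`: `shared` (rows of `a` plus the
#'   matching VAF of `b` in `vaf_b` when both carry VAFs), `a_only`,
#'   `b_only`, and the three counts.
#' @examples
#' a <- data.frame(chrom = "chr1", pos = 1:3, ref = "A", alt = "T")
#' b <- data.frame(chrom = "chr1", pos = 2:4, ref = "A", alt = "T")
#' match_variants(a, b)$n_shared  # 2
#' @export
match_variants <- function(a, b) {
  check_columns(a, c("chrom", "pos", "ref", "alt"), "a")
  check_columns(b, c("chrom", "pos", "ref", "alt"), "b")
  ka <- variant_key(a)
  kb <- variant_key(b)
  if (anyDuplicated(ka)) stop_invalid("duplicate variant keys in `a`")
  if (anyDuplicated(kb)) stop_invalid("duplicate variant keys in `b`")

  shared <- a[ka %in% kb, , drop = FALSE]
  if ("vaf" %in% names(a) && "vaf" %in% names(b)) {
    shared$vaf_b <- b$vaf[match(variant_key(shared), kb)]
  }
  structure(list(
    shared = shared,
    a_only = a[!ka %in% kb, , drop = FALSE],
    b_only = b[!kb %in% ka, , drop = FALSE],
    n_shared = sum(ka %in% kb),
    n_a_only = sum(!ka %in% kb),
    n_b_only = sum(!kb %in% ka)
  ), class = "variant_match")
}

#' Concordance accounting for one cytology-surgical pair
#'
#' Counts shared, cytology-only and surgical-only mutation calls between the
#' two samples of the same tumor, and the surgical recovery fraction — the
#' proportion of alterations identified on the surgical sample that the
#' cytology sample also identified.
#'
#' @param cytology,surgical MAF-like variant tables for the two samples.
#' @param patient_id Optional identifier carried through.
#' @return An object of class `pair_concordance`: counts `n_shared`,
#'   `n_cytology_only`, `n_surgical_only`; `surgical_recovery_fraction`
#'   (`NA` when the surgical sample has no calls); `shared` (variant rows
#'   with `vaf` = cytology VAF and `vaf_b` = surgical VAF),
#'   `cytology_only`, `surgical_only`.
#' @examples
#' v <- simulate_tumor_variants(10, purity = 0.5, seed = 1)
#' pair_concordance(v, v)$surgical_recovery_fraction  # 1
#' @export
pair_concordance <- function(cytology, surgical, patient_id = NA_character_) {
  m <- match_variants(cytology, surgical)
  surg_total <- m$n_shared + m$n_b_only
  structure(list(
    patient_id = patient_id,
    n_shared = m$n_shared,
    n_cytology_only = m$n_a_only,
    n_surgical_only = m$n_b_only,
    surgical_recovery_fraction = if (surg_total > 0) {
      m$n_shared / surg_total
    } else NA_real_,
    shared = m$shared,
    cytology_only = m$a_only,
    surgical_only = m$b_only
  ), class = "pair_concordance")
}

#' @export
print.pair_concordance <- function(x, ...) {
  cat(sprintf(
    "Matched pair%s: %d shared, %d cytology-only, %d surgical-only",
    if (is.na(x$patient_id)) "" else paste0(" ", x$patient_id),
    x$n_shared, x$n_cytology_only, x$n_surgical_only))
  if (!is.na(x$surgical_recovery_fraction)) {
    cat(sprintf(" (surgical recovery %.1f%%)",
                100 * x$surgical_recovery_fraction))
  }
  cat("\n")
  invisible(x)
}

pooled_level_table <- function(pairs) {
  grab <- function(p, what) {
    df <- p[[what]]
    if (is.null(df) || !nrow(df) || !"oncokb_level" %in% names(df)) {
      character(0)
    } else df$oncokb_level
  }
  list(shared = unlist(lapply(pairs, grab, "shared")),
       cytology_only = unlist(lapply(pairs, grab, "cytology_only")),
       surgical_only = unlist(lapply(pairs, grab, "surgical_only")))
}

#' Stratify shared/exclusive mutation proportions by actionability level
#'
#' Pools variants across pairs and, for every level present, reports the
#' proportion found in both samples (shared), only in the cytology sample,
#' or only in the surgical sample. Proportions sum to 1 within each level;
#' levels with no pooled variants are absent from the output.
#'
#' @param pairs A list of [pair_concordance()] objects (a single object is
#'   accepted).
#' @return Data frame with columns `oncokb_level`, `shared`,
#'   `cytology_only`, `surgical_only`, `n_total`.
#' @export
stratify_shared_by_level <- function(pairs) {
  if (inherits(pairs, "pair_concordance")) pairs <- list(pairs)
  pools <- pooled_level_table(pairs)
  levs <- intersect(ONCOKB_LEVELS, unique(unlist(pools)))
  if (!length(levs)) {
    return(data.frame(oncokb_level = character(0), shared = numeric(0),
                      cytology_only = numeric(0), surgical_only = numeric(0),
                      n_total = integer(0)))
  }
  counts <- vapply(levs, function(l) {
    c(shared = sum(pools$shared == l),
      cytology_only = sum(pools$cytology_only == l),
      surgical_only = sum(pools$surgical_only == l))
  }, numeric(3))
  tot <- colSums(counts)
  data.frame(
    oncokb_level = levs,
    shared = counts["shared", ] / tot,
    cytology_only = counts["cytology_only", ] / tot,
    surgical_only = counts["surgical_only", ] / tot,
    n_total = as.integer(tot),
    row.names = NULL,
    stringsAsFactors = FALSE
  )
}

#' Test for a VAF shift between cytology and surgical samples
#'
#' Pools the shared-variant VAF pairs across all matched pairs and compares
#' the cytology and surgical VAF distributions with a two-sided
#' Mann-Whitney (Wilcoxon rank-sum) test, the convention for group
#' comparisons of continuous sequencing metrics. One shared variant yields
#' medians but no test.
#'
#' @param pairs A list of [pair_concordance()] objects (or one object).
#' @return A list: `median_cytology`, `median_surgical`, `p_value` (`NA`
#'   when fewer than two shared variants), `n_shared`.
#' @export
vaf_shift_test <- function(pairs) {
  if (inherits(pairs, "pair_concordance")) pairs <- list(pairs)
  vc <- unlist(lapply(pairs, function(p) p$shared$vaf))
  vs <- unlist(lapply(pairs, function(p) p$shared$vaf_b))
  if (is.null(vc) || length(vc) == 0L) {
    stop_not_estimable("no shared variants; VAF shift not estimable")
  }
  p_value <- if (length(vc) >= 2L) {
    stats::wilcox.test(vc, vs, exact = FALSE)$p.value
  } else NA_real_
  list(median_cytology = stats::median(vc),
       median_surgical = stats::median(vs),
       p_value = p_value,
       n_shared = length(vc))
}
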