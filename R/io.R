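# Plain TSV readers/writers for the pipeline's tabular interchange formats.
# Schemas match the simulator's outputs so files round-trip losslessly.

write_tsv_file <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read/write SNP panels, allele counts, variant tables and manifests
#'
#' Thin TSV wrappers with schema validation on read. Columns:
#' * panel: `site_id`, `chrom`, `pos`, `ref_allele`, `alt_allele`,
#'   `pop_alt_freq`;
#' * allele counts: `site_id`, `depth`, `ref_count`, `alt_count`,
#'   `other_count`;
#' * variants (MAF-like): `gene`, `chrom`, `pos`, `ref`, `alt`, `vaf`,
#'   `nonsynonymous`, `oncokb_level`;
#' * manifest: the [simulate_cohort()] column contract.
#'
#' @param x Data frame to write.
#' @param path File path.
#' @return Readers return the validated data frame; writers return `path`
#'   invisibly.
#' @name cytoqc-io
NULL

#' @rdname cytoqc-io
#' @export
write_snp_panel <- function(x, path) write_tsv_file(check_snp_panel(x), path)

#' @rdname cytoqc-io
#' @export
read_snp_panel <- function(path) {
  check_snp_panel(utils::read.delim(path, stringsAsFactors = FALSE))
}

#' @rdname cytoqc-io
#' @export
write_allele_counts <- function(x, path) {
  write_tsv_file(check_allele_counts(x), path)
}

#' @rdname cytoqc-io
#' @export
read_allele_counts <- function(path) {
  check_allele_counts(utils::read.delim(path, stringsAsFactors = FALSE))
}

#' @rdname cytoqc-io
#' @export
write_variants <- function(x, path) {
  write_tsv_file(check_columns(x, c("gene", "chrom", "pos", "ref", "alt",
                                    "vaf"), "variants"), path)
}

#' @rdname cytoqc-io
#' @export
read_variants <- function(path) {
  check_columns(utils::read.delim(path, stringsAsFactors = FALSE),
                c("gene", "chrom", "pos", "ref", "alt", "vaf"), "variants")
}

#' @rdname cytoqc-io
#' @export
write_manifest <- function(x, path) {
  write_tsv_file(check_columns(x, c("sample_id", "prep_type"), "manifest"),
                 path)
}

#' @rdname cytoqc-io
#' @export
read_manifest <- function(path) {
  m <- utils::read.delim(path, stringsAsFactors = FALSE)
  check_columns(m, c("sample_id", "prep_type"), "manifest")
  if ("collection_date" %in% names(m)) {
    m$collection_date <- as.Date(m$collection_date)
  }
  m
}
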