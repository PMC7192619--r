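## Core domain types. Site tables and count tables are plain data.frames with
## fixed column sets (validated on construction / read); configuration objects
## are small S3 records so defaults are visible and printable.

SITE_COLS <- c("transcript_id", "position", "ref_base", "in_vivo_level")
COUNT_COLS <- c("transcript_id", "position", "sample_id",
                "a_count", "c_count", "g_count", "t_count")

#' Validate a table of known editing sites
#'
#' A site table describes previously known editable adenosines: one row per
#' site with a transcript identifier, a 1-based position on the transcript
#' sense strand, the reference base (always `"A"` -- A-to-I editing is read as
#' A-to-G by the sequencer) and an optional in vivo editing level in `[0, 1]`.
#'
#' @param sites data.frame with columns `transcript_id`, `position`,
#'   `ref_base` and optionally `in_vivo_level`.
#' @return The validated data.frame (with `in_vivo_level` added as `NA` if
#'   absent), invisibly classed as `"editing_sites"`.
#' @export
validate_sites <- function(sites) {
  if (!is.data.frame(sites)) abort_validation("site table must be a data.frame")
  if (!all(c("transcript_id", "position", "ref_base") %in% names(sites)))
    abort_validation("site table needs columns transcript_id, position, ref_base")
  if (!"in_vivo_level" %in% names(sites))
    sites$in_vivo_level <- rep(NA_real_, nrow(sites))
  sites <- sites[SITE_COLS]
  sites$transcript_id <- as.character(sites$transcript_id)
  if (nrow(sites)) {
    if (!all(is_count(sites$position) & sites$position >= 1))
      abort_validation("site positions must be integers >= 1")
    bad <- sites$ref_base != "A"
    if (any(bad))
      abort_validation("site table contains non-A reference bases at rows: ",
                       paste(which(bad), collapse = ", "))
    lvl <- sites$in_vivo_level
    if (any(!is.na(lvl) & (lvl < 0 | lvl > 1)))
      abort_validation("in_vivo_level must be in [0, 1]")
    key <- site_key(sites$transcript_id, sites$position)
    if (anyDuplicated(key))
      abort_validation("duplicate (transcript_id, position) in site table: ",
                       paste(unique(key[duplicated(key)]), collapse = ", "))
  }
  class(sites) <- c("editing_sites", "data.frame")
  sites
}

#' Validate a per-sample per-site base-count table
#'
#' One row per (site, sample): counts of A/C/G/T base calls that passed the
#' upstream quality filters. Coverage is the sum of the four counts.
#'
#' @param counts data.frame with columns `transcript_id`, `position`,
#'   `sample_id`, `a_count`, `c_count`, `g_count`, `t_count`.
#' @return The validated data.frame, classed `"site_base_counts"`.
#' @export
validate_counts <- function(counts) {
  if (!is.data.frame(counts)) abort_validation("count table must be a data.frame")
  if (!all(COUNT_COLS %in% names(counts)))
    abort_validation("count table needs columns: ", paste(COUNT_COLS, collapse = ", "))
  counts <- counts[COUNT_COLS]
  counts$transcript_id <- as.character(counts$transcript_id)
  counts$sample_id <- as.character(counts$sample_id)
  if (nrow(counts)) {
    for (col in c("position", "a_count", "c_count", "g_count", "t_count")) {
      if (!all(is_count(counts[[col]])))
        abort_parse("column ", col, " must contain non-negative integers")
    }
    key <- paste(site_key(counts$transcript_id, counts$position), counts$sample_id)
    if (anyDuplicated(key))
      abort_validation("duplicate (site, sample) rows in count table")
  }
  class(counts) <- c("site_base_counts", "data.frame")
  counts
}

#' Base- and mapping-quality filter settings
#'
#' Records the quality filters applied when base counts are produced from
#' alignments. `min_base_quality` is enforced by [counts_from_pileup()];
#' `min_mapping_quality` applies upstream (when the pileup is generated) and is
#' carried here for provenance.
#'
#' @param min_base_quality minimum Phred base quality; calls below it are
#'   discarded (default 30, i.e. an error floor of about 0.1%).
#' @param min_mapping_quality minimum read mapping quality (default 40).
#' @return An object of class `"quality_filter_config"`.
#' @export
quality_filter_config <- function(min_base_quality = 30, min_mapping_quality = 40) {
  if (!is_count(min_base_quality) || !is_count(min_mapping_quality))
    abort_validation("quality thresholds must be non-negative integers")
  structure(list(min_base_quality = as.integer(min_base_quality),
                 min_mapping_quality = as.integer(min_mapping_quality)),
            class = "quality_filter_config")
}

#' Analysis thresholds
#'
#' @param min_coverage minimum total read depth (all four bases) required at a
#'   site in every sample of the design (default 20).
#' @param fdr_level per-tail Benjamini-Hochberg FDR for the differential caller
#'   (default 0.1; a site is called at adjusted p `<=` this level).
#' @param error_rate_p0 assumed per-base sequencing error probability for the
#'   binomial null (default 0.001, the Q30 error floor).
#' @param detection_adjusted_p adjusted-p cutoff for calling an in vitro
#'   editing event within one dataset (default 0.001, strict `<`).
#' @return An object of class `"threshold_config"`.
#' @export
threshold_config <- function(min_coverage = 20, fdr_level = 0.1,
                             error_rate_p0 = 0.001, detection_adjusted_p = 0.001) {
  if (!is_count(min_coverage)) abort_validation("min_coverage must be a non-negative integer")
  for (v in c(fdr_level, error_rate_p0, detection_adjusted_p))
    if (!is_fraction(v, open = TRUE))
      abort_validation("fdr_level, error_rate_p0 and detection_adjusted_p must lie in (0, 1)")
  structure(list(min_coverage = as.integer(min_coverage), fdr_level = fdr_level,
                 error_rate_p0 = error_rate_p0,
                 detection_adjusted_p = detection_adjusted_p),
            class = "threshold_config")
}

#' Two-compartment replicate design
#'
#' Declares which samples belong to each compartment (e.g. giant axon, GA,
#' versus giant fiber lobe cell bodies, GFL) and, optionally, how replicates
#' pair up by animal of origin.
#'
#' @param a_samples,b_samples character vectors of sample ids; disjoint and
#'   non-empty.
#' @param pairing optional named character vector mapping each sample in A to
#'   its partner in B (a bijection); enables the paired t-test variant.
#' @return An object of class `"compartment_design"`.
#' @export
compartment_design <- function(a_samples, b_samples, pairing = NULL) {
  a_samples <- as.character(a_samples); b_samples <- as.character(b_samples)
  if (!length(a_samples) || !length(b_samples))
    abort_validation("both compartments need at least one sample")
  if (anyDuplicated(c(a_samples, b_samples)))
    abort_validation("compartment sample lists must be disjoint and unique")
  if (!is.null(pairing)) {
    if (!setequal(names(pairing), a_samples) || !setequal(pairing, b_samples) ||
        anyDuplicated(pairing))
      abort_validation("pairing must be a bijection from A samples to B samples")
    pairing <- pairing[a_samples]
  }
  structure(list(a_samples = a_samples, b_samples = b_samples, pairing = pairing),
            class = "compartment_design")
}

#' @export
print.compartment_design <- function(x, ...) {
  cat("compartment design:", length(x$a_samples), "A vs", length(x$b_samples), "B samples\n")
  cat("  A:", paste(x$a_samples, collapse = ", "), "\n")
  cat("  B:", paste(x$b_samples, collapse = ", "), "\n")
  if (!is.null(x$pairing)) cat("  paired by animal of origin\n")
  invisible(x)
}

#' @export
print.threshold_config <- function(x, ...) {
  cat(sprintf(paste0("thresholds: min_coverage=%d, fdr_level=%g, ",
                     "error_rate_p0=%g, detection_adjusted_p=%g\n"),
              x$min_coverage, x$fdr_level, x$error_rate_p0, x$detection_adjusted_p))
  invisible(x)
}

#' @export
print.quality_filter_config <- function(x, ...) {
  cat(sprintf("quality filters: base Q >= %d, mapping quality >= %d\n",
              x$min_base_quality, x$min_mapping_quality))
  invisible(x)
}
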