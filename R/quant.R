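## Per-site editing levels and the two global summaries: the unweighted mean
## editing level and the coverage-weighted editing index.

#' Per-site, per-sample editing levels
#'
#' The editing level at a site is the fraction of G calls among A+G calls,
#' `g / (a + g)`; C and T calls never enter the denominator. When a site has no
#' A or G coverage in a sample the level is `NA` (missing), not zero.
#'
#' @param counts a `site_base_counts` data.frame.
#' @return A data.frame with columns `transcript_id`, `position`, `sample_id`,
#'   `ag_coverage` and `level`.
#' @export
editing_level <- function(counts) {
  counts <- validate_counts(counts)
  ag <- counts$a_count + counts$g_count
  lvl <- ifelse(ag > 0, counts$g_count / ag, NA_real_)
  data.frame(transcript_id = counts$transcript_id, position = counts$position,
             sample_id = counts$sample_id, ag_coverage = ag, level = lvl,
             stringsAsFactors = FALSE)
}

#' Coverage filter over a compartment design
#'
#' Retains a site iff its total coverage (all four base counts) is at least
#' `thresholds$min_coverage` in every sample of the design. A site lacking a
#' count row for some design sample is treated as coverage 0 there (and hence
#' dropped whenever `min_coverage > 0`), with a warning.
#'
#' @param counts a `site_base_counts` data.frame covering the design samples.
#' @param design a [compartment_design()].
#' @param thresholds a [threshold_config()].
#' @return data.frame of retained sites (`transcript_id`, `position`).
#' @export
coverage_filter <- function(counts, design, thresholds = threshold_config()) {
  counts <- validate_counts(counts)
  samples <- c(design$a_samples, design$b_samples)
  counts <- counts[counts$sample_id %in% samples, , drop = FALSE]
  key <- site_key(counts$transcript_id, counts$position)
  cov <- counts$a_count + counts$c_count + counts$g_count + counts$t_count
  n_samp <- tapply(counts$sample_id, key, function(s) length(unique(s)))
  min_cov <- tapply(cov, key, min)
  all_keys <- names(min_cov)
  incomplete <- n_samp[all_keys] < length(samples)
  if (any(incomplete))
    warning(sum(incomplete), " site(s) missing count rows for some design samples; ",
            "treated as coverage 0 there", call. = FALSE)
  eff_min <- ifelse(incomplete, 0, min_cov)  # a missing sample row counts as depth 0
  keep <- all_keys[eff_min >= thresholds$min_coverage]
  first <- !duplicated(key)
  sites <- data.frame(transcript_id = counts$transcript_id[first],
                      position = counts$position[first],
                      stringsAsFactors = FALSE)
  skey <- site_key(sites$transcript_id, sites$position)
  out <- sites[skey %in% keep, , drop = FALSE]
  out[order(out$transcript_id, out$position), , drop = FALSE]
}

restrict_to_sites <- function(levels, sites) {
  lk <- site_key(levels$transcript_id, levels$position)
  sk <- site_key(sites$transcript_id, sites$position)
  levels[lk %in% sk, , drop = FALSE]
}

#' Mean editing level of one sample over a site set
#'
#' Unweighted arithmetic mean of the per-site editing levels.
#'
#' @param levels output of [editing_level()] for a single sample.
#' @param sites data.frame of retained sites (`transcript_id`, `position`).
#' @return A single fraction.
#' @export
mean_editing <- function(levels, sites) {
  levels <- restrict_to_sites(levels, sites)
  if (!nrow(levels)) abort_validation("mean_editing: empty site set")
  if (anyNA(levels$level))
    abort_validation("mean_editing: missing levels in the retained site set")
  mean(levels$level)
}

#' Editing index of one sample over a site set
#'
#' The coverage-weighted average editing level: total G calls divided by total
#' A+G calls over the retained sites, i.e. per-site levels weighted by their
#' A+G coverage. Equals [mean_editing()] exactly when coverage is uniform.
#'
#' @param counts a `site_base_counts` data.frame for a single sample.
#' @param sites data.frame of retained sites.
#' @return A single fraction.
#' @export
editing_index <- function(counts, sites) {
  counts <- validate_counts(restrict_to_sites(counts, sites))
  denom <- sum(counts$a_count) + sum(counts$g_count)
  if (denom == 0) abort_validation("editing_index: zero A+G coverage over the site set")
  sum(counts$g_count) / denom
}

#' Per-sample editing summaries
#'
#' Computes [mean_editing()] and [editing_index()] for every sample in a count
#' table over a retained site set.
#'
#' @param counts a `site_base_counts` data.frame.
#' @param sites data.frame of retained sites.
#' @return data.frame with one row per sample: `sample_id`, `n_sites`,
#'   `mean_editing`, `editing_index`.
#' @export
sample_summaries <- function(counts, sites) {
  counts <- validate_counts(counts)
  lv <- editing_level(counts)
  out <- lapply(unique(counts$sample_id), function(s) {
    data.frame(sample_id = s, n_sites = nrow(sites),
               mean_editing = mean_editing(lv[lv$sample_id == s, ], sites),
               editing_index = editing_index(counts[counts$sample_id == s, ], sites),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
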