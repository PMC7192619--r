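## Site-by-site differential editing between two compartments: two one-tailed
## two-sample t-tests per site, with Benjamini-Hochberg FDR control applied
## separately within each tail. Everything is vectorized over sites so that
## transcriptome-scale tables (tens of thousands of sites) run in seconds.

#' One-tailed t-test pair for one site
#'
#' Computes a single two-sample t statistic for replicate editing levels in
#' compartments A and B and returns its two directional tail probabilities:
#' `p_a_greater` (upper tail, evidence that A > B) and `p_b_greater` (lower
#' tail). For a continuous statistic the two are exact complements. The default
#' is the Welch unequal-variance form with Welch-Satterthwaite degrees of
#' freedom; `paired = TRUE` runs a one-sample t on the paired differences
#' (replicates matched by position in the two vectors).
#'
#' Degenerate variance is resolved by continuity: if both groups are constant
#' with equal means, both tails are 0.5; if constant with different means, the
#' favored tail is 0 and the other 1.
#'
#' @param levels_a,levels_b numeric vectors of replicate editing levels
#'   (at least 2 each; equal lengths when `paired`).
#' @param paired logical; use the paired (one-sample on differences) form.
#' @return Named numeric vector `c(p_a_greater =, p_b_greater =)`.
#' @export
one_tailed_t_pair <- function(levels_a, levels_b, paired = FALSE) {
  res <- welch_tail_matrix(matrix(levels_a, nrow = 1), matrix(levels_b, nrow = 1),
                           paired = paired)
  c(p_a_greater = res$p_a_greater, p_b_greater = res$p_b_greater)
}

## Row-wise directional t-tests: ma, mb are sites x replicates matrices.
welch_tail_matrix <- function(ma, mb, paired = FALSE) {
  na <- ncol(ma); nb <- ncol(mb)
  if (na < 2 || nb < 2)
    abort_validation("need at least 2 replicates per compartment")
  if (anyNA(ma) || anyNA(mb))
    abort_validation("missing levels in tested sites")
  if (paired) {
    if (na != nb) abort_validation("paired test requires equal replicate counts")
    d <- ma - mb
    md <- rowMeans(d)
    vd <- rowSums((d - md)^2) / (na - 1)
    tstat <- md / sqrt(vd / na)
    df <- rep(na - 1, nrow(d))
    delta <- md
  } else {
    mean_a <- rowMeans(ma); mean_b <- rowMeans(mb)
    va <- rowSums((ma - mean_a)^2) / (na - 1)
    vb <- rowSums((mb - mean_b)^2) / (nb - 1)
    se2 <- va / na + vb / nb
    tstat <- (mean_a - mean_b) / sqrt(se2)
    df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
    delta <- mean_a - mean_b
  }
  p_a <- pt(tstat, df, lower.tail = FALSE)
  p_b <- pt(tstat, df, lower.tail = TRUE)
  ## zero-variance limits: t is 0/0 (NaN) or +-Inf handled by pt already;
  ## NaN means both groups constant and equal -> both tails 0.5
  degenerate <- !is.finite(tstat)
  eq <- degenerate & delta == 0
  p_a[eq] <- 0.5; p_b[eq] <- 0.5
  hi <- degenerate & delta > 0
  p_a[hi] <- 0; p_b[hi] <- 1
  lo <- degenerate & delta < 0
  p_a[lo] <- 1; p_b[lo] <- 0
  list(p_a_greater = p_a, p_b_greater = p_b)
}

#' Benjamini-Hochberg step-up adjusted p-values
#'
#' Standard BH adjustment: for sorted p-values, `q(i) = min over j >= i of
#' p(j) * m / j`, capped at 1, returned in the input order. Controls the FDR at
#' level `q` when sites with adjusted value `<= q` are called.
#'
#' @param pvalues numeric vector of p-values in `[0, 1]`.
#' @return Numeric vector of adjusted values, same length and order.
#' @export
bh_adjust <- function(pvalues) {
  if (!length(pvalues)) return(numeric())
  if (anyNA(pvalues) || any(pvalues < 0 | pvalues > 1))
    abort_validation("p-values must lie in [0, 1]")
  m <- length(pvalues)
  o <- order(pvalues, decreasing = TRUE)
  ## walking down from the largest p, take the running minimum of p(j)*m/j
  adj <- pmin(1, cummin(pvalues[o] * m / seq(m, 1)))
  adj[order(o)]
}

#' Differential editing analysis over a compartment design
#'
#' End-to-end site-by-site analysis: applies the coverage filter, computes
#' per-replicate editing levels, runs the one-tailed t-test pair at every
#' retained site, adjusts each tail's p-values separately with
#' Benjamini-Hochberg, and calls each site `A_higher` (adjusted
#' `q_a_greater <= fdr_level`), `B_higher`, or `no_change`. Retained sites
#' with a missing level in any sample (possible only through C/T-only depth)
#' are dropped with a warning before testing.
#'
#' @param counts a `site_base_counts` data.frame covering all design samples.
#' @param design a [compartment_design()].
#' @param thresholds a [threshold_config()].
#' @param paired use the paired t-test variant (requires `design$pairing`).
#' @return data.frame of class `differential_result`: one row per tested site
#'   with `mean_a`, `mean_b`, `delta`, `p_a_greater`, `p_b_greater`,
#'   `q_a_greater`, `q_b_greater`, `call`.
#' @export
differential_editing <- function(counts, design, thresholds = threshold_config(),
                                 paired = FALSE) {
  counts <- validate_counts(counts)
  samples <- c(design$a_samples, design$b_samples)
  missing <- setdiff(samples, unique(counts$sample_id))
  if (length(missing))
    abort_validation("design samples absent from count table: ",
                     paste(missing, collapse = ", "))
  if (paired && is.null(design$pairing))
    abort_validation("paired test requested but the design has no pairing")
  retained <- coverage_filter(counts, design, thresholds)
  if (!nrow(retained)) abort_validation("no sites survive the coverage filter")
  lv <- restrict_to_sites(editing_level(counts), retained)
  lv <- lv[lv$sample_id %in% samples, , drop = FALSE]
  keys <- site_key(retained$transcript_id, retained$position)
  level_mat <- matrix(NA_real_, nrow = length(keys), ncol = length(samples),
                      dimnames = list(keys, samples))
  level_mat[cbind(match(site_key(lv$transcript_id, lv$position), keys),
                  match(lv$sample_id, samples))] <- lv$level
  bad <- rowSums(is.na(level_mat)) > 0
  if (any(bad)) {
    warning(sum(bad), " retained site(s) with missing editing level dropped",
            call. = FALSE)
    level_mat <- level_mat[!bad, , drop = FALSE]
    retained <- retained[!bad, , drop = FALSE]
  }
  b_order <- if (paired) unname(design$pairing) else design$b_samples
  ma <- level_mat[, design$a_samples, drop = FALSE]
  mb <- level_mat[, b_order, drop = FALSE]
  tt <- welch_tail_matrix(ma, mb, paired = paired)
  res <- data.frame(retained,
                    mean_a = rowMeans(ma), mean_b = rowMeans(mb),
                    delta = rowMeans(ma) - rowMeans(mb),
                    p_a_greater = tt$p_a_greater, p_b_greater = tt$p_b_greater,
                    stringsAsFactors = FALSE, row.names = NULL)
  call_sites(res, thresholds)
}

#' Apply per-tail BH adjustment and the significance call
#'
#' Adjusts the `p_a_greater` vector and, separately, the `p_b_greater` vector
#' with [bh_adjust()] and assigns each site one call: `A_higher` iff
#' `q_a_greater <= fdr_level`, else `B_higher` iff `q_b_greater <= fdr_level`,
#' else `no_change`. For complementary one-tailed p-values and
#' `fdr_level < 0.5` the two calls can never both fire; if they do, an
#' internal-consistency error is raised.
#'
#' @param results data.frame with columns `p_a_greater`, `p_b_greater` (plus
#'   any site annotation columns, carried through).
#' @param thresholds a [threshold_config()].
#' @return The input with `q_a_greater`, `q_b_greater` and `call` added,
#'   classed `differential_result`.
#' @export
call_sites <- function(results, thresholds = threshold_config()) {
  results$q_a_greater <- bh_adjust(results$p_a_greater)
  results$q_b_greater <- bh_adjust(results$p_b_greater)
  a_sig <- results$q_a_greater <= thresholds$fdr_level
  b_sig <- results$q_b_greater <= thresholds$fdr_level
  if (any(a_sig & b_sig))
    stop_axonedit("internal consistency: both one-tailed calls fired at one site",
                  class = "axonedit_internal_error")
  results$call <- ifelse(a_sig, "A_higher", ifelse(b_sig, "B_higher", "no_change"))
  class(results) <- c("differential_result", "data.frame")
  results
}

#' Global summary of a differential analysis
#'
#' Counts of the three significance calls (a partition of the tested sites),
#' the raw direction split (strict `mean_a > mean_b`, with ties reported
#' separately), and a binned histogram of the per-site delta.
#'
#' @param results a `differential_result` data.frame.
#' @param histogram_breaks bin edges for the delta histogram (default width
#'   0.05 over `[-1, 1]`).
#' @return A list of class `differential_summary`.
#' @export
summarize_differential <- function(results,
                                   histogram_breaks = seq(-1, 1, by = 0.05)) {
  if (!nrow(results)) abort_validation("no results to summarize")
  calls <- table(factor(results$call,
                        levels = c("A_higher", "B_higher", "no_change")))
  n_raw <- sum(results$delta > 0)
  h <- hist(pmin(pmax(results$delta, min(histogram_breaks)), max(histogram_breaks)),
            breaks = histogram_breaks, plot = FALSE)
  structure(list(
    n_sites_tested = nrow(results),
    n_a_higher_significant = unname(calls["A_higher"]),
    n_b_higher_significant = unname(calls["B_higher"]),
    n_no_change = unname(calls["no_change"]),
    n_a_higher_raw = n_raw,
    n_ties = sum(results$delta == 0),
    fraction_a_higher_raw = n_raw / nrow(results),
    delta_histogram = data.frame(lower = h$breaks[-length(h$breaks)],
                                 upper = h$breaks[-1], count = h$counts)
  ), class = "differential_summary")
}

#' @export
print.differential_summary <- function(x, ...) {
  cat(sprintf("differential editing over %d tested sites\n", x$n_sites_tested))
  cat(sprintf("  significant: %d A_higher, %d B_higher, %d no_change\n",
              x$n_a_higher_significant, x$n_b_higher_significant, x$n_no_change))
  cat(sprintf("  raw direction: %d (%.1f%%) sites with mean_a > mean_b (%d ties)\n",
              x$n_a_higher_raw, 100 * x$fraction_a_higher_raw, x$n_ties))
  invisible(x)
}

#' @importFrom graphics hist
NULL
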