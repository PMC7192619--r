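## In vitro editing-event caller for an amplicon: per-adenosine exact binomial
## test against the sequencing-error floor, BH correction within each
## replicate's dataset, strict adjusted-p cut, replicate averaging and
## fold-over-control reporting.

#' Upper-tail binomial probability under the sequencing-error null
#'
#' `P(X >= g_count)` for `X ~ Binomial(ag_coverage, p0)`: the probability that
#' at least the observed number of A-to-G events arises from random sequencing
#' error alone. Evaluated with the exact survival function (no normal
#' approximation).
#'
#' @param g_count observed G calls (vectorized).
#' @param ag_coverage A+G call depth.
#' @param p0 per-base error probability (default 0.001, the Q30 floor).
#' @return Numeric vector of upper-tail probabilities.
#' @export
binomial_error_p <- function(g_count, ag_coverage, p0 = 0.001) {
  if (any(!is_count(g_count)) || any(!is_count(ag_coverage)) ||
      any(g_count > ag_coverage))
    abort_validation("need integer counts with 0 <= g_count <= ag_coverage")
  if (!is_fraction(p0, open = TRUE)) abort_validation("p0 must lie in (0, 1)")
  pbinom(g_count - 1, ag_coverage, p0, lower.tail = FALSE)
}

#' Call editing events within one replicate's dataset
#'
#' Computes the binomial error p-value at every adenosine position of one
#' replicate, applies Benjamini-Hochberg across all positions of that dataset,
#' and flags a position as edited iff its adjusted p-value is strictly below
#' `thresholds$detection_adjusted_p`.
#'
#' @param observations data.frame with columns `position`, `g_count`,
#'   `ag_coverage` (one row per adenosine; duplicates are an error).
#' @param thresholds a [threshold_config()] supplying `error_rate_p0` and
#'   `detection_adjusted_p`.
#' @return The input with `p_value`, `p_adjusted` and `edited` columns added.
#' @export
detect_in_dataset <- function(observations, thresholds = threshold_config()) {
  need <- c("position", "g_count", "ag_coverage")
  if (!all(need %in% names(observations)))
    abort_validation("observations need columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(observations$position))
    abort_validation("duplicate adenosine positions in one dataset")
  observations$p_value <- binomial_error_p(observations$g_count,
                                           observations$ag_coverage,
                                           thresholds$error_rate_p0)
  observations$p_adjusted <- bh_adjust(observations$p_value)
  observations$edited <- observations$p_adjusted < thresholds$detection_adjusted_p
  observations
}

#' Summarize experimental and control replicates per position
#'
#' For each adenosine position: per-replicate editing percentages
#' (`100 * g / (a + g)`), their mean and SEM (sample SD over `sqrt(n)`) within
#' each group, the per-replicate edited calls from [detect_in_dataset()], a
#' replicate-vote detected flag (edited in at least `min_replicates_detected`
#' experimental replicates), and the fold over control
#' (`mean_exp / mean_ctl`, `NA` when the control mean is zero).
#'
#' @param experimental,control lists of per-replicate data.frames, each with
#'   columns `position`, `g_count`, `ag_coverage`; all replicates must cover
#'   the same positions.
#' @param thresholds a [threshold_config()].
#' @param min_replicates_detected experimental replicates that must
#'   individually pass the adjusted-p cut for `detected` (default 3 of 5).
#' @return data.frame of class `detection_result`, one row per position:
#'   `position`, `n_exp_edited`, `n_ctl_edited`, `detected`, `mean_exp`,
#'   `sem_exp`, `mean_ctl`, `sem_ctl`, `fold_vs_control`.
#' @export
summarize_replicates <- function(experimental, control,
                                 thresholds = threshold_config(),
                                 min_replicates_detected = 3) {
  if (length(experimental) < 2 || length(control) < 2)
    abort_validation("need at least 2 replicates per group")
  positions <- sort(experimental[[1]]$position)
  for (rep in c(experimental, control))
    if (!setequal(rep$position, positions) || length(rep$position) != length(positions))
      abort_validation("all replicates must cover the same adenosine positions")
  pct <- function(rep) {
    rep <- rep[match(positions, rep$position), ]
    100 * rep$g_count / rep$ag_coverage
  }
  edited <- function(rep) {
    d <- detect_in_dataset(rep, thresholds)
    d$edited[match(positions, d$position)]
  }
  exp_pct <- do.call(cbind, lapply(experimental, pct))
  ctl_pct <- do.call(cbind, lapply(control, pct))
  exp_ed <- do.call(cbind, lapply(experimental, edited))
  ctl_ed <- do.call(cbind, lapply(control, edited))
  sem <- function(m) apply(m, 1, sd) / sqrt(ncol(m))
  mean_exp <- rowMeans(exp_pct); mean_ctl <- rowMeans(ctl_pct)
  res <- data.frame(
    position = positions,
    n_exp_edited = rowSums(exp_ed), n_ctl_edited = rowSums(ctl_ed),
    detected = rowSums(exp_ed) >= min_replicates_detected,
    mean_exp = mean_exp, sem_exp = sem(exp_pct),
    mean_ctl = mean_ctl, sem_ctl = sem(ctl_pct),
    fold_vs_control = ifelse(mean_ctl > 0, mean_exp / mean_ctl, NA_real_),
    stringsAsFactors = FALSE)
  class(res) <- c("detection_result", "data.frame")
  res
}

#' Merged per-site report with the fold-over-control flag
#'
#' Joins detection summaries onto the known-site annotation (in vivo editing
#' levels) and applies the explicit fold-rule: a position is flagged iff its
#' mean editing percentage in the experimental group exceeds twice the control
#' mean (strict `fold_vs_control > 2`). This reporting rule is separate from
#' the per-replicate adjusted-p vote carried in `detected`. Result positions
#' absent from the site list are kept and marked `putative_novel`.
#'
#' @param results a data.frame with at least `position`, `mean_exp`, `sem_exp`,
#'   `mean_ctl`, `sem_ctl` (e.g. from [summarize_replicates()]);
#'   `fold_vs_control` is recomputed from the means if absent.
#' @param sites an `editing_sites` table with `in_vivo_level` (the site
#'   positions are matched against result positions; `transcript_id` is
#'   annotation only).
#' @param fold_cutoff strict fold threshold for the flag (default 2).
#' @return data.frame ordered by position with columns `position`,
#'   `in_vivo_level`, `mean_ctl`, `sem_ctl`, `mean_exp`, `sem_exp`,
#'   `fold_vs_control`, `flagged`, `putative_novel` (plus `detected` when
#'   present in `results`).
#' @export
table1_report <- function(results, sites, fold_cutoff = 2) {
  sites <- validate_sites(sites)
  need <- c("position", "mean_exp", "sem_exp", "mean_ctl", "sem_ctl")
  if (!all(need %in% names(results)))
    abort_validation("results need columns: ", paste(need, collapse = ", "))
  if (is.null(results$fold_vs_control))
    results$fold_vs_control <- ifelse(results$mean_ctl > 0,
                                      results$mean_exp / results$mean_ctl, NA_real_)
  idx <- match(results$position, sites$position)
  rep <- data.frame(
    position = results$position,
    in_vivo_level = sites$in_vivo_level[idx],
    mean_ctl = results$mean_ctl, sem_ctl = results$sem_ctl,
    mean_exp = results$mean_exp, sem_exp = results$sem_exp,
    fold_vs_control = results$fold_vs_control,
    flagged = !is.na(results$fold_vs_control) &
      results$fold_vs_control > fold_cutoff,
    putative_novel = is.na(idx),
    stringsAsFactors = FALSE)
  if (!is.null(results$detected)) rep$detected <- results$detected
  rep[order(rep$position), , drop = FALSE]
}
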