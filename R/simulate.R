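## Seeded generators producing count tables with the statistical structure the
## two analyses assume: compartment-specific true editing levels, negative
## binomial coverage, optional beta overdispersion between replicates, and a
## symmetric base-call error floor (a true A read as G with prob error_rate,
## and a true G -- i.e. an edited I -- read back as A with the same prob).

#' Specification for the two-compartment RNA-seq simulation
#'
#' Defaults emulate the design the differential analysis targets: 4 paired
#' replicates per compartment, 92% of sites truly more edited in compartment A
#' with deltas drawn uniformly from 0.05-0.3, baseline (compartment B) levels
#' uniform on 0.05-0.5, negative binomial coverage with mean 100, and the
#' 0.1% error floor.
#'
#' @param n_sites number of editing sites.
#' @param n_pairs replicate pairs per compartment (default 4).
#' @param true_level_a,true_level_b optional per-site true editing fractions
#'   (length `n_sites`); when omitted they are generated from
#'   `fraction_a_higher` and `delta_range`.
#' @param fraction_a_higher fraction of sites with `level_a > level_b`
#'   (default 0.92); remaining sites get `level_b > level_a`.
#' @param delta_range range the absolute level difference is drawn from
#'   (default `c(0.05, 0.3)`).
#' @param base_level_range range baseline levels are drawn from
#'   (default `c(0.05, 0.5)`).
#' @param coverage_mean mean per-site per-sample read depth (default 100).
#' @param coverage_dispersion negative binomial size parameter (default 5;
#'   `Inf` gives fixed coverage equal to `coverage_mean`).
#' @param error_rate per-base miscall probability (default 0.001).
#' @param overdispersion_rho between-replicate variability of the realized
#'   editing level, as the rho parameter of a beta law with the true level as
#'   mean (variance `rho * L * (1 - L)`; 0 = binomial sampling only;
#'   default 0.01).
#' @param seed integer seed; identical seeds give identical output.
#' @return A validated list of class `compartment_sim_spec`.
#' @export
compartment_sim_spec <- function(n_sites, n_pairs = 4,
                                 true_level_a = NULL, true_level_b = NULL,
                                 fraction_a_higher = 0.92,
                                 delta_range = c(0.05, 0.3),
                                 base_level_range = c(0.05, 0.5),
                                 coverage_mean = 100, coverage_dispersion = 5,
                                 error_rate = 0.001, overdispersion_rho = 0.01,
                                 seed = 1L) {
  if (!is_count(n_sites) || n_sites < 1) abort_validation("n_sites must be >= 1")
  if (!is_count(n_pairs) || n_pairs < 1) abort_validation("n_pairs must be >= 1")
  for (lv in list(true_level_a, true_level_b))
    if (!is.null(lv) && (length(lv) != n_sites || any(lv < 0 | lv > 1)))
      abort_validation("true levels must be length n_sites, in [0, 1]")
  if (!is_fraction(fraction_a_higher)) abort_validation("fraction_a_higher in [0, 1]")
  if (coverage_mean <= 0 || coverage_dispersion <= 0)
    abort_validation("coverage_mean and coverage_dispersion must be positive")
  if (!is_fraction(error_rate)) abort_validation("error_rate in [0, 1]")
  if (!is.numeric(overdispersion_rho) || overdispersion_rho < 0 ||
      overdispersion_rho >= 1)
    abort_validation("overdispersion_rho must lie in [0, 1)")
  structure(list(n_sites = as.integer(n_sites), n_pairs = as.integer(n_pairs),
                 true_level_a = true_level_a, true_level_b = true_level_b,
                 fraction_a_higher = fraction_a_higher, delta_range = delta_range,
                 base_level_range = base_level_range,
                 coverage_mean = coverage_mean,
                 coverage_dispersion = coverage_dispersion,
                 error_rate = error_rate,
                 overdispersion_rho = overdispersion_rho,
                 seed = as.integer(seed)),
            class = "compartment_sim_spec")
}

draw_coverage <- function(n, mean, size) {
  if (is.infinite(size)) rep(as.integer(round(mean)), n)
  else pmax(1L, rnbinom(n, mu = mean, size = size))  # floor of 1 read
}

## realized per-replicate level: beta around L with var rho*L*(1-L)
draw_realized_level <- function(true_level, rho) {
  if (rho == 0) return(true_level)
  interior <- true_level > 0 & true_level < 1
  out <- true_level
  if (any(interior)) {
    nu <- 1 / rho - 1
    out[interior] <- rbeta(sum(interior), true_level[interior] * nu,
                           (1 - true_level[interior]) * nu)
  }
  out
}

#' Simulate two-compartment per-site base counts
#'
#' For every site and sample: coverage from the negative binomial law, a
#' realized editing level around the compartment's true level (beta, variance
#' `rho * L * (1-L)`), and a G count drawn binomially at probability
#' `level * (1 - error) + (1 - level) * error`; the A count is the remainder
#' (C and T counts are zero -- the analyses use only A and G).
#'
#' @param spec a [compartment_sim_spec()].
#' @return list with `sites` (an `editing_sites` table), `counts`
#'   (`site_base_counts` over samples GA_1..GA_n, GFL_1..GFL_n), `design`
#'   (a paired [compartment_design()]) and `truth` (data.frame
#'   `transcript_id`, `position`, `true_level_a`, `true_level_b`).
#' @export
simulate_compartment_counts <- function(spec) {
  if (!inherits(spec, "compartment_sim_spec"))
    abort_validation("spec must come from compartment_sim_spec()")
  set.seed(spec$seed)
  n <- spec$n_sites
  lb <- spec$true_level_b
  la <- spec$true_level_a
  if (is.null(la) || is.null(lb)) {
    base <- runif(n, spec$base_level_range[1], spec$base_level_range[2])
    delta <- runif(n, spec$delta_range[1], spec$delta_range[2])
    a_higher <- seq_len(n) <= round(spec$fraction_a_higher * n)
    if (is.null(lb)) lb <- ifelse(a_higher, base, pmin(1, base + delta))
    if (is.null(la)) la <- ifelse(a_higher, pmin(1, base + delta), base)
  }
  sites <- validate_sites(data.frame(
    transcript_id = sprintf("tx%05d", seq_len(n)), position = rep(100L, n),
    ref_base = "A", in_vivo_level = NA_real_, stringsAsFactors = FALSE))
  a_samples <- sprintf("GA_%d", seq_len(spec$n_pairs))
  b_samples <- sprintf("GFL_%d", seq_len(spec$n_pairs))
  design <- compartment_design(a_samples, b_samples,
                               pairing = setNames(b_samples, a_samples))
  one_sample <- function(sample_id, true_level) {
    cov <- draw_coverage(n, spec$coverage_mean, spec$coverage_dispersion)
    lvl <- draw_realized_level(true_level, spec$overdispersion_rho)
    p_g <- lvl * (1 - spec$error_rate) + (1 - lvl) * spec$error_rate
    g <- rbinom(n, cov, p_g)
    data.frame(transcript_id = sites$transcript_id, position = sites$position,
               sample_id = sample_id, a_count = cov - g, c_count = 0L,
               g_count = g, t_count = 0L, stringsAsFactors = FALSE)
  }
  counts <- do.call(rbind, c(lapply(a_samples, one_sample, true_level = la),
                             lapply(b_samples, one_sample, true_level = lb)))
  truth <- data.frame(transcript_id = sites$transcript_id,
                      position = sites$position,
                      true_level_a = la, true_level_b = lb,
                      stringsAsFactors = FALSE)
  list(sites = sites, counts = validate_counts(counts), design = design,
       truth = truth)
}

#' Specification for the in vitro amplicon assay simulation
#'
#' Defaults emulate a densely covered MiSeq amplicon experiment: 126
#' adenosines, 5 experimental and 5 control replicates, 100,000 A+G calls per
#' position per replicate, and the 0.1% error floor. Control replicates have
#' true editing 0 everywhere; experimental replicates edit only the positions
#' named in `edited_positions`.
#'
#' @param n_adenosines number of adenosine positions on the amplicon
#'   (default 126).
#' @param edited_positions named numeric vector: names are 1-based positions
#'   (within `1..n_adenosines` after mapping, see Details), values are true
#'   editing fractions. Positions here index the amplicon coordinate directly.
#' @param n_experimental,n_control replicate counts (defaults 5 and 5).
#' @param coverage_per_replicate A+G call depth per position (default 1e5).
#' @param error_rate per-base miscall probability (default 0.001).
#' @param seed integer seed.
#' @param positions optional integer vector of amplicon coordinates for the
#'   adenosines (default `1:n_adenosines`); `edited_positions` names must be a
#'   subset.
#' @return A validated list of class `assay_sim_spec`.
#' @export
assay_sim_spec <- function(n_adenosines = 126, edited_positions = numeric(),
                           n_experimental = 5, n_control = 5,
                           coverage_per_replicate = 1e5, error_rate = 0.001,
                           seed = 1L, positions = NULL) {
  if (!is_count(n_adenosines) || n_adenosines < 1)
    abort_validation("n_adenosines must be >= 1")
  if (is.null(positions)) positions <- seq_len(n_adenosines)
  if (length(positions) != n_adenosines || anyDuplicated(positions))
    abort_validation("positions must be n_adenosines distinct coordinates")
  if (length(edited_positions)) {
    ep <- as.integer(names(edited_positions))
    if (anyNA(ep) || !all(ep %in% positions))
      abort_validation("edited_positions names must be adenosine coordinates")
    if (any(edited_positions < 0 | edited_positions > 1))
      abort_validation("edited fractions must lie in [0, 1]")
  }
  if (!is_count(n_experimental) || !is_count(n_control))
    abort_validation("replicate counts must be non-negative integers")
  if (!is_count(coverage_per_replicate) || coverage_per_replicate < 1)
    abort_validation("coverage_per_replicate must be a positive integer")
  if (!is_fraction(error_rate)) abort_validation("error_rate in [0, 1]")
  structure(list(n_adenosines = as.integer(n_adenosines),
                 positions = as.integer(positions),
                 edited_positions = edited_positions,
                 n_experimental = as.integer(n_experimental),
                 n_control = as.integer(n_control),
                 coverage_per_replicate = as.integer(coverage_per_replicate),
                 error_rate = error_rate, seed = as.integer(seed)),
            class = "assay_sim_spec")
}

#' Simulate amplicon assay replicate counts
#'
#' @param spec an [assay_sim_spec()].
#' @return list with `experimental` and `control` (lists of per-replicate
#'   data.frames: `position`, `a_count`, `g_count`, `ag_coverage`) and `truth`
#'   (data.frame `position`, `true_level`).
#' @export
simulate_assay_counts <- function(spec) {
  if (!inherits(spec, "assay_sim_spec"))
    abort_validation("spec must come from assay_sim_spec()")
  set.seed(spec$seed)
  true_level <- setNames(numeric(spec$n_adenosines), spec$positions)
  if (length(spec$edited_positions))
    true_level[names(spec$edited_positions)] <- spec$edited_positions
  one_replicate <- function(levels) {
    cov <- spec$coverage_per_replicate
    p_g <- levels * (1 - spec$error_rate) + (1 - levels) * spec$error_rate
    g <- rbinom(length(levels), cov, p_g)
    data.frame(position = spec$positions, a_count = cov - g, g_count = g,
               ag_coverage = cov, stringsAsFactors = FALSE)
  }
  experimental <- lapply(seq_len(spec$n_experimental),
                         function(i) one_replicate(true_level))
  control <- lapply(seq_len(spec$n_control),
                    function(i) one_replicate(numeric(spec$n_adenosines)))
  list(experimental = experimental, control = control,
       truth = data.frame(position = spec$positions,
                          true_level = unname(true_level),
                          stringsAsFactors = FALSE))
}
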