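test_that("one_tailed_t_pair matches the independent Welch-t oracle", {
  a <- c(0.5, 0.6, 0.55, 0.65)
  b <- c(0.10, 0.20, 0.15, 0.12)
  p <- one_tailed_t_pair(a, b)
  oracle_hi <- stats::t.test(a, b, alternative = "greater")$p.value
  oracle_lo <- stats::t.test(a, b, alternative = "less")$p.value
  expect_equal(unname(p["p_a_greater"]), oracle_hi, tolerance = 1e-12)
  expect_equal(unname(p["p_b_greater"]), oracle_lo, tolerance = 1e-12)
  expect_lt(p["p_a_greater"], 0.01)
  expect_gt(p["p_b_greater"], 0.99)

  # random vectors: oracle agreement, antisymmetry under group swap,
  # complementarity of the two tails
  set.seed(123)
  for (i in 1:20) {
    x <- runif(sample(2:6, 1)); y <- runif(sample(2:6, 1))
    p <- one_tailed_t_pair(x, y)
    expect_equal(unname(p["p_a_greater"]),
                 stats::t.test(x, y, alternative = "greater")$p.value,
                 tolerance = 1e-12)
    swapped <- one_tailed_t_pair(y, x)
    expect_equal(unname(p["p_a_greater"]), unname(swapped["p_b_greater"]))
    expect_equal(unname(p["p_a_greater"] + p["p_b_greater"]), 1)
  }
})

test_that("paired variant matches the paired t oracle", {
  set.seed(5)
  a <- runif(4); b <- runif(4)
  p <- one_tailed_t_pair(a, b, paired = TRUE)
  expect_equal(unname(p["p_a_greater"]),
               stats::t.test(a, b, paired = TRUE, alternative = "greater")$p.value,
               tolerance = 1e-12)
})

test_that("degenerate-variance conventions hold", {
  # identical vectors with nonzero variance -> exact symmetry
  v <- c(0.1, 0.2, 0.3)
  expect_equal(unname(one_tailed_t_pair(v, v)), c(0.5, 0.5))
  # both constant and equal -> 0.5 / 0.5
  expect_equal(unname(one_tailed_t_pair(c(0.2, 0.2), c(0.2, 0.2))), c(0.5, 0.5))
  # constant with different means -> 0 / 1 in the favored direction
  expect_equal(unname(one_tailed_t_pair(c(0.9, 0.9), c(0.1, 0.1))), c(0, 1))
  expect_equal(unname(one_tailed_t_pair(c(0.1, 0.1), c(0.9, 0.9))), c(1, 0))
  expect_error(one_tailed_t_pair(0.5, c(0.1, 0.2)),
               class = "axonedit_validation_error")
})

test_that("bh_adjust matches hand-derived values and the brute-force oracle", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.37), 0.37)          # m = 1: unchanged
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_error(bh_adjust(c(0.5, 1.2)), class = "axonedit_validation_error")

  set.seed(77)
  for (i in 1:30) {
    p <- runif(sample(c(1:10, 50, 200), 1))^sample(1:3, 1)
    adj <- bh_adjust(p)
    expect_equal(adj, bh_brute_force(p), tolerance = 1e-14)
    expect_equal(adj, stats::p.adjust(p, method = "BH"), tolerance = 1e-14)
  }
})

test_that("call_sites applies per-tail BH with an inclusive threshold", {
  # single site whose adjusted value lands exactly on the level: called (<=)
  res <- data.frame(p_a_greater = 0.1, p_b_greater = 0.9)
  out <- call_sites(res, threshold_config(fdr_level = 0.1))
  expect_equal(out$call, "A_higher")

  res2 <- data.frame(p_a_greater = 0.11, p_b_greater = 0.89)
  expect_equal(call_sites(res2, threshold_config())$call, "no_change")

  resb <- data.frame(p_a_greater = c(0.9, 0.99), p_b_greater = c(0.1, 0.01))
  expect_equal(call_sites(resb, threshold_config())$call,
               c("B_higher", "B_higher"))

  res3 <- data.frame(p_a_greater = rep(1, 10), p_b_greater = runif(10, 0.5, 1))
  expect_true(all(call_sites(res3, threshold_config())$call != "A_higher"))
})

test_that("differential_editing end to end: signal found, partition exact", {
  set.seed(31)
  spec <- compartment_sim_spec(
    n_sites = 400, n_pairs = 4, fraction_a_higher = 1,
    delta_range = c(0.2, 0.3), coverage_mean = 200, coverage_dispersion = Inf,
    overdispersion_rho = 0, seed = 31L)
  sim <- simulate_compartment_counts(spec)
  res <- differential_editing(sim$counts, sim$design)
  summ <- summarize_differential(res)
  expect_equal(summ$n_a_higher_significant + summ$n_b_higher_significant +
                 summ$n_no_change, summ$n_sites_tested)
  truth_up <- sim$truth$true_level_a > sim$truth$true_level_b
  # strong signal: power >= 0.9 for the planted direction, essentially no
  # calls in the opposite direction
  called_up <- res$call == "A_higher"
  expect_gte(mean(called_up[truth_up]), 0.9)
  expect_lte(sum(res$call == "B_higher"), 2)
  # delta histogram counts cover all tested sites
  expect_equal(sum(summ$delta_histogram$count), summ$n_sites_tested)

  # paired variant runs on the same design
  res_p <- differential_editing(sim$counts, sim$design, paired = TRUE)
  expect_equal(nrow(res_p), nrow(res))
})

test_that("summarize_differential raw-direction bookkeeping", {
  res <- data.frame(p_a_greater = runif(10, 0.4, 0.6),
                    p_b_greater = runif(10, 0.4, 0.6),
                    delta = c(rep(0.1, 9), -0.1))
  out <- summarize_differential(call_sites(res, threshold_config()))
  expect_equal(out$fraction_a_higher_raw, 0.9)
  expect_equal(out$n_ties, 0L)
  res$delta <- 0
  out0 <- summarize_differential(call_sites(res, threshold_config()))
  expect_equal(out0$n_a_higher_raw, 0L)
  expect_equal(out0$n_ties, 10L)
})
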