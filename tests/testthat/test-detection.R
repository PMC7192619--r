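test_that("binomial_error_p: trivial values, closed form and brute force", {
  expect_equal(binomial_error_p(0, 100), 1)
  # closed form for a single event: 1 - (1 - p0)^n
  expect_equal(binomial_error_p(1, 1000, 0.001), 1 - 0.999^1000, tolerance = 1e-12)
  expect_equal(1 - 0.999^1000, 0.6323045752, tolerance = 1e-9)

  # brute-force pmf summation oracle
  for (n in c(10L, 100L, 2000L, 10000L)) {
    for (g in unique(pmin(n, c(0L, 1L, 3L, 17L, n %/% 2L, n)))) {
      brute <- sum(stats::dbinom(g:n, n, 0.001))
      expect_equal(binomial_error_p(g, n, 0.001), brute, tolerance = 1e-12)
    }
  }

  # monotone decreasing in g_count at fixed coverage
  p_seq <- binomial_error_p(0:20, rep(1000L, 21), 0.001)
  expect_true(all(diff(p_seq) < 0))

  expect_error(binomial_error_p(5, 3), class = "axonedit_validation_error")
  expect_error(binomial_error_p(1, 10, p0 = 0), class = "axonedit_validation_error")
})

test_that("detect_in_dataset: BH within a replicate, strict adjusted-p cut", {
  obs <- data.frame(position = 1:126,
                    g_count = c(10000L, rep(100L, 125)),
                    ag_coverage = 100000L)
  d <- detect_in_dataset(obs, threshold_config())
  expect_true(d$edited[d$position == 1])
  expect_lt(d$p_adjusted[1], 1e-100)
  # positions at the error floor are not called
  expect_equal(sum(d$edited), 1L)

  # all-zero g counts: p = 1 everywhere, nothing called
  none <- detect_in_dataset(data.frame(position = 1:10, g_count = 0L,
                                       ag_coverage = 1000L))
  expect_true(all(none$p_value == 1) && !any(none$edited))

  expect_error(detect_in_dataset(data.frame(position = c(1, 1), g_count = 0L,
                                            ag_coverage = 10L)),
               class = "axonedit_validation_error")
})

test_that("the adjusted-p threshold is strict: exactly 0.001 is not edited", {
  # single position, so adjusted p == raw p; choose counts whose tail is
  # exactly representable around the cutoff via a constructed threshold
  obs <- data.frame(position = 1L, g_count = 5L, ag_coverage = 1000L)
  p <- binomial_error_p(5, 1000, 0.001)
  at_cut <- detect_in_dataset(obs, threshold_config(detection_adjusted_p = p))
  expect_false(at_cut$edited)  # p < p is FALSE
  above <- detect_in_dataset(obs, threshold_config(detection_adjusted_p = p * 1.01))
  expect_true(above$edited)
})

test_that("summarize_replicates averages percentages and computes folds", {
  # two planted sites emulating the detected levels, plus an error-floor site
  mk <- function(g) data.frame(position = c(134L, 418L, 500L),
                               g_count = g, ag_coverage = 100000L)
  exp_reps <- lapply(1:5, function(i) mk(c(780L, 10330L, 100L) + i))
  ctl_reps <- lapply(1:5, function(i) mk(c(10L, 40L, 100L) + i))
  out <- summarize_replicates(exp_reps, ctl_reps, threshold_config())
  expect_s3_class(out, "detection_result")
  expect_equal(out$position, c(134L, 418L, 500L))
  # planted positions edited in every replicate; floor position in none
  expect_equal(out$n_exp_edited, c(5L, 5L, 0L))
  expect_equal(out$detected, c(TRUE, TRUE, FALSE))
  # SEM of 100*g/cov for g = base + 1:5 is sd(1:5)/sqrt(5) in percent units
  expect_equal(out$sem_exp, rep(100 * sd(1:5) / sqrt(5) / 100000, 3))
  expect_equal(out$fold_vs_control[1], out$mean_exp[1] / out$mean_ctl[1])

  # fold is scale-invariant in expectation: multiply all counts by 10
  scale10 <- function(d) transform(d, g_count = g_count * 10L,
                                   ag_coverage = ag_coverage * 10L)
  out10 <- summarize_replicates(lapply(exp_reps, scale10),
                                lapply(ctl_reps, scale10), threshold_config())
  expect_equal(out10$fold_vs_control, out$fold_vs_control)

  # zero-mean control and experiment: fold undefined, not detected
  z <- lapply(1:2, function(i) data.frame(position = 1L, g_count = 0L,
                                          ag_coverage = 1000L))
  outz <- summarize_replicates(z, z, threshold_config(),
                               min_replicates_detected = 1)
  expect_true(is.na(outz$fold_vs_control) && !outz$detected)

  expect_error(summarize_replicates(exp_reps[1], ctl_reps, threshold_config()),
               class = "axonedit_validation_error")
  bad <- c(exp_reps[1:4], list(mk(c(1L, 2L, 3L))[1:2, ]))
  expect_error(summarize_replicates(bad, ctl_reps, threshold_config()),
               class = "axonedit_validation_error")
})

test_that("table1_report merges sites and applies the strict fold rule", {
  t1 <- table1_fixture()
  sites <- validate_sites(t1[c("transcript_id", "position", "ref_base",
                               "in_vivo_level")])
  results <- data.frame(position = t1$position,
                        mean_exp = t1$exp_mean, sem_exp = t1$exp_sem,
                        mean_ctl = t1$ctl_mean, sem_ctl = t1$ctl_sem)
  rep <- table1_report(results, sites)
  expect_equal(rep$position, sort(t1$position))
  expect_setequal(rep$position[rep$flagged], c(134, 139, 175, 190, 418))
  expect_equal(sum(!rep$flagged), 17L)
  expect_false(any(rep$putative_novel))

  # a result position outside the site list is kept as putative novel
  results2 <- rbind(results, data.frame(position = 999L, mean_exp = 5,
                                        sem_exp = 0.1, mean_ctl = 0.01,
                                        sem_ctl = 0.001))
  rep2 <- table1_report(results2, sites)
  expect_true(rep2$putative_novel[rep2$position == 999])
  expect_true(is.na(rep2$in_vivo_level[rep2$position == 999]))

  # empty results -> empty report
  expect_equal(nrow(table1_report(results[0, ], sites)), 0L)
})
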