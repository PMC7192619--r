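test_that("compartment simulation is seed-deterministic and structurally valid", {
  spec <- compartment_sim_spec(n_sites = 50, n_pairs = 4, seed = 7L)
  sim1 <- simulate_compartment_counts(spec)
  sim2 <- simulate_compartment_counts(spec)
  expect_identical(sim1$counts, sim2$counts)
  expect_identical(sim1$truth, sim2$truth)
  expect_equal(nrow(sim1$counts), 50 * 8)
  expect_true(all(sim1$counts$c_count == 0 & sim1$counts$t_count == 0))
  expect_setequal(unique(sim1$counts$sample_id),
                  c(sprintf("GA_%d", 1:4), sprintf("GFL_%d", 1:4)))
  # planted direction matches the requested fraction
  expect_equal(mean(sim1$truth$true_level_a > sim1$truth$true_level_b), 0.92,
               tolerance = 0.05)
})

test_that("error-free saturated editing gives g_count == coverage", {
  spec <- compartment_sim_spec(n_sites = 20, n_pairs = 2,
                               true_level_a = rep(1, 20), true_level_b = rep(1, 20),
                               error_rate = 0, overdispersion_rho = 0, seed = 3L)
  sim <- simulate_compartment_counts(spec)
  expect_true(all(sim$counts$a_count == 0))
  expect_true(all(sim$counts$g_count >= 1))
})

test_that("null sites converge to the error floor (closed-form mean)", {
  # true level 0 both sides: pooled G fraction ~ error_rate within 3 binomial SE
  spec <- compartment_sim_spec(n_sites = 200, n_pairs = 4,
                               true_level_a = rep(0, 200), true_level_b = rep(0, 200),
                               coverage_mean = 2000, coverage_dispersion = Inf,
                               overdispersion_rho = 0, seed = 11L)
  sim <- simulate_compartment_counts(spec)
  n_calls <- sum(sim$counts$a_count + sim$counts$g_count)
  frac <- sum(sim$counts$g_count) / n_calls
  se <- sqrt(0.001 * 0.999 / n_calls)
  expect_lt(abs(frac - 0.001), 3 * se)
})

test_that("realized levels converge to level*(1-e) + (1-level)*e", {
  for (L in c(0.2, 0.5, 0.9)) {
    spec <- compartment_sim_spec(n_sites = 100, n_pairs = 2,
                                 true_level_a = rep(L, 100),
                                 true_level_b = rep(L, 100),
                                 coverage_mean = 1e4, coverage_dispersion = Inf,
                                 error_rate = 0.001, overdispersion_rho = 0,
                                 seed = 13L)
    sim <- simulate_compartment_counts(spec)
    expected <- L * 0.999 + (1 - L) * 0.001
    n_calls <- sum(sim$counts$a_count + sim$counts$g_count)
    frac <- sum(sim$counts$g_count) / n_calls
    expect_lt(abs(frac - expected), 3 * sqrt(expected * (1 - expected) / n_calls))
  }
})

test_that("rho = 0 leaves only binomial sampling variance between replicates", {
  # closed form: var of per-replicate level estimates = p(1-p)/coverage
  L <- 0.3; cov <- 400
  spec <- compartment_sim_spec(n_sites = 4000, n_pairs = 2,
                               true_level_a = rep(L, 4000),
                               true_level_b = rep(L, 4000),
                               coverage_mean = cov, coverage_dispersion = Inf,
                               error_rate = 0, overdispersion_rho = 0, seed = 17L)
  sim <- simulate_compartment_counts(spec)
  lv <- editing_level(sim$counts)
  v_obs <- var(lv$level)
  v_expected <- L * (1 - L) / cov
  expect_equal(v_obs, v_expected, tolerance = 0.05)
})

test_that("assay simulation plants editing only at the requested positions", {
  spec <- assay_sim_spec(n_adenosines = 126,
                         edited_positions = c("118" = 0.1),
                         coverage_per_replicate = 1e5, seed = 5L)
  sim <- simulate_assay_counts(spec)
  expect_length(sim$experimental, 5)
  expect_length(sim$control, 5)
  # binomial mean/variance at the planted site and at the error floor
  g_at <- vapply(sim$experimental,
                 function(r) r$g_count[r$position == 118], numeric(1))
  expect_true(all(abs(g_at - 1e5 * (0.1 * 0.999 + 0.9 * 0.001)) <
                    3 * sqrt(1e5 * 0.1 * 0.9) + 1))
  g_floor <- unlist(lapply(sim$experimental,
                           function(r) r$g_count[r$position != 118]))
  expect_lt(abs(mean(g_floor) - 100), 3 * sqrt(1e5 * 0.001 * 0.999 / length(g_floor)))
  # controls carry error only
  g_ctl <- unlist(lapply(sim$control, function(r) r$g_count))
  expect_lt(abs(mean(g_ctl) - 100), 3 * sqrt(1e5 * 0.001 * 0.999 / length(g_ctl)))

  expect_identical(simulate_assay_counts(spec)$experimental,
                   sim$experimental)
  # n_experimental 0 -> only control tables
  sim0 <- simulate_assay_counts(assay_sim_spec(n_adenosines = 10,
                                               n_experimental = 0, seed = 1L))
  expect_length(sim0$experimental, 0)
  expect_length(sim0$control, 5)
})

test_that("simulation specs reject invalid fields", {
  expect_error(compartment_sim_spec(n_sites = 0), class = "axonedit_validation_error")
  expect_error(compartment_sim_spec(n_sites = 10, overdispersion_rho = 1),
               class = "axonedit_validation_error")
  expect_error(compartment_sim_spec(n_sites = 10, true_level_a = rep(2, 10)),
               class = "axonedit_validation_error")
  expect_error(assay_sim_spec(edited_positions = c("999" = 0.5)),
               class = "axonedit_validation_error")
  expect_error(assay_sim_spec(coverage_per_replicate = 0),
               class = "axonedit_validation_error")
})
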