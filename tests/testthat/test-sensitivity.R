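scenario <- kerala_2019_scenario()

test_that("gamma moment fit reproduces mean and sd analytically and the SD=25% rule gives shape 16", {
  g <- fit_gamma_moments(12000, 3000)
  expect_equal(g$shape, 16)
  expect_equal(g$scale, 750)
  expect_equal(g$shape * g$scale, 12000)            # mean
  expect_equal(sqrt(g$shape) * g$scale, 3000)       # sd

  for (m in c(0.5, 2.34, 950, 144000)) {
    g <- fit_gamma_moments(m, 0.25 * m)
    expect_equal(g$shape, 16)
    expect_equal(g$shape * g$scale, m)
  }
  expect_error(fit_gamma_moments(0, 1), "positive")
  expect_error(fit_gamma_moments(1, 0), "positive")
})

test_that("beta moment fit reproduces mean and sd and rejects variance-bound violations", {
  b <- fit_beta_moments(0.70, 0.175)
  expect_equal(b$alpha, 4.1, tolerance = 1e-3)
  expect_equal(b$beta, 1.757, tolerance = 1e-3)
  m <- b$alpha / (b$alpha + b$beta)
  v <- b$alpha * b$beta / ((b$alpha + b$beta)^2 * (b$alpha + b$beta + 1))
  expect_equal(m, 0.70)
  expect_equal(sqrt(v), 0.175)

  b2 <- fit_beta_moments(0.09, 0.0225)
  m2 <- b2$alpha / (b2$alpha + b2$beta)
  expect_equal(m2, 0.09)

  expect_error(fit_beta_moments(0.5, 0.5, name = "u_test"),
               "u_test.*variance bound")
  expect_error(fit_beta_moments(1.2, 0.1), "\\(0, 1\\)")
})

test_that("fitted distributions reproduce their moments empirically over 1e6 draws", {
  n <- 1e6
  set.seed(99)
  g <- fit_gamma_moments(12000, 3000)
  x <- rgamma(n, shape = g$shape, scale = g$scale)
  expect_lt(abs(mean(x) - 12000), 3 * 3000 / sqrt(n))

  b <- fit_beta_moments(0.70, 0.175)
  y <- rbeta(n, b$alpha, b$beta)
  expect_lt(abs(mean(y) - 0.70), 3 * 0.175 / sqrt(n))
  expect_lt(abs(sd(y) - 0.175), 0.002)
})

test_that("the tornado varies one parameter at a time and sorts by span", {
  tor <- one_way_dsa(scenario)
  expect_s3_class(tor, "tornado")
  expect_setequal(tor$parameter, drcea:::sa_registry()$name)
  expect_true(all(diff(tor$span) <= 0))  # descending span
  expect_true(all(is.finite(tor$low_icer)))

  # utilities dominate the span ordering over unit costs
  util_rank <- match(c("u_stdr", "u_blind", "u_gain_cataract"), tor$parameter)
  cost_rank <- match(c("laser_package", "cataract_surgery"), tor$parameter)
  expect_lt(min(util_rank), min(cost_rank))

  # a single-parameter spec yields a one-row table
  one <- one_way_dsa(scenario, dsa_spec(parameters = "laser_package"))
  expect_equal(nrow(one), 1L)
})

test_that("tornado legs at 0% excursion reproduce the central ICER exactly", {
  tor0 <- one_way_dsa(scenario, dsa_spec(rel_range = 0))
  ctr <- attr(tor0, "central_icer")
  expect_equal(tor0$low_icer, rep(ctr, nrow(tor0)))
  expect_equal(tor0$high_icer, rep(ctr, nrow(tor0)))
  expect_equal(tor0$span, rep(0, nrow(tor0)))
})

test_that("laser unit cost legs propagate linearly since QALYs are unaffected", {
  tor <- one_way_dsa(scenario, dsa_spec(parameters = "laser_package"))
  ev <- evaluate_scenario(scenario)
  delta_cost <- 0.1 * scenario$counts$n_stdr_treated * scenario$unit_costs$laser_package
  expect_equal(tor$high_icer - tor$low_icer, 2 * delta_cost / ev$total_qalys)
})

test_that("excursions that would leave [0, 1] are clipped with a warning", {
  sc2 <- scenario
  sc2$params$u_stdr <- 0.95  # 1.1x would exceed 1
  expect_warning(tor <- one_way_dsa(sc2, dsa_spec(parameters = "u_stdr")),
                 "clipped")
  expect_equal(tor$high_value, 1)
})

test_that("PSA draws are seed-reproducible and respect parameter domains", {
  spec <- psa_spec(n_iterations = 500, seed = 11L)
  d1 <- run_psa(scenario, spec)
  d2 <- run_psa(scenario, spec)
  expect_identical(as.data.frame(d1), as.data.frame(d2))
  expect_equal(nrow(d1), 500L)

  for (nm in c("u_stdr", "u_blind", "u_gain_cataract", "hrqol_decline",
               "p_blind_untreated", "p_blind_treated")) {
    expect_true(all(d1[[nm]] >= 0 & d1[[nm]] <= 1))
  }
  for (nm in c("rr_blind", "screening_cost_per_person", "laser_package",
               "cataract_surgery")) {
    expect_true(all(d1[[nm]] >= 0))
  }

  d3 <- run_psa(scenario, psa_spec(n_iterations = 500, seed = 12L))
  expect_false(identical(d1$icer, d3$icer))
})

test_that("per-parameter child streams keep draws stable when a parameter is dropped", {
  full <- run_psa(scenario, psa_spec(n_iterations = 200, seed = 5L))
  # re-sampling any single parameter with its own child seed reproduces the
  # same marginal draws as in the full run
  reg <- drcea:::sa_registry()
  centrals <- central_values(scenario)
  k <- which(reg$name == "laser_package")
  x <- drcea:::sample_parameter(centrals[["laser_package"]], "gamma", 0.25, 200,
                                seed = 5L + k, name = "laser_package")
  expect_identical(full$laser_package, x)
})

test_that("with all SDs at zero the ICER cloud collapses onto the deterministic ICER", {
  d0 <- run_psa(scenario, psa_spec(n_iterations = 20, sd_frac = 0, seed = 3L))
  ctr <- evaluate_scenario(scenario)$icer
  expect_equal(d0$icer, rep(ctr, 20), tolerance = 1e-9)
})

test_that("the vectorised PSA evaluator agrees with the scalar pipeline at central values", {
  centrals <- central_values(scenario)
  samples <- as.data.frame(as.list(centrals))[rep(1L, 3L), ]
  res <- drcea:::psa_evaluate(samples, scenario)
  ev <- evaluate_scenario(scenario)
  expect_equal(res$total_cost[1L], ev$total_cost)
  expect_equal(res$total_qalys[1L], ev$total_qalys)
  expect_equal(res$icer[1L], ev$icer)
})

test_that("the CEAC is monotone, bounded, and has the right limits", {
  d <- run_psa(scenario, psa_spec(n_iterations = 2000, seed = 8L))
  cv <- ceac(d, wtp_grid = c(0, 2e4, 5e4, 1e5, 144000, 3e5, 1e6, 1e12))
  expect_true(all(cv$probability >= 0 & cv$probability <= 1))
  expect_true(all(diff(cv$probability) >= 0))
  # at wtp = 0 only negative-cost draws count: none
  expect_equal(cv$probability[1L], 0)
  # asymptote: the fraction of draws with positive total QALYs
  expect_equal(cv$probability[nrow(cv)], mean(d$total_qalys > 0))
  # degenerate draws reach exactly 1 at large wtp
  d0 <- run_psa(scenario, psa_spec(n_iterations = 10, sd_frac = 0))
  cv0 <- ceac(d0, wtp_grid = c(0, 1e6))
  expect_equal(cv0$probability[2L], 1)
})

test_that("enforced ordering removes treated > untreated draws reproducibly", {
  spec <- psa_spec(n_iterations = 1000, seed = 13L, enforce_ordering = TRUE)
  d <- run_psa(scenario, spec)
  expect_true(all(d$p_blind_treated <= d$p_blind_untreated))
  expect_gte(attr(d, "n_resampled"), 0)
  d2 <- run_psa(scenario, spec)
  expect_identical(as.data.frame(d), as.data.frame(d2))
})

test_that("prob_cost_effective reports a binomial Monte-Carlo standard error", {
  d <- run_psa(scenario, psa_spec(n_iterations = 1000, seed = 21L))
  p <- prob_cost_effective(d, wtp = 144000)
  expect_equal(p$n, 1000L)
  expect_equal(p$se, sqrt(p$probability * (1 - p$probability) / 1000))
  expect_gt(p$probability, 0.5)
})
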