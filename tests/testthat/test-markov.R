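params <- model_params()

test_that("transition rows reproduce hand-computed compositions", {
  lt <- constant_life_table(0.02)

  # death first, progression among survivors (untreated, qx = 0.02)
  r <- transition_row(params, lt, 59, "stdr", treated = FALSE)
  expect_equal(r[["dead"]], 0.038)
  expect_equal(r[["blind"]], 0.09 * 0.962)
  expect_equal(r[["stdr"]], 1 - 0.038 - 0.08658)
  expect_equal(sum(r), 1)

  # blind state: stay or die only
  rb <- transition_row(params, lt, 59, "blind")
  expect_equal(rb[["dead"]], 2.34 * 0.02)
  expect_equal(rb[["stdr"]], 0)
  expect_equal(rb[["blind"]], 1 - 0.0468)

  # zero mortality: treated row is the pure 2% progression split
  lt0 <- constant_life_table(0)
  r0 <- transition_row(params, lt0, 59, "stdr", treated = TRUE)
  expect_equal(unname(r0), c(0.98, 0.02, 0))

  expect_error(transition_row(params, lt, 30, "stdr"), "outside life-table range")
})

test_that("every transition row sums to 1 within 1e-12 across ages, states and arms", {
  lt <- synth_life_table()
  for (age in seq(20, 100, by = 5)) {
    for (state in c("stdr", "blind")) {
      for (treated in c(TRUE, FALSE)) {
        r <- transition_row(params, lt, age, state, treated)
        expect_true(all(r >= 0) && all(r <= 1))
        expect_lt(abs(sum(r) - 1), 1e-12)
      }
    }
  }
})

test_that("cohort trace conserves occupancy and dead is absorbing and non-decreasing", {
  tr <- run_cohort(params, synth_life_table(), treated = FALSE)
  expect_equal(unname(tr[1L, ]), c(1, 0, 0))
  expect_true(all(abs(rowSums(tr) - 1) < 1e-10))
  expect_true(all(diff(tr[, "occ_dead"]) >= 0))
  expect_true(all(tr >= 0 & tr <= 1))
})

test_that("degenerate cohorts behave as closed forms dictate", {
  # certain death: everyone dead at cycle 1
  lt1 <- constant_life_table(1, horizon = 5)
  tr1 <- run_cohort(params, lt1)
  expect_equal(unname(tr1[2L, ]), c(0, 0, 1))
  expect_equal(life_expectancy(tr1), 0)

  # no flow at all: 100% STDR forever
  p0 <- model_params(p_blind_untreated = 0, p_blind_treated = 0)
  lt0 <- constant_life_table(0, horizon = 20)
  tr0 <- run_cohort(p0, lt0)
  expect_equal(tr0[, "occ_stdr"], rep(1, 21))

  # constant qx = 0.1, no progression, rr = 1: alive fraction is 0.9^t
  pg <- model_params(p_blind_untreated = 0, rr_diabetes = 1, rr_blind = 1)
  ltg <- constant_life_table(0.1, horizon = 30)
  trg <- run_cohort(pg, ltg)
  expect_equal(trg[, "occ_stdr"], 0.9^(0:30))
  expect_equal(life_expectancy(trg), sum(0.9^(1:30)))
})

test_that("life expectancy and QALYs respond to treatment and discounting as they must", {
  lt <- synth_life_table()
  fit <- stdr_markov(params, lt)
  expect_gt(fit$le_treated, fit$le_untreated)
  expect_gt(fit$qaly_gain_stdr, 0)
  expect_gt(fit$qaly_gain_cataract, 0)

  # discounting shrinks the sum; rate 0 with unit utilities reduces to LE
  p1 <- model_params(u_stdr = 1, u_blind = 1, discount_rate = 0)
  tr <- run_cohort(p1, lt)
  expect_equal(discounted_qalys(tr, p1), life_expectancy(tr))
  for (r in c(0.01, 0.03, 0.06)) {
    pr <- model_params(discount_rate = r)
    expect_lt(discounted_qalys(tr, pr), discounted_qalys(tr, model_params(discount_rate = 0)))
  }

  # single discounted cycle: utilities 1, no mortality, horizon 1
  ph <- model_params(u_stdr = 1, u_blind = 1, horizon = 1)
  trh <- run_cohort(ph, constant_life_table(0, horizon = 10))
  expect_equal(discounted_qalys(trh, ph), 1 / 1.03)
})

test_that("discounted QALYs are monotone non-increasing in the discount rate", {
  lt <- synth_life_table()
  tr <- run_cohort(params, lt)
  rates <- c(0, 0.01, 0.03, 0.05, 0.10)
  q <- vapply(rates, function(r) discounted_qalys(tr, model_params(discount_rate = r)),
              numeric(1))
  expect_true(all(diff(q) < 0))
})

test_that("treatment gain is zero when rates coincide and monotone in the treated rate", {
  lt <- synth_life_table()
  p_eq <- model_params(p_blind_treated = 0.09)
  expect_equal(stdr_qaly_gain(p_eq, lt), 0)

  gains <- vapply(c(0.01, 0.02, 0.05, 0.08), function(pt) {
    stdr_qaly_gain(model_params(p_blind_treated = pt), lt)
  }, numeric(1))
  expect_true(all(diff(gains) < 0))  # non-increasing in p_blind_treated
  expect_true(all(gains > 0))
})

test_that("cataract gain obeys its closed forms", {
  lt <- synth_life_table()
  expect_equal(cataract_qaly_gain(model_params(u_gain_cataract = 0), lt), 0)

  # no mortality, no discount, no decline, horizon 10: 0.2 * 10
  p <- model_params(discount_rate = 0, hrqol_decline = 0, horizon = 10)
  expect_equal(cataract_qaly_gain(p, constant_life_table(0, horizon = 20)), 2)
})

test_that("discounted QALYs match the fundamental-matrix closed form to 1e-9", {
  q <- 0.1
  H <- 301
  lt <- life_table(59:(59 + H), c(rep(q, H), 1))
  tr <- run_cohort(params, lt, treated = FALSE)
  expect_equal(discounted_qalys(tr, params), oracle_fundamental_qalys(q, params, H),
               tolerance = 1e-9)
})

test_that("cohort trace matches a seeded 1e5-individual microsimulation within 3 MC SE", {
  lt <- synth_life_table()
  n <- 1e5
  for (treated in c(FALSE, TRUE)) {
    tr <- run_cohort(params, lt, treated = treated)
    sim <- oracle_microsim(params, lt, n = n, seed = 42L, treated = treated)
    p <- unclass(tr)
    se <- sqrt(p * (1 - p) / n)
    expect_true(all(abs(sim - p) <= 3 * se + 1e-9))
  }
})

test_that("microsimulation oracle and simulate() method agree in distribution", {
  lt <- synth_life_table()
  fit <- stdr_markov(params, lt)
  states <- simulate(fit, nsim = 20000, seed = 7L, treated = FALSE)
  mid <- 11L  # cycle 10
  prop_dead <- mean(states[, mid] == 3L)
  expect_lt(abs(prop_dead - fit$trace_untreated[mid, "occ_dead"]),
            3 * sqrt(0.25 / 20000) + 0.01)
})

test_that("trace exports cycle, age and occupancies", {
  tr <- run_cohort(params, synth_life_table())
  df <- trace_as_df(tr)
  expect_named(df, c("cycle", "age", "occ_stdr", "occ_blind", "occ_dead"))
  expect_equal(df$age, 59:105)
  expect_equal(df$cycle, 0:46)
})

test_that("half-cycle correction lies between adjacent full-cycle conventions", {
  lt <- synth_life_table()
  le_end <- life_expectancy(run_cohort(params, lt))
  ph <- model_params(half_cycle = TRUE)
  le_half <- life_expectancy(run_cohort(ph, lt))
  expect_gt(le_half, le_end)
  expect_lt(le_half, le_end + 1)
})
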