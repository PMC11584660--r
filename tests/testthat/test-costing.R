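uc <- unit_costs()
counts <- cascade_counts()

test_that("annuitization follows the closed-form annuity factor", {
  # 16 cameras at 300,000, 5 years, 3%: factor 0.03/(1 - 1.03^-5)
  a <- annuitize(4800000, 5, 0.03)
  expect_equal(a, 4800000 * 0.03 / (1 - 1.03^(-5)))
  expect_equal(round_inr(a, 100), 1048100)
  expect_equal(annuitize(4800000, 5, 0), 960000)  # zero-rate limit
  expect_equal(annuitize(0, 5, 0.03), 0)
  expect_error(annuitize(100, 0.5), "lifetime")
  expect_error(annuitize(-1, 5), "capital")
})

test_that("screening cost per patient decomposes as cameras + training + staff + admin + ASHA", {
  spp <- screening_cost_per_patient(uc, 5307)
  expect_equal(uc$training_total / 5307, 105.52, tolerance = 1e-4)
  cameras_pp <- annuitize(16 * 300000, 5, 0.03) / 5307
  expect_equal(spp, cameras_pp + 560000 / 5307 + 70 + 15 + 15)
  expect_equal(round_inr(spp, 100), 400)  # the reported figure

  uc0 <- unit_costs(camera_price = 0, training_total = 0,
                    staff_cost_per_screen = 0, admin_per_screen = 0,
                    asha_per_screen = 0)
  expect_equal(screening_cost_per_patient(uc0, 5307), 0)
  expect_error(screening_cost_per_patient(uc, 0), "positive")
})

test_that("examination cost per patient is 1155 with a 205 health-system core", {
  expect_equal(examination_cost_per_patient(uc), 1155)
  uc_hs <- unit_costs(travel_patient = 0, travel_attendant = 0,
                      opp_cost_patient = 0, opp_cost_attendant = 0)
  expect_equal(examination_cost_per_patient(uc_hs), 205)
  uc0 <- unit_costs(exam_staff_admin = 0, travel_patient = 0, travel_attendant = 0,
                    opp_cost_patient = 0, opp_cost_attendant = 0)
  expect_equal(examination_cost_per_patient(uc0), 0)
})

test_that("treatment costs reproduce the per-patient packages and the bilateral scenario", {
  tc <- treatment_costs(uc, counts)
  expect_equal(tc$laser_total, 345 * 14850)     # 5,123,250
  expect_equal(tc$cataract_total, 160 * 18950)  # 3,032,000

  tc_bi <- treatment_costs(uc, cascade_counts(bilateral_fraction = 0.20))
  expect_equal(tc_bi$laser_total, 345 * 14850 + 0.2 * 345 * 12000)  # ~5.95M
  expect_equal(round(tc_bi$laser_total / 1e6, 1), 6.0)
})

test_that("ledger totals equal line sums exactly and decompose by stage and payer", {
  led <- build_cost_ledger(uc, counts)
  tot <- cost_totals(led)
  df <- as.data.frame(led)

  for (stage in c("screening", "examination", "laser", "cataract")) {
    expect_equal(tot[[paste0(stage, "_total")]],
                 sum(df$amount_inr[df$stage == stage]))
  }
  expect_equal(tot$pathway_total, tot$screening_total + tot$examination_total)
  expect_equal(tot$programme_total,
               tot$pathway_total + tot$laser_total + tot$cataract_total)
  expect_equal(tot$programme_total, sum(df$amount_inr))
  # societal + health-system partition the full economic cost
  expect_equal(tot$societal_total + tot$health_system_total, tot$programme_total)
  expect_equal(tot$societal_total, 950 * 830 + 3 * 950 * 345 + 950 * 160)
})

test_that("programme total is monotone non-decreasing in unit costs and counts", {
  base <- cost_totals(build_cost_ledger(uc, counts))$programme_total
  for (field in c("laser_package", "cataract_surgery", "training_total",
                  "admin_per_screen", "attendance_societal")) {
    uc2 <- uc
    uc2[[field]] <- uc2[[field]] * 1.5
    expect_gte(cost_totals(build_cost_ledger(uc2, counts))$programme_total, base)
  }
  for (field in c("n_screened", "n_examined", "n_stdr_treated", "n_cataract_treated")) {
    cc2 <- counts
    cc2[[field]] <- cc2[[field]] + 100
    expect_gte(cost_totals(build_cost_ledger(uc, cc2))$programme_total, base)
  }
})

test_that("all-zero unit costs give an all-zero ledger", {
  uc0 <- unit_costs(camera_price = 0, training_total = 0, staff_cost_per_screen = 0,
                    admin_per_screen = 0, asha_per_screen = 0, exam_staff_admin = 0,
                    travel_patient = 0, travel_attendant = 0, opp_cost_patient = 0,
                    opp_cost_attendant = 0, laser_package = 0,
                    attendance_societal = 0, cataract_surgery = 0)
  tot <- cost_totals(build_cost_ledger(uc0, counts))
  expect_equal(tot$programme_total, 0)
  expect_equal(tot$cost_per_person_treated, 0)
})

test_that("rate-derived cascade counts use round-half-even and explicit counts override", {
  expect_message(
    cc <- cascade_from_rates(5307, referral_rate = 0.313, attendance_rate = 0.5,
                             stdr_diagnosed = 493, treat_rate_stdr = 0.7,
                             ungradable = 800, cataract_rate = 0.2,
                             override = list(n_referred = 1662, n_examined = 830)),
    "overridden")
  expect_equal(cc$n_referred, 1662)   # computed 1661, overridden
  expect_equal(cc$n_examined, 830)
  expect_equal(cc$n_stdr_treated, 345)
  expect_equal(cc$n_cataract_treated, 160)

  cc0 <- cascade_from_rates(5307, 0, 0, 0, 0, 0, 0)
  expect_equal(cc0$n_referred, 0)
  expect_equal(cc0$n_cataract_treated, 0)

  expect_error(cascade_from_rates(100, 1.2, 0.5, 0, 0, 0, 0), "outside \\[0, 1\\]")
})

test_that("cascade counts enforce ordering and bounds", {
  expect_error(cascade_counts(n_screened = 100, n_referred = 200), "ordering")
  expect_error(cascade_counts(bilateral_fraction = 1.5), "bilateral_fraction")
})

test_that("ledger CSV export round-trips the lines", {
  led <- build_cost_ledger(uc, counts)
  f <- withr::local_tempfile(fileext = ".csv")
  write_cost_ledger(led, f)
  back <- utils::read.csv(f)
  expect_equal(nrow(back), nrow(led))
  expect_equal(sum(back$amount_inr), cost_totals(led)$programme_total)
})
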