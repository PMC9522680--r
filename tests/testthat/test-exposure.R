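test_that("source rates follow the consumption and sidestream arithmetic", {
  reg <- default_constituents()
  car <- default_scenarios("evp")$car_closed
  expect_equal(source_rate(reg$nicotine, car), 2 * (902 / 16) * 4.22)
  cig <- default_scenarios("cigarette")$car_closed
  expect_equal(source_rate(reg$nicotine, cig), 2 * 1 * 5600)
  expect_equal(source_rate(reg$acetaldehyde, car), 0)     # below MDL
  expect_true(is.na(source_rate(reg$propylene_glycol, cig)))  # no sidestream
})

test_that("intake is concentration x duration x minute ventilation", {
  expect_equal(minute_ventilation(), 0.36)
  expect_equal(intake(500, 8), 1440)
  expect_equal(intake(0, 5), 0)
  expect_equal(intake(10, 1), 3.6)
  expect_error(intake(-1, 1), ">= 0")
})

test_that("limit reference intakes and missing limits behave", {
  expect_equal(limit_reference_intake(250)$intake, 720)
  expect_equal(limit_reference_intake(920)$intake_full, 2649.6)
  miss <- limit_reference_intake(NA)
  expect_equal(miss$status, "NA")
  expect_true(is.na(miss$intake))
})

test_that("scenario intakes are proportional to emission factors", {
  res <- run_scenario(default_scenarios("evp")$meeting_room)
  reg <- default_constituents()
  nic <- res$intake_ug[res$constituent == "nicotine"]
  for (nm in c("propylene_glycol", "glycerin", "formaldehyde")) {
    got <- res$intake_ug[res$constituent == nm] / nic
    want <- reg[[nm]]$emission_factor / reg$nicotine$emission_factor
    expect_equal(got, want, tolerance = 1e-9)
  }
})

test_that("statuses propagate through a scenario run", {
  evp <- run_scenario(default_scenarios("evp")$car_open)
  expect_equal(evp$status[evp$constituent == "acetaldehyde"], "BELOW_MDL")
  expect_equal(evp$intake_ug[evp$constituent == "acrolein"], 0)
  cig <- run_scenario(default_scenarios("cigarette")$car_open)
  expect_equal(cig$status[cig$constituent == "glycerin"], "NA")
  expect_true(is.na(cig$intake_ug[cig$constituent == "propylene_glycol"]))
  expect_equal(cig$status[cig$constituent == "acetaldehyde"], "computed")
})

test_that("a space with no users accumulates nothing", {
  sc <- scenario("empty", 50, 2, 1, n_users = 0, n_occupants = 5, "evp")
  res <- run_scenario(sc)
  expect_true(all(res$intake_ug == 0))
})

test_that("doubling the duration in the steady-state regime doubles intake", {
  reg <- default_constituents()["nicotine"]
  s1 <- scenario("s1", 3, 30, 1, 2, 4, "evp")
  s2 <- scenario("s2", 3, 30, 2, 2, 4, "evp")
  i1 <- run_scenario(s1, reg)$intake_ug
  i2 <- run_scenario(s2, reg)$intake_ug
  expect_equal(i2 / i1, 2, tolerance = 0.02)
})

test_that("fold difference reduces to the per-user source-rate ratio", {
  expect_equal(fold_difference(10, 10), 1)
  expect_equal(fold_difference(5, 0), Inf)
  expect_error(fold_difference(NA, 1), "both values")
  reg <- default_constituents()
  want <- source_fold_difference(reg$nicotine)
  # invariant to the scenario: compute from intakes in two different spaces
  for (nm in c("car_closed", "restaurant")) {
    evp <- run_scenario(default_scenarios("evp")[[nm]])
    cig <- run_scenario(default_scenarios("cigarette")[[nm]])
    got <- fold_difference(cig$intake_ug[cig$constituent == "nicotine"],
                           evp$intake_ug[evp$constituent == "nicotine"])
    expect_equal(got, want, tolerance = 1e-9)
  }
})

test_that("ach calibration inverts a forward simulation", {
  reg <- default_constituents()
  sc <- scenario("cal", 40, ach = 3, duration = 2, n_users = 2, 4, "evp")
  rate <- source_rate(reg$nicotine, sc)
  avg <- average_concentration(
    simulate_box(sc$volume, sc$ach, continuous_source(rate), sc$duration))
  expect_equal(calibrate_ach(sc, reg$nicotine, avg), 3, tolerance = 1e-4)
  # steady-state regime: recovered rate approximates S/(target V)
  sc2 <- scenario("cal2", 3, ach = 40, duration = 2, n_users = 2, 4, "evp")
  rate2 <- source_rate(reg$nicotine, sc2)
  target <- rate2 / (40 * sc2$volume)
  expect_equal(calibrate_ach(sc2, reg$nicotine, target), 40, tolerance = 0.02 * 40)
  # infeasible target: above the zero-ventilation average
  too_high <- rate * sc$duration / (2 * sc$volume) * 1.01
  expect_error(calibrate_ach(sc, reg$nicotine, too_high), "unreachable")
})

test_that("every default EVP intake sits far below its reference limit", {
  for (sc in default_scenarios("evp")) {
    res <- run_scenario(sc)
    ok <- !is.na(res$limit_intake_ug) & res$status == "computed"
    expect_true(all(res$intake_ug[ok] <= res$limit_intake_ug[ok] / 100))
  }
})

test_that("scenario validation enforces the physical invariants", {
  expect_error(scenario("x", -1, 1, 1, 1, 2, "evp"), "volume")
  expect_error(scenario("x", 1, -1, 1, 1, 2, "evp"), "ach")
  expect_error(scenario("x", 1, 1, 0, 1, 2, "evp"), "duration")
  expect_error(scenario("x", 1, 1, 1, 3, 2, "evp"), "n_users")
  expect_error(constituent("x", -1), ">= 0")
  expect_error(constituent("x", 1, below_mdl = TRUE), "below-MDL")
})
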