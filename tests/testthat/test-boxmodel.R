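test_that("pure ventilation decay matches the closed form", {
  tr <- simulate_box(10, ach = 1, continuous_source(0), duration = 2,
                     initial_concentration = 10, timestep = 0.001)
  expect_equal(tr$concentration[nrow(tr)], 10 * exp(-2), tolerance = 1e-9)
  expect_equal(tr$concentration, 10 * exp(-tr$time), tolerance = 1e-9)
})

test_that("constant-source trajectory matches the closed form everywhere", {
  v <- 30; lam <- 2.5; s <- 120
  tr <- simulate_box(v, lam, continuous_source(s), duration = 3)
  closed <- s / (lam * v) * (1 - exp(-lam * tr$time))
  rel <- abs(tr$concentration[-1] - closed[-1]) / closed[-1]
  expect_lt(max(rel), 1e-6)
})

test_that("zero ventilation accumulates linearly", {
  tr <- simulate_box(5, 0, continuous_source(50), duration = 2)
  expect_equal(tr$concentration, 50 * tr$time / 5, tolerance = 1e-12)
})

test_that("time averaging is exact for constants and trapezoid-exact ramps", {
  flat <- data.frame(time = seq(0, 4, 0.01), concentration = 7)
  expect_equal(average_concentration(flat), 7)
  expect_equal(average_concentration(flat, c(1, 2.5)), 7)
  ramp <- data.frame(time = seq(0, 2, 0.01))
  ramp$concentration <- 5 * ramp$time / 2
  expect_equal(average_concentration(ramp), 2.5)
  expect_error(average_concentration(flat, c(2, 2)), "increasing")
  expect_error(average_concentration(flat, c(0, 9)), "outside")
})

test_that("average of a decay curve matches its closed form", {
  lam <- 1
  tr <- simulate_box(10, lam, continuous_source(0), duration = 2,
                     initial_concentration = 10, timestep = 0.001)
  expect_equal(average_concentration(tr), 10 * (1 - exp(-2)) / 2,
               tolerance = 1e-6)
})

test_that("mass balance closes for continuous and puff sources", {
  tr1 <- simulate_box(20, 3, continuous_source(200), duration = 2)
  expect_lt(mass_balance_residual(tr1), 1e-3)
  times <- seq(1 / 240, 1 - 1 / 240, by = 1 / 120)   # 30-s puff spacing
  tr2 <- simulate_box(20, 10, puff_source(5, times), duration = 1,
                      timestep = 1 / 3600)
  expect_lt(mass_balance_residual(tr2), 1e-3)
})

test_that("the box model is linear in the source rate", {
  tr1 <- simulate_box(20, 4, continuous_source(100), duration = 1)
  tr2 <- simulate_box(20, 4, continuous_source(200), duration = 1)
  expect_equal(tr2$concentration, 2 * tr1$concentration, tolerance = 1e-12)
})

test_that("average concentration decreases with ventilation and hits the steady state", {
  avgs <- vapply(c(0.5, 1, 2, 4, 8), function(l)
    average_concentration(simulate_box(30, l, continuous_source(90),
                                       duration = 2)), 0)
  expect_true(all(diff(avgs) < 0))
  # ach * T >> 1: average -> S / (ach V)
  tr <- simulate_box(3, 40, continuous_source(500), duration = 2)
  expect_equal(average_concentration(tr), 500 / (40 * 3), tolerance = 0.02)
})

test_that("puff and continuous sources converge to the same average", {
  v <- 25; lam <- 30; dur <- 1; total <- 600
  cont <- simulate_box(v, lam, continuous_source(total / dur), dur,
                       timestep = 1 / 7200)
  n <- 120  # one puff every 30 s, centered in each interval
  times <- (seq_len(n) - 0.5) / n * dur
  puff <- simulate_box(v, lam, puff_source(total / n, times), dur,
                       timestep = 1 / 7200)
  a1 <- average_concentration(cont)
  a2 <- average_concentration(puff)
  expect_lt(abs(a1 - a2) / a1, 0.01)
})

test_that("equilibrium partitioning splits at the saturation concentration", {
  expect_equal(partition_equilibrium(100, NA), list(vapor = 100, particle = 0))
  expect_equal(partition_equilibrium(100, 30), list(vapor = 30, particle = 70))
  expect_equal(partition_equilibrium(20, 30), list(vapor = 20, particle = 0))
  expect_error(partition_equilibrium(-1, 30), ">= 0")
  expect_error(partition_equilibrium(1, -30), ">= 0")
  # phases always sum to the total along a trajectory
  tr <- simulate_box(10, 2, continuous_source(300), duration = 1)
  st <- air_state(tr, saturation = 5)
  expect_equal(st$vapor + st$particle, st$concentration)
  expect_true(all(st$vapor >= 0 & st$particle >= 0 & st$vapor <= 5 + 1e-12))
})

test_that("invalid box-model inputs are rejected", {
  src <- continuous_source(10)
  expect_error(simulate_box(-1, 1, src, 1), "volume")
  expect_error(simulate_box(1, -1, src, 1), "ach")
  expect_error(simulate_box(1, 1, src, 1, timestep = 0.5), "timestep")
  expect_error(continuous_source(-5), ">= 0")
  expect_error(puff_source(1, c(0.2, 0.1)), "increasing")
  expect_error(simulate_box(1, 1, puff_source(1, c(0.100, 0.1001)), 1,
                            timestep = 0.005), "too coarse")
})
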