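test_that("all releasable reporter starts in the ER", {
  tc <- simulate_trafficking(kinetic_params(), times = 0)
  expect_equal(tc$er, 1)
  expect_equal(tc$apical + tc$basolateral + tc$cilium, 0)
})

test_that("a pre-release surface leak is split by the sorting fraction", {
  p <- kinetic_params(leak_fraction = 0.1, phi_bl = 0.62)
  tc <- simulate_trafficking(p, times = 0)
  expect_equal(tc$er, 0.9)
  expect_equal(tc$basolateral, 0.1 * 0.62)
  expect_equal(tc$apical, 0.1 * 0.38)
})

test_that("mass is conserved across random parameter sets", {
  set.seed(101)
  for (i in 1:8) {
    p <- kinetic_params(k_release = runif(1, 0.5, 4),
                        phi_bl = runif(1, 0.1, 0.9),
                        k_transcytosis = runif(1, 0, 2),
                        k_ciliary = runif(1, 0, 2),
                        cilium_capacity = runif(1, 0.01, 0.3),
                        leak_fraction = runif(1, 0, 0.2))
    tc <- simulate_trafficking(p, times = seq(0, 2, by = 0.1))
    total <- tc$er + tc$apical + tc$basolateral + tc$cilium
    expect_true(all(abs(total - 1) < 1e-9))
    # ciliary pool: monotone non-decreasing, never above capacity
    expect_true(all(diff(tc$cilium) > -1e-12))
    expect_true(all(tc$cilium <= p$cilium_capacity + 1e-9))
  }
})

test_that("ER and basolateral pools match the closed-form solution", {
  p <- kinetic_params(k_release = 2, phi_bl = 0.62, k_transcytosis = 0.5,
                      k_ciliary = 0.3)
  t <- c(0.25, 0.5, 1, 1.5, 2)
  tc <- simulate_trafficking(p, times = t)
  expect_equal(tc$er, oracle_er(t, 2), tolerance = 1e-9)
  expect_equal(tc$basolateral, oracle_bl(t, 2, 0.62, 0.5), tolerance = 1e-9)
})

test_that("a pure 2:1 sorting split yields a 2-fold basolateral excess", {
  p <- kinetic_params(phi_bl = 2 / 3, k_transcytosis = 0, k_ciliary = 0)
  tc <- simulate_trafficking(p, times = c(1, 10))
  expect_equal(tc$basolateral / tc$apical, c(2, 2), tolerance = 1e-9)
})

test_that("with transcytosis the basolateral pool peaks before the apical pool", {
  grid <- seq(0, 2, by = 0.01)
  tc <- simulate_trafficking(kinetic_params(), times = grid)
  t_bl <- grid[which.max(tc$basolateral)]
  t_ap <- grid[which.max(tc$apical + tc$cilium)]
  expect_lt(t_bl, t_ap)
  # basolateral peak lands at ~1 h, as calibrated
  expect_equal(t_bl, 0.92, tolerance = 0.02)
  # cross-check the trajectory against an adaptive high-accuracy integrator
  ode_fun <- function(t, y, p) ciliarrival:::traffic_rhs(t, y, p)
  ref <- deSolve::ode(c(er = 1, apical = 0, basolateral = 0, cilium = 0),
                      times = grid, func = ode_fun, parms = kinetic_params(),
                      method = "lsoda", rtol = 1e-10, atol = 1e-12)
  expect_equal(tc$cilium, unname(ref[, "cilium"]), tolerance = 1e-6)
})

test_that("the calibrated ciliary pool saturates near 5 % by 1.5 h", {
  tc <- simulate_trafficking(kinetic_params(), times = c(1, 1.5, 2))
  expect_gt(tc$cilium[2], 0.045)
  expect_lte(tc$cilium[3], 0.05)
})

test_that("invalid kinetic parameters are rejected", {
  expect_error(kinetic_params(k_release = -1), "non-negative")
  expect_error(kinetic_params(phi_bl = 1.2), "\\[0, 1\\]")
  expect_error(simulate_trafficking(kinetic_params(), times = c(1, 0.5)),
               "sorted")
  expect_error(compartment_state(fractions = c(er = 0.5, apical = 0.5,
                                               basolateral = 0.5,
                                               cilium = 0)),
               "sum to 1")
})
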