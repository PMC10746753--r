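test_that("single-dose concentration follows the closed form", {
  pk <- fix_pk()
  expect_equal(conc_single_dose(0, 100, pk), 0)
  ke <- ke_elim(pk)
  tmax <- log(pk$ka / ke) / (pk$ka - ke)
  cmax <- conc_single_dose(tmax, 100, pk)
  expect_equal(cmax, 6.93e4, tolerance = 0.01)
  # tmax is a maximum
  expect_lt(conc_single_dose(tmax - 0.1, 100, pk), cmax)
  expect_lt(conc_single_dose(tmax + 0.1, 100, pk), cmax)
  expect_error(conc_single_dose(-1, 100, pk), "non-negative")
})

test_that("absorption-elimination degeneracy uses the analytic limit", {
  # ka == ke exactly: finite and equal to D ka t exp(-ka t)/V * 1000
  pk_eq <- pk_params(ka = 0.5, cl_f = 0.5, v_f = 1)
  tt <- c(0.5, 1, 4, 12)
  expect_equal(conc_single_dose(tt, 10, pk_eq),
               1000 * 10 * 0.5 * tt * exp(-0.5 * tt) / 1,
               tolerance = 1e-10)
  # continuous with the generic branch nearby
  pk_near <- pk_params(ka = 0.5 + 1e-6, cl_f = 0.5, v_f = 1)
  expect_equal(conc_single_dose(tt, 10, pk_near),
               conc_single_dose(tt, 10, pk_eq), tolerance = 1e-4)
})

test_that("superposition is linear and reduces to a single dose", {
  pk <- fix_pk()
  reg1 <- dose_regimen(25)
  tt <- seq(0, 48, by = 0.5)
  expect_equal(conc_regimen(tt, reg1, pk), conc_single_dose(tt, 25, pk))
  reg4 <- dose_regimen(25, 24, 4)
  expect_equal(conc_regimen(tt, dose_regimen(50, 24, 4), pk),
               2 * conc_regimen(tt, reg4, pk), tolerance = 1e-12)
  # before the second dose the profiles coincide
  early <- tt[tt < 24]
  expect_equal(conc_regimen(early, reg4, pk),
               conc_single_dose(early, 25, pk))
})

test_that("steady-state trough matches the closed-form accumulation", {
  set.seed(7)
  for (i in 1:5) {
    pk <- pk_params(ka = runif(1, 0.3, 3), cl_f = runif(1, 0.1, 1),
                    v_f = runif(1, 0.5, 2))
    dose <- runif(1, 5, 50); tau <- sample(c(12, 24), 1)
    # superposition after many doses vs geometric-series closed form
    n <- 200
    t_trough <- n * tau
    sim <- conc_regimen(t_trough, dose_regimen(dose, tau, n), pk)
    expect_equal(sim, ctrough_closed_form(dose, tau, pk),
                 tolerance = 5e-3)
  }
  # interval to infinity: trough vanishes
  expect_lt(ctrough_closed_form(25, 1000, fix_pk()), 1e-6)
  # linear in dose
  expect_equal(ctrough_closed_form(50, 12, fix_pk()),
               2 * ctrough_closed_form(25, 12, fix_pk()))
})

test_that("analytic effect-site concentration agrees with the ODE route", {
  set.seed(11)
  for (i in 1:4) {
    pk <- pk_params(ka = runif(1, 0.5, 3), cl_f = runif(1, 0.2, 0.8),
                    v_f = runif(1, 0.5, 2))
    pd <- pd_params(ke0 = runif(1, 0.03, 0.5), kin = 29.1, kout = 1.45,
                    imax = 0.91, ic50 = 340)
    reg <- dose_regimen(25, 24, 3)
    sa <- simulate_pkpd(reg, pk, pd, t_end = 96, dt = 0.5, ce = "analytic")
    so <- simulate_pkpd(reg, pk, pd, t_end = 96, dt = 0.5, ce = "ode")
    rel <- abs(sa$ce - so$ce) / pmax(so$ce, max(so$ce) * 1e-3)
    expect_lt(max(rel), 1e-3)
  }
})

test_that("biomarker trajectory respects the turnover bounds", {
  pk <- fix_pk(); pd <- fix_pd()
  base <- pd_baseline(pd); ceil <- pd_ceiling(pd)
  for (dose in c(5, 25, 100)) {
    sim <- simulate_pkpd(dose_regimen(dose, 12, 8), pk, pd, t_end = 200,
                         dt = 0.5)
    expect_gte(min(sim$effect), base * (1 - 1e-6))
    expect_lte(max(sim$effect), ceil * (1 + 1e-6))
  }
  # no dose effect without inhibition capacity
  pd0 <- pd_params(pd$ke0, pd$kin, pd$kout, imax = 0, ic50 = pd$ic50)
  sim0 <- simulate_pkpd(dose_regimen(100, 12, 8), pk, pd0, t_end = 100)
  expect_equal(range(sim0$effect), c(base, base), tolerance = 1e-6)
  # zero-exposure limit: constant baseline 29.1/1.45 = 20.07
  sim_lo <- simulate_pkpd(dose_regimen(1e-9), pk, pd, t_end = 48)
  expect_equal(mean(sim_lo$effect), 20.07, tolerance = 1e-3)
})

test_that("saturating exposure drives the biomarker to its ceiling", {
  pd <- fix_pd()
  # slow elimination keeps Ce far above IC50 throughout
  pk_slow <- pk_params(ka = 2.7, cl_f = 0.001, v_f = 1)
  sim <- simulate_pkpd(dose_regimen(1000, 24, 60), pk_slow, pd,
                       t_end = 1440, dt = 1)
  expect_equal(utils::tail(sim$effect, 1), pd_ceiling(pd), tolerance = 0.02)
  expect_equal(pd_ceiling(pd), 223, tolerance = 0.01)
})

test_that("steady-state metrics converge and order correctly", {
  pk <- fix_pk(); pd <- fix_pd()
  m <- steady_state_metrics(25, 12, pk, pd)
  expect_true(m$converged)
  expect_true(m$c_trough <= m$c_avg && m$c_avg <= m$c_max)
  expect_true(m$e_min <= m$e_max)
  expect_equal(m$c_trough, ctrough_closed_form(25, 12, pk),
               tolerance = 5e-3)
  # monotonicity of the steady-state biomarker minimum in dose
  emins <- vapply(c(5, 10, 25, 50),
                  function(d) steady_state_metrics(d, 12, pk, pd)$e_min,
                  numeric(1))
  expect_true(all(diff(emins) > 0))
})
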