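test_that("PK fit recovers generating parameters from noise-free data", {
  s1 <- generate_study(design_pkpd01(), fix_pk(), fix_pd(), noise_cv = 0,
                       seed = 1)
  s2 <- generate_study(design_pkpd02(), fix_pk(), fix_pd(), noise_cv = 0,
                       seed = 2)
  conc <- rbind(s1$conc_obs, s2$conc_obs)
  fit <- fit_pk(conc, fixed = c(ka = 2.7))
  expect_equal(fit$estimates[["cl_f"]], 0.415, tolerance = 1e-3)
  expect_equal(fit$estimates[["v_f"]], 1.034, tolerance = 1e-3)
  expect_identical(fit$fixed, c(ka = 2.7))
  pk <- fitted_pk_params(fit)
  expect_s3_class(pk, "pk_params")
  expect_equal(pk$ka, 2.7)
})

test_that("PD fit recovers generating parameters from noise-free data", {
  s1 <- generate_study(design_pkpd01(), fix_pk(), fix_pd(), noise_cv = 0,
                       seed = 1)
  s2 <- generate_study(design_pkpd02(), fix_pk(), fix_pd(), noise_cv = 0,
                       seed = 2)
  pdo <- rbind(s1$pd_obs, s2$pd_obs)
  fit <- suppressWarnings(fit_pd(pdo, fix_pk()))
  truth <- c(ke0 = 0.0566, kin = 29.1, kout = 1.45, imax = 0.91,
             ic50 = 340)
  for (nm in names(truth))
    expect_equal(fit$estimates[[nm]], truth[[nm]], tolerance = 0.01,
                 label = nm)
  # optimiser objective is non-increasing along the trace (up to the
  # finite-difference noise floor of the recorded trial steps)
  trace_ok <- function(tr)
    all(diff(tr) <= pmax(1e-6 * utils::head(tr, -1), 1e-9))
  expect_true(trace_ok(fit$rss_trace))
  expect_lt(utils::tail(fit$rss_trace, 1), fit$rss_trace[1])
  expect_true(trace_ok(fit_pk(rbind(s1$conc_obs, s2$conc_obs))$rss_trace))
})

test_that("degenerate fitting inputs raise defined errors", {
  empty <- tiny_obs()[0, ]
  expect_error(fit_pk(empty), "3 distinct")
  expect_error(suppressMessages(fit_pd(tiny_obs()[1:2, ], fix_pk())), ">= 5")
})

test_that("baseline-only biomarker data leaves IC50 unidentified", {
  # all observations at baseline carry no information on IC50/Imax
  obs <- tiny_obs(values = rep(20.07, 12),
                  times = rep(c(24, 48, 72, 96), 3))
  obs$subject <- paste0("m", seq_len(nrow(obs)))
  obs$dose_mg_kg <- 1e-6
  expect_warning(fit <- fit_pd(obs, fix_pk(), n_starts = 2),
                 "poorly identified|bound")
  expect_true(any(fit$cv_percent[c("ic50", "imax")] > 100, na.rm = TRUE) ||
              any(!is.finite(fit$cv_percent[c("ic50", "imax")])))
})

test_that("holdout validation flags systematic mismatch only when present", {
  eff <- generate_study(design_eff01(doses = c(10, 25)), fix_pk(), fix_pd(),
                        noise_cv = 0.1, seed = 5)
  ok <- validate_holdout(fix_pk(), fix_pd(), eff$pd_obs)
  expect_equal(attr(ok, "median_fold_error"), 1, tolerance = 0.1)
  # tenfold IC50 shift: predictions biased high
  pd_shift <- pd_params(0.0566, 29.1, 1.45, 0.91, 34)
  bad <- validate_holdout(fix_pk(), pd_shift, eff$pd_obs)
  expect_gt(attr(bad, "median_fold_error"), 1.2)
  expect_warning(out <- validate_holdout(fix_pk(), fix_pd(),
                                         eff$pd_obs[0, ]), "empty")
  expect_equal(nrow(out), 0)
})

test_that("IC50 unit bridging matches the molar equivalences", {
  conv <- ic50_unit_conversion(340, fu = 0.032)
  expect_equal(round(conv$total_um, 2), 0.88)
  expect_equal(round(conv$free_nm), 28)
  # fu = 1: free (nM) equals total (uM) up to the unit factor
  conv1 <- ic50_unit_conversion(340, fu = 1)
  expect_equal(conv1$free_nm, conv1$total_um * 1000)
  # molar values halve when molar mass doubles
  conv2 <- ic50_unit_conversion(340, fu = 0.032, molar_mass = 2 * 386.4)
  expect_equal(conv2$total_um, conv$total_um / 2)
  expect_error(ic50_unit_conversion(-1, 0.5), "positive")
})
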