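test_that("regimen and parameter constructors enforce invariants", {
  expect_error(dose_regimen(-1), "positive")
  expect_error(dose_regimen(10, interval = 0, n_doses = 2), "interval")
  expect_silent(dose_regimen(10, interval = 0, n_doses = 1))
  expect_error(pk_params(ka = 0, cl_f = 1, v_f = 1), "positive")
  expect_error(pd_params(0.1, 29, 1.4, imax = 1.2, ic50 = 300), "imax")
  expect_error(pd_params(0.1, 29, -1, imax = 0.5, ic50 = 300), "positive")
  pd <- pd_params(0.0566, 29.1, 1.45, 0.91, 340)
  expect_equal(pd_baseline(pd), 29.1 / 1.45)
  expect_equal(pd_ceiling(pd), 29.1 / (1.45 * 0.09))
  expect_equal(pd_ceiling(pd_params(1, 1, 1, 1, 1)), Inf)
})

test_that("built-in species table matches the literal transcription", {
  tab <- species_records()
  mouse <- tab[tab$species == "mouse", ]
  expect_equal(mouse$body_weight, 0.029)
  expect_equal(mouse$cl_obs, 0.378)
  expect_equal(mouse$vss_obs, 0.37)
  expect_equal(mouse$f_obs, 0.38)
  expect_equal(mouse$fu_plasma, 0.032)
  human <- tab[tab$species == "human", ]
  expect_equal(human$fu_plasma, 0.018)
  expect_equal(human$bp_ratio, 0.58)
  expect_equal(human$clint_hep, 6.0)
  expect_equal(human$clint_mic, 12)
  expect_true(all(is.na(human[c("cl_obs", "vss_obs", "f_obs")])))
  # full columns against an independent transcription
  expect_equal(tab$body_weight[1:4], c(0.029, 0.270, 4.60, 8.36))
  expect_equal(tab$fu_plasma, c(0.032, 0.096, 0.044, 0.019, 0.018))
  expect_equal(tab$bp_ratio, c(0.71, 0.74, 0.73, 0.59, 0.58))
  expect_equal(tab$clint_hep, c(120, 30, 3.8, 3.6, 6.0))
  expect_equal(tab$clint_mic, c(60, 29, 19, 11, 12))
  expect_equal(tab$cl_obs[1:4], c(0.378, 0.350, 0.078, 0.034))
  expect_equal(tab$vss_obs[1:4], c(0.37, 1.30, 0.41, 0.23))
})

test_that("built-in mouse model parameters match the fitted estimates", {
  pk <- mouse_pk_params()
  expect_equal(c(pk$ka, pk$cl_f, pk$v_f), c(2.7, 0.415, 1.034))
  pd <- mouse_pd_params()
  expect_equal(c(pd$ke0, pd$kin, pd$kout, pd$imax, pd$ic50),
               c(0.0566, 29.1, 1.45, 0.91, 340))
})

test_that("observation IO round-trips values at full precision", {
  obs <- tiny_obs(values = c(123.456789012345, 0.000321, 9876.5))
  path <- withr::local_tempfile(fileext = ".csv")
  write_observations(obs, path)
  back <- read_observations(path, "conc")
  expect_equal(back$value, obs$value, tolerance = 1e-14)
  expect_equal(back$time_h, obs$time_h)
  expect_identical(attr(back, "kind"), "conc")
})

test_that("observation validation catches malformed tables", {
  obs <- tiny_obs()
  expect_error(validate_observations(obs[, -2], "conc"), "time_h")
  bad <- obs; bad$value[2] <- -1
  expect_error(validate_observations(bad, "conc"), "row")
  shuffled <- tiny_obs()[c(2, 1, 3), ]
  shuffled$subject <- "m1"
  expect_warning(out <- validate_observations(shuffled, "pd"), "re-sorting")
  expect_false(is.unsorted(out$time_h))
})
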