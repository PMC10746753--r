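test_that("log-log regression recovers exact power laws", {
  bw <- c(0.02, 0.25, 5, 10)
  fit <- fit_loglog(bw, 3 * bw^0.8)
  expect_equal(fit$coefficient, 3, tolerance = 1e-10)
  expect_equal(fit$exponent, 0.8, tolerance = 1e-10)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  # two points interpolate exactly
  fit2 <- fit_loglog(c(1, 10), c(2, 5))
  expect_equal(predict(fit2, 10), 5, tolerance = 1e-12)
  expect_equal(fit2$r_squared, 1)
  expect_error(fit_loglog(1, 1), ">= 2")
  expect_error(fit_loglog(c(1, 2), c(-1, 2)), "positive")
})

test_that("regression equals the brute-force normal-equations oracle", {
  tab <- species_records()
  an <- tab[tab$species != "human", ]
  y_sets <- list(
    an$cl_obs * an$body_weight,
    (an$cl_obs / an$fu_plasma) * (12 / an$clint_mic) * an$body_weight,
    (an$vss_obs / an$fu_plasma) * an$body_weight
  )
  for (y in y_sets) {
    fit <- fit_loglog(an$body_weight, y)
    oracle <- brute_force_loglog(an$body_weight, y)
    expect_equal(fit$coefficient, oracle$coefficient, tolerance = 1e-10)
    expect_equal(fit$exponent, oracle$exponent, tolerance = 1e-10)
    expect_equal(fit$r_squared, oracle$r_squared, tolerance = 1e-10)
  }
})

test_that("simple allometry of absolute clearance has a shallow exponent", {
  tab <- species_records()
  an <- tab[tab$species != "human", ]
  fit <- fit_loglog(an$body_weight, an$cl_obs * an$body_weight)
  expect_equal(fit$exponent, 0.583, tolerance = 0.01)
  # hence the rule of exponents selects plain simple allometry
  roe <- rule_of_exponents_cl()
  expect_identical(roe$detail$branch, "SA")
})

test_that("rule of exponents switches branch with the fitted exponent", {
  bw <- c(0.02, 0.25, 5, 10)
  mk_records <- function(expo) {
    data.frame(species = c("mouse", "rat", "monkey", "dog", "human"),
               body_weight = c(bw, 70),
               cl_obs = c(2 * bw^expo / bw, NA),
               fu_plasma = 0.05, clint_mic = 10, vss_obs = 1, f_obs = 0.5,
               bp_ratio = 0.7, clint_hep = 10)
  }
  expect_identical(rule_of_exponents_cl(mk_records(0.85))$detail$branch,
                   "MLP")
  expect_identical(rule_of_exponents_cl(mk_records(1.2))$detail$branch,
                   "BrW")
  expect_identical(rule_of_exponents_cl(mk_records(0.6))$detail$branch, "SA")
})

test_that("corrected allometry degenerates to simple allometry", {
  # identical fu and CLint across species: NAS_fub reduces to simple
  # allometry rescaled by the (common) fu
  bw <- c(0.02, 0.25, 5, 10)
  rec <- data.frame(species = c("mouse", "rat", "monkey", "dog", "human"),
                    body_weight = c(bw, 70),
                    cl_obs = c(0.9 * bw^0.7 / bw, NA),
                    fu_plasma = 0.05, clint_mic = 10,
                    vss_obs = c(2 * bw^0.9 / bw, NA), f_obs = 0.5,
                    bp_ratio = 0.7, clint_hep = 10)
  nas <- nas_fub_cl(rec, human_bw = 70)
  sa <- fit_loglog(bw, 0.9 * bw^0.7)
  expect_equal(nas$cl, predict(sa, 70) / 70, tolerance = 1e-10)
  # and predictions are invariant to the order of species rows
  shuffled <- rec[c(3, 1, 5, 2, 4), ]
  expect_equal(nas_fub_cl(shuffled, 70)$cl, nas$cl, tolerance = 1e-12)
  expect_equal(sa_fub_vss(shuffled, 70)$vss, sa_fub_vss(rec, 70)$vss,
               tolerance = 1e-12)
})

test_that("Tang-Mayersohn prediction scales as the formula dictates", {
  tme <- tang_mayersohn_cl()
  # doubling human fu halves Rfu hence multiplies CL by 2^0.77
  tab <- species_records()
  tab$fu_plasma[tab$species == "human"] <- 0.036
  tme2 <- tang_mayersohn_cl(tab)
  expect_equal(tme2$cl / tme$cl, 2^0.77, tolerance = 1e-10)
  # unit case: a / Rfu = 1 mL/min gives 33.35 mL/min before per-kg scaling
  expect_equal(33.35 * (1)^0.77, 33.35)
})

test_that("Oie-Tozer solve and forward application are self-consistent", {
  tab <- species_records()
  ot <- oie_tozer_vss(tab)
  phys <- oie_tozer_constants()
  an <- tab[tab$species != "human", ]
  for (i in seq_len(nrow(an))) {
    sp <- an$species[i]
    ph <- phys[phys$species == sp, ]
    fut <- ot$detail$fut[[sp]]
    vss_back <- ph$vp * (1 + ph$re_i) +
      an$fu_plasma[i] * ph$vp * (ph$ve / ph$vp - ph$re_i) +
      ph$vr * an$fu_plasma[i] / fut
    expect_equal(vss_back, an$vss_obs[i], tolerance = 1e-10)
  }
  # fu = fu_t = 1 collapses to total body water Vp + Ve + Vr
  ph <- phys[phys$species == "human", ]
  vss_tbw <- ph$vp * (1 + ph$re_i) + 1 * ph$vp * (ph$ve / ph$vp - ph$re_i) +
    ph$vr * 1 / 1
  expect_equal(vss_tbw, ph$vp + ph$ve + ph$vr, tolerance = 1e-12)
})

test_that("human-dog proportionality and half-life are plain arithmetic", {
  dp <- dog_proportionality_vss(0.23, 0.018, 0.019)
  expect_equal(dp$vss, 0.23 * 0.018 / 0.019, tolerance = 1e-12)
  expect_equal(round(dp$vss, 3), 0.218)
  expect_equal(dog_proportionality_vss(0.23, 0.02, 0.02)$vss, 0.23)
  expect_equal(halflife(0.02, 0.21), log(2) * 0.21 / 0.02)
  expect_equal(halflife(0.01, 0.21), 2 * halflife(0.02, 0.21))
  expect_error(halflife(0, 1), "positive")
})

test_that("combining methods gives means and SDs across approaches", {
  mk <- function(m, cl = NA, vss = NA) human_prediction(m, cl, vss)
  comb <- combine_predictions(list(
    mk("a", cl = 0.022), mk("b", cl = 0.018), mk("c", cl = 0.020),
    mk("d", vss = 0.186), mk("e", vss = 0.216), mk("f", vss = 0.215)))
  expect_equal(comb$cl_mean, 0.020)
  expect_equal(comb$cl_sd, 0.002)
  expect_equal(comb$vss_mean, mean(c(0.186, 0.216, 0.215)))
  expect_equal(round(comb$vss_sd, 3), 0.017)
  expect_equal(round(comb$t_half, 1), 7.1)
  single <- combine_predictions(list(mk("a", cl = 0.02)))
  expect_true(is.na(single$cl_sd))
  expect_error(combine_predictions(list()), "no predictions")
})
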