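test_that("microsomal binding correction follows the printed relation", {
  expect_equal(microsomal_fu_inc(2, 0), 1.0)
  # direct evaluation at logD 2, P 0.5 mg/mL
  expected <- 1 / (1 + 0.5 * 10^(0.072 * 4 + 0.067 * 2 - 1.126))
  expect_equal(microsomal_fu_inc(2, 0.5), expected)
  expect_equal(round(microsomal_fu_inc(2, 0.5), 3), 0.910)
  # strictly decreasing in protein concentration
  p <- seq(0, 5, by = 0.5)
  expect_true(all(diff(microsomal_fu_inc(2, p)) < 0))
  expect_error(microsomal_fu_inc(2, -1), "non-negative")
})

test_that("intrinsic clearance scales through the physiological factors", {
  hu <- physio_constants("human")
  expect_equal(scale_clint(0, "hepatocyte", hu), 0)
  expect_equal(scale_clint(6.0, "hepatocyte", hu),
               6.0e-6 * 60 * 99 * 24.4, tolerance = 1e-12)
  # linear in the yield constants
  hu2 <- physio_constants("human", hepatocellularity = 198)
  expect_equal(scale_clint(6.0, "hepatocyte", hu2),
               2 * scale_clint(6.0, "hepatocyte", hu))
  expect_error(physio_constants("hamster"), "unknown")
})

test_that("hepatic clearance model has correct algebraic limits", {
  expect_equal(hepatic_clearance(1.16, 0.018, 0, 0.58), 0)
  # flow limit: clint -> Inf gives plasma clearance q_h * B/P
  expect_equal(hepatic_clearance(1.16, 0.018, 1e12, 0.58), 1.16 * 0.58,
               tolerance = 1e-6)
  # monotone increasing in clint and bounded by the flow limit
  cls <- hepatic_clearance(1.16, 0.018, c(0.1, 1, 10, 100, 1000), 0.58)
  expect_true(all(diff(cls) > 0))
  expect_true(all(cls < 1.16 * 0.58))
  expect_error(hepatic_clearance(-1, 0.5, 1, 1), "positive")
})

test_that("human hepatocyte IVIVE lands in the low-clearance range", {
  hu <- physio_constants("human")
  clint <- scale_clint(6.0, "hepatocyte", hu)
  cl <- hepatic_clearance(hu$q_h, 0.018, clint, 0.58)
  expect_equal(cl, 0.0153, tolerance = 0.01)
  # ~1-2% hepatic extraction
  expect_lt(extraction_ratio(cl, hu$q_h), 2)
  expect_gt(extraction_ratio(cl, hu$q_h), 1)
})

test_that("parallel-tube option is a more efficient liver than well-stirred", {
  ws <- hepatic_clearance(1.16, 0.5, 2, 0.58, model = "well-stirred")
  pt <- hepatic_clearance(1.16, 0.5, 2, 0.58, model = "parallel-tube")
  expect_gt(pt, ws)
  # both agree in the low-extraction limit
  ws_lo <- hepatic_clearance(1.16, 0.018, 0.5, 0.58)
  pt_lo <- hepatic_clearance(1.16, 0.018, 0.5, 0.58, model = "parallel-tube")
  expect_equal(pt_lo, ws_lo, tolerance = 0.01)
})

test_that("extraction ratio behaves as a percentage of liver blood flow", {
  expect_equal(extraction_ratio(0.02, 1.16), 100 * 0.02 / 1.16)
  expect_equal(extraction_ratio(1.16, 1.16), 100)
  expect_equal(extraction_ratio(0, 1.16), 0)
  expect_error(extraction_ratio(0.1, 0), "positive")
})

test_that("four-species hepatocyte scaling predicts within the fold band", {
  pred <- ivive_clearance()
  animals <- pred[pred$species != "human", ]
  expect_true(all(animals$fold_error >= 0.5 & animals$fold_error <= 3))
  # human prediction within twofold of the allometric value
  human_cl <- pred$cl_pred[pred$species == "human"]
  expect_gt(human_cl, 0.022 / 2)
  expect_lt(human_cl, 0.022 * 2)
})
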