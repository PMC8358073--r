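test_that("auditory logistic hits its defining landmarks exactly", {
  for (th in c(-12, -3.1, 4)) {
    for (w in c(4, 7.4, 10.4)) {
      expect_equal(pf_auditory(th, th, w), 0.5, tolerance = 1e-12)
      expect_equal(pf_auditory(th + w / 2, th, w), 0.9, tolerance = 1e-12)
      expect_equal(pf_auditory(th - w / 2, th, w), 0.1, tolerance = 1e-12)
    }
  }
  expect_lt(pf_auditory(-1e4, -12, 7.4), 1e-12)  # lower asymptote
  expect_error(pf_auditory(0, 0, width = -1), "width")
  expect_error(pf_auditory(0, 0, width = 0), "width")
})

test_that("visual exponential hits its defining landmarks", {
  expect_identical(pf_visual(0, 18.3), 1)
  for (th in c(5, 17.7, 18.3))
    expect_equal(pf_visual(th, th), exp(-1), tolerance = 1e-12)
  # a 70-px blur renders the video numerically uninformative
  expect_lt(pf_visual(70, 17.7), 1e-6)
  expect_error(pf_visual(-1, 18), "non-negative")
  expect_error(pf_visual(10, 0), "positive")
})

test_that("psychometric functions are monotone on stimulus grids", {
  snr <- seq(-40, 20, by = 0.5)
  expect_true(all(diff(pf_auditory(snr, -12, 7.4)) > 0))
  blur <- seq(0, 70, by = 0.5)
  expect_true(all(diff(pf_visual(blur, 17.7)) < 0))
})

test_that("lapse and guess transforms behave as linear maps with floors", {
  expect_equal(apply_lapse(1, 0.1), 0.9)
  expect_equal(apply_lapse(0.6, 0), 0.6)
  expect_equal(apply_lapse(0.787, 0.178), 0.647, tolerance = 5e-4)
  expect_equal(apply_guess(0), 0.1)
  expect_equal(apply_guess(1), 1)
  expect_equal(apply_guess(0.5), 0.55)
  p <- runif(50)
  expect_true(all(apply_lapse(p, 0.3) <= p))
  expect_true(all(apply_guess(p) >= 0.1 & apply_guess(p) <= 1))
  expect_error(apply_lapse(1.2, 0.1), "\\[0, 1\\]")
  expect_error(apply_guess(-0.1), "\\[0, 1\\]")
})

test_that("probability summation dominates its channels and stays bounded", {
  expect_equal(prob_summation(0.5, 0.5), 0.75)
  expect_equal(prob_summation(0.37, 0), 0.37)
  expect_equal(prob_summation(0.647, 0.150), 0.700, tolerance = 5e-4)
  grid <- expand.grid(a = seq(0, 1, 0.1), b = seq(0, 1, 0.1))
  s <- prob_summation(grid$a, grid$b)
  expect_true(all(s >= pmax(grid$a, grid$b) - 1e-12))
  expect_true(all(s <= pmin(1, grid$a + grid$b) + 1e-12))
})

test_that("predict_recognition chains the components per task and variant", {
  # visual-only, unblurred: guess(lapse(1)) = 0.9 * 0.54 + 0.1
  p <- predict_recognition(
    data.frame(modality = "V", task = "focused", snr_db = NA, blur_px = 0),
    participant_params(-5, 8, 18, lapse_v = 0.46))
  expect_equal(p, 0.586, tolerance = 1e-12)

  # equal task lapses: the two variants coincide everywhere
  eq <- participant_params(-5, 8, 18, 0.2, 0.2, 0.4)
  g <- condition_grid()
  expect_equal(predict_recognition(g, eq, "trade-off"),
               predict_recognition(g, eq, "strict"))

  # unisensory predictions use the lapse of their own task
  ci <- ci_means()
  aud <- data.frame(modality = "A", task = c("focused", "divided"),
                    snr_db = 10, blur_px = NA)
  p <- predict_recognition(aud, ci)
  expect_gt(p[1], p[2])  # divided attention costs auditory performance
  expect_equal(p[1], apply_guess(apply_lapse(
    pf_auditory(10, -3.1, 10.4), ci$lapse_a_focused)), tolerance = 1e-10)

  expect_error(predict_recognition(
    data.frame(modality = "AV", task = "divided", snr_db = 0, blur_px = NA),
    ci), "audiovisual")
  expect_error(predict_recognition(
    data.frame(modality = "V", task = "divided", snr_db = 0, blur_px = 10),
    ci), "no acoustic signal")
})

test_that("audiovisual prediction reproduces the brute-force oracle", {
  ci <- ci_means()
  av <- data.frame(modality = "AV", task = "divided", snr_db = 0,
                   blur_px = 20)
  p_trade <- predict_recognition(av, ci, "trade-off")
  p_strict <- predict_recognition(av, ci, "strict")
  expect_equal(p_trade,
               oracle_av(0, 20, -3.1, 10.4, 17.7, ci$lapse_a_focused, 0.46),
               tolerance = 1e-12)
  expect_equal(p_strict,
               oracle_av(0, 20, -3.1, 10.4, 17.7, ci$lapse_a_divided, 0.46),
               tolerance = 1e-12)
  # frozen values from the arithmetic chain at the CI group means
  expect_equal(p_trade, 0.7305, tolerance = 1e-3)
  expect_equal(p_strict, 0.5981, tolerance = 1e-3)
})

test_that("audiovisual prediction converges to the unisensory curves", {
  ci <- ci_means()
  # snr -> -inf: AV tends to the visual-only prediction of the variant task
  av_lo <- data.frame(modality = "AV", task = "divided", snr_db = -200,
                      blur_px = 12)
  v_only <- data.frame(modality = "V", task = "focused", snr_db = NA,
                       blur_px = 12)
  expect_equal(predict_recognition(av_lo, ci, "trade-off"),
               predict_recognition(v_only, ci, "trade-off"),
               tolerance = 1e-9)
  # blur -> inf: AV tends to the auditory-only prediction
  av_blur <- data.frame(modality = "AV", task = "divided", snr_db = 2,
                        blur_px = 500)
  a_only <- data.frame(modality = "A", task = "focused", snr_db = 2,
                       blur_px = NA)
  expect_equal(predict_recognition(av_blur, ci, "trade-off"),
               predict_recognition(a_only, ci, "trade-off"),
               tolerance = 1e-9)
})

test_that("MEI is zero under equal lapses and positive under a task cost", {
  eq <- participant_params(-5, 8, 18, 0.2, 0.2, 0.4)
  grid <- expand.grid(snr_db = seq(-15, 5, 5), blur_px = c(0, 10, 20))
  grid$modality <- "AV"; grid$task <- "divided"
  expect_equal(mei(grid, eq), rep(0, nrow(grid)))
  ci <- ci_means()
  expect_true(all(mei(grid, ci) >= 0))
  expect_error(mei(data.frame(modality = "A", task = "divided", snr_db = 0,
                              blur_px = 70), ci), "audiovisual")
})

test_that("MEI surface shows the inverse-effectiveness pattern", {
  ci <- ci_means()
  snr <- seq(-25, 5, 2.5)
  surf <- mei_surface(ci, snr, c(0, 6, 12, 16, 20))
  expect_equal(dim(surf), c(length(snr), 5))
  # larger for higher blur at favourable snr
  expect_gt(surf[nrow(surf), "20"], surf[nrow(surf), "0"])
  # declines toward low snr in every blur column
  expect_true(all(apply(surf, 2, function(col) all(diff(col) > 0))))
  # NH enhancement is far smaller than CI enhancement
  nh_surf <- mei_surface(nh_means(), snr, c(0, 6, 12, 16, 20))
  expect_lt(max(nh_surf), max(surf))
})
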