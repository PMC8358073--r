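test_that("participant draws respect constraints and the seed contract", {
  hyper <- ci_hyperparams()
  a <- draw_participants(hyper, 7, seed = 5)
  b <- draw_participants(hyper, 7, seed = 5)
  expect_identical(a, b)
  c <- draw_participants(hyper, 7, seed = 6)
  expect_false(identical(a, c))
  for (p in a) {
    expect_gt(p$width, 0)
    expect_gt(p$threshold_v, 0)
    expect_true(all(unlist(p[grep("lapse", names(p))]) >= 0))
    expect_true(all(unlist(p[grep("lapse", names(p))]) <= 1))
  }
})

test_that("zero spread collapses draws onto the group locations", {
  hyper <- group_hyperparams("NH", -12, 7.4, 18.3, 0.11, 0.15, 0.54,
                             sd_threshold_a = 0, sd_log_width = 0,
                             sd_log_threshold_v = 0, sd_logit_lapse = 0)
  pp <- draw_participants(hyper, 3, seed = 1)
  for (p in pp) {
    expect_equal(p$threshold_a, -12)
    expect_equal(p$width, 7.4)
    expect_equal(p$threshold_v, 18.3)
    expect_equal(p$lapse_v_focused, 0.54)
  }
  expect_error(group_hyperparams("NH", -12, 7.4, 18.3, .1, .1, .5,
                                 sd_threshold_a = -1), "non-negative")
})

test_that("level individualization inverts the psychometric chain", {
  # closed-form check: zero lapse, target 0.5 post-guess means F = 4/9
  p0 <- participant_params(-10, 8, 18, 0, 0, 0)
  snr <- individualize_levels(p0, 0.5, "A")
  expect_equal(pf_auditory(snr, -10, 8), 4 / 9, tolerance = 1e-10)
  blur <- individualize_levels(p0, 0.5, "V")
  expect_equal(pf_visual(blur, 18), 4 / 9, tolerance = 1e-10)
  # forward evaluation reproduces the targets through the full chain
  nh <- nh_means()
  targets <- c(0.25, 0.5, 0.7)
  snrs <- individualize_levels(nh, targets, "A")
  fwd <- predict_recognition(
    data.frame(modality = "A", task = "focused", snr_db = snrs, blur_px = NA),
    nh)
  expect_equal(fwd, targets, tolerance = 1e-8)
  # floor target: prediction within 1e-3 of the 0.1 guess floor
  lo <- individualize_levels(nh, 0.1, "A")
  p_lo <- predict_recognition(
    data.frame(modality = "A", task = "focused", snr_db = lo, blur_px = NA),
    nh)
  expect_lt(abs(p_lo - 0.1), 1e-3)
  # unreachable target is clipped to the lapse ceiling with a warning
  expect_warning(individualize_levels(nh, 0.95, "A"), "ceiling")
  expect_warning(blur0 <- individualize_levels(nh, 0.9, "V"), "ceiling")
  expect_equal(blur0, 0)
  # common focused-attention blurs map to decreasing performance
  perf <- predict_recognition(
    data.frame(modality = "V", task = "focused", snr_db = NA,
               blur_px = c(0, 6, 12, 16, 20)), nh)
  expect_true(all(diff(perf) < 0))
})

test_that("designs honour the block structure of the two tasks", {
  nh <- nh_means()
  set.seed(1)
  foc <- build_design("focused", nh, n_auditory = 40, n_visual = 40)
  expect_equal(nrow(foc), 80)
  expect_setequal(unique(foc$modality), c("A", "V"))
  expect_true(all(is.na(foc$snr_db[foc$modality == "V"])))
  expect_true(all(foc$blur_px[foc$modality == "A"] == 70))
  expect_equal(length(unique(foc$snr_db[foc$modality == "A"])), 8)
  expect_false(any(duplicated(foc$sentence_id)))

  div <- build_design("divided", nh, n_divided = 100)
  expect_equal(nrow(div), 100)
  combos <- unique(div[, c("snr_db", "blur_px")])
  expect_equal(nrow(combos), 25)  # 5 x 5 stimulus grid
  counts <- table(paste(div$snr_db, div$blur_px))
  expect_true(all(counts == 4))   # balanced allocation of 100 trials
  expect_true(all(div$modality[is.na(div$snr_db)] == "V"))
  expect_true(all(div$modality[div$blur_px == 70 & !is.na(div$snr_db)] == "A"))
  expect_error(build_design("divided", nh, n_divided = 10), "80-120")
  expect_error(build_design("focused", nh, n_auditory = 10), "40-60")
})

test_that("simulated responses are binomial with the model probabilities", {
  nh <- nh_means()
  des <- data.frame(modality = "A", task = "focused",
                    snr_db = -9, blur_px = NA_real_,
                    sentence_id = 1:2000, n_words = 5L)
  sim <- simulate_responses(des, nh, seed = 7)
  expect_true(all(sim$n_correct >= 0 & sim$n_correct <= 5))
  p_true <- predict_recognition(des[1, ], nh)
  # law of large numbers: 10,000 words pin the proportion to within 0.01
  expect_lt(abs(mean(sim$n_correct / 5) - p_true), 0.01)
  # identical seeds give identical tables, distinct seeds differ
  expect_identical(sim, simulate_responses(des, nh, seed = 7))
  expect_false(identical(sim$n_correct,
                         simulate_responses(des, nh, seed = 8)$n_correct))
})

test_that("degenerate probabilities saturate the response counts", {
  perfect <- participant_params(-10, 8, 18, 0, 0, 0)
  des <- data.frame(modality = "V", task = "focused", snr_db = NA_real_,
                    blur_px = 0, sentence_id = 1:50, n_words = 5L)
  sim <- simulate_responses(des, perfect, seed = 1)
  expect_true(all(sim$n_correct == 5))  # zero lapse, zero blur, post-guess 1
  floory <- data.frame(modality = "A", task = "focused", snr_db = -80,
                       blur_px = NA_real_, sentence_id = 1:2000, n_words = 5L)
  sim2 <- simulate_responses(floory, nh_means(), seed = 2)
  expect_lt(abs(mean(sim2$n_correct / 5) - 0.1), 0.015)
})

test_that("a simulated focused NH cohort saturates near 90% correct", {
  sim <- simulate_cohort(list(nh_hyperparams()), n = 14, tasks = "focused",
                         seed = 31)
  aud <- sim$trials[sim$trials$modality == "A", ]
  top <- do.call(rbind, lapply(split(aud, aud$participant_id), function(d)
    d[d$snr_db == max(d$snr_db), ]))
  expect_equal(mean(top$n_correct / top$n_words), 0.85, tolerance = 0.06)
})

test_that("the full study table is deterministic and schema-valid", {
  sim <- simulate_cohort(n = c(3, 2), seed = 9)
  sim2 <- simulate_cohort(n = c(3, 2), seed = 9)
  expect_identical(sim, sim2)
  expect_setequal(unique(sim$trials$cohort), c("NH", "CI"))
  expect_equal(length(unique(sim$trials$participant_id)), 5)
  expect_equal(nrow(sim$truth), 5)
  path <- withr::local_tempfile(fileext = ".csv")
  write_trials(sim$trials, path)
  back <- read_trials(path)
  expect_equal(back$n_correct, sim$trials$n_correct)
  expect_equal(back$snr_db, sim$trials$snr_db, tolerance = 1e-10)
})

test_that("trial-table validation reports offending rows", {
  sim <- simulate_cohort(n = c(2, 1), seed = 4)
  bad <- sim$trials
  bad$modality[3] <- "X"
  expect_error(avspeech:::.validate_trials(bad), "row")
  expect_error(avspeech:::.validate_trials(
    transform(sim$trials, snr_db = NA, blur_px = NA)), "both stimulus")
})
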