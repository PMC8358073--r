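test_that("the binomial log-likelihood matches hand arithmetic", {
  pp <- participant_params(-10, 8, 18, 0, 0, 0)
  # a single sentence with all 5 words correct at the 50% point, post-guess
  trial <- data.frame(participant_id = "P1", cohort = "NH", task = "focused",
                      modality = "A", snr_db = -10, blur_px = NA,
                      n_words = 5L, n_correct = 5L)
  ll <- build_loglik(trial)(list(P1 = pp))
  expect_equal(ll, 5 * log(0.9 * 0.5 + 0.1), tolerance = 1e-12)
})

test_that("the log-likelihood is exchangeable over trial order", {
  sim <- small_ci_sim()
  ll <- build_loglik(sim$trials)
  params <- lapply(split(sim$truth, sim$truth$participant_id), function(r)
    participant_params(r$threshold_a, r$width, r$threshold_v,
                       r$lapse_a_focused, r$lapse_a_divided,
                       r$lapse_v_focused))
  set.seed(1)
  shuffled <- sim$trials[sample(nrow(sim$trials)), ]
  expect_equal(ll(params), build_loglik(shuffled)(params))
  # generating parameters beat a 5 dB threshold perturbation
  worse <- lapply(params, function(p) {
    p$threshold_a <- p$threshold_a + 5; p
  })
  expect_gt(ll(params), ll(worse))
  expect_error(ll(params[-1]), "missing parameters")
})

test_that("the conjugate toy model recovers the Beta posterior", {
  draws <- avspeech:::.fit_binomial_toy(successes = 30, n = 100, seed = 3)
  post_mean <- mean(draws)
  mcse <- sd(draws) / sqrt(ess(draws))
  expect_lt(abs(post_mean - 31 / 102), max(4 * mcse, 0.005))
  h <- hdi(as.numeric(draws))
  expect_lt(h[["lower"]], 31 / 102)
  expect_gt(h[["upper"]], 31 / 102)
})

test_that("a smoke-scale hierarchical fit is deterministic and well-formed", {
  sim <- small_ci_sim()
  fit <- fit_av_model(sim$trials, chains = 2, samples = 300, burn_in = 200,
                      adapt = 200, seed = 77)
  expect_s3_class(fit, "av_fit")
  expect_equal(dim(fit$draws$group_threshold_a), c(300, 2))
  expect_equal(fit$participants, sort(unique(sim$trials$participant_id)))
  # seed-determinism of the sampler
  fit2 <- fit_av_model(sim$trials, chains = 2, samples = 300, burn_in = 200,
                       adapt = 200, seed = 77)
  expect_identical(fit$draws, fit2$draws)
  # row-shuffling the trials leaves the posterior unchanged
  set.seed(2)
  shuf <- sim$trials[sample(nrow(sim$trials)), ]
  fit3 <- fit_av_model(shuf, chains = 2, samples = 300, burn_in = 200,
                       adapt = 200, seed = 77)
  expect_equal(mean(fit$draws$group_threshold_a),
               mean(fit3$draws$group_threshold_a), tolerance = 1e-8)

  s <- summary(fit)
  expect_true(all(s$hdi_low <= s$mean & s$mean <= s$hdi_high))
  expect_true("group_lapse_a_diff" %in% s$parameter)
  # visual lapse shared across tasks under the default constraint
  expect_identical(fit$draws$group_lapse_v_focused,
                   fit$draws$group_lapse_v_divided)
  expect_error(fit_av_model(sim$trials, chains = 1), "2 chains")

  # method surface
  expect_output(print(fit), "Hierarchical audiovisual")
  expect_true(all(c("group_threshold_a", "group_width") %in% names(coef(fit))))
  p <- predict(fit)
  expect_true(all(p >= 0.1 & p <= 1))
  expect_equal(length(residuals(fit)), nrow(sim$trials))
  rep1 <- simulate(fit, seed = 1)
  expect_true(all(rep1$n_correct <= rep1$n_words))
  pe <- participant_estimates(fit, fit$participants[1])
  expect_s3_class(pe, "participant_params")
  pdf(NULL); on.exit(dev.off())
  expect_silent(plot(fit))
})

test_that("derived posterior quantities are computed draw-wise", {
  sim <- small_ci_sim()
  fit <- fit_av_model(sim$trials, chains = 2, samples = 200, burn_in = 150,
                      adapt = 200, seed = 5)
  s <- posterior_summary(fit, pars = "group_lapse_a_diff",
                         derived = list(
                           diff2 = function(d) d$group_lapse_a_divided -
                             d$group_lapse_a_focused))
  expect_equal(s$mean[s$parameter == "group_lapse_a_diff"],
               s$mean[s$parameter == "diff2"], tolerance = 1e-10)
  # draw-wise, not a difference of summaries: check on asymmetric transform
  s2 <- posterior_summary(fit, pars = "group_width",
                          derived = list(
                            logw = function(d) log(d$group_width)))
  expect_false(isTRUE(all.equal(exp(s2$mean[s2$parameter == "logw"]),
                                s2$mean[s2$parameter == "group_width"],
                                tolerance = 1e-6)))
})

test_that("near-degenerate data concentrate the posterior on the truth", {
  # two identical participants, massive trial counts, zero-spread generator
  hyper <- group_hyperparams("NH", -10, 8, 18, 0.12, 0.2, 0.5,
                             sd_threshold_a = 0, sd_log_width = 0,
                             sd_log_threshold_v = 0, sd_logit_lapse = 0)
  parts <- draw_participants(hyper, 2, seed = 1)
  trials <- do.call(rbind, lapply(1:2, function(i) {
    des <- build_design("focused", parts[[i]], n_auditory = 60,
                        n_visual = 60)
    des <- do.call(rbind, replicate(8, des, simplify = FALSE))
    des$sentence_id <- seq_len(nrow(des))
    d <- simulate_responses(des, parts[[i]], seed = i)
    d$participant_id <- paste0("P", i); d$cohort <- "NH"; d
  }))
  fit <- fit_av_model(trials, chains = 2, samples = 500, burn_in = 500,
                      adapt = 300, seed = 9)
  expect_equal(mean(fit$draws$group_threshold_a), -10, tolerance = 0.5)
  expect_equal(mean(fit$draws$group_width), 8, tolerance = 1)
  expect_equal(mean(fit$draws$group_lapse_v_focused), 0.5, tolerance = 0.06)
})

test_that("95% HDIs of group parameters are calibrated over replicate fits", {
  gen <- c(group_threshold_a = -3.1, group_width = 10.4,
           group_theta_v = 17.7, group_lapse_v_focused = 0.46,
           group_lapse_a_diff = 0.22)
  cover <- matrix(FALSE, 20, length(gen),
                  dimnames = list(NULL, names(gen)))
  for (r in 1:20) {
    sim <- simulate_cohort(list(ci_hyperparams()), n = 7,
                           truth_variant = "trade-off", seed = 3000 + r)
    fit <- fit_av_model(sim$trials, chains = 2, samples = 1000,
                        burn_in = 800, adapt = 400, seed = 3000 + r)
    for (p in names(gen)) {
      h <- hdi(as.numeric(fit$draws[[p]]))
      cover[r, p] <- h[["lower"]] <= gen[[p]] && gen[[p]] <= h[["upper"]]
    }
  }
  expect_true(all(colSums(cover) >= 18))
})
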