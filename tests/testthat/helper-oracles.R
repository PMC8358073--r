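# Shared fixtures and independent oracles for the test suite.

# Group-mean parameter sets used throughout: a normal-hearing-like and a
# cochlear-implant-like observer. Focused auditory lapses are implied by the
# saturation levels (0.9 * (1 - lambda) + 0.1 = saturation).
nh_means <- function() {
  participant_params(threshold_a = -12, width = 7.4, threshold_v = 18.3,
                     lapse_a_focused = 1 - 0.8 / 0.9,
                     lapse_a_divided = 1 - 0.8 / 0.9 + 0.039,
                     lapse_v = 0.54)
}

ci_means <- function() {
  participant_params(threshold_a = -3.1, width = 10.4, threshold_v = 17.7,
                     lapse_a_focused = 1 - 0.74 / 0.9,
                     lapse_a_divided = 1 - 0.74 / 0.9 + 0.22,
                     lapse_v = 0.46)
}

# Brute-force scalar oracle for the audiovisual prediction chain, written
# out in raw arithmetic (no package functions). `guess_order` switches
# whether the closed-set guess correction is applied after or before the
# race combination, to pin down the correct ordering empirically.
oracle_av <- function(snr, blur, threshold_a, width, threshold_v,
                      lapse_a, lapse_v, guess = 0.1,
                      guess_order = c("after", "before")) {
  guess_order <- match.arg(guess_order)
  fa <- 1 / (1 + exp(-(2 * log(9) / width) * (snr - threshold_a)))
  fv <- exp(-blur^2 / threshold_v^2)
  psi_a <- (1 - lapse_a) * fa
  psi_v <- (1 - lapse_v) * fv
  if (guess_order == "after") {
    (1 - guess) * (1 - (1 - psi_a) * (1 - psi_v)) + guess
  } else {
    pa <- (1 - guess) * psi_a + guess
    pv <- (1 - guess) * psi_v + guess
    1 - (1 - pa) * (1 - pv)
  }
}

# A tiny deterministic condition grid covering all modalities and tasks.
condition_grid <- function() {
  rbind(
    data.frame(modality = "A", task = "focused", snr_db = c(-15, -5, 0),
               blur_px = 70),
    data.frame(modality = "V", task = "focused", snr_db = NA_real_,
               blur_px = c(0, 12, 20)),
    data.frame(modality = "A", task = "divided", snr_db = c(-10, 0),
               blur_px = 70),
    data.frame(modality = "V", task = "divided", snr_db = NA_real_,
               blur_px = c(6, 16)),
    data.frame(modality = "AV", task = "divided",
               snr_db = c(-10, -5, 0, 5), blur_px = c(0, 6, 12, 20)))
}

# Small synthetic cohort shared by slower tests (simulated once per run).
small_ci_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- simulate_cohort(list(ci_hyperparams()), n = 4, seed = 42)
    cache
  }
})
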