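# avspeech

Modelling word recognition in audiovisual speech-in-noise experiments.

Cochlear-implant (CI) users understand noisy speech far worse than
normal-hearing (NH) listeners and rely heavily on lipreading. In a
closed-set Matrix sentence test (5 words per sentence, 10 alternatives per
word), recognition can be measured against the acoustic signal-to-noise
ratio (SNR) and the Gaussian blur degrading the talker video, either in
*focused-attention* blocks (one informative modality per block) or in a
*divided-attention* block (auditory, visual and audiovisual trials
interleaved). `avspeech` is for psychophysicists and audiologists who want
to ask, on such data: is audiovisual performance just statistical
facilitation of two independent channels, or does dividing attention
change the channels themselves?

## The model

Unisensory word recognition follows

- auditory: F_A(x_A) = 1 / (1 + exp(−(2·ln 9 / ω)(x_A − θ_A))), with
  threshold θ_A (dB SNR, the 50% point) and width ω (dB, the 0.1→0.9
  range);
- visual: F_V(x_V) = exp(−x_V² / θ_V²), with threshold θ_V (px, the
  36.8% point).

A task-dependent lapse probability caps the asymptote, Ψ = (1 − λ)·F, and
a fixed closed-set guess rate maps Ψ to the observed proportion correct,
p = 0.9·Ψ + 0.1. Audiovisual trials are predicted by probability summation
(a race of independent channels), Ψ_sum = Ψ_A + Ψ_V − Ψ_A·Ψ_V, in two
variants: **strict** uses the divided-task auditory lapse, **trade-off**
uses the focused-task lapse, crediting multisensory stimulation with a
release from the divided-attention cost. Their ratio defines the
multisensory enhancement index, MEI = Ψ_trade-off / Ψ_strict − 1.
Participant and group parameters are estimated by hierarchical Bayesian
MCMC (JAGS backend, binomial word-level likelihood) with split-R̂ / ESS
diagnostics and shortest-HDI summaries; the variants are compared by
BIC = ln(n)·k − 2·ln(L̂). A synthetic-cohort generator reproduces the
focused/divided experimental designs and stands in for real data
everywhere.

## Worked example

Evaluate the model at representative CI group parameters (focused auditory
lapse 0.178, i.e. saturation at 84% correct; divided lapse 0.22 higher;
visual lapse 0.46):

```r
library(avspeech)
ci <- participant_params(threshold_a = -3.1, width = 10.4, threshold_v = 17.7,
                         lapse_a_focused = 0.178, lapse_a_divided = 0.398,
                         lapse_v = 0.46)
conds <- data.frame(modality = c("A", "V", "AV"), task = "divided",
                    snr_db = c(0, NA, 0), blur_px = c(70, 20, 20))
predict_recognition(conds, ci, variant = "trade-off")
#> [1] 0.527 0.236 0.730
predict_recognition(conds, ci, variant = "strict")
#> [1] 0.527 0.236 0.598
mei(conds[3, ], ci)
#> [1] 0.221
```

At 0 dB SNR and 20 px blur this listener recognizes 53% of auditory-only
words (the divided-task lapse bites), 24% of visual-only words, and
73% vs 60% of audiovisual words under the trade-off vs strict model — an
enhancement of 0.22 beyond statistical facilitation, exactly the
divided-minus-focused lapse difference resurfacing as multisensory
benefit.

Simulate a full two-cohort study and compare the variants on the CI data:

```r
sim <- simulate_cohort(n = c(14, 7), seed = 1)   # 3780 trials, 21 participants
compare_variants(sim$trials[sim$trials$cohort == "CI", ])
#>  cohort   variant  bic delta_bic r_squared mean_signed_error loglik  k    n
#>      CI trade-off 3840       0.0     0.848         -0.000109  -1736 42 6300
#>      CI    strict 3860      20.6     0.833         -0.001160  -1746 42 6300
```

The trade-off model (the generating model here) wins by ~21 BIC points.
A hierarchical fit of one cohort, with posterior summaries and
convergence diagnostics:

```r
fit <- fit_av_model(sim$trials[sim$trials$cohort == "CI", ],
                    chains = 3, samples = 2000, burn_in = 1000, seed = 1)
summary(fit)     # posterior means, 95%-HDIs, Rhat, ESS per group parameter
plot(fit)        # group psychometric curves over the pooled data
```

A thin command-line front end (`inst/cli/avspeech.R`) exposes the same
pipeline as `simulate`, `fit`, `compare` and `mei` subcommands with
`--config`, `--seed`, `--out` and `--smoke` flags.

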