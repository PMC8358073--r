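# Hierarchical Bayesian estimation of the audiovisual psychometric model.
# The likelihood is binomial at the word level: n_correct ~ Binomial(n_words,
# (1 - g) * psi + g), with psi the lapse-adjusted psychometric value (race
# combination of the two channels for audiovisual trials) and g the 0.1
# closed-set guess rate. Participant parameters are drawn from cohort-level
# Normal distributions on transformed scales (identity for the auditory
# threshold, log for width and visual threshold, logit for lapses).

.SLOPE2LN9 <- 2 * log(9)

.lapse_structure <- function(constraint) {
  switch(constraint,
    aud_free_vis_shared = list(a_free = TRUE,  v_free = FALSE),
    all_free            = list(a_free = TRUE,  v_free = TRUE),
    all_shared          = list(a_free = FALSE, v_free = FALSE),
    stop("unknown lapse constraint: ", constraint, call. = FALSE))
}

#' Number of free participant-level parameters per lapse constraint
#'
#' Three parameters are always free (auditory threshold, width, visual
#' threshold); the lapse constraint decides how many lapse probabilities
#' are: one or two auditory and one or two visual lapses.
#'
#' @param constraint lapse-sharing constraint.
#' @return Integer count of free parameters per participant.
#' @export
n_free_params <- function(constraint = c("aud_free_vis_shared", "all_free",
                                         "all_shared")) {
  constraint <- match.arg(constraint)
  s <- .lapse_structure(constraint)
  3L + (if (s$a_free) 2L else 1L) + (if (s$v_free) 2L else 1L)
}

.lapse_block <- function(which, free) {
  # participant-level lapse priors for channel `which` ("a" or "v")
  if (free) sprintf(
    "    for (e in 1:2) {
      logit_lapse_%s[i, e] ~ dnorm(mu_logit_lapse_%s[e], tau_logit_lapse_%s[e])
      lapse_%s[i, e] <- ilogit(logit_lapse_%s[i, e])
    }\n", which, which, which, which, which)
  else sprintf(
    "    logit_lapse_%s[i] ~ dnorm(mu_logit_lapse_%s, tau_logit_lapse_%s)
    lapse_%s[i, 1] <- ilogit(logit_lapse_%s[i])
    lapse_%s[i, 2] <- lapse_%s[i, 1]\n",
    which, which, which, which, which, which, which)
}

.lapse_hyper <- function(which, free) {
  if (free) sprintf(
    "  for (e in 1:2) {
    mu_logit_lapse_%s[e] ~ dnorm(-1, 0.444)
    sigma_logit_lapse_%s[e] ~ dnorm(0, 1) T(0,)
    tau_logit_lapse_%s[e] <- pow(sigma_logit_lapse_%s[e], -2)
  }
  group_lapse_%s_focused <- ilogit(mu_logit_lapse_%s[1])
  group_lapse_%s_divided <- ilogit(mu_logit_lapse_%s[2])\n",
    which, which, which, which, which, which, which, which)
  else sprintf(
    "  mu_logit_lapse_%s ~ dnorm(-1, 0.444)
  sigma_logit_lapse_%s ~ dnorm(0, 1) T(0,)
  tau_logit_lapse_%s <- pow(sigma_logit_lapse_%s, -2)
  group_lapse_%s_focused <- ilogit(mu_logit_lapse_%s)
  group_lapse_%s_divided <- group_lapse_%s_focused\n",
    which, which, which, which, which, which, which, which)
}

.build_model_string <- function(constraint) {
  s <- .lapse_structure(constraint)
  paste0(
"model {
  for (i in 1:P) {
    theta_a[i] ~ dnorm(mu_theta_a, tau_theta_a)
    log_width[i] ~ dnorm(mu_log_width, tau_log_width)
    width[i] <- exp(log_width[i])
    log_theta_v[i] ~ dnorm(mu_log_theta_v, tau_log_theta_v)
    theta_v[i] <- exp(log_theta_v[i])
", .lapse_block("a", s$a_free), .lapse_block("v", s$v_free),
"    lapse_a_focused[i] <- lapse_a[i, 1]
    lapse_a_divided[i] <- lapse_a[i, 2]
    lapse_v_focused[i] <- lapse_v[i, 1]
    lapse_v_divided[i] <- lapse_v[i, 2]
  }
  for (t in 1:N) {
    FA[t] <- has_a[t] * ilogit(", .SLOPE2LN9,
" / width[pid[t]] * (snr[t] - theta_a[pid[t]]))
    FV[t] <- has_v[t] * exp(-pow(blur[t], 2) / pow(theta_v[pid[t]], 2))
    psiA[t] <- (1 - lapse_a[pid[t], etask_a[t]]) * FA[t]
    psiV[t] <- (1 - lapse_v[pid[t], etask_v[t]]) * FV[t]
    p[t] <- (1 - g) * (psiA[t] + psiV[t] - psiA[t] * psiV[t]) + g
    y[t] ~ dbin(p[t], nw[t])
  }
  # weakly informative hyperpriors on transformed scales
  mu_theta_a ~ dnorm(0, 0.0025)
  sigma_theta_a ~ dnorm(0, 0.04) T(0,)
  tau_theta_a <- pow(sigma_theta_a, -2)
  mu_log_width ~ dnorm(2, 1)
  sigma_log_width ~ dnorm(0, 4) T(0,)
  tau_log_width <- pow(sigma_log_width, -2)
  mu_log_theta_v ~ dnorm(2.7, 1)
  sigma_log_theta_v ~ dnorm(0, 4) T(0,)
  tau_log_theta_v <- pow(sigma_log_theta_v, -2)
", .lapse_hyper("a", s$a_free), .lapse_hyper("v", s$v_free),
"  group_threshold_a <- mu_theta_a
  group_width <- exp(mu_log_width)
  group_theta_v <- exp(mu_log_theta_v)
  group_lapse_a_diff <- group_lapse_a_divided - group_lapse_a_focused
}
")
}

.prepare_jags_data <- function(trials, variant, guess_rate) {
  trials <- .validate_trials(trials)
  pids <- sort(unique(trials$participant_id))
  pid <- match(trials$participant_id, pids)
  variant_task <- if (variant == "trade-off") "focused" else "divided"
  etask <- ifelse(trials$modality == "AV", variant_task, trials$task)
  etask <- ifelse(etask == "focused", 1L, 2L)
  list(data = list(
         P = length(pids), N = nrow(trials), pid = pid,
         snr = ifelse(is.na(trials$snr_db), 0, trials$snr_db),
         blur = ifelse(is.na(trials$blur_px), 0, trials$blur_px),
         has_a = as.integer(!is.na(trials$snr_db)),
         has_v = as.integer(!is.na(trials$blur_px)),
         etask_a = etask, etask_v = etask,
         y = as.integer(trials$n_correct), nw = as.integer(trials$n_words),
         g = guess_rate),
       participants = pids)
}

.jags_inits <- function(jd, constraint, chains, seed) {
  s <- .lapse_structure(constraint)
  a_trials <- jd$data$has_a == 1
  med_snr <- if (any(a_trials)) stats::median(jd$data$snr[a_trials]) else -5
  lapply(seq_len(chains), function(ch) {
    jitter <- 0.5 * (ch - (chains + 1) / 2)
    ini <- list(
      .RNG.name = "base::Mersenne-Twister",
      .RNG.seed = as.integer(seed + ch),
      mu_theta_a = med_snr + jitter,
      theta_a = rep(med_snr + jitter, jd$data$P),
      mu_log_width = 2 + 0.1 * jitter,
      log_width = rep(2, jd$data$P),
      mu_log_theta_v = 2.7 + 0.1 * jitter,
      log_theta_v = rep(2.7, jd$data$P),
      sigma_theta_a = 1, sigma_log_width = 0.2, sigma_log_theta_v = 0.2)
    la0 <- stats::qlogis(0.15) + 0.2 * jitter
    if (s$a_free) {
      ini$mu_logit_lapse_a <- rep(la0, 2)
      ini$sigma_logit_lapse_a <- rep(0.4, 2)
      ini$logit_lapse_a <- matrix(la0, jd$data$P, 2)
    } else {
      ini$mu_logit_lapse_a <- la0
      ini$sigma_logit_lapse_a <- 0.4
      ini$logit_lapse_a <- rep(la0, jd$data$P)
    }
    if (s$v_free) {
      ini$mu_logit_lapse_v <- rep(la0, 2)
      ini$sigma_logit_lapse_v <- rep(0.4, 2)
      ini$logit_lapse_v <- matrix(la0, jd$data$P, 2)
    } else {
      ini$mu_logit_lapse_v <- la0
      ini$sigma_logit_lapse_v <- 0.4
      ini$logit_lapse_v <- rep(la0, jd$data$P)
    }
    ini
  })
}

.GROUP_PARS <- c("group_threshold_a", "group_width", "group_theta_v",
                 "group_lapse_a_focused", "group_lapse_a_divided",
                 "group_lapse_v_focused", "group_lapse_v_divided",
                 "group_lapse_a_diff",
                 "sigma_theta_a", "sigma_log_width", "sigma_log_theta_v")

.PARTICIPANT_PARS <- c("theta_a", "width", "theta_v",
                       "lapse_a_focused", "lapse_a_divided",
                       "lapse_v_focused", "lapse_v_divided")

#' Fit the hierarchical audiovisual psychometric model
#'
#' Fits the full model -- logistic auditory and exponential visual
#' psychometric functions, task-dependent lapse probabilities, probability
#' summation for audiovisual trials and the 0.1 closed-set guess floor --
#' to a trial table by MCMC (Gibbs sampling via JAGS). Participant
#' parameters are partially pooled through cohort-level Normal
#' distributions on transformed scales; one cohort is fitted per call.
#'
#' The default \code{constraint}, \code{"aud_free_vis_shared"}, lets only
#' the auditory lapse probability differ between the focused- and
#' divided-attention tasks, with the visual lapse shared -- the final model
#' of the analysis. \code{variant} selects which task's auditory lapse
#' predicts the audiovisual trials: \code{"trade-off"} (focused, the
#' better-fitting model) or \code{"strict"} (divided, plain probability
#' summation within the task).
#'
#' @param trials trial table (see [read_trials()] for the schema); must
#'   contain a single cohort.
#' @param constraint lapse-sharing constraint: \code{"aud_free_vis_shared"},
#'   \code{"all_free"} or \code{"all_shared"}.
#' @param variant audiovisual model variant, \code{"trade-off"} or
#'   \code{"strict"}.
#' @param chains number of MCMC chains (>= 2 for diagnostics).
#' @param samples retained samples per chain.
#' @param burn_in discarded warm-up samples per chain.
#' @param adapt JAGS adaptation steps.
#' @param thin thinning interval.
#' @param seed integer seed; fixes the per-chain RNG states, so a repeated
#'   call reproduces the draws exactly.
#' @param guess_rate closed-set chance level.
#' @param quiet suppress JAGS progress output.
#' @return An object of class \code{"av_fit"}: a list with the per-parameter
#'   draw matrices (\code{$draws}, iterations x chains), the participant id
#'   map, the data and the sampler settings. Use [summary.av_fit()],
#'   [coef.av_fit()], [diagnose()], [predict.av_fit()].
#' @export
#' @examples
#' \donttest{
#' sim <- simulate_cohort(list(nh_hyperparams()), n = 3,
#'                        tasks = "focused", seed = 1)
#' fit <- fit_av_model(sim$trials, chains = 2, samples = 500, burn_in = 250)
#' summary(fit)
#' }
fit_av_model <- function(trials,
                         constraint = c("aud_free_vis_shared", "all_free",
                                        "all_shared"),
                         variant = c("trade-off", "strict"),
                         chains = 3, samples = 10000, burn_in = 10000,
                         adapt = 1000, thin = 1, seed = 1,
                         guess_rate = 0.1, quiet = TRUE) {
  constraint <- match.arg(constraint)
  variant <- match.arg(variant)
  trials <- .validate_trials(trials)
  if (length(unique(trials$cohort)) != 1)
    stop("fit_av_model() fits one cohort at a time; subset the trial table ",
         "or use fit_cohorts()", call. = FALSE)
  if (chains < 2)
    stop("use at least 2 chains so convergence can be diagnosed",
         call. = FALSE)
  jd <- .prepare_jags_data(trials, variant, guess_rate)
  model_string <- .build_model_string(constraint)
  inits <- .jags_inits(jd, constraint, chains, seed)
  t0 <- Sys.time()
  model <- rjags::jags.model(textConnection(model_string), data = jd$data,
                             inits = inits, n.chains = chains,
                             n.adapt = adapt, quiet = quiet)
  if (burn_in > 0)
    stats::update(model, n.iter = burn_in,
                  progress.bar = if (quiet) "none" else "text")
  monitors <- c(.GROUP_PARS, .PARTICIPANT_PARS)
  mcmc <- rjags::coda.samples(model, variable.names = monitors,
                              n.iter = samples * thin, thin = thin,
                              progress.bar = if (quiet) "none" else "text")
  draws <- .mcmc_to_draws(mcmc)
  # single-participant cohorts: JAGS drops the index from node names
  bare <- names(draws) %in% .PARTICIPANT_PARS
  names(draws)[bare] <- paste0(names(draws)[bare], "[1]")
  fit <- structure(list(
    draws = draws,
    participants = jd$participants,
    data = trials,
    cohort = trials$cohort[1],
    constraint = constraint,
    variant = variant,
    chains = chains, samples = samples, burn_in = burn_in,
    adapt = adapt, thin = thin, seed = seed,
    guess_rate = guess_rate,
    model = model_string,
    runtime_s = as.numeric(Sys.time() - t0, units = "secs")),
    class = "av_fit")
  fit
}

# Minimal conjugate model run through the same backend and extraction path
# as fit_av_model(); a sanity harness for the sampler plumbing (the
# Beta(1 + s, 1 + f) posterior is known in closed form).
.fit_binomial_toy <- function(successes, n, chains = 3, samples = 2000,
                              burn_in = 500, seed = 1) {
  model <- "model { p ~ dbeta(1, 1)\n y ~ dbin(p, n) }"
  inits <- lapply(seq_len(chains), function(ch)
    list(.RNG.name = "base::Mersenne-Twister",
         .RNG.seed = as.integer(seed + ch), p = 0.5))
  jm <- rjags::jags.model(textConnection(model),
                          data = list(y = successes, n = n),
                          inits = inits, n.chains = chains, n.adapt = 200,
                          quiet = TRUE)
  stats::update(jm, n.iter = burn_in, progress.bar = "none")
  mcmc <- rjags::coda.samples(jm, "p", n.iter = samples,
                              progress.bar = "none")
  .mcmc_to_draws(mcmc)$p
}

#' Fit each cohort in a trial table
#'
#' Convenience wrapper running [fit_av_model()] once per cohort with
#' cohort-specific hyperparameters, as the analysis estimates the groups
#' separately.
#'
#' @inheritParams fit_av_model
#' @param ... passed on to [fit_av_model()].
#' @return Named list of \code{"av_fit"} objects, one per cohort.
#' @export
fit_cohorts <- function(trials, ...) {
  cohorts <- sort(unique(trials$cohort))
  fits <- lapply(cohorts, function(g)
    fit_av_model(trials[trials$cohort == g, , drop = FALSE], ...))
  names(fits) <- cohorts
  fits
}

.mcmc_to_draws <- function(mcmc) {
  pars <- colnames(mcmc[[1]])
  draws <- lapply(pars, function(p)
    vapply(mcmc, function(ch) as.numeric(ch[, p]),
           numeric(nrow(mcmc[[1]]))))
  names(draws) <- pars
  draws
}

.draw_matrices <- function(fit) fit$draws

.pooled <- function(fit, par) {
  m <- fit$draws[[par]]
  if (is.null(m)) stop("unknown parameter: ", par, call. = FALSE)
  as.numeric(m)
}

#' Posterior summary table
#'
#' Posterior mean and shortest 95% highest-density interval for each
#' requested parameter, plus split R-hat and effective sample size. Derived
#' quantities (e.g. task or group contrasts) are computed draw-wise from
#' the pooled chains, never from summary statistics.
#'
#' @param fit an \code{"av_fit"} object.
#' @param pars parameter names to summarize; defaults to the cohort-level
#'   parameters.
#' @param derived optional named list of functions; each receives a data
#'   frame of pooled draws (columns = all monitored parameters) and must
#'   return one numeric draw vector.
#' @param prob probability mass of the HDI.
#' @return Data frame with columns \code{parameter}, \code{mean},
#'   \code{hdi_low}, \code{hdi_high}, \code{rhat}, \code{ess}.
#' @export
posterior_summary <- function(fit, pars = NULL, derived = NULL, prob = 0.95) {
  stopifnot(inherits(fit, "av_fit"))
  if (is.null(pars))
    pars <- intersect(.GROUP_PARS, names(fit$draws))
  mats <- fit$draws[pars]
  if (length(derived)) {
    pool <- as.data.frame(lapply(fit$draws, as.numeric))
    names(pool) <- names(fit$draws)
    nchain <- ncol(fit$draws[[1]])
    for (nm in names(derived)) {
      v <- derived[[nm]](pool)
      if (length(v) != nrow(pool))
        stop("derived quantity '", nm, "' must return one value per draw",
             call. = FALSE)
      mats[[nm]] <- matrix(v, ncol = nchain)
    }
  }
  rows <- lapply(names(mats), function(nm) {
    m <- mats[[nm]]
    if (length(m) == 0) stop("empty sample array for ", nm, call. = FALSE)
    h <- hdi(as.numeric(m), prob)
    data.frame(parameter = nm, mean = mean(m),
               hdi_low = h[["lower"]], hdi_high = h[["upper"]],
               rhat = split_rhat(m), ess = ess(m))
  })
  do.call(rbind, rows)
}

#' @export
summary.av_fit <- function(object, pars = NULL, derived = NULL,
                           prob = 0.95, ...) {
  out <- posterior_summary(object, pars, derived, prob)
  structure(out, class = c("summary.av_fit", "data.frame"),
            cohort = object$cohort, constraint = object$constraint,
            variant = object$variant)
}

#' @export
print.summary.av_fit <- function(x, digits = 3, ...) {
  cat(sprintf("Posterior summary (cohort %s, %s, %s variant)\n",
              attr(x, "cohort"), attr(x, "constraint"), attr(x, "variant")))
  print.data.frame(x, digits = digits, row.names = FALSE)
  invisible(x)
}

#' @export
print.av_fit <- function(x, ...) {
  cat("Hierarchical audiovisual psychometric model fit\n")
  cat(sprintf("  cohort: %s (%d participants, %d trials)\n", x$cohort,
              length(x$participants), nrow(x$data)))
  cat(sprintf("  constraint: %s; AV variant: %s\n", x$constraint, x$variant))
  cat(sprintf("  MCMC: %d chains x %d retained after %d burn-in (seed %d, %.1f s)\n",
              x$chains, x$samples, x$burn_in, x$seed, x$runtime_s))
  d <- diagnose(x)
  cat(sprintf("  convergence: max Rhat %.3f, min ESS %.0f (%s)\n",
              max(d$rhat, na.rm = TRUE), min(d$ess, na.rm = TRUE),
              if (isTRUE(attr(d, "pass"))) "pass" else "CHECK"))
  cat(sprintf("  group threshold_a %.2f dB, width %.2f dB, theta_v %.2f px\n",
              mean(x$draws$group_threshold_a), mean(x$draws$group_width),
              mean(x$draws$group_theta_v)))
  invisible(x)
}

#' @export
coef.av_fit <- function(object, ...) {
  pars <- intersect(.GROUP_PARS, names(object$draws))
  pars <- setdiff(pars, "group_lapse_a_diff")
  vapply(object$draws[pars], mean, numeric(1))
}

#' Posterior-mean parameters for one participant
#'
#' @param fit an \code{"av_fit"} object.
#' @param participant_id participant identifier as in the trial table.
#' @return A [participant_params()] object at the posterior means.
#' @export
participant_estimates <- function(fit, participant_id) {
  i <- match(participant_id, fit$participants)
  if (is.na(i)) stop("unknown participant: ", participant_id, call. = FALSE)
  g <- function(p) mean(fit$draws[[sprintf("%s[%d]", p, i)]])
  participant_params(threshold_a = g("theta_a"), width = g("width"),
                     threshold_v = g("theta_v"),
                     lapse_a_focused = g("lapse_a_focused"),
                     lapse_a_divided = g("lapse_a_divided"),
                     lapse_v_focused = g("lapse_v_focused"),
                     lapse_v_divided = g("lapse_v_divided"))
}

#' Cohort-level posterior-mean parameters
#'
#' @param fit an \code{"av_fit"} object.
#' @return A [participant_params()] object at the cohort-level posterior
#'   means (useful for group psychometric curves and MEI surfaces).
#' @export
group_estimates <- function(fit) {
  m <- coef(fit)
  participant_params(threshold_a = m[["group_threshold_a"]],
                     width = m[["group_width"]],
                     threshold_v = m[["group_theta_v"]],
                     lapse_a_focused = m[["group_lapse_a_focused"]],
                     lapse_a_divided = m[["group_lapse_a_divided"]],
                     lapse_v_focused = m[["group_lapse_v_focused"]],
                     lapse_v_divided = m[["group_lapse_v_divided"]])
}

#' @export
predict.av_fit <- function(object, newdata = NULL, level = c("participant",
                                                             "group"), ...) {
  level <- match.arg(level)
  if (is.null(newdata)) newdata <- object$data
  if (level == "group" || is.null(newdata$participant_id)) {
    return(predict_recognition(newdata, group_estimates(object),
                               object$variant, object$guess_rate))
  }
  p <- numeric(nrow(newdata))
  for (id in unique(newdata$participant_id)) {
    sel <- newdata$participant_id == id
    p[sel] <- predict_recognition(newdata[sel, , drop = FALSE],
                                  participant_estimates(object, id),
                                  object$variant, object$guess_rate)
  }
  p
}

#' @export
residuals.av_fit <- function(object, ...) {
  object$data$n_correct / object$data$n_words - predict(object)
}

#' @export
simulate.av_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  p <- predict(object)
  out <- lapply(seq_len(nsim), function(s) {
    d <- object$data
    d$n_correct <- stats::rbinom(nrow(d), d$n_words, p)
    d
  })
  if (nsim == 1) out[[1]] else out
}

#' @export
plot.av_fit <- function(x, ...) {
  gp <- group_estimates(x)
  op <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  # auditory panel
  aud <- x$data[x$data$modality == "A", ]
  snr_grid <- seq(min(aud$snr_db, na.rm = TRUE) - 2,
                  max(aud$snr_db, na.rm = TRUE) + 2, length.out = 101)
  graphics::plot(snr_grid, apply_guess(apply_lapse(
    pf_auditory(snr_grid, gp$threshold_a, gp$width), gp$lapse_a_focused),
    x$guess_rate), type = "l", ylim = c(0, 1), xlab = "SNR (dB)",
    ylab = "proportion correct", main = paste(x$cohort, "auditory"))
  graphics::lines(snr_grid, apply_guess(apply_lapse(
    pf_auditory(snr_grid, gp$threshold_a, gp$width), gp$lapse_a_divided),
    x$guess_rate), lty = 2)
  obs <- stats::aggregate(cbind(pc = n_correct / n_words) ~ snr_db + task,
                          aud, mean)
  graphics::points(obs$snr_db, obs$pc,
                   pch = ifelse(obs$task == "focused", 1, 5))
  graphics::legend("topleft", lty = c(1, 2), bty = "n", cex = 0.8,
                   legend = c("focused", "divided"))
  # visual panel
  vis <- x$data[x$data$modality == "V" & !is.na(x$data$blur_px) &
                  x$data$blur_px < 70, ]
  blur_grid <- seq(0, max(c(vis$blur_px, 25)), length.out = 101)
  graphics::plot(blur_grid, apply_guess(apply_lapse(
    pf_visual(blur_grid, gp$threshold_v), gp$lapse_v_focused),
    x$guess_rate), type = "l", ylim = c(0, 1), xlab = "blur (px)",
    ylab = "proportion correct", main = paste(x$cohort, "visual"))
  if (nrow(vis)) {
    obs <- stats::aggregate(cbind(pc = n_correct / n_words) ~ blur_px,
                            vis, mean)
    graphics::points(obs$blur_px, obs$pc)
  }
  invisible(x)
}
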