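# Model comparison between the strict and trade-off probability-summation
# variants: binomial maximum likelihood per participant, BIC, and Table-style
# fit metrics (R^2 and mean signed error on condition-level proportions).

#' Binomial log-likelihood evaluator for a trial table
#'
#' Returns a closure computing the word-level binomial log-likelihood
#' \code{sum(log dbinom(n_correct, n_words, p))} of a full parameter set --
#' a named list of [participant_params()], one per participant -- with p
#' from [predict_recognition()] under the given audiovisual variant. The
#' log-likelihood is a sum over trials and therefore invariant to row
#' order.
#'
#' @param trials trial table (single or multiple cohorts).
#' @param variant audiovisual model variant.
#' @param guess_rate closed-set chance level.
#' @return Function taking \code{params_list} (named by participant id) and
#'   returning the scalar log-likelihood.
#' @export
build_loglik <- function(trials, variant = c("trade-off", "strict"),
                         guess_rate = 0.1) {
  variant <- match.arg(variant)
  trials <- .validate_trials(trials)
  ids <- unique(trials$participant_id)
  by_id <- split(trials, trials$participant_id)
  function(params_list) {
    miss <- setdiff(ids, names(params_list))
    if (length(miss))
      stop("missing parameters for participant(s): ",
           paste(miss, collapse = ", "), call. = FALSE)
    ll <- 0
    for (id in ids) {
      d <- by_id[[id]]
      p <- predict_recognition(d, params_list[[id]], variant, guess_rate)
      ll <- ll + sum(stats::dbinom(d$n_correct, d$n_words, p, log = TRUE))
    }
    ll
  }
}

# transform participant_params <-> unconstrained vector under a constraint
.pp_to_vec <- function(pp, constraint) {
  s <- .lapse_structure(constraint)
  v <- c(pp$threshold_a, log(pp$width), log(pp$threshold_v),
         stats::qlogis(pmin(pmax(pp$lapse_a_focused, 1e-6), 1 - 1e-6)))
  if (s$a_free)
    v <- c(v, stats::qlogis(pmin(pmax(pp$lapse_a_divided, 1e-6), 1 - 1e-6)))
  v <- c(v, stats::qlogis(pmin(pmax(pp$lapse_v_focused, 1e-6), 1 - 1e-6)))
  if (s$v_free)
    v <- c(v, stats::qlogis(pmin(pmax(pp$lapse_v_divided, 1e-6), 1 - 1e-6)))
  v
}

.vec_to_pp <- function(v, constraint) {
  s <- .lapse_structure(constraint)
  i <- 4
  laf <- stats::plogis(v[i])
  lad <- if (s$a_free) stats::plogis(v[(i <- i + 1)]) else laf
  lvf <- stats::plogis(v[(i <- i + 1)])
  lvd <- if (s$v_free) stats::plogis(v[(i <- i + 1)]) else lvf
  participant_params(threshold_a = v[1], width = exp(v[2]),
                     threshold_v = exp(v[3]),
                     lapse_a_focused = laf, lapse_a_divided = lad,
                     lapse_v_focused = lvf, lapse_v_divided = lvd)
}

#' Maximum-likelihood fit of the psychometric model
#'
#' Maximizes the word-level binomial likelihood per participant (the
#' likelihood separates across participants once no pooling is imposed)
#' with bounded quasi-Newton optimization on transformed parameters
#' (identity / log / logit scales). Each participant is multi-started from
#' the supplied initial values plus a generic fallback start, keeping the
#' best optimum.
#'
#' @param trials trial table.
#' @param init named list of [participant_params()] initial values (e.g.
#'   posterior means from [fit_av_model()], via [participant_estimates()]),
#'   or a single \code{participant_params} used for everyone.
#' @param variant audiovisual model variant.
#' @param constraint lapse-sharing constraint (fixes the free-parameter
#'   count per participant).
#' @param guess_rate closed-set chance level.
#' @return List with \code{params} (named list of ML estimates),
#'   \code{loglik}, \code{k} (total free parameters), \code{n_words} and
#'   \code{n_trials}.
#' @export
fit_ml <- function(trials, init = NULL,
                   variant = c("trade-off", "strict"),
                   constraint = "aud_free_vis_shared", guess_rate = 0.1) {
  variant <- match.arg(variant)
  trials <- .validate_trials(trials)
  ids <- unique(trials$participant_id)
  default_start <- participant_params(-8, 8, 15, 0.15, 0.2, 0.4)
  params <- list()
  ll_total <- 0
  for (id in ids) {
    d <- trials[trials$participant_id == id, , drop = FALSE]
    obj <- function(v) {
      pp <- .vec_to_pp(v, constraint)
      p <- predict_recognition(d, pp, variant, guess_rate)
      -sum(stats::dbinom(d$n_correct, d$n_words, p, log = TRUE))
    }
    ini <- if (is.null(init)) default_start
           else if (inherits(init, "participant_params")) init
           else init[[id]]
    starts <- unique(list(.pp_to_vec(ini, constraint),
                          .pp_to_vec(default_start, constraint)))
    best <- NULL
    for (st in starts) {
      res <- tryCatch(
        stats::optim(st, obj, method = "L-BFGS-B",
                     lower = c(-60, log(0.5), log(1),
                               rep(stats::qlogis(1e-4),
                                   n_free_params(constraint) - 3)),
                     upper = c(30, log(60), log(200),
                               rep(stats::qlogis(0.999),
                                   n_free_params(constraint) - 3))),
        error = function(e) NULL)
      if (!is.null(res) && (is.null(best) || res$value < best$value))
        best <- res
    }
    if (is.null(best)) stop("ML optimization failed for ", id, call. = FALSE)
    params[[id]] <- .vec_to_pp(best$par, constraint)
    ll_total <- ll_total - best$value
  }
  list(params = params, loglik = ll_total,
       k = n_free_params(constraint) * length(ids),
       n_words = sum(trials$n_words), n_trials = nrow(trials))
}

#' Bayesian Information Criterion
#'
#' \code{BIC = log(n) * k - 2 * loglik_max}: the maximized log-likelihood
#' penalized by the parameter count scaled with the log observation count.
#' Lower is better; differences (Delta BIC) compare models on the same data.
#'
#' @param n number of observations (>= 1).
#' @param k number of free parameters (>= 1).
#' @param loglik_max maximized log-likelihood.
#' @return The BIC value.
#' @export
bic <- function(n, k, loglik_max) {
  if (length(n) != 1 || !is.finite(n) || n < 1)
    stop("'n' must be a positive count", call. = FALSE)
  if (length(k) != 1 || !is.finite(k) || k < 1)
    stop("'k' must be a positive count", call. = FALSE)
  log(n) * k - 2 * loglik_max
}

#' Condition-level observed and predicted proportions
#'
#' Aggregates a trial table to unique stimulus conditions per participant
#' and attaches the model-predicted proportion correct.
#'
#' @param trials trial table.
#' @param params_list named list of [participant_params()].
#' @param variant audiovisual model variant.
#' @param guess_rate closed-set chance level.
#' @return Data frame with observed and predicted proportions per condition.
#' @export
condition_proportions <- function(trials, params_list,
                                  variant = c("trade-off", "strict"),
                                  guess_rate = 0.1) {
  variant <- match.arg(variant)
  trials <- .validate_trials(trials)
  key <- paste(trials$participant_id, trials$task, trials$modality,
               ifelse(is.na(trials$snr_db), "absent", trials$snr_db),
               ifelse(is.na(trials$blur_px), "absent", trials$blur_px))
  agg <- do.call(rbind, lapply(split(trials, key), function(d) {
    data.frame(participant_id = d$participant_id[1], cohort = d$cohort[1],
               task = d$task[1], modality = d$modality[1],
               snr_db = d$snr_db[1], blur_px = d$blur_px[1],
               n_words = sum(d$n_words),
               observed = sum(d$n_correct) / sum(d$n_words))
  }))
  rownames(agg) <- NULL
  agg$predicted <- NA_real_
  for (id in unique(agg$participant_id)) {
    sel <- agg$participant_id == id
    agg$predicted[sel] <- predict_recognition(agg[sel, , drop = FALSE],
                                              params_list[[id]], variant,
                                              guess_rate)
  }
  agg
}

#' Compare the strict and trade-off audiovisual model variants
#'
#' For each cohort and each variant, refits the model by maximum likelihood
#' (initialized at the supplied parameter values, typically posterior
#' means) and reports BIC, Delta BIC relative to the better variant within
#' the cohort, R-squared (squared Pearson correlation between observed and
#' predicted condition-level proportions) and mean signed error (mean of
#' observed minus predicted), plus the counts entering the BIC.
#'
#' Both variants share the same free parameters -- they differ only in
#' which task's auditory lapse predicts the audiovisual trials -- so Delta
#' BIC reflects fit alone. Observations are counted at the word level by
#' default.
#'
#' @param trials trial table (any number of cohorts).
#' @param init initial parameter values as in [fit_ml()]; may also be a
#'   named list of \code{"av_fit"} objects per cohort, whose participant
#'   posterior means are then used.
#' @param constraint lapse-sharing constraint.
#' @param n_unit observation count for the BIC: \code{"words"} (default) or
#'   \code{"sentences"}.
#' @param guess_rate closed-set chance level.
#' @return Data frame of class \code{"av_comparison"}: one row per cohort x
#'   variant with columns \code{cohort}, \code{variant}, \code{bic},
#'   \code{delta_bic}, \code{r_squared}, \code{mean_signed_error},
#'   \code{loglik}, \code{k}, \code{n}.
#' @export
compare_variants <- function(trials, init = NULL,
                             constraint = "aud_free_vis_shared",
                             n_unit = c("words", "sentences"),
                             guess_rate = 0.1) {
  n_unit <- match.arg(n_unit)
  trials <- .validate_trials(trials)
  rows <- list()
  for (cohort in sort(unique(trials$cohort))) {
    d <- trials[trials$cohort == cohort, , drop = FALSE]
    ini <- init
    if (is.list(init) && !inherits(init, "participant_params") &&
        !is.null(init[[cohort]]) && inherits(init[[cohort]], "av_fit")) {
      fit <- init[[cohort]]
      ini <- stats::setNames(
        lapply(fit$participants, participant_estimates, fit = fit),
        fit$participants)
    }
    for (variant in c("trade-off", "strict")) {
      ml <- fit_ml(d, ini, variant, constraint, guess_rate)
      n <- if (n_unit == "words") ml$n_words else ml$n_trials
      cp <- condition_proportions(d, ml$params, variant, guess_rate)
      rows[[length(rows) + 1L]] <- data.frame(
        cohort = cohort, variant = variant,
        bic = bic(n, ml$k, ml$loglik),
        r_squared = stats::cor(cp$observed, cp$predicted)^2,
        mean_signed_error = mean(cp$observed - cp$predicted),
        loglik = ml$loglik, k = ml$k, n = n)
    }
  }
  out <- do.call(rbind, rows)
  out$delta_bic <- stats::ave(out$bic, out$cohort, FUN = function(b) b - min(b))
  out <- out[, c("cohort", "variant", "bic", "delta_bic", "r_squared",
                 "mean_signed_error", "loglik", "k", "n")]
  class(out) <- c("av_comparison", "data.frame")
  out
}

#' @export
print.av_comparison <- function(x, digits = 3, ...) {
  cat("Audiovisual model comparison (probability summation variants)\n")
  print.data.frame(x, digits = digits, row.names = FALSE)
  invisible(x)
}
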