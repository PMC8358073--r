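#' Group-level hyperparameters for a cohort
#'
#' Location and spread of the between-participant distribution of each
#' psychometric parameter. Locations are on the natural scale (dB, pixels,
#' probability); spreads are the standard deviations of the distributions
#' participants are drawn from: Normal for the auditory threshold,
#' log-Normal for the (positive) width and visual threshold, logit-Normal
#' for the lapse probabilities. The spread names carry the transform:
#' \code{sd_threshold_a} (dB), \code{sd_log_width}, \code{sd_log_threshold_v},
#' \code{sd_logit_lapse}.
#'
#' @param cohort cohort label, e.g. "NH" or "CI".
#' @param threshold_a,width,threshold_v,lapse_a_focused,lapse_a_divided,lapse_v
#'   group-level locations (natural scale).
#' @param sd_threshold_a,sd_log_width,sd_log_threshold_v,sd_logit_lapse
#'   between-participant spreads; must be non-negative.
#' @param sd_logit_task_shift between-participant spread of the
#'   divided-minus-focused auditory lapse shift (logit scale). The shift is
#'   a within-participant task effect: each participant's divided-attention
#'   lapse is their focused-attention lapse trait plus this shift, rather
#'   than an independent draw.
#' @return Object of class \code{"group_hyperparams"}.
#' @seealso [nh_hyperparams()], [ci_hyperparams()], [draw_participants()]
#' @export
group_hyperparams <- function(cohort, threshold_a, width, threshold_v,
                              lapse_a_focused, lapse_a_divided, lapse_v,
                              sd_threshold_a = 1, sd_log_width = 0.15,
                              sd_log_threshold_v = 0.2,
                              sd_logit_lapse = 0.4,
                              sd_logit_task_shift = 0.2) {
  sds <- c(sd_threshold_a, sd_log_width, sd_log_threshold_v, sd_logit_lapse,
           sd_logit_task_shift)
  if (any(!is.finite(sds)) || any(sds < 0))
    stop("hyperparameter spreads must be non-negative and finite",
         call. = FALSE)
  if (width <= 0 || threshold_v <= 0)
    stop("'width' and 'threshold_v' locations must be positive", call. = FALSE)
  for (l in c(lapse_a_focused, lapse_a_divided, lapse_v))
    .check_prob(l, "lapse")
  structure(list(cohort = cohort,
                 threshold_a = threshold_a, width = width,
                 threshold_v = threshold_v,
                 lapse_a_focused = lapse_a_focused,
                 lapse_a_divided = lapse_a_divided,
                 lapse_v = lapse_v,
                 sd_threshold_a = sd_threshold_a,
                 sd_log_width = sd_log_width,
                 sd_log_threshold_v = sd_log_threshold_v,
                 sd_logit_lapse = sd_logit_lapse,
                 sd_logit_task_shift = sd_logit_task_shift),
            class = "group_hyperparams")
}

#' Default normal-hearing cohort hyperparameters
#'
#' Group locations describing a normal-hearing cohort on the Dutch Matrix
#' test: auditory threshold -12 dB SNR, width 7.4 dB, visual threshold
#' 18.3 px, visual lapse 0.54, focused-attention auditory lapse 0.111
#' (saturation ~90% correct after the 0.1 guess floor) and a small
#' divided-attention increase of 0.039. Between-participant spreads are not
#' separately identified by group summaries and are set to realistic values
#' (1 dB threshold spread; ~15-20% relative spread in width and visual
#' threshold; 0.4 logit units for lapses).
#'
#' @return A [group_hyperparams()] object with cohort "NH".
#' @export
nh_hyperparams <- function() {
  group_hyperparams("NH", threshold_a = -12, width = 7.4, threshold_v = 18.3,
                    lapse_a_focused = 1 - 0.8 / 0.9,
                    lapse_a_divided = 1 - 0.8 / 0.9 + 0.039,
                    lapse_v = 0.54,
                    sd_threshold_a = 1)
}

#' Default cochlear-implant cohort hyperparameters
#'
#' Group locations describing a post-lingually deaf, unilaterally implanted
#' cohort: auditory threshold -3.1 dB SNR, width 10.4 dB, visual threshold
#' 17.7 px, visual lapse 0.46, focused-attention auditory lapse 0.178
#' (saturation ~84% correct) and a large divided-attention increase of 0.22
#' -- the integration-attention trade-off signature. The threshold spread is
#' wider (2 dB) than for normal-hearing listeners, reflecting the larger
#' heterogeneity of implant outcomes.
#'
#' @return A [group_hyperparams()] object with cohort "CI".
#' @export
ci_hyperparams <- function() {
  group_hyperparams("CI", threshold_a = -3.1, width = 10.4, threshold_v = 17.7,
                    lapse_a_focused = 1 - 0.74 / 0.9,
                    lapse_a_divided = 1 - 0.74 / 0.9 + 0.22,
                    lapse_v = 0.46,
                    sd_threshold_a = 2)
}

#' Draw participants from a cohort distribution
#'
#' Samples participant-level psychometric parameters from the group
#' distributions: Normal on the auditory threshold, log-Normal on width and
#' visual threshold, logit-Normal on the lapse probabilities, so every draw
#' satisfies the parameter constraints by construction. The divided-task
#' auditory lapse is generated as the participant's focused-task lapse
#' trait plus a within-participant task shift on the logit scale (the
#' divided-attention cost), not as an independent trait. With all spreads
#' zero every participant equals the group locations.
#'
#' @param hyper a [group_hyperparams()] object.
#' @param n number of participants to draw.
#' @param seed optional integer seed for reproducible draws.
#' @return List of \code{n} [participant_params()] objects.
#' @export
draw_participants <- function(hyper, n, seed = NULL) {
  stopifnot(inherits(hyper, "group_hyperparams"), n >= 1)
  if (!is.null(seed)) set.seed(seed)
  shift0 <- stats::qlogis(hyper$lapse_a_divided) -
    stats::qlogis(hyper$lapse_a_focused)
  lapply(seq_len(n), function(i) {
    logit_laf <- stats::rnorm(1, stats::qlogis(hyper$lapse_a_focused),
                              hyper$sd_logit_lapse)
    shift <- stats::rnorm(1, shift0, hyper$sd_logit_task_shift)
    participant_params(
      threshold_a = stats::rnorm(1, hyper$threshold_a, hyper$sd_threshold_a),
      width = exp(stats::rnorm(1, log(hyper$width), hyper$sd_log_width)),
      threshold_v = exp(stats::rnorm(1, log(hyper$threshold_v),
                                     hyper$sd_log_threshold_v)),
      lapse_a_focused = stats::plogis(logit_laf),
      lapse_a_divided = stats::plogis(logit_laf + shift),
      lapse_v = stats::plogis(stats::rnorm(
        1, stats::qlogis(hyper$lapse_v), hyper$sd_logit_lapse)))
  })
}

# Cap on the stimulus-driven probability used when inverting the auditory
# psychometric function: performance targets above the participant's lapse
# ceiling cannot be reached at any finite SNR and are clipped here.
.F_CAP <- 0.99

#' Individualized stimulus levels for target performance
#'
#' Inverts the psychometric chain (psychometric function, lapse, guess) to
#' find the SNR or blur at which a participant's predicted unisensory
#' proportion correct equals each target -- the role the adaptive
#' familiarization track plays in the live experiment. Targets at or below
#' the 0.1 guess floor map to an SNR far below threshold (or maximal blur);
#' targets above the participant's lapse-limited ceiling are clipped to it
#' with a warning, mirroring participants whose maximum performance never
#' reached the intended level.
#'
#' @param params a [participant_params()] object.
#' @param targets desired proportions correct (post-guess scale), in \[0, 1).
#' @param modality "A" (returns SNRs in dB) or "V" (returns blurs in px).
#' @param task task whose lapse probability applies; levels are
#'   individualized from focused-attention performance.
#' @param guess_rate closed-set chance level.
#' @return Numeric vector of stimulus levels, one per target.
#' @export
#' @examples
#' p <- participant_params(-12, 7.4, 18.3, lapse_a_focused = 0.11, lapse_v = 0.54)
#' individualize_levels(p, c(0.25, 0.5, 0.75), modality = "A")
individualize_levels <- function(params, targets, modality = c("A", "V"),
                                 task = "focused", guess_rate = 0.1) {
  modality <- match.arg(modality)
  if (any(targets < 0 | targets >= 1))
    stop("'targets' must lie in [0, 1)", call. = FALSE)
  lapse <- .lapse_of(params, tolower(modality), task)
  # invert guess and lapse: target = (1-g)*(1-lambda)*F + g
  f <- (targets - guess_rate) / ((1 - guess_rate) * (1 - lapse))
  if (modality == "A") {
    f[targets <= guess_rate] <- 1e-9    # far below threshold: floor target
    clip <- f > .F_CAP
    if (any(clip)) {
      warning(sprintf("%d target(s) above the lapse-limited ceiling; clipped",
                      sum(clip)), call. = FALSE)
      f[clip] <- .F_CAP
    }
    params$threshold_a + params$width / (2 * log(9)) * stats::qlogis(f)
  } else {
    clip <- f >= 1
    if (any(clip)) {
      warning(sprintf("%d target(s) above the lapse-limited ceiling; clipped to blur 0",
                      sum(clip)), call. = FALSE)
      f[clip] <- 1
    }
    f[targets <= guess_rate] <- pf_visual(70, params$threshold_v)  # maximal blur
    params$threshold_v * sqrt(-log(f))
  }
}

#' Build a Matrix-test session design
#'
#' Lays out the trials of one experimental session for one participant.
#' The focused-attention session consists of an auditory-only block
#' (individualized SNRs spanning the psychometric range, uninformative
#' 70-px-blurred video) and a visual-only block (blurs 0, 6, 12, 16 and 20
#' px by default, no acoustic signal). The divided-attention session
#' interleaves one block of trials drawn from a 5 x 5 grid: four
#' individualized SNRs plus a signal-absent column, crossed with four
#' individualized blurs plus a 70-px row, so unisensory auditory (blur 70),
#' unisensory visual (no signal) and audiovisual trials are mixed in
#' pseudo-random order. Sentences are never repeated within a session;
#' identity is tracked as a unique id.
#'
#' @param task "focused" or "divided".
#' @param params a [participant_params()] object used to individualize levels.
#' @param n_auditory,n_visual sentences per focused-attention block (40-60).
#' @param n_divided trials in the divided-attention block (80-120).
#' @param n_snr number of individualized SNRs in the focused auditory block
#'   (4-12).
#' @param blur_levels blurs of the focused visual block, pixels (5-10 values).
#' @param targets_divided_snr unisensory auditory performance targets
#'   defining the four informative SNRs of the divided-attention grid (the
#'   fifth column is signal-absent).
#' @param targets_divided_blur visual performance targets defining the four
#'   informative blurs (the fifth row is the uninformative 70-px blur);
#'   pitched below the lapse-limited lipreading ceiling.
#' @param guess_rate closed-set chance level.
#' @return Data frame of trials with columns \code{task}, \code{modality},
#'   \code{snr_db}, \code{blur_px}, \code{sentence_id}, \code{n_words}.
#' @export
build_design <- function(task = c("focused", "divided"), params,
                         n_auditory = 40, n_visual = 40, n_divided = 100,
                         n_snr = 8, blur_levels = c(0, 6, 12, 16, 20),
                         targets_divided_snr = c(0.1, 0.25, 0.5, 0.75),
                         targets_divided_blur = c(0.2, 0.3, 0.4, 0.5),
                         guess_rate = 0.1) {
  task <- match.arg(task)
  if (task == "focused") {
    if (n_auditory < 40 || n_auditory > 60 || n_visual < 40 || n_visual > 60)
      stop("focused-attention blocks use 40-60 sentences", call. = FALSE)
    if (n_snr < 4 || n_snr > 12)
      stop("the auditory block uses 4-12 individualized SNRs", call. = FALSE)
    if (length(blur_levels) < 5 || length(blur_levels) > 10)
      stop("the visual block uses 5-10 blur levels", call. = FALSE)
    # SNRs spanning the rising part of the individual psychometric function
    snr_targets <- seq(0.15, 0.85, length.out = n_snr)
    snrs <- suppressWarnings(
      individualize_levels(params, snr_targets, "A", "focused", guess_rate))
    aud <- data.frame(task = task, modality = "A",
                      snr_db = rep_len(snrs, n_auditory),
                      blur_px = 70)
    vis <- data.frame(task = task, modality = "V",
                      snr_db = NA_real_,
                      blur_px = rep_len(blur_levels, n_visual))
    design <- rbind(aud, vis)
    # pseudo-random order within each block, blocks kept separate
    design <- design[c(sample(seq_len(n_auditory)),
                       n_auditory + sample(seq_len(n_visual))), ]
  } else {
    if (n_divided < 80 || n_divided > 120)
      stop("the divided-attention block uses 80-120 trials", call. = FALSE)
    snrs <- suppressWarnings(
      individualize_levels(params, targets_divided_snr, "A", "focused",
                           guess_rate))
    blurs <- suppressWarnings(
      individualize_levels(params, targets_divided_blur, "V", "focused",
                           guess_rate))
    grid <- expand.grid(snr_db = c(snrs, NA_real_),
                        blur_px = c(blurs, 70))
    grid$modality <- ifelse(is.na(grid$snr_db), "V",
                            ifelse(grid$blur_px == 70, "A", "AV"))
    # balanced allocation over the 25 combinations, remainder spread randomly
    reps <- rep(n_divided %/% nrow(grid), nrow(grid))
    extra <- n_divided %% nrow(grid)
    if (extra > 0)
      reps <- reps + as.integer(seq_len(nrow(grid)) %in%
                                  sample(nrow(grid), extra))
    design <- grid[rep(seq_len(nrow(grid)), reps), ]
    design$task <- task
    design <- design[sample(nrow(design)), c("task", "modality", "snr_db",
                                             "blur_px")]
  }
  design$sentence_id <- seq_len(nrow(design))  # unique: no sentence repeats
  design$n_words <- 5L
  rownames(design) <- NULL
  design
}

#' Simulate Matrix-test responses for a session design
#'
#' Draws the number of correctly recognized words per sentence as
#' Binomial(n_words, p), with p the [predict_recognition()] probability of
#' each trial under the given generating model variant. Words within a
#' sentence are treated as independent recognitions, matching the binomial
#' observation model used for fitting.
#'
#' @param design a design from [build_design()].
#' @param params the generating [participant_params()].
#' @param truth_variant generating model for audiovisual trials,
#'   \code{"trade-off"} (default) or \code{"strict"}.
#' @param seed optional integer seed.
#' @param guess_rate closed-set chance level.
#' @return The design with columns \code{p_true} and \code{n_correct} added.
#' @export
simulate_responses <- function(design, params,
                               truth_variant = c("trade-off", "strict"),
                               seed = NULL, guess_rate = 0.1) {
  truth_variant <- match.arg(truth_variant)
  if (!is.null(seed)) set.seed(seed)
  p <- predict_recognition(design, params, truth_variant, guess_rate)
  design$p_true <- p
  design$n_correct <- stats::rbinom(nrow(design), design$n_words, p)
  design
}

#' Simulate a full two-cohort study
#'
#' Draws normal-hearing and cochlear-implant cohorts from their group
#' distributions, builds a focused-attention and a divided-attention session
#' per participant, and simulates all responses. This is the generative twin
#' of the hierarchical model and the stand-in for a real data set in all
#' examples and tests.
#'
#' @param hypers list of [group_hyperparams()] objects, one per cohort.
#' @param n integer vector of cohort sizes, same length as \code{hypers}.
#' @param tasks sessions to run per participant.
#' @param truth_variant generating audiovisual model variant.
#' @param seed integer seed governing cohort draws and responses.
#' @param ... further design arguments passed to [build_design()].
#' @return List with \code{trials} (one row per sentence; columns
#'   \code{participant_id}, \code{cohort}, \code{task}, \code{modality},
#'   \code{snr_db}, \code{blur_px}, \code{n_words}, \code{n_correct}) and
#'   \code{truth} (the generating participant parameters, one row each).
#' @export
#' @examples
#' sim <- simulate_cohort(n = c(2, 2), seed = 1)
#' head(sim$trials)
simulate_cohort <- function(hypers = list(nh_hyperparams(), ci_hyperparams()),
                            n = c(14, 7),
                            tasks = c("focused", "divided"),
                            truth_variant = "trade-off", seed = 1, ...) {
  stopifnot(length(hypers) == length(n))
  set.seed(seed)
  trials <- list()
  truth <- list()
  for (g in seq_along(hypers)) {
    cohort <- hypers[[g]]$cohort
    parts <- draw_participants(hypers[[g]], n[g])
    for (i in seq_along(parts)) {
      pid <- sprintf("%s%02d", cohort, i)
      pp <- parts[[i]]
      for (task in tasks) {
        des <- build_design(task, pp, ...)
        des <- simulate_responses(des, pp, truth_variant)
        des$participant_id <- pid
        des$cohort <- cohort
        trials[[length(trials) + 1L]] <- des
      }
      truth[[length(truth) + 1L]] <-
        data.frame(participant_id = pid, cohort = cohort,
                   as.data.frame(unclass(pp)))
    }
  }
  trials <- do.call(rbind, trials)
  cols <- c("participant_id", "cohort", "task", "modality", "snr_db",
            "blur_px", "n_words", "n_correct")
  list(trials = trials[, cols], truth = do.call(rbind, truth))
}
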