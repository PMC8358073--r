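#' Auditory psychometric function (logistic in signal-to-noise ratio)
#'
#' Word-recognition probability for auditory speech in noise as a logistic
#' function of the acoustic signal-to-noise ratio. The curve passes through
#' 0.5 at the recognition threshold and is parameterized by the width
#' \code{width}, the SNR range over which it rises from 0.1 to 0.9, so that
#' the slope factor is \code{2 * log(9) / width}.
#'
#' @param snr acoustic signal-to-noise ratio(s) in dB.
#' @param threshold auditory recognition threshold in dB SNR (50% point).
#' @param width width of the psychometric function in dB (0.1-to-0.9 range);
#'   must be positive.
#' @return Recognition probability in (0, 1), same length as \code{snr}.
#' @seealso [pf_visual()], [apply_lapse()], [predict_recognition()]
#' @export
#' @examples
#' pf_auditory(-12, threshold = -12, width = 7.4)     # 0.5 at threshold
#' pf_auditory(-12 + 7.4 / 2, -12, 7.4)               # 0.9 at threshold + width/2
pf_auditory <- function(snr, threshold, width) {
  if (any(!is.finite(width)) || any(width <= 0))
    stop("'width' must be a positive, finite number", call. = FALSE)
  stats::plogis(2 * log(9) / width * (snr - threshold))
}

#' Visual psychometric function (exponential in blur)
#'
#' Word-recognition probability for visual speech (lipreading) as a
#' decreasing exponential of the Gaussian blur applied to the video,
#' \code{exp(-blur^2 / threshold^2)}. At \code{blur == threshold} the value
#' is \code{exp(-1)}, i.e. 36.8% recognition.
#'
#' @param blur standard deviation of the Gaussian blur in pixels; must be
#'   non-negative.
#' @param threshold visual recognition threshold in pixels; must be positive.
#' @return Recognition probability in (0, 1], same length as \code{blur}.
#' @export
#' @examples
#' pf_visual(0, threshold = 18.3)    # 1: unblurred video
#' pf_visual(18.3, threshold = 18.3) # exp(-1) = 0.368
pf_visual <- function(blur, threshold) {
  if (any(!is.finite(threshold)) || any(threshold <= 0))
    stop("'threshold' must be a positive, finite number", call. = FALSE)
  if (any(blur < 0, na.rm = TRUE))
    stop("'blur' must be non-negative", call. = FALSE)
  exp(-blur^2 / threshold^2)
}

#' Apply a lapse probability to a psychometric value
#'
#' With probability \code{lapse} the observer responds independently of the
#' stimulus (an attentional lapse), capping asymptotic performance at
#' \code{1 - lapse}: \code{psi = (1 - lapse) * p}.
#'
#' @param p stimulus-driven recognition probability, in \[0, 1\].
#' @param lapse lapse probability, in \[0, 1\].
#' @return Lapse-adjusted recognition probability \code{psi}.
#' @export
apply_lapse <- function(p, lapse) {
  .check_prob(p, "p")
  .check_prob(lapse, "lapse")
  (1 - lapse) * p
}

#' Apply the closed-set guess correction
#'
#' In a 10-alternative Matrix test a word is recognized by chance with
#' probability 0.1, independent of the stimulus. The observed proportion
#' correct is therefore \code{(1 - guess_rate) * psi + guess_rate}, mapping
#' \[0, 1\] onto \[0.1, 1\].
#'
#' @param psi lapse-adjusted recognition probability, in \[0, 1\].
#' @param guess_rate chance level of the closed-set response; 0.1 for the
#'   10-alternative Matrix test.
#' @return Predicted proportion correct, in \[\code{guess_rate}, 1\].
#' @export
apply_guess <- function(psi, guess_rate = 0.1) {
  .check_prob(psi, "psi")
  .check_prob(guess_rate, "guess_rate")
  (1 - guess_rate) * psi + guess_rate
}

#' Probability summation of two independent channels
#'
#' Race-model prediction for audiovisual recognition without neural
#' integration: a word is missed only if both the auditory and the visual
#' channel miss it, so \code{psi_sum = psi_a + psi_v - psi_a * psi_v}.
#'
#' @param psi_a,psi_v channel recognition probabilities, in \[0, 1\].
#' @return Combined recognition probability; always at least
#'   \code{max(psi_a, psi_v)} and at most \code{min(1, psi_a + psi_v)}.
#' @export
prob_summation <- function(psi_a, psi_v) {
  .check_prob(psi_a, "psi_a")
  .check_prob(psi_v, "psi_v")
  psi_a + psi_v - psi_a * psi_v
}

.check_prob <- function(x, name) {
  if (any(x < 0 | x > 1, na.rm = TRUE))
    stop(sprintf("'%s' must lie in [0, 1]", name), call. = FALSE)
  invisible(x)
}

#' Participant-level psychometric parameters
#'
#' Bundles the parameters of the unisensory psychometric functions and the
#' task-dependent lapse probabilities for one participant (or for a group,
#' when evaluated at group-level means). In the final model only the
#' auditory lapse varies between the focused- and divided-attention tasks;
#' the visual lapse is shared, which is the default here.
#'
#' @param threshold_a auditory recognition threshold, dB SNR.
#' @param width auditory psychometric width (0.1-to-0.9 range), dB; positive.
#' @param threshold_v visual recognition threshold, pixels; positive.
#' @param lapse_a_focused,lapse_a_divided auditory lapse probability in the
#'   focused- and divided-attention tasks.
#' @param lapse_v visual lapse probability shared across tasks (default
#'   parameterization); ignored if both task-specific visual lapses are given.
#' @param lapse_v_focused,lapse_v_divided task-specific visual lapses;
#'   default to \code{lapse_v}.
#' @return An object of class \code{"participant_params"} (a named list).
#' @export
#' @examples
#' # group-level means for a cochlear-implant cohort
#' participant_params(threshold_a = -3.1, width = 10.4, threshold_v = 17.7,
#'                    lapse_a_focused = 0.178, lapse_a_divided = 0.398,
#'                    lapse_v = 0.46)
participant_params <- function(threshold_a, width, threshold_v,
                               lapse_a_focused = 0,
                               lapse_a_divided = lapse_a_focused,
                               lapse_v = 0,
                               lapse_v_focused = lapse_v,
                               lapse_v_divided = lapse_v) {
  if (!is.finite(width) || width <= 0)
    stop("'width' must be positive", call. = FALSE)
  if (!is.finite(threshold_v) || threshold_v <= 0)
    stop("'threshold_v' must be positive", call. = FALSE)
  for (l in c(lapse_a_focused, lapse_a_divided, lapse_v_focused, lapse_v_divided))
    .check_prob(l, "lapse")
  structure(list(threshold_a = threshold_a, width = width,
                 threshold_v = threshold_v,
                 lapse_a_focused = lapse_a_focused,
                 lapse_a_divided = lapse_a_divided,
                 lapse_v_focused = lapse_v_focused,
                 lapse_v_divided = lapse_v_divided),
            class = "participant_params")
}

#' @export
print.participant_params <- function(x, ...) {
  cat("Psychometric parameters\n")
  cat(sprintf("  auditory: threshold %.2f dB SNR, width %.2f dB\n",
              x$threshold_a, x$width))
  cat(sprintf("  visual:   threshold %.2f px\n", x$threshold_v))
  cat(sprintf("  lapses:   A focused %.3f, A divided %.3f, V focused %.3f, V divided %.3f\n",
              x$lapse_a_focused, x$lapse_a_divided,
              x$lapse_v_focused, x$lapse_v_divided))
  invisible(x)
}

.lapse_of <- function(params, modality = c("a", "v"), task) {
  modality <- match.arg(modality)
  unlist(params[paste0("lapse_", modality, "_", task)], use.names = FALSE)
}

#' Predicted word-recognition probability for stimulus conditions
#'
#' Chains the unisensory psychometric functions, lapse adjustment,
#' probability summation (for audiovisual stimuli) and the closed-set guess
#' correction into the predicted proportion of words recognized.
#'
#' Unisensory conditions use the lapse probability of their own task. For
#' audiovisual conditions (which occur in the divided-attention task) the
#' two model variants differ in which task's auditory lapse feeds the
#' prediction: the \emph{strict} probability-summation model uses the
#' divided-attention lapse, the \emph{trade-off} model the (smaller)
#' focused-attention lapse, crediting multisensory stimulation with a
#' release from the divided-attention lapse. The guess correction is applied
#' after probability summation, i.e. a single closed-set response is made on
#' the combined percept.
#'
#' An absent acoustic signal is encoded as \code{NA} in \code{snr_db} and
#' contributes zero to the race; likewise an absent/blank video is \code{NA}
#' in \code{blur_px}. Auditory-only trials of the divided-attention task
#' carry a 70-pixel blur, which simply yields a numerically negligible
#' visual channel.
#'
#' @param conditions data frame with columns \code{modality} ("A", "V" or
#'   "AV"), \code{task} ("focused" or "divided"), \code{snr_db} (dB, NA when
#'   no acoustic signal) and \code{blur_px} (pixels, NA when no video).
#' @param params a [participant_params()] object.
#' @param variant \code{"trade-off"} or \code{"strict"}; only affects
#'   audiovisual conditions.
#' @param guess_rate closed-set chance level, 0.1 for the Matrix test.
#' @return Numeric vector of predicted proportions correct, one per row.
#' @export
#' @examples
#' ci <- participant_params(-3.1, 10.4, 17.7, 0.178, 0.398, 0.46)
#' av <- data.frame(modality = "AV", task = "divided", snr_db = 0, blur_px = 20)
#' predict_recognition(av, ci, variant = "trade-off")
predict_recognition <- function(conditions, params,
                                variant = c("trade-off", "strict"),
                                guess_rate = 0.1) {
  variant <- match.arg(variant)
  stopifnot(is.data.frame(conditions))
  need <- c("modality", "task", "snr_db", "blur_px")
  miss <- setdiff(need, names(conditions))
  if (length(miss))
    stop("'conditions' lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  modality <- as.character(conditions$modality)
  task <- as.character(conditions$task)
  if (!all(modality %in% c("A", "V", "AV")))
    stop("modality must be one of 'A', 'V', 'AV'", call. = FALSE)
  if (!all(task %in% c("focused", "divided")))
    stop("task must be 'focused' or 'divided'", call. = FALSE)
  snr <- conditions$snr_db
  blur <- conditions$blur_px
  if (any(modality == "AV" & (is.na(snr) | is.na(blur))))
    stop("audiovisual conditions require both snr_db and blur_px",
         call. = FALSE)
  if (any(modality == "V" & !is.na(snr)))
    stop("visual-only conditions must have no acoustic signal (snr_db = NA)",
         call. = FALSE)

  # task whose lapse applies: the condition's own task for unisensory
  # stimuli; the variant-defining task for audiovisual stimuli
  variant_task <- if (variant == "trade-off") "focused" else "divided"
  lapse_task <- ifelse(modality == "AV", variant_task, task)

  has_a <- !is.na(snr)
  has_v <- !is.na(blur)
  psi_a <- numeric(length(snr))
  psi_v <- numeric(length(blur))
  if (any(has_a)) {
    fa <- pf_auditory(snr[has_a], params$threshold_a, params$width)
    psi_a[has_a] <- apply_lapse(fa, .lapse_of(params, "a", lapse_task[has_a]))
  }
  if (any(has_v)) {
    fv <- pf_visual(blur[has_v], params$threshold_v)
    psi_v[has_v] <- apply_lapse(fv, .lapse_of(params, "v", lapse_task[has_v]))
  }
  apply_guess(prob_summation(psi_a, psi_v), guess_rate)
}

#' Multisensory enhancement index
#'
#' Ratio of the trade-off to the strict probability-summation prediction,
#' minus one: \code{MEI = psi_tradeoff / psi_strict - 1}, with both
#' predictions taken after the guess correction. Zero when the auditory
#' lapse does not differ between tasks (pure statistical facilitation);
#' positive when the divided-attention lapse exceeds the focused-attention
#' lapse, i.e. when multisensory stimulation releases performance that
#' divided attention had suppressed.
#'
#' @inheritParams predict_recognition
#' @return Numeric vector of MEI values, one per condition row.
#' @export
#' @examples
#' ci <- participant_params(-3.1, 10.4, 17.7, 0.178, 0.398, 0.46)
#' mei(data.frame(modality = "AV", task = "divided", snr_db = 0, blur_px = 20), ci)
mei <- function(conditions, params, guess_rate = 0.1) {
  if (any(as.character(conditions$modality) != "AV"))
    stop("MEI is defined for audiovisual conditions only", call. = FALSE)
  p_trade <- predict_recognition(conditions, params, "trade-off", guess_rate)
  p_strict <- predict_recognition(conditions, params, "strict", guess_rate)
  p_trade / p_strict - 1
}

#' Multisensory enhancement index over a stimulus grid
#'
#' Evaluates [mei()] on the full grid of acoustic signal-to-noise ratios and
#' visual blurs, e.g. to map where multisensory enhancement is largest
#' (typically at high blur and favourable SNR, declining toward low SNR
#' where the visual channel dominates both variants).
#'
#' @param params a [participant_params()] object (e.g. cohort-level means).
#' @param snr_grid numeric vector of SNRs in dB.
#' @param blur_grid numeric vector of blurs in pixels.
#' @param guess_rate closed-set chance level.
#' @return Matrix of MEI values with one row per SNR and one column per
#'   blur, dimnames giving the grid values.
#' @export
mei_surface <- function(params, snr_grid, blur_grid, guess_rate = 0.1) {
  grid <- expand.grid(snr_db = snr_grid, blur_px = blur_grid)
  grid$modality <- "AV"
  grid$task <- "divided"
  vals <- mei(grid, params, guess_rate)
  matrix(vals, nrow = length(snr_grid), ncol = length(blur_grid),
         dimnames = list(snr_db = format(snr_grid, trim = TRUE),
                         blur_px = format(blur_grid, trim = TRUE)))
}
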