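#' Write a trial table to CSV
#'
#' Writes one row per sentence with the canonical column set
#' (\code{participant_id, cohort, task, modality, snr_db, blur_px, n_words,
#' n_correct}); an absent stimulus dimension (no acoustic signal, no video)
#' is written as an empty field.
#'
#' @param trials trial data frame.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_trials <- function(trials, path) {
  trials <- .validate_trials(trials)
  utils::write.csv(trials[, .TRIAL_COLS], path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a trial table from CSV
#'
#' Reads and validates a trial table written by [write_trials()] (or
#' assembled elsewhere with the same schema). Schema violations are
#' reported with the offending row numbers.
#'
#' @param path CSV file path.
#' @return Validated trial data frame.
#' @export
read_trials <- function(path) {
  trials <- utils::read.csv(path, stringsAsFactors = FALSE)
  .validate_trials(trials)
}

.TRIAL_COLS <- c("participant_id", "cohort", "task", "modality",
                 "snr_db", "blur_px", "n_words", "n_correct")

.validate_trials <- function(trials) {
  stopifnot(is.data.frame(trials))
  miss <- setdiff(.TRIAL_COLS, names(trials))
  if (length(miss))
    stop("trial table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  .bad_rows <- function(bad, what) {
    if (any(bad))
      stop(sprintf("%s in trial row(s) %s", what,
                   paste(utils::head(which(bad), 10), collapse = ", ")),
           call. = FALSE)
  }
  trials$modality <- as.character(trials$modality)
  trials$task <- as.character(trials$task)
  .bad_rows(!trials$modality %in% c("A", "V", "AV"),
            "invalid modality (want A, V or AV)")
  .bad_rows(!trials$task %in% c("focused", "divided"),
            "invalid task (want focused or divided)")
  .bad_rows(is.na(trials$snr_db) & is.na(trials$blur_px),
            "both stimulus dimensions absent")
  .bad_rows(trials$modality == "AV" &
              (is.na(trials$snr_db) | is.na(trials$blur_px)),
            "audiovisual trial missing snr_db or blur_px")
  .bad_rows(trials$modality == "V" & !is.na(trials$snr_db),
            "visual-only trial with an acoustic signal")
  .bad_rows(!is.na(trials$blur_px) & trials$blur_px < 0, "negative blur_px")
  .bad_rows(is.na(trials$n_words) | trials$n_words < 1, "invalid n_words")
  .bad_rows(is.na(trials$n_correct) | trials$n_correct < 0 |
              trials$n_correct > trials$n_words,
            "n_correct outside 0..n_words")
  trials
}
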