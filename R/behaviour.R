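# Behavioural intelligibility indices: comparable 0-1 comprehension scores
# for humans (proportion of words understood) and dogs (rescaled mean of
# best command-response scores on the 1-5 scale).

#' Human intelligibility index
#'
#' Proportion of correctly comprehended words out of the words presented.
#'
#' @param words_understood integer count, 0..`total`.
#' @param total words in the stream (default 5).
#' @return value in `[0, 1]`.
#' @export
human_intelligibility <- function(words_understood, total = 5) {
  if (!is.numeric(words_understood) || words_understood < 0 ||
      words_understood > total)
    abort_canicoh("words_understood must lie in 0..total",
                  "canicoh_invalid_input")
  words_understood / total
}

#' Dog intelligibility index
#'
#' From a long response table (one row per presentation) for one subject
#' and condition: take the maximum behavioural score (1-5 scale) over the
#' up-to-3 presentations of each command, average over commands, and map
#' to `[0, 1]` by (mean - 1) / 4. Two rater columns (`score`, `score2`) are
#' resolved at ingestion by taking the lower score.
#'
#' @param table data.frame with columns `subject`, `condition`,
#'   `command_word`, `presentation`, `score` (and optionally `score2`).
#' @param subject,condition which rows to score.
#' @return value in `[0, 1]`.
#' @export
dog_intelligibility <- function(table, subject, condition) {
  need <- c("subject", "condition", "command_word", "score")
  if (!all(need %in% names(table)))
    abort_canicoh("table must have subject, condition, command_word, score",
                  "canicoh_invalid_input")
  sc <- table$score
  if ("score2" %in% names(table)) sc <- pmin(sc, table$score2)
  if (!all(sc %in% 1:5))
    abort_canicoh("scores must be integers 1..5", "canicoh_invalid_input")
  rows <- table$subject == subject & table$condition == condition
  if (!any(rows))
    abort_canicoh("no rows for that subject/condition", "canicoh_not_found")
  best <- tapply(sc[rows], table$command_word[rows], max)
  (mean(best) - 1) / 4
}
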