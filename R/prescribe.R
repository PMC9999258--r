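# Difficulty initialization from the enrollment Fugl-Meyer score and the
# once-daily prescription adaptation rule.
#
# Training difficulty is set from the FMA total at enrollment and then
# adapted at most once per calendar day from the change in the game-derived
# session score: changes of 5 points or less leave the prescription
# untouched; larger improvements step the difficulty up one level, larger
# declines step it down one level.

#' Initial difficulty from the enrollment FMA total
#'
#' Banded mapping of the Fugl-Meyer total (0-100) to a difficulty level.
#' Default bands: [0, 33] easy, [34, 66] moderate, [67, 100] hard. The cut
#' points are configurable; the mapping is monotone non-decreasing.
#'
#' @param fma_total Enrollment FMA total score in [0, 100].
#' @param cuts Length-2 increasing vector: lowest totals mapped to
#'   moderate and to hard, respectively. Default \code{c(34, 67)}.
#' @return One of \code{"easy"}, \code{"moderate"}, \code{"hard"}.
#' @examples
#' initial_difficulty(50)
#' @export
initial_difficulty <- function(fma_total, cuts = c(34, 67)) {
  assert_scalar_number(fma_total, "fma_total", lower = 0, upper = 100)
  stopifnot(length(cuts) == 2, cuts[1] < cuts[2])
  if (fma_total < cuts[1]) "easy"
  else if (fma_total < cuts[2]) "moderate"
  else "hard"
}

#' A prescription item
#'
#' @param exercise_id Catalog exercise id.
#' @param difficulty Difficulty level.
#' @param target_reps Repetitions prescribed per session.
#' @param session_minutes Session length in minutes (default 30; two
#'   sessions per day is the default regimen).
#' @param sessions_per_day Sessions per day (default 2).
#' @return An object of class \code{prescription_item}.
#' @export
prescription_item <- function(exercise_id, difficulty, target_reps = 10,
                              session_minutes = 30, sessions_per_day = 2) {
  get_exercise(exercise_id)  # validates the id
  difficulty <- match.arg(difficulty, DIFFICULTY_LEVELS)
  assert_scalar_number(target_reps, "target_reps", lower = 0)
  assert_scalar_number(session_minutes, "session_minutes", lower = 0)
  structure(
    list(exercise_id = exercise_id, difficulty = difficulty,
         target_reps = as.integer(target_reps),
         session_minutes = session_minutes,
         sessions_per_day = as.integer(sessions_per_day)),
    class = "prescription_item"
  )
}

#' Adaptation state for the once-daily rule
#'
#' @param last_adjust_date Date of the last adjustment (or \code{NULL}).
#' @param last_session_score Session score (0-100) at the last adjustment.
#' @return An object of class \code{adaptation_state}.
#' @export
adaptation_state <- function(last_adjust_date = NULL,
                             last_session_score = 0) {
  assert_scalar_number(last_session_score, "last_session_score",
                       lower = 0, upper = 100)
  structure(
    list(last_adjust_date = last_adjust_date,
         last_session_score = last_session_score),
    class = "adaptation_state"
  )
}

#' Adapt the difficulty once per day from the session score
#'
#' At most one adjustment happens per calendar date. A change in session
#' score of 5 points or less requires no adjustment; an improvement of
#' more than 5 points steps the difficulty one level harder (capped at
#' hard), a decline of more than 5 points steps it one level easier
#' (floored at easy).
#'
#' @param state An \code{\link{adaptation_state}}.
#' @param new_score Latest session score in [0, 100].
#' @param current Current difficulty level.
#' @param today Calendar date of the adaptation attempt (a \code{Date} or
#'   anything comparable with \code{identical}).
#' @return List with \code{difficulty} (possibly updated) and
#'   \code{state} (updated \code{adaptation_state}).
#' @examples
#' st <- adaptation_state(as.Date("2023-01-01"), 50)
#' adapt_difficulty(st, 60, "moderate", as.Date("2023-01-02"))$difficulty
#' @export
adapt_difficulty <- function(state, new_score, current, today) {
  if (!inherits(state, "adaptation_state")) {
    stop_param("`state` must be an adaptation_state")
  }
  assert_scalar_number(new_score, "new_score", lower = 0, upper = 100)
  current <- match.arg(current, DIFFICULTY_LEVELS)
  if (!is.null(state$last_adjust_date) &&
      identical(state$last_adjust_date, today)) {
    return(list(difficulty = current, state = state))
  }
  delta <- new_score - state$last_session_score
  lvl <- match(current, DIFFICULTY_LEVELS)
  if (delta > 5) lvl <- min(lvl + 1L, 3L)
  if (delta < -5) lvl <- max(lvl - 1L, 1L)
  list(
    difficulty = DIFFICULTY_LEVELS[lvl],
    state = adaptation_state(last_adjust_date = today,
                             last_session_score = new_score)
  )
}
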