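#' Hourly daylight measurement grid
#'
#' The measurement grid used throughout the pipeline: hourly top-view captures
#' during the photoperiod only, `steps_per_day` per day starting at
#' `first_hour`, over a days-after-sowing (DAS) range starting at `first_das`.
#' Nights are absent by construction, so consecutive steps within a day are one
#' measured hour apart and one day equals `steps_per_day` measured steps.
#'
#' @param first_das Integer DAS of step 1 (default 10).
#' @param steps_per_day Captures per day (default 12).
#' @param first_hour Clock hour of the first daily capture (default 8).
#' @param total_steps Total number of grid steps (default 165).
#' @return An object of class `time_grid`.
#' @export
time_grid <- function(first_das = 10L, steps_per_day = 12L, first_hour = 8L,
                      total_steps = 165L) {
  stopifnot(steps_per_day >= 1L, total_steps >= 1L)
  structure(list(first_das = as.integer(first_das),
                 steps_per_day = as.integer(steps_per_day),
                 first_hour = as.integer(first_hour),
                 total_steps = as.integer(total_steps)),
            class = "time_grid")
}

#' Convert grid steps to decimal DAS
#'
#' Decimal DAS appends the clock hour divided by 24 to the integer DAS, so a
#' capture at 17:00 on day 23 displays as 23.71. Values are rounded to two
#' decimals, the convention used in all feature tables.
#'
#' @param step 1-based step index (vectorised).
#' @param grid A [time_grid()].
#' @return Decimal DAS values.
#' @export
step_to_das <- function(step, grid = time_grid()) {
  step <- as.integer(step)
  if (any(step < 1L | step > grid$total_steps)) {
    stop("step out of range 1..", grid$total_steps)
  }
  day <- grid$first_das + (step - 1L) %/% grid$steps_per_day
  hour <- grid$first_hour + (step - 1L) %% grid$steps_per_day
  round(day + hour / 24, 2)
}

#' Convert decimal DAS back to the grid step
#'
#' Left inverse of [step_to_das()] on grid points.
#'
#' @param das Decimal DAS as produced by [step_to_das()].
#' @param grid A [time_grid()].
#' @return 1-based step indices.
#' @export
das_to_step <- function(das, grid = time_grid()) {
  day <- floor(das)
  hour <- round((das - day) * 24)
  step <- (day - grid$first_das) * grid$steps_per_day +
    (hour - grid$first_hour) + 1L
  step <- as.integer(step)
  if (any(step < 1L | step > grid$total_steps)) {
    stop("DAS value off the measurement grid")
  }
  step
}

#' Training/testing window specification
#'
#' A named window over the step grid: an inclusive training period followed by
#' an inclusive, later testing period.
#'
#' @param name Window label.
#' @param train_start,train_end,test_start,test_end 1-based inclusive steps.
#' @return An object of class `window_spec`.
#' @export
window_spec <- function(name, train_start, train_end, test_start, test_end) {
  stopifnot(train_start <= train_end, train_end < test_start,
            test_start <= test_end)
  structure(list(name = name,
                 train_start = as.integer(train_start),
                 train_end = as.integer(train_end),
                 test_start = as.integer(test_start),
                 test_end = as.integer(test_end)),
            class = "window_spec")
}

#' The six stage-windowed training sets
#'
#' The canonical six training windows over the 165-step cycle. Four share the
#' 21-DAS training endpoint (step 140) and differ in their start (15-18 DAS);
#' the last two end training at 20 DAS (step 127). All are tested on the late
#' pre-flowering stage ending at step 165. The step anchors are fixed
#' constants of the study design, not recomputed from the grid formula.
#'
#' @return Named list of six [window_spec()] objects T1..T6.
#' @export
table1_windows <- function() {
  list(
    T1 = window_spec("T1", 60L, 140L, 141L, 165L),
    T2 = window_spec("T2", 72L, 140L, 141L, 165L),
    T3 = window_spec("T3", 84L, 140L, 141L, 165L),
    T4 = window_spec("T4", 96L, 140L, 141L, 165L),
    T5 = window_spec("T5", 72L, 127L, 128L, 165L),
    T6 = window_spec("T6", 84L, 127L, 128L, 165L)
  )
}
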