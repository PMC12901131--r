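# Scoring windows (seconds) and the clip bounds applied to hit/false-alarm
# rates before the d' conversion
FIXATION_WINDOW_S <- 1.4
ONEBACK_WINDOW_S <- c(0.25, 4.25)
RATE_CLIP <- c(0.01, 0.99)

# first press strictly after t0 and at or before t1 (windows open at the
# start, closed at the end); returns NA if none
first_press_in <- function(presses, t0, t1) {
  hit <- which(presses$time_s > t0 & presses$time_s <= t1)
  if (length(hit) == 0L) return(NA_integer_)
  presses$button[hit[which.min(presses$time_s[hit])]]
}

#' Score the fixation (dot-luminance) task
#'
#' For each dot-luminance change, takes the first button press within
#' 0-1400 ms after the change and scores it correct iff button 1 follows a
#' decrement or button 2 follows an increment; no press counts as
#' incorrect. Changes where the level stays the same have no correct
#' button and are excluded from the denominator.
#'
#' @param dot_events Data frame with `time_s` and `level` (the dot
#'   luminance from that time onward), ordered in time; the first row is
#'   the initial state and is not scored.
#' @param presses Data frame with `time_s` and `button` (1 or 2).
#' @return A `behavior_score` list: `task`, `percent_correct`,
#'   `n_scored`, `n_correct`.
#' @export
score_fixation <- function(dot_events, presses) {
  if (nrow(dot_events) < 2L) stop("no dot changes to score")
  stopifnot(all(presses$button %in% c(1L, 2L)))
  d <- diff(dot_events$level)
  times <- dot_events$time_s[-1L]
  scored <- d != 0
  if (!any(scored)) stop("no dot changes to score")
  correct <- logical(sum(scored))
  idx <- which(scored)
  for (j in seq_along(idx)) {
    i <- idx[j]
    b <- first_press_in(presses, times[i], times[i] + FIXATION_WINDOW_S)
    want <- if (d[i] < 0) 1L else 2L
    correct[j] <- !is.na(b) && b == want
  }
  structure(list(task = "FIXATION",
                 percent_correct = 100 * mean(correct),
                 n_scored = length(correct), n_correct = sum(correct)),
            class = "behavior_score")
}

#' Score the one-back task as a signal-detection experiment
#'
#' For each stimulus trial except the first of each run, takes the first
#' button press 250-4250 ms after stimulus onset. One-back trials are
#' signal-present (button 2 = hit; button 1 or no press = miss); all other
#' stimulus trials are signal-absent (button 2 or no press = false alarm;
#' button 1 = correct rejection). Hit and false-alarm rates are clipped to
#' [0.01, 0.99] before conversion to d' via the standard-normal quantile
#' function, bounding d' to [-4.653, 4.653].
#'
#' @param stim_events Data frame with `onset_s`, `is_oneback`, and
#'   optionally `run` (first trial of each run excluded; a single run is
#'   assumed when absent), ordered in time.
#' @param presses Data frame with `time_s` and `button` (1 or 2).
#' @return A `behavior_score` list: `task`, `hit_rate`, `fa_rate`
#'   (clipped), `dprime`, and the raw trial counts.
#' @export
score_oneback <- function(stim_events, presses) {
  stopifnot(all(presses$button %in% c(1L, 2L)))
  run <- if ("run" %in% names(stim_events)) stim_events$run else rep(1L, nrow(stim_events))
  keep <- duplicated(run)   # drop the first stimulus trial of each run
  ev <- stim_events[keep, , drop = FALSE]
  if (sum(ev$is_oneback) < 1L || sum(!ev$is_oneback) < 1L)
    stop("need at least one signal-present and one signal-absent trial")
  resp <- vapply(ev$onset_s, function(t)
    first_press_in(presses, t + ONEBACK_WINDOW_S[1], t + ONEBACK_WINDOW_S[2]),
    integer(1))
  said_old <- !is.na(resp) & resp == 2L
  no_press <- is.na(resp)
  hits <- sum(ev$is_oneback & said_old)
  misses <- sum(ev$is_oneback & !said_old)          # button 1 or no press
  fas <- sum(!ev$is_oneback & (said_old | no_press)) # no press is incorrect
  crs <- sum(!ev$is_oneback) - fas
  hit_rate <- min(max(hits / (hits + misses), RATE_CLIP[1]), RATE_CLIP[2])
  fa_rate <- min(max(fas / (fas + crs), RATE_CLIP[1]), RATE_CLIP[2])
  structure(list(task = "ONEBACK", hit_rate = hit_rate, fa_rate = fa_rate,
                 dprime = stats::qnorm(hit_rate) - stats::qnorm(fa_rate),
                 n_present = hits + misses, n_absent = fas + crs,
                 hits = hits, false_alarms = fas),
            class = "behavior_score")
}

#' @export
print.behavior_score <- function(x, ...) {
  if (x$task == "FIXATION")
    cat(sprintf("fixation task: %.1f%% correct (%d/%d changes)\n",
                x$percent_correct, x$n_correct, x$n_scored))
  else
    cat(sprintf("one-back task: hit %.3f, FA %.3f, d' = %.3f\n",
                x$hit_rate, x$fa_rate, x$dprime))
  invisible(x)
}

#' Simulated button-press responders
#'
#' Generate press tables for testing the scorers against known response
#' policies. The fixation responder answers each dot change correctly with
#' probability `p_correct` (otherwise pressing the wrong button), at a
#' uniform latency within the scoring window; `p_respond` presses are
#' emitted at all. The one-back responder presses "old"/"new" correctly
#' with probability `p_correct` on each stimulus trial.
#'
#' @param dot_events,stim_events Event tables as for the scorers.
#' @param p_correct Probability of the correct button.
#' @param p_respond Probability of pressing any button.
#' @param seed Integer seed.
#' @return A presses data frame (`time_s`, `button`).
#' @export
simulate_fixation_presses <- function(dot_events, p_correct = 0.9,
                                      p_respond = 1.0, seed = 1L) {
  d <- diff(dot_events$level)
  times <- dot_events$time_s[-1L]
  with_seed(seed, {
    out <- lapply(which(d != 0), function(i) {
      if (stats::runif(1) > p_respond) return(NULL)
      want <- if (d[i] < 0) 1L else 2L
      b <- if (stats::runif(1) < p_correct) want else 3L - want
      data.frame(time_s = times[i] + stats::runif(1, 0.05, FIXATION_WINDOW_S),
                 button = b)
    })
    out <- do.call(rbind, out)
    if (is.null(out)) data.frame(time_s = numeric(0), button = integer(0))
    else out[order(out$time_s), ]
  })
}

#' @rdname simulate_fixation_presses
#' @export
simulate_oneback_presses <- function(stim_events, p_correct = 0.9,
                                     p_respond = 1.0, seed = 1L) {
  with_seed(seed, {
    out <- lapply(seq_len(nrow(stim_events)), function(i) {
      if (stats::runif(1) > p_respond) return(NULL)
      want <- if (stim_events$is_oneback[i]) 2L else 1L
      b <- if (stats::runif(1) < p_correct) want else 3L - want
      data.frame(time_s = stim_events$onset_s[i] +
                   stats::runif(1, ONEBACK_WINDOW_S[1] + 0.05, 2.0),
                 button = b)
    })
    out <- do.call(rbind, out)
    if (is.null(out)) data.frame(time_s = numeric(0), button = integer(0))
    else out[order(out$time_s), ]
  })
}
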