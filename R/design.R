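# Design constants: 4-s trials; runs of 107 trials (428 s) with 3 leading
# and 4 trailing blank trials, 7 interior blanks, and 93 stimulus trials
# (83 base + 10 one-back inserts). Interior blanks must split the stimulus
# trials into runs of 9-14 consecutive trials.
TRIAL_S <- 4
RUN_TRIALS <- 107L
RUN_S <- 428
BASE_PER_RUN <- 83L
ONEBACK_PER_RUN <- 10L
STIM_PER_RUN <- BASE_PER_RUN + ONEBACK_PER_RUN
LEAD_BLANKS <- 3L
TRAIL_BLANKS <- 4L
INNER_BLANKS <- 7L
STREAK_MIN <- 9L
STREAK_MAX <- 14L
MAX_ATTEMPTS <- 10000L
DOT_LEVELS <- c(0.17, 0.37, 0.58, 0.79, 1)
DOT_INTERVAL_S <- 1.4

# image indices presented four times per task: the scene subclasses whose
# four members are genuinely distinct scenes (natural, upside-down,
# Mooney, line-drawing), i.e. subclasses 4-7
four_presentation_images <- function(registry = subclass_registry()) {
  r <- registry[registry$subclass_index %in% 4:7, ]
  unlist(lapply(seq_len(nrow(r)), function(i) r$first_index[i]:r$last_index[i]))
}

#' Base stimulus ordering for the four fixation-task runs
#'
#' Randomly orders the complete set of 332 base stimulus trials (268
#' images once + 16 scene-class images four times) and splits them into 4
#' runs of 83 trials, rejecting orderings in which any image appears in
#' two consecutive trials of the same run.
#'
#' @param seed Integer seed.
#' @param registry Subclass registry (defaults to the standard one).
#' @return A list of 4 integer vectors (image indices), with attribute
#'   `attempts` recording how many shuffles were needed.
#' @export
build_base_ordering <- function(seed = 1L, registry = subclass_registry()) {
  four <- four_presentation_images(registry)
  singles <- setdiff(seq_len(sum(registry$n_images)), four)
  pool <- c(singles, rep(four, each = 4L))
  stopifnot(length(pool) == 4L * BASE_PER_RUN)
  with_seed(seed, {
    for (attempt in seq_len(MAX_ATTEMPTS)) {
      ord <- sample(pool)
      runs <- split(ord, rep(1:4, each = BASE_PER_RUN))
      ok <- all(vapply(runs, function(r) !any(diff(r) == 0), logical(1)))
      if (ok) {
        names(runs) <- c("A", "B", "C", "D")
        attr(runs, "attempts") <- attempt
        return(runs)
      }
    }
    stop("could not satisfy the no-back-to-back constraint")
  })
}

#' Insert one-back repeat trials into a run's base ordering
#'
#' Selects 10 distinct base trials and inserts, immediately after each, a
#' repeat of its image flagged as a one-back trial.
#'
#' @param run_base Integer vector of 83 image indices.
#' @param seed Integer seed.
#' @return A data frame with 93 rows: `image_index`, `is_oneback`.
#' @export
insert_oneback <- function(run_base, seed = 1L) {
  stopifnot(length(run_base) == BASE_PER_RUN)
  picks <- with_seed(seed, sort(sample(BASE_PER_RUN, ONEBACK_PER_RUN)))
  img <- integer(0); ob <- logical(0)
  for (i in seq_len(BASE_PER_RUN)) {
    img <- c(img, run_base[i]); ob <- c(ob, FALSE)
    if (i %in% picks) { img <- c(img, run_base[i]); ob <- c(ob, TRUE) }
  }
  data.frame(image_index = img, is_oneback = ob)
}

# sample 8 stimulus-streak lengths in [9, 14] summing to 93, uniformly
# over valid compositions, by rejection
sample_streaks <- function() {
  repeat {
    lens <- sample(STREAK_MIN:STREAK_MAX, INNER_BLANKS + 1L, replace = TRUE)
    if (sum(lens) == STIM_PER_RUN) return(lens)
  }
}

#' Place blank trials around a run's stimulus trials
#'
#' Adds 3 leading and 4 trailing blank trials and positions 7 interior
#' blanks such that every streak of consecutive stimulus trials has length
#' 9 to 14 (rejection-sampled; the draw count is recorded).
#'
#' @param stim_trials Data frame of 93 stimulus trials (`image_index`,
#'   `is_oneback`), as from [insert_oneback()].
#' @param seed Integer seed.
#' @param label Run design label ("A".."D").
#' @return A `run_design`: data frame of 107 trials with columns
#'   `onset_s`, `image_index` (NA for blanks), `is_oneback`, `is_blank`,
#'   and attributes `label` and `attempts`.
#' @export
place_blanks <- function(stim_trials, seed = 1L, label = "A") {
  stopifnot(nrow(stim_trials) == STIM_PER_RUN)
  lens <- with_seed(seed, {
    attempts <- 0L
    repeat {
      attempts <- attempts + 1L
      if (attempts > MAX_ATTEMPTS) stop("could not satisfy the streak constraint")
      lens <- sample(STREAK_MIN:STREAK_MAX, INNER_BLANKS + 1L, replace = TRUE)
      if (sum(lens) == STIM_PER_RUN) break
    }
    attr(lens, "attempts") <- attempts
    lens
  })
  img <- rep(NA_integer_, RUN_TRIALS)
  ob <- rep(FALSE, RUN_TRIALS)
  pos <- LEAD_BLANKS
  k <- 0L
  for (seg in seq_along(lens)) {
    take <- (k + 1L):(k + lens[seg])
    img[(pos + 1L):(pos + lens[seg])] <- stim_trials$image_index[take]
    ob[(pos + 1L):(pos + lens[seg])] <- stim_trials$is_oneback[take]
    pos <- pos + lens[seg] + 1L   # one interior blank after each segment
    k <- k + lens[seg]
  }
  # the blank after the last segment coincides with the first trailing blank;
  # segments + separators: 3 + 93 + 7 + 4 = 107
  out <- data.frame(onset_s = (seq_len(RUN_TRIALS) - 1L) * TRIAL_S,
                    image_index = img, is_oneback = ob,
                    is_blank = is.na(img))
  stopifnot(sum(!out$is_blank) == STIM_PER_RUN,
            all(out$is_blank[1:LEAD_BLANKS]),
            all(out$is_blank[(RUN_TRIALS - TRAIL_BLANKS + 1L):RUN_TRIALS]))
  structure(out, label = label, attempts = attr(lens, "attempts"),
            class = c("run_design", "data.frame"))
}

# dot-luminance sequence for one run: initial level at t = 0, then a new
# level (repeats allowed) every 1.4 s until run end
dot_sequence <- function(seed) {
  n <- floor(RUN_S / DOT_INTERVAL_S) + 1L   # initial state + 305 changes
  with_seed(seed, data.frame(
    time_s = (seq_len(n) - 1L) * DOT_INTERVAL_S,
    level = sample(DOT_LEVELS, n, replace = TRUE)))
}

#' Assemble the full 8-run session design
#'
#' Builds the four run designs A-D (base ordering, one-back inserts, blank
#' placement), then lays out the session with task order XOXOXOXO
#' (X = fixation, O = one-back) and design order ACBDCADB, so each design
#' letter serves once under each task with identical trial sequences. A
#' per-run dot-luminance sequence is drawn for the fixation task.
#'
#' @param seed Integer seed; the whole session is reproducible from it.
#' @param registry Subclass registry.
#' @return A `session_design`: list with `runs` (8 entries, each holding
#'   `trials`, `task`, `design`, `dots`), `design_order`, `task_order`,
#'   and `seed`.
#' @export
assemble_session <- function(seed = 1L, registry = subclass_registry()) {
  base <- build_base_ordering(child_seed(seed, 1), registry)
  designs <- lapply(seq_along(base), function(i) {
    stim <- insert_oneback(base[[i]], child_seed(seed, 10 + i))
    place_blanks(stim, child_seed(seed, 20 + i), label = names(base)[i])
  })
  names(designs) <- names(base)
  design_order <- c("A", "C", "B", "D", "C", "A", "D", "B")
  task_order <- rep(c("FIXATION", "ONEBACK"), 4L)
  runs <- lapply(1:8, function(r) {
    list(trials = designs[[design_order[r]]],
         task = task_order[r], design = design_order[r],
         dots = dot_sequence(child_seed(seed, 30 + r)))
  })
  structure(list(runs = runs, design_order = design_order,
                 task_order = task_order, seed = seed),
            class = "session_design")
}

#' @export
print.session_design <- function(x, ...) {
  n_stim <- sum(vapply(x$runs, function(r) sum(!r$trials$is_blank), integer(1)))
  n_ob <- sum(vapply(x$runs, function(r) sum(r$trials$is_oneback), integer(1)))
  cat(sprintf("session design: 8 runs (tasks %s, designs %s), %d stimulus trials, %d one-back\n",
              paste(ifelse(x$task_order == "FIXATION", "X", "O"), collapse = ""),
              paste(x$design_order, collapse = ""), n_stim, n_ob))
  invisible(x)
}

#' Summarize per-image presentation counts
#'
#' Tabulates, per task, how often each image is presented, excluding and
#' including the one-back repeats, and checks the conservation totals
#' (332 base and 372 total presentations per task).
#'
#' @param session A `session_design`.
#' @return A list with `per_image` (data frame: image, task, base count,
#'   total count) and `histogram` (per task, table of images by total
#'   presentation count).
#' @export
summarize_repetitions <- function(session) {
  rows <- do.call(rbind, lapply(session$runs, function(r) {
    t <- r$trials[!r$trials$is_blank, ]
    data.frame(task = r$task, image_index = t$image_index,
               is_oneback = t$is_oneback)
  }))
  per_image <- do.call(rbind, lapply(split(rows, rows$task), function(d) {
    base <- table(factor(d$image_index[!d$is_oneback], levels = 1:284))
    tot <- table(factor(d$image_index, levels = 1:284))
    data.frame(image_index = 1:284, task = d$task[1],
               base_count = as.integer(base), total_count = as.integer(tot))
  }))
  rownames(per_image) <- NULL
  stopifnot(all(tapply(per_image$base_count, per_image$task, sum) == 332L),
            all(tapply(per_image$total_count, per_image$task, sum) == 372L))
  histogram <- tapply(per_image$total_count, per_image$task,
                      function(x) table(x), simplify = FALSE)
  list(per_image = per_image, histogram = histogram)
}

#' Write a session design as per-run events tables
#'
#' Writes one BIDS-style TSV per run (onset, duration, image_index,
#' subclass_name, is_oneback, is_blank, task) plus a JSON session
#' manifest.
#'
#' @param session A `session_design`.
#' @param dir Output directory.
#' @param registry Subclass registry used to label images.
#' @return Invisibly, the written file paths.
#' @export
write_session_events <- function(session, dir, registry = subclass_registry()) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  subclass_of <- rep(registry$subclass_name, registry$n_images)
  paths <- character(0)
  for (r in seq_along(session$runs)) {
    run <- session$runs[[r]]
    t <- run$trials
    ev <- data.frame(onset = t$onset_s, duration = 2.0,
                     image_index = t$image_index,
                     subclass_name = ifelse(t$is_blank, "n/a",
                                            subclass_of[t$image_index]),
                     is_oneback = t$is_oneback, is_blank = t$is_blank,
                     task = run$task)
    p <- file.path(dir, sprintf("run-%02d_events.tsv", r))
    utils::write.table(ev, p, sep = "\t", row.names = FALSE, quote = FALSE)
    paths <- c(paths, p)
  }
  mpath <- file.path(dir, "session.json")
  jsonlite::write_json(list(seed = session$seed,
                            task_order = session$task_order,
                            design_order = session$design_order),
                       mpath, auto_unbox = TRUE)
  invisible(c(paths, mpath))
}
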