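test_that("base ordering covers 268 singles and 16 quadruples with no adjacent repeats", {
  base <- build_base_ordering(seed = 3L)
  expect_length(base, 4)
  expect_true(all(lengths(base) == 83))
  pooled <- unlist(base)
  counts <- table(pooled)
  expect_equal(length(pooled), 332)
  expect_equal(sum(counts == 1), 268)
  expect_equal(sum(counts == 4), 16)
  expect_setequal(as.integer(names(counts)[counts == 4]), 13:28)
  for (r in base) expect_false(any(diff(r) == 0))
})

test_that("one-back insertion duplicates exactly ten base trials in place", {
  base <- build_base_ordering(seed = 3L)
  stim <- insert_oneback(base$A, seed = 4L)
  expect_equal(nrow(stim), 93)
  expect_equal(sum(stim$is_oneback), 10)
  ob <- which(stim$is_oneback)
  expect_true(all(stim$image_index[ob] == stim$image_index[ob - 1L]))
  expect_false(any(stim$is_oneback[ob - 1L]))   # inserts never stack
})

test_that("blank placement yields the 107-trial run with 9-14 trial streaks", {
  base <- build_base_ordering(seed = 3L)
  run <- place_blanks(insert_oneback(base$B, 5L), seed = 6L, label = "B")
  expect_equal(nrow(run), 107)
  expect_equal(max(run$onset_s) + 4, 428)
  expect_true(all(run$onset_s %% 4 == 0))
  expect_true(all(run$is_blank[1:3]))
  expect_true(all(run$is_blank[104:107]))
  expect_equal(sum(run$is_blank), 14)           # 3 + 4 + 7 interior
  # streaks of stimulus trials: 8 segments, lengths 9-14 summing to 93
  rle_stim <- rle(!run$is_blank)
  streaks <- rle_stim$lengths[rle_stim$values]
  expect_length(streaks, 8)
  expect_true(all(streaks >= 9 & streaks <= 14))
  expect_equal(sum(streaks), 93)
})

test_that("the assembled session satisfies all trial-count arithmetic", {
  ses <- cached_session()
  expect_equal(ses$task_order, rep(c("FIXATION", "ONEBACK"), 4))
  expect_equal(ses$design_order, c("A", "C", "B", "D", "C", "A", "D", "B"))
  n_stim <- vapply(ses$runs, function(r) sum(!r$trials$is_blank), integer(1))
  expect_true(all(n_stim == 93))
  expect_equal(sum(n_stim), 744)
  expect_equal(sum(vapply(ses$runs, function(r) sum(r$trials$is_oneback),
                          integer(1))), 80)
  # dot sequence: initial state + floor(428 / 1.4) changes
  expect_true(all(vapply(ses$runs, function(r) nrow(r$dots), integer(1)) == 306))
  expect_true(all(ses$runs[[1]]$dots$level %in% c(0.17, 0.37, 0.58, 0.79, 1)))
})

test_that("fixation and one-back instances of a design letter are identical", {
  ses <- cached_session()
  for (letter in c("A", "B", "C", "D")) {
    runs <- which(ses$design_order == letter)
    expect_length(runs, 2)
    expect_equal(ses$runs[[runs[1]]]$trials$image_index,
                 ses$runs[[runs[2]]]$trials$image_index)
    expect_equal(ses$runs[[runs[1]]]$trials$is_oneback,
                 ses$runs[[runs[2]]]$trials$is_oneback)
    expect_setequal(vapply(runs, function(r) ses$runs[[r]]$task, character(1)),
                    c("FIXATION", "ONEBACK"))
  }
})

test_that("repetition summary conserves presentations per task", {
  rs <- summarize_repetitions(cached_session())
  for (task in c("FIXATION", "ONEBACK")) {
    d <- rs$per_image[rs$per_image$task == task, ]
    expect_equal(sum(d$base_count), 332)
    expect_equal(sum(d$total_count), 372)
    expect_equal(sum(d$base_count == 1), 268)
    expect_equal(sum(d$base_count == 4), 16)
    expect_equal(sum(d$total_count > 0), 284)   # every image appears
  }
  # both tasks share one design, so the histograms agree
  expect_equal(rs$histogram$FIXATION, rs$histogram$ONEBACK)
})

test_that("session building is deterministic per seed", {
  a <- assemble_session(9L)
  b <- assemble_session(9L)
  expect_identical(lapply(a$runs, `[[`, "trials"),
                   lapply(b$runs, `[[`, "trials"))
  c <- assemble_session(10L)
  expect_false(identical(a$runs[[1]]$trials$image_index,
                         c$runs[[1]]$trials$image_index))
})

test_that("events export writes one TSV per run plus a manifest", {
  ses <- cached_session()
  dir <- withr::local_tempdir()
  paths <- write_session_events(ses, dir)
  expect_length(paths, 9)
  ev <- utils::read.delim(paths[1])
  expect_equal(nrow(ev), 107)
  expect_equal(unique(ev$duration), 2)
  meta <- jsonlite::read_json(file.path(dir, "session.json"))
  expect_equal(unlist(meta$design_order), c("A", "C", "B", "D", "C", "A", "D", "B"))
})
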