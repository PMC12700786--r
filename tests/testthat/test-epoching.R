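tics <- function(onsets, offsets, condition = "tic_freely") {
  event_table(onsets, offsets, "tic", "motor", condition)
}

test_that("tic successions under 2 s apart merge into one sequence", {
  merged <- merge_tic_sequences(tics(c(10.0, 11.0), c(10.5, 11.4)))
  expect_equal(nrow(merged), 1L)
  expect_equal(merged$onset, 10.0)
  expect_equal(merged$offset, 11.4)

  far <- merge_tic_sequences(tics(c(10.0, 13.0), c(10.5, 13.2)))
  expect_equal(nrow(far), 2L)
  expect_equal(far$onset, c(10.0, 13.0))

  expect_equal(nrow(merge_tic_sequences(event_table())), 0L)
  expect_warning(ov <- merge_tic_sequences(tics(c(10, 10.3), c(10.6, 11))),
                 "overlapping")
  expect_equal(nrow(ov), 1L)
})

test_that("isolation keeps only tics with >= 2 s tic-free history", {
  ev <- tics(c(18.0, 20.0), c(18.5, 20.3))    # gap 1.5 s
  sel <- select_isolated_tics(ev)
  expect_equal(sel$onset, 18.0)                # first tic always isolated

  # boundary: previous offset exactly 2.0 s before -> still isolated
  ev2 <- tics(c(18.0, 20.5), c(18.5, 20.8))
  expect_equal(nrow(select_isolated_tics(ev2)), 2L)
})

test_that("merge + select always leaves >= 2 s tic-free history", {
  for (seed in 1:20) {
    ev <- withr::with_seed(seed, {
      on <- sort(runif(15, 0, 120))
      tics(on, on + runif(15, 0.1, 1.5))
    })
    # random tables may contain overlaps, which merge with a warning
    sel <- suppressWarnings(select_isolated_tics(merge_tic_sequences(ev)))
    expect_true(all(diff(sel$onset) >= 0))
    for (i in seq_len(nrow(sel))) {
      prev <- sel$offset[-i]
      expect_false(any(prev > sel$onset[i] - 2 & prev < sel$onset[i]))
    }
  }
})

test_that("tic epochs are cut around onsets and out-of-bounds dropped", {
  rec <- random_lfp_recording(n = 250 * 120, seed = 5)
  on <- seq(10, 100, by = 10)
  ep <- extract_tic_epochs(rec, tics(on, on + 0.5))
  expect_equal(n_trials(ep), 10L)
  expect_equal(dim(ep$data)[3], round(3.0 * 250))
  expect_equal(attr(ep, "n_dropped"), 0L)

  early <- extract_tic_epochs(rec, tics(c(0.5, 50), c(0.9, 50.4)))
  expect_equal(n_trials(early), 1L)
  expect_equal(attr(early, "n_dropped"), 1L)

  expect_error(extract_tic_epochs(rec, tics(0.5, 0.9)), "bounds")
})

test_that("rest epochs tile event-free time greedily", {
  rec <- random_lfp_recording(n = 250 * 60, seed = 6)
  ep <- extract_rest_epochs(rec, event_table())
  expect_equal(n_trials(ep), 15L)               # 60 s / 4 s, no events

  # one tic 10-50 s with 2 s margins: free [0,8] and [52,60] hold 2 each
  ep2 <- extract_rest_epochs(rec, tics(10, 50), margin = 2)
  expect_equal(n_trials(ep2), 4L)

  expect_warning(
    ep3 <- extract_rest_epochs(rec, event_table(), length_s = 4.001),
    "rounded down")
  expect_equal(dim(ep3$data)[3], floor(4.001 * 250))
})

test_that("rest epochs never intersect margined exclusion zones", {
  for (seed in 1:10) {
    rec <- random_lfp_recording(n = 250 * 90, seed = seed)
    ev <- withr::with_seed(seed, {
      on <- sort(runif(6, 0, 85))
      event_table(on, on + 0.5,
                  kind = sample(c("tic", "movement"), 6, TRUE),
                  tic_type = "m", condition = "tic_freely")
    })
    ep <- tryCatch(extract_rest_epochs(rec, ev), error = function(e) NULL)
    if (is.null(ep)) next
    for (i in seq_len(n_trials(ep))) {
      s <- ep$trial_meta$onset[i]
      e <- s + 4
      overlaps <- ev$onset - 1 < e & ev$offset + 1 > s
      expect_false(any(overlaps))
    }
  }
})

test_that("pooling conserves trials and rejects mismatched geometry", {
  rec <- random_lfp_recording(n = 250 * 80, seed = 7)
  a <- extract_tic_epochs(rec, tics(seq(10, 50, 10), seq(10, 50, 10) + .4))
  b <- extract_tic_epochs(rec, tics(seq(55, 73, 3), seq(55, 73, 3) + .3,
                                    condition = "tic_suppression"))
  pooled <- pool_conditions(a, b)
  expect_equal(n_trials(pooled), n_trials(a) + n_trials(b))
  expect_equal(pooled$condition, "pooled")
  expect_equal(pool_conditions(a)$condition, a$condition)

  bad <- b; bad$rate <- 500
  expect_error(pool_conditions(a, bad), "differ")
  expect_equal(n_trials(pool_conditions(NULL, a)), n_trials(a))
})

test_that("channel binding requires aligned trials and unique labels", {
  rec <- random_lfp_recording(n = 250 * 40, seed = 8)
  eeg <- new_recording(matrix(rnorm(250 * 40 * 2), 2), 250, c("Fz", "Cz"),
                       "EEG")
  ev <- tics(c(10, 20, 30), c(10.4, 20.4, 30.4))
  a <- extract_tic_epochs(rec, ev)
  b <- extract_tic_epochs(eeg, ev)
  ab <- bind_epoch_channels(a, b)
  expect_equal(ab$channel_labels, c("LFP_left", "LFP_right", "Fz", "Cz"))
  expect_error(bind_epoch_channels(a, a), "duplicate")
})

test_that("decimation preserves band content on the common time base", {
  withr::local_seed(9)
  t <- (0:(5000 * 4 - 1)) / 5000
  x <- cos(2 * pi * 10 * t)
  rec <- new_recording(rbind(x, x), 5000, c("Fz", "Cz"), "EEG")
  low <- resample_recording(rec, 250)
  expect_equal(low$rate, 250)
  expect_equal(ncol(low$data), 1000L)
  mid <- 300:700                              # away from filter edges
  ref <- cos(2 * pi * 10 * (mid - 1) / 250)
  expect_lt(max(abs(low$data[1, mid] - ref)), 0.02)
  expect_error(resample_recording(rec, 333), "integer")
})
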