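#' Epoch container
#'
#' Trials cut from a `Recording` around an anchor (tic onset or rest
#' segment start), stored as a trials x channels x samples array with the
#' window expressed in seconds relative to the anchor.
#'
#' @param data numeric array, trials x channels x samples.
#' @param rate sampling rate in Hz.
#' @param window length-2 numeric, `(t_start, t_end)` seconds relative to
#'   the anchor; `diff(window) * rate` must equal the sample count to
#'   within one sample.
#' @param anchor `"tic_onset"` or `"segment_start"`.
#' @param condition condition label (`"rest"`, `"tic_freely"`,
#'   `"tic_suppression"`, or `"pooled"` after pooling).
#' @param channel_labels channel names, one per second-dimension slice.
#' @param trial_meta data frame of per-trial provenance (anchor time,
#'   source condition, patient).
#' @return An object of class `EpochSet`.
#' @export
new_epoch_set <- function(data, rate, window, anchor, condition,
                          channel_labels, trial_meta = NULL) {
  stopifnot(is.array(data), length(dim(data)) == 3L)
  if (dim(data)[1] < 1L) stop("an EpochSet needs at least one trial")
  if (length(channel_labels) != dim(data)[2])
    stop("one channel label per channel slice required")
  if (abs(diff(window) * rate - dim(data)[3]) > 1)
    stop("window length and sample count disagree by more than one sample")
  anchor <- match.arg(anchor, c("tic_onset", "segment_start"))
  if (is.null(trial_meta))
    trial_meta <- data.frame(trial = seq_len(dim(data)[1]))
  dimnames(data) <- list(NULL, channel_labels, NULL)
  structure(list(data = data, rate = rate, window = window, anchor = anchor,
                 condition = condition,
                 channel_labels = as.character(channel_labels),
                 trial_meta = trial_meta),
            class = "EpochSet")
}

#' @export
print.EpochSet <- function(x, ...) {
  cat(sprintf(
    "<EpochSet: %d trial(s) x %d channel(s) x %d samples @ %g Hz, window [%g, %g] s re %s>\n",
    dim(x$data)[1], dim(x$data)[2], dim(x$data)[3], x$rate,
    x$window[1], x$window[2], x$anchor))
  invisible(x)
}

#' Number of trials in an epoch set
#' @param epochs an `EpochSet`.
#' @export
n_trials <- function(epochs) dim(epochs$data)[1]

#' Merge rapid tic successions into single tic sequences
#'
#' Tics separated by less than 2 s (gap measured from the offset of one to
#' the onset of the next) are treated as a single tic sequence spanning
#' from the start of the first tic to the end of the last. Overlapping tic
#' annotations are merged with a warning. Non-tic rows pass through
#' unchanged.
#'
#' @param events an `EventTable`, sorted by onset.
#' @param max_gap maximal within-sequence gap in seconds (default 2).
#' @return An `EventTable` with merged tic sequences.
#' @export
merge_tic_sequences <- function(events, max_gap = 2) {
  tics <- events_of_kind(events, "tic")
  others <- events[events$kind != "tic", , drop = FALSE]
  if (nrow(tics) > 1L) {
    gaps <- tics$onset[-1] - tics$offset[-nrow(tics)]
    if (any(gaps < 0)) warning("overlapping tic annotations merged")
    grp <- cumsum(c(1, as.integer(gaps >= max_gap)))
    grp <- factor(grp, levels = unique(grp))
    merged <- do.call(rbind, lapply(split(tics, grp), function(run) {
      data.frame(onset = run$onset[1], offset = max(run$offset),
                 kind = "tic",
                 tic_type = if (nrow(run) > 1)
                   paste0("sequence(", nrow(run), ")") else run$tic_type[1],
                 condition = run$condition[1], stringsAsFactors = FALSE)
    }))
    tics <- merged
  }
  all <- rbind(as.data.frame(tics), as.data.frame(others))
  event_table(all$onset, all$offset, all$kind, all$tic_type, all$condition)
}

#' Select tics preceded by a tic-free interval of at least 2 s
#'
#' A tic is retained iff no other tic's offset falls strictly inside
#' `(onset - min_free, onset)`; a preceding tic ending exactly `min_free`
#' seconds before the onset still counts as isolated ("at least 2 s" is
#' read inclusively). Apply [merge_tic_sequences()] first so that
#' sequences are judged as single events.
#'
#' @param events a merged `EventTable`.
#' @param min_free minimal tic-free history in seconds (default 2).
#' @return An `EventTable` whose tic rows are all isolated; non-tic rows
#'   pass through.
#' @export
select_isolated_tics <- function(events, min_free = 2) {
  tics <- events_of_kind(events, "tic")
  others <- events[events$kind != "tic", , drop = FALSE]
  if (nrow(tics) > 1L) {
    keep <- vapply(seq_len(nrow(tics)), function(i) {
      prev <- tics$offset[-i]
      !any(prev > tics$onset[i] - min_free & prev < tics$onset[i])
    }, logical(1))
    tics <- tics[keep, , drop = FALSE]
  }
  all <- rbind(as.data.frame(tics), as.data.frame(others))
  event_table(all$onset, all$offset, all$kind, all$tic_type, all$condition)
}

#' Cut epochs around tic onsets
#'
#' One trial per tic, anchored at the tic onset. The default window pads
#' the -1.8 to 0.6 s analysis range by 0.3 s on both sides so that 0.3-s
#' sliding windows centred anywhere inside the range have full sample
#' support. Trials whose window would exceed the recording bounds are
#' dropped; the count of dropped trials is attached as
#' `attr(, "n_dropped")`.
#'
#' @param rec a `Recording` (typically LFP and EEG channel-bound at a
#'   common rate).
#' @param events an `EventTable` of merged, isolated tics.
#' @param window length-2 numeric window in seconds around the onset.
#' @return An `EpochSet` anchored at `tic_onset`.
#' @export
extract_tic_epochs <- function(rec, events, window = c(-2.1, 0.9)) {
  tics <- events_of_kind(events, "tic")
  if (!nrow(tics)) stop("no tic events to epoch")
  n_win <- round(diff(window) * rec$rate)
  starts <- round((tics$onset - rec$start_offset + window[1]) * rec$rate) + 1L
  ok <- starts >= 1L & (starts + n_win - 1L) <= ncol(rec$data)
  if (!any(ok)) stop("no tic epoch fits inside the recording bounds")
  kept <- which(ok)
  data <- array(0, dim = c(length(kept), nrow(rec$data), n_win))
  for (k in seq_along(kept)) {
    i0 <- starts[kept[k]]
    data[k, , ] <- rec$data[, i0:(i0 + n_win - 1L), drop = FALSE]
  }
  cond <- unique(tics$condition[kept])
  out <- new_epoch_set(
    data, rec$rate, window, "tic_onset",
    condition = if (length(cond) == 1L) cond else "pooled",
    channel_labels = rec$channel_labels,
    trial_meta = data.frame(onset = tics$onset[kept],
                            condition = tics$condition[kept],
                            tic_type = tics$tic_type[kept]))
  attr(out, "n_dropped") <- sum(!ok)
  out
}

#' Cut movement- and tic-free rest epochs
#'
#' Tiles non-overlapping fixed-length segments greedily left-to-right into
#' the parts of the recording that lie fully outside every tic, movement
#' and stimulation-artifact event, each extended by a guard margin.
#'
#' @param rec a `Recording`.
#' @param events an `EventTable`; `tic`, `movement` and `artifact_sync`
#'   rows define exclusion zones.
#' @param length_s epoch length in seconds (default 4).
#' @param margin guard margin in seconds around each exclusion event
#'   (default 1).
#' @param condition condition label attached to the resulting epochs.
#' @return An `EpochSet` anchored at `segment_start`.
#' @export
extract_rest_epochs <- function(rec, events, length_s = 4, margin = 1,
                                condition = "tic_freely") {
  n_ep <- floor(length_s * rec$rate)
  if (abs(n_ep - length_s * rec$rate) > 1e-9) {
    warning("epoch length is not a multiple of the sample period; ",
            "rounded down to ", n_ep, " samples")
  }
  dur <- ncol(rec$data) / rec$rate
  excl <- events[events$kind %in% c("tic", "movement", "artifact_sync"), ,
                 drop = FALSE]
  iv <- if (nrow(excl))
    cbind(pmax(0, excl$onset - rec$start_offset - margin),
          pmin(dur, excl$offset - rec$start_offset + margin))
  else matrix(numeric(), 0, 2)
  # merge overlapping exclusion intervals, then walk the free gaps
  if (nrow(iv)) {
    iv <- iv[order(iv[, 1]), , drop = FALSE]
    merged <- iv[1, , drop = FALSE]
    for (i in seq_len(nrow(iv))[-1]) {
      if (iv[i, 1] <= merged[nrow(merged), 2])
        merged[nrow(merged), 2] <- max(merged[nrow(merged), 2], iv[i, 2])
      else merged <- rbind(merged, iv[i, ])
    }
    free <- cbind(c(0, merged[, 2]), c(merged[, 1], dur))
    free <- free[free[, 2] - free[, 1] > 0, , drop = FALSE]
  } else {
    free <- matrix(c(0, dur), 1, 2)
  }
  starts <- unlist(lapply(seq_len(nrow(free)), function(i) {
    k <- floor((free[i, 2] - free[i, 1]) * rec$rate / n_ep)
    if (k < 1) return(numeric())
    free[i, 1] + (seq_len(k) - 1) * n_ep / rec$rate
  }))
  if (!length(starts)) stop("no rest epoch fits outside the exclusion zones")
  data <- array(0, dim = c(length(starts), nrow(rec$data), n_ep))
  for (k in seq_along(starts)) {
    i0 <- round(starts[k] * rec$rate) + 1L
    data[k, , ] <- rec$data[, i0:(i0 + n_ep - 1L), drop = FALSE]
  }
  new_epoch_set(data, rec$rate, c(0, n_ep / rec$rate), "segment_start",
                condition = condition, channel_labels = rec$channel_labels,
                trial_meta = data.frame(onset = starts + rec$start_offset,
                                        condition = condition))
}

#' Pool epoch sets across conditions
#'
#' Concatenates the trials of several epoch sets with identical rate,
#' window and channel geometry, keeping per-trial provenance.
#'
#' @param ... `EpochSet`s (empty arguments are allowed and skipped).
#' @return A single pooled `EpochSet`.
#' @export
pool_conditions <- function(...) {
  sets <- Filter(Negate(is.null), list(...))
  sets <- Filter(function(e) n_trials(e) > 0, sets)
  if (!length(sets)) stop("nothing to pool")
  if (length(sets) == 1L) return(sets[[1]])
  ref <- sets[[1]]
  for (e in sets[-1]) {
    if (!isTRUE(all.equal(e$rate, ref$rate)) ||
        !isTRUE(all.equal(e$window, ref$window)) ||
        !identical(e$channel_labels, ref$channel_labels) ||
        !identical(e$anchor, ref$anchor))
      stop("epoch sets differ in rate, window, anchor or channels")
  }
  total <- sum(vapply(sets, n_trials, 0L))
  data <- array(0, dim = c(total, dim(ref$data)[2], dim(ref$data)[3]))
  at <- 0L
  metas <- list()
  for (e in sets) {
    idx <- at + seq_len(n_trials(e))
    data[idx, , ] <- e$data
    m <- e$trial_meta
    m$source_condition <- e$condition
    metas[[length(metas) + 1L]] <- m
    at <- at + n_trials(e)
  }
  cols <- Reduce(intersect, lapply(metas, names))
  meta <- do.call(rbind, lapply(metas, function(m) m[, cols, drop = FALSE]))
  conds <- unique(vapply(sets, function(e) e$condition, ""))
  new_epoch_set(data, ref$rate, ref$window, ref$anchor,
                condition = if (length(conds) == 1L) conds else "pooled",
                channel_labels = ref$channel_labels, trial_meta = meta)
}

#' Channel-bind two epoch sets cut from synchronised streams
#'
#' @param a,b `EpochSet`s with identical trials, rate and window.
#' @return An `EpochSet` with the channels of both inputs.
#' @export
bind_epoch_channels <- function(a, b) {
  if (n_trials(a) != n_trials(b) || !isTRUE(all.equal(a$rate, b$rate)) ||
      !isTRUE(all.equal(a$window, b$window)))
    stop("epoch sets must share trials, rate and window to be channel-bound")
  if (any(b$channel_labels %in% a$channel_labels))
    stop("duplicate channel labels across the bound sets")
  data <- array(0, dim = c(n_trials(a), dim(a$data)[2] + dim(b$data)[2],
                           dim(a$data)[3]))
  data[, seq_len(dim(a$data)[2]), ] <- a$data
  data[, dim(a$data)[2] + seq_len(dim(b$data)[2]), ] <- b$data
  new_epoch_set(data, a$rate, a$window, a$anchor, a$condition,
                c(a$channel_labels, b$channel_labels), a$trial_meta)
}

#' Resample a recording to a lower rate
#'
#' Anti-aliased integer-factor decimation: a zero-phase frequency-domain
#' low-pass (unity gain up to 80% of the new Nyquist, cosine rolloff to
#' zero at the new Nyquist, mirror-padded against wrap-around) followed
#' by subsampling. Used to bring the 5000 Hz EEG onto the 250 Hz LFP
#' time base before epoching so both streams are sample-aligned.
#' Zero phase and exact passband gain matter here: any group delay
#' would bias the LFP-EEG phase difference and hence the PSI, and any
#' passband ripple would distort band power.
#'
#' @param rec a `Recording`.
#' @param new_rate target rate; `rec$rate / new_rate` must be an integer.
#' @return The resampled `Recording`.
#' @export
resample_recording <- function(rec, new_rate) {
  q <- rec$rate / new_rate
  if (abs(q - round(q)) > 1e-9)
    stop("rate ratio must be an integer for decimation")
  q <- as.integer(round(q))
  if (q == 1L) return(rec)
  n <- ncol(rec$data)
  n_mir <- min(n, ceiling(rec$rate / new_rate * 32))
  n_tot <- n + 2L * n_mir
  f <- c(seq(0, floor(n_tot / 2)), seq(-ceiling(n_tot / 2 - 1), -1)) *
    rec$rate / n_tot
  lo <- 0.4 * new_rate
  hi <- 0.5 * new_rate
  mask <- ifelse(abs(f) <= lo, 1,
                 ifelse(abs(f) >= hi, 0,
                        0.5 * (1 + cos(pi * (abs(f) - lo) / (hi - lo)))))
  data <- t(apply(rec$data, 1, function(x) {
    xp <- c(x[n_mir:1], x, x[n:(n - n_mir + 1L)])
    y <- Re(stats::fft(stats::fft(xp) * mask, inverse = TRUE)) / n_tot
    y[n_mir + seq(1, n, by = q)]
  }))
  new_recording(data, new_rate, rec$channel_labels, rec$modality,
                rec$start_offset, rec$meta)
}
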