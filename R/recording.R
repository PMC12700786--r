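#' Multichannel recording container
#'
#' A `Recording` holds a channels-by-samples matrix of voltages (uV) with a
#' sampling rate, unique channel labels, a modality tag and free-form
#' provenance metadata. LFP recordings carry one bipolar channel per
#' implanted hemisphere; EEG recordings carry the scalp montage; SOURCE
#' recordings carry reconstructed region-of-interest time series supplied
#' externally.
#'
#' @param data numeric matrix, channels x samples (uV).
#' @param rate sampling rate in Hz (> 0).
#' @param channel_labels character vector, one unique label per row of `data`.
#' @param modality one of `"LFP"`, `"EEG"`, `"SOURCE"`.
#' @param start_offset start time in seconds relative to the session zero.
#' @param meta named list of provenance metadata (device, sensing contacts,
#'   hemisphere per LFP channel, detected gaps, ...).
#' @return An object of class `Recording`.
#' @export
new_recording <- function(data, rate, channel_labels, modality,
                          start_offset = 0, meta = list()) {
  if (!is.matrix(data) || !is.numeric(data))
    stop("`data` must be a numeric channels x samples matrix")
  if (!is.numeric(rate) || length(rate) != 1L || rate <= 0)
    stop("`rate` must be a single positive number")
  modality <- match.arg(modality, c("LFP", "EEG", "SOURCE"))
  if (length(channel_labels) != nrow(data))
    stop("one channel label per data row required")
  if (anyDuplicated(channel_labels))
    stop("channel labels must be unique")
  if (anyNA(data))
    stop("recording data must not contain NA/NaN; flag gaps in `meta` instead")
  if (modality == "LFP") {
    if (nrow(data) < 1L || nrow(data) > 2L)
      stop("LFP recordings have 1-2 bipolar channels (one per hemisphere)")
    hemi <- meta$hemisphere
    if (is.null(hemi) || length(hemi) != nrow(data))
      stop("LFP recordings need `meta$hemisphere`, one entry per channel")
  }
  rownames(data) <- channel_labels
  structure(
    list(data = data, rate = rate, channel_labels = as.character(channel_labels),
         modality = modality, start_offset = start_offset, meta = meta),
    class = "Recording")
}

#' @export
print.Recording <- function(x, ...) {
  cat(sprintf("<Recording: %s, %d channel(s) x %d samples @ %g Hz (%.1f s)>\n",
              x$modality, nrow(x$data), ncol(x$data), x$rate,
              ncol(x$data) / x$rate))
  invisible(x)
}

#' Number of samples / duration helpers
#' @param rec a `Recording`.
#' @return `n_samples`: integer sample count; `duration`: seconds.
#' @export
n_samples <- function(rec) ncol(rec$data)

#' @rdname n_samples
#' @export
duration <- function(rec) ncol(rec$data) / rec$rate

#' Event annotation table
#'
#' Tic, synchronisation-artifact, block and movement annotations with onset
#' and offset in seconds on the session clock. Tic rows must carry the task
#' condition under which they occurred.
#'
#' @param onset,offset numeric vectors, seconds; `onset <= offset` rowwise.
#' @param kind one of `"tic"`, `"artifact_sync"`, `"block_boundary"`,
#'   `"movement"` per row.
#' @param tic_type free-text tic description (may be `NA` for non-tic rows).
#' @param condition one of `"rest"`, `"tic_freely"`, `"tic_suppression"`;
#'   required for tic rows.
#' @return A data frame of class `EventTable`, sorted by onset.
#' @export
event_table <- function(onset = numeric(), offset = numeric(),
                        kind = character(), tic_type = NA_character_,
                        condition = NA_character_) {
  kinds <- c("tic", "artifact_sync", "block_boundary", "movement")
  conds <- c("rest", "tic_freely", "tic_suppression")
  df <- data.frame(onset = as.numeric(onset), offset = as.numeric(offset),
                   kind = as.character(kind),
                   tic_type = rep_len(as.character(tic_type), length(onset)),
                   condition = rep_len(as.character(condition), length(onset)),
                   stringsAsFactors = FALSE)
  if (nrow(df)) {
    if (!all(df$kind %in% kinds))
      stop("unknown event kind: ", paste(setdiff(df$kind, kinds), collapse = ", "))
    if (any(df$onset > df$offset)) stop("event onset must not exceed offset")
    bad <- df$kind == "tic" & (is.na(df$condition) | !(df$condition %in% conds))
    if (any(bad)) stop("every tic row needs a valid condition label")
    df <- df[order(df$onset), , drop = FALSE]
    rownames(df) <- NULL
  }
  class(df) <- c("EventTable", "data.frame")
  df
}

#' Subset an event table by kind
#' @param events an `EventTable`.
#' @param kind event kind(s) to keep.
#' @return An `EventTable` with only the requested kinds.
#' @export
events_of_kind <- function(events, kind) {
  out <- events[events$kind %in% kind, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("EventTable", "data.frame")
  out
}
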