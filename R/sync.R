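#' Fit a clock-synchronisation model from paired artifact markers
#'
#' The two recording streams (implant LFP and scalp EEG) are aligned
#' offline through stimulation artifacts induced at the start and end of
#' each streaming. Matching the artifact marker times by rank order, this
#' fits the linear clock map
#' `b_time = offset + (1 + drift) * a_time`
#' by least squares and reports the root-mean-square residual. With a
#' single matched marker only the offset is identifiable; the returned
#' model then has `drift = 0` and is flagged (`offset_only = TRUE`).
#'
#' @param events_a,events_b `EventTable`s containing `artifact_sync` rows
#'   for streams A and B, matched first-with-first.
#' @return A list of class `SyncModel`: `offset` (s), `drift` (s per s),
#'   `residual_rms` (s), `n_markers`, `offset_only`.
#' @export
synchronize_streams <- function(events_a, events_b) {
  ta <- events_of_kind(events_a, "artifact_sync")$onset
  tb <- events_of_kind(events_b, "artifact_sync")$onset
  n <- min(length(ta), length(tb))
  if (n < 1L) stop("no artifact_sync markers to match")
  ta <- ta[seq_len(n)]; tb <- tb[seq_len(n)]
  if (n == 1L) {
    warning("single matched marker: drift not identifiable, offset-only model")
    model <- list(offset = tb - ta, drift = 0, residual_rms = 0,
                  n_markers = 1L, offset_only = TRUE)
  } else {
    fit <- stats::lm.fit(cbind(1, ta), tb)
    model <- list(offset = unname(fit$coefficients[1]),
                  drift = unname(fit$coefficients[2]) - 1,
                  residual_rms = sqrt(mean(fit$residuals^2)),
                  n_markers = n, offset_only = FALSE)
  }
  class(model) <- "SyncModel"
  model
}

#' Map times from stream A's clock onto stream B's clock
#' @param model a `SyncModel` from [synchronize_streams()].
#' @param times numeric vector of seconds on stream A's clock.
#' @return Seconds on stream B's clock.
#' @export
apply_sync <- function(model, times) {
  model$offset + (1 + model$drift) * times
}
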