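#' Canonical frequency bands
#'
#' The analysis groups the 2-40 Hz decomposition into theta (3-7 Hz),
#' alpha (8-12 Hz) and beta (13-30 Hz); bounds are inclusive.
#'
#' @param name one of `"theta"`, `"alpha"`, `"beta"`.
#' @return A list with `name`, `lo`, `hi` (class `BandSpec`).
#' @export
band_spec <- function(name = c("theta", "alpha", "beta")) {
  name <- match.arg(name)
  lims <- switch(name, theta = c(3, 7), alpha = c(8, 12), beta = c(13, 30))
  structure(list(name = name, lo = lims[1], hi = lims[2]), class = "BandSpec")
}

#' @rdname band_spec
#' @export
default_bands <- function() lapply(c("theta", "alpha", "beta"), band_spec)

#' Morlet wavelet time-frequency decomposition
#'
#' Convolves every trial and channel with complex Morlet wavelets (fixed
#' number of cycles, so the temporal window shrinks with frequency) over a
#' 1-Hz grid spanning 2-40 Hz by default. The convolution is done in the
#' frequency domain with an analytic (positive-frequency) Gaussian
#' kernel, L2-normalised per frequency so that broadband noise
#' contributes equal expected power to every frequency bin; the absolute
#' coefficient scale is therefore arbitrary (it cancels in normalised
#' spectra, power ratios and all phase measures). Samples closer than two
#' wavelet standard deviations to an epoch edge are flagged as
#' contaminated in the `valid` matrix (freqs x samples); static averages
#' exclude them, sliding series retain them.
#'
#' @param epochs an `EpochSet`.
#' @param freqs frequency grid in Hz (subset of 2-40 for band work).
#' @param cycles wavelet cycles (default 5).
#' @param channels channel labels or indices to decompose (default all).
#' @return A list of class `TFDecomposition`: complex `coeffs`
#'   (trials x channels x freqs x samples), `freqs`, `rate`, `cycles`,
#'   `times` (s relative to the anchor), logical `valid`, `channel_labels`.
#' @export
decompose <- function(epochs, freqs = 2:40, cycles = 5, channels = NULL) {
  stopifnot(inherits(epochs, "EpochSet"))
  if (is.null(channels)) channels <- epochs$channel_labels
  if (is.numeric(channels)) channels <- epochs$channel_labels[channels]
  ch_idx <- match(channels, epochs$channel_labels)
  if (anyNA(ch_idx)) stop("unknown channel(s): ",
                          paste(channels[is.na(ch_idx)], collapse = ", "))
  rate <- epochs$rate
  n_s <- dim(epochs$data)[3]
  n_t <- dim(epochs$data)[1]
  sigma_t <- cycles / (2 * pi * freqs)
  if (n_s / rate < max(2 * 2 * sigma_t))
    stop("epoch shorter than the wavelet at ", min(freqs), " Hz")

  # mirror-pad each epoch past both edges so the wavelet sees locally
  # plausible data there instead of zeros; without this the first and
  # last ~2 sigma_t of every sliding power series are attenuated
  n_mir <- min(n_s, ceiling(3.5 * max(sigma_t) * rate))
  n_tot <- n_s + 2L * n_mir
  n_pad <- stats::nextn(n_tot + ceiling(3.5 * max(sigma_t) * rate), 2)
  f_axis <- (seq_len(n_pad) - 1) / n_pad * rate
  kernels <- vapply(seq_along(freqs), function(k) {
    h <- exp(-2 * pi^2 * sigma_t[k]^2 * (f_axis - freqs[k])^2)
    h[f_axis > rate / 2] <- 0   # analytic: positive frequencies only
    h / sqrt(sum(h^2) / n_pad)  # unit energy per frequency
  }, numeric(n_pad))

  # columns = trial/channel series, transformed once, filtered per frequency
  sig <- matrix(0, n_pad, n_t * length(ch_idx))
  col <- 0L
  for (c_i in ch_idx) for (t_i in seq_len(n_t)) {
    col <- col + 1L
    x <- epochs$data[t_i, c_i, ]
    sig[seq_len(n_tot), col] <- c(x[n_mir:1], x, x[n_s:(n_s - n_mir + 1L)])
  }
  SIG <- stats::mvfft(sig)
  keep <- n_mir + seq_len(n_s)
  coeffs <- array(complex(real = 0), dim = c(n_t, length(ch_idx),
                                             length(freqs), n_s))
  for (k in seq_along(freqs)) {
    filt <- stats::mvfft(SIG * kernels[, k], inverse = TRUE) / n_pad
    col <- 0L
    for (c_j in seq_along(ch_idx)) for (t_i in seq_len(n_t)) {
      col <- col + 1L
      coeffs[t_i, c_j, k, ] <- filt[keep, col]
    }
  }
  n_edge <- pmin(ceiling(2 * sigma_t * rate), floor(n_s / 2))
  valid <- matrix(TRUE, length(freqs), n_s)
  for (k in seq_along(freqs)) {
    e <- n_edge[k]
    if (e > 0) valid[k, c(seq_len(e), n_s - seq_len(e) + 1L)] <- FALSE
  }
  structure(list(coeffs = coeffs, freqs = freqs, rate = rate,
                 cycles = cycles,
                 times = epochs$window[1] + (seq_len(n_s) - 1) / rate,
                 valid = valid, channel_labels = channels),
            class = "TFDecomposition")
}

#' Trial-averaged power spectrum
#'
#' Squared coefficient moduli averaged over valid (edge-free) samples and
#' then over trials.
#'
#' @param tf a `TFDecomposition`.
#' @return A list of class `PowerSpectrum`: `values` (channels x freqs,
#'   arbitrary units proportional to uV^2), `freqs`, `channel_labels`,
#'   `normalised = FALSE`.
#' @export
power_spectrum <- function(tf) {
  stopifnot(inherits(tf, "TFDecomposition"))
  d <- dim(tf$coeffs)
  values <- matrix(0, d[2], d[3],
                   dimnames = list(tf$channel_labels, tf$freqs))
  for (k in seq_len(d[3])) {
    ok <- tf$valid[k, ]
    pw <- Mod(tf$coeffs[, , k, ok, drop = FALSE])^2
    values[, k] <- apply(pw, 2, mean)
  }
  structure(list(values = values, freqs = tf$freqs,
                 channel_labels = tf$channel_labels, normalised = FALSE),
            class = "PowerSpectrum")
}

#' Normalise a power spectrum to percent of total power
#'
#' Each channel is divided by its summed power over the frequency grid and
#' scaled by 100, making spectra comparable across patients and recording
#' gain; a normalised spectrum sums to 100 per channel.
#'
#' @param ps a raw `PowerSpectrum`.
#' @return The normalised `PowerSpectrum`.
#' @export
normalize_power <- function(ps) {
  stopifnot(inherits(ps, "PowerSpectrum"))
  totals <- rowSums(ps$values)
  if (any(totals <= 0)) stop("zero total power in channel(s): ",
                             paste(ps$channel_labels[totals <= 0],
                                   collapse = ", "))
  ps$values <- ps$values / totals * 100
  ps$normalised <- TRUE
  ps
}

#' Average a spectrum or PSI series over a frequency band
#'
#' Unweighted mean over the grid frequencies inside `[lo, hi]` inclusive.
#'
#' @param x a `PowerSpectrum`, or a numeric vector/matrix whose (column)
#'   names or `freqs` attribute give the frequency grid.
#' @param band a `BandSpec` (or band name).
#' @param freqs frequency grid, if `x` does not carry one.
#' @return Per-channel (or per-row) scalar means.
#' @export
band_average <- function(x, band, freqs = NULL) {
  if (is.character(band)) band <- band_spec(band)
  if (inherits(x, "PowerSpectrum")) {
    freqs <- x$freqs
    x <- x$values
  } else if (is.null(freqs)) {
    freqs <- if (!is.null(attr(x, "freqs"))) attr(x, "freqs")
    else if (is.matrix(x)) as.numeric(colnames(x)) else as.numeric(names(x))
  }
  sel <- freqs >= band$lo & freqs <= band$hi
  if (!any(sel)) stop("band ", band$name, " lies outside the frequency grid")
  if (is.matrix(x)) rowMeans(x[, sel, drop = FALSE])
  else mean(x[sel])
}

#' Sliding-window band power
#'
#' Trial-averaged power at each band frequency, averaged inside a window
#' sliding over the epoch, then averaged over the band; the time-resolved
#' companion of [power_spectrum()] used for tic-locked power dynamics.
#'
#' @param tf a `TFDecomposition` over (at least) the band frequencies.
#' @param channel channel label or index.
#' @param band a `BandSpec` or band name.
#' @param window_s,step_s sliding-window length and step in seconds.
#' @param range length-2 vector of window-centre limits in seconds.
#' @return A list of class `SlidingSeries` with `values`, `times`,
#'   `band`, `window_s`, `step_s`, `n_trials`.
#' @export
sliding_band_power <- function(tf, channel, band, window_s = 0.3,
                               step_s = 0.004, range = c(-1.8, 0.6)) {
  if (is.character(band)) band <- band_spec(band)
  if (is.character(channel)) channel <- match(channel, tf$channel_labels)
  sel <- which(tf$freqs >= band$lo & tf$freqs <= band$hi)
  if (!length(sel)) stop("band outside the decomposition grid")
  pw <- Mod(tf$coeffs[, channel, sel, , drop = FALSE])^2
  m <- apply(pw, c(3, 4), mean)                       # freqs x samples
  centers <- seq(range[1], range[2], by = step_s)
  vals <- .sliding_window_mean(m, tf$times, centers, window_s, tf$rate)
  structure(list(values = colMeans(vals), times = centers, band = band$name,
                 window_s = window_s, step_s = step_s,
                 n_trials = dim(tf$coeffs)[1]),
            class = "SlidingSeries")
}

# rows x samples -> rows x centers mean inside [c - w/2, c + w/2]
.sliding_window_mean <- function(m, times, centers, window_s, rate) {
  half <- window_s / 2
  if (min(centers) - half < times[1] - 1e-9 ||
      max(centers) + half > times[length(times)] + 1e-9)
    stop("sliding window exceeds the epoch bounds at the requested centers")
  i0 <- pmax(1L, round((centers - half - times[1]) * rate) + 1L)
  i1 <- pmin(length(times), round((centers + half - times[1]) * rate) + 1L)
  cs <- cbind(0, t(apply(m, 1, cumsum)))
  out <- (cs[, i1 + 1L, drop = FALSE] - cs[, i0, drop = FALSE]) /
    rep(i1 - i0 + 1L, each = nrow(m))
  colnames(out) <- signif(centers, 10)
  out
}
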