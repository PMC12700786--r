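#' Static phase synchronisation index (PSI)
#'
#' The PSI between two channels is the phase-locking value: the modulus of
#' the mean unit phasor of the phase difference, taken over all trials and
#' all edge-free samples, separately per frequency. 0 means no phase
#' coupling, 1 perfect locking.
#'
#' @param tf_a,tf_b `TFDecomposition`s with matching trial counts and
#'   sample geometry (may be the same object).
#' @param chan_a,chan_b channel label or index within each decomposition.
#' @return A named numeric vector of PSI values over the common frequency
#'   grid, with attributes `n_trials` and `freqs`.
#' @export
psi_static <- function(tf_a, tf_b, chan_a, chan_b) {
  ph <- .psi_phasors(tf_a, tf_b, chan_a, chan_b)
  psi <- vapply(seq_along(tf_a$freqs), function(k) {
    ok <- tf_a$valid[k, ] & tf_b$valid[k, ]
    Mod(mean(ph[, k, ok]))
  }, numeric(1))
  names(psi) <- tf_a$freqs
  attr(psi, "freqs") <- tf_a$freqs
  attr(psi, "n_trials") <- dim(ph)[1]
  psi
}

# unit phasors of the phase difference, trials x freqs x samples
.psi_phasors <- function(tf_a, tf_b, chan_a, chan_b) {
  if (is.character(chan_a)) chan_a <- match(chan_a, tf_a$channel_labels)
  if (is.character(chan_b)) chan_b <- match(chan_b, tf_b$channel_labels)
  if (is.na(chan_a) || is.na(chan_b)) stop("unknown channel in PSI pair")
  da <- dim(tf_a$coeffs); db <- dim(tf_b$coeffs)
  if (da[1] != db[1]) stop("mismatched trial counts between decompositions")
  if (da[1] < 2L) stop("PSI needs at least 2 trials")
  if (!identical(tf_a$freqs, tf_b$freqs) || da[4] != db[4])
    stop("decompositions differ in frequency grid or sample count")
  a <- tf_a$coeffs[, chan_a, , , drop = FALSE]
  b <- tf_b$coeffs[, chan_b, , , drop = FALSE]
  dim(a) <- da[c(1, 3, 4)]; dim(b) <- db[c(1, 3, 4)]
  ma <- Mod(a); mb <- Mod(b)
  if (any(ma == 0) || any(mb == 0))
    stop("zero-amplitude coefficient: phase undefined")
  (a / ma) * Conj(b / mb)
}

#' Surrogate PSI by trial-pairing permutation
#'
#' Builds a null PSI by permuting which trial of channel B is paired with
#' each trial of channel A (non-identity permutations only) and
#' recomputing the PSI; the trial-shuffling destroys the phase pairing
#' while preserving the within-trial spectral structure and the trial
#' count. The ensemble mean is the surrogate PSI entered into the
#' original-vs-surrogate comparisons.
#'
#' @inheritParams psi_static
#' @param n_iter number of shuffling iterations (default 100).
#' @param seed optional RNG seed for reproducible ensembles.
#' @return A list of class `SurrogateEnsemble`: `values`
#'   (n_iter x freqs), `mean` (per-freq surrogate PSI), `n_iter`, `seed`,
#'   `n_trials`.
#' @export
surrogate_psi <- function(tf_a, tf_b, chan_a, chan_b, n_iter = 100,
                          seed = NULL) {
  ph_a <- .psi_unit(tf_a, chan_a)
  ph_b <- .psi_unit(tf_b, chan_b)
  n_t <- dim(ph_a)[1]
  if (n_t < 3L)
    stop("surrogates need at least 3 trials for non-identity permutations")
  run <- function() {
    n_f <- length(tf_a$freqs)
    vals <- matrix(0, n_iter, n_f, dimnames = list(NULL, tf_a$freqs))
    for (k in seq_len(n_f)) {
      ok <- tf_a$valid[k, ] & tf_b$valid[k, ]
      # cross-trial phasor sums: entry [t, u] = sum_s A[t,s] * Conj(B[u,s])
      A <- ph_a[, k, ok]; B <- ph_b[, k, ok]
      cross <- A %*% Conj(t(B))
      n_samp <- sum(ok)
      for (it in seq_len(n_iter)) {
        repeat {
          perm <- sample.int(n_t)
          if (any(perm != seq_len(n_t))) break
        }
        vals[it, k] <- Mod(sum(cross[cbind(seq_len(n_t), perm)])) /
          (n_t * n_samp)
      }
    }
    vals
  }
  vals <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  structure(list(values = vals, mean = colMeans(vals), n_iter = n_iter,
                 seed = seed, n_trials = n_t),
            class = "SurrogateEnsemble")
}

# unit phasors of a single channel, trials x freqs x samples
.psi_unit <- function(tf, chan) {
  if (is.character(chan)) chan <- match(chan, tf$channel_labels)
  if (is.na(chan)) stop("unknown channel")
  d <- dim(tf$coeffs)
  a <- tf$coeffs[, chan, , , drop = FALSE]
  dim(a) <- d[c(1, 3, 4)]
  m <- Mod(a)
  if (any(m == 0)) stop("zero-amplitude coefficient: phase undefined")
  a / m
}

#' Sliding-window band PSI
#'
#' PSI over trials using only the samples inside a window of `window_s`
#' seconds centred on each step-grid time point, computed per band
#' frequency and then averaged over the band. Edge-flagged samples are
#' retained here (the tic-epoch padding keeps the analysis range clean).
#'
#' @inheritParams psi_static
#' @param band a `BandSpec` or band name.
#' @param window_s window length in seconds (default 0.3).
#' @param step_s step between window centres in seconds (default 0.004).
#' @param range length-2 vector of window-centre limits (default
#'   `c(-1.8, 0.6)` s around tic onset).
#' @return A list of class `PSISeries`: `values` (one PSI per centre),
#'   `times`, `band`, `window_s`, `step_s`, `n_trials`, `pair`.
#' @export
psi_sliding <- function(tf_a, tf_b, chan_a, chan_b, band = "alpha",
                        window_s = 0.3, step_s = 0.004,
                        range = c(-1.8, 0.6)) {
  if (is.character(band)) band <- band_spec(band)
  ph <- .psi_phasors(tf_a, tf_b, chan_a, chan_b)
  sel <- which(tf_a$freqs >= band$lo & tf_a$freqs <= band$hi)
  if (!length(sel)) stop("band outside the decomposition grid")
  # trial-mean phasor per freq and sample, then windowed sample means
  m <- apply(ph[, sel, , drop = FALSE], c(2, 3), mean)
  if (is.null(dim(m))) m <- matrix(m, nrow = 1)
  centers <- seq(range[1], range[2], by = step_s)
  win <- .sliding_window_mean(m, tf_a$times, centers, window_s, tf_a$rate)
  psi <- colMeans(matrix(Mod(win), nrow = length(sel)))
  structure(list(values = stats::setNames(psi, signif(centers, 10)),
                 times = centers, band = band$name, window_s = window_s,
                 step_s = step_s, n_trials = dim(ph)[1],
                 pair = c(chan_a, chan_b)),
            class = "PSISeries")
}

#' Relative change of a sliding series against a static baseline
#'
#' `(value - baseline) / baseline`, the dimensionless rest-to-tic change
#' reported for both PSI and power dynamics.
#'
#' @param sliding a `PSISeries`/`SlidingSeries` or a numeric vector.
#' @param baseline positive scalar baseline (static rest PSI or power).
#' @return The same shape as `sliding` with transformed values (class
#'   `RelativeChangeSeries` for series inputs).
#' @export
relative_change <- function(sliding, baseline) {
  if (!is.numeric(baseline) || length(baseline) != 1L || baseline <= 0)
    stop("baseline must be a single positive number")
  if (is.list(sliding)) {
    sliding$values <- (sliding$values - baseline) / baseline
    sliding$baseline <- baseline
    class(sliding) <- unique(c("RelativeChangeSeries", class(sliding)))
    sliding
  } else {
    (sliding - baseline) / baseline
  }
}
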