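#' Standard montage helpers
#'
#' `default_montage()` returns the 63-channel extended 10-20 scalp montage
#' (online reference Cz excluded, ground FPz excluded);
#' `frontal_channels()` the frontal preset over which the generator
#' concentrates thalamo-cortical alpha coupling.
#'
#' @return Character vectors of channel labels.
#' @export
default_montage <- function() {
  c("Fp1", "Fp2", "AF7", "AF3", "AFz", "AF4", "AF8",
    "F7", "F5", "F3", "F1", "Fz", "F2", "F4", "F6", "F8",
    "FT9", "FT7", "FC5", "FC3", "FC1", "FCz", "FC2", "FC4", "FC6", "FT8",
    "FT10", "T7", "C5", "C3", "C1", "C2", "C4", "C6", "T8",
    "TP9", "TP7", "CP5", "CP3", "CP1", "CPz", "CP2", "CP4", "CP6", "TP8",
    "TP10", "P7", "P5", "P3", "P1", "Pz", "P2", "P4", "P6", "P8",
    "PO7", "PO3", "POz", "PO4", "PO8", "O1", "Oz", "O2")
}

#' @rdname default_montage
#' @export
frontal_channels <- function() {
  c("Fz", "F1", "F2", "F3", "F4", "AFz", "AF3", "AF4", "FC1", "FC2")
}

#' Draw from a von Mises distribution
#'
#' Best-Fisher (1979) rejection sampler; `kappa = 0` falls back to the
#' uniform circular distribution.
#'
#' @param n number of draws.
#' @param kappa concentration parameter (>= 0).
#' @param mu mean direction in radians.
#' @return Angles in `(-pi, pi]` (shifted by `mu`).
#' @export
rvonmises <- function(n, kappa, mu = 0) {
  if (kappa < 0) stop("kappa must be non-negative")
  # below ~1e-6 the rejection constants cancel catastrophically and the
  # distribution is uniform to machine precision anyway
  if (kappa < 1e-6) return(stats::runif(n, -pi, pi) + mu)
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 1L
  while (i <= n) {
    u <- stats::runif(3)
    z <- cos(pi * u[1])
    f <- (1 + r * z) / (r + z)
    c_ <- kappa * (r - f)
    if (c_ * (2 - c_) - u[2] > 0 || log(c_ / u[2]) + 1 - c_ >= 0) {
      out[i] <- sign(u[3] - 0.5) * acos(f)
      i <- i + 1L
    }
  }
  out + mu
}

#' Expected phase-locking value of von Mises phase jitter
#'
#' The mean resultant length of a von Mises distribution is the Bessel
#' ratio `I1(kappa) / I0(kappa)`; this is the closed-form expectation for
#' the measured PSI of a generated channel with coupling `kappa`.
#'
#' @param kappa concentration parameter(s), >= 0.
#' @return Expected PLV in `[0, 1)`.
#' @export
expected_plv <- function(kappa) {
  ifelse(kappa == 0, 0,
         besselI(kappa, 1, expon.scaled = TRUE) /
           besselI(kappa, 0, expon.scaled = TRUE))
}

#' Ground truth for a synthetic patient
#'
#' Collects everything the generator needs and everything a recovery test
#' must know: per-channel von Mises coupling concentrations to the common
#' alpha oscillator, the oscillator band, the pre-tic decoupling ramp
#' (linear scale-down of the effective kappa from `ramp_start` seconds
#' before each tic onset, removing a fraction `ramp_depth` of the coupling
#' at onset), the tic times, and the monotone negative link from coupling
#' to clinical severity.
#'
#' @param kappa named numeric vector: per-EEG-channel concentration
#'   (>= 0); unnamed channels are uncoupled.
#' @param band_center,band_width oscillator band in Hz (default 10 +- 1).
#' @param ramp_start ramp start in seconds before onset (negative, within
#'   `[-2, 0)`).
#' @param ramp_depth fraction of coupling removed at onset, in `[0, 1]`.
#' @param tic_times tic onset times in seconds.
#' @param tic_duration tic length in seconds.
#' @param clinical_link list with `ygtss_a`, `ygtss_b`, `puts_a`,
#'   `puts_b`, `noise_sd`: scores are `a - b * plv(kappa)` plus Gaussian
#'   noise, truncated at 0.
#' @param seed RNG seed making the patient reproducible.
#' @return A list of class `SyntheticGroundTruth`.
#' @export
ground_truth <- function(kappa, band_center = 10, band_width = 2,
                         ramp_start = -0.3, ramp_depth = 0,
                         tic_times = numeric(), tic_duration = 0.5,
                         clinical_link = default_clinical_link(),
                         seed = 1L) {
  if (any(kappa < 0)) stop("kappa must be non-negative")
  if (ramp_start < -2 || ramp_start >= 0)
    stop("ramp_start must lie in [-2, 0)")
  if (ramp_depth < 0 || ramp_depth > 1)
    stop("ramp_depth must lie in [0, 1]")
  structure(list(kappa = kappa, band_center = band_center,
                 band_width = band_width, ramp_start = ramp_start,
                 ramp_depth = ramp_depth, tic_times = sort(tic_times),
                 tic_duration = tic_duration,
                 clinical_link = clinical_link, seed = as.integer(seed)),
            class = "SyntheticGroundTruth")
}

#' @rdname ground_truth
#' @export
default_clinical_link <- function() {
  # calibrated so that over the default coupling range (kappa 2-30,
  # PLV ~0.70-0.99) the scores span the severity range seen in medicated
  # adult TS cohorts (YGTSS TTS roughly 10-35, PUTS roughly 20-50)
  list(ygtss_a = 420, ygtss_b = 410, puts_a = 460, puts_b = 435,
       noise_sd = 2)
}

# 1/f noise by spectral shaping of white noise; returns the series plus
# its exact standard deviation inside [lo, hi] Hz (from the Parseval sum
# of the shaped coefficients), so oscillation amplitudes can be set to an
# in-band SNR without an extra filtering pass.
.pink_noise <- function(n, rate, lo = 8, hi = 12, exponent = 1) {
  stopifnot(n >= 8)
  half <- if (n %% 2 == 0) n / 2 - 1 else (n - 1) / 2  # positive non-Nyquist
  f <- seq_len(half) * rate / n
  z <- complex(real = stats::rnorm(half), imaginary = stats::rnorm(half)) /
    f^(exponent / 2)
  spec <- complex(real = numeric(n))
  spec[1 + seq_len(half)] <- z
  spec[n + 1 - seq_len(half)] <- Conj(z)
  if (n %% 2 == 0)
    spec[n / 2 + 1] <- stats::rnorm(1) / (rate / 2)^(exponent / 2)
  x <- Re(stats::fft(spec, inverse = TRUE)) / n
  sdx <- stats::sd(x)
  x <- x / sdx
  band <- f >= lo & f <= hi
  band_sd <- sqrt(2 * sum(Mod(spec[1 + which(band)])^2) / n^2) / sdx
  list(x = x, band_sd = band_sd)
}

# piecewise-constant block grid over [0, duration]: baseline blocks of
# block_s seconds, refined to ramp_block_s inside each pre-tic ramp with
# the per-block kappa scale factor of the linear decoupling ramp
.jitter_blocks <- function(duration, truth, block_s = 2, ramp_block_s = 0.15) {
  edges <- seq(0, duration, by = block_s)
  if (edges[length(edges)] < duration) edges <- c(edges, duration)
  for (onset in truth$tic_times) {
    r0 <- max(0, onset + truth$ramp_start)
    r1 <- min(onset + truth$tic_duration, duration)
    if (r1 <= r0) next
    sub <- seq(r0, r1, by = ramp_block_s)
    if (sub[length(sub)] < r1) sub <- c(sub, r1)
    edges <- c(edges, sub)
  }
  edges <- sort(unique(round(edges, 9)))
  starts <- edges[-length(edges)]
  ends <- edges[-1]
  mids <- (starts + ends) / 2
  scale <- rep(1, length(mids))
  for (onset in truth$tic_times) {
    r0 <- onset + truth$ramp_start
    # linear decoupling ramp up to onset, floor held during the tic
    inr <- mids > r0 & mids < onset
    scale[inr] <- 1 - truth$ramp_depth * (mids[inr] - r0) / (onset - r0)
    intic <- mids >= onset & mids < onset + truth$tic_duration
    scale[intic] <- 1 - truth$ramp_depth
  }
  data.frame(start = starts, end = ends, scale = scale)
}

#' Generate one synthetic LFP + EEG session
#'
#' Emulates the study's recording structure: a common band-limited alpha
#' oscillator (phase random walk inside the band) carried by both bipolar
#' thalamic LFP channels on top of 1/f background noise, and EEG channels
#' reproducing the oscillation with channel-specific von Mises phase
#' jitter (concentration `truth$kappa`) plus their own 1/f noise. The
#' jitter is piecewise constant over 2-s blocks so the measured PSI of a
#' channel converges to the Bessel ratio `I1(kappa)/I0(kappa)`; inside
#' `[ramp_start, 0]` before each tic the blocks shrink to 150 ms (on the
#' order of the alpha wavelet integration time, so the decoupling is not
#' smoothed away by the phase estimator) and the effective kappa is
#' linearly scaled down by `ramp_depth`, reaching
#' `kappa * (1 - ramp_depth)` at onset and holding that floor for the
#' tic duration before recovering — the programmed pre-tic decoupling.
#' Stimulation-artifact synchronisation markers are written near the
#' start and end of both streams.
#'
#' @param duration session length in seconds (>= 10).
#' @param truth a `SyntheticGroundTruth`.
#' @param lfp_rate,eeg_rate sampling rates in Hz; their ratio must be an
#'   integer (defaults 250 and 5000).
#' @param snr in-band amplitude signal-to-noise ratio: oscillation RMS
#'   divided by the 8-12 Hz RMS of the background (default 10, a
#'   prominent alpha peak; keeps measurement phase noise well below the
#'   von Mises jitter so the Bessel-ratio PLV expectation holds).
#' @param condition condition label stamped on the tic events.
#' @param sync_margin time of the first sync artifact (and distance of the
#'   last from the end), seconds.
#' @return A list with `lfp` and `eeg` `Recording`s, an `events`
#'   `EventTable` (tics + sync markers) and the `truth`.
#' @export
generate_recording <- function(duration, truth, lfp_rate = 250,
                               eeg_rate = 5000, snr = 10,
                               condition = "tic_freely",
                               sync_margin = 0.5) {
  if (duration < 10)
    stop("duration too short: no 4 s epoch plus margins fits below 10 s")
  ratio <- eeg_rate / lfp_rate
  if (abs(ratio - round(ratio)) > 1e-9)
    stop("eeg_rate must be an integer multiple of lfp_rate")
  ratio <- as.integer(round(ratio))
  withr::with_seed(truth$seed, {
    n_eeg <- round(duration * eeg_rate)
    # band-limited oscillator: instantaneous frequency meanders inside
    # the band between interpolated knots
    osc_phase <- function() {
      knots <- stats::runif(ceiling(duration / 0.5) + 1, -1, 1)
      m <- stats::approx(seq(0, by = 0.5, length.out = length(knots)),
                         knots, xout = (seq_len(n_eeg) - 1) / eeg_rate,
                         rule = 2)$y
      f_inst <- truth$band_center + truth$band_width / 2 * m
      cumsum(2 * pi * f_inst / eeg_rate) + stats::runif(1, -pi, pi)
    }
    phase <- osc_phase()

    amp_of <- function(noise) snr * noise$band_sd * sqrt(2)

    lfp <- matrix(0, 2, round(duration * lfp_rate))
    lfp_idx <- seq(1, n_eeg, by = ratio)[seq_len(ncol(lfp))]
    for (h in 1:2) {
      nz <- .pink_noise(ncol(lfp), lfp_rate)
      lfp[h, ] <- amp_of(nz) * cos(phase[lfp_idx]) + nz$x
    }

    blocks <- .jitter_blocks(duration, truth)
    b0 <- pmin(n_eeg, round(blocks$start * eeg_rate) + 1L)
    b1 <- pmin(n_eeg, round(blocks$end * eeg_rate))
    lens <- pmax(0L, b1 - b0 + 1L)

    chans <- names(truth$kappa)
    eeg <- matrix(0, length(chans), n_eeg)
    for (ci in seq_along(chans)) {
      k <- truth$kappa[ci]
      nz <- .pink_noise(n_eeg, eeg_rate)
      if (k < 0.05) {
        # an uncoupled channel has its own alpha generator, not the
        # thalamic oscillator with scrambled offsets: its phase must
        # drift freely so the original PSI sits at the surrogate level
        eeg[ci, ] <- amp_of(nz) * cos(osc_phase()) + nz$x
      } else {
        draws <- vapply(blocks$scale, function(s) rvonmises(1, k * s),
                        numeric(1))
        theta <- rep(draws, lens)[seq_len(n_eeg)]
        eeg[ci, ] <- amp_of(nz) * cos(phase + theta) + nz$x
      }
    }

    sync <- c(sync_margin, duration - sync_margin)
    onsets <- truth$tic_times[truth$tic_times + truth$tic_duration < duration]
    events <- event_table(
      onset = c(sync, onsets),
      offset = c(sync + 0.02, onsets + truth$tic_duration),
      kind = c("artifact_sync", "artifact_sync", rep("tic", length(onsets))),
      tic_type = c(NA, NA, rep("simple motor", length(onsets))),
      condition = c(NA, NA, rep(condition, length(onsets))))

    list(
      lfp = new_recording(lfp, lfp_rate, c("LFP_left", "LFP_right"), "LFP",
                          meta = list(hemisphere = c("left", "right"),
                                      device = "synthetic BrainSense")),
      eeg = new_recording(eeg, eeg_rate, chans, "EEG",
                          meta = list(device = "synthetic amplifier")),
      events = events, truth = truth)
  })
}

#' Generate a synthetic patient cohort
#'
#' Draws one coupling concentration per patient from `kappa_range`,
#' assigns it to the frontal channel preset (full strength at Fz, 70% on
#' the remaining frontal channels, zero elsewhere), generates the paired
#' LFP/EEG recordings with tic events, and derives clinical severity
#' scores decreasing in the coupling through the monotone link, so the
#' full pipeline should recover a negative PSI-severity correlation.
#'
#' @param n_patients number of patients (>= 2; default 6).
#' @param kappa_range length-2 range the per-patient kappa is drawn from.
#' @param clinical_link see [ground_truth()].
#' @param seed master seed; per-patient seeds are derived from it.
#' @param duration session length per patient in seconds (default 420,
#'   the eyes-open resting portion of a session).
#' @param channels EEG montage (default the 63-channel extended 10-20
#'   set).
#' @param coupled_channels channels that carry the coupling (default the
#'   frontal preset).
#' @param n_tics tics per patient, placed with at least 2 s of tic-free
#'   history plus epoch headroom.
#' @param ramp_start,ramp_depth pre-tic decoupling ramp (defaults -0.3 s,
#'   0.8).
#' @param eeg_rate,lfp_rate,snr,condition passed to
#'   [generate_recording()].
#' @return A list of class `SyntheticCohort`: `patients` (each with `id`,
#'   `lfp`, `eeg`, `events`, `truth`), `clinical` (a `ClinicalTable`),
#'   `seed`.
#' @export
generate_cohort <- function(n_patients = 6, kappa_range = c(2, 30),
                            clinical_link = default_clinical_link(),
                            seed = 1L, duration = 420,
                            channels = default_montage(),
                            coupled_channels = frontal_channels(),
                            n_tics = 10, ramp_start = -0.3,
                            ramp_depth = 0.8, eeg_rate = 5000,
                            lfp_rate = 250, snr = 10,
                            condition = "tic_freely") {
  if (n_patients < 2) stop("a cohort needs at least 2 patients")
  if (diff(range(kappa_range)) == 0)
    warning("degenerate kappa_range: all patients get identical coupling")
  withr::with_seed(seed, {
    kap <- stats::runif(n_patients, kappa_range[1], kappa_range[2])
    pat_seeds <- sample.int(.Machine$integer.max - 1L, n_patients)
    months <- round(stats::runif(n_patients, 3, 164))
    sides <- rep(c("left", "right"), length.out = n_patients)
    noise <- stats::rnorm(2 * n_patients, 0, clinical_link$noise_sd)
  })
  patients <- vector("list", n_patients)
  clin <- vector("list", n_patients)
  for (p in seq_len(n_patients)) {
    kv <- stats::setNames(rep(0, length(channels)), channels)
    kv[intersect(coupled_channels, channels)] <- 0.7 * kap[p]
    if ("Fz" %in% channels) kv["Fz"] <- kap[p]
    tic_times <- withr::with_seed(pat_seeds[p], {
      if (n_tics == 1L) {
        duration / 2
      } else {
        slots <- seq(10, duration - 6, length.out = n_tics)
        spacing <- slots[2] - slots[1]
        if (spacing < 6)
          stop("duration too short to place ", n_tics, " isolated tics")
        slots + stats::runif(n_tics, 0, max(0, min(2, spacing - 5)))
      }
    })
    truth <- ground_truth(kappa = kv, ramp_start = ramp_start,
                          ramp_depth = ramp_depth, tic_times = tic_times,
                          clinical_link = clinical_link,
                          seed = pat_seeds[p])
    rec <- generate_recording(duration, truth, lfp_rate = lfp_rate,
                              eeg_rate = eeg_rate, snr = snr,
                              condition = condition)
    id <- sprintf("P%02d", p)
    patients[[p]] <- c(list(id = id), rec)
    plv <- expected_plv(kap[p])
    ygtss <- max(0, clinical_link$ygtss_a - clinical_link$ygtss_b * plv +
                   noise[2 * p - 1])
    puts <- max(0, clinical_link$puts_a - clinical_link$puts_b * plv +
                  noise[2 * p])
    clin[[p]] <- data.frame(patient_id = id, age = NA_real_, sex = "M",
                            months_since_op = months[p],
                            dbs_target = "CM_Voi", ipg_side = sides[p],
                            ygtss_tts = ygtss, ygtss_global = ygtss + 20,
                            puts = puts, stringsAsFactors = FALSE)
  }
  clinical <- do.call(rbind, clin)
  class(clinical) <- c("ClinicalTable", "data.frame")
  names(patients) <- vapply(patients, `[[`, "", "id")
  structure(list(patients = patients, clinical = clinical, seed = seed),
            class = "SyntheticCohort")
}

#' Tabulate the ground truth of a synthetic cohort
#'
#' @param cohort a `SyntheticCohort`.
#' @return A data frame with one row per patient and coupled channel:
#'   `patient`, `channel`, `kappa`, `ramp_start`, `ramp_depth`,
#'   `expected_plv` (the Bessel-ratio PLV `I1(kappa)/I0(kappa)`).
#' @export
ground_truth_report <- function(cohort) {
  rows <- lapply(cohort$patients, function(p) {
    tr <- p$truth
    data.frame(patient = p$id, channel = names(tr$kappa),
               kappa = unname(tr$kappa), ramp_start = tr$ramp_start,
               ramp_depth = tr$ramp_depth,
               expected_plv = unname(expected_plv(tr$kappa)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
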