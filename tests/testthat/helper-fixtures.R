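# shared fixture builders -------------------------------------------------

# round doubles through float32 so BrainVision IEEE_FLOAT_32 round trips
# are bit-exact
float32_round <- function(x) {
  readBin(writeBin(as.numeric(x), raw(), size = 4L), "numeric",
          n = length(x), size = 4L)
}

random_lfp_recording <- function(n = 1500, rate = 250, seed = 1,
                                 channels = c("LFP_left", "LFP_right")) {
  withr::with_seed(seed, {
    data <- matrix(rnorm(length(channels) * n), length(channels), n)
    new_recording(data, rate, channels, "LFP",
                  meta = list(hemisphere = sub("LFP_", "", channels)))
  })
}

# a TFDecomposition built directly from phase arrays (trials x samples),
# bypassing the wavelet transform, for exact-value PSI tests
phase_tf <- function(phases, freqs = 10, rate = 250, amplitude = 1) {
  if (is.matrix(phases)) phases <- array(phases, c(dim(phases)[1], 1,
                                                   dim(phases)[2]))
  n_t <- dim(phases)[1]; n_s <- dim(phases)[3]
  coeffs <- array(complex(real = 0), c(n_t, 1, length(freqs), n_s))
  for (k in seq_along(freqs))
    coeffs[, 1, k, ] <- amplitude * exp(1i * phases[, 1, ])
  structure(list(coeffs = coeffs, freqs = freqs, rate = rate, cycles = NA,
                 times = (seq_len(n_s) - 1) / rate,
                 valid = matrix(TRUE, length(freqs), n_s),
                 channel_labels = "ch"),
            class = "TFDecomposition")
}

# sinusoid epochs for spectral tests
sinusoid_epochs <- function(freq = 10, amplitude = 1, n_trials = 3,
                            len_s = 4, rate = 250, phase = 0) {
  n <- len_s * rate
  t <- (seq_len(n) - 1) / rate
  data <- array(0, c(n_trials, 1, n))
  for (i in seq_len(n_trials))
    data[i, 1, ] <- amplitude * cos(2 * pi * freq * t + phase)
  new_epoch_set(data, rate, c(0, len_s), "segment_start", "rest", "ch")
}

# small recovery cohort used by pipeline and acceptance tests: reduced
# montage, EEG generated directly on the 250 Hz LFP time base, shortened
# sessions -- the statistical structure (6 patients, frontal coupling,
# negative clinical link, pre-tic decoupling ramp) is unchanged
recovery_cohort <- function(seed, duration = 120, n_tics = 8,
                            ramp_start = -0.3, ramp_depth = 0.8,
                            noise_sd = 2) {
  link <- default_clinical_link()
  link$noise_sd <- noise_sd
  generate_cohort(
    n_patients = 6, kappa_range = c(2, 30), clinical_link = link,
    seed = seed, duration = duration,
    channels = c("Fz", "F1", "F2", "FC1", "FC2",
                 "Cz", "Pz", "Oz", "C3", "C4"),
    n_tics = n_tics, ramp_start = ramp_start, ramp_depth = ramp_depth,
    eeg_rate = 250)
}

# reduced-size analysis configuration for pipeline tests: three grid
# frequencies per band and fewer Monte-Carlo iterations
recovery_config <- function(seed = 1, n_perm = 300) {
  analysis_config(
    freqs = c(3, 5, 7, 8, 10, 12, 13, 21, 30),
    surrogate_iters = 50,
    stats = stats_config(n_permutations = n_perm, seed = seed))
}
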