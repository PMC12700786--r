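#' Analysis configuration
#'
#' Bundles the study parameters shared by the three analyses: the
#' frequency grid and wavelet cycles of the decomposition, the canonical
#' bands, the 4-s rest epochs, the -1.8 to 0.6 s tic-locked range with
#' the 0.3 s / 0.004 s sliding PSI window and the 0.1 s / 0.02 s test
#' windows, the channel of interest (Fz) and the cortical
#' regions-of-interest label set, plus a `StatsConfig`.
#'
#' @param bands list of `BandSpec`s.
#' @param rest_epoch_s rest epoch length (s).
#' @param tic_range analysis range around tic onset (s).
#' @param test_window,test_step statistical test-window length and step
#'   (s); windows tile `[tic_range[1], tic_range[2] - test_window]`.
#' @param slide_window,slide_step sliding-PSI window length and step (s).
#' @param channel_of_interest EEG channel for correlations and tic
#'   dynamics.
#' @param roi_labels cortical source regions of interest.
#' @param band_of_interest band for the tic-locked and correlation
#'   analyses.
#' @param freqs decomposition grid (Hz).
#' @param wavelet_cycles Morlet cycles.
#' @param surrogate_iters trial-shuffling iterations for surrogate PSI.
#' @param stats a `StatsConfig`.
#' @return A list of class `AnalysisConfig`.
#' @export
analysis_config <- function(bands = default_bands(), rest_epoch_s = 4,
                            tic_range = c(-1.8, 0.6), test_window = 0.1,
                            test_step = 0.02, slide_window = 0.3,
                            slide_step = 0.004,
                            channel_of_interest = "Fz",
                            roi_labels = c("M1", "S1", "CMC", "SMA",
                                           "PMC", "IC_FOp", "ACC_mPFC",
                                           "IPC"),
                            band_of_interest = "alpha", freqs = 2:40,
                            wavelet_cycles = 5, surrogate_iters = 100,
                            stats = stats_config()) {
  stopifnot(test_window > test_step)
  structure(list(bands = bands, rest_epoch_s = rest_epoch_s,
                 tic_range = tic_range, test_window = test_window,
                 test_step = test_step, slide_window = slide_window,
                 slide_step = slide_step,
                 channel_of_interest = channel_of_interest,
                 roi_labels = roi_labels,
                 band_of_interest = band_of_interest, freqs = freqs,
                 wavelet_cycles = wavelet_cycles,
                 surrogate_iters = surrogate_iters, stats = stats),
            class = "AnalysisConfig")
}

#' Cut the standard epoch types from one synthetic or loaded session
#'
#' Applies the tic-selection rules (sequence merging, >= 2 s isolation),
#' brings the EEG onto the LFP time base, and cuts channel-bound rest and
#' tic epochs from the paired recordings.
#'
#' @param session list with `lfp` and `eeg` `Recording`s and an `events`
#'   `EventTable` (e.g. one element of a `SyntheticCohort`).
#' @param cfg an `AnalysisConfig`.
#' @param tic_window tic epoch window (s around onset).
#' @return A list with `rest` and `tic` `EpochSet`s (either may be `NULL`
#'   when nothing survives) and the processed `events`.
#' @export
session_epochs <- function(session, cfg = analysis_config(),
                           tic_window = c(-2.1, 0.9)) {
  eeg <- resample_recording(session$eeg, session$lfp$rate)
  events <- select_isolated_tics(merge_tic_sequences(session$events))
  cond <- unique(events_of_kind(events, "tic")$condition)
  rest <- tryCatch({
    a <- extract_rest_epochs(session$lfp, events, cfg$rest_epoch_s,
                             condition = if (length(cond) == 1) cond
                             else "tic_freely")
    b <- extract_rest_epochs(eeg, events, cfg$rest_epoch_s,
                             condition = a$condition)
    bind_epoch_channels(a, b)
  }, error = function(e) NULL)
  tic <- tryCatch({
    a <- extract_tic_epochs(session$lfp, events, tic_window)
    b <- extract_tic_epochs(eeg, events, tic_window)
    bind_epoch_channels(a, b)
  }, error = function(e) NULL)
  list(rest = rest, tic = tic, events = events)
}

.lfp_channels <- c("LFP_left", "LFP_right")

.eeg_channels <- function(epochs) setdiff(epochs$channel_labels,
                                          .lfp_channels)

# trial subset of a TFDecomposition (bootstrap matching)
.tf_subset_trials <- function(tf, idx) {
  tf$coeffs <- tf$coeffs[idx, , , , drop = FALSE]
  tf
}

# static band PSI, band power helpers
.band_psi <- function(tf, chan_a, chan_b, band) {
  unname(band_average(psi_static(tf, tf, chan_a, chan_b), band))
}

.band_power_norm <- function(tf, band) {
  ps <- normalize_power(power_spectrum(tf))
  band_average(ps, band)
}

#' Resting-state connectivity analysis
#'
#' For every EEG channel and hemisphere, band-averaged original and
#' trial-shuffled surrogate PSI between the thalamic LFP and that channel
#' enter a three-way Condition (original vs surrogate) x Frequency
#' (theta/alpha/beta) x Hemisphere permutation ANOVA, each thalamus
#' counting as one independent sample. Channels whose
#' Condition-by-Frequency interaction survives FDR and whose post-hoc
#' original-vs-surrogate difference is significant in the alpha band and
#' larger than in any other band are flagged as the spatially and
#' spectrally specific network (strict alpha exclusivity is reported per
#' channel in `alpha_exclusive`). The peak
#' alpha channel is tested against the mean of all other channels (paired
#' over hemispheres), and the hemisphere-averaged alpha PSI at the
#' channel of interest is correlated (Spearman, exact permutation p) with
#' the clinical severity scores, with thalamic and channel alpha power as
#' controls.
#'
#' @param epochs named list (one per patient) of rest `EpochSet`s whose
#'   channels include `LFP_left`, `LFP_right` and the EEG montage.
#' @param clinical a `ClinicalTable` covering every patient in `epochs`.
#' @param cfg an `AnalysisConfig`.
#' @return A list of class `RestAnalysisResult`; see Details in the
#'   package vignette.
#' @export
run_rest_analysis <- function(epochs, clinical, cfg = analysis_config()) {
  if (length(epochs) < 1L) stop("no rest epochs supplied")
  eeg_ch <- .eeg_channels(epochs[[1]])
  seed0 <- if (is.null(cfg$stats$seed)) 0L else cfg$stats$seed
  psi_rows <- list()
  pow_rows <- list()
  n_hemi <- 0L
  for (pid in names(epochs)) {
    ep <- epochs[[pid]]
    tf <- decompose(ep, freqs = cfg$freqs, cycles = cfg$wavelet_cycles)
    ps <- normalize_power(power_spectrum(tf))
    for (b in cfg$bands) {
      bp <- band_average(ps, b)
      pow_rows[[length(pow_rows) + 1L]] <- data.frame(
        patient = pid, channel = names(bp), band = b$name,
        power = unname(bp), stringsAsFactors = FALSE)
    }
    counter <- 0L
    for (hemi in c("left", "right")) {
      n_hemi <- n_hemi + 1L
      lfp_ch <- paste0("LFP_", hemi)
      for (e in eeg_ch) {
        counter <- counter + 1L
        orig <- psi_static(tf, tf, lfp_ch, e)
        sur <- surrogate_psi(tf, tf, lfp_ch, e,
                             n_iter = cfg$surrogate_iters,
                             seed = (seed0 + 7919L * match(pid, names(epochs))
                                     + counter) %% .Machine$integer.max)
        for (b in cfg$bands) {
          psi_rows[[length(psi_rows) + 1L]] <- data.frame(
            patient = pid, hemisphere = hemi, channel = e, band = b$name,
            condition = c("original", "surrogate"),
            psi = c(band_average(orig, b),
                    band_average(sur$mean, b, freqs = tf$freqs)),
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  psi_tab <- do.call(rbind, psi_rows)
  pow_tab <- do.call(rbind, pow_rows)
  if (n_hemi < 2L) stop("rest analysis needs at least 2 hemispheres")

  # per-channel 2 x 3 x 2 permutation ANOVA + post-hoc per band
  bands <- vapply(cfg$bands, `[[`, "", "name")
  anova_by_channel <- list()
  posthoc_by_channel <- list()
  for (e in eeg_ch) {
    sub <- psi_tab[psi_tab$channel == e, ]
    fac <- data.frame(Condition = sub$condition, Frequency = sub$band,
                      Hemisphere = sub$hemisphere)
    anova_by_channel[[e]] <- perm_anova(sub$psi, fac, cfg$stats)
    int_p <- anova_by_channel[[e]][["Condition:Frequency"]]$p_mc
    if (int_p <= cfg$stats$alpha) {
      pairs <- cbind(paste0("original:", bands),
                     paste0("surrogate:", bands))
      posthoc_by_channel[[e]] <- perm_posthoc(
        sub$psi, fac, c("Condition", "Frequency"), cfg$stats, pairs)
      posthoc_by_channel[[e]]$band <- bands
    }
  }

  # one FDR family over interaction p-values and all post-hoc p-values
  int_p <- vapply(anova_by_channel, function(a)
    a[["Condition:Frequency"]]$p_mc, numeric(1))
  ph_p <- unlist(lapply(posthoc_by_channel, `[[`, "p_mc"))
  fam <- c(int_p, ph_p)
  fdr <- fdr_bh(fam, cfg$stats$fdr_alpha)
  int_rej <- fdr$rejected[seq_along(int_p)]
  names(int_rej) <- names(int_p)
  ph_rej <- fdr$rejected[-seq_along(int_p)]
  at <- 0L
  flagged <- character()
  alpha_exclusive <- logical()
  for (e in names(posthoc_by_channel)) {
    ph <- posthoc_by_channel[[e]]
    rej <- ph_rej[at + seq_len(nrow(ph))]
    posthoc_by_channel[[e]]$fdr_significant <- rej
    at <- at + length(rej)
    # spectral specificity: the alpha original-vs-surrogate difference is
    # significant and dominates the other bands; strict "alpha and
    # nothing else" exclusivity is reported alongside (wavelet skirts
    # leak strong alpha coupling into the 13-16 Hz bins, so exclusivity
    # only obtains at weak coupling)
    a <- bands == "alpha"
    dominant <- rej[a] &&
      ph$difference[a] > max(abs(ph$difference[!a]))
    alpha_exclusive[e] <- rej[a] && !any(rej[!a])
    if (int_rej[[e]] && dominant) flagged <- c(flagged, e)
  }

  # peak alpha channel vs the mean of all other channels
  alpha_orig <- psi_tab[psi_tab$band == cfg$band_of_interest &
                          psi_tab$condition == "original", ]
  hemi_key <- paste(alpha_orig$patient, alpha_orig$hemisphere)
  psi_mat <- tapply(alpha_orig$psi, list(hemi_key, alpha_orig$channel),
                    mean)
  ch_means <- colMeans(psi_mat)
  peak_channel <- names(which.max(ch_means))
  peak_vals <- psi_mat[, peak_channel]
  other_means <- rowMeans(psi_mat[, colnames(psi_mat) != peak_channel,
                                  drop = FALSE])
  peak_test <- perm_ttest_paired(peak_vals, other_means, cfg$stats)
  peak <- list(channel = peak_channel, mean = mean(peak_vals),
               sem = stats::sd(peak_vals) / sqrt(length(peak_vals)),
               test = peak_test)

  # clinical correlations on hemisphere-averaged values per patient
  coi <- cfg$channel_of_interest
  per_patient <- function(tab, chan) {
    v <- tab[tab$channel == chan, ]
    tapply(v$value, v$patient, mean)[names(epochs)]
  }
  alpha_orig$value <- alpha_orig$psi
  coi_psi <- per_patient(alpha_orig, coi)
  pow_alpha <- pow_tab[pow_tab$band == cfg$band_of_interest, ]
  pow_alpha$value <- pow_alpha$power
  lfp_alpha <- pow_alpha[pow_alpha$channel %in% .lfp_channels, ]
  lfp_alpha$channel <- "LFP"
  lfp_power <- per_patient(lfp_alpha, "LFP")
  coi_power <- per_patient(pow_alpha, coi)
  row <- match(names(epochs), clinical$patient_id)
  if (anyNA(row)) stop("missing clinical scores for patient(s): ",
                       paste(names(epochs)[is.na(row)], collapse = ", "))
  scores <- list(ygtss_tts = clinical$ygtss_tts[row],
                 puts = clinical$puts[row])
  correlate <- function(vals) {
    res <- lapply(scores, function(s) perm_spearman(vals, s, cfg$stats))
    ps <- vapply(res, `[[`, 0, "p")
    adj <- fdr_bh(ps, cfg$stats$fdr_alpha)
    for (i in seq_along(res)) {
      res[[i]]$p_fdr <- adj$adjusted[i]
      res[[i]]$fdr_significant <- adj$rejected[i]
    }
    res
  }
  correlations <- list(psi = correlate(coi_psi),
                       lfp_power = correlate(lfp_power),
                       channel_power = correlate(coi_power))

  structure(list(psi_table = psi_tab, power_table = pow_tab,
                 anova = anova_by_channel, posthoc = posthoc_by_channel,
                 interaction_fdr_significant = int_rej,
                 flagged_channels = flagged,
                 alpha_exclusive = alpha_exclusive, peak = peak,
                 per_patient = list(psi = coi_psi, lfp_power = lfp_power,
                                    channel_power = coi_power),
                 correlations = correlations),
            class = "RestAnalysisResult")
}

#' Tic-suppression contrast
#'
#' Paired permutation t-tests comparing the tic-freely and
#' tic-suppression conditions on (a) per-patient tic frequency (tics per
#' minute, rest-recording tics excluded), (b) alpha PSI between the
#' thalamus and the channel of interest per hemisphere, (c) normalised
#' thalamic alpha LFP power per hemisphere, and (d) normalised alpha
#' power at the channel of interest per patient. Patients lacking one of
#' the conditions are dropped and listed in `dropped`.
#'
#' @param epochs_rest,epochs_supp named per-patient lists of `EpochSet`s
#'   for the tic-freely rest epochs and the suppression epochs.
#' @param tic_counts data frame with `patient`, `condition`
#'   (`tic_freely` / `tic_suppression`), `n_tics`, `duration_s` per task
#'   block set (rest-recording tics already excluded).
#' @param cfg an `AnalysisConfig`.
#' @return A list of class `SuppressionResult` with `tic_rate`, `psi`,
#'   `lfp_power`, `channel_power` (`StatResult`s) and `dropped`.
#' @export
run_suppression_analysis <- function(epochs_rest, epochs_supp, tic_counts,
                                     cfg = analysis_config()) {
  common <- intersect(names(epochs_rest), names(epochs_supp))
  dropped <- setdiff(union(names(epochs_rest), names(epochs_supp)), common)
  if (length(dropped))
    message("dropped from suppression analysis (missing condition): ",
            paste(dropped, collapse = ", "))
  if (length(common) < 2L) stop("suppression contrast needs >= 2 paired patients")
  coi <- cfg$channel_of_interest
  band <- cfg$band_of_interest
  vals <- list(psi = list(), lfp = list(), chan = list())
  for (pid in common) {
    for (cond in c("rest", "supp")) {
      ep <- if (cond == "rest") epochs_rest[[pid]] else epochs_supp[[pid]]
      tf <- decompose(ep, freqs = cfg$freqs, cycles = cfg$wavelet_cycles)
      bp <- .band_power_norm(tf, band)
      vals$chan[[paste(pid, cond)]] <- unname(bp[coi])
      for (hemi in c("left", "right")) {
        lfp_ch <- paste0("LFP_", hemi)
        vals$psi[[paste(pid, hemi, cond)]] <-
          .band_psi(tf, lfp_ch, coi, band)
        vals$lfp[[paste(pid, hemi, cond)]] <- unname(bp[lfp_ch])
      }
    }
  }
  paired <- function(keys_rest, keys_supp, store)
    perm_ttest_paired(unlist(store[keys_rest]), unlist(store[keys_supp]),
                      cfg$stats)
  hemi_keys <- as.vector(t(outer(common, c("left", "right"), paste)))
  psi_t <- paired(paste(hemi_keys, "rest"), paste(hemi_keys, "supp"),
                  vals$psi)
  lfp_t <- paired(paste(hemi_keys, "rest"), paste(hemi_keys, "supp"),
                  vals$lfp)
  chan_t <- paired(paste(common, "rest"), paste(common, "supp"), vals$chan)

  tc <- tic_counts[tic_counts$patient %in% common, ]
  rate <- function(cond) {
    sub <- tc[tc$condition == cond, ]
    r <- sub$n_tics / sub$duration_s * 60
    stats::setNames(r, sub$patient)[common]
  }
  rate_t <- perm_ttest_paired(rate("tic_freely"), rate("tic_suppression"),
                              cfg$stats)
  structure(list(tic_rate = rate_t, psi = psi_t, lfp_power = lfp_t,
                 channel_power = chan_t, patients = common,
                 dropped = dropped),
            class = "SuppressionResult")
}

#' Tic-locked connectivity and power dynamics
#'
#' For each target, band-limited sliding series (0.3 s window, 0.004 s
#' steps by default) are computed per statistical unit (hemisphere for
#' LFP-involving targets, patient for scalp/source power), aggregated
#' into 0.1 s test windows stepping at 0.02 s across the analysis range,
#' and compared window-wise against the static rest value of the same
#' unit (rest trials bootstrap-matched to the tic trial count) with
#' paired permutation t-tests; the window p-series is cluster-corrected,
#' and a linear trend is fitted to the grand-average relative-change
#' series from -1.8 s to tic onset.
#'
#' @param tic_epochs named per-patient list of pooled tic `EpochSet`s.
#' @param rest_epochs named per-patient list of rest `EpochSet`s (the
#'   baseline).
#' @param targets list with `psi` (channel labels paired against each
#'   thalamic LFP) and `power` (channel labels; `"LFP"` expands to the
#'   per-hemisphere thalamic channels).
#' @param cfg an `AnalysisConfig`.
#' @return A named list of class `TicAnalysisResult`, one entry per
#'   target (`psi:<ch>` / `power:<ch>`), each with the sliding times,
#'   `rel_change`, `window_starts`, `window_p`, `cluster`, `trend`,
#'   `n_units`, `skipped`.
#' @export
run_tic_analysis <- function(tic_epochs, rest_epochs,
                             targets = list(psi = "Fz",
                                            power = c("LFP", "Fz")),
                             cfg = analysis_config()) {
  band <- band_spec(cfg$band_of_interest)
  bfreqs <- cfg$freqs[cfg$freqs >= band$lo & cfg$freqs <= band$hi]
  seed0 <- if (is.null(cfg$stats$seed)) 0L else cfg$stats$seed
  pats <- intersect(names(tic_epochs), names(rest_epochs))
  if (!length(pats)) stop("no patients with both tic and rest epochs")

  need <- unique(c(.lfp_channels, targets$psi,
                   setdiff(targets$power, "LFP")))
  tf_tic <- list(); tf_rest <- list(); boot_idx <- list()
  usable <- character()
  for (pid in pats) {
    chs <- intersect(need, tic_epochs[[pid]]$channel_labels)
    if (n_trials(tic_epochs[[pid]]) < 5L) {
      message("skipping ", pid, ": fewer than 5 tic trials")
      next
    }
    usable <- c(usable, pid)
    tf_tic[[pid]] <- decompose(tic_epochs[[pid]], freqs = bfreqs,
                               cycles = cfg$wavelet_cycles,
                               channels = chs)
    tf_rest[[pid]] <- decompose(rest_epochs[[pid]], freqs = bfreqs,
                                cycles = cfg$wavelet_cycles,
                                channels = chs)
    boot_idx[[pid]] <- withr::with_seed(
      (seed0 + 104729L * match(pid, pats)) %% .Machine$integer.max,
      sample.int(n_trials(rest_epochs[[pid]]),
                 n_trials(tic_epochs[[pid]]), replace = TRUE))
  }
  if (!length(usable)) stop("insufficient trials in every patient")

  centers <- seq(cfg$tic_range[1], cfg$tic_range[2], by = cfg$slide_step)
  w_starts <- seq(cfg$tic_range[1], cfg$tic_range[2] - cfg$test_window,
                  by = cfg$test_step)
  w_bins <- lapply(w_starts, function(t0)
    which(centers >= t0 - 1e-9 & centers < t0 + cfg$test_window - 1e-9))

  analyse_series <- function(series_mat, rest_vals) {
    W <- t(vapply(seq_len(nrow(series_mat)), function(u)
      vapply(w_bins, function(b) mean(series_mat[u, b]), numeric(1)),
      numeric(length(w_bins))))
    pvals <- vapply(seq_along(w_bins), function(w)
      perm_ttest_paired(W[, w], rest_vals, cfg$stats)$p_mc, numeric(1))
    cluster <- cluster_mcs(pvals, cfg$stats)
    grand <- colMeans(series_mat)
    rel <- relative_change(grand, mean(rest_vals))
    pre <- centers >= cfg$tic_range[1] - 1e-9 & centers <= 1e-9
    trend <- linreg_trend(centers[pre], rel[pre], cfg$stats)
    list(times = centers, rel_change = rel, window_starts = w_starts,
         window_p = pvals, cluster = cluster, trend = trend,
         n_units = nrow(series_mat))
  }

  results <- list()
  skipped <- character()

  for (ch in targets$psi) {
    if (!all(vapply(usable, function(p)
      ch %in% tf_tic[[p]]$channel_labels, TRUE))) {
      skipped <- c(skipped, paste0("psi:", ch))
      message("skipping PSI target ", ch, ": channel missing")
      next
    }
    rows <- list(); rest_v <- numeric()
    for (pid in usable) {
      sub_rest <- .tf_subset_trials(tf_rest[[pid]], boot_idx[[pid]])
      for (hemi in c("left", "right")) {
        lfp_ch <- paste0("LFP_", hemi)
        sl <- psi_sliding(tf_tic[[pid]], tf_tic[[pid]], lfp_ch, ch,
                          band, cfg$slide_window, cfg$slide_step,
                          range = cfg$tic_range)
        rows[[length(rows) + 1L]] <- sl$values
        rest_v <- c(rest_v, .band_psi(sub_rest, lfp_ch, ch, band))
      }
    }
    results[[paste0("psi:", ch)]] <-
      analyse_series(do.call(rbind, rows), rest_v)
  }

  for (tgt in targets$power) {
    # "LFP" pools both hemispheres as units; scalp/source channels use
    # one unit per patient
    chans_of <- function() if (tgt == "LFP") .lfp_channels else tgt
    if (!all(vapply(usable, function(p)
      all(chans_of() %in% tf_tic[[p]]$channel_labels), TRUE))) {
      skipped <- c(skipped, paste0("power:", tgt))
      message("skipping power target ", tgt, ": channel missing")
      next
    }
    rows <- list(); rest_v <- numeric()
    for (pid in usable) {
      sub_rest <- .tf_subset_trials(tf_rest[[pid]], boot_idx[[pid]])
      ps <- power_spectrum(sub_rest)
      bp <- band_average(ps, band)
      for (ch in chans_of()) {
        sl <- sliding_band_power(tf_tic[[pid]], ch, band,
                                 cfg$slide_window, cfg$slide_step,
                                 range = cfg$tic_range)
        rows[[length(rows) + 1L]] <- sl$values
        rest_v <- c(rest_v, unname(bp[ch]))
      }
    }
    results[[paste0("power:", tgt)]] <-
      analyse_series(do.call(rbind, rows), rest_v)
  }
  structure(c(results, list(.skipped = skipped, .patients = usable)),
            class = "TicAnalysisResult")
}
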