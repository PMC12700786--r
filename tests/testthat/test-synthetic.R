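test_that("the Bessel-ratio PLV oracle has the right endpoints", {
  expect_equal(expected_plv(0), 0)
  expect_equal(expected_plv(2), besselI(2, 1) / besselI(2, 0))
  expect_equal(round(expected_plv(2), 3), 0.698)
  expect_gt(expected_plv(500), 0.998)
  expect_true(all(diff(expected_plv(c(0, 1, 2, 5, 10, 50))) > 0))
})

test_that("the von Mises sampler matches its analytic resultant", {
  withr::local_seed(11)
  for (k in c(0.5, 2, 10)) {
    th <- rvonmises(20000, k)
    expect_lt(abs(Mod(mean(exp(1i * th))) - expected_plv(k)), 0.02)
    expect_equal(Arg(mean(exp(1i * th))), 0, tolerance = 0.05)
  }
  expect_error(rvonmises(5, -1), "non-negative")
})

test_that("generation is bit-identical under a fixed seed", {
  tr <- ground_truth(kappa = c(Fz = 5, Cz = 0), tic_times = c(20, 40),
                     ramp_depth = 0.5, seed = 77)
  a <- generate_recording(60, tr, eeg_rate = 250)
  b <- generate_recording(60, tr, eeg_rate = 250)
  expect_identical(a$lfp$data, b$lfp$data)
  expect_identical(a$eeg$data, b$eeg$data)
  expect_identical(a$events, b$events)
  expect_error(generate_recording(5, tr), "too short")
})

test_that("measured PSI of generated channels matches I1(k)/I0(k)", {
  # 200 rest epochs per kappa; MC tolerance 0.03
  for (k in c(0, 2, 10, 50)) {
    tr <- ground_truth(kappa = c(Fz = k), seed = 100 + k)
    rec <- generate_recording(830, tr, eeg_rate = 250)
    ep <- session_epochs(rec)
    expect_gte(n_trials(ep$rest), 200)
    tf <- decompose(ep$rest, freqs = 8:12,
                    channels = c("LFP_left", "Fz"))
    psi <- band_average(psi_static(tf, tf, "LFP_left", "Fz"), "alpha")
    expect_lt(abs(psi - expected_plv(k)), 0.03,
              label = sprintf("|PSI - PLV| at kappa=%g", k))
  }
})

test_that("a strongly coupled channel is maximal and uncoupled ones idle", {
  tr <- ground_truth(kappa = c(Fz = 50, Cz = 0, Pz = 0), seed = 301)
  rec <- generate_recording(420, tr, eeg_rate = 250)
  ep <- session_epochs(rec)
  tf <- decompose(ep$rest, freqs = 8:12)
  psis <- vapply(c("Fz", "Cz", "Pz"), function(ch)
    band_average(psi_static(tf, tf, "LFP_left", ch), "alpha"), numeric(1))
  expect_gt(psis["Fz"], 0.8)
  expect_equal(names(which.max(psis)), "Fz")
  # kappa = 0: statistically indistinguishable from the surrogate level
  sur <- surrogate_psi(tf, tf, "LFP_left", "Cz", n_iter = 100, seed = 1)
  sur_alpha <- band_average(sur$mean, "alpha", freqs = tf$freqs)
  expect_lt(abs(psis["Cz"] - sur_alpha), 3 / sqrt(n_trials(ep$rest)))
})

test_that("the programmed pre-tic ramp depresses the sliding PSI", {
  tic_times <- seq(15, 225, by = 12)
  tr <- ground_truth(kappa = c(Fz = 10), ramp_start = -0.5,
                     ramp_depth = 0.8, tic_times = tic_times, seed = 55)
  rec <- generate_recording(240, tr, eeg_rate = 250)
  ep <- session_epochs(rec)
  tf <- decompose(ep$tic, freqs = 8:12)
  sl <- psi_sliding(tf, tf, "LFP_left", "Fz", "alpha")
  inramp <- mean(sl$values[sl$times >= -0.5 & sl$times <= 0])
  baseline <- mean(sl$values[sl$times <= -1.0])
  expect_lt(inramp, baseline)
  # the decoupling floor around onset is a pronounced drop
  floor_psi <- mean(sl$values[sl$times >= -0.25 & sl$times <= 0.3])
  expect_lt(floor_psi, baseline - 0.1)
})

test_that("generated tic events respect isolation and ordering", {
  cohort <- recovery_cohort(seed = 5, duration = 100)
  for (p in cohort$patients) {
    ev <- events_of_kind(p$events, "tic")
    expect_true(all(diff(ev$onset) > 0))
    sel <- select_isolated_tics(merge_tic_sequences(p$events))
    expect_equal(nrow(events_of_kind(sel, "tic")), nrow(ev))
  }
})

test_that("the clinical link is monotone decreasing in coupling", {
  cohort <- recovery_cohort(seed = 9, duration = 30, n_tics = 1,
                            noise_sd = 0)
  kap <- vapply(cohort$patients, function(p) p$truth$kappa[["Fz"]], 0)
  expect_equal(cor(expected_plv(kap), cohort$clinical$ygtss_tts,
                   method = "spearman"), -1)
  expect_equal(cor(expected_plv(kap), cohort$clinical$puts,
                   method = "spearman"), -1)
  expect_true(all(cohort$clinical$ygtss_tts <=
                    cohort$clinical$ygtss_global))
  expect_warning(generate_cohort(n_patients = 2, kappa_range = c(5, 5),
                                 duration = 30, n_tics = 1,
                                 eeg_rate = 250,
                                 channels = c("Fz", "Cz")),
                 "degenerate")
})

test_that("the ground-truth report carries the Bessel-ratio expectations", {
  cohort <- recovery_cohort(seed = 3, duration = 30, n_tics = 1)
  rep <- ground_truth_report(cohort)
  expect_equal(rep$expected_plv[rep$kappa == 0],
               rep(0, sum(rep$kappa == 0)))
  expect_equal(rep$expected_plv, unname(expected_plv(rep$kappa)))
  expect_equal(nrow(rep), 6 * 10)
  fz <- rep[rep$channel == "Fz", ]
  expect_true(all(fz$kappa >= 2 & fz$kappa <= 30))
})
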