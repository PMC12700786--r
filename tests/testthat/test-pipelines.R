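# one reduced recovery cohort shared across the pipeline tests
cohort <- recovery_cohort(seed = 1)
cfg <- recovery_config(seed = 1)
eps <- lapply(cohort$patients, session_epochs, cfg = cfg)
rest <- lapply(eps, `[[`, "rest")
tic <- lapply(eps, `[[`, "tic")
rest_res <- run_rest_analysis(rest, cohort$clinical, cfg)

test_that("rest analysis recovers the frontal alpha network", {
  frontal <- c("Fz", "F1", "F2", "FC1", "FC2")
  expect_true(all(frontal %in% rest_res$flagged_channels))
  # frontal channels carry the largest alpha original-surrogate effects
  alpha_diff <- vapply(names(rest_res$anova), function(ch) {
    tab <- rest_res$psi_table
    sub <- tab[tab$channel == ch & tab$band == "alpha", ]
    mean(sub$psi[sub$condition == "original"]) -
      mean(sub$psi[sub$condition == "surrogate"])
  }, numeric(1))
  top <- names(sort(alpha_diff, decreasing = TRUE))[seq_along(frontal)]
  expect_setequal(top, frontal)
  expect_equal(rest_res$peak$channel, "Fz")
  expect_lt(rest_res$peak$test$p_mc, 0.05)
  expect_gt(rest_res$peak$mean, 0.5)
  expect_lt(rest_res$peak$sem, 0.1)
})

test_that("clinical correlations recover the negative severity link", {
  co <- rest_res$correlations$psi
  expect_lt(co$ygtss_tts$rho, -0.6)
  expect_lt(co$puts$rho, -0.6)
  expect_true(co$ygtss_tts$exact)        # n = 6 -> full enumeration
  # correlations are computed per patient on hemisphere-averaged PSI
  expect_equal(length(rest_res$per_patient$psi), 6L)
})

test_that("tic analysis finds the programmed pre-onset decoupling", {
  tres <- run_tic_analysis(tic, rest,
                           targets = list(psi = "Fz",
                                          power = c("LFP", "Fz")),
                           cfg)
  ps <- tres[["psi:Fz"]]
  expect_equal(ps$n_units, 12L)          # hemispheres as samples
  expect_equal(length(ps$window_p), 116L)
  expect_equal(length(ps$times), 601L)
  sig <- ps$cluster$clusters[ps$cluster$clusters$significant, ,
                             drop = FALSE]
  expect_gt(nrow(sig), 0)
  t_lo <- ps$window_starts[sig$start]
  t_hi <- ps$window_starts[sig$end] + cfg$test_window
  expect_true(any(t_lo <= 0.2 & t_hi >= -0.3))  # overlaps the ramp
  # pre-onset regression on the full 0.004 s grid
  expect_equal(ps$trend$n, 451L)
  expect_equal(ps$trend$df, c(1, 449))
  expect_lt(ps$trend$slope, 0)
  expect_lt(ps$trend$p_mc, 0.05)
  # power targets exist and use the expected units
  expect_equal(tres[["power:LFP"]]$n_units, 12L)
  expect_equal(tres[["power:Fz"]]$n_units, 6L)
})

test_that("an uncoupled cohort is not flagged and shows no clusters", {
  link <- default_clinical_link()
  null_cohort <- generate_cohort(
    n_patients = 6, kappa_range = c(0, 1e-6), clinical_link = link,
    seed = 11, duration = 120,
    channels = c("Fz", "F1", "Cz", "Pz"), n_tics = 8,
    ramp_start = -0.3, ramp_depth = 0, eeg_rate = 250)
  cfg0 <- recovery_config(seed = 11)
  eps0 <- lapply(null_cohort$patients, session_epochs, cfg = cfg0)
  res0 <- run_rest_analysis(lapply(eps0, `[[`, "rest"),
                            null_cohort$clinical, cfg0)
  expect_length(res0$flagged_channels, 0)
  tres0 <- run_tic_analysis(lapply(eps0, `[[`, "tic"),
                            lapply(eps0, `[[`, "rest"),
                            targets = list(psi = "Fz", power = character()),
                            cfg0)
  cl <- tres0[["psi:Fz"]]$cluster$clusters
  expect_false(any(cl$significant))
  expect_lt(abs(tres0[["psi:Fz"]]$trend$r2_adjusted), 0.25)
})

test_that("suppression contrast is null for identical conditions and
           detects halved coupling", {
  counts <- data.frame(
    patient = rep(names(cohort$patients), 2),
    condition = rep(c("tic_freely", "tic_suppression"), each = 6),
    n_tics = c(8, 7, 9, 8, 8, 7, 8, 7, 9, 8, 8, 7),
    duration_s = 300)
  same <- run_suppression_analysis(rest, rest, counts, cfg)
  expect_gt(same$psi$p_mc, 0.5)
  expect_gt(same$lfp_power$p_mc, 0.5)
  expect_gt(same$tic_rate$p_mc, 0.5)

  # suppression condition with halved coupling: PSI test fires, and a
  # patient missing the suppression condition is dropped with a log
  supp_cohort <- recovery_cohort(seed = 21)
  for (i in seq_along(supp_cohort$patients)) {
    p <- supp_cohort$patients[[i]]
    p$truth$kappa <- p$truth$kappa / 4
    p$truth$seed <- p$truth$seed + 1L
    supp_cohort$patients[[i]] <- generate_recording(
      60, p$truth, eeg_rate = 250, condition = "tic_suppression")
    supp_cohort$patients[[i]]$id <- p$id
  }
  supp_eps <- lapply(supp_cohort$patients, session_epochs, cfg = cfg)
  supp <- lapply(supp_eps, `[[`, "rest")
  supp <- supp[-1]                        # patient 1 lacks suppression
  expect_message(
    res <- run_suppression_analysis(rest, supp, counts, cfg),
    "dropped")
  expect_equal(res$dropped, names(cohort$patients)[1])
  expect_lt(res$psi$p_mc, 0.05)
})

test_that("pooled statistics are invariant to hemisphere relabeling", {
  tab <- rest_res$psi_table
  sub <- tab[tab$channel == "Fz", ]
  fac <- data.frame(Condition = sub$condition, Frequency = sub$band,
                    Hemisphere = sub$hemisphere)
  swapped <- fac
  swapped$Hemisphere <- ifelse(fac$Hemisphere == "left", "right", "left")
  a <- perm_anova(sub$psi, fac, stats_config(n_permutations = 100,
                                             seed = 3))
  b <- perm_anova(sub$psi, swapped, stats_config(n_permutations = 100,
                                                 seed = 3))
  for (e in names(a))
    expect_equal(a[[e]]$statistic, b[[e]]$statistic)
})

test_that("identical configuration and seed reproduce results exactly", {
  cfg2 <- recovery_config(seed = 1)
  eps2 <- lapply(recovery_cohort(seed = 1)$patients, session_epochs,
                 cfg = cfg2)
  res2 <- run_rest_analysis(lapply(eps2, `[[`, "rest"), cohort$clinical,
                            cfg2)
  expect_identical(rest_res$psi_table, res2$psi_table)
  expect_identical(rest_res$correlations$psi$ygtss_tts$rho,
                   res2$correlations$psi$ygtss_tts$rho)
  expect_identical(rest_res$flagged_channels, res2$flagged_channels)
})

test_that("source-level ROI series flow through the tic pipeline", {
  # externally supplied ROI time series enter as a SOURCE recording and
  # run through the identical machinery; a missing ROI is skipped with
  # a log entry rather than failing the run
  two <- cohort$patients[1:2]
  sessions <- lapply(two, function(p) {
    roi <- new_recording(p$eeg$data[c("Fz", "Cz"), , drop = FALSE],
                         p$eeg$rate, c("S1", "IPC"), "SOURCE",
                         meta = list(origin = "synthetic ROI stand-in"))
    list(lfp = p$lfp, eeg = roi, events = p$events)
  })
  eps2 <- lapply(sessions, session_epochs, cfg = cfg)
  expect_message(
    tres <- run_tic_analysis(lapply(eps2, `[[`, "tic"),
                             lapply(eps2, `[[`, "rest"),
                             targets = list(psi = c("S1", "M1"),
                                            power = "S1"),
                             cfg),
    "skipping PSI target M1")
  expect_equal(tres$.skipped, "psi:M1")
  expect_equal(tres[["psi:S1"]]$n_units, 4L)   # 2 patients x 2 hemis
  expect_length(tres[["power:S1"]]$rel_change, 601L)
})
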