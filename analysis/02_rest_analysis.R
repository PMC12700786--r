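#!/usr/bin/env Rscript
# Resting-state analysis over the simulated cohort written by
# 01_simulate.R: loads the recordings back from disk, cuts 4-s rest
# epochs, and runs the per-channel original-vs-surrogate PSI ANOVA with
# FDR, the peak-channel test, and the clinical correlations. Results go
# to results/rest/.

suppressPackageStartupMessages(library(thalcortex))

args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args)) as.integer(args[1]) else 1L
sim <- "results/sim"
out <- "results/rest"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cfg <- analysis_config(freqs = c(3, 5, 7, 8, 10, 12, 13, 21, 30),
                       surrogate_iters = 50,
                       stats = stats_config(n_permutations = 1000,
                                            seed = seed))

ids <- sub("_lfp\\.json$", "",
           basename(list.files(sim, pattern = "_lfp\\.json$")))
sessions <- lapply(ids, function(id) {
  lfp <- read_percept_json(file.path(sim, paste0(id, "_lfp.json")))
  bv <- read_brainvision(file.path(sim, paste0(id, "_eeg.vhdr")))
  ev <- utils::read.csv(file.path(sim, paste0(id, "_events.csv")))
  list(lfp = lfp, eeg = bv$recording,
       events = event_table(ev$onset, ev$offset, ev$kind, ev$tic_type,
                            ev$condition))
})
names(sessions) <- ids
clinical <- load_clinical_table(file.path(sim, "clinical.csv"))

rest <- lapply(lapply(sessions, session_epochs, cfg = cfg), `[[`, "rest")
res <- run_rest_analysis(rest, clinical, cfg)

utils::write.csv(res$psi_table, file.path(out, "psi_by_channel.csv"),
                 row.names = FALSE)
anova_tab <- do.call(rbind, lapply(names(res$anova), function(ch) {
  do.call(rbind, lapply(names(res$anova[[ch]]), function(e) {
    a <- res$anova[[ch]][[e]]
    data.frame(channel = ch, effect = e, F = a$statistic,
               df1 = a$df[1], df2 = a$df[2], p_mc = a$p_mc)
  }))
}))
utils::write.csv(anova_tab, file.path(out, "anova.csv"), row.names = FALSE)

summary <- list(
  flagged_channels = res$flagged_channels,
  peak = list(channel = res$peak$channel,
              psi_mean = res$peak$mean, psi_sem = res$peak$sem,
              t = res$peak$test$statistic, df = res$peak$test$df,
              p_mc = res$peak$test$p_mc),
  correlations = lapply(res$correlations, function(m)
    lapply(m, function(r) list(rho = r$rho, p = r$p, p_fdr = r$p_fdr,
                               n = r$n))))
jsonlite::write_json(summary, file.path(out, "summary.json"),
                     auto_unbox = TRUE, digits = NA, pretty = TRUE)

cat("flagged channels:", paste(res$flagged_channels, collapse = ", "), "\n")
cat(sprintf("peak channel %s: alpha PSI %.2f +- %.2f (t(%d) = %.2f, p = %.3f)\n",
            res$peak$channel, res$peak$mean, res$peak$sem,
            res$peak$test$df, res$peak$test$statistic,
            res$peak$test$p_mc))
cat(sprintf("Spearman alpha PSI vs YGTSS TTS: rho = %.2f, p = %.3f\n",
            res$correlations$psi$ygtss_tts$rho,
            res$correlations$psi$ygtss_tts$p))
cat(sprintf("Spearman alpha PSI vs PUTS:      rho = %.2f, p = %.3f\n",
            res$correlations$psi$puts$rho, res$correlations$psi$puts$p))
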