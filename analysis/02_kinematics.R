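#!/usr/bin/env Rscript
# Stage 2 — kinematics: Butterworth filtering, derivatives, per-trial
# measures, 2-SD outlier rejection, and the mixed-effects model of
# movement extent on peak velocity and movement time.
#
# Writes: results/kinematics.csv, results/lmm.json

suppressMessages(library(gammareach))
co <- readRDS("scratch/cohort.rds")

kin <- kinematics_table(co$reaches, co$cfg)
rej <- reject_outliers(kin)
kin$kept <- !(seq_len(nrow(kin)) %in% rej$rejected)
message(nrow(kin), " trials; ", length(rej$rejected),
        " rejected by the per-subject 2-SD rule")

ext <- tapply(kin$extent_cm[kin$kept], kin$distance_cm[kin$kept], mean)
message("Mean extent per distance (cm): ",
        paste(sprintf("%.2f", ext), collapse = ", "),
        "  [targets 4, 7, 10]")

kept <- kin[kin$kept, ]
cmp <- compare_lmm(kept$extent_cm, kept$pv_cm_s, kept$mt_s, kept$subject)
fx <- cmp$fit_slope$fixed_effects
message(sprintf(
  "Extent ~ PV + MT (random intercept+slope): slopes PV %.3f, MT %.3f; R2adj %.3f",
  fx$slope[fx$term == "pv"], fx$slope[fx$term == "mt"],
  cmp$fit_slope$r2_adjusted))
message(sprintf("BIC intercept %.1f vs intercept+slope %.1f -> %s; TLRT p = %.3g",
                cmp$bic_intercept, cmp$bic_slope, cmp$preferred,
                cmp$lrt_p))

write_trials_csv(kin, "results/kinematics.csv")
write_report_json(list(
  n_trials = nrow(kin), n_rejected = length(rej$rejected),
  pv_slope = fx$slope[fx$term == "pv"],
  mt_slope = fx$slope[fx$term == "mt"],
  pv_ci = c(fx$ci_lo[fx$term == "pv"], fx$ci_hi[fx$term == "pv"]),
  mt_ci = c(fx$ci_lo[fx$term == "mt"], fx$ci_hi[fx$term == "mt"]),
  r2_adjusted = cmp$fit_slope$r2_adjusted,
  bic_intercept = cmp$bic_intercept, bic_slope = cmp$bic_slope,
  preferred = cmp$preferred, lrt_p = cmp$lrt_p), "results/lmm.json")
saveRDS(kin, "scratch/kinematics.rds")
message("Stage 2 done.")
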