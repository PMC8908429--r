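#!/usr/bin/env Rscript
# Stage 7 — linking gamma to behaviour: simple regressions of
# per-subject band-power and subnetwork-wPLI summaries on mean peak
# velocity and movement time, all z-transformed.
#
# Writes: results/regression_screen.tsv

suppressMessages(library(gammareach))
kin <- readRDS("scratch/kinematics.rds")
sp <- readRDS("scratch/spectral.rds")
nbs <- readRDS("scratch/nbs.rds")

kept <- kin[kin$kept, ]
kin_subj <- aggregate(cbind(pv = pv_cm_s, mt = mt_s) ~ subject,
                      data = kept, FUN = mean)
wpli_table <- NULL
if (!is.null(nbs$subnet))
  wpli_table <- data.frame(subject = kin_subj$subject,
                           wpli_exec_subnet = nbs$subnet)

screen <- gamma_kinematics_screen(sp$power, wpli_table, kin_subj,
                                  exclude_sd = NULL)
print(screen, digits = 3)
utils::write.table(screen, "results/regression_screen.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
message("Stage 7 done.")
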