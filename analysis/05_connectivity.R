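#!/usr/bin/env Rscript
# Stage 5 — functional connectivity: debiased squared wPLI matrices in
# the high-gamma band for the planning, execution and post-movement
# windows, one matrix per subject, plus the cohort means as TSV.
#
# Writes: results/wpli_planning.tsv, results/wpli_execution.tsv,
#         results/wpli_post.tsv

suppressMessages(library(gammareach))
co <- readRDS("scratch/cohort.rds")
wins <- analysis_windows()
band <- gamma_bands()$high

conn <- list()
for (w in names(wins)) {
  conn[[w]] <- lapply(seq_len(co$cfg$n_subjects), function(s)
    wpli_matrix(subset_epochs(co$epochs,
                              which(co$epochs$trials$subject == s)),
                band = band, window = wins[[w]]))
  mean_W <- Reduce(`+`, lapply(conn[[w]], `[[`, "W")) /
    length(conn[[w]])
  off <- mean_W[upper.tri(mean_W)]
  message(sprintf("%-9s mean dwPLI^2 over pairs: %+.4f (range %.3f..%.3f)",
                  w, mean(off), min(off), max(off)))
  write_conn_tsv(mean_W, sprintf("results/wpli_%s.tsv", w))
}
saveRDS(conn, "scratch/connectivity.rds")
message("Stage 5 done.")
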