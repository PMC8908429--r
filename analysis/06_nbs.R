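#!/usr/bin/env Rscript
# Stage 6 — Network Based Statistics on the wPLI stacks: omnibus
# repeated-measures F over the three windows, then the directional
# execution > planning paired-t contrast; per-subject subnetwork means
# for the regression stage.
#
# Writes: results/nbs.json, results/nbs_exec_vs_plan_edges.tsv

suppressMessages(library(gammareach))
co <- readRDS("scratch/cohort.rds")
conn <- readRDS("scratch/connectivity.rds")

stacks <- lapply(conn, function(mats) conn_stack(mats)$edges)
n <- nrow(stacks[[1]])

omni <- nbs_test(stacks, "rm_F",
                 threshold = qf(0.999, 2, (n - 1) * 2),
                 n_perm = 1000, seed = 44)
message("Omnibus (planning / execution / post):")
print(omni)

post_hoc <- nbs_test(list(stacks$execution, stacks$planning), "paired_t",
                     threshold = qt(0.999, n - 1), n_perm = 1000,
                     mode = "extent", alternative = "greater", seed = 45)
message("Execution > planning:")
print(post_hoc)

write_nbs_json(post_hoc, "results/nbs.json", ch_names = co$layout$names)
if (length(post_hoc$components)) {
  write_nbs_edges_tsv(post_hoc, 1, "results/nbs_exec_vs_plan_edges.tsv",
                      ch_names = co$layout$names)
  subnet <- vapply(conn$execution, subnetwork_mean, numeric(1),
                   component = post_hoc$components[[1]]$pairs)
  message("Per-subject subnetwork mean dwPLI^2: ",
          paste(sprintf("%.3f", subnet), collapse = " "))
  saveRDS(list(post_hoc = post_hoc, subnet = subnet), "scratch/nbs.rds")
} else {
  message("No execution > planning component at this cohort size.")
  saveRDS(list(post_hoc = post_hoc, subnet = NULL), "scratch/nbs.rds")
}
message("Stage 6 done.")
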