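#!/usr/bin/env Rscript
# Stage 4 — target-distance effect on execution-window gamma power:
# repeated-measures F cluster permutation test over channels x 24 ms
# bins, with the sensor adjacency of the simulated layout.
#
# Writes: results/distance_cluster.json

suppressMessages(library(gammareach))
co <- readRDS("scratch/cohort.rds")
sp <- readRDS("scratch/spectral.rds")

res <- cluster_test(sp$dist_maps, "rm_F", alpha_point = 0.001,
                    neighbors = co$layout$neighbors, min_neighbors = 0,
                    n_perm = 1000, seed = 43)
print(res)
write_cluster_json(res, "results/distance_cluster.json",
                   ch_names = co$layout$names)
message("Stage 4 done.")
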