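#!/usr/bin/env Rscript
# Cluster/switch scoring demonstration: synthetic word streams with known
# block structure, segmented at the default threshold, battery-level totals.

suppressPackageStartupMessages(library(tvfb))
set.seed(20260930)

streams <- list(
  generate_word_stream(14, c(4, 3, 5, 2), within = 0.8, between = 0.2,
                       trial = "pvf_f"),
  generate_word_stream(16, c(6, 4, 6), within = 0.8, between = 0.2,
                       trial = "svf_ani"),
  generate_word_stream(12, c(3, 3, 3, 3), within = 0.8, between = 0.2,
                       trial = "avf_fani"))

for (s in streams) {
  rep_ <- segment_clusters(s, theta = 0.5)
  cat(sprintf("%-8s %2d words: %d clusters, %d switches, mean cluster size %.2f (truth: %d/%d/%.2f)\n",
              s$trial, length(s$words), rep_$n_clusters, rep_$switches,
              rep_$mean_cluster_size, s$truth$n_clusters, s$truth$switches,
              s$truth$mean_cluster_size))
}
bm <- battery_cluster_metrics(streams, theta = 0.5)
cat(sprintf("battery: %d switches in total, pooled mean cluster size %.2f\n",
            bm$total_switches, bm$mean_cluster_size))
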