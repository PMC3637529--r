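#!/usr/bin/env Rscript
# Stage 4 — FDR-thresholded correlation networks per group.
#
# All-pairs correlations over fatigue + 51 analytes on the unsmoothed view,
# Benjamini-Hochberg thresholded at a 0.01 false-discovery rate, laid out
# with the classic Fruchterman-Reingold algorithm, and exported as GraphML,
# TSV edge lists and layout CSVs.

library(dailycyto)

cohort <- read_cohort("results/cohort.csv")
views <- build_analysis_views(cohort, window = 3)
seed <- as.integer(Sys.getenv("DAILYCYTO_SEED", "20260929"))

for (g in c("patient", "control")) {
  net <- build_network(pairwise_matrix(views$unsmoothed, g), q = 0.01)
  coords <- fr_layout(net, seed = derive_seed(seed, "layout"))
  write_network_graphml(net, sprintf("results/network_%s.graphml", g))
  write_edge_list(net, sprintf("results/network_%s_edges.tsv", g))
  write_layout_csv(coords, sprintf("results/network_%s_layout.csv", g))
  cat(sprintf(
    "%s network: %d edges (realized p <= %.2e); leptin degree %d; fatigue-leptin edge: %s\n",
    g, nrow(net$edges), net$threshold, net$leptin_degree,
    net$fatigue_leptin_edge))
}
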