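#!/usr/bin/env Rscript

# Stage 5: TF-TF interaction networks and internal-TF enrichment.
#
# Joins each tissue's called pairs that share a TF into networks (2 or
# more pairs), matches identical topologies across tissues, censuses
# internal TFs (degree >= 2), and bootstrap-tests whether the planted TFs
# are enriched at internal positions of the observed networks, relabelling
# each network from the full PWM universe while preserving its size and
# order.
#
# Writes: networks.tsv, hub_census.tsv, internal_enrichment.json.

suppressPackageStartupMessages({library(concordtf); library(data.table)})

out <- "results/analysis"
for (f in c("tissue_pairs.tsv", "thresholds.tsv")) {
  if (!file.exists(file.path(out, f))) {
    stop("missing ", file.path(out, f), " - run the earlier stages first")
  }
}
tissue_pairs_dt <- fread(file.path(out, "tissue_pairs.tsv"))
universe <- fread(file.path(out, "thresholds.tsv"))$pwm
info <- jsonlite::read_json(file.path(out, "run_info.json"))
gt <- jsonlite::read_json(file.path(out, "study", "ground_truth.json"),
                          simplifyVector = TRUE)

tissues <- sort(unique(tissue_pairs_dt$tissue))
nets_by_tissue <- lapply(stats::setNames(nm = tissues), function(t) {
  build_networks(tissue_pairs_dt[tissue == t, pair], tissue = t)
})
nets <- unlist(nets_by_tissue, recursive = FALSE)

if (length(nets) == 0) {
  cat("no networks: no tissue had two called pairs sharing a TF\n")
  fwrite(data.table(tissue = character(), network = integer(),
                    edge = character()),
         file.path(out, "networks.tsv"), sep = "\t")
} else {
  fwrite(rbindlist(lapply(seq_along(nets), function(i) {
    data.table(tissue = nets[[i]]$tissue, network = i,
               edge = nets[[i]]$edges)
  })), file.path(out, "networks.tsv"), sep = "\t")
  cen <- hub_census(nets)
  fwrite(data.table(tf = names(cen), n_internal = as.integer(cen)),
         file.path(out, "hub_census.tsv"), sep = "\t")

  planted_tfs <- unique(unlist(strsplit(
    c(gt$pairs$pair, gt$triplets$triplet), ":")))
  boot <- internal_enrichment_bootstrap(
    nets, intersect(planted_tfs, universe), universe, n_boot = 10000,
    seed = concordtf:::derive_seed(as.integer(info$seed), "netboot"))
  jsonlite::write_json(boot, file.path(out, "internal_enrichment.json"),
                       auto_unbox = TRUE, digits = NA)
  cat(sprintf("%d networks; planted TFs internal in %d (bootstrap p = %.4g)\n",
              length(nets), boot$obs_internal, boot$p_internal))
  cat(sprintf("top internal TFs: %s\n",
              paste(utils::head(names(cen), 5), collapse = " ")))
}
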