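#!/usr/bin/env Rscript

# Stage 3: conserved TF pair prediction per gene list, then housekeeping
# subtraction.
#
# For every tissue list and the housekeeping list: distance-profile
# enrichment against the shuffled backgrounds in both species, candidate
# selection (ratio > 1 in more than 5 of the 10 constraints), the >= 10%
# orthologous-overlap filter, the correlation/permutation conservation
# test, per-list BH q-values, and the human/mouse intersection. Tissue TF
# pairs are what survives subtraction of the housekeeping calls.
#
# Writes: pair_calls.tsv, called_pairs.tsv, tissue_pairs.tsv.

suppressPackageStartupMessages({library(concordtf); library(data.table)})

out <- "results/analysis"
for (f in c("hits_real.tsv", "hits_background.tsv")) {
  if (!file.exists(file.path(out, f))) {
    stop("missing ", file.path(out, f), " - run analysis/02_scan.R first")
  }
}
info <- jsonlite::read_json(file.path(out, "run_info.json"))
seed <- as.integer(info$seed)

hits_real <- fread(file.path(out, "hits_real.tsv"))
hits_bg <- fread(file.path(out, "hits_background.tsv"))
orthologs <- fread(file.path(out, "study", "orthologs.tsv"))
gene_lists <- fread(file.path(out, "study", "gene_lists.tsv"))
pwm_ids <- fread(file.path(out, "thresholds.tsv"))$pwm

split_species <- function(h) list(human = h[species == "human"],
                                  mouse = h[species == "mouse"])
hr <- split_species(hits_real)
hb <- split_species(hits_bg)

lists <- split(gene_lists$gene, gene_lists$tissue)
results <- lapply(stats::setNames(nm = names(lists)), function(ln) {
  predict_list_pairs(hr, hb, lists[[ln]], orthologs, pwm_ids,
                     seed = concordtf:::derive_seed(seed, "pairs", ln))
})

calls <- rbindlist(lapply(names(results), function(ln) {
  tab <- copy(results[[ln]]$table)
  if (nrow(tab)) tab[, list_name := ln]
  tab
}), fill = TRUE)
fwrite(calls, file.path(out, "pair_calls.tsv"), sep = "\t")

called <- rbindlist(lapply(names(results), function(ln) {
  data.table(list_name = ln, pair = results[[ln]]$called)
}))
fwrite(called, file.path(out, "called_pairs.tsv"), sep = "\t")

tissues <- setdiff(names(lists), "HK")
hk_called <- called[list_name == "HK", pair]
tissue_pairs <- rbindlist(lapply(tissues, function(t) {
  sub <- subtract_housekeeping(called[list_name == t, pair], hk_called)
  cat(sprintf("%s: %d called, %.0f%% removed by housekeeping, %d tissue pairs\n",
              t, length(called[list_name == t, pair]),
              100 * sub$removed_fraction, length(sub$pairs)))
  data.table(tissue = t, pair = sub$pairs)
}))
fwrite(tissue_pairs, file.path(out, "tissue_pairs.tsv"), sep = "\t")
cat(sprintf("total: %d tissue TF pairs across %d tissues (%d unique keys)\n",
            nrow(tissue_pairs), length(tissues),
            length(unique(tissue_pairs$pair))))
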