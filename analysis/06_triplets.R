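#!/usr/bin/env Rscript

# Stage 6: conserved three-TF modules.
#
# For each tissue: site-level occurrences of the tissue TF pairs, all
# three-site combinations sharing one identical site, cross-species
# conservation of order and orientation, and calls requiring support on at
# least 10 orthologous gene pairs at q < 0.05 (hypergeometric overlap of
# the two carrier sets within the tissue's genes).
#
# Writes: triplet_calls.tsv.

suppressPackageStartupMessages({library(concordtf); library(data.table)})

out <- "results/analysis"
for (f in c("tissue_pairs.tsv", "hits_real.tsv")) {
  if (!file.exists(file.path(out, f))) {
    stop("missing ", file.path(out, f), " - run the earlier stages first")
  }
}
tissue_pairs_dt <- fread(file.path(out, "tissue_pairs.tsv"))
hits_real <- fread(file.path(out, "hits_real.tsv"))
orthologs <- fread(file.path(out, "study", "orthologs.tsv"))
gene_lists <- fread(file.path(out, "study", "gene_lists.tsv"))

tissues <- sort(unique(tissue_pairs_dt$tissue))
calls <- rbindlist(lapply(tissues, function(t) {
  tp <- tissue_pairs_dt[tissue == t, pair]
  genes_t <- gene_lists[tissue == t, gene]
  map <- orthologs[human %in% genes_t]
  occ_h <- pair_occurrences(
    hits_real[species == "human" & gene_id %in% genes_t], tp, 200L)
  occ_m <- pair_occurrences(
    hits_real[species == "mouse" & gene_id %in% map$mouse], tp, 200L)
  trip_h <- compose_triplets(occ_h)
  trip_m <- compose_triplets(occ_m)
  cons <- conserved_occurrences(trip_h, trip_m, map)
  tab <- call_triplets(cons, trip_h, trip_m, length(genes_t), map)
  if (nrow(tab)) tab[, tissue := t]
  tab
}), fill = TRUE)

fwrite(calls, file.path(out, "triplet_calls.tsv"), sep = "\t")
if (nrow(calls)) {
  cat(sprintf("%d candidate triplet keys, %d called:\n", nrow(calls),
              sum(calls$called)))
  print(calls[called == TRUE, .(tissue, triplet, support, p, q)])
} else {
  cat("no conserved three-site combinations found\n")
}
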