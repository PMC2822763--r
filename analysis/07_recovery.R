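#!/usr/bin/env Rscript

# Stage 7: score the run against the generator's ground truth.
#
# Regenerates the study configuration from the recorded seed (the study is
# deterministic), compares the tissue TF pairs and triplet calls from
# stages 3 and 6 with what was planted, and reports recall, the
# housekeeping subtraction outcome, and the empirical false-call count
# (pairs with no planted, triplet-derived or emergent cross-element
# signal).
#
# Writes: recovery_summary.tsv.

suppressPackageStartupMessages({library(concordtf); library(data.table)})

out <- "results/analysis"
for (f in c("tissue_pairs.tsv", "triplet_calls.tsv", "called_pairs.tsv")) {
  if (!file.exists(file.path(out, f))) {
    stop("missing ", file.path(out, f), " - run the earlier stages first")
  }
}
info <- jsonlite::read_json(file.path(out, "run_info.json"))
study <- generate_study(default_study_config(seed = as.integer(info$seed)))
truth <- planted_pair_truth(study)

tissue_pairs_dt <- fread(file.path(out, "tissue_pairs.tsv"))
called_pairs <- fread(file.path(out, "called_pairs.tsv"))
triplet_calls <- fread(file.path(out, "triplet_calls.tsv"))

planted <- truth[kind == "planted" & housekeeping == FALSE]
planted[, called := mapply(function(t, pk) {
  nrow(tissue_pairs_dt[tissue == t & pair == pk]) > 0
}, list_name, pair)]

hk <- truth[housekeeping == TRUE,
            .(pair = unique(pair))]
hk[, called_hk := pair %in% called_pairs[list_name == "HK", pair]]
hk[, in_tissue_sets := pair %in% tissue_pairs_dt$pair]

tissue_pairs_dt[, true_signal := mapply(function(t, pk) {
  nrow(truth[list_name == t & pair == pk]) > 0
}, tissue, pair)]

trip_truth <- study$ground_truth$triplets
trip_called <- mapply(function(key, t) {
  nrow(triplet_calls[tissue == t & triplet == key & called == TRUE]) > 0
}, trip_truth$triplet, trip_truth$tissue)

summary <- data.table(
  metric = c("planted_pairs_called", "planted_pairs_total",
             "hk_pairs_called_in_hk", "hk_pairs_leaking_into_tissues",
             "tissue_pair_calls", "false_calls", "triplets_called",
             "triplets_planted"),
  value = c(sum(planted$called), nrow(planted), sum(hk$called_hk),
            sum(hk$in_tissue_sets), nrow(tissue_pairs_dt),
            sum(!tissue_pairs_dt$true_signal), sum(trip_called),
            nrow(trip_truth)))
fwrite(summary, file.path(out, "recovery_summary.tsv"), sep = "\t")

cat(sprintf("planted pair recall: %d/%d\n", sum(planted$called),
            nrow(planted)))
cat(sprintf("housekeeping pairs: %d/%d called in HK, %d leaked into tissue sets\n",
            sum(hk$called_hk), nrow(hk), sum(hk$in_tissue_sets)))
cat(sprintf("tissue pair calls: %d (%d without planted signal)\n",
            nrow(tissue_pairs_dt), sum(!tissue_pairs_dt$true_signal)))
cat(sprintf("planted triplet called: %d/%d\n", sum(trip_called),
            nrow(trip_truth)))
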