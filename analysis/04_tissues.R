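#!/usr/bin/env Rscript

# Stage 4: tissue-unique pairs, tissue clustering, tissue-type pairs.
#
# Builds the binary pair-by-tissue presence matrix from the tissue TF
# pairs, computes the asymmetric-binary (Jaccard) distance between
# tissues, clusters them by complete linkage, and extracts tissue-type TF
# pairs (present in at least 50% of a group's tissues). With the default
# four synthetic tissues every tissue carries its own planted pairs, so
# the interesting outputs here are the unique-pair table and the
# distances; tissue-type pairs are reported for the all-tissue group.
#
# Writes: unique_pairs.tsv, tissue_distance.tsv, tissue_clusters.tsv,
# tissue_type_pairs.tsv.

suppressPackageStartupMessages({library(concordtf); library(data.table)})

out <- "results/analysis"
if (!file.exists(file.path(out, "tissue_pairs.tsv"))) {
  stop("missing ", file.path(out, "tissue_pairs.tsv"),
       " - run analysis/03_pairs.R first")
}
tissue_pairs_dt <- fread(file.path(out, "tissue_pairs.tsv"))
tissues <- sort(unique(tissue_pairs_dt$tissue))
sets <- lapply(stats::setNames(nm = tissues), function(t) {
  tissue_pairs_dt[tissue == t, pair]
})

uniq <- tissue_unique_pairs(sets)
fwrite(rbindlist(lapply(names(uniq), function(t) {
  if (length(uniq[[t]]) == 0) return(NULL)
  data.table(tissue = t, pair = uniq[[t]])
})), file.path(out, "unique_pairs.tsv"), sep = "\t")

pm <- presence_matrix(sets)
d <- binary_distance_matrix(pm)
fwrite(data.table(tissue = rownames(d), as.data.table(d)),
       file.path(out, "tissue_distance.tsv"), sep = "\t")

n_groups <- min(2L, length(tissues))
cl <- complete_linkage_clusters(d, n_groups)
fwrite(cl, file.path(out, "tissue_clusters.tsv"), sep = "\t")

tt <- tissue_type_pairs(tissues, sets, min_fraction = 0.5)
fwrite(data.table(group = "all", pair = tt),
       file.path(out, "tissue_type_pairs.tsv"), sep = "\t")

cat(sprintf("unique pairs per tissue: %s\n",
            paste(sprintf("%s=%d", names(uniq), lengths(uniq)),
                  collapse = " ")))
cat(sprintf("%d tissue-type pairs shared by >= 50%% of all %d tissues\n",
            length(tt), length(tissues)))
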