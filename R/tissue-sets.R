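#' Subtract housekeeping TF pairs from a tissue's called pairs
#'
#' Removes TF pairs called in a tissue that are also called from the
#' housekeeping gene list; the remainder are the tissue TF pairs. The
#' operation is idempotent.
#'
#' @param tissue_pairs character vector of canonical pair keys.
#' @param housekeeping_pairs character vector of canonical pair keys.
#' @return list with `pairs` (the set difference) and `removed_fraction`.
#' @export
subtract_housekeeping <- function(tissue_pairs, housekeeping_pairs) {
  tissue_pairs <- unique(tissue_pairs)
  kept <- setdiff(tissue_pairs, housekeeping_pairs)
  frac <- if (length(tissue_pairs) == 0) 0 else {
    1 - length(kept) / length(tissue_pairs)
  }
  if (length(tissue_pairs) > 0 && length(kept) == 0) {
    warning("subtract_housekeeping: every tissue pair was housekeeping")
  }
  list(pairs = kept, removed_fraction = frac)
}

#' Pairs unique to a single tissue
#'
#' A pair is tissue-unique when it occurs in exactly one tissue's set.
#'
#' @param tissue_sets named list of canonical pair key vectors.
#' @return named list (same names) of unique-pair vectors.
#' @export
tissue_unique_pairs <- function(tissue_sets) {
  if (length(tissue_sets) < 2) stop("tissue_unique_pairs: need >= 2 tissues")
  all_pairs <- unlist(lapply(tissue_sets, unique), use.names = FALSE)
  counts <- table(all_pairs)
  singletons <- names(counts)[counts == 1]
  lapply(tissue_sets, function(s) intersect(unique(s), singletons))
}

#' Pair-by-tissue presence matrix
#'
#' @param tissue_sets named list of canonical pair key vectors.
#' @return 0/1 matrix, pairs as rows, tissues as columns.
#' @export
presence_matrix <- function(tissue_sets) {
  pairs <- sort(unique(unlist(tissue_sets, use.names = FALSE)))
  m <- matrix(0L, length(pairs), length(tissue_sets),
              dimnames = list(pairs, names(tissue_sets)))
  for (nm in names(tissue_sets)) m[unique(tissue_sets[[nm]]), nm] <- 1L
  m
}

#' Binary (asymmetric Jaccard) distance between tissues
#'
#' d(s, t) = (b + c) / (a + b + c) where a counts pairs present in both
#' tissues and b, c pairs present in exactly one; the R "binary" distance.
#' Two all-zero tissues get distance 0 by convention.
#'
#' @param presence 0/1 matrix with pairs as rows, tissues as columns.
#' @return symmetric distance matrix with a zero diagonal.
#' @export
binary_distance_matrix <- function(presence) {
  d <- stats::dist(t(presence > 0), method = "binary")
  m <- as.matrix(d)
  m[is.na(m)] <- 0
  m
}

#' Complete-linkage clustering of tissues
#'
#' Agglomerative clustering by maximum inter-cluster distance (the paper
#' trail of `hclust(method = "complete")`), cut into `n_groups` groups.
#' Tissue labels are sorted before clustering so the merge order, and hence
#' tie-breaking, is deterministic.
#'
#' @param dist_matrix symmetric, zero-diagonal distance matrix.
#' @param n_groups number of groups to cut the dendrogram into.
#' @return `data.table` with `tissue` and `group` (cluster id), plus the
#'   `hclust` object as attribute `tree`.
#' @export
complete_linkage_clusters <- function(dist_matrix, n_groups) {
  n <- nrow(dist_matrix)
  if (n_groups > n) {
    stop("complete_linkage_clusters: n_groups exceeds tissue count")
  }
  ord <- order(rownames(dist_matrix))
  dm <- dist_matrix[ord, ord]
  tree <- stats::hclust(stats::as.dist(dm), method = "complete")
  cut <- stats::cutree(tree, k = n_groups)
  out <- data.table::data.table(tissue = names(cut), group = unname(cut))
  data.table::setattr(out, "tree", tree)
  out
}

#' Tissue-type TF pairs of a tissue group
#'
#' Pairs present in at least `min_fraction` of the group's tissues (the
#' boundary is inclusive: 2 of 4 tissues passes at 0.5).
#'
#' @param group_tissues tissue names of one group (>= 2).
#' @param tissue_sets named list of tissue pair sets.
#' @param min_fraction minimum fraction of member tissues (default 0.5).
#' @return character vector of tissue-type pair keys.
#' @export
tissue_type_pairs <- function(group_tissues, tissue_sets,
                              min_fraction = 0.5) {
  if (length(group_tissues) < 2) {
    stop("tissue_type_pairs: a group needs >= 2 tissues")
  }
  sets <- tissue_sets[group_tissues]
  counts <- table(unlist(lapply(sets, unique), use.names = FALSE))
  sort(names(counts)[counts / length(sets) >= min_fraction])
}
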