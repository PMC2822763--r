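site_sig <- function(pwm, start, end, strand) {
  paste(pwm, start, end, strand, sep = "@")
}

#' Site-level co-occurrences of called TF pairs
#'
#' For each gene and called pair, every arrangement of one hit per pair
#' member (two distinct hits for homotypic pairs) with an edge-to-edge gap
#' in `[0, max_gap]`. Sites are reported left to right.
#'
#' @param hits hit table from [scan_promoters()].
#' @param pairs canonical pair keys to retain (the tissue TF pairs).
#' @param max_gap maximum gap, bp (default: top of the distance grid).
#' @return `data.table` with `gene_id`, `pair` and the two sites
#'   (`pwm1`, `start1`, `end1`, `strand1`, `pwm2`, ...), `start1 < start2`.
#' @export
pair_occurrences <- function(hits, pairs, max_gap = 200L) {
  empty <- data.table::data.table(
    gene_id = character(), pair = character(),
    pwm1 = character(), start1 = integer(), end1 = integer(),
    strand1 = character(), pwm2 = character(), start2 = integer(),
    end2 = integer(), strand2 = character())
  if (length(pairs) == 0 || nrow(hits) == 0) return(empty)
  members <- unique(unlist(strsplit(pairs, ":")))
  h <- hits[pwm %in% members,
            .(gene_id, pwm, start, end, strand)]
  if (nrow(h) == 0) return(empty)
  h[, rid := .I]
  j <- h[h, on = "gene_id", allow.cartesian = TRUE]
  j <- j[rid < i.rid]
  j[, gap := pmax(i.start - end, start - i.end)]
  j <- j[gap >= 0 & gap <= max_gap]
  if (nrow(j) == 0) return(empty)
  j[, pair := pair_key(pwm, i.pwm)]
  j <- j[pair %in% pairs]
  if (nrow(j) == 0) return(empty)
  first_left <- j$start <= j$i.start
  out <- data.table::data.table(
    gene_id = j$gene_id, pair = j$pair,
    pwm1 = ifelse(first_left, j$pwm, j$i.pwm),
    start1 = ifelse(first_left, j$start, j$i.start),
    end1 = ifelse(first_left, j$end, j$i.end),
    strand1 = ifelse(first_left, j$strand, j$i.strand),
    pwm2 = ifelse(first_left, j$i.pwm, j$pwm),
    start2 = ifelse(first_left, j$i.start, j$start),
    end2 = ifelse(first_left, j$i.end, j$end),
    strand2 = ifelse(first_left, j$i.strand, j$strand))
  data.table::setorder(out, gene_id, start1, start2)
  out
}

#' Compose three-TFBS combinations from pair occurrences
#'
#' Two pair occurrences on the same promoter sharing one literally identical
#' site (same PWM, interval and strand) compose a three-site combination.
#' The three sites must be mutually non-overlapping; duplicates (the same
#' three intervals reached through different pairings) are emitted once.
#' Homotypic chains are permitted, so the triplet key is a multiset.
#'
#' @param occs pair occurrence table from [pair_occurrences()].
#' @return `data.table` with `gene_id`, `triplet` (sorted multiset key),
#'   `order` (PWM ids left to right), `strands` (site strands left to
#'   right), and the three site intervals.
#' @export
compose_triplets <- function(occs) {
  empty <- data.table::data.table(
    gene_id = character(), triplet = character(), order = character(),
    strands = character(), start1 = integer(), start2 = integer(),
    start3 = integer())
  if (nrow(occs) == 0) return(empty)
  o <- data.table::copy(occs)
  o[, oid := .I]
  long <- data.table::rbindlist(list(
    o[, .(gene_id, oid, sig = site_sig(pwm1, start1, end1, strand1),
          pwm = pwm1, start = start1, end = end1, strand = strand1)],
    o[, .(gene_id, oid, sig = site_sig(pwm2, start2, end2, strand2),
          pwm = pwm2, start = start2, end = end2, strand = strand2)]))
  shared <- merge(long, long, by = c("gene_id", "sig"),
                  allow.cartesian = TRUE, suffixes = c("_a", "_b"))
  shared <- shared[oid_a < oid_b]
  if (nrow(shared) == 0) return(empty)
  sites_of <- split(long, by = "oid", keep.by = TRUE)
  rows <- vector("list", nrow(shared))
  for (i in seq_len(nrow(shared))) {
    sa <- sites_of[[as.character(shared$oid_a[i])]]
    sb <- sites_of[[as.character(shared$oid_b[i])]]
    sites <- unique(rbind(sa, sb)[, .(pwm, start, end, strand)])
    if (nrow(sites) != 3) next
    data.table::setorder(sites, start)
    if (any(sites$start[-1] < sites$end[-3])) next  # overlapping sites
    rows[[i]] <- data.table::data.table(
      gene_id = shared$gene_id[i],
      triplet = paste(sort(sites$pwm), collapse = ":"),
      order = paste(sites$pwm, collapse = ","),
      strands = paste(sites$strand, collapse = ""),
      start1 = sites$start[1], start2 = sites$start[2],
      start3 = sites$start[3])
  }
  out <- data.table::rbindlist(rows[!vapply(rows, is.null, logical(1))])
  if (nrow(out) == 0) return(empty)
  unique(out)
}

#' Cross-species conserved three-TFBS combinations
#'
#' A human candidate is conserved when its mouse ortholog carries a
#' candidate with the same triplet key, the same PWM sequence along the
#' promoter (left to right) and identical per-site strands.
#'
#' @param trip_h,trip_m candidate tables from [compose_triplets()] for the
#'   two species.
#' @param ortholog_map `data.table` with `human`, `mouse` columns.
#' @return conserved subset of `trip_h`, one row per (gene, key, order,
#'   strands).
#' @export
conserved_occurrences <- function(trip_h, trip_m, ortholog_map) {
  if (nrow(trip_h) == 0 || nrow(trip_m) == 0) return(trip_h[0])
  map <- stats::setNames(ortholog_map$human, ortholog_map$mouse)
  tm <- trip_m[, .(gene_id = unname(map[gene_id]), triplet, order, strands)]
  tm <- unique(tm[!is.na(gene_id)])
  merge(trip_h, tm, by = c("gene_id", "triplet", "order", "strands"))
}

#' Call enriched multiple interacting TFs (three-TF modules)
#'
#' Triplet keys are tissue-level calls: support is the number of distinct
#' orthologous gene pairs carrying a conserved combination; significance is
#' the hypergeometric overlap of the human and mouse carrier sets within
#' the tissue's expressed genes; q-values are BH within the tissue. A call
#' requires support >= `min_support` and q < `q_cutoff`.
#'
#' @param conserved conserved occurrences from [conserved_occurrences()].
#' @param trip_h,trip_m per-species candidate tables (for the carrier set
#'   sizes S1 and S2).
#' @param n_genes number of tissue-expressed genes (the universe N).
#' @param ortholog_map `data.table` with `human`, `mouse` columns.
#' @param min_support minimum supporting orthologous gene pairs (default 10).
#' @param q_cutoff q-value threshold (default 0.05).
#' @return `data.table` with `triplet`, `support`, `S1`, `S2`, `p`, `q`,
#'   `called`.
#' @export
call_triplets <- function(conserved, trip_h, trip_m, n_genes, ortholog_map,
                          min_support = 10L, q_cutoff = 0.05) {
  empty <- data.table::data.table(
    triplet = character(), support = integer(), S1 = integer(),
    S2 = integer(), p = numeric(), q = numeric(), called = logical())
  if (nrow(conserved) == 0) return(empty)
  map <- stats::setNames(ortholog_map$human, ortholog_map$mouse)
  s1 <- trip_h[, .(S1 = data.table::uniqueN(gene_id)), by = triplet]
  tm <- trip_m[, .(gene_id = unname(map[gene_id]), triplet)]
  s2 <- tm[!is.na(gene_id), .(S2 = data.table::uniqueN(gene_id)),
           by = triplet]
  sup <- conserved[, .(support = data.table::uniqueN(gene_id)), by = triplet]
  tab <- Reduce(function(a, b) merge(a, b, by = "triplet"),
                list(sup, s1, s2))
  if (any(tab$S1 > n_genes | tab$S2 > n_genes)) {
    stop("call_triplets: carrier sets exceed the tissue gene universe")
  }
  tab[, p := mapply(hypergeom_overlap_pvalue, support, n_genes, S1, S2)]
  tab[, q := bh_qvalues(p)]
  tab[, called := support >= min_support & q < q_cutoff]
  data.table::setorder(tab, p)
  tab[]
}
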