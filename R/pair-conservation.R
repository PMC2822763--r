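#' Canonical key of an unordered TF pair
#'
#' Pairs are unordered and homotypic (self) pairs are allowed; the canonical
#' form sorts the two PWM ids lexicographically and joins them with `:`.
#'
#' @param a,b PWM ids (vectorised).
#' @return character vector of canonical keys.
#' @export
pair_key <- function(a, b) {
  ifelse(a <= b, paste(a, b, sep = ":"), paste(b, a, sep = ":"))
}

#' Enumerate the unordered pair universe of a PWM library
#'
#' All k(k+1)/2 unordered pairs (self-pairs included) of `k` PWM ids.
#'
#' @param pwm_ids character vector of PWM ids.
#' @return character vector of canonical pair keys.
#' @export
enumerate_pair_universe <- function(pwm_ids) {
  if (length(pwm_ids) < 1) stop("enumerate_pair_universe: need >= 1 PWM")
  ids <- sort(unique(pwm_ids))
  idx <- which(upper.tri(diag(length(ids)), diag = TRUE), arr.ind = TRUE)
  pair_key(ids[idx[, 1]], ids[idx[, 2]])
}

#' The default distance-constraint grid
#'
#' Maximum-gap cutoffs from 20 bp to 200 bp in 20 bp increments.
#' @return integer vector of 10 cutoffs.
#' @export
distance_grid <- function() seq(20L, 200L, by = 20L)

check_grid <- function(grid) {
  if (length(grid) < 2 || any(diff(grid) <= 0) || any(grid <= 0)) {
    stop("distance grid must be strictly increasing and positive")
  }
  as.integer(grid)
}

#' Minimum co-occurrence gap per gene and TF pair
#'
#' For every gene and unordered PWM pair (homotypic pairs need two distinct
#' hits), the smallest non-negative edge-to-edge gap between one hit of each
#' member, in either order and on either strand. Overlapping sites do not
#' count as co-occurring. Pairs/genes with no arrangement within `max_gap`
#' are absent.
#'
#' @param hits hit table from [scan_promoters()].
#' @param pwm_levels sorted PWM id vector used for pair canonicalisation
#'   (defaults to the ids present in `hits`).
#' @param max_gap largest gap of interest (top of the distance grid).
#' @return `data.table` with `gene_id`, `pair`, `min_gap`.
#' @export
pair_gene_gaps <- function(hits, pwm_levels = NULL, max_gap = 200L) {
  if (nrow(hits) == 0) {
    return(data.table::data.table(gene_id = character(), pair = character(),
                                  min_gap = integer()))
  }
  if (is.null(pwm_levels)) pwm_levels <- sort(unique(hits$pwm))
  h <- hits[order(gene_id, start)]
  gene_f <- factor(h$gene_id)
  pwm_i <- match(h$pwm, pwm_levels)
  res <- cpp_pair_min_gaps(as.integer(gene_f), pwm_i,
                           h$start, h$end, as.integer(max_gap))
  data.table::data.table(
    gene_id = levels(gene_f)[res$gene],
    pair = paste(pwm_levels[res$pwm1], pwm_levels[res$pwm2], sep = ":"),
    min_gap = res$min_gap)
}

#' Genes with a co-occurring TF pair under a distance constraint
#'
#' @param hits hit table from [scan_promoters()].
#' @param pair canonical pair key (see [pair_key()]).
#' @param max_gap maximum edge-to-edge gap, bp.
#' @return character vector of gene ids.
#' @export
cooccurring_genes <- function(hits, pair, max_gap) {
  members <- strsplit(pair, ":")[[1]]
  gaps <- pair_gene_gaps(hits[pwm %in% members], max_gap = as.integer(max_gap))
  sort(gaps[pair == paste(sort(members), collapse = ":") &
              min_gap <= max_gap, gene_id])
}

# Pairs x cutoffs matrix of gene counts: entry [pair, d] is the number of
# genes whose minimal gap for that pair is <= grid[d]. Monotone along d by
# construction.
cutoff_count_matrix <- function(gaps, grid, pairs = NULL) {
  grid <- check_grid(grid)
  if (is.null(pairs)) pairs <- sort(unique(gaps$pair))
  m <- matrix(0, length(pairs), length(grid),
              dimnames = list(pairs, paste0("d", grid)))
  if (nrow(gaps) == 0 || length(pairs) == 0) return(m)
  g <- gaps[pair %in% pairs]
  if (nrow(g) == 0) return(m)
  g[, idx := findInterval(min_gap - 1e-9, grid) + 1L]
  g <- g[idx <= length(grid)]
  agg <- g[, .N, by = .(pair, idx)]
  m[cbind(match(agg$pair, pairs), agg$idx)] <- agg$N
  t(apply(m, 1, cumsum))
}

# Mean background count matrix across shuffle replicates.
background_count_matrix <- function(bg_gaps_by_rep, grid, pairs) {
  mats <- lapply(bg_gaps_by_rep, cutoff_count_matrix, grid = grid,
                 pairs = pairs)
  Reduce(`+`, mats) / length(mats)
}

#' Site co-occurrence enrichment profile
#'
#' Ratio of real to background gene counts per distance cutoff, with the
#' background denominator floored at 1 so ratios stay finite when shuffled
#' corpora contain no co-occurrence.
#'
#' @param real_counts,bg_counts matrices (pairs x cutoffs) of gene counts.
#' @return matrix of enrichment ratios, same shape.
#' @export
site_enrichment_profile <- function(real_counts, bg_counts) {
  real_counts / pmax(bg_counts, 1)
}

#' Select candidate TF pairs from enrichment profiles
#'
#' A pair is a candidate when its site enrichment ratio exceeds 1 in more
#' than 5 of the 10 distance constraints (i.e. >= 6 cells).
#'
#' @param ratio_matrix pairs x cutoffs enrichment matrix.
#' @param min_cells minimum number of cells with ratio > 1 (default 6).
#' @return character vector of candidate pair keys.
#' @export
select_candidate_pairs <- function(ratio_matrix, min_cells = 6L) {
  keep <- rowSums(ratio_matrix > 1) >= min_cells
  rownames(ratio_matrix)[keep]
}

# Orthologous-overlap counts per pair and cutoff. Both gap tables must be in
# the same (human) gene id space; a gene pair overlaps at cutoff d when both
# species' minimal gaps are <= d.
overlap_count_matrix <- function(gaps_h, gaps_m, grid, pairs) {
  grid <- check_grid(grid)
  m <- matrix(0, length(pairs), length(grid),
              dimnames = list(pairs, paste0("d", grid)))
  if (length(pairs) == 0) return(m)
  j <- merge(gaps_h[pair %in% pairs], gaps_m[pair %in% pairs],
             by = c("pair", "gene_id"), suffixes = c("_h", "_m"))
  if (nrow(j) == 0) return(m)
  j[, g := pmax(min_gap_h, min_gap_m)]
  j[, idx := findInterval(g - 1e-9, grid) + 1L]
  j <- j[idx <= length(grid)]
  agg <- j[, .N, by = .(pair, idx)]
  m[cbind(match(agg$pair, pairs), agg$idx)] <- agg$N
  t(apply(m, 1, cumsum))
}

#' Ortholog-overlap enrichment and fraction profiles
#'
#' For each pair and cutoff: the overlap count (orthologous gene pairs with
#' the co-occurrence in both species), the overlap fraction
#' overlap / max(min(|H_d|, |M_d|), 1), and the overlap enrichment ratio
#' against the shuffled-background overlap (denominator floored at 1).
#'
#' @param overlap_real,overlap_bg overlap count matrices (pairs x cutoffs).
#' @param counts_h,counts_m per-species real gene count matrices.
#' @return list of matrices `ratio` and `fraction`.
#' @export
overlap_profile <- function(overlap_real, overlap_bg, counts_h, counts_m) {
  list(ratio = overlap_real / pmax(overlap_bg, 1),
       fraction = overlap_real / pmax(pmin(counts_h, counts_m), 1))
}

# Eligibility under the >= 10% orthologous-overlap filter. scope "all":
# the fraction must reach the cutoff at every distance constraint where both
# species have non-empty gene sets; scope "any": at least one such cutoff.
overlap_eligible <- function(fraction, counts_h, counts_m,
                             overlap_min = 0.10, scope = c("all", "any")) {
  scope <- match.arg(scope)
  populated <- counts_h > 0 & counts_m > 0
  ok <- fraction >= overlap_min
  vapply(seq_len(nrow(fraction)), function(i) {
    pop <- populated[i, ]
    if (!any(pop)) return(FALSE)
    if (scope == "all") all(ok[i, pop]) else any(ok[i, pop])
  }, logical(1))
}

#' Conservation test for one TF pair
#'
#' Pearson correlation between the 10-point site enrichment profile and the
#' 10-point ortholog-overlap enrichment profile, with a one-sided
#' permutation p-value. Constant profiles make a pair untestable; this is
#' reported, not silently dropped.
#'
#' @param site_ratio,overlap_ratio numeric profiles over the distance grid.
#' @param n_perm permutation count.
#' @param seed integer seed.
#' @return list with `r`, `p`, and `untestable` (reason string or `NA`).
#' @export
conservation_call <- function(site_ratio, overlap_ratio, n_perm = 10000L,
                              seed = 1L) {
  if (stats::sd(site_ratio) == 0 || stats::sd(overlap_ratio) == 0) {
    return(list(r = NA_real_, p = NA_real_, untestable = "constant profile"))
  }
  res <- permutation_corr_pvalue(site_ratio, overlap_ratio, n_perm = n_perm,
                                 seed = seed)
  list(r = res$r, p = res$p, untestable = NA_character_)
}

#' Predict conserved TF pairs for one gene list
#'
#' Runs the full function-conservation procedure for one tissue (or
#' housekeeping) gene list: distance-profile enrichment against shuffled
#' backgrounds in each species, candidate selection (ratio > 1 in more than
#' 5 constraints), the >= 10% orthologous-overlap filter, the
#' correlation/permutation conservation test per species, per-list BH
#' q-values, and the cross-species intersection (a pair is called only when
#' q < `q_cutoff` in both species).
#'
#' @param hits_real named list (`human`, `mouse`) of real-promoter hit
#'   tables restricted or restrictable to the list's genes.
#' @param hits_bg named list (`human`, `mouse`) of background hit tables
#'   (with a `replicate` column).
#' @param genes human gene ids of the list.
#' @param ortholog_map `data.table` with `human`, `mouse` columns (1:1).
#' @param pwm_ids PWM id universe (for canonical pair coding).
#' @param grid distance grid (default [distance_grid()]).
#' @param min_cells candidate rule: cells with ratio > 1 (default 6).
#' @param overlap_min minimum orthologous-overlap fraction (default 0.10).
#' @param overlap_scope `"all"` (default) or `"any"` populated cutoff.
#' @param n_perm permutations per pair (default 10000).
#' @param q_cutoff q-value call threshold (default 0.05).
#' @param seed integer seed; per-pair permutation seeds are derived from it.
#' @return list with `table` (per tested pair: r/p/q per species, called
#'   flags), `called` (canonical keys called in both species), `profiles`
#'   (site ratio per species, overlap ratio/fraction matrices) and
#'   `untestable` (pairs with constant profiles).
#' @export
predict_list_pairs <- function(hits_real, hits_bg, genes, ortholog_map,
                               pwm_ids, grid = distance_grid(),
                               min_cells = 6L, overlap_min = 0.10,
                               overlap_scope = "all", n_perm = 10000L,
                               q_cutoff = 0.05, seed = 1L) {
  grid <- check_grid(grid)
  pwm_ids <- sort(pwm_ids)
  max_gap <- max(grid)
  map <- stats::setNames(ortholog_map$human, ortholog_map$mouse)

  # restrict to the list's genes; mouse hits relabelled to human id space
  hh <- hits_real$human[gene_id %in% genes]
  hm <- hits_real$mouse[, .(gene_id = unname(map[gene_id]), pwm, start, end)]
  hm <- hm[gene_id %in% genes]
  bh <- hits_bg$human[gene_id %in% genes]
  bm <- hits_bg$mouse[, .(gene_id = unname(map[gene_id]), pwm, start, end,
                          replicate)]
  bm <- bm[gene_id %in% genes]

  gaps_h <- pair_gene_gaps(hh, pwm_ids, max_gap)
  gaps_m <- pair_gene_gaps(hm, pwm_ids, max_gap)
  bg_h_rep <- lapply(split(bh, by = "replicate"), pair_gene_gaps,
                     pwm_levels = pwm_ids, max_gap = max_gap)
  bg_m_rep <- lapply(split(bm, by = "replicate"), pair_gene_gaps,
                     pwm_levels = pwm_ids, max_gap = max_gap)

  pairs <- sort(unique(c(gaps_h$pair, gaps_m$pair)))
  counts_h <- cutoff_count_matrix(gaps_h, grid, pairs)
  counts_m <- cutoff_count_matrix(gaps_m, grid, pairs)
  bg_counts_h <- background_count_matrix(bg_h_rep, grid, pairs)
  bg_counts_m <- background_count_matrix(bg_m_rep, grid, pairs)

  ratio_h <- site_enrichment_profile(counts_h, bg_counts_h)
  ratio_m <- site_enrichment_profile(counts_m, bg_counts_m)
  cand_h <- select_candidate_pairs(ratio_h, min_cells)
  cand_m <- select_candidate_pairs(ratio_m, min_cells)

  ov_real <- overlap_count_matrix(gaps_h, gaps_m, grid, pairs)
  # background overlap: replicate-matched, then averaged
  n_rep <- max(length(bg_h_rep), 1L)
  ov_bg <- Reduce(`+`, lapply(seq_len(n_rep), function(r) {
    overlap_count_matrix(bg_h_rep[[min(r, length(bg_h_rep))]],
                         bg_m_rep[[min(r, length(bg_m_rep))]], grid, pairs)
  })) / n_rep
  ov <- overlap_profile(ov_real, ov_bg, counts_h, counts_m)
  eligible <- pairs[overlap_eligible(ov$fraction, counts_h, counts_m,
                                     overlap_min, overlap_scope)]

  test_species <- function(cand, ratio, species) {
    tested <- intersect(cand, eligible)
    rows <- lapply(tested, function(pk) {
      # seed depends on the pair only (not the species label), so swapping
      # the species of the input corpora leaves the called set unchanged
      cc <- conservation_call(ratio[pk, ], ov$ratio[pk, ], n_perm,
                              derive_seed(seed, "perm", pk))
      data.table::data.table(pair = pk, r = cc$r, p = cc$p,
                             untestable = cc$untestable)
    })
    tab <- if (length(rows)) data.table::rbindlist(rows) else
      data.table::data.table(pair = character(), r = numeric(),
                             p = numeric(), untestable = character())
    ok <- is.na(tab$untestable)
    tab[, q := NA_real_]
    if (any(ok)) tab$q[ok] <- bh_qvalues(tab$p[ok])
    tab[, called := !is.na(q) & q < q_cutoff]
    tab
  }
  th <- test_species(cand_h, ratio_h, "human")
  tm <- test_species(cand_m, ratio_m, "mouse")

  tab <- merge(th, tm, by = "pair", all = TRUE, suffixes = c("_human",
                                                             "_mouse"))
  tab[, called := !is.na(called_human) & called_human &
        !is.na(called_mouse) & called_mouse]
  data.table::setorder(tab, pair)

  list(table = tab,
       called = tab[called == TRUE, pair],
       profiles = list(site_ratio = list(human = ratio_h, mouse = ratio_m),
                       overlap_ratio = ov$ratio,
                       overlap_fraction = ov$fraction,
                       counts = list(human = counts_h, mouse = counts_m,
                                     bg_human = bg_counts_h,
                                     bg_mouse = bg_counts_m)),
       candidates = list(human = cand_h, mouse = cand_m),
       eligible = eligible,
       untestable = tab[!is.na(untestable_human) | !is.na(untestable_mouse),
                        pair],
       gaps = list(human = gaps_h, mouse = gaps_m))
}
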