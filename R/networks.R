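#' Build TF-TF interaction networks from called pairs of one tissue
#'
#' Joins pairs sharing a TF into connected components; components with a
#' single edge are not networks (a network needs 2 or more pairs). Homotypic
#' pairs contribute self-loops, which count toward degree (+2) but not
#' connectivity. Internal TFs are nodes of degree >= 2.
#'
#' @param pairs character vector of canonical pair keys.
#' @param tissue optional tissue label stored on each network.
#' @return list of networks; each has `nodes`, `edges` (canonical keys),
#'   `internal` and `tissue`.
#' @export
build_networks <- function(pairs, tissue = NA_character_) {
  pairs <- unique(pairs)
  if (length(pairs) == 0) return(list())
  ends <- do.call(rbind, strsplit(pairs, ":"))
  g <- igraph::graph_from_data_frame(
    data.frame(from = ends[, 1], to = ends[, 2]), directed = FALSE)
  comp <- igraph::components(g)
  out <- list()
  for (k in seq_len(comp$no)) {
    nodes <- names(comp$membership)[comp$membership == k]
    sub <- igraph::induced_subgraph(g, nodes)
    if (igraph::ecount(sub) < 2) next
    deg <- igraph::degree(sub, loops = TRUE)  # self-loop counts +2
    el <- igraph::as_edgelist(sub)
    out[[length(out) + 1L]] <- list(
      nodes = sort(nodes),
      edges = sort(pair_key(el[, 1], el[, 2])),
      internal = sort(names(deg)[deg >= 2]),
      tissue = tissue)
  }
  out
}

network_signature <- function(net) paste(net$edges, collapse = "|")

#' Tissue-type TF-TF interaction networks
#'
#' Networks whose labeled edge sets are identical in at least 2 tissues of
#' the same tissue-type group; each topology is reported once with its
#' supporting tissues.
#'
#' @param networks_by_tissue named list (tissue -> list of networks from
#'   [build_networks()]).
#' @param group_tissues tissue names of the group (>= 2).
#' @return list of networks, each with an extra `tissues` field.
#' @export
match_tissue_type_networks <- function(networks_by_tissue, group_tissues) {
  if (length(group_tissues) < 2) {
    stop("match_tissue_type_networks: a group needs >= 2 tissues")
  }
  sigs <- list()
  for (t in sort(group_tissues)) {
    for (net in networks_by_tissue[[t]]) {
      s <- network_signature(net)
      if (is.null(sigs[[s]])) {
        sigs[[s]] <- c(net, list(tissues = t))
      } else {
        sigs[[s]]$tissues <- sort(unique(c(sigs[[s]]$tissues, t)))
      }
    }
  }
  out <- Filter(function(n) length(n$tissues) >= 2, sigs)
  names(out) <- NULL
  out
}

#' Census of internal TFs across tissue-type networks
#'
#' For every TF, the number of networks in which it is internal, in
#' descending count order with ties broken by label.
#'
#' @param networks list of networks with `internal` fields.
#' @return named integer vector.
#' @export
hub_census <- function(networks) {
  all_tfs <- sort(unique(unlist(lapply(networks, `[[`, "nodes"))))
  counts <- vapply(all_tfs, function(tf) {
    sum(vapply(networks, function(n) tf %in% n$internal, logical(1)))
  }, integer(1))
  counts[order(-counts, names(counts))]
}

#' Bootstrap enrichment of a TF subset at internal network positions
#'
#' Tests whether a designated TF set (e.g. known tissue-specific TFs) is
#' over-represented at internal positions of the observed networks. Each
#' replicate relabels every network with a uniform sample without
#' replacement from the PWM universe, preserving the network's size and
#' order (node and edge counts), independently across networks.
#' p = (1 + #\{replicates >= observed\}) / (n_boot + 1), so p-values are
#' bounded below by 1/(n_boot + 1).
#'
#' @param networks list of networks (from [build_networks()] or
#'   [match_tissue_type_networks()]).
#' @param special_set character vector of designated TF ids.
#' @param universe character vector of all TF ids (superset of
#'   `special_set`).
#' @param n_boot bootstrap replicates (>= 1000 for reported p-values).
#' @param seed integer seed.
#' @return list with `p_internal` (networks containing >= 1 special
#'   internal TF), `p_total` (total special node count), and the observed
#'   statistics `obs_internal`, `obs_total`.
#' @export
internal_enrichment_bootstrap <- function(networks, special_set, universe,
                                          n_boot = 10000L, seed = 1L) {
  if (!all(special_set %in% universe)) {
    stop("internal_enrichment_bootstrap: special_set must lie in universe")
  }
  if (length(networks) == 0) {
    stop("internal_enrichment_bootstrap: no networks")
  }
  obs_internal <- sum(vapply(networks, function(n) {
    any(n$internal %in% special_set)
  }, logical(1)))
  obs_total <- sum(vapply(networks, function(n) {
    sum(n$nodes %in% special_set)
  }, integer(1)))
  sizes <- lapply(networks, function(n) {
    c(n_nodes = length(n$nodes), n_internal = length(n$internal))
  })
  with_seed(derive_seed(seed, "network_bootstrap"), {
    ge_internal <- 0L; ge_total <- 0L
    for (b in seq_len(n_boot)) {
      rep_internal <- 0L; rep_total <- 0L
      for (sz in sizes) {
        labels <- sample(universe, sz[["n_nodes"]])
        spec <- labels %in% special_set
        # assignment to positions is exchangeable: the first n_internal
        # sampled labels stand for the internal positions
        if (sz[["n_internal"]] > 0 &&
            any(spec[seq_len(sz[["n_internal"]])])) {
          rep_internal <- rep_internal + 1L
        }
        rep_total <- rep_total + sum(spec)
      }
      if (rep_internal >= obs_internal) ge_internal <- ge_internal + 1L
      if (rep_total >= obs_total) ge_total <- ge_total + 1L
    }
    list(p_internal = (1 + ge_internal) / (n_boot + 1),
         p_total = (1 + ge_total) / (n_boot + 1),
         obs_internal = obs_internal, obs_total = obs_total)
  })
}
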