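#' Assemble an end-to-end pipeline configuration
#'
#' Bundles the synthetic study (or pre-loaded inputs) with every stage's
#' tunables: the distance grid, shuffle mode and replicate count, the
#' permutation and bootstrap budgets, the q-value cutoffs (0.05 for pairs
#' and triplets, 0.1 for term enrichment), the tissue-type fraction (0.5)
#' and the minimum triplet support (10). All randomness flows from
#' `seed` through named substreams, so per-entity results do not depend on
#' iteration order.
#'
#' @param study a [study_config()] or a generated study (from
#'   [generate_study()]).
#' @param grid distance-constraint grid (default [distance_grid()]).
#' @param shuffle_mode `"complete"` (default) or `"dinucleotide"`.
#' @param n_replicates shuffled replicates per promoter (default 1).
#' @param n_perm permutations per conservation test (default 10000).
#' @param q_pairs q cutoff for pair and triplet calls (default 0.05).
#' @param q_terms q cutoff for term enrichment (default 0.1).
#' @param min_tissue_fraction tissue-type membership fraction (default 0.5).
#' @param min_support minimum triplet support (default 10).
#' @param overlap_min,overlap_scope orthologous-overlap filter (>= 10%,
#'   evaluated at `"all"` populated cutoffs by default).
#' @param tissue_groups optional named list: group -> tissue names; default
#'   is one group holding every tissue.
#' @param term_map optional named list term -> genes for the enrichment
#'   stage.
#' @param calibration_samples positive/negative draws per PWM calibration.
#' @param seed global seed (defaults to the study's seed).
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(study, grid = distance_grid(),
                            shuffle_mode = "complete", n_replicates = 1L,
                            n_perm = 10000L, q_pairs = 0.05, q_terms = 0.1,
                            min_tissue_fraction = 0.5, min_support = 10L,
                            overlap_min = 0.10, overlap_scope = "all",
                            tissue_groups = NULL, term_map = NULL,
                            calibration_samples = 1000L, seed = NULL) {
  stopifnot(q_pairs > 0, q_pairs < 1, q_terms > 0, q_terms < 1,
            min_tissue_fraction > 0, min_tissue_fraction <= 1)
  if (is.null(seed)) {
    seed <- if (inherits(study, "study_config")) study$seed
            else study$config$seed
  }
  structure(list(study = study, grid = check_grid(grid),
                 shuffle_mode = shuffle_mode,
                 n_replicates = as.integer(n_replicates),
                 n_perm = as.integer(n_perm), q_pairs = q_pairs,
                 q_terms = q_terms,
                 min_tissue_fraction = min_tissue_fraction,
                 min_support = as.integer(min_support),
                 overlap_min = overlap_min, overlap_scope = overlap_scope,
                 tissue_groups = tissue_groups, term_map = term_map,
                 calibration_samples = as.integer(calibration_samples),
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

config_hash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(config, f, version = 2)
  unname(tools::md5sum(f))
}

corpus_composition <- function(promoters) {
  counts <- colSums(Biostrings::letterFrequency(
    Biostrings::DNAStringSet(promoters$sequence), DNA_LETTERS))
  counts / sum(counts)
}

#' Run the end-to-end discovery pipeline
#'
#' Executes, in dependency order: study simulation (or adoption of supplied
#' inputs), background shuffling, threshold calibration and scanning of
#' real and background corpora in both species, per-list conserved-pair
#' prediction, housekeeping subtraction and tissue-level sets, tissue
#' clustering and tissue-type pairs, network reconstruction, triplet
#' composition/conservation/calling, and (when a term map is supplied)
#' annotation enrichment. Re-running with an identical configuration
#' reproduces identical outputs.
#'
#' @param config a [pipeline_config()].
#' @param out_dir optional directory; when given, stage tables are written
#'   as TSV plus a JSON `manifest.json` recording the configuration hash,
#'   seed and per-stage row counts.
#' @return list with `study`, `hits`, `pair_results` (per gene list),
#'   `tissue_pairs` (post-subtraction), `removed_fraction`, `unique_pairs`,
#'   `clusters`, `tissue_type_pairs`, `networks`, `tissue_type_networks`,
#'   `triplets` (per tissue call tables), `enrichment`, `manifest`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  seed <- config$seed
  manifest <- list(config_hash = config_hash(config), seed = seed,
                   stages = list())
  note <- function(stage, ...) {
    manifest$stages[[stage]] <<- list(...)
  }

  ## stage 1: simulate (or adopt supplied inputs)
  study <- if (inherits(config$study, "study_config")) {
    generate_study(config$study)
  } else config$study
  tissues <- setdiff(unique(study$gene_lists$tissue), "HK")
  note("simulate", n_promoters = nrow(study$promoters$human),
       n_pwms = length(study$pwm_lib), n_tissues = length(tissues))

  ## stage 2: shuffled backgrounds
  background <- lapply(study$promoters, make_background_set,
                       mode = config$shuffle_mode,
                       n_replicates = config$n_replicates,
                       seed = derive_seed(seed, "shuffle"))
  note("background", mode = config$shuffle_mode,
       n_records = sum(vapply(background, nrow, integer(1))))

  ## stage 3: calibrate thresholds and scan all corpora
  comp <- corpus_composition(study$promoters$human)
  lib <- calibrate_library(study$pwm_lib, background_composition = comp,
                           n_samples = config$calibration_samples,
                           seed = derive_seed(seed, "calibration"))
  hits <- list(
    real = lapply(study$promoters, function(pr) scan_promoters(lib, pr)),
    background = lapply(background, function(bg) {
      out <- lapply(split(bg, by = "replicate"), function(b) {
        h <- scan_promoters(lib, b[, .(gene_id, species, sequence)])
        h[, replicate := b$replicate[1]]
        h
      })
      data.table::rbindlist(out)
    }))
  note("scan", n_hits_real = sum(vapply(hits$real, nrow, integer(1))),
       n_hits_background = sum(vapply(hits$background, nrow, integer(1))))

  ## stage 4: conserved pairs per gene list (tissues + housekeeping)
  lists <- split(study$gene_lists$gene, study$gene_lists$tissue)
  pair_results <- lapply(stats::setNames(nm = names(lists)), function(ln) {
    predict_list_pairs(
      hits_real = hits$real, hits_bg = hits$background,
      genes = lists[[ln]], ortholog_map = study$ortholog_map,
      pwm_ids = names(lib), grid = config$grid,
      overlap_min = config$overlap_min,
      overlap_scope = config$overlap_scope, n_perm = config$n_perm,
      q_cutoff = config$q_pairs, seed = derive_seed(seed, "pairs", ln))
  })
  called_pre <- lapply(pair_results, `[[`, "called")
  note("pairs", n_called = lengths(called_pre))

  ## stage 5: housekeeping subtraction, unique pairs, clustering
  hk_called <- if ("HK" %in% names(called_pre)) called_pre$HK else character()
  subtraction <- lapply(called_pre[tissues], subtract_housekeeping,
                        housekeeping_pairs = hk_called)
  tissue_pairs <- lapply(subtraction, `[[`, "pairs")
  removed_fraction <- vapply(subtraction, `[[`, numeric(1),
                             "removed_fraction")
  unique_pairs <- if (length(tissues) >= 2) {
    tissue_unique_pairs(tissue_pairs)
  } else NULL
  groups <- config$tissue_groups
  if (is.null(groups)) groups <- list(all = tissues)
  clusters <- if (length(tissues) >= 2 &&
                  any(lengths(tissue_pairs) > 0)) {
    complete_linkage_clusters(
      binary_distance_matrix(presence_matrix(tissue_pairs)),
      n_groups = length(groups))
  } else NULL
  note("tissues", removed_fraction = round(removed_fraction, 3),
       n_tissue_pairs = lengths(tissue_pairs))

  ## stage 6: tissue-type pairs and networks
  tt_pairs <- lapply(groups, function(g) {
    if (length(g) < 2) character() else {
      tissue_type_pairs(g, tissue_pairs, config$min_tissue_fraction)
    }
  })
  networks_by_tissue <- lapply(stats::setNames(nm = tissues), function(t) {
    grp <- groups[vapply(groups, function(g) t %in% g, logical(1))]
    present <- if (length(grp)) {
      intersect(tt_pairs[[names(grp)[1]]], tissue_pairs[[t]])
    } else character()
    build_networks(present, tissue = t)
  })
  tt_networks <- lapply(groups, function(g) {
    if (length(g) < 2) list() else {
      match_tissue_type_networks(networks_by_tissue, g)
    }
  })
  note("networks",
       n_networks = sum(lengths(networks_by_tissue)),
       n_tissue_type_networks = sum(lengths(tt_networks)))

  ## stage 7: triplets per tissue
  triplets <- lapply(stats::setNames(nm = tissues), function(t) {
    tp <- tissue_pairs[[t]]
    genes_t <- lists[[t]]
    map <- study$ortholog_map[human %in% genes_t]
    occ_h <- pair_occurrences(
      hits$real$human[gene_id %in% genes_t], tp, max(config$grid))
    occ_m <- pair_occurrences(
      hits$real$mouse[gene_id %in% map$mouse], tp, max(config$grid))
    trip_h <- compose_triplets(occ_h)
    trip_m <- compose_triplets(occ_m)
    cons <- conserved_occurrences(trip_h, trip_m, map)
    call_triplets(cons, trip_h, trip_m, length(genes_t), map,
                  min_support = config$min_support,
                  q_cutoff = config$q_pairs)
  })
  note("triplets",
       n_called = vapply(triplets, function(x) sum(x$called), integer(1)))

  ## stage 8: annotation enrichment (optional)
  enrichment <- NULL
  if (!is.null(config$term_map)) {
    genome <- study$ortholog_map$human
    enrichment <- lapply(stats::setNames(nm = tissues), function(t) {
      gaps <- pair_results[[t]]$gaps$human
      targets <- unique(gaps[pair %in% tissue_pairs[[t]], gene_id])
      if (length(targets) == 0) return(NULL)
      enrich_terms(targets, config$term_map, genome,
                   q_cutoff = config$q_terms)
    })
    note("enrich", n_lists = sum(!vapply(enrichment, is.null, logical(1))))
  }

  result <- list(study = study, lib = lib, hits = hits,
                 pair_results = pair_results, called_pre = called_pre,
                 tissue_pairs = tissue_pairs,
                 removed_fraction = removed_fraction,
                 unique_pairs = unique_pairs, clusters = clusters,
                 tissue_type_pairs = tt_pairs,
                 networks = networks_by_tissue,
                 tissue_type_networks = tt_networks, triplets = triplets,
                 enrichment = enrichment, manifest = manifest)
  if (!is.null(out_dir)) write_pipeline_outputs(result, out_dir)
  result
}

write_pipeline_outputs <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  tissues <- names(result$tissue_pairs)
  pair_tab <- data.table::rbindlist(lapply(names(result$pair_results),
                                           function(ln) {
    t <- data.table::copy(result$pair_results[[ln]]$table)
    t[, list_name := ln]
    t
  }), fill = TRUE)
  data.table::fwrite(pair_tab, file.path(out_dir, "pair_calls.tsv"),
                     sep = "\t")
  data.table::fwrite(
    data.table::rbindlist(lapply(tissues, function(t) {
      data.table::data.table(tissue = t, pair = result$tissue_pairs[[t]])
    })), file.path(out_dir, "tissue_pairs.tsv"), sep = "\t")
  trip_tab <- data.table::rbindlist(lapply(tissues, function(t) {
    tt <- data.table::copy(result$triplets[[t]])
    if (nrow(tt)) tt[, tissue := t]
    tt
  }), fill = TRUE)
  data.table::fwrite(trip_tab, file.path(out_dir, "triplet_calls.tsv"),
                     sep = "\t")
  edges <- data.table::rbindlist(lapply(tissues, function(t) {
    data.table::rbindlist(lapply(result$networks[[t]], function(n) {
      data.table::data.table(tissue = t, edge = n$edges)
    }))
  }), fill = TRUE)
  if (nrow(edges) == 0) {
    edges <- data.table::data.table(tissue = character(),
                                    edge = character())
  }
  data.table::fwrite(edges, file.path(out_dir, "network_edges.tsv"),
                     sep = "\t")
  jsonlite::write_json(result$manifest,
                       file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}
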