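#' Planted-truth table of a synthetic study
#'
#' One row per (gene list, pair key) that carries generator-created signal:
#' the deliberately planted pairs (`kind = "planted"`), the three pairs
#' implied by a planted triplet (`kind = "triplet"`; its sites co-occur
#' under the distance constraint), and emergent cross-element pairs
#' (`kind = "emergent"`): combinations of two motifs whose elements are
#' co-planted in the same gene list. Elements land in overlapping carrier
#' subsets at random positions, so cross combinations genuinely co-occur
#' and are conserved — calling them is not an error of the method.
#'
#' @param study a generated study (from [generate_study()]).
#' @return `data.table` with `list_name`, `pair`, `housekeeping`, `kind`.
#' @export
planted_pair_truth <- function(study) {
  gt <- study$ground_truth
  rows <- list()
  members <- list()   # list_name -> planted PWM ids
  add_members <- function(lname, ids) {
    members[[lname]] <<- unique(c(members[[lname]], ids))
  }
  if (nrow(gt$pairs)) {
    p <- gt$pairs
    rows[[length(rows) + 1L]] <-
      data.table::data.table(list_name = p$list_name, pair = p$pair,
                             housekeeping = p$housekeeping, kind = "planted")
    for (i in seq_len(nrow(p))) {
      add_members(p$list_name[i], strsplit(p$pair[i], ":")[[1]])
    }
  }
  if (nrow(gt$triplets)) {
    trip <- gt$triplets
    for (i in seq_len(nrow(trip))) {
      ids <- strsplit(trip$triplet[i], ":")[[1]]
      combs <- utils::combn(ids, 2)
      rows[[length(rows) + 1L]] <- data.table::data.table(
        list_name = trip$tissue[i],
        pair = unique(pair_key(combs[1, ], combs[2, ])),
        housekeeping = FALSE, kind = "triplet")
      add_members(trip$tissue[i], ids)
    }
  }
  for (lname in names(members)) {
    ids <- members[[lname]]
    if (length(ids) < 2) next
    combs <- utils::combn(sort(ids), 2)
    rows[[length(rows) + 1L]] <- data.table::data.table(
      list_name = lname, pair = pair_key(combs[1, ], combs[2, ]),
      housekeeping = FALSE, kind = "emergent")
  }
  if (length(rows) == 0) {
    return(data.table::data.table(list_name = character(), pair = character(),
                                  housekeeping = logical(),
                                  kind = character()))
  }
  out <- data.table::rbindlist(rows)
  # deliberate plantings take precedence over the emergent expansion
  out[order(factor(kind, levels = c("planted", "triplet", "emergent")))][
    !duplicated(paste(list_name, pair))]
}

#' Null-study configuration
#'
#' The default study conditions with nothing planted; used as the negative
#' control for the call rate of the full pipeline.
#'
#' @param seed integer seed.
#' @return a [study_config()].
#' @export
null_study_config <- function(seed = 1L) {
  cfg <- default_study_config(seed)
  cfg$planted_pairs <- list()
  cfg$planted_triplets <- list()
  cfg
}

#' Run the default synthetic study end to end
#'
#' @param seed integer seed (drives the study and every stage).
#' @param config a [study_config()]; defaults to [default_study_config()].
#' @param ... further arguments for [pipeline_config()].
#' @return a [run_pipeline()] result.
#' @export
run_synthetic_study <- function(seed = 1L,
                                config = default_study_config(seed), ...) {
  run_pipeline(pipeline_config(config, ...))
}

#' Score a pipeline run against its planted ground truth
#'
#' Compares the post-subtraction tissue TF pair sets and the triplet calls
#' with what the generator planted.
#'
#' @param result a [run_pipeline()] result on a synthetic study.
#' @return list with: `planted` (per tissue-planted pair: called in its
#'   tissue or not), `housekeeping` (per ubiquitous pair: called from the
#'   housekeeping list, and removed from every tissue set), `calls`
#'   (every called tissue pair with its truth flag), `n_called`,
#'   `n_false`, `fdr`, and `triplets` (per planted triplet: called in its
#'   tissue or not).
#' @export
evaluate_recovery <- function(result) {
  truth <- planted_pair_truth(result$study)
  tissues <- names(result$tissue_pairs)

  tissue_truth <- truth[list_name %in% tissues]
  planted <- unique(truth[kind == "planted" & housekeeping == FALSE &
                            list_name %in% tissues, .(list_name, pair)])
  planted[, called := mapply(function(t, pk) {
    pk %in% result$tissue_pairs[[t]]
  }, list_name, pair)]

  hk_keys <- unique(truth[housekeeping == TRUE, pair])
  housekeeping <- data.table::data.table(
    pair = hk_keys,
    called_hk = hk_keys %in% result$called_pre$HK,
    removed_everywhere = vapply(hk_keys, function(pk) {
      !any(vapply(tissues, function(t) {
        pk %in% result$tissue_pairs[[t]]
      }, logical(1)))
    }, logical(1)))

  calls <- data.table::rbindlist(lapply(tissues, function(t) {
    pk <- result$tissue_pairs[[t]]
    if (length(pk) == 0) return(NULL)
    data.table::data.table(
      tissue = t, pair = pk,
      true_signal = pk %in% tissue_truth[list_name == t, pair])
  }))
  n_called <- if (is.null(calls)) 0L else nrow(calls)
  n_false <- if (n_called == 0) 0L else sum(!calls$true_signal)

  trip_truth <- result$study$ground_truth$triplets
  triplets <- if (nrow(trip_truth)) {
    data.table::data.table(
      triplet = trip_truth$triplet, tissue = trip_truth$tissue,
      called = mapply(function(key, t) {
        tab <- result$triplets[[t]]
        nrow(tab[triplet == key & called == TRUE]) > 0
      }, trip_truth$triplet, trip_truth$tissue))
  } else data.table::data.table(triplet = character(), tissue = character(),
                                called = logical())

  list(planted = planted, housekeeping = housekeeping, calls = calls,
       n_called = n_called, n_false = n_false,
       fdr = if (n_called == 0) 0 else n_false / n_called,
       triplets = triplets)
}
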