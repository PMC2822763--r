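#' Specification for a planted, distance-constrained TFBS pair
#'
#' Describes one conserved binding-site pair to plant in a synthetic study:
#' which two motifs (possibly the same, giving a homotypic pair), the
#' maximum edge-to-edge gap (planted gaps are drawn uniformly in
#' `[0, gap_max]`), what fraction of a list's genes carry the pair, and what
#' fraction of carriers replicate the sites with identical order and
#' orientation in the orthologous promoter.
#'
#' @param pwm_a,pwm_b PWM ids from the study's library (may be equal).
#' @param gap_max maximum planted gap, bp (<= 200 for recoverable pairs).
#' @param gene_fraction fraction of list genes carrying the pair.
#' @param conserve_fraction fraction of carriers conserved in the ortholog.
#' @param tissues character vector of tissue list names to plant in.
#' @param housekeeping also plant in the housekeeping list (a ubiquitous
#'   pair is planted in tissue lists *and* housekeeping).
#' @return a `plant_spec` list.
#' @export
plant_spec <- function(pwm_a, pwm_b, gap_max = 60L, gene_fraction = 0.3,
                       conserve_fraction = 0.9, tissues = character(),
                       housekeeping = FALSE) {
  stopifnot(gap_max >= 0, gap_max <= 200,
            gene_fraction >= 0, gene_fraction <= 1,
            conserve_fraction >= 0, conserve_fraction <= 1)
  structure(list(pwm_a = pwm_a, pwm_b = pwm_b, gap_max = as.integer(gap_max),
                 gene_fraction = gene_fraction,
                 conserve_fraction = conserve_fraction,
                 tissues = tissues, housekeeping = housekeeping),
            class = "plant_spec")
}

#' Specification for a planted conserved three-TFBS combination
#'
#' Three sites A-B-C planted left to right with independent uniform gaps in
#' `[0, gap_max]` on a fixed number of carrier genes of one tissue;
#' `conserve_fraction` of carriers replicate all three sites with identical
#' order and orientation in the ortholog.
#'
#' @param pwms character vector of exactly 3 PWM ids.
#' @param gap_max maximum gap between adjacent sites, bp.
#' @param n_carriers number of carrier genes (drawn without replacement).
#' @param conserve_fraction fraction of carriers conserved in the ortholog.
#' @param tissue tissue list name to plant in.
#' @return a `triplet_spec` list.
#' @export
triplet_spec <- function(pwms, gap_max = 60L, n_carriers = 30L,
                         conserve_fraction = 1.0, tissue) {
  stopifnot(length(pwms) == 3, gap_max >= 0, n_carriers >= 1,
            conserve_fraction >= 0, conserve_fraction <= 1)
  structure(list(pwms = pwms, gap_max = as.integer(gap_max),
                 n_carriers = as.integer(n_carriers),
                 conserve_fraction = conserve_fraction, tissue = tissue),
            class = "triplet_spec")
}

#' Configuration of a synthetic two-species promoter study
#'
#' The generator emulates the shape of a comparative promoter analysis:
#' per-tissue gene lists plus a housekeeping list, 1 kb orthologous promoter
#' pairs for two species, a PWM library, and planted distance-constrained
#' conserved binding-site pairs/triplets recorded as ground truth.
#'
#' @param n_pwms PWM library size.
#' @param pwm_length_range motif length range, bp.
#' @param ic_target mean information content per column, bits.
#' @param n_tissues number of tissue gene lists.
#' @param genes_per_tissue genes per tissue list.
#' @param n_housekeeping housekeeping gene count.
#' @param promoter_length promoter length, bp.
#' @param planted_pairs list of [plant_spec()] objects.
#' @param planted_triplets list of [triplet_spec()] objects.
#' @param ortholog_divergence per-base substitution rate applied to the
#'   second species outside planted sites, in [0, 1].
#' @param gc_content background GC fraction (i.i.d. background letters).
#' @param seed integer seed; the whole study is deterministic per seed.
#' @return a `study_config` list.
#' @export
study_config <- function(n_pwms = 40L, pwm_length_range = c(12L, 16L),
                         ic_target = 1.95, n_tissues = 4L,
                         genes_per_tissue = 250L, n_housekeeping = 900L,
                         promoter_length = 1000L,
                         planted_pairs = list(), planted_triplets = list(),
                         ortholog_divergence = 0.75, gc_content = 0.5,
                         seed = 1L) {
  stopifnot(n_pwms >= 2, n_tissues >= 1, genes_per_tissue >= 1,
            n_housekeeping >= 0, promoter_length >= 1,
            ortholog_divergence >= 0, ortholog_divergence <= 1,
            gc_content > 0, gc_content < 1)
  gaps <- vapply(planted_pairs, `[[`, integer(1), "gap_max")
  if (promoter_length < 2 * max(pwm_length_range) +
      max(c(gaps, 0L))) {
    stop("study_config: promoter too short for the planted elements")
  }
  structure(list(n_pwms = as.integer(n_pwms),
                 pwm_length_range = as.integer(pwm_length_range),
                 ic_target = ic_target, n_tissues = as.integer(n_tissues),
                 genes_per_tissue = as.integer(genes_per_tissue),
                 n_housekeeping = as.integer(n_housekeeping),
                 promoter_length = as.integer(promoter_length),
                 planted_pairs = planted_pairs,
                 planted_triplets = planted_triplets,
                 ortholog_divergence = ortholog_divergence,
                 gc_content = gc_content, seed = as.integer(seed)),
            class = "study_config")
}

#' Default synthetic study
#'
#' The package's reference validation conditions: a library of 40 PWMs
#' (12-16 bp), 4 tissue lists of 250 genes plus 900 housekeeping orthologs,
#' 5 tissue-planted conserved pairs (gap <= 60 bp, carried by 30% of the
#' tissue's genes, 90% conserved) spread over the tissues on disjoint
#' motifs, 2 pairs planted in the housekeeping list,
#' and one conserved triplet with 30 fully conserved carrier genes.
#'
#' @param seed integer seed.
#' @return a [study_config()].
#' @export
default_study_config <- function(seed = 1L) {
  ts <- paste0("T", 1:4)
  pid <- function(i) sprintf("PWM%03d", i)
  pairs <- lapply(1:5, function(i) {
    plant_spec(pid(2 * i - 1), pid(2 * i), gap_max = 60L,
               gene_fraction = 0.3, conserve_fraction = 0.9,
               tissues = ts[(i - 1) %% 4 + 1])
  })
  hk <- lapply(1:2, function(i) {
    plant_spec(pid(10 + 2 * i - 1), pid(10 + 2 * i), gap_max = 60L,
               gene_fraction = 0.3, conserve_fraction = 0.9,
               housekeeping = TRUE)
  })
  trip <- list(triplet_spec(pid(15:17), gap_max = 60L, n_carriers = 30L,
                            conserve_fraction = 1.0, tissue = "T1"))
  study_config(n_pwms = 40L, pwm_length_range = c(12L, 16L), ic_target = 1.95,
               n_tissues = 4L, genes_per_tissue = 250L, n_housekeeping = 900L,
               promoter_length = 1000L, planted_pairs = c(pairs, hk),
               planted_triplets = trip, seed = seed)
}

# Sample a site (letter codes 1..4) from a PWM's columns.
sample_site_codes <- function(mat) {
  vapply(seq_len(nrow(mat)), function(j) {
    sample.int(4L, 1L, prob = mat[j, ])
  }, integer(1))
}

# Codes as planted on the forward strand for a site with the given strand.
oriented_codes <- function(codes, strand) {
  if (strand == "+") codes else rev(5L - codes)
}

# Find a start for a span of `width` bp avoiding `occupied` intervals
# (2-column matrix start/end, 0-based half-open). NA if no luck.
draw_free_start <- function(width, plen, occupied, max_try = 50L) {
  for (k in seq_len(max_try)) {
    s <- sample.int(plen - width + 1L, 1L) - 1L
    if (nrow(occupied) == 0 ||
        all(s + width <= occupied[, 1] | s >= occupied[, 2])) {
      return(s)
    }
  }
  NA_integer_
}

#' Generate a synthetic two-species study
#'
#' Produces orthologous promoter corpora for two species with i.i.d.
#' background sequence, per-base divergence in the second species outside
#' planted loci, and planted conserved binding-site pairs and triplets per
#' the configuration. Every output is deterministic given `config$seed`.
#'
#' @param config a [study_config()].
#' @return list with `pwm_lib`, `promoters` (named list of two promoter
#'   tables), `ortholog_map` (`data.table` with `human`, `mouse`),
#'   `gene_lists` (`data.table` with `tissue`, `gene`; the housekeeping list
#'   is named `"HK"`), and `ground_truth` (planted element keys and site
#'   coordinates).
#' @export
generate_study <- function(config) {
  seed <- config$seed
  plen <- config$promoter_length
  lib <- generate_pwm_library(config$n_pwms, config$pwm_length_range,
                              config$ic_target, seed = derive_seed(seed, "lib"))
  for (ps in config$planted_pairs) {
    if (!all(c(ps$pwm_a, ps$pwm_b) %in% names(lib))) {
      stop("generate_study: planted pair references unknown PWM")
    }
  }
  for (ts in config$planted_triplets) {
    if (!all(ts$pwms %in% names(lib))) {
      stop("generate_study: planted triplet references unknown PWM")
    }
  }

  tissues <- paste0("T", seq_len(config$n_tissues))
  lists <- c(stats::setNames(lapply(tissues, function(t) {
    sprintf("%s_G%03d", t, seq_len(config$genes_per_tissue))
  }), tissues),
  list(HK = if (config$n_housekeeping > 0) {
    sprintf("HK_G%03d", seq_len(config$n_housekeeping))
  } else character(0)))
  genes <- unlist(lists, use.names = FALSE)
  ngene <- length(genes)
  gidx <- stats::setNames(seq_len(ngene), genes)

  gc <- config$gc_content
  base_prob <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)

  # background letters (codes 1..4), one column per gene
  hmat <- with_seed(derive_seed(seed, "bg_human"), {
    matrix(sample.int(4L, plen * ngene, replace = TRUE, prob = base_prob),
           nrow = plen)
  })
  mmat <- with_seed(derive_seed(seed, "bg_mouse"), {
    mut <- matrix(stats::runif(plen * ngene) < config$ortholog_divergence,
                  nrow = plen)
    shift <- matrix(sample.int(3L, plen * ngene, replace = TRUE), nrow = plen)
    out <- hmat
    out[mut] <- ((hmat[mut] - 1L + shift[mut]) %% 4L) + 1L
    out
  })

  truth_sites <- list()
  truth_pairs <- list()
  truth_triplets <- list()
  occupied <- lapply(seq_len(ngene), function(i) {
    matrix(integer(0), ncol = 2)
  })

  plant_element <- function(gene, pwm_ids, gap_max, conserve, label, kind) {
    # draws sites, strands and gaps; plants into both species' matrices
    gi <- gidx[[gene]]
    mats <- lapply(pwm_ids, function(id) lib[[id]]$mat)
    widths <- vapply(mats, nrow, integer(1))
    gaps <- sample.int(gap_max + 1L, length(pwm_ids) - 1L,
                       replace = TRUE) - 1L
    span <- sum(widths) + sum(gaps)
    if (span > plen) stop("generate_study: planted element exceeds promoter")
    s0 <- draw_free_start(span, plen, occupied[[gi]])
    if (is.na(s0)) {
      stop("generate_study: could not place element in gene ", gene,
           " after bounded retries")
    }
    starts <- s0 + cumsum(c(0L, widths[-length(widths)] +
                              gaps))
    strands <- sample(c("+", "-"), length(pwm_ids), replace = TRUE)
    conserved <- stats::runif(1) < conserve
    rows <- vector("list", length(pwm_ids))
    for (k in seq_along(pwm_ids)) {
      codes <- sample_site_codes(mats[[k]])
      fwd <- oriented_codes(codes, strands[k])
      pos <- (starts[k] + 1L):(starts[k] + widths[k])
      hmat[pos, gi] <<- fwd
      if (conserved) mmat[pos, gi] <<- fwd
      rows[[k]] <- data.table::data.table(
        element = label, kind = kind, gene_human = gene,
        gene_mouse = paste0("mm_", gene), pwm = pwm_ids[k],
        start = starts[k], end = starts[k] + widths[k],
        strand = strands[k], conserved = conserved)
    }
    occupied[[gi]] <<- rbind(occupied[[gi]],
                             cbind(starts, starts + widths))
    data.table::rbindlist(rows)
  }

  with_seed(derive_seed(seed, "plant"), {
    for (i in seq_along(config$planted_pairs)) {
      ps <- config$planted_pairs[[i]]
      label <- sprintf("pair%02d", i)
      key <- pair_key(ps$pwm_a, ps$pwm_b)
      target_lists <- c(ps$tissues, if (ps$housekeeping) "HK")
      for (lname in target_lists) {
        carriers <- lists[[lname]][
          stats::runif(length(lists[[lname]])) < ps$gene_fraction]
        for (g in carriers) {
          truth_sites[[length(truth_sites) + 1L]] <-
            plant_element(g, c(ps$pwm_a, ps$pwm_b), ps$gap_max,
                          ps$conserve_fraction, label, "pair")
        }
        truth_pairs[[length(truth_pairs) + 1L]] <- data.table::data.table(
          element = label, list_name = lname, pair = key,
          housekeeping = ps$housekeeping, n_carriers = length(carriers))
      }
    }
    for (i in seq_along(config$planted_triplets)) {
      ts <- config$planted_triplets[[i]]
      label <- sprintf("triplet%02d", i)
      carriers <- sample(lists[[ts$tissue]], ts$n_carriers)
      for (g in carriers) {
        truth_sites[[length(truth_sites) + 1L]] <-
          plant_element(g, ts$pwms, ts$gap_max, ts$conserve_fraction,
                        label, "triplet")
      }
      truth_triplets[[length(truth_triplets) + 1L]] <- data.table::data.table(
        element = label, tissue = ts$tissue,
        triplet = paste(sort(ts$pwms), collapse = ":"),
        n_carriers = ts$n_carriers)
    }
  })

  to_seq <- function(mat) {
    apply(matrix(DNA_LETTERS[mat], nrow = plen), 2, paste, collapse = "")
  }
  promoters <- list(
    human = data.table::data.table(gene_id = genes, species = "human",
                                   sequence = to_seq(hmat)),
    mouse = data.table::data.table(gene_id = paste0("mm_", genes),
                                   species = "mouse",
                                   sequence = to_seq(mmat)))
  gene_lists <- data.table::rbindlist(lapply(names(lists), function(nm) {
    data.table::data.table(tissue = nm, gene = lists[[nm]])
  }))

  list(pwm_lib = lib,
       promoters = promoters,
       ortholog_map = data.table::data.table(human = genes,
                                             mouse = paste0("mm_", genes)),
       gene_lists = gene_lists,
       ground_truth = list(
         sites = if (length(truth_sites)) data.table::rbindlist(truth_sites)
                 else data.table::data.table(),
         pairs = if (length(truth_pairs)) data.table::rbindlist(truth_pairs)
                 else data.table::data.table(),
         triplets = if (length(truth_triplets))
           data.table::rbindlist(truth_triplets)
         else data.table::data.table()),
       config = config)
}

#' Write a synthetic study to disk
#'
#' FASTA per species, 2-column ortholog map TSV, gene-list TSV, PWM library
#' in JASPAR PFM text, and the ground truth as a JSON manifest.
#'
#' @param study result of [generate_study()].
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_promoters(study$promoters$human, file.path(dir, "promoters_human.fa"))
  write_promoters(study$promoters$mouse, file.path(dir, "promoters_mouse.fa"))
  data.table::fwrite(study$ortholog_map, file.path(dir, "orthologs.tsv"),
                     sep = "\t")
  data.table::fwrite(study$gene_lists, file.path(dir, "gene_lists.tsv"),
                     sep = "\t")
  write_jaspar_pfm(study$pwm_lib, file.path(dir, "pwm_library.pfm"))
  gt <- lapply(study$ground_truth, function(x) {
    if (data.table::is.data.table(x)) as.data.frame(x) else x
  })
  jsonlite::write_json(gt, file.path(dir, "ground_truth.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
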