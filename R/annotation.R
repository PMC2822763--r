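#' Read a gene annotation term map
#'
#' Accepts GMT (term, description, genes...) or 2-column TSV
#' (term <TAB> gene) formats, auto-detected per line shape.
#'
#' @param path annotation file.
#' @return named list: term id -> character vector of gene ids.
#' @export
read_term_map <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) stop("read_term_map: empty file ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  two_col <- all(lengths(fields) == 2)
  if (two_col) {
    term <- vapply(fields, `[[`, "", 1L)
    gene <- vapply(fields, `[[`, "", 2L)
    map <- split(gene, term)
  } else {
    map <- stats::setNames(
      lapply(fields, function(f) unique(f[-(1:2)])),
      vapply(fields, `[[`, "", 1L))
  }
  map <- lapply(map, unique)
  if (any(lengths(map) == 0)) stop("read_term_map: empty term sets")
  map
}

#' Term enrichment of a target gene set
#'
#' One-sided Fisher (hypergeometric) enrichment of each term in the target
#' set against the genome universe, with BH q-values. Depletion is not
#' tested.
#'
#' @param targets character vector of target gene ids (subset of genome).
#' @param term_map named list term -> gene ids (see [read_term_map()]).
#' @param genome character vector: the gene universe.
#' @param q_cutoff significance threshold on q (default 0.1).
#' @return `data.table` with `term`, `k` (targets in term), `K` (term
#'   size), `p`, `q`, `significant`, ordered by p.
#' @export
enrich_terms <- function(targets, term_map, genome, q_cutoff = 0.1) {
  targets <- unique(targets)
  genome <- unique(genome)
  if (!all(targets %in% genome)) {
    stop("enrich_terms: targets outside the genome universe")
  }
  if (length(targets) == 0) {
    warning("enrich_terms: empty target set")
    return(data.table::data.table(term = character(), k = integer(),
                                  K = integer(), p = numeric(),
                                  q = numeric(), significant = logical()))
  }
  terms <- sort(names(term_map))
  rows <- lapply(terms, function(tm) {
    tset <- intersect(term_map[[tm]], genome)
    k <- length(intersect(targets, tset))
    data.table::data.table(
      term = tm, k = k, K = length(tset),
      p = fisher_enrichment(k, length(targets), length(tset),
                            length(genome)))
  })
  tab <- data.table::rbindlist(rows)
  tab[, q := bh_qvalues(p)]
  tab[, significant := q < q_cutoff]
  data.table::setorder(tab, p, term)
  tab[]
}

#' Significance of the overlap between two sets
#'
#' Hypergeometric upper tail for the observed intersection of two sets
#' drawn from a common universe; used for overlap of tissue TF pair sets
#' (universe: the pair universe) and of their annotated functions
#' (universe: the term vocabulary). Symmetric in its two sets.
#'
#' @param set_a,set_b character vectors (subsets of `universe`).
#' @param universe character vector.
#' @return probability of an overlap at least as large.
#' @export
overlap_significance <- function(set_a, set_b, universe) {
  a <- unique(set_a); b <- unique(set_b); u <- unique(universe)
  if (!all(a %in% u) || !all(b %in% u)) {
    stop("overlap_significance: sets must lie in the universe")
  }
  hypergeom_overlap_pvalue(length(intersect(a, b)), length(u),
                           length(a), length(b))
}
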