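#' Read promoter sequences from FASTA
#'
#' Promoters are 5'->3' upstream sequences with the transcription start site
#' immediately to the right of the last base; coordinates elsewhere in the
#' package are 0-based with half-open intervals.
#'
#' @param fasta_path FASTA file, one record per gene, headers = gene ids.
#' @param species species label attached to every record.
#' @return `data.table` with columns `gene_id`, `species`, `sequence`.
#' @export
read_promoters <- function(fasta_path, species) {
  ss <- Biostrings::readDNAStringSet(fasta_path)
  if (length(ss) == 0) {
    warning("read_promoters: no records in ", fasta_path)
    return(data.table::data.table(gene_id = character(),
                                  species = character(),
                                  sequence = character()))
  }
  ids <- sub("\\s.*$", "", names(ss))
  if (anyDuplicated(ids)) {
    stop("read_promoters: duplicate gene ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  seqs <- toupper(as.character(ss))
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad)) {
    stop("read_promoters: non-ACGTN characters in record(s): ",
         paste(ids[bad], collapse = ", "))
  }
  data.table::data.table(gene_id = ids, species = species, sequence = seqs)
}

#' Write promoter records as FASTA
#' @param records `data.table` as returned by [read_promoters()].
#' @param path output FASTA path.
#' @return `path`, invisibly.
#' @export
write_promoters <- function(records, path) {
  ss <- Biostrings::DNAStringSet(records$sequence)
  names(ss) <- records$gene_id
  Biostrings::writeXStringSet(ss, path, width = 70L)
  invisible(path)
}

#' Complete (mononucleotide) promoter shuffle
#'
#' Uniform random permutation of the letters; the mononucleotide multiset is
#' preserved exactly.
#'
#' @param sequence nucleotide string.
#' @param seed integer seed.
#' @return shuffled string.
#' @export
shuffle_complete <- function(sequence, seed = 1L) {
  if (nchar(sequence) == 0) stop("shuffle_complete: empty sequence")
  letters <- strsplit(sequence, "")[[1]]
  with_seed(seed, paste(sample(letters), collapse = ""))
}

#' Dinucleotide-preserving promoter shuffle
#'
#' Altschul-Erickson Eulerian-path shuffle: the full 16-cell (plus N)
#' dinucleotide count matrix, the first letter and the last letter are all
#' preserved exactly.
#'
#' @param sequence nucleotide string of length >= 2.
#' @param seed integer seed.
#' @return shuffled string.
#' @export
shuffle_dinucleotide <- function(sequence, seed = 1L) {
  s <- strsplit(sequence, "")[[1]]
  n <- length(s)
  if (n < 2) stop("shuffle_dinucleotide: need length >= 2")
  verts <- unique(s)
  if (length(verts) == 1) return(sequence)
  from <- s[-n]; to <- s[-1]
  last <- s[n]
  out_edges <- split(to, factor(from, levels = verts))
  with_seed(seed, {
    repeat {
      # pick a random "last exit" edge for every vertex except the terminal
      last_exit <- vapply(verts, function(v) {
        if (v == last || length(out_edges[[v]]) == 0) return(NA_character_)
        sample(out_edges[[v]], 1L)
      }, character(1))
      # the last-exit edges must form an arborescence into the terminal
      ok <- TRUE
      for (v in verts) {
        if (v == last || length(out_edges[[v]]) == 0) next
        seen <- character(0); cur <- v
        while (!is.na(cur) && cur != last && !(cur %in% seen)) {
          seen <- c(seen, cur)
          cur <- last_exit[[cur]]
        }
        if (is.na(cur) || cur != last) { ok <- FALSE; break }
      }
      if (ok) break
    }
    lists <- lapply(verts, function(v) {
      ed <- out_edges[[v]]
      if (length(ed) == 0) return(character(0))
      if (v == last || is.na(last_exit[[v]])) return(sample(ed))
      le <- last_exit[[v]]
      i <- match(le, ed)
      c(sample(ed[-i]), le)
    })
    names(lists) <- verts
    ptr <- stats::setNames(rep(1L, length(verts)), verts)
    walk <- character(n)
    walk[1] <- s[1]
    cur <- s[1]
    for (i in 2:n) {
      nxt <- lists[[cur]][ptr[[cur]]]
      ptr[[cur]] <- ptr[[cur]] + 1L
      walk[i] <- nxt
      cur <- nxt
    }
    paste(walk, collapse = "")
  })
}

#' Build a shuffled background corpus
#'
#' One or more shuffles per promoter. Each record's shuffle is seeded by
#' (seed, gene id, replicate, mode) so results do not depend on input order.
#'
#' @param promoters promoter `data.table` (see [read_promoters()]).
#' @param mode `"complete"` (default, mononucleotide) or `"dinucleotide"`.
#' @param n_replicates shuffles per promoter (>= 1).
#' @param seed integer seed.
#' @return `data.table` with `gene_id`, `species`, `replicate`, `sequence`.
#' @export
make_background_set <- function(promoters, mode = c("complete", "dinucleotide"),
                                n_replicates = 1L, seed = 1L) {
  mode <- match.arg(mode)
  if (n_replicates < 1) stop("make_background_set: n_replicates must be >= 1")
  shuf <- if (mode == "complete") shuffle_complete else shuffle_dinucleotide
  out <- lapply(seq_len(n_replicates), function(rep_i) {
    seqs <- vapply(seq_len(nrow(promoters)), function(i) {
      shuf(promoters$sequence[i],
           derive_seed(seed, "background", promoters$gene_id[i], rep_i, mode))
    }, character(1))
    data.table::data.table(gene_id = promoters$gene_id,
                           species = promoters$species,
                           replicate = rep_i, sequence = seqs)
  })
  data.table::rbindlist(out)
}

#' Dinucleotide count matrix of a sequence
#' @param sequence nucleotide string.
#' @return table of adjacent letter pairs.
#' @export
dinucleotide_counts <- function(sequence) {
  s <- strsplit(sequence, "")[[1]]
  if (length(s) < 2) return(table(character(0)))
  table(paste0(s[-length(s)], s[-1]))
}
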