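DNA_LETTERS <- c("A", "C", "G", "T")

#' Construct a position weight matrix object
#'
#' A PWM is stored as an L x 4 positional frequency matrix (columns A, C, G,
#' T; rows sum to 1) together with its per-position information vector
#' I_i = sum_b f(i,b) ln(4 f(i,b)) and, once calibrated, a detection
#' threshold on the 0-1 matrix-similarity scale.
#'
#' @param id identifier string.
#' @param mat L x 4 matrix of frequencies or counts (normalised per row).
#' @param name optional display name (defaults to `id`).
#' @param threshold detection threshold in [0, 1] or `NA` before calibration.
#' @return an object of class `pwm`.
#' @export
pwm <- function(id, mat, name = id, threshold = NA_real_) {
  mat <- as.matrix(mat)
  if (ncol(mat) != 4) stop("pwm: matrix must have 4 columns (A,C,G,T)")
  if (nrow(mat) < 5) stop("pwm: length must be >= 5")
  if (any(mat < 0)) stop("pwm: negative frequencies")
  mat <- mat / rowSums(mat)
  colnames(mat) <- DNA_LETTERS
  structure(list(id = as.character(id), name = as.character(name),
                 mat = mat, threshold = threshold),
            class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("PWM %s (%s), length %d, mean IC %.2f bits, threshold %s\n",
              x$id, x$name, nrow(x$mat),
              mean(pwm_information(x)) / log(2),
              if (is.na(x$threshold)) "uncalibrated"
              else sprintf("%.2f", x$threshold)))
  invisible(x)
}

#' Per-position information vector of a PWM
#'
#' I_i = sum_b f(i,b) ln(4 f(i,b)), in nats; 0 for background-like positions
#' and ln(4) for point-mass positions.
#'
#' @param p a [pwm()] object.
#' @return numeric vector of length L.
#' @export
pwm_information <- function(p) {
  f <- p$mat
  term <- ifelse(f > 0, f * log(4 * f), 0)
  rowSums(term)
}

#' Core positions of a PWM
#'
#' The five positions with the highest information content (Match-style
#' "core"); reported for inspection only, the scanner scores all positions.
#'
#' @param p a [pwm()] object.
#' @return integer vector of 5 position indices (fewer if L < 5).
#' @export
pwm_core_positions <- function(p) {
  info <- pwm_information(p)
  utils::head(order(info, decreasing = TRUE), 5L)
}

#' Consensus sequence of a PWM
#' @param p a [pwm()] object.
#' @return character string of the per-position most frequent letters.
#' @export
pwm_consensus <- function(p) {
  paste(DNA_LETTERS[max.col(p$mat, ties.method = "first")], collapse = "")
}

# Reverse complement of a PWM frequency matrix.
pwm_revcomp_mat <- function(mat) {
  mat[rev(seq_len(nrow(mat))), c(4, 3, 2, 1), drop = FALSE]
}

# Scanner internals: 5 x L contribution matrix (rows A,C,G,T,N) and the
# raw-score normalisation bounds. N is scored at the uniform background
# frequency 1/4 so composition invariants of shuffled corpora stay exact.
pwm_scan_weights <- function(mat) {
  info <- rowSums(ifelse(mat > 0, mat * log(4 * mat), 0))
  w <- t(mat * info)                     # 4 x L
  w <- rbind(w, N = info * 0.25)         # 5 x L
  list(w = w,
       minsum = sum(info * apply(mat, 1, min)),
       maxsum = sum(info * apply(mat, 1, max)))
}

# Solve the off-consensus mass e such that a column (1-e, e/3, e/3, e/3)
# has information content ic_bits (0 < ic_bits <= 2).
column_mass_for_ic <- function(ic_bits) {
  if (ic_bits >= 2) return(0)
  f <- function(e) {
    (1 - e) * log2(4 * (1 - e)) + ifelse(e > 0, e * log2(4 * e / 3), 0) -
      ic_bits
  }
  stats::uniroot(f, c(1e-9, 0.7499), tol = 1e-10)$root
}

#' Generate a synthetic PWM library
#'
#' Builds `n` distinct positional frequency matrices with lengths drawn
#' uniformly from `length_range` and a mean per-column information content
#' within 20% of `ic_target` bits. Each column has one dominant letter with
#' the remaining mass spread evenly; per-column targets are jittered around
#' `ic_target` so the matrices are not all equally sharp. Deterministic for
#' a given seed.
#'
#' @param n number of matrices (>= 2).
#' @param length_range integer vector `c(min, max)` of motif lengths (>= 6).
#' @param ic_target mean information content per column, bits (0 < x <= 2).
#' @param seed integer seed.
#' @return list of [pwm()] objects named by id (`PWM001`, ...).
#' @export
generate_pwm_library <- function(n, length_range = c(8L, 12L),
                                 ic_target = 1.95, seed = 1L) {
  if (n < 2) stop("generate_pwm_library: n must be >= 2")
  if (min(length_range) < 6) stop("generate_pwm_library: lengths must be >= 6")
  if (ic_target <= 0 || ic_target > 2) {
    stop("generate_pwm_library: ic_target must lie in (0, 2] bits")
  }
  with_seed(derive_seed(seed, "pwm_library"), {
    lens <- seq(length_range[1], length_range[2])
    lapply(seq_len(n), function(i) {
      L <- if (length(lens) == 1) lens else sample(lens, 1L)
      jitter <- if (ic_target >= 2) rep(2, L) else {
        pmin(stats::runif(L, 0.95 * ic_target, 1.05 * ic_target), 2)
      }
      dom <- sample.int(4L, L, replace = TRUE)
      mat <- t(vapply(seq_len(L), function(j) {
        e <- column_mass_for_ic(jitter[j])
        col <- rep(e / 3, 4)
        col[dom[j]] <- 1 - e
        col
      }, numeric(4)))
      pwm(sprintf("PWM%03d", i), mat)
    }) -> lib
    names(lib) <- vapply(lib, `[[`, "", "id")
    lib
  })
}

#' Write a PWM library as JASPAR-style PFM text
#'
#' One record per matrix: a `>id name` header followed by four rows
#' `A [ ... ]` ... `T [ ... ]` of per-position frequencies.
#'
#' @param lib list of [pwm()] objects.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_jaspar_pfm <- function(lib, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (p in lib) {
    writeLines(sprintf(">%s %s", p$id, p$name), con)
    for (b in 1:4) {
      writeLines(sprintf("%s [ %s ]", DNA_LETTERS[b],
                         paste(formatC(p$mat[, b], digits = 6, format = "f"),
                               collapse = " ")), con)
    }
  }
  invisible(path)
}

#' Read a JASPAR PFM file
#'
#' Accepts counts or frequencies (rows are normalised); both the bracketed
#' (`A [ 1 2 3 ]`) and bare (`1 2 3`) row styles are understood.
#'
#' @param path PFM text file.
#' @return named list of [pwm()] objects.
#' @export
read_jaspar_pfm <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  starts <- grep("^>", lines)
  if (length(starts) == 0) stop("read_jaspar_pfm: no '>' records in ", path)
  ends <- c(starts[-1] - 1L, length(lines))
  lib <- lapply(seq_along(starts), function(k) {
    hdr <- sub("^>", "", lines[starts[k]])
    parts <- strsplit(trimws(hdr), "\\s+")[[1]]
    id <- parts[1]
    name <- if (length(parts) > 1) paste(parts[-1], collapse = " ") else id
    rows <- lines[(starts[k] + 1L):ends[k]]
    if (length(rows) < 4) stop("read_jaspar_pfm: record ", id, " truncated")
    num <- lapply(rows[1:4], function(r) {
      r <- sub("^\\s*[ACGT]\\s*", "", r)
      r <- gsub("\\[|\\]", " ", r)
      as.numeric(strsplit(trimws(r), "\\s+")[[1]])
    })
    if (length(unique(lengths(num))) != 1) {
      stop("read_jaspar_pfm: ragged rows in record ", id)
    }
    pwm(id, matrix(unlist(num), ncol = 4), name = name)
  })
  names(lib) <- vapply(lib, `[[`, "", "id")
  lib
}

#' Read a TRANSFAC-flat matrix file
#'
#' Minimal reader for the flat dialect: records delimited by `//`, with
#' `ID`/`NA` tags, a `P0` column header and numbered per-position count rows
#' (`01  3 5 2 1  R`).
#'
#' @param path TRANSFAC-flat text file.
#' @return named list of [pwm()] objects.
#' @export
read_transfac <- function(path) {
  lines <- readLines(path)
  recs <- split(lines, cumsum(grepl("^//", lines)))
  lib <- list()
  for (rec in recs) {
    idl <- grep("^ID\\s+", rec, value = TRUE)
    if (length(idl) == 0) next
    id <- strsplit(trimws(sub("^ID\\s+", "", idl[1])), "\\s+")[[1]][1]
    nal <- grep("^NA\\s+", rec, value = TRUE)
    name <- if (length(nal)) trimws(sub("^NA\\s+", "", nal[1])) else id
    p0 <- grep("^P0", rec)
    if (length(p0) == 0) stop("read_transfac: record ", id, " lacks P0 header")
    order4 <- strsplit(trimws(sub("^P0\\s*", "", rec[p0[1]])), "\\s+")[[1]][1:4]
    rows <- grep("^\\d\\d?\\s", rec, value = TRUE)
    vals <- t(vapply(rows, function(r) {
      as.numeric(strsplit(trimws(r), "\\s+")[[1]][2:5])
    }, numeric(4)))
    colnames(vals) <- toupper(order4)
    lib[[id]] <- pwm(id, vals[, DNA_LETTERS, drop = FALSE], name = name)
  }
  if (length(lib) == 0) stop("read_transfac: no matrix records in ", path)
  lib
}
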