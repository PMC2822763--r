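#' Match-style matrix similarity score of one window
#'
#' score = (sum_i I_i f(i, b_i) - min) / (max - min), where I_i is the
#' information vector of the PWM and min/max run over the worst/best letter
#' per position. The score lies in [0, 1]; the consensus scores 1 and the
#' anti-consensus 0. `N` is scored at the uniform background frequency 1/4.
#'
#' @param p a [pwm()] object.
#' @param window string of length `nrow(p$mat)` over ACGTN.
#' @return similarity score in [0, 1].
#' @export
score_window <- function(p, window) {
  L <- nrow(p$mat)
  if (nchar(window) != L) {
    stop("score_window: window length ", nchar(window), " != PWM length ", L)
  }
  codes <- match(strsplit(toupper(window), "")[[1]],
                 c(DNA_LETTERS, "N"))
  if (anyNA(codes)) stop("score_window: window must be over ACGTN")
  sw <- pwm_scan_weights(p$mat)
  raw <- sum(sw$w[cbind(codes, seq_len(L))])
  span <- sw$maxsum - sw$minsum
  if (span <= 0) return(0)
  (raw - sw$minsum) / span
}

# Vectorised scores for an n x L integer code matrix (1..4).
score_code_matrix <- function(codes, sw) {
  L <- ncol(codes)
  raw <- rowSums(vapply(seq_len(L), function(j) sw$w[codes[, j], j],
                        numeric(nrow(codes))))
  span <- sw$maxsum - sw$minsum
  (raw - sw$minsum) / max(span, .Machine$double.eps)
}

#' Calibrate a PWM detection threshold
#'
#' Grid search over thresholds 0, 0.01, ..., 1 for the cutoff minimising the
#' sum of the false-positive rate on background-composition windows and the
#' false-negative rate on windows sampled from the PWM's own columns
#' (the "minimise false positives plus false negatives" profile). Ties are
#' broken toward the higher threshold.
#'
#' @param p a [pwm()] object.
#' @param background_composition length-4 probability vector (A,C,G,T).
#' @param n_samples positive and negative sample count (>= 200).
#' @param seed integer seed; calibration is deterministic per seed.
#' @return threshold in [0, 1], with attribute `fp_fn` (the minimised sum)
#'   and logical attribute `degenerate` (no separation found).
#' @export
calibrate_threshold <- function(p, background_composition = rep(0.25, 4),
                                n_samples = 1000L, seed = 1L) {
  if (n_samples < 200) stop("calibrate_threshold: n_samples must be >= 200")
  info <- pwm_information(p)
  if (sum(info) < 1e-9) {
    stop("calibrate_threshold: PWM ", p$id, " carries no information")
  }
  bg <- background_composition / sum(background_composition)
  L <- nrow(p$mat)
  sw <- pwm_scan_weights(p$mat)
  with_seed(derive_seed(seed, "calibrate", p$id), {
    pos <- vapply(seq_len(L), function(j) {
      sample.int(4L, n_samples, replace = TRUE, prob = p$mat[j, ])
    }, integer(n_samples))
    neg <- matrix(sample.int(4L, n_samples * L, replace = TRUE, prob = bg),
                  ncol = L)
    pos_sc <- score_code_matrix(pos, sw)
    neg_sc <- score_code_matrix(neg, sw)
    grid <- seq(0, 1, by = 0.01)
    fn <- vapply(grid, function(t) mean(pos_sc < t), numeric(1))
    fp <- vapply(grid, function(t) mean(neg_sc >= t), numeric(1))
    total <- fn + fp
    best <- max(grid[total == min(total)])
    degenerate <- min(total) >= 0.95
    if (degenerate) {
      warning("calibrate_threshold: PWM ", p$id,
              " barely separates from background (FP+FN = ",
              round(min(total), 3), ")")
    }
    structure(best, fp_fn = min(total), degenerate = degenerate)
  })
}

#' Calibrate every PWM of a library
#'
#' @param lib list of [pwm()] objects.
#' @inheritParams calibrate_threshold
#' @return the library with `threshold` fields filled in.
#' @export
calibrate_library <- function(lib, background_composition = rep(0.25, 4),
                              n_samples = 1000L, seed = 1L) {
  lapply(lib, function(p) {
    p$threshold <- as.numeric(calibrate_threshold(
      p, background_composition, n_samples, seed))
    p
  })
}

#' Scan promoters with a calibrated PWM library
#'
#' Reports every window on either strand whose matrix similarity score
#' reaches the PWM's calibrated threshold. Reverse-strand hits are reported
#' in forward (0-based, half-open) coordinates. Promoters shorter than a
#' motif are skipped for that motif.
#'
#' @param lib list of calibrated [pwm()] objects.
#' @param promoters promoter `data.table` (`gene_id`, `species`, `sequence`).
#' @return `data.table` with `gene_id`, `species`, `pwm`, `start`, `end`,
#'   `strand`, `score`, sorted by gene and start.
#' @export
scan_promoters <- function(lib, promoters) {
  thr <- vapply(lib, `[[`, numeric(1), "threshold")
  if (anyNA(thr)) {
    stop("scan_promoters: uncalibrated PWMs: ",
         paste(names(lib)[is.na(thr)], collapse = ", "))
  }
  if (nrow(promoters) == 0) {
    return(data.table::data.table(gene_id = character(), species = character(),
                                  pwm = character(), start = integer(),
                                  end = integer(), strand = character(),
                                  score = numeric()))
  }
  encoded <- cpp_encode_dna(promoters$sequence)
  res <- lapply(lib, function(p) {
    L <- nrow(p$mat)
    fwd <- pwm_scan_weights(p$mat)
    rev <- pwm_scan_weights(pwm_revcomp_mat(p$mat))
    hf <- cpp_scan_pwm(encoded, fwd$w, fwd$minsum, fwd$maxsum, p$threshold)
    hr <- cpp_scan_pwm(encoded, rev$w, rev$minsum, rev$maxsum, p$threshold)
    data.table::data.table(
      idx = c(hf$seq, hr$seq),
      pwm = p$id,
      start = c(hf$start, hr$start),
      end = c(hf$start, hr$start) + L,
      strand = rep(c("+", "-"), c(length(hf$seq), length(hr$seq))),
      score = c(hf$score, hr$score))
  })
  hits <- data.table::rbindlist(res)
  hits[, `:=`(gene_id = promoters$gene_id[idx],
              species = promoters$species[idx])]
  hits[, idx := NULL]
  data.table::setcolorder(hits, c("gene_id", "species", "pwm", "start",
                                  "end", "strand", "score"))
  data.table::setorder(hits, gene_id, start, pwm, strand)
  hits[]
}
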