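#' Upper-tail binomial enrichment probability
#'
#' Probability of observing as many (or strictly more) successes as `n_obs`
#' in `n_trials` draws with success probability `p_success`. Used to test
#' whether a designated subset of TF pairs (e.g. experimentally proven
#' composite elements) occurs in a predicted pair list more often than in a
#' random draw from the pair universe.
#'
#' Two tail conventions are exposed because published worked examples are
#' consistent only under the strict tail P(X > n), while narrative wording
#' usually implies the inclusive tail P(X >= n). The default is inclusive.
#'
#' @param n_obs observed success count.
#' @param n_trials number of trials.
#' @param p_success background success probability in [0, 1].
#' @param strict_tail if `TRUE` return P(X > n_obs); if `FALSE` (default)
#'   return P(X >= n_obs).
#' @return a single probability in [0, 1].
#' @examples
#' binomial_upper_tail(30, 162, 820 / 23005, strict_tail = TRUE)
#' @export
binomial_upper_tail <- function(n_obs, n_trials, p_success,
                                strict_tail = FALSE) {
  stopifnot(length(n_obs) == 1, length(n_trials) == 1, length(p_success) == 1)
  if (is.na(n_obs) || is.na(n_trials) || is.na(p_success) ||
      n_obs < 0 || n_trials < 0 || n_obs > n_trials ||
      p_success < 0 || p_success > 1) {
    stop("binomial_upper_tail: need 0 <= n_obs <= n_trials and p in [0, 1]")
  }
  q <- if (strict_tail) n_obs else n_obs - 1
  stats::pbinom(q, size = n_trials, prob = p_success, lower.tail = FALSE)
}

#' Hypergeometric overlap probability
#'
#' P(overlap >= c) for two gene sets of sizes `S1` and `S2` drawn without
#' replacement from a universe of `N` genes. This is the test used for
#' overlap of orthologous target genes between species and for overlap of
#' tissue TF pair sets between tissues.
#'
#' @param c observed overlap count.
#' @param N universe size.
#' @param S1,S2 sizes of the two sets.
#' @return a single probability in [0, 1].
#' @examples
#' hypergeom_overlap_pvalue(5, 10, 5, 5) # 1/252
#' @export
hypergeom_overlap_pvalue <- function(c, N, S1, S2) {
  stopifnot(length(c) == 1, length(N) == 1)
  if (any(c(c, N, S1, S2) < 0) || S1 > N || S2 > N) {
    stop("hypergeom_overlap_pvalue: need S1, S2 <= N and non-negative counts")
  }
  if (c > min(S1, S2)) {
    stop("hypergeom_overlap_pvalue: c exceeds min(S1, S2)")
  }
  stats::phyper(c - 1, m = S1, n = N - S1, k = S2, lower.tail = FALSE)
}

#' One-sided Fisher enrichment probability
#'
#' Enrichment p-value for `k_in_term` of `n_targets` target genes falling in
#' an annotation term of size `K_term_total` out of `N_genome` genes. This is
#' the same tail as [hypergeom_overlap_pvalue()] with the target set and the
#' term as the two sets.
#'
#' @param k_in_term targets annotated with the term.
#' @param n_targets size of the target gene set.
#' @param K_term_total genes with the term in the genome.
#' @param N_genome genome (universe) size.
#' @return a single probability in [0, 1].
#' @export
fisher_enrichment <- function(k_in_term, n_targets, K_term_total, N_genome) {
  if (k_in_term > min(n_targets, K_term_total) ||
      n_targets > N_genome || K_term_total > N_genome) {
    stop("fisher_enrichment: inconsistent margins")
  }
  hypergeom_overlap_pvalue(k_in_term, N_genome, n_targets, K_term_total)
}

#' Pearson correlation of two enrichment profiles
#'
#' Thin wrapper around [stats::cor()] that turns constant input into an
#' explicit error, so that untestable TF pairs are reported rather than
#' silently producing `NA`.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return correlation coefficient in [-1, 1].
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3) {
    stop("pearson_r: need equal lengths >= 3")
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("pearson_r: constant vector (degenerate profile)")
  }
  stats::cor(x, y)
}

# All permutations of 1..n as a matrix (n! rows); used for the exhaustive
# branch of the permutation test (n <= 6, at most 720 rows).
all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, nrow(sub) * n, n)
  row <- 1L
  for (k in seq_len(n)) {
    ins <- cbind(sub[, seq_len(k - 1L), drop = FALSE], n,
                 sub[, seq(k, n - 1L)[seq_len(n - k)], drop = FALSE])
    out[row:(row + nrow(sub) - 1L), ] <- ins
    row <- row + nrow(sub)
  }
  out
}

#' One-sided permutation p-value for positive correlation
#'
#' Tests whether the observed Pearson correlation between two enrichment
#' profiles exceeds what random matching of the profile entries produces:
#' p = (1 + #\{r_perm >= r_obs\}) / (n_perm + 1). One-sided for positive r,
#' since function conservation predicts positive coupling of the site and
#' ortholog-overlap enrichment profiles. For profiles of length <= 6 all
#' permutations are enumerated instead of sampled.
#'
#' @param x,y numeric profiles (see [pearson_r()]).
#' @param n_perm number of sampled permutations (ignored on the exhaustive
#'   branch). Values below 100 trigger a warning.
#' @param seed integer seed; identical inputs and seed give identical p.
#' @param exact force (`TRUE`) or forbid (`FALSE`) exhaustive enumeration;
#'   `NULL` (default) enumerates iff `length(x) <= 6`.
#' @return list with `r` (observed correlation) and `p`.
#' @export
permutation_corr_pvalue <- function(x, y, n_perm = 10000L, seed = 1L,
                                    exact = NULL) {
  r_obs <- pearson_r(x, y)
  n <- length(x)
  if (is.null(exact)) exact <- n <= 6
  if (exact) {
    perms <- all_permutations(n)
    xs <- x - mean(x); ys <- y - mean(y)
    denom <- sqrt(sum(xs^2) * sum(ys^2))
    r_all <- apply(perms, 1L, function(ix) sum(xs * ys[ix]) / denom)
    p <- sum(r_all >= r_obs - 1e-9) / nrow(perms)
  } else {
    if (n_perm < 100) {
      warning("permutation_corr_pvalue: n_perm < 100 gives a coarse p-value")
    }
    hits <- cpp_perm_corr_count(as.numeric(x), as.numeric(y),
                                as.integer(n_perm), r_obs,
                                as.integer(seed %% 2147483647L))
    p <- (1 + hits) / (n_perm + 1)
  }
  list(r = r_obs, p = p)
}

#' Benjamini-Hochberg q-values
#'
#' Step-up adjusted values via [stats::p.adjust()], preserving input order
#' and names. Within a batch, q-values are monotone in p-values.
#'
#' @param pvals vector of probabilities in [0, 1].
#' @return adjusted q-values, same length and order as `pvals`.
#' @export
bh_qvalues <- function(pvals) {
  if (length(pvals) == 0) return(numeric(0))
  if (any(pvals < 0 | pvals > 1, na.rm = TRUE)) {
    stop("bh_qvalues: p-values must lie in [0, 1]")
  }
  stats::p.adjust(pvals, method = "BH")
}
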