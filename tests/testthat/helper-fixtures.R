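# Shared fixtures, built in code at test time.

# A point-mass PWM for the given consensus string.
consensus_pwm <- function(id, consensus) {
  codes <- match(strsplit(consensus, "")[[1]], c("A", "C", "G", "T"))
  mat <- matrix(0, length(codes), 4)
  mat[cbind(seq_along(codes), codes)] <- 1
  pwm(id, mat)
}

# A sharp but non-degenerate PWM: dominant letter with mass 1 - e.
sharp_pwm <- function(id, consensus, e = 0.06) {
  codes <- match(strsplit(consensus, "")[[1]], c("A", "C", "G", "T"))
  mat <- matrix(e / 3, length(codes), 4)
  mat[cbind(seq_along(codes), codes)] <- 1 - e
  pwm(id, mat)
}

# Random i.i.d. promoter table.
random_promoters <- function(n, len, species = "human", seed = 1,
                             prefix = "G") {
  withr::with_seed(seed, {
    seqs <- vapply(seq_len(n), function(i) {
      paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
            collapse = "")
    }, character(1))
  })
  data.table::data.table(gene_id = sprintf("%s%03d", prefix, seq_len(n)),
                         species = species, sequence = seqs)
}

# A small, fast study for structural tests: 12 PWMs, 2 tissues x 60 genes,
# 80 housekeeping genes, 2 planted pairs and nothing else.
small_study_config <- function(seed = 1, gene_fraction = 0.4,
                               conserve_fraction = 0.9) {
  study_config(
    n_pwms = 12L, pwm_length_range = c(12L, 16L), ic_target = 1.95,
    n_tissues = 2L, genes_per_tissue = 60L, n_housekeeping = 80L,
    planted_pairs = list(
      plant_spec("PWM001", "PWM002", gap_max = 60L,
                 gene_fraction = gene_fraction,
                 conserve_fraction = conserve_fraction, tissues = "T1"),
      plant_spec("PWM003", "PWM004", gap_max = 60L,
                 gene_fraction = gene_fraction,
                 conserve_fraction = conserve_fraction, tissues = "T2")),
    seed = seed)
}

# Exhaustive hypergeometric upper tail by direct enumeration over all draws
# of S2 from N (valid for small N).
enum_hypergeom_tail <- function(c, N, S1, S2) {
  ks <- max(0, S1 + S2 - N):min(S1, S2)
  probs <- choose(S1, ks) * choose(N - S1, S2 - ks) / choose(N, S2)
  sum(probs[ks >= c])
}

# Exhaustive binomial tail by pmf summation.
enum_binom_tail <- function(n_obs, n_trials, p, strict) {
  ks <- 0:n_trials
  pmf <- choose(n_trials, ks) * p^ks * (1 - p)^(n_trials - ks)
  if (strict) sum(pmf[ks > n_obs]) else sum(pmf[ks >= n_obs])
}
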