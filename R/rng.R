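# Deterministic seed substreams. Every stochastic stage derives its seed
# from (global seed, string labels) so per-entity results are independent of
# iteration order. 32-bit FNV-1a folded into [1, 2^31 - 2].
derive_seed <- function(seed, ...) {
  labels <- paste(c(format(seed), unlist(list(...))), collapse = "\x1f")
  h <- 2166136261
  for (b in utf8ToInt(labels)) {
    # XOR with the low byte (codepoints are folded to 8 bits), in doubles
    # because the running hash exceeds R's integer range
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), as.integer(b %% 256))
    # 32-bit multiply by the FNV prime 16777619, done in two 16-bit halves
    lo <- h %% 65536; hi <- h %/% 65536
    h <- (lo * 16777619 + (hi * 16777619 %% 65536) * 65536) %% 4294967296
  }
  as.integer(h %% 2147483645) + 1L
}

# Evaluate expr with a locally-set RNG seed, restoring the caller's state.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
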