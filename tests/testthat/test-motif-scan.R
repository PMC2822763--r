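test_that("matrix similarity score hits its closed-form anchors", {
  p <- consensus_pwm("P1", "ACGTACGT")
  expect_equal(score_window(p, "ACGTACGT"), 1.0)
  # any non-consensus letter on a point-mass PWM is a worst letter
  expect_equal(score_window(p, "CCGTACGT") < 1, TRUE)

  # 4-position mixed matrix against "ACGT": direct arithmetic oracle
  mat <- rbind(c(0.7, 0.1, 0.1, 0.1),
               c(0.1, 0.6, 0.2, 0.1),
               c(0.25, 0.25, 0.25, 0.25),
               c(0.05, 0.05, 0.1, 0.8))
  p4 <- pwm("P4", rbind(mat, c(0.97, 0.01, 0.01, 0.01)))
  m <- p4$mat
  info <- rowSums(ifelse(m > 0, m * log(4 * m), 0))
  window <- "ACGTA"
  got <- sum(info * m[cbind(1:5, c(1, 2, 3, 4, 1))])
  lo <- sum(info * apply(m, 1, min)); hi <- sum(info * apply(m, 1, max))
  expect_equal(score_window(p4, window), (got - lo) / (hi - lo))

  # anti-consensus scores 0
  worst <- paste(c("A", "C", "G", "T")[apply(p4$mat, 1, which.min)],
                 collapse = "")
  expect_equal(score_window(p4, worst), 0.0)
  expect_error(score_window(p4, "ACGT"), "length")
})

test_that("improving a window letter toward the consensus never lowers the
           score", {
  withr::with_seed(21, {
    for (rep in 1:20) {
      lib <- generate_pwm_library(2, c(8, 10), ic_target = 1.3,
                                  seed = rep)
      p <- lib[[1]]
      L <- nrow(p$mat)
      letters4 <- c("A", "C", "G", "T")
      w <- sample(letters4, L, replace = TRUE)
      j <- sample(L, 1)
      s0 <- score_window(p, paste(w, collapse = ""))
      better <- letters4[which.max(p$mat[j, ])]
      if (p$mat[j, better] >= p$mat[j, w[j]]) {
        w2 <- w; w2[j] <- better
        expect_gte(score_window(p, paste(w2, collapse = "")), s0 - 1e-12)
      }
    }
  })
})

test_that("threshold calibration separates point-mass PWMs perfectly, flags
           degenerate matrices and matches the grid-search oracle", {
  pm <- consensus_pwm("PM", "ACGTACGTAC")
  thr <- calibrate_threshold(pm, seed = 3)
  expect_equal(as.numeric(thr), 1.0)
  expect_equal(attr(thr, "fp_fn"), 0)

  flat <- pwm("FLAT", matrix(0.25, 8, 4))
  expect_error(calibrate_threshold(flat), "information")
  near_flat <- pwm("NF", matrix(c(0.2505, 0.2495, 0.25, 0.25), 8, 4,
                                byrow = TRUE))
  expect_warning(thr2 <- calibrate_threshold(near_flat, seed = 5),
                 "barely separates")
  expect_true(attr(thr2, "degenerate"))

  # brute-force oracle: recompute FP+FN over all 101 cutoffs from the same
  # seeded samples and compare the argmin (ties toward the higher cutoff)
  lib <- generate_pwm_library(2, c(8, 8), ic_target = 1.2, seed = 7)
  p <- lib[[1]]
  thr3 <- calibrate_threshold(p, n_samples = 500, seed = 7)
  sw <- concordtf:::pwm_scan_weights(p$mat)
  concordtf:::with_seed(concordtf:::derive_seed(7, "calibrate", p$id), {
    pos <- vapply(1:8, function(j) {
      sample.int(4L, 500, replace = TRUE, prob = p$mat[j, ])
    }, integer(500))
    neg <- matrix(sample.int(4L, 500 * 8, replace = TRUE,
                             prob = rep(0.25, 4)), ncol = 8)
  })
  pos_sc <- concordtf:::score_code_matrix(pos, sw)
  neg_sc <- concordtf:::score_code_matrix(neg, sw)
  grid <- seq(0, 1, by = 0.01)
  tot <- vapply(grid, function(t) mean(pos_sc < t) + mean(neg_sc >= t),
                numeric(1))
  expect_equal(as.numeric(thr3), max(grid[tot == min(tot)]))
  expect_error(calibrate_threshold(p, n_samples = 100), "n_samples")
})

test_that("scanning finds planted sites on both strands in forward
           coordinates", {
  p <- sharp_pwm("P1", "ACGTTGCAAC", e = 0.03)
  p$threshold <- 0.97
  bgseq <- paste(rep("A", 300), collapse = "")
  fwd <- paste0(substr(bgseq, 1, 100), "ACGTTGCAAC",
                substr(bgseq, 1, 190))
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString("ACGTTGCAAC")))
  rev <- paste0(substr(bgseq, 1, 100), rc, substr(bgseq, 1, 190))
  pr <- data.table::data.table(gene_id = c("gf", "gr"), species = "human",
                               sequence = c(fwd, rev))
  hits <- scan_promoters(list(P1 = p), pr)
  hf <- hits[gene_id == "gf"]
  expect_equal(nrow(hf), 1)
  expect_equal(hf$start, 100)
  expect_equal(hf$end, 110)
  expect_equal(hf$strand, "+")
  hr <- hits[gene_id == "gr"]
  expect_equal(nrow(hr), 1)
  expect_equal(hr$start, 100)
  expect_equal(hr$strand, "-")
  # a promoter shorter than the motif is skipped, not an error
  short <- data.table::data.table(gene_id = "gs", species = "human",
                                  sequence = "ACGT")
  expect_equal(nrow(scan_promoters(list(P1 = p), short)), 0)
  p_na <- sharp_pwm("P2", "ACGTTGCAAC")
  expect_error(scan_promoters(list(P2 = p_na), pr), "uncalibrated")
})

test_that("scanning is strand-symmetric on random sequence/PWM draws", {
  # scan(seq, pwm) must mirror scan(revcomp(seq), revcomp(pwm))
  withr::with_seed(31, {
    for (i in 1:100) {
      lib <- generate_pwm_library(2, c(6, 9), ic_target = 1.0, seed = i)
      p <- lib[[1]]
      p$threshold <- 0.7
      L <- nrow(p$mat)
      len <- sample(40:80, 1)
      seq <- paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
                   collapse = "")
      pr <- data.table::data.table(gene_id = "g", species = "s",
                                   sequence = seq)
      rc_seq <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(seq)))
      pr_rc <- data.table::data.table(gene_id = "g", species = "s",
                                      sequence = rc_seq)
      p_rc <- p
      p_rc$mat <- concordtf:::pwm_revcomp_mat(p$mat)
      h1 <- scan_promoters(list(P = p), pr)
      h2 <- scan_promoters(list(P = p_rc), pr_rc)
      # mirrored coordinates: start' = len - end, strands flipped
      expect_equal(nrow(h1), nrow(h2))
      if (nrow(h1) > 0) {
        sig1 <- paste(h1$start, h1$strand, signif(h1$score, 9))
        # revcomp of both sequence and matrix preserves the strand label:
        # rc(P) scoring rc(w) equals P scoring w on the same strand
        sig2 <- paste(len - h2$end, h2$strand, signif(h2$score, 9))
        expect_setequal(sig1, sig2)
      }
    }
  })
})

test_that("the scanner agrees with Biostrings matchPWM as an independent
           oracle", {
  withr::with_seed(55, {
    for (i in 1:5) {
      lib <- generate_pwm_library(2, c(8, 11), ic_target = 1.4,
                                  seed = 100 + i)
      p <- lib[[1]]
      p$threshold <- 0.8
      seq <- paste(sample(c("A", "C", "G", "T"), 2000, replace = TRUE),
                   collapse = "")
      pr <- data.table::data.table(gene_id = "g", species = "s",
                                   sequence = seq)
      ours <- scan_promoters(list(P = p), pr)[strand == "+"]
      # matchPWM with the information-weighted matrix and the equivalent
      # absolute raw-score cutoff
      sw <- concordtf:::pwm_scan_weights(p$mat)
      cutoff <- sw$minsum + p$threshold * (sw$maxsum - sw$minsum)
      hits <- Biostrings::matchPWM(sw$w[1:4, ], seq, min.score = cutoff)
      expect_setequal(ours$start, BiocGenerics::start(hits) - 1L)
    }
  })
})
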