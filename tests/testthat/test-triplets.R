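occ_row <- function(gene, p1, s1, e1, st1, p2, s2, e2, st2, pair = NULL) {
  data.table::data.table(
    gene_id = gene, pair = if (is.null(pair)) pair_key(p1, p2) else pair,
    pwm1 = p1, start1 = as.integer(s1), end1 = as.integer(e1), strand1 = st1,
    pwm2 = p2, start2 = as.integer(s2), end2 = as.integer(e2), strand2 = st2)
}

test_that("pair occurrences keep site-level detail within the gap window", {
  hits <- data.table::data.table(
    gene_id = "g1", species = "human",
    pwm = c("A", "B", "C"),
    start = c(10L, 40L, 300L), end = c(18L, 48L, 308L),
    strand = c("+", "-", "+"), score = 1)
  occ <- pair_occurrences(hits, c("A:B", "A:C"), max_gap = 200)
  expect_equal(nrow(occ), 1) # A-C gap is 282, outside the window
  expect_equal(occ$pair, "A:B")
  expect_equal(occ$start1, 10)
  expect_equal(occ$start2, 40)
  expect_equal(occ$strand2, "-")
})

test_that("triplets compose only through a literally shared site", {
  # shared B site at [40, 48): compose A,B,C
  occs <- rbind(
    occ_row("g1", "A", 10, 18, "+", "B", 40, 48, "-"),
    occ_row("g1", "B", 40, 48, "-", "C", 80, 88, "+"))
  tr <- compose_triplets(occs)
  expect_equal(nrow(tr), 1)
  expect_equal(tr$triplet, "A:B:C")
  expect_equal(tr$order, "A,B,C")
  expect_equal(tr$strands, "+-+")

  # same pair content but different B intervals: no triplet
  occs2 <- rbind(
    occ_row("g1", "A", 10, 18, "+", "B", 40, 48, "-"),
    occ_row("g1", "B", 60, 68, "-", "C", 80, 88, "+"))
  expect_equal(nrow(compose_triplets(occs2)), 0)

  # homotypic chain (A,A) + (A,C) sharing the middle A site
  occs3 <- rbind(
    occ_row("g1", "A", 10, 18, "+", "A", 40, 48, "+"),
    occ_row("g1", "A", 40, 48, "+", "C", 80, 88, "+"))
  tr3 <- compose_triplets(occs3)
  expect_equal(tr3$triplet, "A:A:C")

  # duplicates (same three intervals twice) are emitted once
  occs4 <- rbind(occs, occs)
  expect_equal(nrow(compose_triplets(occs4)), 1)
})

test_that("conservation requires the same key, order and orientation", {
  map <- data.table::data.table(human = "g1", mouse = "m1")
  th <- compose_triplets(rbind(
    occ_row("g1", "A", 10, 18, "+", "B", 40, 48, "-"),
    occ_row("g1", "B", 40, 48, "-", "C", 80, 88, "+")))
  tm_same <- compose_triplets(rbind(
    occ_row("m1", "A", 12, 20, "+", "B", 45, 53, "-"),
    occ_row("m1", "B", 45, 53, "-", "C", 90, 98, "+")))
  expect_equal(nrow(conserved_occurrences(th, tm_same, map)), 1)

  # reversed order on the mouse promoter: not conserved
  tm_rev <- compose_triplets(rbind(
    occ_row("m1", "C", 10, 18, "+", "B", 40, 48, "-"),
    occ_row("m1", "B", 40, 48, "-", "A", 80, 88, "+")))
  expect_equal(tm_rev$triplet, "A:B:C")
  expect_equal(nrow(conserved_occurrences(th, tm_rev, map)), 0)

  # strand flip on one site: not conserved
  tm_flip <- compose_triplets(rbind(
    occ_row("m1", "A", 12, 20, "+", "B", 45, 53, "+"),
    occ_row("m1", "B", 45, 53, "+", "C", 90, 98, "+")))
  expect_equal(nrow(conserved_occurrences(th, tm_flip, map)), 0)
})

test_that("triplet calls enforce the support floor and hypergeometric
           significance", {
  map <- data.table::data.table(human = sprintf("g%d", 1:250),
                                mouse = sprintf("m%d", 1:250))
  mk <- function(genes, species_prefix) {
    data.table::rbindlist(lapply(genes, function(g) {
      compose_triplets(rbind(
        occ_row(g, "A", 10, 18, "+", "B", 40, 48, "+"),
        occ_row(g, "B", 40, 48, "+", "C", 80, 88, "+")))
    }))
  }
  th <- mk(sprintf("g%d", 1:12))
  tm <- mk(sprintf("m%d", 1:12))
  cons <- conserved_occurrences(th, tm, map)
  calls <- call_triplets(cons, th, tm, 250, map)
  expect_equal(calls$support, 12)
  expect_equal(calls$S1, 12)
  expect_equal(calls$S2, 12)
  # log-gamma cross-check of the hypergeometric value
  expect_equal(calls$p, enum_hypergeom_tail(12, 250, 12, 12),
               tolerance = 1e-10)
  expect_true(calls$called)

  # support 9 never calls, however significant
  th9 <- mk(sprintf("g%d", 1:9)); tm9 <- mk(sprintf("m%d", 1:9))
  cons9 <- conserved_occurrences(th9, tm9, map)
  calls9 <- call_triplets(cons9, th9, tm9, 250, map)
  expect_lt(calls9$p, 1e-6)
  expect_false(calls9$called)
})

test_that("conserved occurrences are a subset of the per-species
           candidates and keys are order-invariant", {
  study <- generate_study(small_study_config(seed = 12))
  lib <- calibrate_library(study$pwm_lib, seed = 12)
  hits <- lapply(study$promoters, function(p) scan_promoters(lib, p))
  pairs <- enumerate_pair_universe(names(lib)[1:4])
  occ_h <- pair_occurrences(hits$human, pairs)
  occ_m <- pair_occurrences(hits$mouse, pairs)
  th <- compose_triplets(occ_h)
  tm <- compose_triplets(occ_m)
  cons <- conserved_occurrences(th, tm, study$ortholog_map)
  if (nrow(cons)) {
    expect_true(all(paste(cons$gene_id, cons$order, cons$strands) %in%
                      paste(th$gene_id, th$order, th$strands)))
  }
  # permuting the occurrence rows changes nothing
  th_perm <- compose_triplets(occ_h[rev(seq_len(nrow(occ_h)))])
  expect_setequal(paste(th$gene_id, th$triplet, th$order, th$strands),
                  paste(th_perm$gene_id, th_perm$triplet, th_perm$order,
                        th_perm$strands))
})
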