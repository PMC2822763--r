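toy_hits <- function(...) {
  rows <- list(...)
  data.table::data.table(
    gene_id = vapply(rows, `[[`, "", 1),
    species = "human",
    pwm = vapply(rows, `[[`, "", 2),
    start = as.integer(vapply(rows, `[[`, "", 3)),
    end = as.integer(vapply(rows, `[[`, "", 4)),
    strand = "+", score = 1)
}

test_that("co-occurrence respects the edge-to-edge gap rule", {
  # gap 15: counted at every cutoff of the grid
  h <- toy_hits(c("g1", "A", "10", "20"), c("g1", "B", "35", "45"))
  expect_identical(cooccurring_genes(h, "A:B", 20), "g1")
  expect_identical(cooccurring_genes(h, "A:B", 200), "g1")
  # gap 55: counted for cutoffs >= 60 only
  h2 <- toy_hits(c("g1", "A", "10", "20"), c("g1", "B", "75", "85"))
  expect_length(cooccurring_genes(h2, "A:B", 40), 0)
  expect_identical(cooccurring_genes(h2, "A:B", 60), "g1")
  # overlapping sites (negative gap) never count
  h3 <- toy_hits(c("g1", "A", "10", "20"), c("g1", "B", "15", "25"))
  expect_length(cooccurring_genes(h3, "A:B", 200), 0)
  # a gene counts once regardless of hit multiplicity, either order
  h4 <- toy_hits(c("g1", "B", "10", "20"), c("g1", "A", "30", "40"),
                 c("g1", "B", "60", "70"))
  expect_identical(cooccurring_genes(h4, "A:B", 200), "g1")
  # homotypic pairs need two distinct hits
  h5 <- toy_hits(c("g1", "A", "10", "20"))
  expect_length(cooccurring_genes(h5, "A:A", 200), 0)
  h6 <- toy_hits(c("g1", "A", "10", "20"), c("g1", "A", "25", "35"))
  expect_identical(cooccurring_genes(h6, "A:A", 200), "g1")
})

test_that("minimal gaps produce monotone cutoff counts", {
  gaps <- pair_gene_gaps(toy_hits(
    c("g1", "A", "0", "10"), c("g1", "B", "30", "40"),
    c("g1", "B", "150", "160"), c("g2", "A", "5", "15"),
    c("g2", "B", "100", "110")))
  expect_equal(gaps[gene_id == "g1" & pair == "A:B", min_gap], 20)
  expect_equal(gaps[gene_id == "g2" & pair == "A:B", min_gap], 85)
  cm <- concordtf:::cutoff_count_matrix(gaps, distance_grid())
  expect_equal(unname(cm["A:B", ]), c(1, 1, 1, 1, 2, 2, 2, 2, 2, 2))
  expect_true(all(apply(cm, 1, function(x) all(diff(x) >= 0))))
})

test_that("site enrichment ratios floor the background at one and the
           candidate rule is a strict boundary", {
  real <- matrix(12, 1, 10, dimnames = list("A:B", NULL))
  bg <- matrix(6, 1, 10, dimnames = list("A:B", NULL))
  expect_equal(unname(site_enrichment_profile(real, bg)["A:B", ]),
               rep(2, 10))
  bg0 <- matrix(0, 1, 10, dimnames = list("A:B", NULL))
  real3 <- matrix(3, 1, 10, dimnames = list("A:B", NULL))
  expect_equal(unname(site_enrichment_profile(real3, bg0)["A:B", ]),
               rep(3, 10))

  m <- rbind(six = c(rep(1.1, 6), rep(0.9, 4)),
             five = c(rep(1.1, 5), rep(0.9, 5)),
             flat = rep(1, 10))
  expect_identical(select_candidate_pairs(m), "six")
})

test_that("overlap profiles count orthologous co-occurrence and fractions", {
  grid <- distance_grid()
  gh <- data.table::data.table(gene_id = c("g1", "g2", "g3"), pair = "A:B",
                               min_gap = c(10L, 30L, 10L))
  gm <- data.table::data.table(gene_id = c("g1", "g2"), pair = "A:B",
                               min_gap = c(50L, 10L))
  ov <- concordtf:::overlap_count_matrix(gh, gm, grid, "A:B")
  # g1 overlaps from d60 (max gap 50), g2 from d40
  expect_equal(unname(ov["A:B", ]), c(0, 1, 2, 2, 2, 2, 2, 2, 2, 2))

  counts_h <- concordtf:::cutoff_count_matrix(gh, grid, "A:B")
  counts_m <- concordtf:::cutoff_count_matrix(gm, grid, "A:B")
  prof <- overlap_profile(ov, ov * 0, counts_h, counts_m)
  # fraction = overlap / min(|H|, |M|); at d200: 2 / min(3, 2) = 1
  expect_equal(unname(prof$fraction["A:B", 10]), 1)
  expect_equal(unname(prof$ratio["A:B", 10]), 2) # background floored at 1
})

test_that("conservation calls are untestable on constant profiles and exact
           on identical ones", {
  flat <- rep(1, 10)
  res <- conservation_call(flat, c(1:9, 11))
  expect_equal(res$untestable, "constant profile")
  x <- c(1, 3, 2, 5, 4, 6, 8, 7, 9, 10)
  res2 <- conservation_call(x, x, n_perm = 500, seed = 1)
  expect_equal(res2$r, 1.0)
  expect_lt(res2$p, 0.05)
})

test_that("the full pair stage recovers a planted pair, keeps gene sets
           monotone, and is symmetric under species swap", {
  study <- generate_study(small_study_config(seed = 4))
  comp <- concordtf:::corpus_composition(study$promoters$human)
  lib <- calibrate_library(study$pwm_lib, comp, seed = 4)
  hits_real <- lapply(study$promoters, function(p) scan_promoters(lib, p))
  bg <- lapply(study$promoters, make_background_set, seed = 4)
  hits_bg <- lapply(bg, function(b) {
    h <- scan_promoters(lib, b[, .(gene_id, species, sequence)])
    h[, replicate := 1L]
    h
  })
  genes <- study$gene_lists[tissue == "T1", gene]
  r <- predict_list_pairs(hits_real, hits_bg, genes, study$ortholog_map,
                          names(lib), n_perm = 2000L, seed = 9)
  expect_true("PWM001:PWM002" %in% r$called)

  # monotonicity of gene counts along the grid, every pair, both species
  for (cm in r$profiles$counts[c("human", "mouse")]) {
    expect_true(all(apply(cm, 1, function(x) all(diff(x) >= 0))))
  }

  # swapping the species labels leaves the called set unchanged
  swap_map <- data.table::data.table(human = study$ortholog_map$mouse,
                                     mouse = study$ortholog_map$human)
  genes_m <- study$ortholog_map[human %in% genes, mouse]
  r_swap <- predict_list_pairs(
    list(human = hits_real$mouse, mouse = hits_real$human),
    list(human = hits_bg$mouse, mouse = hits_bg$human),
    genes_m, swap_map, names(lib), n_perm = 2000L, seed = 9)
  expect_setequal(r$called, r_swap$called)
})
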