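test_that("networks are components with two or more pairs; internal TFs
           have degree >= 2", {
  nets <- build_networks(c("P:Q", "Q:R"))
  expect_length(nets, 1)
  expect_setequal(nets[[1]]$nodes, c("P", "Q", "R"))
  expect_identical(nets[[1]]$internal, "Q")

  expect_length(build_networks("P:Q"), 0)
  expect_length(build_networks(c("P:Q", "R:S")), 0)

  # chain A-B-C-D: internal = {B, C}
  chain <- build_networks(c("A:B", "B:C", "C:D"))
  expect_identical(chain[[1]]$internal, c("B", "C"))

  # a self-loop counts +2 toward degree but not connectivity
  loops <- build_networks(c("A:A", "A:B"))
  expect_length(loops, 1)
  expect_identical(loops[[1]]$internal, "A")
  expect_length(build_networks(c("A:A", "B:C")), 0)
})

test_that("tissue-type networks need identical labeled edge sets in at
           least two group tissues", {
  n1 <- build_networks(c("P:Q", "Q:R"), tissue = "t1")
  n2 <- build_networks(c("P:Q", "Q:R"), tissue = "t2")
  n3 <- build_networks(c("P:Q", "Q:S"), tissue = "t3")
  by_tissue <- list(t1 = n1, t2 = n2, t3 = n3)
  tt <- match_tissue_type_networks(by_tissue, c("t1", "t2", "t3"))
  expect_length(tt, 1)
  expect_setequal(tt[[1]]$tissues, c("t1", "t2"))
  # a topology seen in one tissue only is not reported
  expect_length(match_tissue_type_networks(list(t1 = n1, t3 = n3),
                                           c("t1", "t3")), 0)
  # permuting tissue order changes nothing
  tt_rev <- match_tissue_type_networks(by_tissue, c("t3", "t2", "t1"))
  expect_equal(length(tt_rev), length(tt))
  expect_setequal(tt_rev[[1]]$tissues, tt[[1]]$tissues)
})

test_that("hub census counts internal memberships in deterministic order", {
  nets <- c(build_networks(c("A:B", "B:C"), "t1"),
            build_networks(c("B:D", "D:E", "E:F"), "t2"),
            build_networks(c("A:C", "C:D"), "t3"))
  cen <- hub_census(nets)
  expect_equal(unname(cen["B"]), 1L) # internal in t1 only
  expect_equal(unname(cen["D"]), 1L) # internal in t2; a leaf in t3
  expect_equal(unname(cen["C"]), 1L)
  expect_equal(unname(cen["A"]), 0L)
  expect_true(all(diff(unname(cen)) <= 0))
})

test_that("bootstrap enrichment of a TF subset matches exhaustive
           assignment probabilities and the trivial bounds", {
  net <- build_networks(c("P:Q", "Q:R"))[[1]]
  uni <- sprintf("U%d", 1:6)
  # exhaustive truth: the single internal position carries a special label
  # with probability |special| / |universe| = 2/6
  res <- internal_enrichment_bootstrap(list(net), uni[1:2], uni,
                                       n_boot = 20000, seed = 2)
  expect_equal(res$obs_internal, 0)
  # observed 0 means every replicate >= observed: p_internal = 1
  expect_equal(res$p_internal, 1)

  # relabel the network so its internal node is special, then the
  # replicate probability of >= 1 special internal is 1/3
  net2 <- net
  net2$internal <- "U1"; net2$nodes <- c("U1", "U5", "U6")
  res2 <- internal_enrichment_bootstrap(list(net2), uni[1:2], uni,
                                        n_boot = 20000, seed = 3)
  expect_equal(res2$obs_internal, 1)
  p_exact <- 2 / 6 # P(special at the internal position), enumeration
  expect_lt(abs(res2$p_internal - p_exact),
            3 * sqrt(p_exact * (1 - p_exact) / 20000) + 1e-4)

  # special = universe: observed is maximal, p = 1
  res3 <- internal_enrichment_bootstrap(list(net2), uni, uni,
                                        n_boot = 1000, seed = 4)
  expect_equal(res3$p_internal, 1)
  expect_equal(res3$p_total, 1)
  # empty special set: observed 0, p = 1
  res4 <- internal_enrichment_bootstrap(list(net2), character(0), uni,
                                        n_boot = 1000, seed = 5)
  expect_equal(res4$p_internal, 1)
  expect_gte(res4$p_internal, 1 / 1001)
  expect_error(internal_enrichment_bootstrap(list(net2), "Z", uni),
               "universe")
  # determinism
  expect_identical(
    internal_enrichment_bootstrap(list(net2), uni[1:2], uni, 2000, 9),
    internal_enrichment_bootstrap(list(net2), uni[1:2], uni, 2000, 9))
})
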