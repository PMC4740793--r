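test_that("hypergeometric enrichment matches hand-computed probabilities", {
  universe <- paste0("g", 1:10)
  pathways <- list(P1 = paste0("g", 1:5))
  query <- paste0("g", 1:4)
  res <- ora_enrichment(query, pathways, universe)
  expect_equal(res$p, choose(5, 4) * choose(5, 0) / choose(10, 4))  # 5/210
  expect_equal(res$q, res$p)  # BH with a single pathway

  # zero overlap: upper tail from zero is 1
  res0 <- ora_enrichment(paste0("g", 6:9), list(P1 = paste0("g", 1:5))["P1"],
                         universe)
  expect_lt(res0$k, 1)
  res00 <- ora_enrichment(c("g6", "g7"), list(P1 = c("g1", "g2")), universe)
  expect_equal(res00$p, 1)

  expect_error(ora_enrichment(character(0), pathways, universe), "empty")
  expect_error(ora_enrichment("not_there", pathways, universe), "universe")
})

test_that("BH never decreases p-values and the enriched set shrinks with alpha", {
  universe <- paste0("g", 1:50)
  pathways <- withr::with_seed(8, lapply(stats::setNames(1:12, paste0("P", 1:12)),
                                         function(i) sample(universe, 10)))
  query <- paste0("g", 1:12)
  res <- ora_enrichment(query, pathways, universe)
  expect_true(all(res$q >= res$p - 1e-15))
  strict <- ora_enrichment(query, pathways, universe, alpha = 0.01)
  expect_true(all(strict$pathway[strict$enriched] %in%
                    res$pathway[res$enriched]))
})

test_that("participation counts intermediate-node pathway memberships with multiplicity", {
  net <- toy_net(c("R", "A", 0.95), c("A", "B", 0.95), c("B", "L", 0.95))
  sn <- build_subnetwork(net, "R", "L", builder_config(depth = 5))
  expect_setequal(intermediate_nodes(sn), c("A", "B"))
  ps <- participation(sn, list(P1 = c("A", "B"), P2 = c("A")))
  expect_equal(unname(ps$counts), c(2L, 1L))
  expect_equal(ps$P, 3L)  # a node in m pathways contributes m instances

  # root in a key pathway contributes nothing; leaves excluded by default
  ps2 <- participation(sn, list(P1 = c("R", "L")))
  expect_equal(ps2$P, 0L)
  ps3 <- participation(sn, list(P1 = c("R", "L")), include_leaves = TRUE)
  expect_equal(ps3$P, 1L)
  ps4 <- participation(sn, list(P1 = c("X", "Y")))
  expect_equal(ps4$P, 0L)
  expect_error(participation(sn, list()), "empty")
})

test_that("Z-scores are centered and scaled by the reference cohort", {
  ref <- c(100, 110, 120, 130, 140)
  expect_equal(participation_zscore(mean(ref), ref)$z, 0)
  zz <- vapply(ref, function(p) participation_zscore(p, ref)$z, 1)
  expect_equal(mean(zz), 0)
  expect_equal(stats::sd(zz), 1)
  # arithmetic consistent with the published normalization: a participation
  # of 160.9 against a reference with mean 117.6 and SD 15.6 gives Z ~ 2.78
  ref2 <- c(117.6 - 15.6 / sqrt(2), 117.6 + 15.6 / sqrt(2))
  res <- participation_zscore(160.9, ref2)
  expect_equal(res$mu_ref, 117.6)
  expect_equal(res$sd_ref, 15.6)
  expect_equal(res$z, (160.9 - 117.6) / 15.6)
  expect_equal(res$z, 2.776, tolerance = 1e-3)
  expect_error(participation_zscore(5, c(3, 3, 3)), "zero standard deviation")
  expect_error(participation_zscore(5, 3), ">= 2")
})

test_that("Welch test matches stats::t.test and a permutation oracle on raw samples", {
  x <- withr::with_seed(21, stats::rnorm(18, 131, 19))
  y <- withr::with_seed(22, stats::rnorm(15, 117, 13))
  ours <- welch_test(mean(x), stats::sd(x), length(x),
                     mean(y), stats::sd(y), length(y))
  ref <- stats::t.test(x, y)
  expect_equal(ours$t, unname(ref$statistic))
  expect_equal(ours$df, unname(ref$parameter))
  expect_equal(ours$p, ref$p.value)
  perm <- oracle_permutation_p(x, y)
  expect_lt(abs(ours$p - perm), 0.05)  # Monte-Carlo agreement
})

test_that("Welch test handles degenerate and symmetric inputs", {
  same <- welch_test(10, 2, 12, 10, 2, 12)
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  a <- welch_test(131.4, 18.8, 21, 117.6, 15.6, 16)
  b <- welch_test(117.6, 15.6, 16, 131.4, 18.8, 21)
  expect_equal(a$t, -b$t)
  expect_equal(a$p, b$p)
  expect_true(a$p > 0 && a$p <= 1)
  expect_error(welch_test(1, 0, 5, 2, 1, 5), "> 0")
  expect_error(welch_test(1, 1, 1, 2, 1, 5), ">= 2")
})

test_that("enriched pathways are counted overall and restricted to a cancer list", {
  res <- data.frame(pathway = c("A", "B", "C"), q = c(0.01, 0.2, 0.03))
  expect_equal(count_enriched(res, 0.05, cancer_related = c("C", "Z")),
               c(total = 2L, cancer = 1L))
  expect_equal(count_enriched(res, 0.001), c(total = 0L, cancer = 0L))
})
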