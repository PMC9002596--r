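test_that("upper-tail hypergeometric matches hand-enumerated values", {
  expect_equal(hypergeom_upper_tail(0, 4, 5, 10), 1.0)
  expect_equal(hypergeom_upper_tail(4, 4, 5, 10), 6 / 252)
  expect_equal(hypergeom_upper_tail(2, 2, 2, 4), 1 / 6)
  expect_error(hypergeom_upper_tail(5, 4, 5, 10), "invalid")
  expect_error(hypergeom_upper_tail(1, 11, 5, 10), "invalid")
})

test_that("upper tail agrees with enumeration on a parameter grid", {
  for (N in c(5L, 8L, 10L)) {
    for (K in 0:N) for (n in 0:N) for (k in 0:min(K, n)) {
      expect_equal(hypergeom_upper_tail(k, K, n, N),
                   enum_hyper_upper(k, K, n, N), tolerance = 1e-13,
                   label = sprintf("k=%d K=%d n=%d N=%d", k, K, n, N))
    }
  }
})

test_that("increasing k never increases the upper-tail probability", {
  set.seed(1)
  for (i in 1:50) {
    N <- sample(4:40, 1); K <- sample(0:N, 1); n <- sample(1:N, 1)
    ks <- 0:min(K, n)
    p <- hypergeom_upper_tail(ks, K, n, N)
    expect_true(all(diff(p) <= 1e-15))
  }
})

test_that("BH adjustment matches the step-up definition", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.04), 0.04)
  expect_equal(bh_adjust(c(0.05, 0.05)), c(0.05, 0.05))
  expect_identical(bh_adjust(numeric(0)), numeric(0))
  expect_error(bh_adjust(c(0.5, 0)), "\\(0, 1\\]")
  set.seed(7)
  for (i in 1:100) {
    p <- runif(sample(1:50, 1))
    expect_equal(bh_adjust(p), brute_bh(p), tolerance = 1e-13)
  }
})

test_that("incidence is binary per herb for both feature kinds", {
  herbs <- herbs_from_levels(c(3L, 3L, 4L, -3L, -3L, 0L))
  cat <- structure(list(
    herb_ingredient = data.frame(
      herb_id = c("h001", "h001", "h002", "h004", "h006"),
      canonical_id = c("ingA", "ingA", "ingA", "ingB", "ingA"),
      stringsAsFactors = FALSE),
    ingredient_target = data.frame(
      canonical_id = c("ingA", "ingA", "ingB"),
      gene_symbol = c("G1", "G2", "G1"), stringsAsFactors = FALSE)
  ), class = "herb_catalog")
  inc <- build_incidence(cat, herbs, "ingredient")
  expect_equal(sum(inc[, "ingA"]), 3)  # duplicate listing counts once
  expect_equal(dim(inc), c(6L, 2L))
  tg <- build_incidence(cat, herbs, "target_gene")
  # h004 reaches G1 through ingB; h001 through ingA: one count per herb
  expect_equal(sum(tg[, "G1"]), 4)
  expect_equal(sum(tg[, "G2"]), 3)
  # 3 hot-group herbs, ingA present in 2 of them
  k_hg <- sum(inc[herbs$herb_id[herbs$HG], "ingA"])
  expect_equal(k_hg, 2)
})

test_that("feature enrichment tests the top-k by focal occurrence", {
  herbs <- herbs_from_levels(c(rep(3L, 4), rep(-3L, 4)))
  hot <- herbs$herb_id[herbs$HG]; cold <- herbs$herb_id[herbs$CG]
  inc <- incidence_from_list(c(
    stats::setNames(rep(list(c("planted", "shared")), 4), hot),
    stats::setNames(list("shared", "shared", "rare", character(0)), cold)
  ), herb_ids = herbs$herb_id)
  res <- enrich_features(inc, herbs, "HG", "CG")
  planted <- res[res$feature == "planted", ]
  # present in all focal herbs, absent from reference: single-term tail
  expect_equal(planted$p_raw, 1 / choose(8, 4))
  expect_equal(planted[, c("k", "n", "K", "N")],
               data.frame(k = 4L, n = 4L, K = 4L, N = 8L),
               ignore_attr = TRUE)
  # absent from focal: p = 1, can never be called specific
  expect_equal(res$p_raw[res$feature == "rare"], 1)
  # top_k truncates to exactly k results, ranked by focal count then name
  res2 <- enrich_features(inc, herbs, "HG", "CG", top_k = 2)
  expect_equal(nrow(res2), 2L)
  expect_equal(res2$feature, c("planted", "shared"))
  expect_error(enrich_features(inc, herbs, "HG", "HGE"), "overlap")
})

test_that("specificity requires both comparisons to pass", {
  r1 <- data.frame(feature = c("f1", "f2", "f3"),
                   p_adj = c(0.001, 0.001, 0.5))
  r2 <- data.frame(feature = c("f1", "f2", "f3"),
                   p_adj = c(0.002, 0.5, 0.001))
  sp <- call_specific(r1, r2, alpha = 0.01)
  expect_equal(sp$is_specific[sp$feature == "f1"], TRUE)
  expect_equal(sp$is_specific[sp$feature == "f2"], FALSE) # fails comparison 2
  expect_equal(sp$is_specific[sp$feature == "f3"], FALSE)
  expect_equal(sp$rank[sp$feature == "f1"], 1L)
  # truncation keeps the top-ranked specific features only
  many1 <- data.frame(feature = paste0("g", 1:7), p_adj = (1:7) / 1e4)
  many2 <- data.frame(feature = paste0("g", 1:7), p_adj = (7:1) / 1e4)
  top <- call_specific(many1, many2, alpha = 0.01, select_top = 5)
  expect_equal(nrow(top), 5L)
  expect_equal(top$rank, 1:5)
  expect_error(call_specific(r1, r2[1:2, ]), "different feature sets")
})

test_that("common targets intersect informative ingredients only", {
  targets <- list(A = c("g1", "g2"), B = "g1", C = character(0))
  ct <- common_targets(c("A", "B"), targets)
  expect_equal(ct$genes, "g1")
  # an ingredient without target information cannot erase the intersection
  ct2 <- common_targets(c("A", "C"), targets)
  expect_equal(ct2$genes, c("g1", "g2"))
  expect_equal(ct2$uninformative, "C")
  expect_false(ct2$all_uninformative)
  # disjoint target sets
  expect_equal(common_targets(c("A", "D"),
                              c(targets, list(D = "g9")))$genes,
               character(0))
  # nothing informative: empty result with an explicit flag
  ct3 <- common_targets("C", targets)
  expect_true(ct3$all_uninformative)
  expect_equal(ct3$genes, character(0))
  expect_error(common_targets(character(0), targets), "at least one")
  # membership table supports Venn-style readout
  expect_true(ct$membership["g1", "A"] && ct$membership["g1", "B"])
  expect_false(ct$membership["g2", "B"])
})

test_that("z-score profiles standardize bin ratios", {
  herbs <- herbs_from_levels(c(-3L, -1L, 0L, 1L, 3L))
  inc_flat <- incidence_from_list(
    stats::setNames(rep(list("f"), 5), herbs$herb_id))
  prof <- zscore_profile("f", inc_flat, herbs)
  expect_equal(prof$z, rep(0, 5)) # constant ratios: zero vector by convention
  inc_peak <- incidence_from_list(
    stats::setNames(list(character(0), character(0), character(0),
                         character(0), "f"), herbs$herb_id))
  prof2 <- zscore_profile("f", inc_peak, herbs)
  expect_equal(prof2$ratio, c(0, 0, 0, 0, 1))
  expect_equal(prof2$z, c(rep(-0.4472136, 4), 1.7888544), tolerance = 1e-6)
  expect_equal(mean(prof2$z), 0)
  # an empty display bin is a hard error naming the bin
  herbs4 <- herbs_from_levels(c(-3L, -1L, 1L, 3L))
  inc4 <- incidence_from_list(
    stats::setNames(rep(list("f"), 4), herbs4$herb_id))
  expect_error(zscore_profile("f", inc4, herbs4), "EG")
})
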