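make_component_herbs <- function() {
  # 25 herbs across the five bins; component "hotcomp" concentrated in HG,
  # "coldcomp" in CG, "flatcomp" everywhere
  levels <- rep(c(-3L, -1L, 0L, 1L, 3L), each = 5L)
  herbs <- herbs_from_levels(levels)
  hg <- herbs$herb_id[herbs$bin == "HG"]
  cg <- herbs$herb_id[herbs$bin == "CG"]
  map <- rbind(
    data.frame(component_id = "hotcomp", herb_id = hg),
    data.frame(component_id = "hotcomp", herb_id = cg[1]),
    data.frame(component_id = "coldcomp", herb_id = cg),
    data.frame(component_id = "flatcomp", herb_id = herbs$herb_id)
  )
  list(herbs = herbs, map = map)
}

test_that("components are classed by the peak bin of their z-profile", {
  fx <- make_component_herbs()
  sel <- select_components(fx$map, fx$herbs)
  expect_equal(sel$class[sel$component_id == "hotcomp"], "HC")
  expect_equal(sel$class[sel$component_id == "coldcomp"], "CC")
  expect_equal(sel$class[sel$component_id == "flatcomp"], "unselected")
  # exclusion fires after classification, with the reason logged
  sel2 <- select_components(fx$map, fx$herbs, exclude_ids = "coldcomp")
  row <- sel2[sel2$component_id == "coldcomp", ]
  expect_equal(row$class, "unselected")
  expect_match(row$reason, "excluded .was classified CC.")
  # a component with no herbs in the harmonized set is an error
  bad <- rbind(fx$map, data.frame(component_id = "ghost", herb_id = "nope"))
  expect_error(select_components(bad, fx$herbs), "ghost")
})

test_that("gene ranking is a pooled t with floor, antisymmetric in groups", {
  set.seed(21)
  genes <- sprintf("g%03d", 1:50)
  expr <- matrix(rnorm(50 * 6, sd = 0.1), 50, 6,
                 dimnames = list(genes, sprintf("s%d", 1:6)))
  expr["g001", 1:3] <- expr["g001", 1:3] + 2 # planted shift
  rk <- rank_genes(expr, sprintf("s%d", 1:3), sprintf("s%d", 4:6))
  expect_equal(rk$gene[1], "g001")
  expect_gt(rk$stat[1], 10)
  # hand-check the pooled t for the planted gene (floor inactive there)
  x1 <- expr["g001", 1:3]; x2 <- expr["g001", 4:6]
  s2 <- (var(x1) + var(x2)) / 2
  s2 <- max(s2, 0.01 * median((apply(expr[, 1:3], 1, var) +
                                 apply(expr[, 4:6], 1, var)) / 2))
  expect_equal(rk$stat[1], (mean(x1) - mean(x2)) / sqrt(s2 * (2 / 3)))
  # swapping the group labels negates every statistic
  rk_sw <- rank_genes(expr, sprintf("s%d", 4:6), sprintf("s%d", 1:3))
  expect_equal(rk_sw$stat[match(rk$gene, rk_sw$gene)], -rk$stat)
  # identical group means everywhere: all zero, lexicographic order
  const <- matrix(1, 5, 4, dimnames = list(c("b", "a", "d", "c", "e"),
                                           sprintf("t%d", 1:4)))
  rk0 <- rank_genes(const, c("t1", "t2"), c("t3", "t4"))
  expect_equal(rk0$stat, rep(0, 5))
  expect_equal(rk0$gene, c("a", "b", "c", "d", "e"))
  expect_error(rank_genes(expr, "s1", sprintf("s%d", 4:6)), "at least 2")
  expect_error(rank_genes(expr, sprintf("s%d", 1:3), sprintf("s%d", 3:6)),
               "both groups")
})

test_that("enrichment scores match the hand-enumerated running sums", {
  r4 <- stats::setNames(c(4, 3, 2, 1), paste0("g", 1:4))
  top <- gsea_es(r4, "g1")
  expect_equal(top$es, 1.0)
  expect_equal(top$running, c(1, 2 / 3, 1 / 3, 0))
  bottom <- gsea_es(r4, "g4")
  expect_equal(bottom$es, -1.0)
  expect_equal(bottom$running, c(-1 / 3, -2 / 3, -1, 0))
  expect_error(gsea_es(r4, "absent"), "shares no genes")
  expect_error(gsea_es(r4, paste0("g", 1:4)), "entire ranking")
})

test_that("ES is bounded, row-order invariant, and antisymmetric", {
  set.seed(5)
  for (i in 1:25) {
    N <- sample(20:200, 1)
    s <- sort(rnorm(N), decreasing = TRUE)
    names(s) <- sprintf("g%04d", sample.int(9999, N))
    gs <- sample(names(s), sample(2:(N %/% 2), 1))
    es <- gsea_es(s, gs)$es
    expect_lte(abs(es), 1)
    # permuting the stored row order of a data frame input changes nothing
    df <- data.frame(gene = names(s), stat = unname(s))
    expect_equal(gsea_es(df[sample(N), ], gs)$es, es)
    # negating and reversing the ranking negates the score
    neg <- rev(-s)
    expect_equal(gsea_es(neg, gs)$es, -es, tolerance = 1e-12)
  }
})

test_that("position-based ES used for permutations equals the full scan", {
  set.seed(6)
  for (i in 1:50) {
    N <- sample(15:300, 1)
    s <- sort(rnorm(N), decreasing = TRUE)
    names(s) <- sprintf("g%04d", 1:N)
    m <- sample(1:(N - 1), 1)
    pos <- sort(sample.int(N, m))
    full <- gsea_es(s, names(s)[pos])$es
    fast <- thermoherb:::es_from_positions(pos, abs(s), N, 1)
    expect_equal(fast, full, tolerance = 1e-12)
  }
})

test_that("ES agrees with an independent preranked implementation", {
  skip_if_not_installed("fgsea")
  set.seed(8)
  s <- sort(rnorm(500), decreasing = TRUE)
  names(s) <- sprintf("g%03d", 1:500)
  for (i in 1:10) {
    pos <- sort(sample.int(500, sample(5:60, 1)))
    ours <- gsea_es(s, names(s)[pos])$es
    ref <- fgsea::calcGseaStat(s, selectedStats = pos, gseaParam = 1)
    expect_equal(ours, ref, tolerance = 1e-10)
  }
})

test_that("permutation GSEA is deterministic and finds a planted set", {
  cfg <- synth_config(seed = 3)
  e <- generate_expression(cfg)
  hc <- e$sample_map$sample_id[e$sample_map$class == "HC"]
  cc <- e$sample_map$sample_id[e$sample_map$class == "CC"]
  rk <- rank_genes(e$expr, hc, cc)
  set.seed(99)
  decoys <- stats::setNames(
    lapply(1:3, function(i) sample(rownames(e$expr), 50)),
    sprintf("DECOY%d", 1:3))
  coll <- c(list(PLANTED = e$truth$planted_genes), decoys)
  res1 <- gsea_significance(rk, coll, n_perm = 500, seed = 17)
  res2 <- gsea_significance(rk, coll, n_perm = 500, seed = 17)
  expect_identical(res1, res2)
  planted <- res1[res1$set == "PLANTED", ]
  expect_gt(planted$nes, 0)
  expect_lt(planted$p_adj, 0.05)
  expect_true(all(planted$leading_edge[[1]] %in% e$truth$planted_genes))
  expect_true(all(res1$p_perm > 0 & res1$p_perm <= 1))
  expect_equal(sign(res1$nes[!res1$degenerate & res1$es != 0]),
               sign(res1$es[!res1$degenerate & res1$es != 0]))
  # sets disjoint from the ranking are dropped with a message
  expect_message(
    gsea_significance(rk, c(coll, list(ALIEN = c("x", "y"))),
                      n_perm = 100, seed = 1),
    "dropped")
  expect_error(gsea_significance(rk, coll, n_perm = 50, seed = 1),
               "at least 100")
  expect_error(gsea_significance(rk, coll, n_perm = 500), "seed")
})

test_that("GSEA results serialize with a comma-joined leading edge", {
  r4 <- stats::setNames(sort(rnorm(30), decreasing = TRUE),
                        sprintf("g%02d", 1:30))
  res <- gsea_significance(r4, list(S = names(r4)[1:5]), n_perm = 100,
                           seed = 2)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_gsea(res, path)
  back <- utils::read.delim(path)
  expect_equal(back$set, "S")
  expect_true(grepl(",", back$leading_edge) ||
                length(res$leading_edge[[1]]) <= 1L)
})
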