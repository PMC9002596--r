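# Shared fixtures and independent oracles used across the suite.

# Brute-force upper-tail hypergeometric probability by enumeration of the
# probability mass over the support (independent of stats::phyper).
enum_hyper_upper <- function(k, K, n, N) {
  xs <- max(0, n - (N - K)):min(K, n)
  mass <- choose(K, xs) * choose(N - K, n - xs) / choose(N, n)
  sum(mass[xs >= k])
}

# Brute-force BH step-up: sort, scale by m/rank, cumulative minimum from the
# largest p, cap at 1, restore input order.
brute_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  scaled <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(scaled)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# Grouped-herb table straight from resolved levels, for unit tests that do
# not need a full catalog.
herbs_from_levels <- function(levels, scheme = default_group_scheme()) {
  herbs <- data.frame(
    herb_id = sprintf("h%03d", seq_along(levels)),
    level_a = levels, level_b = levels,
    match_class = "exact",
    resolved_level = as.integer(levels),
    stringsAsFactors = FALSE
  )
  assign_groups(herbs, scheme)
}

# Incidence matrix from a named list herb_id -> feature vector.
incidence_from_list <- function(feature_lists, herb_ids = names(feature_lists)) {
  feats <- sort(unique(unlist(feature_lists)))
  inc <- matrix(FALSE, length(herb_ids), length(feats),
                dimnames = list(herb_ids, feats))
  for (h in names(feature_lists)) inc[h, feature_lists[[h]]] <- TRUE
  inc
}

# Tiny two-table property fixture.
toy_property_tables <- function() {
  list(
    a = data.frame(
      herb_id = c("hb1", "hb2", "hb3", "hb4", "hb5"),
      label = c("hot", "hot", "warm", "even/mild", "cool"),
      stringsAsFactors = FALSE
    ),
    b = data.frame(
      herb_id = c("hb1", "hb2", "hb3", "hb4", "hb5", "hb6"),
      label = c("hot", "warm", "cool", "mild", "cold", "hot"),
      stringsAsFactors = FALSE
    )
  )
}
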