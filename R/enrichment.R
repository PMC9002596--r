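#' Build a herb-by-feature incidence matrix
#'
#' Incidence is binary per herb: an ingredient listed several times for one
#' herb counts once, and a herb carries a target gene if any of its
#' ingredients targets that gene (multiplicity across ingredients is
#' discarded). Catalog herbs absent from the harmonized set are skipped with
#' a message.
#'
#' @param catalog A canonicalized catalog (see
#'   \code{\link{canonicalize_ingredients}}).
#' @param herbs Grouped herbs from \code{\link{assign_groups}}.
#' @param feature_kind \code{"ingredient"} or \code{"target_gene"}.
#' @return Logical matrix, herbs in rows (all harmonized herbs, including
#'   those with no features), features in columns, sorted names.
#' @export
build_incidence <- function(catalog, herbs,
                            feature_kind = c("ingredient", "target_gene")) {
  feature_kind <- match.arg(feature_kind)
  hi <- catalog$herb_ingredient
  unknown <- setdiff(unique(hi$herb_id), herbs$herb_id)
  if (length(unknown)) {
    message(length(unknown),
            " catalog herb(s) absent from the harmonized set; skipped")
    hi <- hi[hi$herb_id %in% herbs$herb_id, , drop = FALSE]
  }
  if (feature_kind == "ingredient") {
    pairs <- unique(hi[c("herb_id", "canonical_id")])
    feat <- pairs$canonical_id
  } else {
    tg <- catalog$ingredient_target
    m <- merge(hi, tg, by = "canonical_id")
    pairs <- unique(data.frame(herb_id = m$herb_id,
                               canonical_id = m$gene_symbol,
                               stringsAsFactors = FALSE))
    feat <- pairs$canonical_id
  }
  rown <- sort(unique(herbs$herb_id))
  coln <- sort(unique(feat))
  inc <- matrix(FALSE, length(rown), length(coln),
                dimnames = list(rown, coln))
  if (nrow(pairs))
    inc[cbind(match(pairs$herb_id, rown), match(feat, coln))] <- TRUE
  inc
}

#' Upper-tail hypergeometric probability
#'
#' Probability of observing at least \code{k} marked herbs in a draw of
#' \code{n} from a population of \code{N} containing \code{K} marked herbs:
#' \eqn{P(X \ge k)} for \eqn{X \sim} Hypergeom(\code{N}, \code{K},
#' \code{n}), evaluated through the survival function for numerical
#' stability.
#'
#' @param k Observed count (vectorized).
#' @param K Marked herbs in the population.
#' @param n Draw size.
#' @param N Population size.
#' @return Upper-tail probability in \code{(0, 1]}.
#' @export
hypergeom_upper_tail <- function(k, K, n, N) {
  args <- cbind(k, K, n, N)
  k <- args[, 1]; K <- args[, 2]; n <- args[, 3]; N <- args[, 4]
  if (any(k < 0 | K < 0 | n < 0 | N < 0) || any(K > N) || any(n > N) ||
      any(k > pmin(K, n)))
    stop("invalid hypergeometric counts: need 0 <= k <= min(K, n), K <= N, n <= N")
  unname(stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment; order-preserving with the input
#' and capped at 1.
#'
#' @param p Numeric vector of raw p-values in \code{(0, 1]}.
#' @return Adjusted p-values, same length and order as \code{p}.
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0L) return(numeric(0))
  if (any(is.na(p)) || any(p <= 0 | p > 1))
    stop("p-values must lie in (0, 1]")
  stats::p.adjust(p, method = "BH")
}

group_ids <- function(herbs, category) {
  if (!category %in% names(herbs))
    stop("unknown category: ", category)
  herbs$herb_id[herbs[[category]]]
}

#' Over-representation of features in one herb category versus another
#'
#' Features are first ranked by their occurrence count in the focal category
#' (ties broken lexicographically) and the top \code{top_k} are tested; the
#' BH family is exactly this tested set. For each tested feature the counts
#' are \code{k} = focal herbs carrying it, \code{n} = focal size, \code{K} =
#' carriers in the union of the two categories, \code{N} = combined size,
#' and the p-value is the upper-tail hypergeometric probability.
#'
#' @param incidence Logical herb-by-feature matrix from
#'   \code{\link{build_incidence}}.
#' @param herbs Grouped herbs from \code{\link{assign_groups}}.
#' @param focal,reference Category names among the group columns (e.g.
#'   \code{"HG"}, \code{"CG"}, \code{"NHG"}); the two must be disjoint herb
#'   sets.
#' @param top_k Number of top features to test (default all).
#' @return Data frame: \code{feature}, \code{k}, \code{n}, \code{K},
#'   \code{N}, \code{p_raw}, \code{p_adj}, in the tested ranking order.
#' @export
enrich_features <- function(incidence, herbs, focal, reference,
                            top_k = Inf) {
  A <- intersect(group_ids(herbs, focal), rownames(incidence))
  B <- intersect(group_ids(herbs, reference), rownames(incidence))
  if (length(intersect(A, B)))
    stop("focal and reference categories overlap (", focal, " vs ",
         reference, "); choose disjoint categories")
  if (!length(A) || !length(B))
    stop("empty category: ", if (!length(A)) focal else reference)
  kA <- colSums(incidence[A, , drop = FALSE])
  kB <- colSums(incidence[B, , drop = FALSE])
  ord <- order(-kA, colnames(incidence))
  keep <- ord[seq_len(min(top_k, length(ord)))]
  res <- data.frame(
    feature = colnames(incidence)[keep],
    k = as.integer(kA[keep]),
    n = length(A),
    K = as.integer(kA[keep] + kB[keep]),
    N = length(A) + length(B),
    stringsAsFactors = FALSE
  )
  res$p_raw <- hypergeom_upper_tail(res$k, res$K, res$n, res$N)
  res$p_adj <- bh_adjust(res$p_raw)
  rownames(res) <- NULL
  res
}

#' Call property-specific features from two comparisons
#'
#' A feature is specific to the focal category when its BH-adjusted p-value
#' is below \code{alpha} in \emph{both} comparisons (e.g. hot group versus
#' cold group and versus non-hot group). Specific features are ranked by
#' their worse adjusted p-value (ascending; ties lexicographic) and can be
#' truncated to a headline set.
#'
#' @param res1,res2 Results from \code{\link{enrich_features}} sharing the
#'   same focal category; their feature sets must coincide.
#' @param alpha Significance cutoff on the adjusted p-values.
#' @param select_top Optional truncation of the specific list (e.g. 5).
#' @return Data frame: \code{feature}, \code{p_adj_1}, \code{p_adj_2},
#'   \code{is_specific}, \code{rank} (NA for non-specific), ordered specific
#'   first.
#' @export
call_specific <- function(res1, res2, alpha = 0.01, select_top = NULL) {
  if (!setequal(res1$feature, res2$feature))
    stop("the two comparisons test different feature sets")
  res2 <- res2[match(res1$feature, res2$feature), , drop = FALSE]
  out <- data.frame(
    feature = res1$feature,
    p_adj_1 = res1$p_adj,
    p_adj_2 = res2$p_adj,
    stringsAsFactors = FALSE
  )
  out$is_specific <- out$p_adj_1 < alpha & out$p_adj_2 < alpha
  worst <- pmax(out$p_adj_1, out$p_adj_2)
  out <- out[order(!out$is_specific, worst, out$feature), , drop = FALSE]
  out$rank <- NA_integer_
  out$rank[out$is_specific] <- seq_len(sum(out$is_specific))
  if (!is.null(select_top)) {
    out <- out[out$is_specific & out$rank <= select_top, , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

#' Common targets of a set of specific ingredients
#'
#' Intersects the target-gene sets of the given ingredients. Ingredients
#' whose target information is unavailable (an explicit empty set) cannot
#' constrain the intersection and are excluded from it but reported, so one
#' uncharacterized ingredient does not erase the shared target of the rest.
#'
#' @param ingredient_ids Character vector of canonical ingredient IDs.
#' @param targets Named list mapping ingredient ID to a character vector of
#'   gene symbols (see \code{\link{target_map}}).
#' @return List with \code{genes} (the intersection over informative
#'   ingredients), \code{membership} (logical gene-by-ingredient table over
#'   the union of targets, for Venn-style output), \code{uninformative}
#'   (ingredients with empty target sets), and \code{all_uninformative}
#'   flag.
#' @export
common_targets <- function(ingredient_ids, targets) {
  if (!length(ingredient_ids)) stop("need at least one ingredient")
  sets <- lapply(ingredient_ids, function(i) targets[[i]] %||% character(0))
  names(sets) <- ingredient_ids
  informative <- lengths(sets) > 0L
  all_genes <- sort(unique(unlist(sets)))
  membership <- matrix(
    vapply(sets, function(s) all_genes %in% s, logical(length(all_genes))),
    nrow = length(all_genes), ncol = length(ingredient_ids),
    dimnames = list(all_genes, ingredient_ids))
  genes <- if (any(informative))
    sort(Reduce(intersect, sets[informative])) else character(0)
  list(
    genes = genes,
    membership = membership,
    uninformative = ingredient_ids[!informative],
    all_uninformative = !any(informative)
  )
}

#' Occurrence-ratio profile of a feature across the five display bins
#'
#' For each ordered bin (CG, CGE-only, EG, HE, HG) the ratio of herbs in the
#' bin carrying the feature is computed; the five ratios are standardized to
#' z-scores with the sample standard deviation. A flat profile (zero
#' standard deviation) yields a zero z-vector by convention.
#'
#' @param feature Feature (column) name in \code{incidence}.
#' @param incidence Logical herb-by-feature matrix.
#' @param herbs Grouped herbs with a \code{bin} column.
#' @return Data frame: \code{bin}, \code{n}, \code{k}, \code{ratio},
#'   \code{z}.
#' @export
zscore_profile <- function(feature, incidence, herbs) {
  if (!feature %in% colnames(incidence))
    stop("feature not in incidence matrix: ", feature)
  herbs <- herbs[herbs$herb_id %in% rownames(incidence), , drop = FALSE]
  bins <- levels(herbs$bin)
  n <- table(herbs$bin)
  if (any(n == 0L))
    stop("empty display bin(s): ",
         paste(bins[n == 0L], collapse = ", "))
  carrier <- rownames(incidence)[incidence[, feature]]
  k <- table(herbs$bin[herbs$herb_id %in% carrier])
  ratio <- as.numeric(k) / as.numeric(n)
  s <- stats::sd(ratio)
  z <- if (is.na(s) || s == 0) rep(0, length(ratio)) else
    (ratio - mean(ratio)) / s
  data.frame(bin = bins, n = as.integer(n), k = as.integer(k),
             ratio = ratio, z = z, stringsAsFactors = FALSE)
}
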