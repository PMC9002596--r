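#' Select hot and cold components by category skew
#'
#' Each assayed component (an ingredient with expression data) is profiled
#' by the ratio of herbs containing it in each of the five ordered display
#' bins, standardized to z-scores. A component whose profile peaks at the
#' hot-group bin with z at or above the threshold is a hot component (HC);
#' one peaking at the cold-group bin is a cold component (CC). Components on
#' the exclusion list are removed after classification with a logged
#' reason (mirroring the removal of a previously hot-classified compound
#' from a cold list).
#'
#' @param component_herb_map Data frame with columns \code{component_id},
#'   \code{herb_id}: the herbs each assayed component occurs in.
#' @param herbs Grouped herbs from \code{\link{assign_groups}}.
#' @param z_threshold Minimum peak z-score for selection.
#' @param exclude_ids Components never to classify.
#' @return Data frame: \code{component_id}, the five z-scores
#'   (\code{z_CG}, \code{z_CGE}, \code{z_EG}, \code{z_HE}, \code{z_HG}),
#'   \code{class} in \{HC, CC, unselected\}, and \code{reason}.
#' @export
select_components <- function(component_herb_map, herbs, z_threshold = 1.0,
                              exclude_ids = character(0)) {
  need <- c("component_id", "herb_id")
  if (!all(need %in% names(component_herb_map)))
    stop("component_herb_map needs columns: ", paste(need, collapse = ", "))
  comps <- sort(unique(component_herb_map$component_id))
  known <- component_herb_map$herb_id %in% herbs$herb_id
  cmap <- component_herb_map[known, , drop = FALSE]
  orphan <- setdiff(comps, unique(cmap$component_id))
  if (length(orphan))
    stop("component(s) with no herbs in any bin: ",
         paste(orphan, collapse = ", "))
  pairs <- unique(cmap[c("herb_id", "component_id")])
  rown <- sort(unique(herbs$herb_id))
  inc <- matrix(FALSE, length(rown), length(comps),
                dimnames = list(rown, comps))
  inc[cbind(match(pairs$herb_id, rown), match(pairs$component_id, comps))] <- TRUE
  prof <- lapply(comps, function(cid) zscore_profile(cid, inc, herbs))
  z <- t(vapply(prof, `[[`, numeric(5), "z"))
  colnames(z) <- paste0("z_", prof[[1L]]$bin)
  peak_bin <- prof[[1L]]$bin[max.col(z, ties.method = "first")]
  peak_z <- z[cbind(seq_along(comps), max.col(z, ties.method = "first"))]
  cls <- ifelse(peak_bin == "HG" & peak_z >= z_threshold, "HC",
          ifelse(peak_bin == "CG" & peak_z >= z_threshold, "CC",
                 "unselected"))
  reason <- ifelse(cls == "unselected", "no qualifying skew", "selected")
  excl <- comps %in% exclude_ids
  reason[excl] <- paste0("excluded (was classified ", cls[excl], ")")
  cls[excl] <- "unselected"
  out <- data.frame(component_id = comps, z, class = cls, reason = reason,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Rank genes by a two-group differential statistic
#'
#' Pooled-variance t statistic per gene between the hot-component and
#' cold-component sample groups, with a relative variance floor
#' \eqn{s^2 \leftarrow \max(s^2, \epsilon\,\mathrm{median}(s^2))}
#' (\eqn{\epsilon = 0.01}) that keeps near-constant genes from dominating
#' the ranking. Genes are returned in descending statistic order with ties
#' broken by gene name; a gene with no variance and no mean difference gets
#' statistic 0.
#'
#' @param expr Numeric matrix, genes x samples, already normalized (log
#'   scale).
#' @param samples_hc,samples_cc Column names of the two groups (at least 2
#'   each).
#' @param statistic \code{"t"} (default) for the moderated pooled t, or
#'   \code{"lfc"} for the plain mean difference (log fold change).
#' @param var_floor_eps Relative variance floor (ignored for \code{"lfc"}).
#' @return Data frame: \code{gene}, \code{stat}, sorted for preranked GSEA.
#' @export
rank_genes <- function(expr, samples_hc, samples_cc,
                       statistic = c("t", "lfc"), var_floor_eps = 0.01) {
  statistic <- match.arg(statistic)
  miss <- setdiff(c(samples_hc, samples_cc), colnames(expr))
  if (length(miss))
    stop("sample(s) missing from the matrix: ", paste(miss, collapse = ", "))
  if (length(intersect(samples_hc, samples_cc)))
    stop("a sample cannot belong to both groups")
  n1 <- length(samples_hc); n2 <- length(samples_cc)
  if (n1 < 2L || n2 < 2L) stop("need at least 2 samples per group")
  x1 <- expr[, samples_hc, drop = FALSE]
  x2 <- expr[, samples_cc, drop = FALSE]
  m1 <- rowMeans(x1); m2 <- rowMeans(x2)
  diff <- m1 - m2
  if (statistic == "lfc") {
    stat <- diff
  } else {
    v1 <- apply(x1, 1L, stats::var); v2 <- apply(x2, 1L, stats::var)
    s2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    s2 <- pmax(s2, var_floor_eps * stats::median(s2))
    denom <- sqrt(s2 * (1 / n1 + 1 / n2))
    stat <- ifelse(denom == 0,
                   ifelse(diff == 0, 0, sign(diff) / .Machine$double.eps),
                   diff / denom)
  }
  out <- data.frame(gene = rownames(expr), stat = stat,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$stat, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}

as_ranking <- function(ranked) {
  if (is.data.frame(ranked)) {
    if (!all(c("gene", "stat") %in% names(ranked)))
      stop("ranked list needs columns gene, stat")
    ranked <- stats::setNames(ranked$stat, ranked$gene)
  }
  if (is.null(names(ranked)) || anyDuplicated(names(ranked)))
    stop("ranking must be a named vector without duplicate genes")
  if (any(!is.finite(ranked))) stop("ranking statistics must be finite")
  # the ranking is defined by the statistic (descending, ties by gene name),
  # never by the stored row order
  ranked[order(-ranked, names(ranked))]
}

#' Running-sum enrichment score
#'
#' Classic preranked enrichment statistic: walking down the ranked list, the
#' running sum rises by \eqn{|s_j|^w / \sum_{hits} |s|^w} at genes in the
#' set and falls by \eqn{1/(N - N_{hits})} elsewhere; the enrichment score
#' is the signed value of maximal absolute deviation from zero. When every
#' hit statistic is zero the hit increments fall back to equal weights.
#'
#' @param ranked Data frame from \code{\link{rank_genes}} or a named numeric
#'   vector sorted in descending order.
#' @param gene_set Character vector; must share at least one gene with the
#'   ranking but not cover it entirely.
#' @param weight Exponent on the hit statistics (0, 1, or 1.5; default 1).
#' @return List: \code{es}, \code{running} (the full running sum),
#'   \code{hits} (hit positions), \code{peak} (index of the extremum).
#' @export
gsea_es <- function(ranked, gene_set, weight = 1) {
  s <- as_ranking(ranked)
  N <- length(s)
  hit <- names(s) %in% gene_set
  m <- sum(hit)
  if (m == 0L) stop("gene set shares no genes with the ranking")
  if (m == N) stop("gene set covers the entire ranking")
  w <- abs(s[hit])^weight
  tot <- sum(w)
  inc <- numeric(N)
  inc[hit] <- if (tot == 0) 1 / m else w / tot
  inc[!hit] <- -1 / (N - m)
  running <- cumsum(inc)
  peak <- which.max(abs(running))
  es <- running[[peak]]
  hi <- max(running); lo <- min(running)
  if (abs(hi) == abs(lo)) { es <- hi; peak <- which.max(running) } # tie: positive
  list(es = unname(es), running = unname(running), hits = which(hit),
       peak = unname(peak))
}

# ES from hit positions only; O(m log m) per permutation. Agrees with
# gsea_es on the same inputs (property-tested).
es_from_positions <- function(pos, abs_stat, N, weight) {
  m <- length(pos)
  w <- abs_stat[pos]^weight
  tot <- sum(w)
  w <- if (tot == 0) rep(1 / m, m) else w / tot
  cw <- cumsum(w)
  missd <- 1 / (N - m)
  at_hit <- cw - (pos - seq_len(m)) * missd
  before_hit <- at_hit - w
  hi <- max(at_hit)
  lo <- min(before_hit, 0)
  if (hi >= -lo) hi else lo
}

#' Preranked GSEA with a gene-label permutation null
#'
#' For each gene set the observed enrichment score is referred to a null of
#' scores from random same-size gene sets drawn from the ranking. The
#' permutation p-value is \eqn{(1 + \#\{|ES_{null}| \ge |ES|,\ same\ sign\})
#' / (1 + \#\{same\ sign\ nulls\})}; the normalized score divides the
#' observed ES by the mean magnitude of same-sign null scores. BH adjustment
#' runs across the collection. Results are reproducible for a fixed seed.
#'
#' @param ranked Ranked gene list (see \code{\link{gsea_es}}).
#' @param collection Named list of gene sets; sets sharing no gene with the
#'   ranking are dropped with a message.
#' @param n_perm Number of null draws per set (at least 100).
#' @param seed Integer seed (mandatory).
#' @param weight Hit-weight exponent.
#' @return Data frame: \code{set}, \code{size}, \code{es}, \code{nes},
#'   \code{p_perm}, \code{p_adj}, \code{degenerate} (no same-sign nulls),
#'   and list column \code{leading_edge}.
#' @export
gsea_significance <- function(ranked, collection, n_perm = 1000, seed,
                              weight = 1) {
  if (missing(seed)) stop("a seed is required for the permutation null")
  if (n_perm < 100L) stop("n_perm must be at least 100")
  s <- as_ranking(ranked)
  N <- length(s)
  abs_stat <- abs(s)
  usable <- vapply(collection, function(gs) {
    m <- sum(names(s) %in% gs); m >= 1L && m < N
  }, logical(1))
  if (!all(usable))
    message(sum(!usable), " gene set(s) share no genes with the ranking ",
            "(or cover it); dropped")
  collection <- collection[usable]
  if (!length(collection)) stop("no testable gene sets")
  set.seed(seed)
  rows <- lapply(names(collection), function(nm) {
    obs <- gsea_es(s, collection[[nm]], weight = weight)
    m <- length(obs$hits)
    null_es <- vapply(seq_len(n_perm), function(i)
      es_from_positions(sort(sample.int(N, m)), abs_stat, N, weight),
      numeric(1))
    es <- obs$es
    if (es == 0) {
      p <- 1; nes <- 0; degen <- FALSE
    } else {
      same <- null_es[sign(null_es) == sign(es)]
      if (!length(same)) {
        p <- 1 / (1 + n_perm); nes <- NA_real_; degen <- TRUE
      } else {
        p <- (1 + sum(abs(same) >= abs(es))) / (1 + length(same))
        nes <- es / mean(abs(same)); degen <- FALSE
      }
    }
    le <- if (es >= 0) {
      names(s)[intersect(obs$hits, seq_len(obs$peak))]
    } else {
      names(s)[intersect(obs$hits, seq(obs$peak, N))]
    }
    list(set = nm, size = m, es = es, nes = nes, p_perm = p,
         degenerate = degen, leading_edge = le)
  })
  out <- data.frame(
    set = vapply(rows, `[[`, character(1), "set"),
    size = vapply(rows, `[[`, integer(1), "size"),
    es = vapply(rows, `[[`, numeric(1), "es"),
    nes = vapply(rows, `[[`, numeric(1), "nes"),
    p_perm = vapply(rows, `[[`, numeric(1), "p_perm"),
    degenerate = vapply(rows, `[[`, logical(1), "degenerate"),
    stringsAsFactors = FALSE
  )
  out$p_adj <- bh_adjust(out$p_perm)
  out$leading_edge <- lapply(rows, `[[`, "leading_edge")
  rownames(out) <- NULL
  out
}

#' Write GSEA results as TSV
#' @param results Data frame from \code{\link{gsea_significance}}.
#' @param path Output path; the leading edge is comma-joined.
#' @export
write_gsea <- function(results, path) {
  flat <- results
  flat$leading_edge <- vapply(results$leading_edge, paste,
                              character(1), collapse = ",")
  utils::write.table(flat, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
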