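#' Configuration for the synthetic catalog and expression generators
#'
#' The generator emulates the statistical structure of two herb-property
#' database exports and of a component-treatment expression experiment:
#' herbs with a true nine-level temperament, a second database annotation
#' drawn per concordance class, ingredient occurrences with planted
#' hot-specific ingredients, ingredient-target records with one planted
#' shared target, and a genes-by-samples matrix with a planted shifted gene
#' set. All defaults are sized so the planted signal is recoverable under
#' the pipeline's standard settings while generation stays fast.
#'
#' @param seed Integer seed (mandatory); separate RNG streams are derived
#'   per table so generating the expression data never perturbs the catalog
#'   draws.
#' @param n_herbs Number of herbs common to both databases.
#' @param level_probs Probabilities over the nine levels \code{-4..4}.
#' @param p_exact,p_similar,p_discordant Concordance-class probabilities
#'   (must sum to 1). Defaults follow the observed proportions of
#'   exact/similar/discordant matches between two real property databases
#'   (roughly 83/11/6 percent).
#' @param n_ingredients Total ingredients, including the planted ones.
#' @param planted_hot IDs of the planted hot-specific ingredients.
#' @param p_in_hg,p_background Occurrence probability of planted ingredients
#'   in hot-group herbs (true level +3/+4) versus all other herbs.
#' @param background_rate Occurrence probability of background ingredients
#'   in any herb.
#' @param n_target_genes Size of the target-gene pool.
#' @param targets_per_ingredient Target genes drawn per informative
#'   ingredient.
#' @param common_target Gene symbol attached to every informative planted
#'   ingredient.
#' @param n_planted_empty How many planted ingredients carry no target
#'   information (explicit empty set).
#' @param frac_empty_targets Fraction of background ingredients without
#'   target information.
#' @param alias_dup_rate Fraction of herb-ingredient rows emitted under an
#'   alternate alias sharing the PubChem ID, to exercise synonym merging.
#' @param n_genes,planted_set_size,delta,noise_sd,n_per_group Expression
#'   parameters: matrix size, planted-set size, mean shift added to planted
#'   genes in hot-component samples, noise standard deviation, samples per
#'   side.
#' @return A validated list of class \code{synth_config}.
#' @export
synth_config <- function(seed,
                         n_herbs = 300,
                         level_probs = c(0.07, 0.18, 0.10, 0.08, 0.14,
                                         0.08, 0.10, 0.18, 0.07),
                         p_exact = 0.83, p_similar = 0.11,
                         p_discordant = 0.06,
                         n_ingredients = 400,
                         planted_hot = sprintf("hotspec%02d", 1:5),
                         p_in_hg = 0.5, p_background = 0.05,
                         background_rate = 0.08,
                         n_target_genes = 250,
                         targets_per_ingredient = 4,
                         common_target = "COMMONTGT",
                         n_planted_empty = 1,
                         frac_empty_targets = 0.10,
                         alias_dup_rate = 0.10,
                         n_genes = 2000, planted_set_size = 50,
                         delta = 1.0, noise_sd = 1.0, n_per_group = 5) {
  if (missing(seed)) stop("synth_config requires a seed")
  cfg <- as.list(environment())
  probs <- c(p_exact, p_similar, p_discordant)
  if (any(probs < 0) || abs(sum(probs) - 1) > 1e-8)
    stop("concordance probabilities must be non-negative and sum to 1")
  if (length(level_probs) != 9L || any(level_probs < 0) ||
      abs(sum(level_probs) - 1) > 1e-8)
    stop("level_probs must be 9 non-negative values summing to 1")
  if (any(c(p_in_hg, p_background, background_rate, frac_empty_targets,
            alias_dup_rate) < 0) ||
      any(c(p_in_hg, p_background, background_rate, frac_empty_targets,
            alias_dup_rate) > 1))
    stop("probabilities must lie in [0, 1]")
  if (planted_set_size > n_genes)
    stop("planted gene set larger than the gene universe")
  if (n_per_group < 2L) stop("need at least 2 samples per side")
  if (n_planted_empty > length(planted_hot))
    stop("cannot empty more planted ingredients than exist")
  class(cfg) <- "synth_config"
  cfg
}

# Independent per-table streams: a fixed offset per table keeps draws for
# one table stable when another table's generation changes.
with_stream <- function(seed, offset, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed((as.integer(seed) %% 1000003L) * 2011L + offset)
  expr
}

level_label <- function(level, variant = FALSE) {
  canon <- stats::setNames(property_classes()$class, property_classes()$level)
  if (!variant) return(unname(canon[as.character(level)]))
  syn <- default_property_synonyms()
  vapply(level, function(lv) {
    opts <- syn$label[syn$level == lv]
    opts[1 + (lv + 4L) %% length(opts)]
  }, character(1))
}

#' Generate a synthetic two-database herb catalog
#'
#' Database A records each herb's true temperament level; database B's label
#' is drawn per concordance class -- an exact copy, a same-sign level one
#' step toward zero where possible (one step away for the mildest levels,
#' so the milder of the two values is always well defined), or an
#' opposite-sign (mirrored) level for discordant herbs. An even herb drawn
#' into the similar class is recorded as exact, since a zero-level pair
#' cannot differ. Planted hot-specific ingredients occur with probability
#' \code{p_in_hg} in herbs of true level +3/+4 and \code{p_background}
#' elsewhere; every informative planted ingredient carries the planted
#' common target gene. A configured fraction of ingredients is emitted with
#' zero target rows. Output is fully reproducible from the seed.
#'
#' @param config A \code{synth_config}.
#' @return List: \code{catalog} (a \code{herb_catalog}) and \code{truth}
#'   (per-herb true levels and match classes, planted ingredient and target
#'   IDs).
#' @export
generate_catalog <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  n <- config$n_herbs
  herb_ids <- sprintf("herb%04d", seq_len(n))
  true_level <- with_stream(config$seed, 11L,
    sample(-4:4, n, replace = TRUE, prob = config$level_probs))

  drawn <- with_stream(config$seed, 12L, {
    cls <- sample(c("exact", "similar", "discordant"), n, replace = TRUE,
                  prob = c(config$p_exact, config$p_similar,
                           config$p_discordant))
    level_b <- true_level
    sim <- which(cls == "similar")
    if (length(sim)) {
      toward <- abs(true_level[sim]) > 1L
      level_b[sim] <- ifelse(true_level[sim] == 0L, 0L,
        true_level[sim] - sign(true_level[sim]) * ifelse(toward, 1L, -1L))
      cls[sim][true_level[sim] == 0L] <- "exact"
    }
    dis <- which(cls == "discordant")
    if (length(dis)) {
      level_b[dis] <- ifelse(true_level[dis] == 0L,
                             sample(c(-4:-1, 1:4), length(dis), replace = TRUE),
                             -true_level[dis])
    }
    list(cls = cls, level_b = level_b)
  })

  herb_property_a <- data.frame(herb_id = herb_ids,
                                label = level_label(true_level),
                                stringsAsFactors = FALSE)
  herb_property_b <- data.frame(herb_id = herb_ids,
                                label = level_label(drawn$level_b,
                                                    variant = TRUE),
                                stringsAsFactors = FALSE)

  planted <- config$planted_hot
  n_bg <- config$n_ingredients - length(planted)
  bg_ids <- sprintf("ing%04d", seq_len(n_bg))
  in_hg <- true_level >= 3L
  occ <- with_stream(config$seed, 13L, {
    p_planted <- ifelse(in_hg, config$p_in_hg, config$p_background)
    occ_p <- matrix(stats::runif(n * length(planted)) <
                      rep(p_planted, length(planted)),
                    nrow = n, dimnames = list(herb_ids, planted))
    occ_b <- matrix(stats::runif(n * n_bg) < config$background_rate,
                    nrow = n, dimnames = list(herb_ids, bg_ids))
    dup <- stats::runif(n * config$n_ingredients) < config$alias_dup_rate
    list(m = cbind(occ_p, occ_b), dup = dup)
  })
  idx <- which(occ$m, arr.ind = TRUE)
  ing_of_row <- colnames(occ$m)[idx[, 2L]]
  pubchem <- stats::setNames(
    sprintf("%06d", seq_len(config$n_ingredients) + 100000L),
    colnames(occ$m))
  dup_row <- occ$dup[(idx[, 2L] - 1L) * n + idx[, 1L]]
  herb_ingredient <- data.frame(
    herb_id = rownames(occ$m)[idx[, 1L]],
    alias = ifelse(dup_row, paste0("zz-alias-", ing_of_row), ing_of_row),
    pubchem_id = unname(pubchem[ing_of_row]),
    cas_id = NA_character_,
    stringsAsFactors = FALSE
  )
  # every ingredient keeps one row under its primary alias so the canonical
  # ID (lexicographically smallest alias) is the primary name
  first_of <- !duplicated(ing_of_row)
  herb_ingredient$alias[first_of] <- ing_of_row[first_of]
  ord <- order(herb_ingredient$herb_id, herb_ingredient$alias)
  herb_ingredient <- herb_ingredient[ord, , drop = FALSE]
  rownames(herb_ingredient) <- NULL

  genes <- c(config$common_target,
             sprintf("GENE%04d", seq_len(config$n_target_genes - 1L)))
  tgt <- with_stream(config$seed, 14L, {
    empty_planted <- utils::head(planted, config$n_planted_empty)
    empty_bg <- bg_ids[stats::runif(n_bg) < config$frac_empty_targets]
    informative <- setdiff(colnames(occ$m), c(empty_planted, empty_bg))
    rows <- lapply(informative, function(ing) {
      pool <- setdiff(genes, config$common_target)
      pick <- sample(pool, min(config$targets_per_ingredient, length(pool)))
      if (ing %in% planted) pick <- c(config$common_target,
                                      pick[-1L])
      data.frame(canonical_id = ing, gene_symbol = sort(pick),
                 stringsAsFactors = FALSE)
    })
    list(table = do.call(rbind, rows),
         empty = sort(c(empty_planted, empty_bg)))
  })

  catalog <- structure(list(
    herb_property_a = herb_property_a,
    herb_property_b = herb_property_b,
    herb_ingredient = herb_ingredient,
    ingredient_target = tgt$table
  ), class = "herb_catalog")
  validate_catalog(catalog)

  truth <- list(
    herbs = data.frame(herb_id = herb_ids, true_level = true_level,
                       level_b = drawn$level_b, match_class = drawn$cls,
                       stringsAsFactors = FALSE),
    planted_ingredients = planted,
    planted_empty_target = utils::head(planted, config$n_planted_empty),
    common_target = config$common_target,
    empty_target_ingredients = tgt$empty
  )
  list(catalog = catalog, truth = truth)
}

#' Generate a synthetic normalized expression matrix
#'
#' Background values are i.i.d. Normal(0, \code{noise_sd}^2); genes of the
#' planted set are shifted by \code{+delta} in the hot-component samples.
#' Deterministic under the config seed, independent of catalog generation.
#'
#' @param config A \code{synth_config}.
#' @return List: \code{expr} (genes x samples matrix), \code{sample_map}
#'   (sample_id, component_id, class), and \code{truth} (planted gene set
#'   and shift).
#' @export
generate_expression <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  genes <- sprintf("EXPR%05d", seq_len(config$n_genes))
  planted <- genes[seq_len(config$planted_set_size)]
  k <- config$n_per_group
  samples <- c(sprintf("HC_s%02d", seq_len(k)), sprintf("CC_s%02d", seq_len(k)))
  cls <- rep(c("HC", "CC"), each = k)
  expr <- with_stream(config$seed, 21L, {
    m <- matrix(stats::rnorm(config$n_genes * 2L * k, sd = config$noise_sd),
                nrow = config$n_genes, dimnames = list(genes, samples))
    m[planted, cls == "HC"] <- m[planted, cls == "HC"] + config$delta
    m
  })
  sample_map <- data.frame(
    sample_id = samples,
    component_id = paste0(tolower(cls), "_component"),
    class = cls,
    stringsAsFactors = FALSE
  )
  list(expr = expr, sample_map = sample_map,
       truth = list(planted_genes = planted, delta = config$delta))
}

#' Write all synthetic inputs to a directory
#'
#' Emits the catalog TSVs, the expression matrix and sample map, a GMT with
#' the planted set plus random decoy sets, and a machine-readable
#' \code{truth.json} sufficient to score recovery of every planted element.
#'
#' @param config A \code{synth_config}.
#' @param dir Output directory.
#' @param n_decoy_sets Random same-size decoy gene sets written to the GMT.
#' @return The directory, invisibly.
#' @export
write_synthetic_inputs <- function(config, dir, n_decoy_sets = 4) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cat_out <- generate_catalog(config)
  expr_out <- generate_expression(config)
  write_catalog(cat_out$catalog, dir)
  write_expression(expr_out$expr, file.path(dir, "expression.tsv"))
  utils::write.table(expr_out$sample_map, file.path(dir, "sample_map.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  genes <- rownames(expr_out$expr)
  decoys <- with_stream(config$seed, 22L, {
    stats::setNames(
      lapply(seq_len(n_decoy_sets), function(i)
        sample(genes, config$planted_set_size)),
      sprintf("DECOY_SET_%02d", seq_len(n_decoy_sets)))
  })
  sets <- c(list(PLANTED_SET = expr_out$truth$planted_genes), decoys)
  write_gmt(sets, file.path(dir, "gene_sets.gmt"))
  truth <- c(cat_out$truth, expr_out$truth)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns")
  invisible(dir)
}
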