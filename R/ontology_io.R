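#' Canonical temperament classes
#'
#' The nine ordinal temperament classes used to describe a herb's
#' physiological effect along the cold--hot axis, encoded as integers
#' \code{-4} (great/extreme cold) through \code{+4} (great/extreme hot),
#' with \code{0} for even/mild herbs.
#'
#' @return A data frame with columns \code{level} (integer) and
#'   \code{class} (the canonical label of that level).
#' @export
property_classes <- function() {
  data.frame(
    level = -4:4,
    class = c(
      "great/extreme cold", "cold", "cool", "mildly/minor/slightly cold",
      "even/mild",
      "mildly/minor warm", "warm", "hot", "great/extreme hot"
    ),
    stringsAsFactors = FALSE
  )
}

#' Default property-label synonym table
#'
#' Maps the label spellings found in herb-property exports onto the nine
#' ordinal levels. Separators (slash, comma, hyphen) are treated
#' equivalently, so only one spelling per separator family is listed.
#' Users may extend the table for database dialects not covered here.
#'
#' @return A data frame with columns \code{label} (normalized spelling) and
#'   \code{level} (integer in \code{-4..4}).
#' @export
default_property_synonyms <- function() {
  syn <- list(
    `4`  = c("great/extreme hot", "great hot", "extreme hot"),
    `3`  = c("hot"),
    `2`  = c("warm"),
    `1`  = c("mildly/minor warm", "mildly warm", "minor warm", "mild warm"),
    `0`  = c("even/mild", "even", "mild", "neutral"),
    `-1` = c("mildly/minor/slightly cold", "mildly/minor cold",
             "mildly cold", "minor cold", "slightly cold", "mild cold"),
    `-2` = c("cool"),
    `-3` = c("cold"),
    `-4` = c("great/extreme cold", "great cold", "extreme cold")
  )
  out <- data.frame(
    label = normalize_label(unlist(syn, use.names = FALSE)),
    level = rep(as.integer(names(syn)), lengths(syn)),
    stringsAsFactors = FALSE
  )
  out
}

# Case-fold, trim, squeeze whitespace, and map the separator family
# ("/", ",", "-") onto "/" so dialect spellings collide onto one key.
normalize_label <- function(x) {
  x <- tolower(trimws(as.character(x)))
  x <- gsub("[,/-]+", "/", x)
  x <- gsub("[[:space:]]*\\/[[:space:]]*", "/", x)
  x <- gsub("[[:space:]]+", " ", x)
  x
}

#' Parse property labels to ordinal levels
#'
#' @param raw Character vector of raw property labels.
#' @param synonyms Synonym table as returned by
#'   \code{\link{default_property_synonyms}}.
#' @return Integer vector of levels in \code{-4..4}.
#' @examples
#' parse_property_label(c("warm", "even/mild", "GREAT/EXTREME COLD"))
#' @export
parse_property_label <- function(raw, synonyms = default_property_synonyms()) {
  if (length(raw) == 0L) return(integer(0))
  if (any(is.na(raw) | !nzchar(trimws(raw))))
    stop("property labels must be non-empty strings")
  key <- normalize_label(raw)
  idx <- match(key, synonyms$label)
  if (anyNA(idx)) {
    bad <- unique(raw[is.na(idx)])
    stop(sprintf(
      "unrecognized property label(s): %s; accepted classes are: %s",
      paste(sQuote(bad), collapse = ", "),
      paste(property_classes()$class, collapse = "; ")
    ))
  }
  synonyms$level[idx]
}

#' Merge ingredient synonym records into canonical entities
#'
#' Raw ingredient records that share any identifying key -- an alias name, a
#' PubChem ID, or a CAS ID -- describe the same chemical entity. Entities are
#' the connected components of the record graph linked by shared keys
#' (transitive closure), so a chain A--B on alias and B--C on CAS collapses
#' to one entity. The canonical ID of an entity is the lexicographically
#' smallest alias among its records (falling back to the smallest
#' \code{PUBCHEM:}/\code{CAS:} key when no alias exists), which makes the
#' result independent of input row order.
#'
#' @param records Data frame with character columns \code{alias},
#'   \code{pubchem_id}, \code{cas_id}; missing keys are \code{NA}. Every row
#'   must carry at least one non-missing key.
#' @return A list with \code{entities}, a data frame (one row per entity;
#'   columns \code{canonical_id}, plus list columns \code{aliases},
#'   \code{pubchem_ids}, \code{cas_ids}), and \code{row_map}, the canonical
#'   ID assigned to each input row.
#' @export
merge_ingredient_synonyms <- function(records) {
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  need <- c("alias", "pubchem_id", "cas_id")
  miss <- setdiff(need, names(records))
  if (length(miss))
    stop("records lack column(s): ", paste(miss, collapse = ", "))
  for (cl in need) {
    v <- as.character(records[[cl]])
    v[!is.na(v) & !nzchar(trimws(v))] <- NA_character_
    records[[cl]] <- trimws(v)
  }
  n <- nrow(records)
  if (n == 0L)
    return(list(entities = data.frame(canonical_id = character(0)),
                row_map = character(0)))
  empty <- which(is.na(records$alias) & is.na(records$pubchem_id) &
                   is.na(records$cas_id))
  if (length(empty))
    stop("record(s) with all identifying keys missing at row(s): ",
         paste(empty, collapse = ", "))

  # union-find over rows, linked through namespaced key values
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  unite <- function(i, j) {
    ri <- find(i); rj <- find(j)
    if (ri != rj) parent[min(ri, rj)] <<- max(ri, rj) # root choice is arbitrary
  }
  keys <- data.frame(
    row = rep(seq_len(n), 3L),
    key = c(paste0("A:", records$alias),
            paste0("P:", records$pubchem_id),
            paste0("C:", records$cas_id)),
    drop = rep(c(is.na(records$alias), is.na(records$pubchem_id),
                 is.na(records$cas_id))),
    stringsAsFactors = FALSE
  )
  keys <- keys[!keys$drop, c("row", "key")]
  for (rows in split(keys$row, keys$key)) {
    if (length(rows) > 1L)
      for (j in rows[-1L]) unite(rows[1L], j)
  }
  root <- vapply(seq_len(n), find, integer(1))
  comps <- split(seq_len(n), root)

  ent <- lapply(comps, function(rows) {
    al <- sort(unique(stats::na.omit(records$alias[rows])))
    pc <- sort(unique(stats::na.omit(records$pubchem_id[rows])))
    ca <- sort(unique(stats::na.omit(records$cas_id[rows])))
    canon <- if (length(al)) al[1L]
      else if (length(pc)) paste0("PUBCHEM:", pc[1L])
      else paste0("CAS:", ca[1L])
    list(canonical_id = canon, aliases = al, pubchem_ids = pc, cas_ids = ca,
         rows = rows)
  })
  ord <- order(vapply(ent, `[[`, character(1), "canonical_id"))
  ent <- ent[ord]
  row_map <- character(n)
  for (e in ent) row_map[e$rows] <- e$canonical_id
  entities <- data.frame(
    canonical_id = vapply(ent, `[[`, character(1), "canonical_id"),
    stringsAsFactors = FALSE
  )
  entities$aliases <- lapply(ent, `[[`, "aliases")
  entities$pubchem_ids <- lapply(ent, `[[`, "pubchem_ids")
  entities$cas_ids <- lapply(ent, `[[`, "cas_ids")
  list(entities = entities, row_map = row_map)
}

#' Read a GMT gene-set collection
#'
#' Each line holds a set name, a description, and one or more member genes,
#' tab-separated. Gene symbols are upper-cased and whitespace-stripped;
#' no alias or orthology mapping is attempted.
#'
#' @param path Path to a GMT file.
#' @return Named list of character vectors (gene sets); set descriptions are
#'   kept in the \code{"descriptions"} attribute.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 3L)
  if (length(bad))
    stop("malformed GMT line(s) (fewer than 3 tab-separated fields) at line(s): ",
         paste(bad, collapse = ", "))
  sets <- lapply(parts, function(p) unique(toupper(trimws(p[-(1:2)]))))
  names(sets) <- vapply(parts, `[[`, character(1), 1L)
  if (anyDuplicated(names(sets)))
    stop("duplicated gene-set names in GMT: ",
         paste(unique(names(sets)[duplicated(names(sets))]), collapse = ", "))
  attr(sets, "descriptions") <-
    stats::setNames(vapply(parts, `[[`, character(1), 2L), names(sets))
  sets
}

#' Write a GMT gene-set collection
#'
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @param descriptions Optional named character vector of set descriptions;
#'   defaults to the \code{"descriptions"} attribute of \code{sets} or "na".
#' @export
write_gmt <- function(sets, path, descriptions = attr(sets, "descriptions")) {
  if (is.null(descriptions)) descriptions <- stats::setNames(
    rep("na", length(sets)), names(sets))
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, descriptions[[nm]], sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a normalized expression matrix
#'
#' Expects a tab-separated file whose first column holds gene identifiers and
#' whose remaining columns hold per-sample values (already normalized, log
#' scale). Duplicated gene identifiers are rejected rather than collapsed.
#'
#' @param path Path to the TSV file.
#' @return Numeric matrix, genes in rows (upper-cased), samples in columns.
#' @export
read_expression <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("expression table needs a gene column plus >=1 sample")
  genes <- toupper(trimws(as.character(df[[1L]])))
  dup <- unique(genes[duplicated(genes)])
  if (length(dup))
    stop("duplicated gene IDs in expression matrix: ",
         paste(dup, collapse = ", "))
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- genes
  m
}

#' Write an expression matrix as TSV
#' @param mat Numeric matrix with gene rownames.
#' @param path Output path.
#' @export
write_expression <- function(mat, path) {
  df <- data.frame(gene = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample-to-component map
#'
#' @param path TSV with columns \code{sample_id}, \code{component_id},
#'   \code{class}.
#' @return Data frame of the same three columns.
#' @export
read_sample_map <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "component_id", "class")
  if (!all(need %in% names(df)))
    stop("sample map must have columns: ", paste(need, collapse = ", "))
  df[need]
}

catalog_files <- c(
  herb_property_a = "herb_property_a.tsv",
  herb_property_b = "herb_property_b.tsv",
  herb_ingredient = "herb_ingredient.tsv",
  ingredient_target = "ingredient_target.tsv"
)

#' Read a herb catalog from a directory of TSV tables
#'
#' A catalog mirrors the exports of two herb-property databases: two
#' herb-property tables (\code{herb_id}, \code{label}), one herb-ingredient
#' table with synonym keys (\code{herb_id}, \code{alias}, \code{pubchem_id},
#' \code{cas_id}), and one ingredient-target table (\code{canonical_id},
#' \code{gene_symbol}). An ingredient with no target rows is a legitimate
#' state ("target information unavailable"), distinct from absence from the
#' catalog.
#'
#' @param dir Directory holding \code{herb_property_a.tsv},
#'   \code{herb_property_b.tsv}, \code{herb_ingredient.tsv},
#'   \code{ingredient_target.tsv}.
#' @return A list of the four data frames, class \code{herb_catalog}.
#' @export
read_catalog <- function(dir) {
  paths <- file.path(dir, catalog_files)
  missing <- !file.exists(paths)
  if (any(missing))
    stop("missing catalog file(s): ", paste(paths[missing], collapse = ", "))
  cat <- lapply(paths, function(p)
    utils::read.delim(p, stringsAsFactors = FALSE,
                      colClasses = "character", na.strings = c("NA", "")))
  names(cat) <- names(catalog_files)
  cat$ingredient_target$gene_symbol <-
    toupper(trimws(cat$ingredient_target$gene_symbol))
  class(cat) <- "herb_catalog"
  validate_catalog(cat)
  cat
}

#' Write a herb catalog to a directory
#' @param catalog A \code{herb_catalog} list.
#' @param dir Output directory (created if needed).
#' @export
write_catalog <- function(catalog, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(catalog_files)) {
    utils::write.table(catalog[[nm]], file.path(dir, catalog_files[[nm]]),
                       sep = "\t", quote = FALSE, row.names = FALSE, na = "")
  }
  invisible(dir)
}

#' Validate a herb catalog
#'
#' Checks the schema closure every pipeline stage relies on: non-empty herb
#' IDs, required columns, no duplicated (herb, property) rows, and at least
#' one identifying key per ingredient record. Rejects with row numbers rather
#' than silently coercing.
#'
#' @param catalog A \code{herb_catalog} list (see \code{\link{read_catalog}}).
#' @return The catalog, invisibly, if valid.
#' @export
validate_catalog <- function(catalog) {
  need <- list(
    herb_property_a = c("herb_id", "label"),
    herb_property_b = c("herb_id", "label"),
    herb_ingredient = c("herb_id", "alias", "pubchem_id", "cas_id"),
    ingredient_target = c("canonical_id", "gene_symbol")
  )
  for (nm in names(need)) {
    df <- catalog[[nm]]
    if (is.null(df)) stop("catalog lacks table: ", nm)
    miss <- setdiff(need[[nm]], names(df))
    if (length(miss))
      stop(nm, " lacks column(s): ", paste(miss, collapse = ", "))
  }
  for (nm in c("herb_property_a", "herb_property_b", "herb_ingredient")) {
    bad <- which(is.na(catalog[[nm]]$herb_id) |
                   !nzchar(trimws(catalog[[nm]]$herb_id)))
    if (length(bad))
      stop(nm, ": empty herb_id at row(s): ", paste(bad, collapse = ", "))
  }
  for (nm in c("herb_property_a", "herb_property_b")) {
    d <- which(duplicated(catalog[[nm]]$herb_id))
    if (length(d))
      stop(nm, ": duplicated herb_id at row(s): ", paste(d, collapse = ", "))
  }
  hi <- catalog$herb_ingredient
  nokey <- which(
    (is.na(hi$alias) | !nzchar(trimws(hi$alias))) &
    (is.na(hi$pubchem_id) | !nzchar(trimws(hi$pubchem_id))) &
    (is.na(hi$cas_id) | !nzchar(trimws(hi$cas_id))))
  if (length(nokey))
    stop("herb_ingredient: record with no identifying key at row(s): ",
         paste(nokey, collapse = ", "))
  invisible(catalog)
}

#' Canonicalize a catalog's ingredient records
#'
#' Merges ingredient synonym records into canonical entities and rewrites the
#' herb-ingredient table to deduplicated (\code{herb_id},
#' \code{canonical_id}) pairs; the ingredient-target table is remapped
#' through the alias-to-canonical map so both tables use the same entity IDs.
#'
#' @param catalog A validated \code{herb_catalog}.
#' @return The catalog with \code{herb_ingredient} replaced by canonical
#'   pairs, target IDs remapped, and the entity table attached as
#'   \code{$entities}.
#' @export
canonicalize_ingredients <- function(catalog) {
  merged <- merge_ingredient_synonyms(
    catalog$herb_ingredient[c("alias", "pubchem_id", "cas_id")])
  pairs <- unique(data.frame(
    herb_id = catalog$herb_ingredient$herb_id,
    canonical_id = merged$row_map,
    stringsAsFactors = FALSE
  ))
  # an alias used as a target key may itself be non-canonical
  alias_to_canon <- stats::setNames(
    rep(merged$entities$canonical_id, lengths(merged$entities$aliases)),
    unlist(merged$entities$aliases)
  )
  tg <- catalog$ingredient_target
  hit <- tg$canonical_id %in% names(alias_to_canon)
  tg$canonical_id[hit] <- alias_to_canon[tg$canonical_id[hit]]
  tg <- unique(tg)
  catalog$herb_ingredient <- pairs[order(pairs$herb_id, pairs$canonical_id), ,
                                   drop = FALSE]
  rownames(catalog$herb_ingredient) <- NULL
  catalog$ingredient_target <- tg
  catalog$entities <- merged$entities
  catalog
}

#' Ingredient-to-target map
#'
#' @param catalog A canonicalized catalog.
#' @param ingredient_ids Optional subset of canonical ingredient IDs; IDs not
#'   present in the target table get an explicit empty set (target
#'   information unavailable).
#' @return Named list mapping canonical ingredient ID to a character vector
#'   of target gene symbols (possibly empty).
#' @export
target_map <- function(catalog, ingredient_ids = NULL) {
  tg <- catalog$ingredient_target
  m <- split(tg$gene_symbol, tg$canonical_id)
  m <- lapply(m, function(g) sort(unique(toupper(trimws(g)))))
  if (!is.null(ingredient_ids)) {
    out <- stats::setNames(
      lapply(ingredient_ids, function(i) m[[i]] %||% character(0)),
      ingredient_ids)
    return(out)
  }
  m
}

`%||%` <- function(a, b) if (is.null(a)) b else a
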