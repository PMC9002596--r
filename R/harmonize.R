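#' Integrate two herb-property annotations
#'
#' Herbs present in both property tables are harmonized: a pair with equal
#' levels is an \emph{exact} match; a pair on the same side of the scale
#' (both hot or both cold) at different strengths is a \emph{similar} match
#' and resolves to the level of smaller magnitude (the milder of the two
#' annotations); anything else -- opposite sides, or one even and one not --
#' is \emph{discordant} and carries no resolved level. Herbs found in only
#' one table are reported separately and excluded from analysis by default.
#'
#' @param prop_a,prop_b Data frames with columns \code{herb_id},
#'   \code{label}. Duplicate herb IDs within one table are rejected.
#' @param synonyms Property-label synonym table.
#' @param include_single_db If \code{TRUE}, herbs present in only one table
#'   are kept at their single annotation (match class \code{single_db}).
#' @return A list with \code{herbs} (data frame: \code{herb_id},
#'   \code{level_a}, \code{level_b}, \code{match_class},
#'   \code{resolved_level}), \code{summary} (counts: common, exact, similar,
#'   discordant, analyzed, single_db), and \code{single_db} (the herbs seen
#'   in one table only).
#' @export
integrate_annotations <- function(prop_a, prop_b,
                                  synonyms = default_property_synonyms(),
                                  include_single_db = FALSE) {
  for (tab in list(a = prop_a, b = prop_b)) {
    if (!all(c("herb_id", "label") %in% names(tab)))
      stop("property tables need columns herb_id, label")
  }
  if (anyDuplicated(prop_a$herb_id))
    stop("duplicated herb_id in table A: ",
         paste(unique(prop_a$herb_id[duplicated(prop_a$herb_id)]),
               collapse = ", "))
  if (anyDuplicated(prop_b$herb_id))
    stop("duplicated herb_id in table B: ",
         paste(unique(prop_b$herb_id[duplicated(prop_b$herb_id)]),
               collapse = ", "))
  la <- parse_property_label(prop_a$label, synonyms)
  lb <- parse_property_label(prop_b$label, synonyms)
  common <- intersect(prop_a$herb_id, prop_b$herb_id)
  ia <- match(common, prop_a$herb_id)
  ib <- match(common, prop_b$herb_id)
  a <- la[ia]; b <- lb[ib]
  match_class <- ifelse(a == b, "exact",
                  ifelse(sign(a) == sign(b) & a != 0L, "similar",
                         "discordant"))
  resolved <- ifelse(match_class == "exact", a,
               ifelse(match_class == "similar",
                      ifelse(abs(a) <= abs(b), a, b), NA_integer_))
  herbs <- data.frame(
    herb_id = common,
    level_a = a, level_b = b,
    match_class = match_class,
    resolved_level = as.integer(resolved),
    stringsAsFactors = FALSE
  )
  only_a <- setdiff(prop_a$herb_id, common)
  only_b <- setdiff(prop_b$herb_id, common)
  single <- data.frame(
    herb_id = c(only_a, only_b),
    source = rep(c("A", "B"), c(length(only_a), length(only_b))),
    level = c(la[match(only_a, prop_a$herb_id)],
              lb[match(only_b, prop_b$herb_id)]),
    stringsAsFactors = FALSE
  )
  if (include_single_db && nrow(single)) {
    herbs <- rbind(herbs, data.frame(
      herb_id = single$herb_id,
      level_a = ifelse(single$source == "A", single$level, NA_integer_),
      level_b = ifelse(single$source == "B", single$level, NA_integer_),
      match_class = "single_db",
      resolved_level = single$level,
      stringsAsFactors = FALSE
    ))
  }
  summary <- data.frame(
    common = length(common),
    exact = sum(match_class == "exact"),
    similar = sum(match_class == "similar"),
    discordant = sum(match_class == "discordant"),
    analyzed = sum(match_class %in% c("exact", "similar")),
    single_db = nrow(single)
  )
  list(herbs = herbs, summary = summary, single_db = single)
}

#' Default group scheme
#'
#' Levels defining the analysis groups: hot group HG = \{+3, +4\}, cold group
#' CG = \{-4, -3\}, even group EG = \{0\}, extended groups HGE = \{+1..+4\}
#' and CGE = \{-4..-1\}. Their complements within the harmonized herbs are
#' NHG (non-hot) and NCG (non-cold). The five ordered display bins are CG,
#' CGE-only (CGE minus CG), EG, HE (HGE minus HG), and HG, which partition
#' the analyzed herbs.
#'
#' @return List of integer level sets, class \code{group_scheme}.
#' @export
default_group_scheme <- function() {
  scheme <- list(hg = c(3L, 4L), cg = c(-4L, -3L), eg = 0L,
                 hge = 1:4, cge = -4:-1)
  class(scheme) <- "group_scheme"
  validate_group_scheme(scheme)
}

#' Validate a group scheme
#'
#' Enforces the containment structure the display bins rely on: HG inside
#' HGE, CG inside CGE, the extended hot and cold sets disjoint, and EG
#' disjoint from both.
#'
#' @param scheme List with integer elements \code{hg}, \code{cg}, \code{eg},
#'   \code{hge}, \code{cge}.
#' @return The scheme, invisibly classed \code{group_scheme}, if valid.
#' @export
validate_group_scheme <- function(scheme) {
  need <- c("hg", "cg", "eg", "hge", "cge")
  miss <- setdiff(need, names(scheme))
  if (length(miss)) stop("scheme lacks: ", paste(miss, collapse = ", "))
  if (!all(scheme$hg %in% scheme$hge)) stop("scheme invalid: HG must be a subset of HGE")
  if (!all(scheme$cg %in% scheme$cge)) stop("scheme invalid: CG must be a subset of CGE")
  if (length(intersect(scheme$hge, scheme$cge)))
    stop("scheme invalid: HGE and CGE must be disjoint")
  if (length(intersect(scheme$eg, union(scheme$hge, scheme$cge))))
    stop("scheme invalid: EG must be disjoint from HGE and CGE")
  class(scheme) <- "group_scheme"
  invisible(scheme)
}

#' Assign harmonized herbs to analysis groups
#'
#' Populates per-herb group memberships (HG, CG, EG, HGE, CGE and the
#' complements NHG, NCG) and the ordered display bin from the resolved
#' level. Herbs without a resolved level (discordant matches) are dropped.
#'
#' @param herbs Data frame from \code{\link{integrate_annotations}$herbs}.
#' @param scheme A \code{group_scheme}.
#' @return Data frame of analyzed herbs with logical group columns
#'   \code{HG}, \code{CG}, \code{EG}, \code{HGE}, \code{CGE}, \code{NHG},
#'   \code{NCG} and a \code{bin} factor with ordered levels
#'   \code{CG < CGE < EG < HE < HG}; group sizes in attribute
#'   \code{"group_counts"}.
#' @export
assign_groups <- function(herbs, scheme = default_group_scheme()) {
  scheme <- validate_group_scheme(scheme)
  h <- herbs[!is.na(herbs$resolved_level), , drop = FALSE]
  lv <- h$resolved_level
  uncovered <- setdiff(unique(lv), c(scheme$hge, scheme$cge, scheme$eg))
  if (length(uncovered))
    stop("resolved level(s) covered by no group in the scheme: ",
         paste(uncovered, collapse = ", "))
  h$HG <- lv %in% scheme$hg
  h$CG <- lv %in% scheme$cg
  h$EG <- lv %in% scheme$eg
  h$HGE <- lv %in% scheme$hge
  h$CGE <- lv %in% scheme$cge
  h$NHG <- !h$HGE
  h$NCG <- !h$CGE
  bin <- ifelse(h$CG, "CG",
          ifelse(h$CGE, "CGE",
           ifelse(h$EG, "EG",
            ifelse(h$HG, "HG", "HE"))))
  h$bin <- factor(bin, levels = c("CG", "CGE", "EG", "HE", "HG"))
  counts <- c(
    HG = sum(h$HG), CG = sum(h$CG), EG = sum(h$EG),
    HGE = sum(h$HGE), CGE = sum(h$CGE), NHG = sum(h$NHG), NCG = sum(h$NCG)
  )
  attr(h, "group_counts") <- counts
  rownames(h) <- NULL
  h
}
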