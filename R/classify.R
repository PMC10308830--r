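#' Class taxonomies: precedence-ordered chemical list collections
#'
#' Substances are assigned to exactly one class by matching against an
#' ordered collection of chemical lists. Precedence resolves conflicts:
#' the highest-precedence (lowest rank number) list containing a CASRN
#' wins. A broad suspect-screening list of chemicals of emerging concern
#' (CEC) sits below every named class: substances found only there are
#' labelled `"CEC-only"`, and substances on no list at all fall through to
#' `fallback_label`.
#'
#' @param lists List of [chemical_list()] objects. Missing precedence
#'   ranks are filled from list order; ranks must end up strictly ordered.
#' @param cec_list Optional [chemical_list()] of CECs (lowest precedence).
#' @param fallback_label Label for substances on no list.
#' @return An object of class `class_taxonomy`.
#' @export
class_taxonomy <- function(lists, cec_list = NULL,
                           fallback_label = "not characterized") {
  stopifnot(length(lists) > 0,
            all(vapply(lists, inherits, logical(1), "chemical_list")))
  prec <- vapply(lists, `[[`, integer(1), "precedence")
  if (anyNA(prec)) prec <- seq_along(lists)
  if (anyDuplicated(prec)) rlang::abort("precedence ranks must be unique")
  lists <- lists[order(prec)]
  for (i in seq_along(lists)) lists[[i]]$precedence <- i
  nm <- vapply(lists, `[[`, character(1), "name")
  if (anyDuplicated(nm)) rlang::abort("list names must be unique")
  names(lists) <- nm
  structure(list(lists = lists, cec_list = cec_list,
                 fallback_label = fallback_label),
            class = "class_taxonomy")
}

#' @rdname class_taxonomy
#' @param x A `class_taxonomy`.
#' @export
taxonomy_labels <- function(x) {
  c(names(x$lists),
    if (!is.null(x$cec_list)) "CEC-only",
    x$fallback_label)
}

#' Read a taxonomy from a config table
#'
#' The config is a TSV with columns `label`, `path`, `precedence` and an
#' optional `role` column marking one row `cec`; paths are resolved
#' relative to the config file.
#'
#' @param config_path Path to the taxonomy config TSV.
#' @return A [class_taxonomy()].
#' @export
read_taxonomy <- function(config_path) {
  cfg <- readr::read_tsv(config_path, col_types = readr::cols(
    label = readr::col_character(), path = readr::col_character(),
    precedence = readr::col_integer(), .default = readr::col_character()
  ), progress = FALSE)
  stopifnot(all(c("label", "path", "precedence") %in% names(cfg)))
  base <- dirname(config_path)
  is_cec <- if ("role" %in% names(cfg)) {
    !is.na(cfg$role) & tolower(cfg$role) == "cec"
  } else rep(FALSE, nrow(cfg))
  lists <- purrr::pmap(cfg[!is_cec, ], function(label, path, precedence, ...) {
    read_chemical_list(file.path(base, path), name = label,
                       precedence = precedence)
  })
  cec <- NULL
  if (any(is_cec)) {
    row <- cfg[which(is_cec)[1], ]
    cec <- read_chemical_list(file.path(base, row$path), name = row$label)
  }
  class_taxonomy(lists, cec_list = cec)
}

#' Resolve cross-list duplicates in a taxonomy
#'
#' A CASRN present on several named lists is kept only on the
#' highest-precedence one (the broad plastics-additives list, for
#' instance, is edited so bisphenols stay with the bisphenols class). The
#' collision report enumerates every moved member.
#'
#' @param taxonomy A [class_taxonomy()].
#' @return List with `taxonomy` (lists now pairwise disjoint) and
#'   `collisions`: tibble `casrn`, `kept_in`, `removed_from`.
#' @export
dedupe_lists <- function(taxonomy) {
  stopifnot(inherits(taxonomy, "class_taxonomy"))
  seen <- character()
  owner <- character()
  collisions <- list()
  for (i in seq_along(taxonomy$lists)) {
    li <- taxonomy$lists[[i]]
    dup <- li$members[li$members %in% seen]
    if (length(dup) > 0) {
      collisions[[length(collisions) + 1]] <- tibble::tibble(
        casrn = dup,
        kept_in = owner[match(dup, seen)],
        removed_from = li$name
      )
      taxonomy$lists[[i]]$members <- setdiff(li$members, dup)
    }
    new <- setdiff(li$members, seen)
    seen <- c(seen, new)
    owner <- c(owner, rep(li$name, length(new)))
  }
  list(
    taxonomy = taxonomy,
    collisions = if (length(collisions) > 0) {
      dplyr::bind_rows(collisions)
    } else {
      tibble::tibble(casrn = character(), kept_in = character(),
                     removed_from = character())
    }
  )
}

#' Assign each substance to exactly one class
#'
#' Single-label classification by precedence: a substance receives the
#' label of the highest-precedence list containing it; substances only on
#' the CEC list become `"CEC-only"`; the rest keep the fallback label.
#' The summary partitions the input exactly.
#'
#' @param x A `substance_profiles` object.
#' @param taxonomy A [class_taxonomy()].
#' @return List with `profiles` (class labels set) and `summary`
#'   (class `classification_summary`): tibble of per-label counts plus
#'   attributes `known_count` (on any named list), `cec_only_count`,
#'   `uncharacterized_count`.
#' @export
assign_classes <- function(x, taxonomy) {
  stopifnot(inherits(x, "substance_profiles"),
            inherits(taxonomy, "class_taxonomy"))
  prof <- x$profiles
  label <- rep(taxonomy$fallback_label, nrow(prof))
  for (li in rev(taxonomy$lists)) {
    label[prof$casrn %in% li$members] <- li$name
  }
  if (!is.null(taxonomy$cec_list)) {
    cec_only <- label == taxonomy$fallback_label &
      prof$casrn %in% taxonomy$cec_list$members
    label[cec_only] <- "CEC-only"
  }
  prof$class_label <- label
  x$profiles <- prof
  list(profiles = x, summary = classification_summary(prof, taxonomy))
}

#' Summarize a classification
#'
#' Recomputes the per-class counts for classified profiles, e.g. after
#' [annotate_transformation_products()] has moved TPs into their parent
#' classes.
#'
#' @param x A classified `substance_profiles` object.
#' @param taxonomy The [class_taxonomy()] used.
#' @return A `classification_summary` tibble (see [assign_classes()]).
#' @export
summarize_classification <- function(x, taxonomy) {
  stopifnot(inherits(x, "substance_profiles"))
  classification_summary(x$profiles, taxonomy)
}

classification_summary <- function(prof, taxonomy) {
  lv <- taxonomy_labels(taxonomy)
  counts <- table(factor(prof$class_label, levels = lv))
  out <- tibble::tibble(class_label = lv, n = as.integer(counts))
  structure(out,
            known_count = sum(out$n[out$class_label %in% names(taxonomy$lists)]),
            cec_only_count = sum(out$n[out$class_label == "CEC-only"]),
            uncharacterized_count =
              sum(out$n[out$class_label == taxonomy$fallback_label]),
            class = c("classification_summary", class(out)))
}

#' Annotate transformation products with their parent's class
#'
#' Environmental transformation products (TPs) are mostly absent from the
#' curated class lists; a parent-to-TP mapping assigns them their parent
#' class. A TP already classified by a named list keeps its list class
#' (list precedence beats the map); TPs picked up here are flagged
#' `tp_flag`. Map rows whose class is not in the taxonomy are skipped
#' with a warning.
#'
#' @param x A classified `substance_profiles` object.
#' @param tp_map Tibble (or TSV path) with columns `parent_casrn`,
#'   `tp_casrn`, `class`.
#' @param taxonomy The [class_taxonomy()] used for classification.
#' @return The `substance_profiles` with TP classes and flags applied.
#' @export
annotate_transformation_products <- function(x, tp_map, taxonomy) {
  stopifnot(inherits(x, "substance_profiles"))
  if (is.character(tp_map)) {
    tp_map <- readr::read_tsv(tp_map, col_types = readr::cols(
      .default = readr::col_character()), progress = FALSE)
  }
  tp_map <- tibble::as_tibble(tp_map)
  if (nrow(tp_map) == 0) return(x)
  stopifnot(all(c("parent_casrn", "tp_casrn", "class") %in% names(tp_map)))
  known <- names(taxonomy$lists)
  bad <- !tp_map$class %in% known
  if (any(bad)) {
    rlang::warn(paste0("tp_map rows with unknown class skipped: ",
                       paste(unique(tp_map$class[bad]), collapse = ", ")))
    tp_map <- tp_map[!bad, , drop = FALSE]
  }
  tp_map$tp_casrn <- casrn_canonicalize(tp_map$tp_casrn)
  prof <- x$profiles
  # only substances not already on a named list take the mapped class
  open <- prof$class_label %in% c(taxonomy$fallback_label, "CEC-only")
  idx <- match(prof$casrn, tp_map$tp_casrn)
  hit <- open & !is.na(idx)
  prof$class_label[hit] <- tp_map$class[idx[hit]]
  prof$tp_flag[hit] <- TRUE
  x$profiles <- prof
  x
}
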