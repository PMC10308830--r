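#' Earliest-year deduplication of substance reports
#'
#' Collapses a corpus to one row per substance, retaining for each CASRN
#' its earliest-year occurrence — duplicates are removed sequentially
#' starting from the earliest year, so the first-report year of every
#' substance is well defined. Output order is deterministic and depends
#' only on corpus content (first_year ascending, then canonical CASRN
#' ascending), never on record order.
#'
#' @param x A [corpus()].
#' @return Tibble with columns `casrn`, `first_year`, ordered by
#'   `(first_year, casrn)`.
#' @export
dedup_earliest <- function(x) {
  stopifnot(is_corpus(x))
  if (nrow(x) == 0) rlang::abort("corpus is empty")
  corpus_long(x) |>
    dplyr::summarise(first_year = min(.data$year), .by = "casrn") |>
    dplyr::arrange(.data$first_year, .data$casrn)
}

#' Build per-substance profiles from a corpus
#'
#' Aggregates a corpus into one profile per CASRN: first-report year,
#' per-year citation counts (complete over the corpus year range, zeros
#' included), and total count. Counts are conserved: profile totals sum
#' to the corpus total CASRN count.
#'
#' @param x A [corpus()].
#' @return An object of class `substance_profiles`: a list with
#'   \describe{
#'     \item{profiles}{tibble `casrn`, `first_year`, `total_count`,
#'       `class_label` (initially "not characterized"), `excluded_by`,
#'       `tp_flag`}
#'     \item{counts}{long tibble `casrn`, `year`, `count`, complete over
#'       the year range}
#'     \item{year_range}{integer length-2}
#'   }
#' @export
build_profiles <- function(x) {
  stopifnot(is_corpus(x))
  long <- corpus_long(x)
  yr <- year_range(x)
  counts <- long |>
    dplyr::count(.data$casrn, .data$year, name = "count") |>
    tidyr::complete(casrn = unique(long$casrn),
                    year = seq.int(yr[1], yr[2]),
                    fill = list(count = 0L))
  profiles <- counts |>
    dplyr::summarise(
      first_year = min(.data$year[.data$count > 0]),
      total_count = sum(.data$count),
      .by = "casrn"
    ) |>
    dplyr::arrange(.data$first_year, .data$casrn) |>
    dplyr::mutate(
      class_label = "not characterized",
      excluded_by = NA_character_,
      tp_flag = FALSE
    )
  structure(list(profiles = profiles, counts = counts, year_range = yr),
            class = "substance_profiles")
}

#' @export
print.substance_profiles <- function(x, ...) {
  cat(sprintf("<substance_profiles> %d substances, %d total counts, years %d-%d\n",
              nrow(x$profiles), sum(x$profiles$total_count),
              x$year_range[1], x$year_range[2]))
  print(x$profiles, ...)
  invisible(x)
}

#' Construct profiles directly from a substance table
#'
#' Convenience constructor for fixtures and screening tests where a full
#' corpus is unnecessary: takes a tibble of per-substance aggregates.
#'
#' @param profiles Tibble with at least a `casrn` column; `first_year`,
#'   `total_count`, `class_label` are filled with defaults if absent.
#' @param year_range Optional integer length-2.
#' @return A `substance_profiles` object (with an empty counts table).
#' @export
as_profiles <- function(profiles, year_range = NULL) {
  profiles <- tibble::as_tibble(profiles)
  stopifnot("casrn" %in% names(profiles))
  if (anyDuplicated(profiles$casrn)) rlang::abort("duplicated casrn in profiles")
  defaults <- list(first_year = NA_integer_, total_count = 1L,
                   class_label = "not characterized",
                   excluded_by = NA_character_, tp_flag = FALSE)
  for (nm in names(defaults)) {
    if (!nm %in% names(profiles)) profiles[[nm]] <- defaults[[nm]]
  }
  structure(list(profiles = profiles,
                 counts = tibble::tibble(casrn = character(),
                                         year = integer(), count = integer()),
                 year_range = year_range %||%
                   suppressWarnings(range(profiles$first_year, na.rm = TRUE))),
            class = "substance_profiles")
}

#' Exclusion rule sets
#'
#' The screening step that trims the raw substance list to analysis-ready
#' substances is declarative: categories are ordered (name, CASRN set)
#' pairs read from files, and a whitelist exempts well-known water
#' pollutants (perchlorate, nitrate, phosphate, sulfate, cyanide ion in
#' the canonical use) from every category. A substance matching several
#' categories is counted once, under the first matching category in rule
#' order.
#'
#' @param categories Named list of character vectors of CASRNs (order =
#'   precedence), or a list of [chemical_list()] objects.
#' @param whitelist Character vector of CASRNs exempt from all categories.
#' @return An object of class `exclusion_ruleset`.
#' @export
exclusion_ruleset <- function(categories = list(), whitelist = character()) {
  if (length(categories) > 0 && inherits(categories[[1]], "chemical_list")) {
    nm <- vapply(categories, `[[`, character(1), "name")
    categories <- stats::setNames(lapply(categories, `[[`, "members"), nm)
  }
  if (length(categories) > 0 &&
      (is.null(names(categories)) || anyDuplicated(names(categories)))) {
    rlang::abort("exclusion categories must have unique names")
  }
  categories <- lapply(categories, casrn_canonicalize)
  structure(list(categories = categories,
                 whitelist = casrn_canonicalize(whitelist)),
            class = "exclusion_ruleset")
}

#' Read exclusion categories and whitelist from files
#'
#' Either one TSV per category (columns `casrn`, optional `name`) with the
#' category named after the file, or a combined TSV with columns `casrn`,
#' `category` (category precedence = first appearance order).
#'
#' @param paths Character vector of category file paths, or a single
#'   combined file with a `category` column.
#' @param whitelist_path Optional flat CASRN file.
#' @return An [exclusion_ruleset()].
#' @export
read_exclusion_rules <- function(paths, whitelist_path = NULL) {
  cats <- list()
  for (p in paths) {
    parsed <- read_casrn_table(p)
    if ("category" %in% names(parsed$table)) {
      for (cat in unique(parsed$table$category)) {
        cats[[cat]] <- c(cats[[cat]],
                         parsed$table$casrn[parsed$table$category == cat])
      }
    } else {
      cats[[file_stem(p)]] <- parsed$table$casrn
    }
  }
  wl <- character()
  if (!is.null(whitelist_path)) {
    wl <- read_casrn_table(whitelist_path)$table$casrn
  }
  exclusion_ruleset(cats, wl)
}

#' Apply an exclusion screen to substance profiles
#'
#' Removes substances matching any exclusion category, except whitelist
#' members, which are always kept. Each removed substance is tagged
#' `excluded_by` with its first matching category. The attached
#' `screening_report` satisfies `input = kept + removed` and
#' `removed = sum(removed_by_category)` exactly.
#'
#' @param x A `substance_profiles` object.
#' @param ruleset An [exclusion_ruleset()].
#' @return List with `kept` (a `substance_profiles`), `removed` (tibble of
#'   removed profiles with `excluded_by` set), and `report` (class
#'   `screening_report`: `input_count`, `removed_total`,
#'   `removed_by_category`, `kept_count`).
#' @export
apply_exclusions <- function(x, ruleset) {
  stopifnot(inherits(x, "substance_profiles"),
            inherits(ruleset, "exclusion_ruleset"))
  prof <- x$profiles
  excluded_by <- rep(NA_character_, nrow(prof))
  for (cat in names(ruleset$categories)) {
    hit <- is.na(excluded_by) & prof$casrn %in% ruleset$categories[[cat]]
    excluded_by[hit] <- cat
  }
  excluded_by[prof$casrn %in% ruleset$whitelist] <- NA_character_
  removed <- prof[!is.na(excluded_by), , drop = FALSE]
  removed$excluded_by <- excluded_by[!is.na(excluded_by)]
  kept <- x
  kept$profiles <- prof[is.na(excluded_by), , drop = FALSE]
  kept$counts <- x$counts[x$counts$casrn %in% kept$profiles$casrn, , drop = FALSE]
  by_cat <- table(factor(removed$excluded_by, levels = names(ruleset$categories)))
  report <- structure(list(
    input_count = nrow(prof),
    removed_total = nrow(removed),
    removed_by_category = stats::setNames(as.integer(by_cat), names(by_cat)),
    kept_count = nrow(kept$profiles)
  ), class = "screening_report")
  list(kept = kept, removed = removed, report = report)
}

#' @export
print.screening_report <- function(x, ...) {
  cat(sprintf("<screening_report> input %d = kept %d + removed %d\n",
              x$input_count, x$kept_count, x$removed_total))
  if (length(x$removed_by_category) > 0) {
    for (nm in names(x$removed_by_category)) {
      cat(sprintf("  %-30s %d\n", nm, x$removed_by_category[[nm]]))
    }
  }
  invisible(x)
}

#' Screen out food constituents
#'
#' Natural food constituents (sugars, common dietary compounds) inflate
#' occurrence counts without being environmental contaminants. This screen
#' behaves as one more exclusion category named after the food list and is
#' composable with [apply_exclusions()]: whitelisted substances survive it.
#'
#' @param x A `substance_profiles` object.
#' @param food_list A [chemical_list()] of food-constituent CASRNs.
#' @param whitelist Character vector of CASRNs exempt from removal.
#' @return Same shape as [apply_exclusions()].
#' @export
food_constituent_screen <- function(x, food_list, whitelist = character()) {
  rs <- exclusion_ruleset(
    stats::setNames(list(food_list$members), food_list$name),
    whitelist = whitelist
  )
  apply_exclusions(x, rs)
}

#' Emit a screening report as a tibble (for TSV export)
#'
#' @param report A `screening_report`.
#' @return Tibble with columns `category`, `removed`.
#' @export
screening_report_table <- function(report) {
  tibble::tibble(
    category = c(names(report$removed_by_category), "(kept)", "(input)"),
    removed = c(as.integer(report$removed_by_category),
                report$kept_count, report$input_count)
  )
}
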