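#' Read a citation corpus from delimited text
#'
#' The on-disk contract is a TSV/CSV with a header naming the columns
#' `record_id`, `year`, `roles`, `casrns`; the `roles` and `casrns` cells
#' hold within-cell `cell_sep`-delimited lists. Every CASRN token is
#' validated (pattern + check digit); invalid tokens are dropped and
#' tallied in the ingest report, never silently. Rows with an unparseable
#' year, or a year outside `year_window`, are rejected and tallied. A
#' duplicated `record_id` is a hard error naming the id. Record order is
#' preserved.
#'
#' @param path Path to the delimited file.
#' @param delim Field delimiter (default tab).
#' @param cell_sep Within-cell delimiter for roles and CASRNs (default ";").
#' @param year_window Two integers; records outside are rejected at ingest.
#' @return A [corpus()] with an `ingest_report` attribute: a list with
#'   `rows_read`, `rows_rejected_year`, `records_kept`,
#'   `casrns_dropped_malformed`, `casrns_dropped_checksum`,
#'   `records_dropped_empty` (rows whose every CASRN failed validation).
#' @export
read_corpus <- function(path, delim = "\t", cell_sep = ";",
                        year_window = c(1900L, default_max_year())) {
  raw <- readr::read_delim(path, delim = delim, col_types = readr::cols(
    .default = readr::col_character()
  ), progress = FALSE)
  required <- c("record_id", "year", "roles", "casrns")
  missing <- setdiff(required, names(raw))
  if (length(missing) > 0) {
    rlang::abort(paste0("corpus file lacks required column(s): ",
                        paste(missing, collapse = ", ")))
  }
  dup <- raw$record_id[duplicated(raw$record_id)]
  if (length(dup) > 0) {
    rlang::abort(paste0("duplicated record_id: ",
                        paste(unique(dup), collapse = ", ")))
  }
  rows_read <- nrow(raw)
  year <- suppressWarnings(as.integer(raw$year))
  ok_year <- !is.na(year) & year >= year_window[1] & year <= year_window[2]
  rows_rejected_year <- sum(!ok_year)
  raw <- raw[ok_year, , drop = FALSE]
  year <- year[ok_year]

  roles <- stringr::str_split(dplyr::coalesce(raw$roles, ""), stringr::fixed(cell_sep))
  roles <- purrr::map(roles, ~ stringr::str_trim(.x)[nzchar(stringr::str_trim(.x))])
  tokens <- stringr::str_split(dplyr::coalesce(raw$casrns, ""), stringr::fixed(cell_sep))
  tokens <- purrr::map(tokens, ~ stringr::str_trim(.x)[nzchar(stringr::str_trim(.x))])

  val <- validate_casrn(unlist(tokens, use.names = FALSE))
  split_idx <- rep(seq_along(tokens), lengths(tokens))
  kept <- split(val$casrn[val$valid], split_idx[val$valid])
  casrns <- vector("list", length(tokens))
  casrns[as.integer(names(kept))] <- lapply(kept, unique)
  casrns[vapply(casrns, is.null, logical(1))] <- list(character(0))

  nonempty <- lengths(casrns) > 0
  out <- corpus(tibble::tibble(
    record_id = raw$record_id[nonempty],
    year = year[nonempty],
    roles = roles[nonempty],
    casrns = casrns[nonempty]
  ))
  attr(out, "ingest_report") <- list(
    rows_read = rows_read,
    rows_rejected_year = rows_rejected_year,
    records_kept = sum(nonempty),
    records_dropped_empty = sum(!nonempty),
    casrns_dropped_malformed = sum(val$reason == "malformed"),
    casrns_dropped_checksum = sum(val$reason == "checksum")
  )
  out
}

#' @rdname read_corpus
#' @param x A `bib_corpus`.
#' @export
ingest_report <- function(x) attr(x, "ingest_report")

#' Write a corpus to delimited text
#'
#' Inverse of [read_corpus()]: `read_corpus(write_corpus(x, f))` is the
#' identity on canonical corpora. Output is UTF-8 with LF line endings.
#'
#' @inheritParams read_corpus
#' @param x A `bib_corpus`.
#' @return `path`, invisibly.
#' @export
write_corpus <- function(x, path, delim = "\t", cell_sep = ";") {
  stopifnot(is_corpus(x))
  flat <- tibble::tibble(
    record_id = x$record_id,
    year = x$year,
    roles = vapply(x$roles, paste, character(1), collapse = cell_sep),
    casrns = vapply(x$casrns, paste, character(1), collapse = cell_sep)
  )
  readr::write_delim(flat, path, delim = delim)
  invisible(path)
}

default_max_year <- function() as.integer(format(Sys.Date(), "%Y"))

#' Named CASRN sets: chemical class lists and inventories
#'
#' A chemical list is a named set of canonical CASRNs with a class tag
#' (e.g. "pharmaceutical") and a precedence rank used by the classifier.
#' An inventory is a named CASRN set with a `declared_size`: the official
#' size of the real inventory, which may exceed the members shipped in a
#' fixture file — coverage percentages always use `declared_size`.
#'
#' @param name List name.
#' @param members Character vector of CASRNs (validated; invalid entries
#'   are an error here, but tallied-and-dropped by the file readers).
#' @param category Class tag.
#' @param precedence Integer rank; lower ranks win classification conflicts.
#' @return `chemical_list()`: an object of class `chemical_list`.
#' @export
chemical_list <- function(name, members, category = name, precedence = NA_integer_) {
  members <- unique(members)
  bad <- members[!casrn_is_valid(members)]
  if (length(bad) > 0) {
    rlang::abort(paste0("invalid CASRN(s) in list '", name, "': ",
                        paste(utils::head(bad, 5), collapse = ", ")))
  }
  structure(
    list(name = name, members = casrn_canonicalize(members),
         category = category, precedence = as.integer(precedence)),
    class = "chemical_list"
  )
}

#' @rdname chemical_list
#' @param declared_size Declared (real) inventory size; must be at least
#'   the number of members.
#' @return `inventory()`: an object of class `inventory`.
#' @export
inventory <- function(name, members, declared_size = length(unique(members))) {
  members <- unique(members)
  bad <- members[!casrn_is_valid(members)]
  if (length(bad) > 0) {
    rlang::abort(paste0("invalid CASRN(s) in inventory '", name, "': ",
                        paste(utils::head(bad, 5), collapse = ", ")))
  }
  declared_size <- as.integer(declared_size)
  if (declared_size < length(members)) {
    rlang::abort(sprintf(
      "inventory '%s': declared_size (%d) below member count (%d)",
      name, declared_size, length(members)))
  }
  structure(
    list(name = name, members = casrn_canonicalize(members),
         declared_size = declared_size),
    class = "inventory"
  )
}

# Shared reader for newline-delimited CASRN files with optional
# name/category columns. Header comments of the form '#key=value' are
# parsed into metadata; invalid CASRNs are tallied and dropped,
# duplicates collapsed. Empty file -> error.
read_casrn_table <- function(path) {
  lines <- readr::read_lines(path)
  meta_lines <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (m in meta_lines) {
    kv <- stringr::str_match(m, "^#\\s*([A-Za-z_]+)\\s*=\\s*(.+)$")
    if (!is.na(kv[1, 1])) meta[[kv[1, 2]]] <- stringr::str_trim(kv[1, 3])
  }
  body <- lines[!grepl("^#", lines)]
  body <- body[nzchar(stringr::str_trim(body))]
  if (length(body) == 0) rlang::abort(paste0("empty CASRN file: ", path))
  tab <- readr::read_tsv(I(paste(body, collapse = "\n")),
                         col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  if (!"casrn" %in% names(tab)) {
    # headerless single-column file: treat the first column as casrn
    tab <- readr::read_tsv(I(paste(body, collapse = "\n")),
                           col_names = "casrn",
                           col_types = readr::cols(.default = readr::col_character()),
                           progress = FALSE)
  }
  val <- validate_casrn(tab$casrn)
  kept <- tab[val$valid, , drop = FALSE] |>
    dplyr::mutate(casrn = val$casrn[val$valid])
  # a combined category file may legitimately list one CASRN under two
  # categories; collapse duplicates within, not across, categories
  kept <- if ("category" %in% names(kept)) {
    dplyr::distinct(kept, .data$casrn, .data$category, .keep_all = TRUE)
  } else {
    dplyr::distinct(kept, .data$casrn, .keep_all = TRUE)
  }
  list(
    table = kept,
    dropped = sum(!val$valid),
    meta = meta
  )
}

#' Read a chemical class list or inventory file
#'
#' File contract: TSV with a `casrn` column and optional `name` /
#' `category` columns; a headerless file is read as a flat CASRN list.
#' `#declared_size=N` in a header comment sets an inventory's declared
#' size. Invalid CASRNs are dropped and tallied (see the `dropped`
#' attribute); duplicate members are collapsed.
#'
#' @param path File path.
#' @param name List/inventory name; defaults to the file stem.
#' @param category,precedence Passed to [chemical_list()].
#' @return A [chemical_list()] (or [inventory()]) with a `dropped`
#'   attribute counting invalid lines.
#' @export
read_chemical_list <- function(path, name = file_stem(path),
                               category = name, precedence = NA_integer_) {
  parsed <- read_casrn_table(path)
  out <- chemical_list(name, parsed$table$casrn, category = category,
                       precedence = precedence)
  attr(out, "dropped") <- parsed$dropped
  out
}

#' @rdname read_chemical_list
#' @param declared_size Overrides any `#declared_size=` header.
#' @export
read_inventory <- function(path, name = file_stem(path), declared_size = NULL) {
  parsed <- read_casrn_table(path)
  if (is.null(declared_size)) {
    declared_size <- if (!is.null(parsed$meta$declared_size)) {
      as.integer(parsed$meta$declared_size)
    } else {
      nrow(parsed$table)
    }
  }
  out <- inventory(name, parsed$table$casrn, declared_size = declared_size)
  attr(out, "dropped") <- parsed$dropped
  out
}

file_stem <- function(path) tools::file_path_sans_ext(basename(path))
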