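#' Citation corpus objects
#'
#' A corpus is the unit of analysis: one row per literature record, each
#' carrying a publication year, a set of indexing roles (free strings such
#' as `ANST`, `POL`, `BIOL`; matched case-insensitively), and the set of
#' CASRNs the record reports. The corpus "total counts" figure used as the
#' denominator throughout the analysis is the sum over records of the
#' number of CASRNs per record (one record reporting many substances
#' contributes once per substance).
#'
#' @param records A tibble with columns `record_id` (character), `year`
#'   (integer), `roles` (list of character vectors), `casrns` (list of
#'   character vectors of canonical CASRNs).
#' @return An object of class `bib_corpus`: the records tibble with a
#'   `year_range` attribute.
#' @export
corpus <- function(records) {
  records <- tibble::as_tibble(records)
  required <- c("record_id", "year", "roles", "casrns")
  missing <- setdiff(required, names(records))
  if (length(missing) > 0) {
    rlang::abort(paste0("corpus records lack column(s): ",
                        paste(missing, collapse = ", ")))
  }
  dup <- records$record_id[duplicated(records$record_id)]
  if (length(dup) > 0) {
    rlang::abort(paste0("duplicated record_id: ",
                        paste(unique(dup), collapse = ", ")))
  }
  if (any(lengths(records$casrns) == 0)) {
    rlang::abort("every record must report at least one CASRN")
  }
  records$year <- as.integer(records$year)
  yr <- if (nrow(records) > 0) range(records$year) else
    c(NA_integer_, NA_integer_)
  structure(records,
            year_range = yr,
            class = c("bib_corpus", class(records)))
}

#' @rdname corpus
#' @param x A `bib_corpus`.
#' @export
is_corpus <- function(x) inherits(x, "bib_corpus")

#' @rdname corpus
#' @export
year_range <- function(x) attr(x, "year_range")

#' Total CASRN count of a corpus
#'
#' Sum over records of the number of CASRNs reported — the denominator the
#' concentration and share statistics use.
#'
#' @param x A `bib_corpus`.
#' @return Integer scalar.
#' @export
total_counts <- function(x) {
  stopifnot(is_corpus(x))
  sum(lengths(x$casrns))
}

#' Long (record, year, casrn) view of a corpus
#'
#' @param x A `bib_corpus`.
#' @return Tibble with columns `record_id`, `year`, `casrn`.
#' @export
corpus_long <- function(x) {
  stopifnot(is_corpus(x))
  tibble::tibble(
    record_id = rep(x$record_id, lengths(x$casrns)),
    year = rep(x$year, lengths(x$casrns)),
    casrn = unlist(x$casrns, use.names = FALSE)
  )
}

#' @export
print.bib_corpus <- function(x, ...) {
  yr <- year_range(x)
  cat(sprintf("<bib_corpus> %d records, %d CASRN counts, years %d-%d\n",
              nrow(x), total_counts(x), yr[1], yr[2]))
  NextMethod()
}

#' Filter a corpus by indexing roles
#'
#' Retains records whose role set satisfies the requirement: under
#' `mode = "all"` every required role must be present, under `mode = "any"`
#' at least one. Roles are compared case-insensitively after trimming.
#' An empty requirement retains every record. Required roles absent from
#' the corpus vocabulary trigger a warning, not an error — the role
#' vocabulary is open.
#'
#' @param x A `bib_corpus`.
#' @param required Character vector of role codes.
#' @param mode `"all"` or `"any"`.
#' @return A filtered `bib_corpus`.
#' @examples
#' # records indexed both as analytical study and pollutant:
#' # filter_by_roles(corp, c("ANST", "POL"), mode = "all")
#' @export
filter_by_roles <- function(x, required, mode = c("all", "any")) {
  stopifnot(is_corpus(x))
  mode <- match.arg(mode)
  req <- toupper(stringr::str_trim(required))
  if (length(req) == 0) return(x)
  vocab <- toupper(unique(unlist(x$roles, use.names = FALSE)))
  unknown <- setdiff(req, vocab)
  if (length(unknown) > 0) {
    rlang::warn(paste0("role code(s) not in corpus vocabulary: ",
                       paste(unknown, collapse = ", ")))
  }
  keep <- vapply(x$roles, function(r) {
    r <- toupper(stringr::str_trim(r))
    if (mode == "all") all(req %in% r) else any(req %in% r)
  }, logical(1))
  corpus(x[keep, , drop = FALSE])
}
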