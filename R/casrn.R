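#' CAS Registry Number validation and canonicalization
#'
#' A CAS Registry Number (CASRN) is a hyphenated identifier of the form
#' `NNNNNNN-NN-R`: a first group of two to seven digits, a second group of
#' two digits, and a single check digit. The check digit is the weighted sum
#' of all other digits, numbered 1, 2, 3, ... from the digit immediately left
#' of the check digit towards the left, taken modulo 10. For example, for
#' 1746-01-6 the sum is 1*1 + 0*2 + 6*3 + 4*4 + 7*5 + 1*6 = 76 and
#' 76 mod 10 = 6.
#'
#' CASRNs are identifiers, not numbers: the package stores them canonically
#' *with* hyphens and compares them by string equality on the canonical form.
#' Canonicalization trims whitespace and strips leading zeros from the first
#' digit group (keeping at least two digits); it is idempotent.
#'
#' @param x Character vector of raw tokens.
#' @return `validate_casrn()` returns a tibble with one row per input token
#'   and columns `input`, `casrn` (canonical form, `NA` when invalid),
#'   `valid` (logical), and `reason` (`"ok"`, `"malformed"`, or
#'   `"checksum"`). Failures are returned values, never conditions, so
#'   corpus readers can tally them.
#' @examples
#' validate_casrn(c("1746-01-6", "50-00-0", "50-00-1", "ABC-12-3"))
#' @export
validate_casrn <- function(x) {
  stopifnot(is.character(x))
  canon <- casrn_canonicalize(x)
  malformed <- is.na(canon)
  ok_sum <- rep(FALSE, length(x))
  ok_sum[!malformed] <- vapply(
    canon[!malformed], casrn_checksum_ok, logical(1),
    USE.NAMES = FALSE
  )
  reason <- dplyr::case_when(
    malformed ~ "malformed",
    !ok_sum ~ "checksum",
    TRUE ~ "ok"
  )
  tibble::tibble(
    input = x,
    casrn = ifelse(reason == "ok", canon, NA_character_),
    valid = reason == "ok",
    reason = reason
  )
}

#' @rdname validate_casrn
#' @return `casrn_is_valid()` returns a logical vector.
#' @export
casrn_is_valid <- function(x) {
  validate_casrn(x)$valid
}

#' @rdname validate_casrn
#' @return `casrn_canonicalize()` returns the canonical rendering (or `NA`
#'   where the token does not match the CASRN pattern). It does not check
#'   the checksum.
#' @export
casrn_canonicalize <- function(x) {
  x <- stringr::str_trim(x)
  ok <- stringr::str_detect(x, "^\\d{2,7}-\\d{2}-\\d$")
  out <- rep(NA_character_, length(x))
  if (any(ok, na.rm = TRUE)) {
    idx <- which(ok)
    parts <- stringr::str_split_fixed(x[idx], "-", 3)
    first <- stringr::str_remove(parts[, 1], "^0+(?=\\d{2})")
    out[idx] <- paste(first, parts[, 2], parts[, 3], sep = "-")
  }
  out
}

# Weighted mod-10 checksum on a canonical "b-b-c" string.
# Weight 1 at the rightmost non-check digit, increasing leftwards.
casrn_checksum_ok <- function(casrn) {
  digits <- as.integer(strsplit(gsub("-", "", casrn), "")[[1]])
  n <- length(digits)
  check <- digits[n]
  body <- digits[-n]
  weights <- seq.int(length(body), 1L)
  (sum(body * weights) %% 10L) == check
}

#' Construct a CASRN from its digit body
#'
#' Computes the mod-10 check digit for a digit body (first two groups,
#' without hyphens or check digit) and renders the canonical hyphenated
#' CASRN. Used by the synthetic corpus generator and in tests.
#'
#' @param body Character vector of 4-9 digit strings; the last two digits
#'   become the middle group.
#' @return Character vector of canonical CASRNs.
#' @examples
#' casrn_from_body("174601") # "1746-01-6"
#' @export
casrn_from_body <- function(body) {
  stopifnot(all(stringr::str_detect(body, "^\\d{4,9}$")))
  vapply(body, function(b) {
    digits <- as.integer(strsplit(b, "")[[1]])
    weights <- seq.int(length(digits), 1L)
    check <- sum(digits * weights) %% 10L
    first <- substr(b, 1L, nchar(b) - 2L)
    first <- sub("^0+(?=\\d{2})", "", first, perl = TRUE)
    paste0(first, "-", substr(b, nchar(b) - 1L, nchar(b)), "-", check)
  }, character(1), USE.NAMES = FALSE)
}
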