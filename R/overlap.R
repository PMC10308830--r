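#' Drop classes before inventory comparison
#'
#' Industrial chemical inventories generally exclude pesticides and
#' pharmaceuticals (separate regulatory regimes), so those classes are
#' removed from the analysis list before computing overlap. Unknown
#' labels warn; the operation never grows the set and is idempotent.
#'
#' @param x A classified `substance_profiles` object.
#' @param excluded_classes Character vector of class labels to drop.
#' @return Character vector of remaining CASRNs, with a `removed`
#'   attribute giving the number dropped.
#' @export
reduce_for_overlap <- function(x, excluded_classes = character()) {
  stopifnot(inherits(x, "substance_profiles"))
  prof <- x$profiles
  unknown <- setdiff(excluded_classes, unique(prof$class_label))
  if (length(unknown) > 0) {
    rlang::warn(paste0("excluded class label(s) with no members: ",
                       paste(unknown, collapse = ", ")))
  }
  keep <- !prof$class_label %in% excluded_classes
  structure(prof$casrn[keep], removed = sum(!keep))
}

#' Three-set overlap with a reference list
#'
#' Computes the seven region counts of a three-inventory Venn diagram,
#' restricted to a reference universe (the analysis list): each reference
#' CASRN found in at least one inventory is assigned to its membership
#' pattern. Region counts sum to the reference-inventory union size, and
#' the per-inventory overlap is the sum of the regions containing it.
#'
#' @param reference Character vector of CASRNs (the analysis list).
#' @param inv_a,inv_b,inv_c [inventory()] objects (or CASRN vectors).
#' @return An object of class `venn_result`: list with `region_counts`
#'   (named integer vector over patterns like `"A&!B&!C"`), `union_count`,
#'   `per_set_overlap` (named by inventory), `set_names`.
#' @export
venn3 <- function(reference, inv_a, inv_b, inv_c) {
  nms <- vapply(list(inv_a, inv_b, inv_c), function(v) {
    if (inherits(v, "inventory")) v$name else NA_character_
  }, character(1))
  nms[is.na(nms)] <- c("A", "B", "C")[is.na(nms)]
  sets <- lapply(list(inv_a, inv_b, inv_c), function(v) {
    if (inherits(v, "inventory")) v$members else unique(v)
  })
  reference <- unique(reference)
  in_a <- reference %in% sets[[1]]
  in_b <- reference %in% sets[[2]]
  in_c <- reference %in% sets[[3]]
  any_set <- in_a | in_b | in_c
  pattern_names <- c("A&!B&!C", "!A&B&!C", "A&B&!C",
                     "!A&!B&C", "A&!B&C", "!A&B&C", "A&B&C")
  pat_index <- in_a + 2L * in_b + 4L * in_c # 1..7 for members of the union
  counts <- tabulate(pat_index[any_set], nbins = 7L)
  region_counts <- stats::setNames(counts, pattern_names)
  per_set <- c(sum(in_a), sum(in_b), sum(in_c))
  structure(list(
    region_counts = region_counts,
    union_count = sum(any_set),
    per_set_overlap = stats::setNames(per_set, nms),
    set_names = nms
  ), class = "venn_result")
}

#' @export
print.venn_result <- function(x, ...) {
  cat(sprintf("<venn_result> sets %s; union with reference: %d\n",
              paste(x$set_names, collapse = ", "), x$union_count))
  print(x$region_counts)
  invisible(x)
}

#' Export a Venn result as a (pattern, count) table
#'
#' Patterns use `&`/`!` notation with the letters A, B, C in the order the
#' inventories were supplied; the row order matches the conventional
#' 7-region Venn layout.
#'
#' @param x A `venn_result`.
#' @return Tibble `pattern`, `count`.
#' @export
venn_table <- function(x) {
  stopifnot(inherits(x, "venn_result"))
  tibble::tibble(pattern = names(x$region_counts),
                 count = as.integer(x$region_counts))
}

#' Inventory coverage percentage
#'
#' The fraction of an inventory's declared (real) size represented by its
#' overlap with the analysis list. Using the declared size rather than
#' the members present in a fixture file lets small fixtures reproduce
#' the published coverages exactly.
#'
#' @param overlap_count Number of inventory members on the analysis list.
#' @param inv An [inventory()].
#' @param rule A [percent_rule()].
#' @return Formatted percentage string; the numeric percentage is
#'   attached as attribute `pct`.
#' @examples
#' tsca <- inventory("TSCA", casrn_from_body("500001"), declared_size = 67950)
#' inventory_coverage(3499, tsca) # "5.1%"
#' @export
inventory_coverage <- function(overlap_count, inv, rule = percent_rule()) {
  stopifnot(inherits(inv, "inventory"))
  if (inv$declared_size <= 0) rlang::abort("declared_size must be positive")
  structure(format_percent(overlap_count / inv$declared_size, rule),
            pct = 100 * overlap_count / inv$declared_size)
}
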