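#' Percent formatting rules
#'
#' The survey's summary tables mix display precisions: shares of at least
#' 10% print as whole percentages ("34%"), smaller shares with two
#' significant figures ("0.79%", "1.1%"). Rounding is half-up (0.185 ->
#' "0.19%"), not banker's rounding. `percent_rule()` captures the rule so
#' every table in a run formats identically.
#'
#' @param integer_from Threshold (in percent) at and above which shares
#'   print as integers.
#' @param sigfigs Significant figures used below the threshold.
#' @return An object of class `percent_rule`.
#' @export
percent_rule <- function(integer_from = 10, sigfigs = 2) {
  structure(list(integer_from = integer_from, sigfigs = sigfigs),
            class = "percent_rule")
}

#' Format a fraction as a percentage string
#'
#' @param x Numeric vector of fractions (0.34 means 34%).
#' @param rule A [percent_rule()], or for fixed precision pass `decimals`.
#' @param decimals If non-NULL, round to this many decimal places in
#'   percent instead of applying `rule`.
#' @return Character vector like `"34%"`, `"0.79%"`, `"0%"`.
#' @examples
#' format_percent(0.3402)            # "34%"
#' format_percent(0.0078948)         # "0.79%"
#' format_percent(0.3402, decimals = 1) # "34.0%"
#' @export
format_percent <- function(x, rule = percent_rule(), decimals = NULL) {
  stopifnot(all(x >= 0, na.rm = TRUE))
  pct <- 100 * x
  out <- character(length(pct))
  if (!is.null(decimals)) {
    v <- round_half_up(pct, decimals)
    out <- paste0(formatC(v, format = "f", digits = decimals), "%")
  } else {
    for (i in seq_along(pct)) {
      p <- pct[i]
      if (is.na(p)) {
        out[i] <- NA_character_
      } else if (p == 0) {
        out[i] <- "0%"
      } else if (p >= rule$integer_from) {
        out[i] <- paste0(format(round_half_up(p, 0), scientific = FALSE), "%")
      } else {
        v <- signif_half_up(p, rule$sigfigs)
        # print enough decimals to show the significant figures
        dec <- max(0L, rule$sigfigs - 1L - floor(log10(abs(v))))
        out[i] <- paste0(formatC(v, format = "f", digits = dec), "%")
      }
    }
  }
  out[is.na(pct)] <- NA_character_
  out
}

# Half-up rounding: round(0.5) == 1 always (base R rounds half to even).
round_half_up <- function(x, digits = 0) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5 + sqrt(.Machine$double.eps)) / scale
}

signif_half_up <- function(x, sigfigs) {
  out <- x
  nz <- !is.na(x) & x != 0
  mag <- floor(log10(abs(x[nz])))
  out[nz] <- round_half_up(x[nz], sigfigs - 1 - mag)
  out
}

#' Annual citation counts by class
#'
#' Builds the year-by-class count matrix underlying the temporal-trend
#' panels: cell (y, c) is the number of CASRN reports in year y for
#' substances of class c. When the taxonomy partitions all substances the
#' row sums equal the corpus per-year totals (conservation).
#'
#' @param x A [corpus()].
#' @param profiles Classified `substance_profiles` for the same corpus.
#' @param labels Optional label set for the columns (e.g.
#'   [taxonomy_labels()]), so classes with no members still appear as
#'   zero columns; defaults to the labels observed in the corpus.
#' @return An object of class `trend_table`: list with `years` (integer),
#'   `counts` (year x class integer matrix), `totals_by_year`.
#' @export
annual_class_counts <- function(x, profiles, labels = NULL) {
  stopifnot(is_corpus(x), inherits(profiles, "substance_profiles"))
  long <- corpus_long(x)
  cls <- profiles$profiles$class_label[match(long$casrn, profiles$profiles$casrn)]
  cls[is.na(cls)] <- "(unclassified)"
  yr <- year_range(x)
  years <- seq.int(yr[1], yr[2])
  labels <- sort(union(labels, unique(cls)))
  counts <- table(factor(long$year, levels = years),
                  factor(cls, levels = labels))
  counts <- matrix(as.integer(counts), nrow = length(years),
                   dimnames = list(year = years, class = labels))
  structure(list(years = years, counts = counts,
                 totals_by_year = rowSums(counts)),
            class = "trend_table")
}

#' @export
print.trend_table <- function(x, ...) {
  cat(sprintf("<trend_table> years %d-%d, %d classes, %d total counts\n",
              min(x$years), max(x$years), ncol(x$counts), sum(x$counts)))
  invisible(x)
}

#' Per-year share of total reports for one class
#'
#' share(y) = 100 * counts\[y, label\] / total(y). Years with zero total
#' reports yield `NA` (undefined), not 0.
#'
#' @param trend A [annual_class_counts()] result.
#' @param label Class label present in the trend table.
#' @return Tibble `year`, `count`, `share_pct`.
#' @export
share_series <- function(trend, label) {
  stopifnot(inherits(trend, "trend_table"))
  if (!label %in% colnames(trend$counts)) {
    rlang::abort(paste0("unknown class label: ", label))
  }
  tot <- unname(trend$totals_by_year)
  cnt <- unname(trend$counts[, label])
  tibble::tibble(
    year = trend$years,
    count = cnt,
    share_pct = ifelse(tot > 0, 100 * cnt / tot, NA_real_)
  )
}

#' Long-format export of a trend table
#'
#' @param trend A `trend_table`.
#' @param rule A [percent_rule()] for the formatted share column.
#' @return Tibble `year`, `class`, `count`, `share_pct`, `share_fmt`.
#' @export
trend_table_long <- function(trend, rule = percent_rule()) {
  stopifnot(inherits(trend, "trend_table"))
  out <- as.data.frame.table(trend$counts, responseName = "count") |>
    tibble::as_tibble() |>
    dplyr::mutate(year = as.integer(as.character(.data$year)),
                  class = as.character(.data$class),
                  count = as.integer(.data$count))
  tot <- unname(trend$totals_by_year[as.character(out$year)])
  out$share_pct <- ifelse(tot > 0, 100 * out$count / tot, NA_real_)
  out$share_fmt <- format_percent(out$share_pct / 100, rule)
  out
}

#' Citation-concentration curves and top-N shares
#'
#' Repeated measurement of the same substances (the "Matthew effect")
#' is quantified by the share of total citation counts captured by the N
#' most-reported substances. The curve sorts per-substance totals in
#' descending order, breaking ties by canonical CASRN ascending so
#' results are deterministic.
#'
#' @param totals Named numeric vector of per-substance total counts
#'   (names are CASRNs), or a `substance_profiles` object.
#' @return An object of class `concentration_curve`: list with
#'   `casrn`, `sorted_totals`, `cum_share`, `grand_total`.
#' @export
concentration_curve <- function(totals) {
  if (inherits(totals, "substance_profiles")) {
    totals <- stats::setNames(totals$profiles$total_count,
                              totals$profiles$casrn)
  }
  stopifnot(is.numeric(totals), !is.null(names(totals)),
            all(totals >= 0))
  ord <- order(-totals, names(totals))
  sorted <- totals[ord]
  grand <- sum(sorted)
  structure(list(
    casrn = names(sorted),
    sorted_totals = unname(sorted),
    cum_share = if (grand > 0) cumsum(unname(sorted)) / grand else
      rep(NA_real_, length(sorted)),
    grand_total = grand
  ), class = "concentration_curve")
}

#' @rdname concentration_curve
#' @param curve A `concentration_curve`.
#' @param n Number of top substances, `1 <= n <= length(curve$casrn)`.
#' @return `top_n_share()`: the fraction of the grand total captured by
#'   the `n` most-reported substances.
#' @examples
#' cc <- concentration_curve(c(`50-00-0` = 5, `1746-01-6` = 3, `71-43-2` = 2))
#' top_n_share(cc, 2) # 0.8
#' @export
top_n_share <- function(curve, n) {
  stopifnot(inherits(curve, "concentration_curve"))
  if (n < 1 || n > length(curve$casrn)) {
    rlang::abort(sprintf("n must be in [1, %d]", length(curve$casrn)))
  }
  curve$cum_share[n]
}

#' @rdname concentration_curve
#' @param total_count,grand_total Counts for a single substance (or the
#'   printed top-N sum) and the grand total.
#' @param rule A [percent_rule()].
#' @return `substance_share()`: formatted percentage string.
#' @examples
#' substance_share(140527, 413007)   # "34%"
#' substance_share(73043, 9251975)   # "0.79%"
#' @export
substance_share <- function(total_count, grand_total, rule = percent_rule()) {
  stopifnot(grand_total > 0)
  format_percent(total_count / grand_total, rule)
}

#' Export a concentration curve as a rank table
#'
#' @param curve A `concentration_curve`.
#' @return Tibble `rank`, `casrn`, `total`, `cum_share`.
#' @export
concentration_table <- function(curve) {
  stopifnot(inherits(curve, "concentration_curve"))
  tibble::tibble(
    rank = seq_along(curve$casrn),
    casrn = curve$casrn,
    total = curve$sorted_totals,
    cum_share = curve$cum_share
  )
}

#' Newly reported substances per year
#'
#' Counts substances whose first report falls in each year, and expresses
#' them as a percentage of that year's total reports. Summed over years,
#' the new-substance counts equal the number of unique substances
#' (conservation).
#'
#' @param first_years Tibble from [dedup_earliest()] (columns `casrn`,
#'   `first_year`).
#' @param trend A `trend_table` built on the same corpus (supplies the
#'   per-year total-report denominators).
#' @return Tibble `year`, `n_new`, `pct_of_total` (NA when the year's
#'   total is zero).
#' @export
newly_reported_series <- function(first_years, trend) {
  stopifnot(inherits(trend, "trend_table"),
            all(c("casrn", "first_year") %in% names(first_years)))
  n_new <- table(factor(first_years$first_year, levels = trend$years))
  tot <- unname(trend$totals_by_year)
  tibble::tibble(
    year = trend$years,
    n_new = as.integer(n_new),
    pct_of_total = ifelse(tot > 0, 100 * as.integer(n_new) / tot, NA_real_)
  )
}
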