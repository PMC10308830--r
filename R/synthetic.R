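#' Configuration for the synthetic literature-corpus generator
#'
#' The generator emulates the statistical structure of a chemical
#' occurrence literature corpus: exponential growth in annual publication
#' volume, heavy-tailed per-substance citation counts (a Zipf popularity
#' law optionally mixed with citation-proportional preferential
#' attachment, which produces the rich-get-richer concentration the
#' analysis quantifies), staggered substance emergence years, and class
#' labels drawn from a configurable mixture.
#'
#' Defaults describe a 30-year window with publication volume growing
#' 8.4% per year (about 5-fold over 20 years), a mean of 4.4 CASRNs per
#' record, Zipf exponent 1.1, attachment weight 0.3, and 30% of
#' substances available at the window start with the rest emerging
#' uniformly.
#'
#' @param n_substances Number of substances in the registry.
#' @param years Integer `c(start, end)` calendar window.
#' @param base_records_per_year Records in the start year.
#' @param annual_growth_rate Multiplicative growth factor (>= 1).
#' @param popularity_exponent Zipf exponent s > 0 for the fixed
#'   popularity weights (rank^-s).
#' @param preferential_attachment_weight Fraction in \[0, 1\] mixing the
#'   fixed Zipf weights (1 - w) with citation-proportional attachment (w).
#' @param emergence_p0 Fraction of substances available at the start year;
#'   the rest emerge uniformly over the window.
#' @param casrns_per_record_mean Mean of the (1-shifted geometric) number
#'   of CASRNs per record.
#' @param casrns_per_record_max Cap on CASRNs per record.
#' @param class_mixture Named numeric vector of class fractions summing
#'   to at most 1; the remainder is labelled "not characterized". The
#'   name "CEC-only" designates the broad suspect-screening class.
#' @param seed Integer root seed; per-year substreams are derived from it
#'   so extending the window does not perturb earlier years.
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_substances = 5000L,
                             years = c(1989L, 2018L),
                             base_records_per_year = 200L,
                             annual_growth_rate = 1.084,
                             popularity_exponent = 1.1,
                             preferential_attachment_weight = 0.3,
                             emergence_p0 = 0.3,
                             casrns_per_record_mean = 4.4,
                             casrns_per_record_max = 25L,
                             class_mixture = default_class_mixture(),
                             seed = 1L) {
  stopifnot(
    n_substances > 0, years[2] >= years[1],
    base_records_per_year > 0, annual_growth_rate >= 1,
    popularity_exponent > 0,
    preferential_attachment_weight >= 0, preferential_attachment_weight <= 1,
    emergence_p0 >= 0, emergence_p0 <= 1,
    casrns_per_record_mean >= 1, casrns_per_record_max >= 1,
    all(class_mixture >= 0), sum(class_mixture) <= 1 + 1e-9,
    !is.null(names(class_mixture))
  )
  structure(list(
    n_substances = as.integer(n_substances),
    years = as.integer(years),
    base_records_per_year = as.integer(base_records_per_year),
    annual_growth_rate = annual_growth_rate,
    popularity_exponent = popularity_exponent,
    preferential_attachment_weight = preferential_attachment_weight,
    emergence_p0 = emergence_p0,
    casrns_per_record_mean = casrns_per_record_mean,
    casrns_per_record_max = as.integer(casrns_per_record_max),
    class_mixture = class_mixture,
    seed = as.integer(seed)
  ), class = "synthetic_config")
}

#' @rdname synthetic_config
#' @export
default_class_mixture <- function() {
  c(pharmaceutical = 0.091,
    `current-use pesticide` = 0.092,
    `plastics additive` = 0.080,
    `PAH/PAC` = 0.050,
    `metal/isotope` = 0.030,
    `VOC/gas` = 0.030,
    `flame retardant` = 0.025,
    PCB = 0.020,
    `legacy OC pesticide` = 0.020,
    PFAS = 0.012,
    fragrance = 0.020,
    `CEC-only` = 0.150)
}

# Derived per-year seed; kept below 2^31 - 1.
year_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 1009 + offset * 7919 + 17) %% 2147483646L) + 1L
}

#' Generate a synthetic citation corpus with ground truth
#'
#' Draws, for each year y of the window, `round(base * growth^(y - start))`
#' records. Each record samples k CASRNs (1-shifted geometric, capped)
#' without replacement from the substances that have emerged by y, with
#' probability proportional to
#' `(1 - w) * zipf + w * (1 + citations so far)`; Zipf weights are
#' renormalized over the currently-emerged substances. Identical
#' configurations (including seed) produce byte-identical corpora.
#'
#' @param config A [synthetic_config()].
#' @return List of class `synthetic_corpus` with
#'   \describe{
#'     \item{corpus}{a [corpus()]; every record carries roles ANST and
#'       POL, and about half additionally BIOL}
#'     \item{taxonomy}{a [class_taxonomy()] whose lists hold the true
#'       class members}
#'     \item{ground_truth}{tibble `casrn`, `class`, `emergence_year`,
#'       `zipf_rank`, `realized_total`, `realized_first_year` (NA when a
#'       substance was never drawn)}
#'     \item{config}{the input configuration}
#'   }
#' @export
generate_corpus <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  n <- config$n_substances
  y0 <- config$years[1]; y1 <- config$years[2]
  ny <- y1 - y0 + 1L

  set.seed(config$seed)
  casrns <- synthetic_casrns(n)
  zipf_rank <- sample.int(n) # which popularity rank each substance holds
  zipf_w <- zipf_rank^(-config$popularity_exponent)
  mix <- config$class_mixture
  labels <- c(names(mix), "not characterized")
  probs <- c(mix, max(0, 1 - sum(mix)))
  class_of <- sample(labels, n, replace = TRUE, prob = probs)
  emergence <- ifelse(stats::runif(n) < config$emergence_p0, y0,
                      sample.int(ny, n, replace = TRUE) + y0 - 1L)

  w <- config$preferential_attachment_weight
  cites <- numeric(n)
  totals <- integer(n)
  first_seen <- rep(NA_integer_, n)
  n_rec_by_year <- round(config$base_records_per_year *
                           config$annual_growth_rate^(seq_len(ny) - 1))
  n_total_rec <- sum(n_rec_by_year)
  rec_year <- integer(n_total_rec)
  rec_casrns <- vector("list", n_total_rec)
  rec_biol <- logical(n_total_rec)
  rec_counter <- 0L

  for (yi in seq_len(ny)) {
    y <- y0 + yi - 1L
    set.seed(year_seed(config$seed, yi))
    eligible <- which(emergence <= y)
    if (length(eligible) == 0) {
      rlang::abort(sprintf("no substances have emerged by year %d", y))
    }
    n_rec <- n_rec_by_year[yi]
    if (n_rec == 0) next
    zel <- zipf_w[eligible]
    zel <- zel / sum(zel)
    p_geom <- 1 / config$casrns_per_record_mean
    for (r in seq_len(n_rec)) {
      k <- min(stats::rgeom(1, p_geom) + 1L, config$casrns_per_record_max,
               length(eligible))
      att <- 1 + cites[eligible]
      pr <- (1 - w) * zel + w * att / sum(att)
      pick <- eligible[sample.int(length(eligible), k, prob = pr)]
      cites[pick] <- cites[pick] + 1
      totals[pick] <- totals[pick] + 1L
      first_seen[pick] <- pmin(first_seen[pick], y, na.rm = TRUE)
      rec_counter <- rec_counter + 1L
      rec_year[rec_counter] <- y
      rec_casrns[[rec_counter]] <- casrns[sort(pick)]
      rec_biol[rec_counter] <- stats::runif(1) < 0.5
    }
  }

  corp <- corpus(tibble::tibble(
    record_id = sprintf("R%07d", seq_len(rec_counter)),
    year = rec_year,
    roles = purrr::map(rec_biol, ~ c("ANST", "POL", if (.x) "BIOL")),
    casrns = rec_casrns
  ))

  named <- setdiff(names(mix), "CEC-only")
  lists <- purrr::imap(stats::setNames(named, named), function(lab, nm) {
    chemical_list(lab, casrns[class_of == lab])
  })
  lists <- lists[vapply(lists, function(l) length(l$members) > 0, logical(1))]
  cec <- if (any(class_of == "CEC-only")) {
    chemical_list("CEC", casrns[class_of == "CEC-only"])
  }
  taxonomy <- class_taxonomy(unname(lists), cec_list = cec)

  ground_truth <- tibble::tibble(
    casrn = casrns,
    class = class_of,
    emergence_year = as.integer(emergence),
    zipf_rank = zipf_rank,
    realized_total = totals,
    realized_first_year = first_seen
  )
  structure(list(corpus = corp, taxonomy = taxonomy,
                 ground_truth = ground_truth, config = config),
            class = "synthetic_corpus")
}

# n unique valid CASRNs with 6-digit bodies, deterministic given the RNG state.
synthetic_casrns <- function(n) {
  bodies <- sprintf("%06d", sample.int(899999L, n) + 100000L)
  casrn_from_body(bodies)
}

#' Recovery check: pipeline vs generator ground truth
#'
#' Runs the analysis pipeline on a generated corpus and compares against
#' the generator's ground truth: first-report years (determined by the
#' corpus, so recovery must be exact), per-class substance counts among
#' substances that were ever reported, and the top-N concentration share
#' versus the share computed from the realized ground-truth totals.
#'
#' @param gen A `synthetic_corpus` from [generate_corpus()].
#' @param top_n Top-N value for the concentration comparison.
#' @return List of class `recovery_report`: `n_reported`,
#'   `first_year_match_rate`, `class_count_max_dev`,
#'   `total_count_pipeline`, `total_count_truth`, `top_n_share_pipeline`,
#'   `top_n_share_truth`.
#' @export
recover <- function(gen, top_n = 100L) {
  stopifnot(inherits(gen, "synthetic_corpus"))
  gt <- gen$ground_truth
  prof <- build_profiles(gen$corpus)
  if (!all(prof$profiles$casrn %in% gt$casrn)) {
    rlang::abort("corpus contains CASRNs absent from ground truth")
  }
  m <- match(prof$profiles$casrn, gt$casrn)
  fy_match <- mean(prof$profiles$first_year == gt$realized_first_year[m])
  cls <- assign_classes(prof, gen$taxonomy)
  # ground-truth class counts among reported substances, mapped onto the
  # taxonomy's effective labels
  reported <- gt[gt$realized_total > 0, ]
  truth_label <- reported$class
  truth_label[truth_label == "CEC-only"] <- "CEC-only"
  lv <- taxonomy_labels(gen$taxonomy)
  truth_label[!truth_label %in% lv] <- gen$taxonomy$fallback_label
  truth_counts <- table(factor(truth_label, levels = lv))
  pipe_counts <- table(factor(cls$profiles$profiles$class_label, levels = lv))
  top_n <- min(top_n, nrow(prof$profiles))
  cc_pipe <- concentration_curve(cls$profiles)
  cc_truth <- concentration_curve(
    stats::setNames(reported$realized_total, reported$casrn))
  structure(list(
    n_reported = nrow(prof$profiles),
    first_year_match_rate = fy_match,
    class_count_max_dev = max(abs(as.integer(pipe_counts) -
                                    as.integer(truth_counts))),
    total_count_pipeline = sum(prof$profiles$total_count),
    total_count_truth = sum(gt$realized_total),
    top_n_share_pipeline = top_n_share(cc_pipe, top_n),
    top_n_share_truth = top_n_share(cc_truth, top_n)
  ), class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat(sprintf(paste0(
    "<recovery_report> %d substances reported\n",
    "  first-year match rate: %.4f\n",
    "  max class-count deviation: %d\n",
    "  totals (pipeline / truth): %d / %d\n",
    "  top-N share (pipeline / truth): %.4f / %.4f\n"),
    x$n_reported, x$first_year_match_rate, x$class_count_max_dev,
    x$total_count_pipeline, x$total_count_truth,
    x$top_n_share_pipeline, x$top_n_share_truth))
  invisible(x)
}

#' Write a synthetic corpus bundle to disk
#'
#' Emits the corpus, one TSV per class list, the CEC list, and the ground
#' truth, in the package's standard file formats.
#'
#' @param gen A `synthetic_corpus`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_synthetic <- function(gen, dir) {
  stopifnot(inherits(gen, "synthetic_corpus"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_corpus(gen$corpus, file.path(dir, "corpus.tsv"))
  for (li in gen$taxonomy$lists) {
    readr::write_tsv(tibble::tibble(casrn = li$members),
                     file.path(dir, paste0("list_", gsub("[^A-Za-z0-9]+", "_",
                                                         li$name), ".tsv")))
  }
  if (!is.null(gen$taxonomy$cec_list)) {
    readr::write_tsv(tibble::tibble(casrn = gen$taxonomy$cec_list$members),
                     file.path(dir, "list_CEC.tsv"))
  }
  readr::write_tsv(gen$ground_truth, file.path(dir, "ground_truth.tsv"))
  invisible(dir)
}
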