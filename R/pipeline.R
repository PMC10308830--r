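#' Run configuration for the full pipeline
#'
#' Bundles the file paths and options of an end-to-end run: corpus,
#' taxonomy config, exclusion category files, whitelist, inventories,
#' role filter, year window, percent-format rule, top-N values, classes
#' excluded before the inventory overlap, and output directory.
#'
#' @param corpus_path Path to the corpus TSV.
#' @param taxonomy_path Path to the taxonomy config TSV
#'   (see [read_taxonomy()]).
#' @param exclusion_paths Character vector of exclusion category files
#'   (optional).
#' @param whitelist_path Optional whitelist file.
#' @param inventory_paths Named character vector of inventory files
#'   (optional).
#' @param roles,role_mode Role filter applied at ingest.
#' @param year_window Ingest window, integer length-2.
#' @param top_n Top-N values for the concentration table.
#' @param overlap_excluded_classes Class labels dropped before overlap.
#' @param rule A [percent_rule()].
#' @param out_dir Output directory for the report bundle.
#' @return An object of class `run_config`.
#' @export
run_config <- function(corpus_path, taxonomy_path = NULL,
                       exclusion_paths = character(),
                       whitelist_path = NULL,
                       inventory_paths = character(),
                       roles = character(), role_mode = "all",
                       year_window = c(1900L, default_max_year()),
                       top_n = c(10L, 100L, 500L),
                       overlap_excluded_classes = character(),
                       rule = percent_rule(),
                       out_dir = NULL) {
  for (p in c(corpus_path, taxonomy_path, exclusion_paths,
              whitelist_path, inventory_paths)) {
    if (!is.null(p) && !file.exists(p)) {
      rlang::abort(paste0("input path does not exist: ", p))
    }
  }
  structure(as.list(environment()), class = "run_config")
}

#' Run the full bibliometric pipeline
#'
#' Orchestrates ingest, role filtering, deduplication, exclusion
#' screening, classification, trend and concentration statistics, the
#' newly-reported series, and (when inventories are supplied) the
#' three-way overlap. Outputs are deterministic given identical inputs;
#' every emitted table carries an MD5 digest of the corpus file in a
#' header comment. A failure in any stage aborts with the stage name.
#'
#' @param config A [run_config()].
#' @return A list (report bundle) with elements `corpus`, `profiles`,
#'   `screening`, `classification`, `trend`, `concentration`,
#'   `newly_reported`, `venn` (NULL without inventories), and `paths`
#'   of written tables (NULL when `out_dir` is unset).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      rlang::abort(paste0("stage '", name, "' failed: ",
                          conditionMessage(e)))
    })
  }
  corp <- stage("ingest", read_corpus(config$corpus_path,
                                      year_window = config$year_window))
  if (length(config$roles) > 0) {
    corp <- stage("role-filter",
                  filter_by_roles(corp, config$roles, config$role_mode))
  }
  prof <- stage("profiles", build_profiles(corp))
  screening <- NULL
  if (length(config$exclusion_paths) > 0) {
    rules <- stage("screening-rules",
                   read_exclusion_rules(config$exclusion_paths,
                                        config$whitelist_path))
    scr <- stage("screening", apply_exclusions(prof, rules))
    prof <- scr$kept
    screening <- scr$report
  }
  classification <- NULL
  if (!is.null(config$taxonomy_path)) {
    taxonomy <- stage("classification", {
      tx <- read_taxonomy(config$taxonomy_path)
      dedupe_lists(tx)$taxonomy
    })
    cls <- stage("classification", assign_classes(prof, taxonomy))
    prof <- cls$profiles
    classification <- cls$summary
  }
  trend <- stage("trends", annual_class_counts(corp, prof))
  curve <- stage("concentration", concentration_curve(prof))
  first_years <- stage("dedup", dedup_earliest(corp))
  newly <- stage("trends", newly_reported_series(first_years, trend))
  venn <- NULL
  coverage <- NULL
  if (length(config$inventory_paths) >= 3) {
    invs <- stage("overlap", purrr::imap(
      config$inventory_paths[1:3],
      function(p, nm) read_inventory(p, name = if (nzchar(nm)) nm else NULL)))
    ref <- reduce_for_overlap(prof, config$overlap_excluded_classes)
    venn <- stage("overlap", venn3(ref, invs[[1]], invs[[2]], invs[[3]]))
    coverage <- purrr::map2_chr(
      as.list(venn$per_set_overlap), invs,
      function(ov, inv) inventory_coverage(ov, inv, config$rule))
  }
  bundle <- list(
    corpus = corp, profiles = prof, screening = screening,
    classification = classification, trend = trend,
    concentration = curve, newly_reported = newly,
    venn = venn, coverage = coverage, paths = NULL
  )
  if (!is.null(config$out_dir)) {
    bundle$paths <- write_report_bundle(bundle, config)
  }
  bundle
}

write_report_bundle <- function(bundle, config) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  digest <- unname(tools::md5sum(config$corpus_path))
  emit <- function(tab, name) {
    path <- file.path(config$out_dir, name)
    con <- file(path, open = "wb") # LF endings on every platform
    on.exit(close(con))
    writeLines(paste0("#input_md5=", digest), con)
    readr::write_tsv(tab, con, append = TRUE, col_names = TRUE)
    path
  }
  paths <- c(
    if (!is.null(bundle$screening)) {
      emit(screening_report_table(bundle$screening), "screening_report.tsv")
    },
    if (!is.null(bundle$classification)) {
      emit(tibble::as_tibble(bundle$classification), "classification_summary.tsv")
    },
    emit(trend_table_long(bundle$trend, config$rule), "trend_table.tsv"),
    emit(concentration_table(bundle$concentration), "concentration.tsv"),
    emit(bundle$newly_reported, "newly_reported.tsv"),
    if (!is.null(bundle$venn)) emit(venn_table(bundle$venn), "venn.tsv")
  )
  paths
}

#' Summary table of substance counts and concentration shares
#'
#' Builds the survey's headline table: one row per requested top-N with
#' the captured count and its formatted share of the grand total, then
#' one row per substance of interest. An unknown CASRN of interest warns
#' and yields a zero-count row.
#'
#' @param profiles A `substance_profiles` object.
#' @param n_values Integer vector of top-N sizes.
#' @param substances_of_interest Character vector of CASRNs (optionally
#'   named with display names).
#' @param rule A [percent_rule()].
#' @return Tibble `row`, `casrn`, `count`, `share`.
#' @export
make_table1 <- function(profiles, n_values = c(10L, 100L, 500L),
                        substances_of_interest = character(),
                        rule = percent_rule()) {
  stopifnot(inherits(profiles, "substance_profiles"))
  curve <- concentration_curve(profiles)
  grand <- curve$grand_total
  n_values <- n_values[n_values <= length(curve$casrn)]
  top_rows <- tibble::tibble(
    row = paste0("top ", n_values),
    casrn = NA_character_,
    count = vapply(n_values, function(n) {
      as.integer(sum(curve$sorted_totals[seq_len(n)]))
    }, integer(1)),
    share = vapply(n_values, function(n) {
      format_percent(top_n_share(curve, n), rule)
    }, character(1))
  )
  sub_rows <- NULL
  if (length(substances_of_interest) > 0) {
    nm <- names(substances_of_interest) %||% substances_of_interest
    nm[!nzchar(nm)] <- substances_of_interest[!nzchar(nm)]
    counts <- profiles$profiles$total_count[
      match(substances_of_interest, profiles$profiles$casrn)]
    if (anyNA(counts)) {
      rlang::warn(paste0("substance(s) of interest not in profiles: ",
                         paste(substances_of_interest[is.na(counts)],
                               collapse = ", ")))
      counts[is.na(counts)] <- 0L
    }
    sub_rows <- tibble::tibble(
      row = nm,
      casrn = unname(substances_of_interest),
      count = as.integer(counts),
      share = substance_share(counts, grand, rule)
    )
  }
  dplyr::bind_rows(top_rows, sub_rows)
}
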