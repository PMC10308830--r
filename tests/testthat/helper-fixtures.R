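# Shared fixture builders. Everything is generated in code; no binary or
# stored corpora.

# n unique valid CASRNs, deterministic given the RNG state.
rand_casrns <- function(n, from = 100000L) {
  casrn_from_body(sprintf("%06d", from + seq_len(n) * 7L))
}

# Independent check-digit oracle, written directly from the definition:
# digit positions are numbered 1, 2, 3, ... from the rightmost non-check
# digit leftwards, so with d read left-to-right the weight of d[j] is
# length(d) - j + 1.
oracle_check_digit <- function(body) {
  d <- as.integer(strsplit(body, "")[[1]])
  weights <- seq.int(length(d), 1L)
  sum(d * weights) %% 10L
}

# Small deterministic corpus used across modules:
#   A appears 1999 (x2 records) and 2001; B 2001, 2005; C 2005 only.
toy_corpus <- function() {
  cs <- rand_casrns(3)
  corpus(tibble::tibble(
    record_id = paste0("r", 1:5),
    year = c(1999L, 1999L, 2001L, 2001L, 2005L),
    roles = list(c("ANST", "POL"), "ANST", c("ANST", "POL"),
                 "BIOL", c("anst", " pol ")),
    casrns = list(cs[1], cs[1], c(cs[1], cs[2]), cs[2], c(cs[2], cs[3]))
  ))
}

toy_casrns <- function() rand_casrns(3)

# A corpus as a temp TSV file, returning the path.
write_tmp_corpus <- function(lines) {
  path <- withr::local_tempfile(fileext = ".tsv",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

# Taxonomy over generated CASRN pools: three named classes + a CEC list.
toy_taxonomy <- function(pool = rand_casrns(40)) {
  class_taxonomy(
    lists = list(
      chemical_list("pharmaceutical", pool[1:10], precedence = 1L),
      chemical_list("current-use pesticide", pool[9:20], precedence = 2L),
      chemical_list("PCB", pool[21:25], precedence = 3L)
    ),
    cec_list = chemical_list("CEC", pool[c(24:32)])
  )
}
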