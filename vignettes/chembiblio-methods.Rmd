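---
title: "Methods: bibliometric analysis of chemicals measured in environmental media"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: bibliometric analysis of chemicals measured in environmental media}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chembiblio)
```

## The problem

Environmental chemistry has measured a tremendous number of individual
substances over the past half century, but the literature concentrates
heavily on a small set of well-known pollutants — heavy metals, priority
PAHs, legacy organochlorines — while most substances in commerce are
rarely or never determined. `chembiblio` implements the full analysis
pipeline for quantifying that picture from a citation corpus indexed by
CAS Registry Number (CASRN): which substances have been reported, when
each was first reported, how reports distribute across chemical classes
over time, how concentrated measurement effort is on the most-studied
substances, and how the measured-substance list overlaps the industrial
chemical inventories of the US (TSCA), EU (REACH), and China (IECSC).

The corpora such analyses run on (commercial literature databases with
substance-role indexing, e.g. roles like "analytical study", "pollutant",
"biological study") are proprietary. The package therefore treats the
corpus as an input file with a simple delimited contract, and ships a
seeded synthetic-corpus generator with exported ground truth so the
entire pipeline is testable end to end without access to any commercial
database.

## Pipeline and model

1. **Ingest and validation** (`read_corpus()`). Every CASRN token is
   validated against the CAS positional mod-10 check digit: with the
   non-check digits numbered 1, 2, 3, … from the rightmost leftwards,
   the check digit is the weighted digit sum mod 10. Invalid tokens are
   dropped and tallied (malformed pattern vs checksum failure), never
   silently discarded. CASRNs are identifiers, not numbers: they are
   stored canonically with hyphens and compared as strings.
2. **Role filtering** (`filter_by_roles()`). The substance list of
   interest is defined by indexing roles (e.g. records carrying both an
   analytical-study and a pollutant role). The role vocabulary is open —
   free strings matched case-insensitively — because role codes are
   database conventions, not a closed enum.
3. **Earliest-year deduplication** (`dedup_earliest()`). Duplicate
   reports of a substance are removed sequentially starting from the
   earliest year, so each substance's first-report year is well defined.
   Ties within a year are broken by canonical CASRN sort, making the
   output a deterministic function of corpus *content*, invariant to
   record order.
4. **Exclusion screening** (`apply_exclusions()`). Raw substance lists
   contain essential elements, minerals, polymers, natural products,
   mass-labelled compounds and similar entries that are not usefully
   called contaminants. The screen is *declarative*: categories are
   CASRN sets read from files, applied in file order, with each removed
   substance attributed to its first matching category; a whitelist
   (canonically the well-known water pollutants perchlorate, nitrate,
   phosphate, sulfate and cyanide ion) is exempt from every category.
   Making the screen data rather than code keeps the
   input − removed = kept arithmetic exactly testable. A food-constituent
   screen (`food_constituent_screen()`) composes as one more category.
5. **Classification** (`assign_classes()`). Each substance gets exactly
   one class label by precedence-ordered list matching; substances found
   only on a broad suspect-screening list of chemicals of emerging
   concern (CEC) are labelled `"CEC-only"`, and the rest
   `"not characterized"`. Single-label-with-precedence is a design
   choice: published class breakdowns present disjoint classes without
   stating a conflict rule, and an explicit precedence (a config file)
   makes the rule reproducible. `dedupe_lists()` applies the same
   precedence to the lists themselves; `annotate_transformation_products()`
   maps transformation products onto their parent's class (list
   membership, being curated, outranks the TP map).
6. **Trends and concentration** (`annual_class_counts()`,
   `share_series()`, `newly_reported_series()`, `concentration_curve()`,
   `top_n_share()`). Trend series are raw per-year counts — no
   smoothing — and percent-of-total shares; years with zero total
   reports are undefined (`NA`), not zero. Measurement concentration
   (the "Matthew effect": the already-measured get measured again) is
   the share of total citation counts captured by the top N substances;
   boundary ties are broken by canonical CASRN so the statistic is
   deterministic.
7. **Inventory overlap** (`venn3()`, `inventory_coverage()`,
   `reduce_for_overlap()`). Before comparing with industrial inventories
   the pharmaceutical and pesticide classes are dropped (those classes
   are regulated outside industrial-inventory law). The three-set region
   counts are computed on the reference-restricted universe. Coverage
   percentages divide by an inventory's *declared* size rather than the
   members present in a fixture file, so small packaged stand-ins
   reproduce published coverages exactly while real inventory files work
   unchanged.

## Display conventions

Published summary tables of this kind mix precisions: shares of at least
10% print as whole percentages, smaller shares with two significant
figures. `percent_rule()` fixes that rule package-wide, and rounding is
half-up (`0.185 -> "0.19%"`) rather than R's default half-to-even,
implemented directly since `round()`/`signif()` cannot express it. The
rule is configurable per call.

## The synthetic corpus generator

`generate_corpus()` emulates the statistical structure the analysis
assumes, with defaults chosen once as the package's study conditions:

| Parameter | Default | Why |
|---|---|---|
| `n_substances` | 5,000 | enough substances for stable top-100 statistics at tractable runtime |
| `years` | 1989–2018 | a 30-year window typical of occurrence surveys |
| `base_records_per_year` | 200 | yields ~25,000 records and ~10^5 substance counts over the window |
| `annual_growth_rate` | 1.084 | 5-fold growth in annual publication volume over 20 years, the scale seen in occurrence literature |
| `casrns_per_record_mean` | 4.4 | multi-analyte papers: mean substances per record observed in such corpora |
| `popularity_exponent` | 1.1 | heavy-tailed (Zipf) per-substance citation counts |
| `preferential_attachment_weight` | 0.3 | mixes fixed popularity with rich-get-richer citation feedback |
| `emergence_p0` | 0.3 | 30% of substances measurable from the window start; the rest emerge uniformly |

Per year *y*, `round(base × growth^(y−start))` records are drawn; each
samples its CASRNs without replacement from substances emerged by *y*
with probability ∝ `(1−w)·zipf + w·(1 + citations so far)`, Zipf weights
renormalized over the currently-emerged set (this keeps per-year
sampling well defined as the registry grows). A single root seed derives
per-year substreams, so extending the year window never perturbs earlier
years. Class labels come from a configurable mixture whose unnamed
remainder is "not characterized".

The generator exports ground truth (true class, emergence year,
realized totals and realized first-report years), and `recover()` checks
the pipeline against it. First-report years and per-class counts are
*determined* by the emitted corpus, so recovery must be exact — these are
integration checks of the pipeline's bookkeeping, not statistical
estimates.

What the generator does **not** emulate: CASRN-level semantics (no real
substances), within-record role correlation structure, database
curation artifacts (retrospective re-indexing, UVCB entries, records
with unresolvable identifiers), or any calibration to a real corpus'
series. Passing recovery tests therefore demonstrates correct
aggregation arithmetic on corpora with realistic *statistical* shape,
not fidelity to any particular database.

## Numerical and degenerate-input choices

- Ingest rejects years outside a configurable window (default 1900 to
  the current year); survey windows vary, so the window is config, not
  constant.
- An empty role requirement is the identity filter; an unknown role or
  class label warns rather than errors (open vocabularies), while
  structural faults — duplicated record ids, missing columns, empty list
  files, a declared inventory size below the member count — are hard
  errors.
- A record whose every CASRN fails validation is dropped and tallied
  separately from row-level rejections.
- Zero-total years produce `NA` shares; `top_n_share()` errors outside
  `1 ≤ n ≤ |substances|`.
- In a multi-category screen a substance is counted once, under its
  first matching category — category files are ordered for exactly this
  reason.

## Worked example at small scale

```{r example}
gen <- generate_corpus(synthetic_config(
  n_substances = 300, years = c(2000, 2009),
  base_records_per_year = 40, seed = 7))
prof <- build_profiles(gen$corpus)
cls <- assign_classes(prof, gen$taxonomy)
make_table1(cls$profiles, n_values = c(10, 50))
recover(gen, top_n = 50)
```

## Problem sizes used by the test suite

The shipped tests and the acceptance script run the screening
arithmetic at its published scale (23,458 substances), the venn oracle
on 200 random three-set instances, the concentration-vs-exponent
comparison on 20 paired replicates of a 400-substance corpus, and the
end-to-end recovery on the full default generator configuration
(5,000 substances, 30 years) — sizes the package treats as its standard
verification conditions.

## Known limitations

- Matching across lists and inventories is CASRN-exact; no name-based or
  structure-based matching, no UVCB/mixture resolution (a large fraction
  of real inventory entries are UVCBs and will never match).
- Identifiers beyond the CASRN (SMILES/InChI) are pass-through text.
- The exclusion screen reproduces the *effect* of expert curation from
  category files; it embodies no judgment about what is a natural
  product or polymer.
- Trend statistics are descriptive (no changepoint or significance
  testing), matching standard practice for these surveys.
```
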