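# Packaged fixture tables (transcribed survey tables) and the taxonomy map.
#
# The fixtures carry metadata only (species, accession, source database,
# domain-copy annotations) -- no sequences are shipped -- so tabulation can
# be exercised on the published records while classification is exercised
# on synthetic sequences.

.extdata <- function(file) {
  path <- system.file("extdata", file, package = "tpppscan")
  if (!nzchar(path)) {
    abort(sprintf("packaged fixture '%s' not found; broken installation", file))
  }
  path
}

#' Load a packaged fixture table
#'
#' Three metadata tables are packaged, transcribed row-for-row from the
#' published survey: `T2_truncated` (truncated TPPPs, 22 rows),
#' `T3_multidomain` (multidomain TPPP-like proteins, 18 rows) and
#' `T4_partial` (proteins with partial p25alpha domain(s) other than
#' apicortins, 20 rows). Footnote flags are carried in `questionable`;
#' `excluded` marks the one truncated row (the flatworm *Clonorchis
#' sinensis* entry) that the survey's own phylogenetic analysis removed
#' from its headline counts.
#'
#' @param table_id One of `"T2_truncated"`, `"T3_multidomain"`,
#'   `"T4_partial"`.
#' @return Tibble with columns `table_id`, `species`, `accession`,
#'   `source_db`, `is_est`, `questionable`, `excluded`, `n_p25_domains`,
#'   `n_partial_domains`, `rossmann_flags` (list of logicals, one per
#'   partial copy), `other_domains` (list of character).
#' @examples
#' nrow(load_fixture_table("T2_truncated"))
#' @export
load_fixture_table <- function(table_id = c("T2_truncated", "T3_multidomain",
                                            "T4_partial")) {
  table_id <- match.arg(table_id)
  file <- switch(table_id,
    T2_truncated = "table2_truncated.tsv",
    T3_multidomain = "table3_multidomain.tsv",
    T4_partial = "table4_partial.tsv"
  )
  raw <- readr::read_tsv(.extdata(file), col_types = readr::cols(),
                         progress = FALSE)
  split_list <- function(x) {
    map(x, ~ if (is.na(.x) || !nzchar(.x)) character(0) else
      strsplit(.x, ",", fixed = TRUE)[[1]])
  }
  out <- tibble(
    table_id = table_id,
    species = raw$species,
    accession = raw$accession,
    source_db = raw$source_db,
    is_est = if ("is_est" %in% names(raw)) raw$is_est else FALSE,
    questionable = if ("questionable" %in% names(raw)) raw$questionable else FALSE,
    excluded = if ("excluded" %in% names(raw)) raw$excluded else FALSE
  )
  out$n_p25_domains <- switch(table_id,
    T2_truncated = 1L,
    T3_multidomain = as.integer(raw$n_p25_domains),
    T4_partial = 0L
  )
  out$n_partial_domains <- switch(table_id,
    T4_partial = as.integer(raw$n_partial_domains),
    0L
  )
  out$rossmann_flags <- if (table_id == "T4_partial") {
    map2(split_list(raw$rossmann), out$n_partial_domains, function(flags, n) {
      flags <- trimws(flags) == "yes"
      # a single printed flag covers every copy of the row
      if (length(flags) == 1 && n > 1) flags <- rep(flags, n)
      flags
    })
  } else {
    map(seq_len(nrow(out)), ~ logical(0))
  }
  out$other_domains <- if (table_id == "T3_multidomain") {
    split_list(raw$other_domains)
  } else {
    map(seq_len(nrow(out)), ~ character(0))
  }
  if (table_id == "T2_truncated" &&
      !all(out$n_p25_domains == 1L & lengths(out$other_domains) == 0)) {
    abort("T2 rows must have exactly one p25alpha domain and no other domains")
  }
  out
}

#' Load the packaged species taxonomy
#'
#' Maps every species appearing in the fixture tables (plus the synthetic
#' generator's default taxa) to its eukaryotic supergroup, megagroup
#' (unikonts; photosynthetic = Archaeplastida + Chromalveolata + Rhizaria;
#' Excavata) and a `|`-separated sub-taxon path. `group` is the row label
#' used by the distribution table.
#'
#' @return Tibble with columns `species`, `supergroup`, `megagroup`,
#'   `group`, `path`.
#' @export
load_taxonomy <- function() {
  readr::read_tsv(.extdata("taxonomy.tsv"), col_types = readr::cols(),
                  progress = FALSE)
}

#' Turn fixture rows into subfamily calls for tabulation
#'
#' Attaches the subfamily label each fixture table documents (`truncated`,
#' `multidomain` or `partial_only`) so the rows can be fed to
#' [tabulate_distribution()].
#'
#' @param table_id Passed to [load_fixture_table()].
#' @return Tibble with `id`, `species`, `label`, `is_est`, `questionable`,
#'   `excluded`.
#' @export
fixture_calls <- function(table_id = c("T2_truncated", "T3_multidomain",
                                       "T4_partial")) {
  table_id <- match.arg(table_id)
  rows <- load_fixture_table(table_id)
  tibble(
    id = rows$accession,
    species = rows$species,
    label = switch(table_id,
      T2_truncated = "truncated",
      T3_multidomain = "multidomain",
      T4_partial = "partial_only"
    ),
    is_est = rows$is_est,
    questionable = rows$questionable,
    excluded = rows$excluded
  )
}
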