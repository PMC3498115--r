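# End-to-end pipeline: FASTA in, classified calls + distribution +
# disorder summaries (+ optional tree) out.

#' Run the full TPPP-like survey pipeline
#'
#' Reads protein records, classifies every sequence into an architecture
#' subfamily, tabulates the phyletic distribution, summarises per-protein
#' disorder, and optionally builds a neighbor-joining identity tree. Result
#' tables are written as TSV (plus a rendered "total (est)" text table)
#' when `out_dir` is given; any stage failure aborts with a stage-named
#' error and removes partial outputs.
#'
#' @param fasta Path to a FASTA file (see [read_fasta()] for the header
#'   metadata dialect).
#' @param taxonomy Optional taxonomy TSV path or tibble; defaults to the
#'   packaged [load_taxonomy()].
#' @param annotations Optional foreign-domain annotation TSV path or tibble
#'   (`id`, `name`, `start`, `end`).
#' @param out_dir Optional output directory for the report files.
#' @param config A [run_config()]; every threshold used is logged.
#' @param model A `p25_model`.
#' @param tree Also build an NJ tree (requires >= 3 records) and write it
#'   as Newick.
#' @return A `tppp_report`: list with `calls`, `distribution`, `disorder`,
#'   `tree` (or `NULL`), `config` and `files`. Returned invisibly when
#'   `out_dir` is set.
#' @examples
#' ds <- generate_dataset(dplyr::bind_rows(
#'   synth_spec("long_type", n = 2), synth_spec("short_type", n = 2)
#' ), seed = 7)
#' rep <- run_pipeline(ds$fasta, annotations = ds$annotations_path)
#' rep$calls$label
#' @export
run_pipeline <- function(fasta, taxonomy = NULL, annotations = NULL,
                         out_dir = NULL, config = run_config(),
                         model = default_p25_model(), tree = FALSE) {
  stopifnot(inherits(config, "tppp_config"))
  say <- function(...) if (config$verbosity != "quiet") inform(sprintf(...))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
    })
  }
  say("thresholds: min_normalized=%.2f tiers=%.2f/%.2f truncated_affinity=%.2f gap=%d min_tail=%d window=%d disorder_threshold=%.2f",
      config$min_normalized, config$tier_strong, config$tier_weak,
      config$truncated_affinity, config$gap_tolerance, config$min_tail,
      config$disorder_window, config$disorder_threshold)

  taxonomy <- stage("taxonomy", {
    if (is.null(taxonomy)) load_taxonomy()
    else if (is.character(taxonomy)) readr::read_tsv(taxonomy, col_types = readr::cols(), progress = FALSE)
    else taxonomy
  })
  annotations <- stage("annotations", {
    if (is.null(annotations)) NULL
    else if (is.character(annotations)) readr::read_tsv(annotations, col_types = readr::cols(), progress = FALSE)
    else annotations
  })
  records <- stage("read", read_fasta(fasta))

  empty_report <- function() {
    structure(list(calls = tibble(), distribution = NULL, disorder = tibble(),
                   tree = NULL, config = config, files = character(0)),
              class = "tppp_report")
  }
  if (nrow(records) == 0) {
    warn("no records in input; empty report")
    return(empty_report())
  }

  calls <- stage("classify",
                 classify_proteins(records, model, annotations = annotations,
                                   taxonomy = taxonomy, config = config))
  dist <- stage("tabulate", tabulate_distribution(calls, taxonomy))
  dis <- stage("disorder",
               disorder_profiles(records, config$disorder_window,
                                 config$disorder_threshold))
  nj <- NULL
  if (tree && nrow(records) >= 3) {
    nj <- stage("tree", nj_tree(distance_matrix(records)))
  }

  files <- character(0)
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    written <- character(0)
    res <- tryCatch({
      flat_calls <- calls |>
        mutate(has_rossmann = map_chr(.data$has_rossmann, ~ paste(.x, collapse = ",")),
               other_domains = map_chr(.data$other_domains, ~ paste(.x, collapse = ","))) |>
        select(-"evidence")
      p <- file.path(out_dir, "calls.tsv")
      readr::write_tsv(flat_calls, p, progress = FALSE); written <- c(written, p)
      p <- file.path(out_dir, "distribution.tsv")
      readr::write_tsv(as_tibble(dist), p, progress = FALSE); written <- c(written, p)
      p <- file.path(out_dir, "distribution.txt")
      writeLines(render_distribution(dist), p); written <- c(written, p)
      p <- file.path(out_dir, "disorder.tsv")
      readr::write_tsv(dis, p, progress = FALSE); written <- c(written, p)
      if (!is.null(nj)) {
        p <- file.path(out_dir, "tree.nwk")
        ape::write.tree(nj, p); written <- c(written, p)
      }
      written
    }, error = function(e) {
      unlink(written)
      abort(sprintf("pipeline stage 'write' failed: %s", conditionMessage(e)))
    })
    files <- res
    say("wrote %d report file(s) to %s", length(files), out_dir)
  }

  report <- structure(
    list(calls = calls, distribution = dist, disorder = dis, tree = nj,
         config = config, files = files),
    class = "tppp_report"
  )
  if (is.null(out_dir)) report else invisible(report)
}

#' @export
print.tppp_report <- function(x, ...) {
  cat("<tppp_report>\n")
  if (nrow(x$calls) == 0) {
    cat("  (empty)\n")
    return(invisible(x))
  }
  cat(sprintf("  %d records classified:\n", nrow(x$calls)))
  tab <- table(x$calls$label)
  for (nm in names(tab)) cat(sprintf("    %-14s %d\n", nm, tab[[nm]]))
  if (length(x$files)) cat("  files:", paste(basename(x$files), collapse = ", "), "\n")
  invisible(x)
}

#' Subfamily composition plot for a set of calls
#'
#' @param calls A [classify_proteins()] result (or `tppp_report$calls`).
#' @return A ggplot bar chart of label counts.
#' @export
plot_calls <- function(calls) {
  stopifnot(is.data.frame(calls), "label" %in% names(calls))
  ggplot2::ggplot(calls, ggplot2::aes(x = .data$label)) +
    ggplot2::geom_bar() +
    ggplot2::labs(x = "subfamily", y = "proteins",
                  title = "Architecture subfamily composition") +
    ggplot2::theme_minimal()
}
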