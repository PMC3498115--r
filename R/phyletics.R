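# Phyletic distribution: taxon assignment and the supergroup x subfamily
# count table with EST sub-counts.

#' Assign supergroup / megagroup / path to records
#'
#' Deterministic lookup of each record's species in the taxonomy table.
#' Unknown species are routed to an explicit `"unassigned"` value, never
#' dropped.
#'
#' @param records Tibble with a `species` column (protein records, calls,
#'   or fixture rows).
#' @param taxonomy Taxonomy tibble; defaults to the packaged
#'   [load_taxonomy()].
#' @return `records` with `supergroup`, `megagroup`, `group`, `path`
#'   columns appended.
#' @examples
#' assign_taxon(tibble::tibble(species = c("Homo sapiens", "Xxx yyy")))
#' @export
assign_taxon <- function(records, taxonomy = NULL) {
  stopifnot(is.data.frame(records), "species" %in% names(records))
  taxonomy <- taxonomy %||% load_taxonomy()
  out <- left_join(records, taxonomy, by = "species")
  mutate(out, across(c("supergroup", "megagroup", "group", "path"),
                     ~ dplyr::coalesce(.x, "unassigned")))
}

# Fixed display order of taxa rows and subfamily columns.
.SUPERGROUP_ORDER <- c("Opisthokonta", "Amoebozoa", "Apusozoa",
                       "Archaeplastida", "Chromalveolata", "Rhizaria",
                       "Excavata", "unassigned")
.MEGAGROUP_ORDER <- c("unikonts", "photosynthetic", "Excavata", "unassigned")
.SUBFAMILY_ORDER <- setdiff(SUBFAMILY_LABELS, "none")

#' Tabulate the phyletic distribution of subfamily calls
#'
#' Counts labelled records per (megagroup, supergroup, group) row and
#' subfamily column, with EST sub-counts, in the layout of a supergroup x
#' subfamily census. Headline counts omit rows flagged `excluded` (entries
#' the survey's own phylogenetic analysis removed); those rows, and all
#' rows flagged `questionable`, are reported in the `footnotes` attribute.
#' Records labelled `none` are diverted to the `diagnostics` attribute and
#' never counted in the main table.
#'
#' @param calls Tibble with `species`, `label` and optionally `is_est`,
#'   `questionable`, `excluded` (see [classify_proteins()],
#'   [fixture_calls()]).
#' @param taxonomy Taxonomy tibble; defaults to the packaged one.
#' @return A `tppp_distribution`: a tibble with columns `megagroup`,
#'   `supergroup`, `group`, one `<subfamily>` and `<subfamily>_est` count
#'   pair per subfamily, plus attributes `footnotes` (excluded/questionable
#'   rows) and `diagnostics` (unlabelled records).
#' @examples
#' tabulate_distribution(fixture_calls("T3_multidomain"))
#' @export
tabulate_distribution <- function(calls, taxonomy = NULL) {
  stopifnot(is.data.frame(calls), all(c("species", "label") %in% names(calls)))
  taxonomy <- taxonomy %||% load_taxonomy()
  calls <- mutate(calls,
    is_est = if ("is_est" %in% names(calls)) .data$is_est else FALSE,
    questionable = if ("questionable" %in% names(calls)) .data$questionable else FALSE,
    excluded = if ("excluded" %in% names(calls)) .data$excluded else FALSE
  )
  calls <- assign_taxon(calls, taxonomy)
  diagnostics <- filter(calls, .data$label == "none")
  footnotes <- filter(calls, .data$label != "none",
                      .data$questionable | .data$excluded)
  headline <- filter(calls, .data$label != "none", !.data$excluded)

  counted <- headline |>
    group_by(.data$megagroup, .data$supergroup, .data$group, .data$path,
             .data$label) |>
    summarise(n = n(), n_est = sum(.data$is_est), .groups = "drop")
  wide <- counted |>
    tidyr::pivot_wider(
      names_from = "label",
      values_from = c("n", "n_est"),
      values_fill = 0L,
      names_glue = "{label}{ifelse(.value == 'n_est', '_est', '')}"
    )
  for (lab in .SUBFAMILY_ORDER) {
    if (!lab %in% names(wide)) wide[[lab]] <- 0L
    est_col <- paste0(lab, "_est")
    if (!est_col %in% names(wide)) wide[[est_col]] <- 0L
  }
  cols <- c("megagroup", "supergroup", "group", "path",
            as.vector(rbind(.SUBFAMILY_ORDER, paste0(.SUBFAMILY_ORDER, "_est"))))
  wide <- wide[, cols]
  wide <- arrange(wide,
                  match(.data$megagroup, .MEGAGROUP_ORDER),
                  match(.data$supergroup, .SUPERGROUP_ORDER),
                  .data$group)
  structure(wide,
            footnotes = footnotes,
            diagnostics = diagnostics,
            class = c("tppp_distribution", class(wide)))
}

#' Count records under a named taxon
#'
#' Sums distribution cells over every row whose sub-taxon path contains
#' `taxon` (or whose supergroup/megagroup/group equals it), so rollups like
#' "Metazoa" or "Chloroplastida" that sit above the table's leaf rows are
#' one call away.
#'
#' @param dist A [tabulate_distribution()] result.
#' @param taxon Taxon name, e.g. `"Arthropoda"`, `"Excavata"`.
#' @param subfamily Optional subfamily column; default sums all subfamilies.
#' @param est Count ESTs instead of totals.
#' @return Integer count.
#' @export
taxon_count <- function(dist, taxon, subfamily = NULL, est = FALSE) {
  stopifnot(inherits(dist, "tppp_distribution"))
  hit <- dist$supergroup == taxon | dist$megagroup == taxon |
    dist$group == taxon |
    grepl(paste0("(^|\\|)", taxon, "(\\||$)"), dist$path)
  cols <- if (is.null(subfamily)) .SUBFAMILY_ORDER else subfamily
  if (est) cols <- paste0(cols, "_est")
  sum(vapply(cols, function(cl) sum(dist[[cl]][hit]), numeric(1)))
}

#' Marginal totals of a distribution table
#'
#' @param dist A [tabulate_distribution()] result.
#' @return List with `supergroup` (per-supergroup totals), `megagroup`, and
#'   `grand` (one row of per-subfamily grand totals), each carrying count
#'   and EST columns.
#' @export
distribution_margins <- function(dist) {
  stopifnot(inherits(dist, "tppp_distribution"))
  num_cols <- c(.SUBFAMILY_ORDER, paste0(.SUBFAMILY_ORDER, "_est"))
  roll <- function(by) {
    dist |>
      as_tibble() |>
      group_by(across(dplyr::all_of(by))) |>
      summarise(across(dplyr::all_of(num_cols), sum), .groups = "drop")
  }
  list(
    supergroup = roll(c("megagroup", "supergroup")),
    megagroup = roll("megagroup"),
    grand = summarise(as_tibble(dist), across(dplyr::all_of(num_cols), sum))
  )
}

#' Render a distribution table in "total (est)" style
#'
#' @param dist A [tabulate_distribution()] result.
#' @return Character vector of text lines, invisibly printed with `cat()`
#'   when `print = TRUE`.
#' @param print Print the lines to the console.
#' @export
render_distribution <- function(dist, print = FALSE) {
  stopifnot(inherits(dist, "tppp_distribution"))
  cell <- function(n, e) ifelse(n == 0, ".",
                                ifelse(e > 0, sprintf("%d (%d)", n, e),
                                       sprintf("%d", n)))
  header <- sprintf("%-16s %-16s %s", "supergroup", "group",
                    paste(sprintf("%-14s", .SUBFAMILY_ORDER), collapse = " "))
  body <- vapply(seq_len(nrow(dist)), function(i) {
    cells <- vapply(.SUBFAMILY_ORDER, function(lab) {
      cell(dist[[lab]][[i]], dist[[paste0(lab, "_est")]][[i]])
    }, character(1))
    sprintf("%-16s %-16s %s", dist$supergroup[[i]], dist$group[[i]],
            paste(sprintf("%-14s", cells), collapse = " "))
  }, character(1))
  m <- distribution_margins(dist)
  totals <- vapply(.SUBFAMILY_ORDER, function(lab) {
    cell(m$grand[[lab]], m$grand[[paste0(lab, "_est")]])
  }, character(1))
  total_line <- sprintf("%-16s %-16s %s", "Total", "",
                        paste(sprintf("%-14s", totals), collapse = " "))
  lines <- c(header, body, total_line)
  fn <- attr(dist, "footnotes")
  if (!is.null(fn) && nrow(fn) > 0) {
    lines <- c(lines, "", "Footnotes (questionable/excluded records):",
               sprintf("  %s %s [%s]%s", fn$id %||% fn$species, fn$species,
                       fn$label, ifelse(fn$excluded, " excluded from counts", "")))
  }
  if (print) cat(lines, sep = "\n")
  invisible(lines)
}

#' @export
print.tppp_distribution <- function(x, ...) {
  render_distribution(x, print = TRUE)
  invisible(x)
}

#' @rdname tabulate_distribution
#' @param x A `tppp_distribution`.
#' @param ... Unused.
#' @export
tidy.tppp_distribution <- function(x, ...) {
  base <- as_tibble(x)
  keys <- c("megagroup", "supergroup", "group", "path")
  n_long <- base |>
    select(!dplyr::ends_with("_est")) |>
    tidyr::pivot_longer(dplyr::all_of(.SUBFAMILY_ORDER),
                        names_to = "subfamily", values_to = "n")
  est_long <- base |>
    select(dplyr::all_of(keys), dplyr::ends_with("_est")) |>
    tidyr::pivot_longer(dplyr::ends_with("_est"),
                        names_to = "subfamily", values_to = "n_est") |>
    mutate(subfamily = sub("_est$", "", .data$subfamily))
  left_join(n_long, est_long, by = c(keys, "subfamily"))
}

#' @rdname tabulate_distribution
#' @export
glance.tppp_distribution <- function(x, ...) {
  g <- distribution_margins(x)$grand
  bind_cols(tibble(n_rows = nrow(x)), g)
}

#' @export
autoplot.tppp_distribution <- function(object, ...) {
  long <- as_tibble(object) |>
    tidyr::pivot_longer(dplyr::all_of(.SUBFAMILY_ORDER),
                        names_to = "subfamily", values_to = "n") |>
    filter(.data$n > 0)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$subfamily, y = .data$group,
                                     fill = .data$n)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$n), colour = "white") +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$supergroup),
                        scales = "free_y", space = "free_y") +
    ggplot2::labs(x = "subfamily", y = NULL,
                  title = "Phyletic distribution of TPPP-like proteins") +
    ggplot2::theme_minimal()
}
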