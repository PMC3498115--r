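# Architecture classification: from domain/motif hits to subfamily labels.

#' Subfamily labels
#'
#' The six architecture subfamilies plus `none` for proteins without a
#' qualifying p25alpha region.
#'
#' @format Character vector of length 7.
#' @export
SUBFAMILY_LABELS <- c("long_type", "short_type", "truncated", "partial_only",
                      "multidomain", "apicortin", "none")

#' Classify one protein into an architecture subfamily
#'
#' Applies the decision rules that define the TPPP-like subfamilies, in
#' fixed precedence order:
#'
#' 1. scan the sequence for long-domain fragments
#'    ([measure_fragments()]), full partial-core blocks, Rossmann-like
#'    motifs and extensions;
#' 2. a free-standing partial core together with an annotated DCX domain
#'    is an **apicortin** (this outranks the long-domain rule; a conflict
#'    is logged as a warning);
#' 3. a single contiguous region spanning core plus partial core (gap at
#'    most `gap_tolerance`), 140-160 aa, with no foreign domains, is a
#'    **long-type** TPPP; an N-terminal tail is flagged when at least
#'    `min_tail` residues precede the domain;
#' 4. a single core-like region without the partial block and without
#'    foreign domains is a **short-type** TPPP by default, or **truncated**
#'    when its normalized core affinity reaches `truncated_affinity` *and*
#'    the caller-supplied taxon is metazoan (truncated TPPPs are
#'    arthropod-specific paralogs; sequence alone cannot separate the two,
#'    so the undecidable case defaults to short-type and the ambiguity is
#'    recorded in the evidence);
#' 5. p25alpha fragments (70-140 aa) co-occurring with foreign domains, or
#'    two or more fragments in one protein, make a **multidomain** protein;
#' 6. only free-standing partial cores make a **partial-only** protein,
#'    with per-copy Rossmann-motif flags and an extension flag;
#' 7. otherwise the label is **none**.
#'
#' Foreign domains (DCX, EFh, IQ, ...) are taken from annotations, not
#' detected ab initio.
#'
#' @param seq Amino-acid sequence (single string).
#' @param model A `p25_model`.
#' @param foreign Optional tibble of foreign-domain annotations with columns
#'   `name`, `start`, `end`.
#' @param taxon Optional species binomial for the truncated/short decision.
#' @param taxonomy Optional taxonomy table ([load_taxonomy()]) used to
#'   decide whether `taxon` is metazoan.
#' @param config A [run_config()].
#' @return A one-row tibble: `label`, `n_p25_copies`, `n_partial_copies`,
#'   `has_rossmann` (list column, one logical per partial copy),
#'   `has_extension`, `has_ntail`, `other_domains` (list column),
#'   `evidence` (list column of hit tibbles).
#' @examples
#' model <- default_p25_model()
#' seq <- paste0(model$segments$core$consensus,
#'               model$segments$partial_core$consensus)
#' classify_architecture(seq, model)$label
#' @export
classify_architecture <- function(seq, model, foreign = NULL, taxon = NULL,
                                  taxonomy = NULL, config = run_config()) {
  .check_sequence(seq)
  stopifnot(inherits(model, "p25_model"))
  foreign <- foreign %||% tibble(name = character(), start = integer(),
                                 end = integer())
  foreign_names <- unique(foreign$name)

  frags <- measure_fragments(seq, model, config$min_normalized)
  partial_hits <- scan_profile(seq, model, "partial_core",
                               config$min_normalized, config)
  motifs <- find_rossmann_motifs(seq)

  overlaps_frag <- function(s, e) {
    nrow(frags) > 0 && any(s <= frags$end & e >= frags$start)
  }
  standalone <- partial_hits[!purrr::map2_lgl(partial_hits$start,
                                              partial_hits$end,
                                              overlaps_frag), ]
  evidence <- list(fragments = frags, partial_hits = partial_hits,
                   motifs = motifs, notes = character())

  partial_flags <- function(hits) {
    map_lgl(seq_len(nrow(hits)), function(i) {
      any(motifs$start >= hits$start[[i]] & motifs$end <= hits$end[[i]])
    })
  }
  extension_after <- function(hits) {
    any(map_lgl(seq_len(nrow(motifs)), function(i) {
      inside <- any(motifs$start[[i]] >= hits$start & motifs$end[[i]] <= hits$end)
      inside && !is.null(detect_extension(seq, motifs[i, ], model,
                                          config$min_normalized))
    }))
  }
  call_row <- function(label, n_p25 = 0L, n_partial = 0L,
                       rossmann = logical(0), has_ext = FALSE,
                       has_ntail = FALSE) {
    tibble(
      label = label, n_p25_copies = as.integer(n_p25),
      n_partial_copies = as.integer(n_partial),
      has_rossmann = list(rossmann), has_extension = has_ext,
      has_ntail = has_ntail, other_domains = list(foreign_names),
      evidence = list(evidence)
    )
  }

  single_long <- nrow(frags) == 1 && frags$length[[1]] >= 140 &&
    frags$length[[1]] <= 160
  any_partial <- nrow(partial_hits) > 0

  # (2) apicortin: partial p25alpha combined with an annotated DCX domain
  if ("DCX" %in% foreign_names && any_partial) {
    hits <- if (nrow(standalone)) standalone else partial_hits
    if (single_long) {
      warn("sequence matches both the apicortin and long-type rules; apicortin takes precedence")
    }
    return(call_row("apicortin", n_partial = nrow(hits),
                    rossmann = partial_flags(hits),
                    has_ext = extension_after(hits)))
  }

  # (3) long-type: one contiguous core + partial-core span of 140-160 aa
  if (single_long && length(foreign_names) == 0 && nrow(standalone) == 0) {
    inside <- partial_hits[partial_hits$start >= frags$start[[1]] &
                             partial_hits$end <= frags$end[[1]] +
                             config$gap_tolerance, ]
    if (nrow(inside) > 0) {
      first_hit <- frags[1, ]
      return(call_row("long_type", n_p25 = 1L, n_partial = nrow(inside),
                      rossmann = partial_flags(inside),
                      has_ext = extension_after(inside),
                      has_ntail = detect_nterminal_tail(seq, first_hit,
                                                        config$min_tail)))
    }
  }

  # (4) short-type / truncated: one core-like region, no partial block
  if (nrow(frags) == 1 && frags$length[[1]] < 140 &&
      length(foreign_names) == 0 && nrow(standalone) == 0) {
    core_aff <- .core_affinity(seq, model, frags[1, ])
    metazoan <- .is_metazoan(taxon, taxonomy)
    if (is.na(metazoan)) {
      evidence$notes <- c(evidence$notes,
                          "no taxon supplied; truncated/short undecidable, defaulting to short_type")
    }
    label <- if (core_aff >= config$truncated_affinity && isTRUE(metazoan)) {
      "truncated"
    } else {
      "short_type"
    }
    return(call_row(label, n_p25 = 1L))
  }

  # (5) multidomain: fragment(s) with foreign domains, or >= 2 fragments
  if ((nrow(frags) >= 1 && length(foreign_names) > 0) || nrow(frags) >= 2) {
    return(call_row("multidomain", n_p25 = nrow(frags),
                    n_partial = nrow(standalone),
                    rossmann = partial_flags(standalone),
                    has_ext = FALSE))
  }

  # (6) partial-only: free-standing partial cores and nothing else
  if (nrow(frags) == 0 && nrow(standalone) >= 1) {
    return(call_row("partial_only", n_partial = nrow(standalone),
                    rossmann = partial_flags(standalone),
                    has_ext = extension_after(standalone)))
  }

  # (7) none
  call_row("none")
}

# Normalized affinity of a core-like region to the full core profile,
# computed over the columns the region actually covers.
.core_affinity <- function(seq, model, frag) {
  mat <- model$segments$core$mat
  w <- min(ncol(mat), frag$length[[1]], nchar(seq) - frag$start[[1]] + 1L)
  cols <- seq_len(w)
  idx <- .seq_idx(seq)[frag$start[[1]] + cols - 1L]
  raw <- sum(mat[cbind(idx, cols)])
  raw / sum(apply(mat[AA_ALPHABET, cols, drop = FALSE], 2, max))
}

.is_metazoan <- function(taxon, taxonomy) {
  if (is.null(taxon) || is.na(taxon)) return(NA)
  taxonomy <- taxonomy %||% load_taxonomy()
  row <- taxonomy[taxonomy$species == taxon, ]
  if (nrow(row) == 0) return(NA)
  grepl("(^|\\|)Metazoa(\\||$)", row$path[[1]])
}

#' Classify a table of protein records
#'
#' Tidy front end to [classify_architecture()]: takes a record tibble (as
#' returned by [read_fasta()] or [generate_dataset()]), classifies every
#' sequence and returns one call row per record.
#'
#' @param records Tibble with columns `id`, `species`, `sequence` (and
#'   optionally `is_est`).
#' @param model A `p25_model`.
#' @param annotations Optional tibble of foreign-domain annotations with
#'   columns `id`, `name`, `start`, `end`.
#' @param taxonomy Optional taxonomy tibble; defaults to the packaged one.
#' @param config A [run_config()].
#' @return Tibble: `id`, `species`, `is_est` plus the
#'   [classify_architecture()] columns.
#' @export
classify_proteins <- function(records, model = default_p25_model(),
                              annotations = NULL, taxonomy = NULL,
                              config = run_config()) {
  stopifnot(is.data.frame(records), all(c("id", "sequence") %in% names(records)))
  taxonomy <- taxonomy %||% load_taxonomy()
  calls <- purrr::list_rbind(map(seq_len(nrow(records)), function(i) {
    foreign <- NULL
    if (!is.null(annotations)) {
      foreign <- annotations[annotations$id == records$id[[i]],
                             c("name", "start", "end")]
    }
    classify_architecture(records$sequence[[i]], model, foreign = foreign,
                          taxon = records$species[[i]], taxonomy = taxonomy,
                          config = config)
  }))
  bind_cols(
    tibble(id = records$id,
           species = records$species %||% NA_character_,
           is_est = if ("is_est" %in% names(records)) records$is_est else FALSE),
    calls
  )
}

#' Count disjoint domain copies
#'
#' @param hits Tibble of hits with `start` and `end`; they must be
#'   non-overlapping (scanning output always is).
#' @return Integer count of disjoint hits.
#' @export
count_domain_copies <- function(hits) {
  if (nrow(hits) <= 1) return(nrow(hits))
  h <- arrange(hits, .data$start)
  if (any(h$start[-1] <= h$end[-nrow(h)])) {
    abort("hits overlap; count_domain_copies expects non-overlapping hits")
  }
  nrow(h)
}

#' Detect an N-terminal tail before the first domain hit
#'
#' @param seq The sequence (used only for validation).
#' @param first_hit One-row tibble with the `start` of the first domain hit
#'   (1-based).
#' @param min_tail Minimum number of residues preceding the hit.
#' @return `TRUE` when at least `min_tail` residues precede the domain.
#' @export
detect_nterminal_tail <- function(seq, first_hit, min_tail = 40L) {
  s <- as.integer(first_hit$start[[1]])
  if (is.na(s) || s < 1 || s > nchar(seq)) abort("first_hit must lie within seq")
  (s - 1L) >= min_tail
}
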