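# Gapless profile scanning, motif matching and fragment measurement.
# Coordinates are 1-based and inclusive throughout the package, the usual R
# convention; a hit of width w satisfies end - start + 1 == w.

# Raw window scores of a score matrix at every offset of a sequence.
.window_scores <- function(idx, mat) {
  w <- ncol(mat)
  n <- length(idx)
  if (n < w) return(numeric(0))
  offsets <- seq_len(n - w + 1L)
  cols <- seq_len(w)
  vapply(offsets, function(o) sum(mat[cbind(idx[o + cols - 1L], cols)]),
         numeric(1))
}

# Greedy non-overlap selection: highest score first, leftmost wins ties.
# Scores are rounded to 1e-9 for ordering so that exact score ties (common
# with two-valued single-sequence profile columns) break deterministically
# by position regardless of floating-point summation order.
.greedy_select <- function(start, end, score) {
  ord <- order(-round(score, 9), start)
  taken_s <- integer(0)
  taken_e <- integer(0)
  keep <- logical(length(start))
  for (i in ord) {
    if (!any(start[i] <= taken_e & end[i] >= taken_s)) {
      keep[i] <- TRUE
      taken_s <- c(taken_s, start[i])
      taken_e <- c(taken_e, end[i])
    }
  }
  keep
}

.tier_of <- function(normalized, config) {
  dplyr::case_when(
    normalized >= config$tier_strong ~ "strong",
    normalized >= config$tier_weak ~ "weak",
    TRUE ~ "candidate"
  )
}

#' Scan a sequence with one segment profile
#'
#' Slides the segment's score columns gaplessly across the sequence, scoring
#' every offset, and returns non-overlapping hits whose normalized score
#' (raw score divided by the maximum attainable score, i.e. the sum of
#' per-column maxima) reaches `min_normalized`. Overlapping candidates are
#' resolved greedily by score, leftmost winning ties, so the reported hits
#' are the local maxima of the score landscape. Hits are tiered `strong`
#' (normalized score >= 0.80 by default), `weak` (>= 0.55) or `candidate`.
#'
#' @param seq Amino-acid sequence (single string).
#' @param model A [build_model()] / [default_p25_model()] object.
#' @param segment Segment name, e.g. `"core"` or `"partial_core"`.
#' @param min_normalized Minimum normalized score in `[0, 1]` for a hit.
#' @param config A [run_config()]; supplies the tier thresholds.
#' @return Tibble with columns `segment`, `start`, `end`, `score`,
#'   `normalized_score`, `tier`, sorted by `start`. A segment longer than
#'   the sequence yields zero rows (not an error).
#' @examples
#' model <- default_p25_model()
#' scan_profile(model$segments$core$consensus, model, "core")
#' @export
scan_profile <- function(seq, model, segment, min_normalized = 0.55,
                         config = run_config()) {
  .check_sequence(seq)
  stopifnot(inherits(model, "p25_model"))
  if (!segment %in% names(model$segments)) {
    abort(sprintf("unknown model segment '%s'", segment))
  }
  if (min_normalized < 0 || min_normalized > 1) {
    abort("min_normalized must lie in [0, 1]")
  }
  mat <- model$segments[[segment]]$mat
  idx <- .seq_idx(seq)
  raw <- .window_scores(idx, mat)
  empty <- tibble(segment = character(), start = integer(), end = integer(),
                  score = numeric(), normalized_score = numeric(),
                  tier = character())
  if (!length(raw)) return(empty)
  max_attainable <- sum(apply(mat[AA_ALPHABET, , drop = FALSE], 2, max))
  normalized <- raw / max_attainable
  cand <- which(normalized >= min_normalized)
  if (!length(cand)) return(empty)
  w <- ncol(mat)
  start <- cand
  end <- cand + w - 1L
  keep <- .greedy_select(start, end, raw[cand])
  out <- tibble(
    segment = segment,
    start = start[keep],
    end = end[keep],
    score = raw[cand][keep],
    normalized_score = normalized[cand][keep],
    tier = .tier_of(normalized[cand][keep], config)
  )
  arrange(out, .data$start)
}

#' Locate GXGXGXXGR Rossmann-like motifs
#'
#' Finds every (possibly overlapping) 9-mer matching the pattern: glycine at
#' motif positions 1, 3, 5 and 8, arginine at position 9, any residue
#' elsewhere.
#'
#' @param seq Amino-acid sequence (single string). An empty result is a
#'   zero-row tibble.
#' @return Tibble with `start`, `end` (1-based inclusive, `end - start = 8`)
#'   and `matched`, ordered left to right.
#' @examples
#' find_rossmann_motifs("GAGAGAAGR")
#' @export
find_rossmann_motifs <- function(seq) {
  if (!nzchar(seq)) {
    return(tibble(start = integer(), end = integer(), matched = character()))
  }
  .check_sequence(seq)
  m <- gregexpr(paste0("(?=", ROSSMANN_PATTERN, ")"), seq, perl = TRUE)[[1]]
  starts <- as.integer(m[m > 0])
  tibble(
    start = starts,
    end = starts + 8L,
    matched = stringr::str_sub(seq, starts, starts + 8L)
  )
}

#' Detect the 14-residue extension block after a Rossmann-like motif
#'
#' Scores the 14-residue window starting immediately after the motif against
#' the model's `extension` columns. The region is reported only when at
#' least 14 residues remain and the normalized score reaches
#' `min_normalized`; its length is always exactly 14.
#'
#' @param seq Amino-acid sequence containing the motif.
#' @param motif One row of [find_rossmann_motifs()] output (or a list with
#'   `start` and `end`).
#' @param model A `p25_model` with an `extension` segment.
#' @param min_normalized Minimum normalized score for acceptance.
#' @return A one-row tibble (`start`, `end`, `score`, `normalized_score`) or
#'   `NULL` when no extension qualifies.
#' @export
detect_extension <- function(seq, motif, model, min_normalized = 0.55) {
  .check_sequence(seq)
  stopifnot(inherits(model, "p25_model"))
  if (!"extension" %in% names(model$segments)) {
    abort("model has no extension segment")
  }
  m_end <- as.integer(motif$end[[1]])
  if (is.na(m_end) || m_end < 1 || m_end > nchar(seq)) {
    abort("motif must be a hit within seq")
  }
  mat <- model$segments$extension$mat
  w <- ncol(mat)
  start <- m_end + 1L
  if (start + w - 1L > nchar(seq)) return(NULL)
  idx <- .seq_idx(seq)[start:(start + w - 1L)]
  raw <- sum(mat[cbind(idx, seq_len(w))])
  max_attainable <- sum(apply(mat[AA_ALPHABET, , drop = FALSE], 2, max))
  normalized <- raw / max_attainable
  if (normalized < min_normalized) return(NULL)
  tibble(start = start, end = start + w - 1L, score = raw,
         normalized_score = normalized)
}

#' Measure p25alpha fragments of variable length
#'
#' Multidomain TPPP-like proteins carry p25alpha fragments of roughly 70-140
#' aa: the first half of the domain is always present while the C-terminal
#' extent varies. This scanner anchors candidate fragments with the first 70
#' columns of the combined core + partial-core profile, then chooses the
#' fragment end as the width `w` maximizing the cumulative column score
#' minus a per-column penalty of half a consensus match, which stops the
#' extension at the point where columns cease to look like the domain (on a
#' noise-free sequence the measured width equals the planted width exactly).
#'
#' @param seq Amino-acid sequence.
#' @param model A `p25_model`.
#' @param min_normalized Minimum normalized score of the 70-column anchor.
#' @param anchor_width Anchor width in columns (default 70, the documented
#'   minimum fragment length).
#' @return Tibble with `start`, `end`, `length`, `score`,
#'   `normalized_score` (over the measured columns), sorted by `start`.
#' @export
measure_fragments <- function(seq, model, min_normalized = 0.55,
                              anchor_width = 70L) {
  .check_sequence(seq)
  stopifnot(inherits(model, "p25_model"))
  long_mat <- cbind(model$segments$core$mat, model$segments$partial_core$mat)
  if (anchor_width > ncol(long_mat)) {
    abort("anchor_width exceeds the long-domain profile width")
  }
  anchor_mat <- long_mat[, seq_len(anchor_width), drop = FALSE]
  idx <- .seq_idx(seq)
  raw <- .window_scores(idx, anchor_mat)
  empty <- tibble(start = integer(), end = integer(), length = integer(),
                  score = numeric(), normalized_score = numeric())
  if (!length(raw)) return(empty)
  anchor_max <- sum(apply(anchor_mat[AA_ALPHABET, , drop = FALSE], 2, max))
  cand <- which(raw / anchor_max >= min_normalized)
  if (!length(cand)) return(empty)
  keep <- .greedy_select(cand, cand + anchor_width - 1L, raw[cand])
  anchors <- cand[keep]

  col_max <- apply(long_mat[AA_ALPHABET, , drop = FALSE], 2, max)
  half_match <- mean(col_max) / 2
  frags <- purrr::list_rbind(map(anchors, function(s) {
    wmax <- min(ncol(long_mat), nchar(seq) - s + 1L)
    cols <- seq_len(wmax)
    colscore <- long_mat[cbind(idx[s + cols - 1L], cols)]
    objective <- cumsum(colscore) - half_match * cols
    w <- which.max(objective)          # ties: shortest width
    if (w < anchor_width) w <- anchor_width
    tibble(
      start = s, end = s + w - 1L, length = w,
      score = sum(colscore[seq_len(w)]),
      normalized_score = sum(colscore[seq_len(w)]) / sum(col_max[seq_len(w)])
    )
  }))
  # extensions may collide when anchors were close; keep the higher score
  frags <- frags[.greedy_select(frags$start, frags$end, frags$score), ]
  arrange(frags, .data$start)
}
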