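# Global pairwise alignment statistics and reciprocal best hits.

# Substitution matrix over the 21-letter alphabet: +match on the diagonal,
# +mismatch elsewhere; X never counts as a match.
.identity_matrix <- function(match, mismatch) {
  m <- matrix(mismatch, nrow = length(.AA_X), ncol = length(.AA_X),
              dimnames = list(.AA_X, .AA_X))
  diag(m) <- match
  m["X", "X"] <- mismatch
  m
}

#' Global alignment identity and similarity
#'
#' Aligns two sequences globally with affine gap penalties (Needleman-
#' Wunsch/Gotoh, via `Biostrings::pairwiseAlignment()`) and reports percent
#' identity and percent similarity over the alignment columns, excluding
#' terminal gap columns. Similarity additionally credits substitutions
#' within the strong residue classes of [SIMILARITY_GROUPS].
#'
#' @param a,b Amino-acid sequences (single strings).
#' @param gap_open,gap_extend Affine gap penalties (positive costs; opening
#'   a gap costs `gap_open + gap_extend`).
#' @param match,mismatch Substitution scores.
#' @return One-row tibble: `identity`, `similarity` (percent), `score`
#'   (alignment score), `columns` (columns counted, i.e. excluding terminal
#'   gaps).
#' @examples
#' pairwise_align_stats("AAAA", "AAAT")
#' @export
pairwise_align_stats <- function(a, b, gap_open = 10, gap_extend = 0.5,
                                 match = 2, mismatch = -1) {
  .check_sequence(a, "a")
  .check_sequence(b, "b")
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b),
    substitutionMatrix = .identity_matrix(match, mismatch),
    gapOpening = gap_open, gapExtension = gap_extend, type = "global"
  )
  pa <- .seq_chars(as.character(Biostrings::alignedPattern(aln)))
  pb <- .seq_chars(as.character(Biostrings::alignedSubject(aln)))
  .alignment_stats(pa, pb, score = Biostrings::score(aln))
}

# Identity/similarity from two aligned character vectors.
.alignment_stats <- function(pa, pb, score = NA_real_) {
  gap_a <- pa == "-"
  gap_b <- pb == "-"
  non_gap <- which(!(gap_a & gap_b))
  # trim terminal gap columns (leading/trailing columns gapped in either row)
  interior <- which(!gap_a & !gap_b)
  if (length(interior) == 0) {
    return(tibble(identity = 0, similarity = 0, score = score, columns = 0L))
  }
  keep <- seq(min(interior), max(interior))
  pa <- pa[keep]
  pb <- pb[keep]
  ncol_counted <- length(keep)
  ident <- pa == pb & pa != "-"
  simil <- ident | (pa != "-" & pb != "-" &
                      .sim_group_id[pa] == .sim_group_id[pb] &
                      .sim_group_id[pa] != 0)
  tibble(
    identity = 100 * sum(ident) / ncol_counted,
    similarity = 100 * sum(simil) / ncol_counted,
    score = score,
    columns = ncol_counted
  )
}

#' Reciprocal best hits between two protein sets
#'
#' A pair `(a, b)` is reported when `b` is the highest-scoring match of `a`
#' in `set_b` *and* `a` is the highest-scoring match of `b` in `set_a` --
#' the classic operational test for 1:1 orthology. Ties at an argmax are
#' broken by lexicographic id and reported via a message.
#'
#' @param set_a,set_b Tibbles of protein records (`id`, `sequence`).
#' @param scorer Function of two sequences returning a numeric score;
#'   defaults to percent identity from [pairwise_align_stats()].
#' @return Tibble with `id_a`, `id_b` and `score`, ordered by `id_a`.
#' @export
reciprocal_best_hits <- function(set_a, set_b, scorer = NULL) {
  stopifnot(is.data.frame(set_a), is.data.frame(set_b),
            nrow(set_a) > 0, nrow(set_b) > 0)
  scorer <- scorer %||% function(x, y) pairwise_align_stats(x, y)$identity
  scores <- matrix(
    NA_real_, nrow = nrow(set_a), ncol = nrow(set_b),
    dimnames = list(set_a$id, set_b$id)
  )
  for (i in seq_len(nrow(set_a))) {
    for (j in seq_len(nrow(set_b))) {
      scores[i, j] <- scorer(set_a$sequence[[i]], set_b$sequence[[j]])
    }
  }
  best_of <- function(v, ids) {
    top <- which(v == max(v))
    if (length(top) > 1) {
      inform(sprintf("argmax tie among {%s}; lexicographic id wins",
                     paste(ids[top], collapse = ", ")))
      top <- top[order(ids[top])]
    }
    top[[1]]
  }
  best_b <- vapply(seq_len(nrow(scores)), function(i)
    best_of(scores[i, ], colnames(scores)), integer(1))
  best_a <- vapply(seq_len(ncol(scores)), function(j)
    best_of(scores[, j], rownames(scores)), integer(1))
  pairs <- tibble(
    id_a = rownames(scores),
    id_b = colnames(scores)[best_b],
    score = scores[cbind(seq_len(nrow(scores)), best_b)]
  )
  keep <- vapply(seq_len(nrow(pairs)), function(i) {
    best_a[[best_b[[i]]]] == i
  }, logical(1))
  arrange(pairs[keep, ], .data$id_a)
}
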