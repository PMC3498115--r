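# Independent brute-force oracles used to verify the package's scanners and
# aligner. These deliberately re-derive everything with plain loops.

# one shared model for the whole suite (cheap to build, but tidier to reuse)
test_model <- local({
  m <- NULL
  function() {
    if (is.null(m)) m <<- default_p25_model()
    m
  }
})

consensus_of <- function(segment) test_model()$segments[[segment]]$consensus

long_consensus <- function(with_ntail = TRUE, with_extension = TRUE) {
  m <- test_model()
  paste0(
    if (with_ntail) m$segments$ntail$consensus else "",
    m$segments$core$consensus,
    m$segments$partial_core$consensus,
    if (with_extension) m$segments$extension$consensus else ""
  )
}

random_seq <- function(n) paste(sample(AA_ALPHABET, n, replace = TRUE), collapse = "")

# --- profile-scan oracle: explicit loops over every offset -----------------

oracle_scan <- function(seq, model, segment, min_normalized) {
  mat <- model$segments[[segment]]$mat
  w <- ncol(mat)
  chars <- strsplit(seq, "")[[1]]
  n <- length(chars)
  out <- data.frame(start = integer(0), end = integer(0), score = numeric(0),
                    normalized_score = numeric(0))
  if (n < w) return(out)
  max_att <- 0
  for (j in seq_len(w)) max_att <- max_att + max(mat[AA_ALPHABET, j])
  scores <- numeric(n - w + 1)
  for (o in seq_len(n - w + 1)) {
    s <- 0
    for (j in seq_len(w)) s <- s + mat[chars[o + j - 1], j]
    scores[o] <- s
  }
  norm <- scores / max_att
  cand <- which(norm >= min_normalized)
  if (!length(cand)) return(out)
  # greedy: best score first, leftmost on ties (scores rounded as in the
  # implementation so fp summation order cannot flip a tie), no overlaps
  ord <- cand[order(-round(scores[cand], 9), cand)]
  chosen <- integer(0)
  for (o in ord) {
    if (!any(abs(chosen - o) < w)) chosen <- c(chosen, o)
  }
  chosen <- sort(chosen)
  data.frame(start = chosen, end = chosen + w - 1L, score = scores[chosen],
             normalized_score = norm[chosen])
}

# --- motif oracle: positional 9-mer check at every offset ------------------

oracle_motifs <- function(seq) {
  chars <- strsplit(seq, "")[[1]]
  n <- length(chars)
  starts <- integer(0)
  if (n >= 9) {
    for (i in seq_len(n - 8)) {
      if (chars[i] == "G" && chars[i + 2] == "G" && chars[i + 4] == "G" &&
          chars[i + 7] == "G" && chars[i + 8] == "R") {
        starts <- c(starts, i)
      }
    }
  }
  starts
}

# --- global affine-gap alignment score oracle (Gotoh, three matrices) ------

oracle_align_score <- function(a, b, gap_open = 10, gap_extend = 0.5,
                               match = 2, mismatch = -1) {
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  n <- length(A)
  m <- length(B)
  NEG <- -1e9
  open1 <- gap_open + gap_extend
  M <- matrix(NEG, n + 1, m + 1)
  X <- matrix(NEG, n + 1, m + 1)  # gap in b (vertical)
  Y <- matrix(NEG, n + 1, m + 1)  # gap in a (horizontal)
  M[1, 1] <- 0
  for (i in 2:(n + 1)) X[i, 1] <- -(gap_open + gap_extend * (i - 1))
  for (j in 2:(m + 1)) Y[1, j] <- -(gap_open + gap_extend * (j - 1))
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      s <- if (A[i - 1] == B[j - 1]) match else mismatch
      M[i, j] <- max(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1]) + s
      X[i, j] <- max(M[i - 1, j] - open1, X[i - 1, j] - gap_extend,
                     Y[i - 1, j] - open1)
      Y[i, j] <- max(M[i, j - 1] - open1, X[i, j - 1] - open1,
                     Y[i, j - 1] - gap_extend)
    }
  }
  max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
}

# --- reciprocal-best-hit oracle: brute-force double argmax -----------------

oracle_rbh <- function(scores) {
  pairs <- list()
  for (i in seq_len(nrow(scores))) {
    for (j in seq_len(ncol(scores))) {
      row_best <- which(scores[i, ] == max(scores[i, ]))
      row_best <- row_best[order(colnames(scores)[row_best])][1]
      col_best <- which(scores[, j] == max(scores[, j]))
      col_best <- col_best[order(rownames(scores)[col_best])][1]
      if (row_best == j && col_best == i) {
        pairs[[length(pairs) + 1]] <- c(rownames(scores)[i], colnames(scores)[j])
      }
    }
  }
  if (!length(pairs)) return(data.frame(id_a = character(0), id_b = character(0)))
  df <- as.data.frame(do.call(rbind, pairs), stringsAsFactors = FALSE)
  names(df) <- c("id_a", "id_b")
  df[order(df$id_a), , drop = FALSE]
}
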