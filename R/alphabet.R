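# Amino-acid alphabet, hydropathy and charge constants shared across modules.

#' The 20-letter amino-acid alphabet
#'
#' Standard one-letter residue codes. Sequences handled by the package may
#' additionally contain `X` for an unknown or non-standard residue; parsers
#' map the ambiguity codes `B`, `Z`, `U` and the stop marker `*` to `X`.
#'
#' @format Character vector of length 20.
#' @export
AA_ALPHABET <- c(
  "A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
  "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V"
)

# Alphabet used in scoring matrices: 20 residues plus X (scored as unseen).
.AA_X <- c(AA_ALPHABET, "X")

# Kyte-Doolittle hydropathy index, the standard per-residue scale.
.KD_HYDROPATHY <- c(
  A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5,
  Q = -3.5, E = -3.5, G = -0.4, H = -3.2, I = 4.5,
  L = 3.8, K = -3.9, M = 1.9, F = 2.8, P = -1.6,
  S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2
)

# Formal side-chain charge at neutral pH used by the disorder profiler:
# K and R count +1, D and E count -1, everything else 0.
.AA_CHARGE <- c(K = 1, R = 1, D = -1, E = -1)

#' Strong similarity groups used for percent-similarity
#'
#' Residue classes within which a substitution is counted as "similar" by
#' [pairwise_align_stats()]. These are the conventional strong groups used by
#' multiple-alignment viewers.
#'
#' @format A list of character vectors.
#' @export
SIMILARITY_GROUPS <- list(
  c("I", "L", "V", "M"),
  c("F", "Y", "W"),
  c("K", "R", "H"),
  c("D", "E"),
  c("S", "T"),
  c("N", "Q"),
  c("A", "G")
)

# residue -> similarity group id (0 = no group)
.sim_group_id <- local({
  g <- setNames(rep(0L, length(.AA_X)), .AA_X)
  for (i in seq_along(SIMILARITY_GROUPS)) g[SIMILARITY_GROUPS[[i]]] <- i
  g
})

# Split a sequence string into residue characters.
.seq_chars <- function(seq) strsplit(seq, "", fixed = TRUE)[[1]]

# Map residues to row indices of a scoring matrix (21 rows: AA + X).
.seq_idx <- function(seq) {
  idx <- match(.seq_chars(seq), .AA_X)
  if (anyNA(idx)) {
    abort(paste0(
      "sequence contains characters outside the amino-acid alphabet: ",
      paste(unique(.seq_chars(seq)[is.na(idx)]), collapse = ", ")
    ))
  }
  idx
}

# Validate a protein sequence: non-empty, alphabet only.
.check_sequence <- function(seq, what = "sequence") {
  if (!is.character(seq) || length(seq) != 1 || is.na(seq) || !nzchar(seq)) {
    abort(sprintf("%s must be a single non-empty string", what))
  }
  invisible(.seq_idx(seq))
}

#' Sanitize non-standard residues
#'
#' Maps the ambiguity codes `B`, `Z`, `U` and the stop/frameshift marker `*`
#' to `X`, with a warning. Translated EST reads routinely carry these.
#'
#' @param seq Character vector of amino-acid sequences.
#' @return The sanitized character vector.
#' @export
sanitize_sequence <- function(seq) {
  bad <- stringr::str_detect(seq, "[BZU*]")
  if (any(bad)) {
    warn(sprintf(
      "%d sequence(s) contained non-standard residues (B/Z/U/*); mapped to X",
      sum(bad)
    ))
    seq <- stringr::str_replace_all(seq, "[BZU*]", "X")
  }
  toupper(seq)
}
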