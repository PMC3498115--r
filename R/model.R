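# The segmented p25alpha domain model: per-segment position-specific score
# columns built from seed alignments, plus the packaged synthetic consensus.

# Designed synthetic consensus segments. These are not copied from any
# database sequence: the core is hydrophobic-leaning (ordered), the partial
# core and extension are charge-enriched (disordered), and the partial core
# carries exactly one planted GXGXGXXGR Rossmann-like motif. Geometry:
# core 119 aa + partial core 31 aa = 150 aa long domain (within the
# documented 140-160 aa band), extension 14 aa, N-tail 50 aa.
.CONSENSUS <- list(
  ntail = "KSDRKRTGDEKEGSQPGHSQTKGEKSESASPDPKAGQEQSAGQDPQEPQG",
  core = paste0(
    "AYAVLLIFGAMIAIGVAELYIKIIAMYAENASAISVSLVVVLGYEEAAKTGIIWTVLAHT",
    "NSIAVLSLAGWAAVSAFVVTFLLGHTFFWFGTVVSAVSLYTFIAFVFLIVIMAEMALIS"
  ),
  partial_core = "KDAASSRGQDRKKRPRKQQTPGGEGKGEKGR",
  extension = "SERKDEAKQKKPKK"
)

#' The GXGXGXXGR Rossmann-like motif pattern
#'
#' Glycines at motif positions 1, 3, 5 and 8 and an arginine at position 9;
#' any residue elsewhere. Used as a perl regex by [find_rossmann_motifs()].
#'
#' @format A single string (regular expression).
#' @export
ROSSMANN_PATTERN <- "G.G.G..GR"

# Length constraints the model must satisfy (amino acids).
.LENGTH_BOUNDS <- list(
  long_domain = c(140L, 160L),
  partial_core = c(31L, 32L),
  extension = c(14L, 14L),
  fragment = c(70L, 140L),
  ntail = c(30L, 70L)
)

#' Build a segmented p25alpha profile model
#'
#' Constructs per-position log-odds score columns for each domain segment
#' from a (possibly single-sequence) gapless alignment. The score of residue
#' `a` at position `i` is
#' `log((count(i, a) + pseudocount) / (n + 20 * pseudocount)) - log(1/20)`,
#' i.e. observed frequency with additive smoothing against a uniform
#' background. The consensus is the argmax residue of each column. `X`
#' residues in scanned sequences are scored as unseen (count 0).
#'
#' @param seed_alignments Named list of character vectors. Names must include
#'   `core` and `partial_core`; `ntail` and `extension` are optional. Each
#'   vector is an alignment: all sequences the same length, no gaps.
#' @param pseudocount Positive smoothing constant added to every residue
#'   count in every column. Default 0.5.
#' @return An object of class `p25_model`: a list with `segments` (per
#'   segment: `consensus` string and `mat`, a 21 x width score matrix),
#'   `rossmann_offset` and `pseudocount`.
#' @details Validation enforces the domain geometry: combined core +
#'   partial-core length in 140-160 aa, partial core 31-32 aa containing
#'   exactly one Rossmann-like motif match, extension exactly 14 aa.
#' @seealso [default_p25_model()] for the packaged synthetic model,
#'   [scan_profile()] for scanning.
#' @examples
#' m <- build_model(list(
#'   core = paste(rep("ACDEFGHIKLMNPQRSTVWY", 6), collapse = ""),
#'   partial_core = "KDAASSRGQDRKKRPRKQQTPGGEGKGEKGR"
#' ))
#' glance(m)
#' @export
build_model <- function(seed_alignments, pseudocount = 0.5) {
  if (!is.list(seed_alignments) || is.null(names(seed_alignments))) {
    abort("seed_alignments must be a named list of character vectors")
  }
  if (!is.numeric(pseudocount) || pseudocount <= 0) {
    abort("pseudocount must be a positive real")
  }
  required <- c("core", "partial_core")
  missing <- setdiff(required, names(seed_alignments))
  if (length(missing)) {
    abort(paste0("seed_alignments must contain segment(s): ",
                 paste(missing, collapse = ", ")))
  }
  segments <- imap(seed_alignments, function(aln, nm) {
    if (!is.character(aln) || length(aln) == 0) {
      abort(sprintf("segment '%s': alignment must be a non-empty character vector", nm))
    }
    widths <- nchar(aln)
    if (length(unique(widths)) != 1) {
      abort(sprintf("segment '%s': ragged alignment (lengths %s)",
                    nm, paste(unique(widths), collapse = ", ")))
    }
    .profile_columns(aln, pseudocount)
  })
  model <- structure(
    list(segments = segments, rossmann_offset = NA_integer_,
         pseudocount = pseudocount),
    class = "p25_model"
  )
  .validate_model(model)
}

# Log-odds columns for one segment alignment.
.profile_columns <- function(aln, pseudocount) {
  w <- nchar(aln[[1]])
  nseq <- length(aln)
  chars <- do.call(rbind, lapply(aln, .seq_chars))
  mat <- matrix(0, nrow = length(.AA_X), ncol = w,
                dimnames = list(.AA_X, NULL))
  background <- 1 / 20
  for (j in seq_len(w)) {
    counts <- table(factor(chars[, j], levels = AA_ALPHABET))
    freq <- (as.numeric(counts) + pseudocount) / (nseq + 20 * pseudocount)
    mat[AA_ALPHABET, j] <- log(freq) - log(background)
    # X (unseen/unknown residue) scores as a zero-count residue
    mat["X", j] <- log(pseudocount / (nseq + 20 * pseudocount)) - log(background)
  }
  consensus <- paste(AA_ALPHABET[apply(mat[AA_ALPHABET, , drop = FALSE], 2, which.max)],
                     collapse = "")
  list(consensus = consensus, mat = mat)
}

.validate_model <- function(model) {
  seg <- model$segments
  w <- function(nm) if (nm %in% names(seg)) ncol(seg[[nm]]$mat) else 0L
  long_len <- w("core") + w("partial_core")
  b <- .LENGTH_BOUNDS
  if (long_len < b$long_domain[1] || long_len > b$long_domain[2]) {
    abort(sprintf(
      "core + partial_core length %d violates the long-domain bound [%d, %d]",
      long_len, b$long_domain[1], b$long_domain[2]))
  }
  pw <- w("partial_core")
  if (pw < b$partial_core[1] || pw > b$partial_core[2]) {
    abort(sprintf("partial_core length %d violates the bound {31, 32}", pw))
  }
  hits <- find_rossmann_motifs(seg$partial_core$consensus)
  if (nrow(hits) != 1) {
    abort(sprintf(
      "partial_core consensus must contain exactly one Rossmann-like motif (found %d)",
      nrow(hits)))
  }
  model$rossmann_offset <- hits$start[[1]]
  if ("extension" %in% names(seg) && w("extension") != b$extension[1]) {
    abort(sprintf("extension length %d violates the bound of exactly 14 aa",
                  w("extension")))
  }
  model
}

#' The packaged synthetic p25alpha domain model
#'
#' A designed consensus model (one sequence per segment) satisfying the
#' documented domain geometry: 50 aa N-tail, 119 aa core, 31 aa partial core
#' containing one GXGXGXXGR motif, and a 14 aa extension; core +
#' partial core = 150 aa. The core consensus is hydrophobic-leaning and the
#' partial core/extension are charge-enriched, so ordered/disordered
#' contrasts between subfamilies are reproduced by construction.
#'
#' @param pseudocount Passed to [build_model()].
#' @return A `p25_model`.
#' @examples
#' model <- default_p25_model()
#' nchar(model$segments$core$consensus)
#' @export
default_p25_model <- function(pseudocount = 0.5) {
  build_model(lapply(.CONSENSUS, identity), pseudocount = pseudocount)
}

#' @export
print.p25_model <- function(x, ...) {
  widths <- map_int(x$segments, ~ ncol(.x$mat))
  cat("<p25_model>\n")
  cat("  segments:",
      paste(sprintf("%s (%d aa)", names(widths), widths), collapse = ", "), "\n")
  cat("  long domain:", sum(widths[names(widths) %in% c("core", "partial_core")]),
      "aa; Rossmann motif offset in partial_core:", x$rossmann_offset, "\n")
  invisible(x)
}

#' @rdname build_model
#' @param x A `p25_model`.
#' @param ... Unused.
#' @export
tidy.p25_model <- function(x, ...) {
  purrr::list_rbind(imap(x$segments, function(s, nm) {
    tibble(
      segment = nm,
      position = seq_len(ncol(s$mat)),
      consensus = .seq_chars(s$consensus),
      max_score = apply(s$mat[AA_ALPHABET, , drop = FALSE], 2, max)
    )
  }))
}

#' @rdname build_model
#' @export
glance.p25_model <- function(x, ...) {
  w <- map_int(x$segments, ~ ncol(.x$mat))
  tibble(
    n_segments = length(w),
    core_length = unname(w["core"]),
    partial_core_length = unname(w["partial_core"]),
    long_domain_length = unname(w["core"] + w["partial_core"]),
    extension_length = if ("extension" %in% names(w)) unname(w["extension"]) else NA_integer_,
    ntail_length = if ("ntail" %in% names(w)) unname(w["ntail"]) else NA_integer_,
    rossmann_offset = x$rossmann_offset,
    pseudocount = x$pseudocount
  )
}

#' @export
autoplot.p25_model <- function(object, ...) {
  td <- tidy(object)
  td$segment <- factor(td$segment, levels = names(object$segments))
  ggplot2::ggplot(td, ggplot2::aes(x = .data$position, y = .data$max_score)) +
    ggplot2::geom_col(width = 1) +
    ggplot2::facet_grid(cols = ggplot2::vars(.data$segment),
                        scales = "free_x", space = "free_x") +
    ggplot2::labs(x = "column", y = "max attainable column score",
                  title = "p25alpha profile model") +
    ggplot2::theme_minimal()
}
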