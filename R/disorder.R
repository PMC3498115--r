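# Per-residue intrinsic-disorder profiling.
#
# The predictor is an explicitly documented charge-hydropathy fold-index
# method: windowed mean Kyte-Doolittle hydropathy (rescaled to [0, 1]) and
# windowed mean absolute net charge feed the fold index
# f = 2.785 <H> - |<R>| - 1.151; the disorder score is a logistic mapping of
# -f onto [0, 1] centred so that f = 0 maps to 0.5. It is a stand-in for
# machine-learned disorder predictors, not a reimplementation of one; it
# reproduces the qualitative ordered/disordered contrast that composition
# drives, with the conventional 0.5 significance threshold.

# Steepness of the logistic mapping from fold index to [0, 1].
.DISORDER_STEEPNESS <- 8

.win_mean <- function(x, window) {
  half <- (window - 1L) %/% 2L
  n <- length(x)
  cs <- cumsum(c(0, x))
  lo <- pmax(1L, seq_len(n) - half)
  hi <- pmin(n, seq_len(n) + half)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Per-residue disorder profile
#'
#' Computes, for every residue, the windowed mean Kyte-Doolittle hydropathy
#' `<H>` (rescaled to `[0, 1]`), the windowed mean net charge (K, R = +1;
#' D, E = -1), the fold index `f = 2.785 <H> - |<R>| - 1.151` and the
#' disorder score `1 / (1 + exp(k * f))` with steepness `k = 8`, so `f = 0`
#' maps exactly to 0.5 and negative fold indices (charge-rich,
#' hydropathy-poor composition) score as disordered. Windows are truncated
#' at the termini. `X` residues contribute hydropathy 0 and charge 0.
#'
#' @param seq Amino-acid sequence (single string).
#' @param window Odd window width (default 21). A sequence shorter than the
#'   window is scored with a single whole-sequence window, with a warning.
#' @param threshold Disorder significance threshold (convention: 0.5).
#' @return A `disorder_profile`: list with `scores` (tibble: `position`,
#'   `residue`, `hydropathy`, `net_charge`, `fold_index`, `score`),
#'   `window`, `threshold`, `disordered_fraction` and `regions` (maximal
#'   runs of residues scoring above the threshold).
#' @examples
#' prof <- disorder_scores(strrep("EK", 50))
#' glance(prof)
#' @export
disorder_scores <- function(seq, window = 21L, threshold = 0.5) {
  .check_sequence(seq)
  window <- as.integer(window)
  if (window < 1L || window %% 2L == 0L) abort("window must be a positive odd integer")
  n <- nchar(seq)
  if (n < window) {
    warn(sprintf("sequence (%d aa) shorter than window (%d); using one whole-sequence window",
                 n, window))
    window <- if (n %% 2L == 1L) n else n - 1L
    window <- max(window, 1L)
  }
  a <- .seq_chars(seq)
  kd <- unname(.KD_HYDROPATHY[a])
  kd[is.na(kd)] <- 0          # X
  charge <- unname(.AA_CHARGE[a])
  charge[is.na(charge)] <- 0
  H <- .win_mean((kd + 4.5) / 9, window)
  R <- abs(.win_mean(charge, window))
  f <- 2.785 * H - R - 1.151
  score <- 1 / (1 + exp(.DISORDER_STEEPNESS * f))
  scores <- tibble(position = seq_len(n), residue = a, hydropathy = H,
                   net_charge = R, fold_index = f, score = score)
  above <- score > threshold
  runs <- rle(above)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  regions <- tibble(start = starts[runs$values], end = ends[runs$values])
  structure(
    list(scores = scores, window = window, threshold = threshold,
         disordered_fraction = mean(above), regions = regions, seq = seq),
    class = "disorder_profile"
  )
}

#' Fraction of disordered residues
#'
#' @param profile A [disorder_scores()] result.
#' @param region Optional `c(start, end)` (1-based inclusive) restricting
#'   the computation; an empty region is an error.
#' @return Fraction in `[0, 1]` of residues with score above the profile's
#'   threshold.
#' @export
disordered_fraction <- function(profile, region = NULL) {
  stopifnot(inherits(profile, "disorder_profile"))
  s <- profile$scores$score
  if (!is.null(region)) {
    region <- as.integer(region)
    if (length(region) != 2 || region[1] > region[2] ||
        region[1] < 1 || region[2] > length(s)) {
      abort("region must be c(start, end) within the sequence, start <= end")
    }
    s <- s[region[1]:region[2]]
  }
  mean(s > profile$threshold)
}

#' @export
print.disorder_profile <- function(x, ...) {
  cat("<disorder_profile>\n")
  cat(sprintf("  %d residues, window %d, threshold %.2f\n",
              nrow(x$scores), x$window, x$threshold))
  cat(sprintf("  disordered fraction: %.3f across %d region(s)\n",
              x$disordered_fraction, nrow(x$regions)))
  invisible(x)
}

#' @rdname disorder_scores
#' @param x A `disorder_profile`.
#' @param ... Unused.
#' @export
tidy.disorder_profile <- function(x, ...) x$scores

#' @rdname disorder_scores
#' @export
glance.disorder_profile <- function(x, ...) {
  tibble(
    n_residues = nrow(x$scores),
    window = x$window,
    threshold = x$threshold,
    disordered_fraction = x$disordered_fraction,
    n_disordered_regions = nrow(x$regions),
    longest_region = if (nrow(x$regions)) max(x$regions$end - x$regions$start + 1L) else 0L
  )
}

#' @export
autoplot.disorder_profile <- function(object, ...) {
  ggplot2::ggplot(object$scores,
                  ggplot2::aes(x = .data$position, y = .data$score)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = object$threshold, linetype = "dashed") +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "residue", y = "disorder score",
                  title = "Charge-hydropathy disorder profile",
                  subtitle = sprintf("window %d; residues above %.2f are called disordered",
                                     object$window, object$threshold)) +
    ggplot2::theme_minimal()
}

#' Disorder summaries for a table of records
#'
#' @param records Tibble with `id` and `sequence`.
#' @param window,threshold Passed to [disorder_scores()].
#' @return Tibble with one [glance()] row per record, keyed by `id`.
#' @export
disorder_profiles <- function(records, window = 21L, threshold = 0.5) {
  stopifnot(is.data.frame(records), all(c("id", "sequence") %in% names(records)))
  purrr::list_rbind(map(seq_len(nrow(records)), function(i) {
    bind_cols(tibble(id = records$id[[i]]),
              glance(disorder_scores(records$sequence[[i]], window, threshold)))
  }))
}
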