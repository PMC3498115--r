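# Labelled synthetic protein generator: assembles sequences with the six
# subfamily architectures (and exact truth labels) so that scanning,
# classification, tabulation, disorder and tree building are all testable
# without any database download.

# Fixed divergent variants of the core consensus. The short-type variant
# differs at 21 fixed positions (~18%), mimicking the paralogous divergence
# between short- and long-type TPPPs; the truncated variant differs at 4
# fixed positions (~3%), mimicking a recent arthropod paralog that is still
# close to its long-type parent. Substitutions are hydrophobic-for-
# hydrophobic so the ordered character of the core is preserved.
.SHORT_CORE <- paste0(
  "AYAVLFIFGAMFAIGVAILYVKIFAMFALNASAISVSLVMMLGVEEVAKTGIIWTVAAHT",
  "NSIAVLSLAGWAAISIFVVTFLLGHTFFVLFTVISAISLYTMIAFVFFIVIMAEMALIS"
)
.TRUNC_CORE <- paste0(
  "AYAVLLIFGAMIAIGVAELYILIIAMYAENASAISVSVVVVLGYEEAAKTGIIWTVLAHT",
  "VSIIVLSLAGWAAVSAFVVTFLLGHTFFWFGTVVSAVSLYTFIAFVFLIVIMAEMALIS"
)
# Partial-core variant with the Rossmann-like motif destroyed.
.PARTIAL_NOMOTIF <- "KDAASSRGQDRKKRPRKQQTPGELKDSAQTP"

# Foreign-domain placeholder blocks with compositions (C/H/W/Y-rich) that
# are distinct from both the ordered core and the charged partial core, so
# they never confuse the profile scanner. Classification consumes the
# emitted annotations, not the blocks themselves.
.FOREIGN_MARKERS <- list(
  DCX = strrep("CHWYP", 8),
  EFh = strrep("DHNCW", 6),
  IQ = substr(strrep("IQWRH", 5), 1, 23),
  Znf_BBOX = strrep("CHCYW", 4),
  Kelch = strrep("YWNHC", 6)
)

# Disordered linker composition (matches the N-tail/partial design).
.DIS_ALPHA <- c("E", "K", "S", "P", "Q", "G", "A", "D", "R", "T", "N", "H")
.DIS_W <- c(18, 16, 12, 9, 8, 8, 7, 9, 6, 4, 2, 1)

.DEFAULT_TAXON <- c(
  long_type = "Homo sapiens",
  short_type = "Tetrahymena thermophila",
  truncated = "Drosophila melanogaster",
  partial_only = "Giardia lamblia",
  multidomain = "Micromonas pusilla",
  apicortin = "Toxoplasma gondii"
)

.CLASS_PREFIX <- c(
  long_type = "LONG", short_type = "SHORT", truncated = "TRUNC",
  partial_only = "PART", multidomain = "MULTI", apicortin = "APICO"
)

.rand_linker <- function(n) {
  paste(sample(.DIS_ALPHA, n, replace = TRUE, prob = .DIS_W), collapse = "")
}

#' Specification of one synthetic protein class
#'
#' @param class_label One of the six subfamily labels.
#' @param n Number of proteins to generate from this spec.
#' @param substitution_rate Per-residue point-substitution probability in
#'   `[0, 1)`; motif positions are protected so truth labels stay exact.
#' @param indel_rate Per-residue insertion/deletion probability in
#'   `[0, 0.05]`, applied only to linkers and tails so domain geometry is
#'   preserved.
#' @param n_partial_copies Partial-core copy count for `partial_only`
#'   (default: sampled from 1-4 per protein).
#' @param n_fragments Fragment count for `multidomain` (default: sampled
#'   from 1-2 per protein).
#' @param include_ntail Give long-type proteins the ~50 aa N-terminal tail.
#' @param rossmann Logical (recycled per partial copy): does the copy carry
#'   the Rossmann-like motif?
#' @param with_extension Append the 14 aa extension after motif-bearing
#'   partial copies.
#' @param taxon Species binomial for downstream tabulation (defaults are
#'   class-typical species).
#' @param seed Optional per-spec seed; by default the caller's RNG stream
#'   is used.
#' @return One-row tibble of class parameters.
#' @export
synth_spec <- function(class_label, n = 1L, substitution_rate = 0,
                       indel_rate = 0, n_partial_copies = NA_integer_,
                       n_fragments = NA_integer_, include_ntail = TRUE,
                       rossmann = TRUE, with_extension = TRUE,
                       taxon = NA_character_, seed = NA_integer_) {
  if (!class_label %in% setdiff(SUBFAMILY_LABELS, "none")) {
    abort(sprintf("unknown class_label '%s'", class_label))
  }
  if (substitution_rate < 0 || substitution_rate >= 1) {
    abort("substitution_rate must lie in [0, 1)")
  }
  if (indel_rate < 0 || indel_rate > 0.05) {
    abort("indel_rate must lie in [0, 0.05]")
  }
  if (n < 1) abort("n must be >= 1")
  if (class_label == "apicortin" && !is.na(n_partial_copies) &&
      n_partial_copies < 1) {
    abort("an apicortin must carry at least one partial p25alpha copy")
  }
  if (is.na(taxon)) taxon <- unname(.DEFAULT_TAXON[class_label])
  tibble(
    class_label = class_label, n = as.integer(n),
    substitution_rate = substitution_rate, indel_rate = indel_rate,
    n_partial_copies = as.integer(n_partial_copies),
    n_fragments = as.integer(n_fragments),
    include_ntail = include_ntail, rossmann = list(rossmann),
    with_extension = with_extension, taxon = taxon, seed = as.integer(seed)
  )
}

# Point substitutions outside protected positions.
.mutate_string <- function(text, rate, protect = integer(0)) {
  if (rate <= 0 || !nzchar(text)) return(text)
  a <- .seq_chars(text)
  hit <- setdiff(which(stats::runif(length(a)) < rate), protect)
  for (i in hit) a[i] <- sample(setdiff(AA_ALPHABET, a[i]), 1)
  paste(a, collapse = "")
}

# Indels (deletions and single-residue insertions) for linker segments.
.indel_string <- function(text, rate) {
  if (rate <= 0 || !nzchar(text)) return(text)
  a <- .seq_chars(text)
  u <- stats::runif(length(a))
  out <- character(0)
  for (i in seq_along(a)) {
    if (u[i] < rate / 2) next                       # deletion
    out <- c(out, a[i])
    if (u[i] >= rate / 2 && u[i] < rate) {          # insertion
      out <- c(out, sample(.DIS_ALPHA, 1, prob = .DIS_W))
    }
  }
  paste(out, collapse = "")
}

# Ensure the first residue of a segment following a domain fragment differs
# from the profile's next consensus column, so fragment ends are measured
# exactly (generator boundary guarantee).
.protect_boundary <- function(text, forbidden) {
  if (!nzchar(text) || is.na(forbidden)) return(text)
  a <- .seq_chars(text)
  if (a[[1]] == forbidden) {
    a[[1]] <- sample(setdiff(.DIS_ALPHA, forbidden), 1)
  }
  paste(a, collapse = "")
}

#' Generate one synthetic protein with its truth label
#'
#' Assembles the sequence architecture of the requested subfamily from the
#' model's consensus segments, then applies point substitutions (motif
#' positions protected) and linker-only indels. The returned truth call is
#' exact by construction.
#'
#' @param spec A one-row [synth_spec()] tibble.
#' @param model A `p25_model` (the packaged consensus model by default).
#' @param id Record id.
#' @return List with `record` (one-row protein tibble), `truth` (one-row
#'   call tibble with planted `domain_spans`), and `annotations` (foreign-
#'   domain tibble: `id`, `name`, `start`, `end`).
#' @export
generate_class_sequence <- function(spec, model = default_p25_model(),
                                    id = "SYN_001") {
  stopifnot(is.data.frame(spec), nrow(spec) == 1)
  if (!is.na(spec$seed)) set.seed(spec$seed)
  segs <- .assemble_segments(spec, model)
  rate <- spec$substitution_rate
  irate <- spec$indel_rate
  pieces <- map(segs, function(s) {
    text <- s$text
    if (s$indelable) text <- .indel_string(text, irate)
    if (s$mutable) text <- .mutate_string(text, rate, s$protect)
    s$text <- text
    s
  })
  lens <- map_int(pieces, ~ nchar(.x$text))
  ends <- cumsum(lens)
  starts <- ends - lens + 1L
  seq <- paste(map_chr(pieces, "text"), collapse = "")
  types <- map_chr(pieces, "type")
  spans <- tibble(type = types, start = starts, end = ends)
  markers <- which(types %in% names(.FOREIGN_MARKERS) |
                     grepl("^marker:", types))
  marker_names <- sub("^marker:", "", types[markers])
  annotations <- tibble(id = id, name = marker_names,
                        start = starts[markers], end = ends[markers])
  truth_extra <- attr(segs, "truth")
  truth <- bind_cols(
    tibble(id = id, label = spec$class_label, species = spec$taxon,
           is_est = FALSE),
    truth_extra,
    tibble(other_domains = list(marker_names),
           domain_spans = list(filter(spans, !.data$type %in% c("linker"))))
  )
  record <- tibble(id = id, species = spec$taxon, sequence = seq,
                   source_db = "other", is_est = FALSE)
  list(record = record, truth = truth, annotations = annotations)
}

# Build the (pre-mutation) segment list for one protein; attaches the truth
# columns as an attribute.
.assemble_segments <- function(spec, model) {
  con <- function(nm) model$segments[[nm]]$consensus
  long_consensus <- paste0(con("core"), con("partial_core"))
  motif_protect <- model$rossmann_offset + 0:8
  seg <- function(text, type, mutable = TRUE, indelable = FALSE,
                  protect = integer(0)) {
    list(text = text, type = type, mutable = mutable, indelable = indelable,
         protect = protect)
  }
  label <- spec$class_label
  segs <- switch(label,
    long_type = {
      s <- list()
      if (spec$include_ntail) s <- c(s, list(seg(con("ntail"), "ntail", indelable = TRUE)))
      c(s, list(
        seg(con("core"), "core"),
        seg(con("partial_core"), "partial_core", protect = motif_protect),
        seg(con("extension"), "extension")
      ))
    },
    short_type = list(seg(.SHORT_CORE, "core")),
    truncated = list(seg(.TRUNC_CORE, "core")),
    partial_only = {
      k <- spec$n_partial_copies
      if (is.na(k)) k <- sample(1:4, 1)
      flags <- rep_len(spec$rossmann[[1]], k)
      s <- list(seg(.rand_linker(sample(5:15, 1)), "linker", indelable = TRUE))
      for (i in seq_len(k)) {
        if (flags[[i]]) {
          s <- c(s, list(seg(con("partial_core"), "partial_core",
                             protect = motif_protect)))
          if (spec$with_extension) s <- c(s, list(seg(con("extension"), "extension")))
        } else {
          s <- c(s, list(seg(.PARTIAL_NOMOTIF, "partial_core_nomotif")))
        }
        s <- c(s, list(seg(.rand_linker(sample(10:25, 1)), "linker",
                           indelable = TRUE)))
      }
      attr(s, "truth_partial") <- flags
      s
    },
    multidomain = {
      nf <- spec$n_fragments
      if (is.na(nf)) nf <- sample(1:2, 1)
      marker_pool <- setdiff(names(.FOREIGN_MARKERS), "DCX")
      marker_names <- sample(marker_pool, sample(1:2, 1))
      s <- list(seg(.rand_linker(sample(5:15, 1)), "linker", indelable = TRUE))
      frag_lens <- integer(0)
      for (i in seq_len(nf)) {
        flen <- sample(70:140, 1)
        frag_lens <- c(frag_lens, flen)
        s <- c(s, list(seg(substr(long_consensus, 1, flen), "fragment")))
        next_col_char <- if (flen < nchar(long_consensus)) {
          substr(long_consensus, flen + 1, flen + 1)
        } else NA_character_
        link <- .protect_boundary(.rand_linker(sample(10:20, 1)), next_col_char)
        s <- c(s, list(seg(link, "linker", indelable = TRUE)))
        if (i <= length(marker_names)) {
          s <- c(s, list(seg(.FOREIGN_MARKERS[[marker_names[[i]]]],
                             paste0("marker:", marker_names[[i]]),
                             mutable = FALSE)))
          s <- c(s, list(seg(.rand_linker(sample(5:15, 1)), "linker",
                             indelable = TRUE)))
        }
      }
      # place any marker not yet emitted at the C-terminus
      if (length(marker_names) > nf) {
        for (m in marker_names[(nf + 1):length(marker_names)]) {
          s <- c(s, list(seg(.FOREIGN_MARKERS[[m]], paste0("marker:", m),
                             mutable = FALSE),
                         seg(.rand_linker(sample(5:15, 1)), "linker",
                             indelable = TRUE)))
        }
      }
      attr(s, "frag_lens") <- frag_lens
      s
    },
    apicortin = {
      k <- spec$n_partial_copies
      if (is.na(k)) k <- 1L
      s <- list(seg(.rand_linker(sample(8:15, 1)), "linker", indelable = TRUE))
      for (i in seq_len(k)) {
        s <- c(s, list(seg(con("partial_core"), "partial_core",
                           protect = motif_protect)))
        if (spec$with_extension) s <- c(s, list(seg(con("extension"), "extension")))
        s <- c(s, list(seg(.rand_linker(sample(10:20, 1)), "linker",
                           indelable = TRUE)))
      }
      c(s, list(seg(.FOREIGN_MARKERS$DCX, "marker:DCX", mutable = FALSE),
                seg(.rand_linker(sample(5:12, 1)), "linker", indelable = TRUE)))
    },
    abort(sprintf("cannot generate class '%s'", label))
  )
  truth <- switch(label,
    long_type = tibble(n_p25_copies = 1L, n_partial_copies = 1L,
                       has_rossmann = list(TRUE), has_extension = TRUE,
                       has_ntail = spec$include_ntail),
    short_type = ,
    truncated = tibble(n_p25_copies = 1L, n_partial_copies = 0L,
                       has_rossmann = list(logical(0)), has_extension = FALSE,
                       has_ntail = FALSE),
    partial_only = {
      flags <- attr(segs, "truth_partial")
      tibble(n_p25_copies = 0L, n_partial_copies = length(flags),
             has_rossmann = list(flags),
             has_extension = spec$with_extension && any(flags),
             has_ntail = FALSE)
    },
    multidomain = tibble(n_p25_copies = length(attr(segs, "frag_lens")),
                         n_partial_copies = 0L,
                         has_rossmann = list(logical(0)),
                         has_extension = FALSE, has_ntail = FALSE),
    apicortin = {
      k <- if (is.na(spec$n_partial_copies)) 1L else spec$n_partial_copies
      tibble(n_p25_copies = 0L, n_partial_copies = k,
             has_rossmann = list(rep(TRUE, k)),
             has_extension = spec$with_extension, has_ntail = FALSE)
    }
  )
  attr(segs, "truth") <- truth
  segs
}

#' Generate a labelled synthetic dataset
#'
#' Expands a table of [synth_spec()] rows into `sum(n)` proteins, writes
#' them as FASTA plus a truth TSV and a foreign-domain annotation TSV, and
#' returns everything as tibbles. Fully reproducible: the same seed yields
#' byte-identical files.
#'
#' @param specs Tibble of [synth_spec()] rows (bind them with
#'   `dplyr::bind_rows()`).
#' @param model A `p25_model`.
#' @param seed Integer master seed.
#' @param dir Output directory (created if needed).
#' @param basename Stem for the three output files.
#' @return List with `records`, `truth`, `annotations` tibbles and the
#'   `fasta`, `truth_path`, `annotations_path` file paths.
#' @examples
#' specs <- dplyr::bind_rows(
#'   synth_spec("long_type", n = 2),
#'   synth_spec("apicortin", n = 1)
#' )
#' ds <- generate_dataset(specs, seed = 1, dir = tempdir())
#' ds$truth$label
#' @export
generate_dataset <- function(specs, model = default_p25_model(), seed = 1L,
                             dir = tempdir(), basename = "synthetic") {
  stopifnot(is.data.frame(specs), nrow(specs) > 0)
  set.seed(seed)
  counter <- integer(0)
  out <- list()
  for (r in seq_len(nrow(specs))) {
    spec <- specs[r, ]
    for (k in seq_len(spec$n)) {
      lab <- spec$class_label
      cur <- if (lab %in% names(counter)) counter[[lab]] else 0L
      counter[lab] <- cur + 1L
      id <- sprintf("%s_%03d", .CLASS_PREFIX[[lab]], counter[[lab]])
      out[[length(out) + 1]] <- generate_class_sequence(spec, model, id = id)
    }
  }
  records <- purrr::list_rbind(map(out, "record"))
  truth <- purrr::list_rbind(map(out, "truth"))
  annotations <- purrr::list_rbind(map(out, "annotations"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  fasta <- file.path(dir, paste0(basename, ".fasta"))
  truth_path <- file.path(dir, paste0(basename, "_truth.tsv"))
  annotations_path <- file.path(dir, paste0(basename, "_annotations.tsv"))
  write_fasta(records, fasta)
  truth_flat <- truth |>
    mutate(
      has_rossmann = map_chr(.data$has_rossmann, ~ paste(.x, collapse = ",")),
      other_domains = map_chr(.data$other_domains, ~ paste(.x, collapse = ","))
    ) |>
    select(-"domain_spans")
  readr::write_tsv(truth_flat, truth_path, progress = FALSE)
  readr::write_tsv(annotations, annotations_path, progress = FALSE)
  list(records = records, truth = truth, annotations = annotations,
       fasta = fasta, truth_path = truth_path,
       annotations_path = annotations_path)
}
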