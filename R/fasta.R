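# FASTA I/O with key=value header metadata.
#
# Header dialect: ">ID key=value key=value ...". Recognised keys are
# species (underscores for spaces), source (database) and est (0/1). The
# dialect is FASTA-legal and round-trips losslessly.

#' Read protein records from FASTA
#'
#' @param path Path to a FASTA file.
#' @return Tibble with columns `id`, `species`, `sequence`, `source_db`,
#'   `is_est` -- one row per entry. Metadata keys absent from a header
#'   default to `NA` / `"other"` / `FALSE`. An empty file yields an empty
#'   tibble with a warning. Duplicate ids and malformed headers are errors.
#' @examples
#' f <- tempfile(fileext = ".fasta")
#' writeLines(c(">A species=Homo_sapiens", "MKR"), f)
#' read_fasta(f)
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) abort(sprintf("FASTA file not found: %s", path))
  empty <- tibble(id = character(), species = character(),
                  sequence = character(), source_db = character(),
                  is_est = logical())
  lines <- readLines(path, warn = FALSE)
  content <- which(nzchar(trimws(lines)))
  if (!length(content)) {
    warn(sprintf("empty FASTA file: %s", path))
    return(empty)
  }
  if (!startsWith(trimws(lines[[content[[1]]]]), ">")) {
    abort(sprintf("malformed FASTA: line %d of %s does not start a record",
                  content[[1]], path))
  }
  aa <- Biostrings::readAAStringSet(path)
  headers <- names(aa)
  meta <- purrr::list_rbind(map(headers, .parse_header))
  if (anyDuplicated(meta$id)) {
    dups <- unique(meta$id[duplicated(meta$id)])
    abort(sprintf("duplicate record id(s) in %s: %s", path,
                  paste(dups, collapse = ", ")))
  }
  seqs <- sanitize_sequence(as.character(aa))
  if (any(!nzchar(seqs))) {
    abort(sprintf("empty sequence for record(s): %s",
                  paste(meta$id[!nzchar(seqs)], collapse = ", ")))
  }
  mutate(meta, sequence = unname(seqs), .after = "species")
}

.parse_header <- function(header) {
  tokens <- strsplit(trimws(header), "\\s+")[[1]]
  id <- tokens[[1]]
  if (!nzchar(id)) abort("FASTA header with empty id")
  kv <- tokens[-1][grepl("=", tokens[-1], fixed = TRUE)]
  keys <- sub("=.*$", "", kv)
  vals <- sub("^[^=]*=", "", kv)
  get <- function(k, default) if (k %in% keys) vals[[match(k, keys)]] else default
  tibble(
    id = id,
    species = {
      sp <- get("species", NA_character_)
      if (is.na(sp)) sp else gsub("_", " ", sp, fixed = TRUE)
    },
    source_db = get("source", "other"),
    is_est = get("est", "0") %in% c("1", "true", "TRUE")
  )
}

#' Write protein records to FASTA
#'
#' Serializes a record tibble to standard FASTA, 60 characters per sequence
#' line, with metadata as `key=value` header tokens so that
#' `read_fasta(write_fasta(x))` is the identity.
#'
#' @param records Tibble with `id` and `sequence`; `species`, `source_db`
#'   and `is_est` are serialized when present.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  stopifnot(is.data.frame(records))
  if (nrow(records) == 0) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  if (!all(c("id", "sequence") %in% names(records))) {
    abort("records must have 'id' and 'sequence' columns")
  }
  headers <- vapply(seq_len(nrow(records)), function(i) {
    h <- records$id[[i]]
    sp <- if ("species" %in% names(records)) records$species[[i]] else NA
    if (!is.na(sp)) h <- paste0(h, " species=", gsub(" ", "_", sp, fixed = TRUE))
    db <- if ("source_db" %in% names(records)) records$source_db[[i]] else NA
    if (!is.na(db) && db != "other") h <- paste0(h, " source=", db)
    est <- if ("is_est" %in% names(records)) isTRUE(records$is_est[[i]]) else FALSE
    if (est) h <- paste0(h, " est=1")
    h
  }, character(1))
  aa <- Biostrings::AAStringSet(records$sequence)
  names(aa) <- headers
  Biostrings::writeXStringSet(aa, path, width = 60L)
  invisible(path)
}
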