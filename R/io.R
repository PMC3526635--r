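# file-format helpers: FASTA in, Vienna dot-bracket files, TSV tracks

#' Read an RNA sequence from a FASTA file
#'
#' Single- or multi-record FASTA; the first record is used unless `id` names
#' another one.
#'
#' @param path FASTA file path.
#' @param id Optional record identifier to select.
#' @return An [rna_sequence()].
#' @export
read_fasta_rna <- function(path, id = NULL) {
  if (!requireNamespace("Biostrings", quietly = TRUE)) {
    abort("reading FASTA requires the Biostrings package")
  }
  set <- Biostrings::readBStringSet(path)
  if (!length(set)) abort(sprintf("no records in %s", path))
  nms <- sub("\\s.*$", "", names(set))
  idx <- 1L
  if (!is.null(id)) {
    idx <- match(id, nms)
    if (is.na(idx)) abort(sprintf("record '%s' not found in %s", id, path))
  }
  rna_sequence(as.character(set[[idx]]), id = nms[idx])
}

#' Write sequences to a FASTA file
#'
#' @param seqs An [rna_sequence()] or list of them.
#' @param path Output path (or `""` for stdout).
#' @export
write_fasta_rna <- function(seqs, path = "") {
  if (inherits(seqs, "rna_sequence")) seqs <- list(seqs)
  lines <- unlist(lapply(seqs, function(s) c(paste0(">", s$id), s$seq)))
  writeLines(lines, con = if (identical(path, "")) stdout() else path)
  invisible(seqs)
}

#' Read a Vienna-layout dot-bracket file
#'
#' Line 1: optional `>` header; line 2: sequence; line 3: structure (the
#' conventional layout).  A file without a header shifts everything up one
#' line; a file with only a structure line yields `seq = NULL`.
#'
#' @param path File path.
#' @param theta Minimum hairpin size used for parsing.
#' @return A list with `id`, `seq` (an [rna_sequence()] or NULL) and
#'   `structure` (a `secondary_structure`).
#' @export
read_vienna <- function(path, theta = 3L) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines)]
  if (!length(lines)) abort(sprintf("empty file: %s", path))
  id <- NULL
  if (startsWith(lines[1L], ">")) {
    id <- sub("^>\\s*", "", lines[1L])
    lines <- lines[-1L]
  }
  is_db <- grepl("^[.()]+$", lines)
  db <- lines[is_db][1L]
  sq <- lines[!is_db][1L]
  if (is.na(db)) abort(sprintf("no dot-bracket line found in %s", path))
  st <- parse_dot_bracket(db, theta = theta)
  sq <- if (is.na(sq)) NULL else rna_sequence(sq, id = if (is.null(id)) "seq" else id)
  list(id = id, seq = sq, structure = st)
}

#' Write a scan track as TSV
#'
#' @param track A `scan_track` from [window_scan()].
#' @param path Output path (or `""` for stdout).
#' @export
write_scan_tsv <- function(track, path = "") {
  hdr <- c(sprintf("# target: %s", attr(track, "target")),
           sprintf("# window: %d", attr(track, "window")),
           sprintf("# step: %d", attr(track, "step")))
  body <- sprintf("%d\t%.6f", track$offset, track$expected_distance)
  writeLines(c(hdr, "offset\texpected_distance", body),
             con = if (identical(path, "")) stdout() else path)
  invisible(track)
}
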