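# File formats.  FASTA/FASTQ go through Biostrings (gzip transparent);
# SAM hints are a lenient plain-text parse of the four leading columns.
# All internal coordinates are 0-based half-open; the only 1-based text
# convention handled here is the SAM POS field.

#' Read a FASTA file
#'
#' @param path FASTA file, plain or gzip.
#' @return Tibble with columns `id` (first word of the header) and
#'   `sequence` (uppercased).
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fasta")
  if (length(x) == 0) stop(sprintf("no FASTA records in '%s'", path),
                           call. = FALSE)
  tibble::tibble(id = sub("\\s.*$", "", names(x)),
                 sequence = unname(toupper(as.character(x))))
}

#' Write sequences to a FASTA file
#'
#' @param x Tibble with `id` and `sequence` columns, or a named character
#'   vector.
#' @param path Output path.
#' @param width Line-wrap width (default 70).
#' @export
write_fasta <- function(x, path, width = 70L) {
  if (is.data.frame(x)) x <- setNames(x$sequence, x$id)
  set <- Biostrings::DNAStringSet(x)
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Decode a quality string to Phred scores
#'
#' @param quality Quality string.
#' @param offset Encoding offset, 33 (default) or 64.
#' @return Integer vector of Phred scores.
#' @export
decode_quality <- function(quality, offset = 33L) {
  utf8ToInt(quality) - as.integer(offset)
}

#' Read a FASTQ file
#'
#' @param path FASTQ file (4-line records), plain or gzip.
#' @param quality_offset Quality encoding offset (33 default, 64 for
#'   legacy Illumina).
#' @return Tibble with columns `id`, `sequence` (uppercased) and
#'   `quality` (raw quality string; decode with [decode_quality()]).
#' @export
read_fastq <- function(path, quality_offset = 33L) {
  # shape validation on the raw 4-line records: the parser pads short
  # quality strings silently, so length mismatches must be caught here
  con <- gzfile(path, "rt")
  lines <- readLines(con, warn = FALSE)
  close(con)
  if (length(lines) >= 4 && length(lines) %% 4 == 0) {
    sl <- nchar(lines[seq(2, length(lines), by = 4)])
    ql <- nchar(lines[seq(4, length(lines), by = 4)])
    bad <- which(sl != ql)
    if (length(bad) > 0) {
      id <- sub("^@", "", sub("\\s.*$", "", lines[(bad[1] - 1) * 4 + 1]))
      stop(sprintf("record '%s': sequence and quality lengths differ", id),
           call. = FALSE)
    }
  }
  x <- Biostrings::readDNAStringSet(path, format = "fastq",
                                    with.qualities = TRUE)
  if (length(x) == 0) stop(sprintf("no FASTQ records in '%s'", path),
                           call. = FALSE)
  out <- tibble::tibble(
    id = sub("\\s.*$", "", names(x)),
    sequence = unname(toupper(as.character(x))),
    quality = unname(as.character(S4Vectors::mcols(x)$qualities)))
  attr(out, "quality_offset") <- as.integer(quality_offset)
  out
}

#' Write reads to a FASTQ file
#'
#' @param reads Tibble with `id`, `sequence`, `quality` columns.
#' @param path Output path (`.gz` for gzip).
#' @export
write_fastq <- function(reads, path) {
  set <- Biostrings::DNAStringSet(setNames(reads$sequence, reads$id))
  Biostrings::writeXStringSet(
    set, path, format = "fastq",
    qualities = Biostrings::BStringSet(reads$quality),
    compress = grepl("\\.gz$", path))
  invisible(path)
}

#' Read mapping-position hints from a SAM file
#'
#' Lenient text parse of the leading SAM columns.  Unmapped records
#' (FLAG bit 0x4), secondary (0x100) and supplementary (0x800) alignments
#' are skipped; for duplicate read names the first primary record wins
#' with a warning; unparsable lines are skipped with a warning.  The
#' 1-based SAM POS is converted to the package's 0-based convention.
#'
#' @param path SAM text file.
#' @return Named integer vector: read id to 0-based reference position.
#' @export
read_sam_hints <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!startsWith(lines, "@") & nzchar(lines)]
  hints <- integer(0)
  dupes <- character(0)
  for (ln in lines) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) < 4) {
      warning(sprintf("skipping unparsable SAM line: %s",
                      substr(ln, 1, 40)))
      next
    }
    flag <- suppressWarnings(as.integer(f[2]))
    pos <- suppressWarnings(as.integer(f[4]))
    if (is.na(flag) || is.na(pos)) {
      warning(sprintf("skipping unparsable SAM line: %s",
                      substr(ln, 1, 40)))
      next
    }
    if (bitwAnd(flag, 4L) != 0L) next            # unmapped
    if (bitwAnd(flag, 256L) != 0L) next          # secondary
    if (bitwAnd(flag, 2048L) != 0L) next         # supplementary
    if (f[1] %in% names(hints)) {
      dupes <- c(dupes, f[1])
      next
    }
    hints[f[1]] <- pos - 1L
  }
  if (length(dupes) > 0) {
    warning(sprintf("duplicate primary records for: %s (first kept)",
                    paste(unique(dupes), collapse = ", ")))
  }
  hints
}

#' Write the outputs of an assembly run
#'
#' Writes `<prefix>.fasta` (consensus), `<prefix>_reads.tsv` (per-read
#' log), `<prefix>_coverage.tsv` (per-position coverage of the untrimmed
#' final reference) and `<prefix>.json` (run summary: configuration echo,
#' bases covered, final length).
#'
#' @param x An `nl_assembly`.
#' @param prefix Output path prefix.
#' @param name Sequence name for the consensus FASTA record.
#' @return Invisibly, the vector of files written.
#' @export
write_assembly <- function(x, prefix, name = "consensus") {
  stopifnot(inherits(x, "nl_assembly"))
  files <- c(fasta = paste0(prefix, ".fasta"),
             reads = paste0(prefix, "_reads.tsv"),
             coverage = paste0(prefix, "_coverage.tsv"),
             json = paste0(prefix, ".json"))
  write_fasta(setNames(x$consensus, name), files["fasta"])
  utils::write.table(x$read_log, files["reads"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(position = seq_along(x$coverage) - 1L,
               coverage = x$coverage),
    files["coverage"], sep = "\t", quote = FALSE, row.names = FALSE)
  cfg <- unclass(x$config)
  cfg[vapply(cfg, is.null, TRUE)] <- NA
  jsonlite::write_json(
    list(config = cfg,
         bases_covered = x$bases_covered,
         final_length = nchar(x$consensus),
         n_reads = nrow(x$read_log)),
    files["json"], auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(files)
}
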