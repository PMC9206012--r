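# Readers and writers for the plain-text formats the pipeline consumes:
# FASTA, TSV tables (alignments, expression, CT, GO annotations) and JSON
# truth sidecars. All tabular outputs carry a commented header recording
# the tool version and, where relevant, the seed.

#' Read a FASTA file into sequence records
#'
#' Multi-line sequences are joined; the record id is the header token before
#' the first whitespace; sequences are uppercased. Duplicate ids and empty
#' records are errors. The alphabet of each record is auto-detected
#' (`ACGTN`-only sequences are nucleotide).
#'
#' @param path Path to a FASTA file.
#' @return List of [sequence_record()] objects.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  set <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids)) {
    stop("duplicate FASTA ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  seqs <- unname(as.character(set))
  empty <- !nzchar(seqs)
  if (any(empty)) {
    stop("empty FASTA record(s): ", paste(ids[empty], collapse = ", "),
         call. = FALSE)
  }
  lapply(seq_along(ids), function(i) sequence_record(ids[i], seqs[i]))
}

#' Write sequence records to FASTA
#'
#' @param records List of [sequence_record()] objects.
#' @param path Output path.
#' @param width Line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 70L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (rec in records) {
    writeLines(paste0(">", rec$id), con)
    s <- rec$sequence
    starts <- seq(1L, max(nchar(s), 1L), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

BLAST6_COLUMNS <- c("query_id", "subject_id", "identity", "align_length",
                    "mismatches", "gap_opens", "query_start", "query_end",
                    "subject_start", "subject_end", "evalue", "bitscore")

#' Read a BLAST outfmt-6 style alignment table
#'
#' Expects the 12 standard tab-separated columns (query, subject, percent
#' identity, alignment length, mismatches, gap opens, query start/end,
#' subject start/end, e-value, bit score); lines starting with `#` are
#' skipped. Malformed rows raise an error naming the line.
#'
#' @param path Path to a tab-separated alignment table.
#' @return A data frame with columns named as in `famscan:::BLAST6_COLUMNS`.
#' @export
read_alignment_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L) {
    return(empty_alignment_table())
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) != 12L)
  if (length(bad)) {
    stop("malformed alignment record at line ", bad[1],
         ": expected 12 tab-separated columns, got ",
         length(fields[[bad[1]]]), call. = FALSE)
  }
  m <- do.call(rbind, fields)
  out <- data.frame(
    query_id = m[, 1], subject_id = m[, 2],
    identity = as.numeric(m[, 3]), align_length = as.integer(m[, 4]),
    mismatches = as.integer(m[, 5]), gap_opens = as.integer(m[, 6]),
    query_start = as.integer(m[, 7]), query_end = as.integer(m[, 8]),
    subject_start = as.integer(m[, 9]), subject_end = as.integer(m[, 10]),
    evalue = as.numeric(m[, 11]), bitscore = as.numeric(m[, 12]),
    stringsAsFactors = FALSE
  )
  bad_num <- which(is.na(out$identity) | is.na(out$align_length) |
                     is.na(out$evalue))
  if (length(bad_num)) {
    stop("malformed alignment record at line ", bad_num[1],
         ": non-numeric identity/length/e-value", call. = FALSE)
  }
  validate_alignment_table(out)
  out
}

empty_alignment_table <- function() {
  out <- data.frame(
    query_id = character(), subject_id = character(),
    identity = numeric(), align_length = integer(),
    mismatches = integer(), gap_opens = integer(),
    query_start = integer(), query_end = integer(),
    subject_start = integer(), subject_end = integer(),
    evalue = numeric(), bitscore = numeric(), stringsAsFactors = FALSE
  )
  out
}

validate_alignment_table <- function(tab) {
  stopifnot(is.data.frame(tab))
  missing_cols <- setdiff(BLAST6_COLUMNS, names(tab))
  if (length(missing_cols)) {
    stop("alignment table lacks columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (nrow(tab)) {
    if (any(tab$identity < 0 | tab$identity > 100)) {
      stop("identity outside [0, 100]", call. = FALSE)
    }
    if (any(tab$align_length < 1)) stop("align_length < 1", call. = FALSE)
    if (any(tab$evalue < 0)) stop("negative e-value", call. = FALSE)
  }
  invisible(tab)
}

#' Write an alignment table in BLAST outfmt-6 layout
#' @param tab Data frame as returned by [read_alignment_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_alignment_table <- function(tab, path) {
  validate_alignment_table(tab)
  write.table(tab[, BLAST6_COLUMNS], path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# Commented provenance header prepended to pipeline TSV outputs.
output_header <- function(seed = NULL, extra = character()) {
  ver <- as.character(utils::packageVersion("famscan"))
  c(paste0("# famscan ", ver),
    "# coordinates: 1-based inclusive",
    if (!is.null(seed)) paste0("# seed: ", seed),
    extra)
}

#' Write a data frame as TSV with a provenance header
#'
#' @param df Data frame.
#' @param path Output path.
#' @param seed Optional seed to record in the header.
#' @param extra Additional `# `-prefixed header lines.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(df, path, seed = NULL, extra = character()) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(output_header(seed, extra), con)
  suppressWarnings(write.table(df, con, sep = "\t", quote = FALSE,
                               row.names = FALSE, col.names = TRUE))
  invisible(path)
}

#' Read a TSV written by [write_tsv()] (comment lines are skipped)
#' @param path Input path.
#' @return Data frame.
#' @export
read_tsv <- function(path) {
  read.delim(path, sep = "\t", comment.char = "#", stringsAsFactors = FALSE)
}

#' Read an expression matrix from TSV
#'
#' First column transcript ids, remaining columns one sample each.
#' @param path Input path.
#' @return Numeric matrix, transcripts in rows.
#' @export
read_expression_matrix <- function(path) {
  df <- read_tsv(path)
  ids <- df[[1]]
  if (anyDuplicated(ids)) stop("duplicate transcript ids", call. = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) stop("non-numeric expression values", call. = FALSE)
  rownames(m) <- ids
  m
}

#' Write an expression matrix to TSV
#' @param m Numeric matrix with row and column names.
#' @param path Output path.
#' @param seed Optional seed recorded in the header.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(m, path, seed = NULL) {
  df <- data.frame(transcript_id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_tsv(df, path, seed = seed)
}
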