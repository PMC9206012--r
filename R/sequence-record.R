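#' Create a sequence record
#'
#' A `sequence_record` is the package's lightweight container for one named
#' sequence: a list with `id`, `sequence` (uppercase canonical form) and
#' `alphabet` (`"protein"` or `"nucleotide"`). Protein sequences may use the
#' 20 standard residues plus `X`; nucleotide sequences `ACGTN`.
#'
#' @param id Non-empty identifier.
#' @param sequence Residue string; converted to uppercase.
#' @param alphabet `"protein"`, `"nucleotide"`, or `NULL` to auto-detect
#'   (sequences over `ACGTN` only are called nucleotide).
#' @return An object of class `sequence_record`.
#' @examples
#' sequence_record("zf1", "MKCAACLLLLLLLLLLLLHAAH")
#' @export
sequence_record <- function(id, sequence, alphabet = NULL) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id),
            is.character(sequence), length(sequence) == 1L)
  sequence <- unname(toupper(sequence))
  if (is.null(alphabet)) {
    alphabet <- if (grepl("^[ACGTN]*$", sequence)) "nucleotide" else "protein"
  }
  alphabet <- match.arg(alphabet, c("protein", "nucleotide"))
  allowed <- if (alphabet == "protein") "^[ACDEFGHIKLMNPQRSTVWYX]*$" else "^[ACGTN]*$"
  if (!grepl(allowed, sequence)) {
    stop("sequence for '", id, "' contains characters outside the ",
         alphabet, " alphabet", call. = FALSE)
  }
  structure(list(id = id, sequence = sequence, alphabet = alphabet),
            class = "sequence_record")
}

#' @export
print.sequence_record <- function(x, ...) {
  n <- nchar(x$sequence)
  shown <- if (n > 60) paste0(substr(x$sequence, 1, 57), "...") else x$sequence
  cat(sprintf("<sequence_record> %s (%s, %d %s)\n  %s\n",
              x$id, x$alphabet, n,
              if (x$alphabet == "protein") "aa" else "nt", shown))
  invisible(x)
}

#' @export
length.sequence_record <- function(x) nchar(x$sequence)

as_sequence_record <- function(x, alphabet = NULL) {
  if (inherits(x, "sequence_record")) return(x)
  stop("expected a sequence_record", call. = FALSE)
}

assert_alphabet <- function(record, alphabet) {
  if (!inherits(record, "sequence_record")) {
    stop("expected a sequence_record", call. = FALSE)
  }
  if (record$alphabet != alphabet) {
    stop("sequence '", record$id, "' is ", record$alphabet,
         "; a ", alphabet, " sequence is required", call. = FALSE)
  }
  invisible(record)
}
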