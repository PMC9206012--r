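# Conserved protein motif scanning, promoter cis-regulatory element
# scanning with functional classification, GO Venn bookkeeping and
# chi-square enrichment.

#' Define a protein motif
#'
#' The pattern mini-language: uppercase letters are literal residues,
#' `[ABC]` is a position alternative, lowercase `x` matches any residue.
#' For example `[QRK]ALGGH` (the QALGGH DNA-binding motif and its R/KALGGH
#' variants), `[LF]DLN[LF]xP` (the EAR repression motif), `ExExxAxCLxxL`
#' (the leucine-rich L-box).
#'
#' @param name Motif name.
#' @param pattern Pattern string.
#' @return List with `name`, `pattern`, and the compiled `regex`.
#' @export
motif_definition <- function(name, pattern) {
  stopifnot(nzchar(name), nzchar(pattern))
  list(name = name, pattern = pattern, regex = motif_pattern_to_regex(pattern))
}

motif_pattern_to_regex <- function(pattern) {
  if (!grepl("^(\\[[A-WY]+\\]|[A-WYx])+$", pattern)) {
    stop("invalid motif pattern: ", pattern, call. = FALSE)
  }
  gsub("x", "[A-Z]", pattern, fixed = TRUE)
}

#' The default catalog of named C2H2-ZFP motifs
#'
#' QALGGH (with R/K first-position variants), the EAR transcriptional
#' repression motif and the L-box protein-interaction region.
#'
#' @return List of [motif_definition()]s.
#' @export
default_motifs <- function() {
  list(
    motif_definition("QALGGH", "[QRK]ALGGH"),
    motif_definition("EAR", "[LF]DLN[LF]xP"),
    motif_definition("L-box", "ExExxAxCLxxL")
  )
}

#' Scan a protein for named conserved motifs
#'
#' Matches of each motif are found greedily left-to-right and are
#' non-overlapping within one motif; different motifs may overlap each
#' other.
#'
#' @inheritParams scan_c2h2
#' @param motifs List of [motif_definition()]s (default [default_motifs()]).
#' @return Data frame with `sequence_id`, `motif`, `start` (1-based),
#'   `match`.
#' @examples
#' scan_named_motifs(sequence_record("p", "AAQALGGHAA", "protein"))
#' @export
scan_named_motifs <- function(protein, motifs = default_motifs()) {
  assert_alphabet(protein, "protein")
  rows <- lapply(motifs, function(m) {
    hits <- gregexpr(m$regex, protein$sequence)[[1]]
    if (hits[1] == -1L) return(NULL)
    data.frame(sequence_id = protein$id, motif = m$name,
               start = as.integer(hits),
               match = substring(protein$sequence, hits,
                                 hits + attr(hits, "match.length") - 1L),
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L) {
    return(data.frame(sequence_id = character(), motif = character(),
                      start = integer(), match = character(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Load a cis-regulatory element catalog
#'
#' The catalog is a TSV with columns `name`, `consensus` (IUPAC nucleotide
#' string) and `class` (one of hormone, stress, growth, core, other). The
#' bundled default covers ~20 canonical PlantCARE-style elements (TATA-box,
#' CAAT-box, ABRE, ARE, MBS, LTR, AuxRR-core, TGA-element, GARE-motif,
#' P-box, TCA-element, CGTCA/TGACG-motif, G-box, Box 4, Skn-1, GCN4,
#' RY-element, CAT-box, O2-site, TC-rich repeats).
#'
#' @param path Path to a catalog TSV; default the bundled catalog.
#' @return Data frame with `name`, `consensus`, `class`.
#' @export
cis_element_catalog <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "cis_elements.tsv", package = "famscan")
  }
  cat <- read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  need <- c("name", "consensus", "class")
  if (!all(need %in% names(cat))) {
    stop("catalog must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(cat$name)) stop("duplicate element names", call. = FALSE)
  bad <- !cat$class %in% c("hormone", "stress", "growth", "core", "other")
  if (any(bad)) {
    stop("unknown element class: ", paste(unique(cat$class[bad]),
                                          collapse = ", "), call. = FALSE)
  }
  cat$consensus <- toupper(cat$consensus)
  ok <- grepl("^[ACGTRYSWKMBDHVN]+$", cat$consensus)
  if (!all(ok)) stop("non-IUPAC consensus: ",
                     paste(cat$name[!ok], collapse = ", "), call. = FALSE)
  cat
}

iupac_to_regex <- function(consensus) {
  chars <- strsplit(consensus, "", fixed = TRUE)[[1]]
  paste(vapply(chars, function(ch) {
    bases <- IUPAC_DNA[[ch]]
    if (length(bases) == 1L) bases else paste0("[", paste(bases, collapse = ""), "]")
  }, character(1)), collapse = "")
}

# All match start positions (overlapping included) of a regex in a string.
all_match_starts <- function(regex, text) {
  hits <- gregexpr(paste0("(?=", regex, ")"), text, perl = TRUE)[[1]]
  if (hits[1] == -1L) integer(0) else as.integer(hits)
}

#' Scan a promoter for cis-regulatory elements
#'
#' IUPAC-aware exact matching of every catalog consensus on the forward
#' and (optionally) reverse strand. Reverse-strand hits are reported in
#' forward-strand coordinates; a hit found at the same genomic span on both
#' strands (palindromic consensus) is counted once. Promoters are expected
#' to be the 1500-bp upstream window; longer sequences trigger a warning
#' but are scanned in full.
#'
#' @param promoter A nucleotide [sequence_record()].
#' @param catalog Data frame from [cis_element_catalog()].
#' @param search_both_strands Scan the reverse strand too (default TRUE).
#' @param expected_window Declared upstream window length (default 1500).
#' @return List with `hits` (data frame: `sequence_id`, `element`, `class`,
#'   `start`, `end`, `strand`) and `class_tallies` (named counts over
#'   hormone/stress/growth/core/other).
#' @export
scan_cis_elements <- function(promoter, catalog = cis_element_catalog(),
                              search_both_strands = TRUE,
                              expected_window = 1500L) {
  assert_alphabet(promoter, "nucleotide")
  if (nchar(promoter$sequence) > expected_window) {
    warning("promoter '", promoter$id, "' is longer than the declared ",
            expected_window, "-bp window; scanning the full sequence")
  }
  fwd <- promoter$sequence
  L <- nchar(fwd)
  rev <- if (search_both_strands) {
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(fwd)))
  } else NULL

  rows <- lapply(seq_len(nrow(catalog)), function(i) {
    regex <- iupac_to_regex(catalog$consensus[i])
    w <- nchar(catalog$consensus[i])
    starts_f <- all_match_starts(regex, fwd)
    df <- data.frame(start = starts_f,
                     end = starts_f + w - 1L,
                     strand = rep("+", length(starts_f)),
                     stringsAsFactors = FALSE)
    if (!is.null(rev)) {
      starts_r <- all_match_starts(regex, rev)
      # map reverse-strand spans back onto forward coordinates
      df_r <- data.frame(start = L - (starts_r + w - 1L) + 1L,
                         end = L - starts_r + 1L,
                         strand = rep("-", length(starts_r)),
                         stringsAsFactors = FALSE)
      df <- rbind(df, df_r)
      # palindromic consensus: same span on both strands counts once
      df <- df[!duplicated(df[, c("start", "end")]), , drop = FALSE]
    }
    if (nrow(df) == 0L) return(NULL)
    cbind(data.frame(sequence_id = promoter$id,
                     element = catalog$name[i],
                     class = catalog$class[i],
                     stringsAsFactors = FALSE),
          df)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  hits <- if (length(rows)) {
    h <- do.call(rbind, rows)
    h <- h[order(h$start, h$element), , drop = FALSE]
    rownames(h) <- NULL
    h
  } else {
    data.frame(sequence_id = character(), element = character(),
               class = character(), start = integer(), end = integer(),
               strand = character(), stringsAsFactors = FALSE)
  }
  classes <- c("hormone", "stress", "growth", "core", "other")
  tallies <- setNames(integer(length(classes)), classes)
  tab <- table(factor(hits$class, levels = classes))
  tallies[names(tab)] <- as.integer(tab)
  list(hits = hits, class_tallies = tallies)
}

GO_CATEGORIES <- c("MF", "BP", "CC")

#' Venn partition of transcripts over GO primary categories
#'
#' Each annotated transcript is placed in exactly one of the 7 Venn regions
#' according to the set of primary categories (MF, BP, CC) it carries.
#'
#' @param annotations Data frame with `transcript_id`, `primary_category`
#'   (MF/BP/CC) and optionally `level2_subcategory`.
#' @return List with `regions` (named counts for `MF`, `BP`, `CC`,
#'   `MF&BP`, `MF&CC`, `BP&CC`, `MF&BP&CC`), `totals` (per-category
#'   transcript totals) and `n_annotated`.
#' @export
go_venn <- function(annotations) {
  stopifnot(is.data.frame(annotations),
            all(c("transcript_id", "primary_category") %in% names(annotations)))
  bad <- setdiff(unique(annotations$primary_category), GO_CATEGORIES)
  if (length(bad)) {
    stop("unknown GO primary category: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  region_names <- c("MF", "BP", "CC", "MF&BP", "MF&CC", "BP&CC", "MF&BP&CC")
  regions <- setNames(integer(7L), region_names)
  if (nrow(annotations)) {
    per_tx <- split(annotations$primary_category, annotations$transcript_id)
    labels <- vapply(per_tx, function(cats) {
      paste(GO_CATEGORIES[GO_CATEGORIES %in% cats], collapse = "&")
    }, character(1))
    tab <- table(factor(labels, levels = region_names))
    regions[names(tab)] <- as.integer(tab)
  }
  totals <- c(
    MF = sum(regions[c("MF", "MF&BP", "MF&CC", "MF&BP&CC")]),
    BP = sum(regions[c("BP", "MF&BP", "BP&CC", "MF&BP&CC")]),
    CC = sum(regions[c("CC", "MF&CC", "BP&CC", "MF&BP&CC")])
  )
  list(regions = regions, totals = totals, n_annotated = sum(regions))
}

#' Chi-square enrichment of GO subcategories against a background
#'
#' For each subcategory a 2x2 table (in/out of the subcategory x
#' family/background) is tested with the Pearson chi-square statistic
#' (1 df, no continuity correction). Direction is `up` when the observed
#' family count exceeds the expectation under background proportions.
#' No multiple-testing correction is applied by default; set
#' `adjust = "BH"` for Benjamini-Hochberg adjusted flags.
#'
#' @param observed Named counts: family transcripts per subcategory.
#' @param background Named counts: background transcripts per subcategory
#'   (must cover all tested subcategories with positive counts).
#' @param adjust `"none"` (default) or `"BH"`.
#' @return Data frame with `subcategory`, `observed`, `expected`,
#'   `chi_square`, `p_value`, `direction` (up/down/none), `significance`
#'   (ns/p05/p01), `unreliable` (TRUE when an expected cell < 1).
#' @export
chi_square_enrichment <- function(observed, background, adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  stopifnot(length(observed) > 0, length(background) > 0,
            !is.null(names(observed)), !is.null(names(background)))
  subs <- names(observed)
  missing_bg <- setdiff(subs, names(background))
  if (length(missing_bg)) {
    stop("subcategories absent from background: ",
         paste(missing_bg, collapse = ", "), call. = FALSE)
  }
  n_fam <- sum(observed)
  n_bg <- sum(background)
  if (n_fam <= 0 || n_bg <= 0) stop("totals must be > 0", call. = FALSE)
  if (any(background[subs] <= 0)) {
    stop("background count must be > 0 for tested subcategories",
         call. = FALSE)
  }
  res <- lapply(subs, function(s) {
    a <- observed[[s]]; b <- n_fam - a
    c_ <- background[[s]]; d <- n_bg - c_
    expected <- n_fam * c_ / n_bg
    tab <- matrix(c(a, b, c_, d), nrow = 2, byrow = TRUE)
    exp_cells <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    if (all(tab == 0) || any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
      chi <- 0; p <- 1
    } else {
      chi <- sum((tab - exp_cells)^2 / exp_cells)
      p <- pchisq(chi, df = 1, lower.tail = FALSE)
    }
    data.frame(
      subcategory = s, observed = a, expected = expected,
      chi_square = chi, p_value = p,
      direction = if (a > expected) "up" else if (a < expected) "down" else "none",
      unreliable = any(exp_cells < 1),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, res)
  p_for_flag <- if (adjust == "BH") stats::p.adjust(out$p_value, "BH") else out$p_value
  out$significance <- ifelse(p_for_flag <= 0.01, "p01",
                             ifelse(p_for_flag <= 0.05, "p05", "ns"))
  if (adjust == "BH") out$p_adjusted <- p_for_flag
  rownames(out) <- NULL
  out
}
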