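# Family identification: C2H2 zinc-finger pattern scanning, ORF finding
# and ProtParam-style physicochemical properties.

#' Scan a protein for C2H2 zinc-finger domains
#'
#' Finds matches of the canonical C2H2 pattern
#' `X2-C-X(2-4)-C-X12-H-X(2-8)-H` (two cysteines and two histidines
#' coordinating the zinc ion; `X` is any residue) by a left-to-right scan.
#' Matches are greedy and non-overlapping: after a hit, scanning resumes at
#' the residue following the hit's second histidine. At a given start
#' position the shortest valid first gap, then the shortest valid second
#' gap, is chosen.
#'
#' @param protein A [sequence_record()] with protein alphabet.
#' @return Data frame with one row per hit: `sequence_id`, `start`, `end`
#'   (1-based inclusive residue coordinates), `gap1_len`, `gap2_len`,
#'   `matched_subsequence`.
#' @examples
#' scan_c2h2(sequence_record("zf", "MKCAACLLLLLLLLLLLLHAAH", "protein"))
#' @export
scan_c2h2 <- function(protein) {
  assert_alphabet(protein, "protein")
  chars <- strsplit(protein$sequence, "", fixed = TRUE)[[1]]
  L <- length(chars)
  hits <- list()
  s <- 1L
  # minimal hit length: 2 + 1 + 2 + 1 + 12 + 1 + 2 + 1 = 22
  while (s <= L - 21L) {
    match <- NULL
    c1 <- s + 2L
    if (chars[c1] == "C") {
      for (g1 in 2:4) {
        c2 <- c1 + g1 + 1L
        if (c2 > L || chars[c2] != "C") next
        h1 <- c2 + 13L
        if (h1 > L || chars[h1] != "H") next
        for (g2 in 2:8) {
          h2 <- h1 + g2 + 1L
          if (h2 > L) break
          if (chars[h2] == "H") {
            match <- list(start = s, end = h2, gap1 = g1, gap2 = g2)
            break
          }
        }
        if (!is.null(match)) break
      }
    }
    if (is.null(match)) {
      s <- s + 1L
    } else {
      hits[[length(hits) + 1L]] <- data.frame(
        sequence_id = protein$id,
        start = match$start, end = match$end,
        gap1_len = match$gap1, gap2_len = match$gap2,
        matched_subsequence = substr(protein$sequence, match$start, match$end),
        stringsAsFactors = FALSE
      )
      s <- match$end + 1L
    }
  }
  if (length(hits) == 0L) {
    return(data.frame(sequence_id = character(), start = integer(),
                      end = integer(), gap1_len = integer(),
                      gap2_len = integer(),
                      matched_subsequence = character(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, hits)
}

#' Classify a protein as a C2H2-ZFP family member
#'
#' A protein is called a family member when it carries at least
#' `min_fingers` C2H2 finger hits. Plant C2H2-ZFP family members typically
#' carry one to six fingers; `in_expected_range` flags hit counts in 1-6.
#'
#' @inheritParams scan_c2h2
#' @param min_fingers Minimum finger count for membership (default 1).
#' @return List with `is_member`, `n_fingers`, `in_expected_range`, and the
#'   hit table `hits`.
#' @export
classify_family_member <- function(protein, min_fingers = 1L) {
  stopifnot(min_fingers >= 1L)
  hits <- scan_c2h2(protein)
  n <- nrow(hits)
  list(is_member = n >= min_fingers,
       n_fingers = n,
       in_expected_range = n >= 1L && n <= 6L,
       hits = hits)
}

STOP_CODONS <- c("TAA", "TAG", "TGA")

translate_codons <- function(codons) {
  code <- Biostrings::GENETIC_CODE
  aa <- unname(code[codons])
  aa[is.na(aa)] <- "X"  # codons containing N
  aa
}

#' Find open reading frames in a nucleotide sequence
#'
#' Scans all six reading frames for ATG...stop spans. Within a frame the
#' scan is greedy left-to-right: each ATG opens an ORF that extends to the
#' next in-frame stop (scanning resumes after the stop). ORFs reaching the
#' sequence end without a stop are reported with `partial = TRUE`. Codons
#' containing `N` are never starts or stops and translate as `X`.
#'
#' @param nucleotide A [sequence_record()] with nucleotide alphabet.
#' @param min_protein_len Minimum encoded protein length in residues
#'   (default 25).
#' @return Data frame sorted by protein length (longest first) with columns
#'   `sequence_id`, `frame` (+1..+3, -1..-3), `start`, `end` (1-based
#'   inclusive forward-strand nucleotide coordinates, stop codon included),
#'   `partial`, `protein`.
#' @export
find_orfs <- function(nucleotide, min_protein_len = 25L) {
  assert_alphabet(nucleotide, "nucleotide")
  seq_fwd <- nucleotide$sequence
  L <- nchar(seq_fwd)
  seq_rev <- as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(seq_fwd)))
  orfs <- list()
  for (strand in c(1L, -1L)) {
    s <- if (strand == 1L) seq_fwd else seq_rev
    for (off in 0:2) {
      n_codons <- (L - off) %/% 3L
      if (n_codons < 1L) next
      starts_nt <- off + 1L + 3L * (seq_len(n_codons) - 1L)
      codons <- substring(s, starts_nt, starts_nt + 2L)
      i <- 1L
      while (i <= n_codons) {
        if (codons[i] == "ATG") {
          j <- i + 1L
          while (j <= n_codons && !codons[j] %in% STOP_CODONS) j <- j + 1L
          partial <- j > n_codons
          last <- if (partial) n_codons else j
          prot_codons <- codons[i:(if (partial) last else last - 1L)]
          prot <- paste(translate_codons(prot_codons), collapse = "")
          a <- starts_nt[i]
          b <- starts_nt[last] + 2L
          if (strand == -1L) {
            tmp <- L - b + 1L
            b <- L - a + 1L
            a <- tmp
          }
          orfs[[length(orfs) + 1L]] <- data.frame(
            sequence_id = nucleotide$id,
            frame = strand * (off + 1L),
            start = a, end = b, partial = partial,
            protein = prot, stringsAsFactors = FALSE
          )
          i <- last + 1L
        } else {
          i <- i + 1L
        }
      }
    }
  }
  if (length(orfs) == 0L) {
    return(data.frame(sequence_id = character(), frame = integer(),
                      start = integer(), end = integer(),
                      partial = logical(), protein = character(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, orfs)
  out <- out[nchar(out$protein) >= min_protein_len, , drop = FALSE]
  out <- out[order(-nchar(out$protein), out$frame, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' ProtParam-style physicochemical properties of a protein
#'
#' Computes molecular weight (average isotopic residue masses plus one
#' water), GRAVY (mean Kyte-Doolittle hydropathy), the Guruprasad
#' instability index (10/L times the sum of DIWV dipeptide weights; > 40
#' predicts in vitro instability), the Ikai aliphatic index
#' (100*(xAla + 2.9*xVal + 3.9*(xIle + xLeu)) on mole fractions), and the
#' isoelectric point (bisection of the Bjellqvist-pKa net-charge curve to
#' |charge| < 1e-4). `X` residues are excluded from the mass, hydropathy
#' and aliphatic computations; when present, pI and instability are `NA`
#' with a warning.
#'
#' @inheritParams scan_c2h2
#' @return List of class `protein_properties` with fields `length`,
#'   `molecular_weight` (Da), `isoelectric_point`, `gravy`,
#'   `instability_index`, `aliphatic_index`, `is_hydrophilic`
#'   (GRAVY < 0), `is_unstable` (instability > 40).
#' @examples
#' protein_properties(sequence_record("p", "MKWVTFISLLLLFSSAYS", "protein"))
#' @export
protein_properties <- function(protein) {
  assert_alphabet(protein, "protein")
  if (nchar(protein$sequence) == 0L) {
    stop("empty protein sequence", call. = FALSE)
  }
  chars <- strsplit(protein$sequence, "", fixed = TRUE)[[1]]
  has_x <- any(chars == "X")
  core <- chars[chars != "X"]
  if (length(core) == 0L) stop("sequence is all X", call. = FALSE)
  L <- length(core)

  mw <- sum(AA_RESIDUE_MASS[core]) + MASS_WATER
  gravy <- mean(KD_HYDROPATHY[core])
  frac <- table(factor(core, levels = AA_STANDARD)) / L
  aliphatic <- 100 * (frac[["A"]] + ALIPHATIC_COEF[["V"]] * frac[["V"]] +
                        ALIPHATIC_COEF[["I"]] * (frac[["I"]] + frac[["L"]]))

  if (has_x) {
    warning("sequence '", protein$id,
            "' contains X; pI and instability index set to NA")
    pi_val <- NA_real_
    instability <- NA_real_
  } else {
    pi_val <- isoelectric_point(chars)
    instability <- instability_index(chars)
  }

  structure(list(
    length = length(chars),
    molecular_weight = mw,
    isoelectric_point = pi_val,
    gravy = gravy,
    instability_index = instability,
    aliphatic_index = unname(aliphatic),
    is_hydrophilic = gravy < 0,
    is_unstable = if (is.na(instability)) NA else instability > 40
  ), class = "protein_properties")
}

#' @export
print.protein_properties <- function(x, ...) {
  cat(sprintf(paste0(
    "<protein_properties> %d aa\n",
    "  MW %.2f Da | pI %.2f | GRAVY %+.3f (%s)\n",
    "  instability %.2f (%s) | aliphatic index %.2f\n"),
    x$length, x$molecular_weight, x$isoelectric_point, x$gravy,
    if (isTRUE(x$is_hydrophilic)) "hydrophilic" else "hydrophobic",
    x$instability_index,
    if (isTRUE(x$is_unstable)) "unstable" else "stable",
    x$aliphatic_index))
  invisible(x)
}

instability_index <- function(chars) {
  L <- length(chars)
  if (L < 2L) return(0)
  w <- DIWV[cbind(chars[-L], chars[-1])]
  (10 / L) * sum(w)
}

# Net charge of the peptide at a given pH under the Bjellqvist pKa set,
# with residue-specific terminal pKa overrides.
peptide_charge <- function(pH, counts, nterm_res, cterm_res) {
  pk_nt <- if (nterm_res %in% names(PKA_NTERM_BY_RESIDUE)) {
    PKA_NTERM_BY_RESIDUE[[nterm_res]]
  } else PKA_POSITIVE[["Nterm"]]
  pk_ct <- if (cterm_res %in% names(PKA_CTERM_BY_RESIDUE)) {
    PKA_CTERM_BY_RESIDUE[[cterm_res]]
  } else PKA_NEGATIVE[["Cterm"]]
  pos <- 1 / (1 + 10^(pH - pk_nt)) +
    counts[["K"]] / (1 + 10^(pH - PKA_POSITIVE[["K"]])) +
    counts[["R"]] / (1 + 10^(pH - PKA_POSITIVE[["R"]])) +
    counts[["H"]] / (1 + 10^(pH - PKA_POSITIVE[["H"]]))
  neg <- 1 / (1 + 10^(pk_ct - pH)) +
    counts[["D"]] / (1 + 10^(PKA_NEGATIVE[["D"]] - pH)) +
    counts[["E"]] / (1 + 10^(PKA_NEGATIVE[["E"]] - pH)) +
    counts[["C"]] / (1 + 10^(PKA_NEGATIVE[["C"]] - pH)) +
    counts[["Y"]] / (1 + 10^(PKA_NEGATIVE[["Y"]] - pH))
  pos - neg
}

isoelectric_point <- function(chars, tol = 1e-4) {
  counts <- as.list(table(factor(chars, levels = AA_STANDARD)))
  lo <- 0; hi <- 14
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    q <- peptide_charge(mid, counts, chars[1], chars[length(chars)])
    if (abs(q) < tol) break
    if (q > 0) lo <- mid else hi <- mid
  }
  mid
}
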