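# Independent oracles used across the suite. These deliberately re-derive
# results from first principles (definition-level checks, brute-force
# enumeration) rather than reusing package internals.

# Residue-by-residue re-validation of a C2H2 finger hit against the
# pattern definition X2-C-X(gap1)-C-X12-H-X(gap2)-H.
revalidate_c2h2_hit <- function(sequence, start, end, gap1, gap2) {
  len <- end - start + 1L
  if (len != 2L + 1L + gap1 + 1L + 12L + 1L + gap2 + 1L) return(FALSE)
  if (gap1 < 2L || gap1 > 4L || gap2 < 2L || gap2 > 8L) return(FALSE)
  ch <- function(i) substr(sequence, start + i - 1L, start + i - 1L)
  c1 <- 3L
  c2 <- c1 + gap1 + 1L
  h1 <- c2 + 13L
  h2 <- h1 + gap2 + 1L
  ch(c1) == "C" && ch(c2) == "C" && ch(h1) == "H" && ch(h2) == "H"
}

# Brute-force Nei-Gojobori pathway oracle: enumerates every ordering of the
# differing codon positions as an explicit list of intermediate codons,
# drops orderings that pass through a stop codon, classifies each single
# step by comparing translations, and averages with equal weights.
oracle_pathway_diffs <- function(codon_a, codon_b) {
  code <- Biostrings::GENETIC_CODE
  a <- strsplit(codon_a, "")[[1]]
  b <- strsplit(codon_b, "")[[1]]
  pos <- which(a != b)
  if (length(pos) == 0L) return(c(syn = 0, nonsyn = 0))
  orderings <- all_orderings(pos)
  results <- list()
  for (ord in orderings) {
    path <- list(a)
    cur <- a
    for (p in ord) {
      cur[p] <- b[p]
      path[[length(path) + 1L]] <- cur
    }
    codons <- vapply(path, paste, character(1), collapse = "")
    aas <- unname(code[codons])
    if (any(aas[-1] == "*")) next  # blocked by a stop codon
    steps_syn <- sum(aas[-1] == aas[-length(aas)])
    results[[length(results) + 1L]] <-
      c(syn = steps_syn, nonsyn = length(pos) - steps_syn)
  }
  if (length(results) == 0L) {
    # all pathways blocked: count steps ignoring the stop constraint
    for (ord in orderings) {
      path <- list(a); cur <- a
      for (p in ord) { cur[p] <- b[p]; path[[length(path) + 1L]] <- cur }
      codons <- vapply(path, paste, character(1), collapse = "")
      aas <- unname(code[codons])
      steps_syn <- sum(aas[-1] == aas[-length(aas)])
      results[[length(results) + 1L]] <-
        c(syn = steps_syn, nonsyn = length(pos) - steps_syn)
    }
  }
  colMeans(do.call(rbind, results))
}

all_orderings <- function(x) {
  if (length(x) <= 1L) return(list(x))
  out <- list()
  for (i in seq_along(x)) {
    for (tail in all_orderings(x[-i])) out[[length(out) + 1L]] <- c(x[i], tail)
  }
  out
}

# Random sense codon (no stop), uniform over the 61.
random_sense_codons <- function(n) {
  code <- Biostrings::GENETIC_CODE
  sense <- names(code)[code != "*"]
  sample(sense, n, replace = TRUE)
}
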