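# Comparative genomics: alignment filtering at the study's threshold
# profiles, pan/core family composition, and duplication dating from
# Nei-Gojobori (1986) Ka/Ks.

#' Alignment threshold profiles
#'
#' Two fixed profiles are used: `within_species` (identity >= 99%,
#' alignment length >= 200 bp, e-value <= 1.0e-100) for mapping family
#' members onto conspecific genome assemblies, and `cross_species`
#' (identity >= 75%, length >= 80 bp, e-value <= 1.0e-10) for distant
#' comparisons such as Arabidopsis.
#'
#' @param name `"within_species"` or `"cross_species"`.
#' @return List with `min_identity`, `min_cover_length`, `max_evalue`,
#'   `name`.
#' @export
threshold_profile <- function(name = c("within_species", "cross_species")) {
  name <- match.arg(name)
  if (name == "within_species") {
    list(min_identity = 99, min_cover_length = 200, max_evalue = 1.0e-100,
         name = name)
  } else {
    list(min_identity = 75, min_cover_length = 80, max_evalue = 1.0e-10,
         name = name)
  }
}

#' Filter alignment records at a threshold profile
#'
#' A record is kept iff identity >= `min_identity` AND alignment length >=
#' `min_cover_length` AND e-value <= `max_evalue` (all boundaries
#' inclusive). Input order is preserved; the filter is idempotent.
#'
#' @param records Alignment table (see [read_alignment_table()]).
#' @param profile A profile from [threshold_profile()] or a list with the
#'   same fields.
#' @return The subset of `records` passing all three thresholds.
#' @export
filter_alignments <- function(records, profile = threshold_profile()) {
  validate_alignment_table(records)
  keep <- records$identity >= profile$min_identity &
    records$align_length >= profile$min_cover_length &
    records$evalue <= profile$max_evalue
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build a gene-by-assembly presence matrix from filtered alignments
#'
#' @param records Filtered alignment table; `subject_id` is read as the
#'   assembly label.
#' @param genes Optional gene universe (row order); defaults to the queries
#'   observed.
#' @param assemblies Optional assembly universe (column order); defaults to
#'   the subjects observed.
#' @return Logical matrix, genes in rows, assemblies in columns.
#' @export
presence_from_alignments <- function(records, genes = NULL,
                                     assemblies = NULL) {
  if (is.null(genes)) genes <- sort(unique(records$query_id))
  if (is.null(assemblies)) assemblies <- sort(unique(records$subject_id))
  m <- matrix(FALSE, nrow = length(genes), ncol = length(assemblies),
              dimnames = list(genes, assemblies))
  if (nrow(records)) {
    idx <- cbind(match(records$query_id, genes),
                 match(records$subject_id, assemblies))
    idx <- idx[stats::complete.cases(idx), , drop = FALSE]
    m[idx] <- TRUE
  }
  m
}

#' Pan/core composition of a gene family across assemblies
#'
#' Computes the pan set (union of per-assembly gene sets), core set
#' (intersection) and dispensable count (pan minus core). For up to three
#' assemblies the exclusive Venn regions are reported, named by the
#' assemblies sharing each region joined with `&`.
#'
#' @param presence Logical gene-by-assembly matrix (rows genes, columns
#'   assemblies) with unique dimnames.
#' @return List with `pan`, `core`, `dispensable`, `per_assembly` (named
#'   present-gene counts) and, for <= 3 assemblies, `per_region_counts`.
#' @examples
#' m <- matrix(c(TRUE, TRUE, FALSE, FALSE, TRUE, TRUE, FALSE, TRUE, FALSE),
#'             nrow = 3, dimnames = list(c("g1", "g2", "g3"), c("A", "B", "C")))
#' pan_core(m)
#' @export
pan_core <- function(presence) {
  if (!is.matrix(presence) || !is.logical(presence) ||
      nrow(presence) == 0L || ncol(presence) == 0L) {
    stop("presence must be a non-empty logical matrix", call. = FALSE)
  }
  if (anyDuplicated(rownames(presence)) || anyDuplicated(colnames(presence))) {
    stop("presence matrix labels must be unique", call. = FALSE)
  }
  anywhere <- rowSums(presence) > 0
  everywhere <- rowSums(presence) == ncol(presence)
  pan <- sum(anywhere)
  core <- sum(everywhere)
  out <- list(pan = pan, core = core, dispensable = pan - core,
              per_assembly = colSums(presence))
  if (ncol(presence) <= 3L) {
    labs <- colnames(presence)
    pattern <- apply(presence, 1, function(r) paste(labs[r], collapse = "&"))
    pattern <- pattern[nzchar(pattern)]
    # every non-empty subset of assemblies gets a (possibly zero) region
    subsets <- unlist(lapply(seq_along(labs), function(k) {
      apply(combn(labs, k), 2, paste, collapse = "&")
    }))
    counts <- setNames(integer(length(subsets)), subsets)
    tab <- table(pattern)
    counts[names(tab)] <- as.integer(tab)
    out$per_region_counts <- counts
  }
  out
}

#' Construct a three-assembly presence matrix from Venn region counts
#'
#' Builds a logical gene-by-assembly matrix whose exclusive Venn regions
#' have exactly the given sizes — the inverse of [pan_core()]'s
#' `per_region_counts`. Useful for reconstructing a family composition
#' from published Venn counts.
#'
#' @param singles Counts of genes exclusive to each assembly, length 3.
#' @param pairs Counts of genes shared by exactly two assemblies, in the
#'   order (1st&2nd, 1st&3rd, 2nd&3rd).
#' @param core Count of genes present in all three assemblies.
#' @param assemblies Assembly labels (default A, B, C).
#' @return Logical presence matrix with `sum(singles) + sum(pairs) + core`
#'   rows.
#' @export
venn_presence_matrix <- function(singles, pairs, core,
                                 assemblies = c("A", "B", "C")) {
  stopifnot(length(singles) == 3, length(pairs) == 3, length(core) == 1,
            length(assemblies) == 3, all(c(singles, pairs, core) >= 0))
  patterns <- list(c(1), c(2), c(3), c(1, 2), c(1, 3), c(2, 3), c(1, 2, 3))
  counts <- c(singles, pairs, core)
  n <- sum(counts)
  m <- matrix(FALSE, n, 3,
              dimnames = list(sprintf("gene%03d", seq_len(n)), assemblies))
  row <- 0L
  for (k in seq_along(patterns)) {
    for (i in seq_len(counts[k])) {
      row <- row + 1L
      m[row, patterns[[k]]] <- TRUE
    }
  }
  m
}

## ---- Nei-Gojobori (1986) Ka/Ks -------------------------------------------

sense_codons <- function() {
  code <- Biostrings::GENETIC_CODE
  names(code)[code != "*"]
}

codon_aa <- function(codon) {
  aa <- Biostrings::GENETIC_CODE[[codon]]
  if (is.null(aa)) NA_character_ else aa
}

# Number of synonymous sites in one sense codon: at each of the 3
# positions, the fraction of the 3 possible single-nucleotide changes that
# preserve the encoded amino acid. Changes creating a stop codon count as
# nonsynonymous so that syn + nonsyn sites always sum to 3.
codon_syn_sites <- function(codon) {
  bases <- c("A", "C", "G", "T")
  aa0 <- codon_aa(codon)
  s <- 0
  for (pos in 1:3) {
    for (b in setdiff(bases, substr(codon, pos, pos))) {
      alt <- codon
      substr(alt, pos, pos) <- b
      aa1 <- codon_aa(alt)
      if (!is.na(aa1) && aa1 != "*" && aa1 == aa0) s <- s + 1 / 3
    }
  }
  s
}

# Pathway-averaged synonymous/nonsynonymous difference counts between two
# sense codons: all minimal substitution pathways (orderings of the
# differing positions) are enumerated with equal weights; pathways passing
# through a stop codon are excluded (if every pathway is blocked, all are
# used). Returns c(syn, nonsyn).
codon_pair_diffs <- function(codon_a, codon_b) {
  diff_pos <- which(strsplit(codon_a, "")[[1]] != strsplit(codon_b, "")[[1]])
  k <- length(diff_pos)
  if (k == 0L) return(c(syn = 0, nonsyn = 0))
  perms <- permutations_of(diff_pos)
  tally <- matrix(NA_real_, nrow = length(perms), ncol = 2)
  blocked <- logical(length(perms))
  for (p in seq_along(perms)) {
    cur <- codon_a
    sd <- 0; nd <- 0
    for (pos in perms[[p]]) {
      nxt <- cur
      substr(nxt, pos, pos) <- substr(codon_b, pos, pos)
      aa_cur <- codon_aa(cur); aa_nxt <- codon_aa(nxt)
      if (aa_nxt == "*") { blocked[p] <- TRUE; break }
      if (aa_nxt == aa_cur) sd <- sd + 1 else nd <- nd + 1
      cur <- nxt
    }
    if (!blocked[p]) tally[p, ] <- c(sd, nd)
  }
  if (all(blocked)) {
    # degenerate: count every step, ignoring the stop constraint
    tally <- matrix(NA_real_, nrow = length(perms), ncol = 2)
    for (p in seq_along(perms)) {
      cur <- codon_a; sd <- 0; nd <- 0
      for (pos in perms[[p]]) {
        nxt <- cur
        substr(nxt, pos, pos) <- substr(codon_b, pos, pos)
        if (identical(codon_aa(nxt), codon_aa(cur))) sd <- sd + 1 else nd <- nd + 1
        cur <- nxt
      }
      tally[p, ] <- c(sd, nd)
    }
    blocked[] <- FALSE
  }
  ok <- tally[!blocked, , drop = FALSE]
  c(syn = mean(ok[, 1]), nonsyn = mean(ok[, 2]))
}

permutations_of <- function(x) {
  if (length(x) <= 1L) return(list(x))
  out <- list()
  for (i in seq_along(x)) {
    for (rest in permutations_of(x[-i])) {
      out[[length(out) + 1L]] <- c(x[i], rest)
    }
  }
  out
}

split_codons <- function(record) {
  assert_alphabet(record, "nucleotide")
  L <- nchar(record$sequence)
  if (L %% 3 != 0) {
    stop("sequence '", record$id, "' length is not a multiple of 3",
         call. = FALSE)
  }
  substring(record$sequence, seq(1, L, 3), seq(3, L, 3))
}

#' Nei-Gojobori (1986) Ka/Ks for a pre-aligned codon pair
#'
#' Counts synonymous and nonsynonymous sites per codon by mutational
#' opportunity under the standard genetic code (site counts averaged over
#' the two sequences), counts differences with equal-weight averaging over
#' all minimal substitution pathways for multi-site codons (pathways through
#' stop codons excluded), and applies the Jukes-Cantor correction
#' d = -(3/4) ln(1 - 4p/3) to the proportions ps and pn.
#'
#' @param cds_a,cds_b Codon-aligned nucleotide [sequence_record()]s of equal
#'   length (multiple of 3, no internal stop codons; a shared terminal stop
#'   codon is dropped).
#' @param lambda_rate Synonymous substitution rate per site per year used
#'   for dating (default 6.5e-9).
#' @param band Neutral band from [selection_band()].
#' @return List of class `kaks_result`: `ka`, `ks`, `ratio` (`NA` when
#'   ks = 0), `syn_sites`, `nonsyn_sites`, `syn_diffs`, `nonsyn_diffs`,
#'   `ps`, `pn`, `divergence_time_mya`, `selection_mode`.
#' @examples
#' a <- sequence_record("a", "GGGGGG", "nucleotide")
#' b <- sequence_record("b", "GGAGGG", "nucleotide")
#' ng86_kaks(a, b)
#' @export
ng86_kaks <- function(cds_a, cds_b, lambda_rate = 6.5e-9,
                      band = selection_band()) {
  ca <- split_codons(cds_a)
  cb <- split_codons(cds_b)
  if (length(ca) != length(cb)) {
    stop("sequences differ in length (", 3 * length(ca), " vs ",
         3 * length(cb), " nt)", call. = FALSE)
  }
  # drop a shared terminal stop codon, reject stops anywhere else
  n <- length(ca)
  if (n > 0 && ca[n] %in% STOP_CODONS && cb[n] %in% STOP_CODONS) {
    ca <- ca[-n]; cb <- cb[-n]; n <- n - 1L
  }
  if (any(ca %in% STOP_CODONS) || any(cb %in% STOP_CODONS)) {
    stop("internal stop codon in input CDS", call. = FALSE)
  }
  if (n == 0L) stop("no codons to compare", call. = FALSE)

  syn_a <- sum(vapply(ca, memo_syn_sites, numeric(1)))
  syn_b <- sum(vapply(cb, memo_syn_sites, numeric(1)))
  S <- (syn_a + syn_b) / 2
  N <- 3 * n - S

  sd_total <- 0; nd_total <- 0
  for (i in seq_len(n)) {
    if (ca[i] != cb[i]) {
      d <- memo_pair_diffs(ca[i], cb[i])
      sd_total <- sd_total + d[[1]]
      nd_total <- nd_total + d[[2]]
    }
  }
  ps <- sd_total / S
  pn <- nd_total / N
  ks <- jukes_cantor(ps)
  ka <- jukes_cantor(pn)
  ratio <- if (ks == 0) NA_real_ else ka / ks
  structure(list(
    ka = ka, ks = ks, ratio = ratio,
    syn_sites = S, nonsyn_sites = N,
    syn_diffs = sd_total, nonsyn_diffs = nd_total,
    ps = ps, pn = pn,
    divergence_time_mya = divergence_time(ks, lambda_rate),
    selection_mode = classify_selection(ratio, band)
  ), class = "kaks_result")
}

#' @export
print.kaks_result <- function(x, ...) {
  cat(sprintf(paste0(
    "<kaks_result> Ka = %.4f  Ks = %.4f  Ka/Ks = %s\n",
    "  sites S = %.2f, N = %.2f | diffs Sd = %.2f, Nd = %.2f\n",
    "  divergence %.1f MYA | selection: %s\n"),
    x$ka, x$ks, ifelse(is.na(x$ratio), "undefined", sprintf("%.3f", x$ratio)),
    x$syn_sites, x$nonsyn_sites, x$syn_diffs, x$nonsyn_diffs,
    x$divergence_time_mya, x$selection_mode))
  invisible(x)
}

# Jukes-Cantor multiple-hit correction; undefined at p >= 3/4.
jukes_cantor <- function(p) {
  if (p < 0) stop("negative difference proportion", call. = FALSE)
  if (p == 0) return(0)
  if (p >= 3 / 4) {
    stop("difference proportion ", signif(p, 4),
         " >= 3/4: Jukes-Cantor correction saturated", call. = FALSE)
  }
  -0.75 * log(1 - 4 * p / 3)
}

#' Duplication/divergence time from Ks
#'
#' T (in million years) = Ks / (2 * lambda) * 1e-6, with lambda the
#' synonymous substitution rate per site per year (default 6.5e-9).
#'
#' @param ks Synonymous substitutions per synonymous site (>= 0).
#' @param lambda_rate Substitution rate (> 0).
#' @return Time in million years.
#' @examples
#' divergence_time(0.234)  # 18.0 MYA
#' @export
divergence_time <- function(ks, lambda_rate = 6.5e-9) {
  if (any(ks < 0)) stop("ks must be >= 0", call. = FALSE)
  if (lambda_rate <= 0) stop("lambda_rate must be > 0", call. = FALSE)
  ks / (2 * lambda_rate) * 1e-6
}

#' Neutral selection band around Ka/Ks = 1
#' @param center Band center (1.0).
#' @param half_width Band half width (0.1).
#' @return List with `center` and `half_width`.
#' @export
selection_band <- function(center = 1.0, half_width = 0.1) {
  stopifnot(half_width > 0)
  list(center = center, half_width = half_width)
}

#' Classify selection mode from a Ka/Ks ratio
#'
#' Ratios below `center - half_width` are purifying, within the closed band
#' neutral, above it positive; `NA` ratios (Ks = 0) are `"undefined"`.
#'
#' @param ratio Ka/Ks ratio, or `NA`.
#' @param band Band from [selection_band()].
#' @return One of `"purifying"`, `"neutral"`, `"positive"`, `"undefined"`.
#' @export
classify_selection <- function(ratio, band = selection_band()) {
  vapply(ratio, function(r) {
    if (is.na(r)) return("undefined")
    lo <- band$center - band$half_width
    hi <- band$center + band$half_width
    if (r < lo) "purifying" else if (r <= hi) "neutral" else "positive"
  }, character(1))
}

#' Best reciprocal pairs from filtered cross-species alignments
#'
#' A lightweight stand-in for synteny detection: for each query its best
#' subject (highest identity, ties by lowest e-value then lexicographic
#' subject id) and vice versa; pairs that are mutual bests are returned.
#'
#' @param records Filtered alignment table.
#' @return Data frame with `query_id`, `subject_id`.
#' @export
best_reciprocal_pairs <- function(records) {
  validate_alignment_table(records)
  if (nrow(records) == 0L) {
    return(data.frame(query_id = character(), subject_id = character(),
                      stringsAsFactors = FALSE))
  }
  best_by <- function(tab, key, other) {
    tab <- tab[order(tab[[key]], -tab$identity, tab$evalue, tab[[other]]), ]
    tab[!duplicated(tab[[key]]), c(key, other)]
  }
  fwd <- best_by(records, "query_id", "subject_id")
  rev <- best_by(records, "subject_id", "query_id")
  merged <- merge(fwd, rev, by = c("query_id", "subject_id"))
  merged[order(merged$query_id), , drop = FALSE]
}

# memoization caches for the per-codon computations
.ng86_cache <- new.env(parent = emptyenv())

memo_syn_sites <- function(codon) {
  key <- paste0("s_", codon)
  val <- .ng86_cache[[key]]
  if (is.null(val)) {
    val <- codon_syn_sites(codon)
    .ng86_cache[[key]] <- val
  }
  val
}

memo_pair_diffs <- function(a, b) {
  key <- paste0("d_", a, b)
  val <- .ng86_cache[[key]]
  if (is.null(val)) {
    val <- codon_pair_diffs(a, b)
    .ng86_cache[[key]] <- val
  }
  val
}
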