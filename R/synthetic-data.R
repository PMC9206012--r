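# Synthetic-data generators. Every generator is a pure function of its
# seed (one global seeded RNG per call) and returns its ground truth
# alongside the data, so each downstream stage can be tested against known
# answers without external downloads.

#' Generate a protein with planted C2H2 zinc fingers
#'
#' Builds `linker - finger - linker - ... - finger - linker` where each
#' finger realises the C2H2 pattern X2-C-X(gap1)-C-X12-H-X(gap2)-H. All
#' non-anchor residues (linkers and finger X positions) are drawn from the
#' 18 standard amino acids excluding C and H, so the planted fingers are
#' the only pattern matches and scanner recall/precision on generator
#' output is exactly 100%.
#'
#' @param n_fingers Number of fingers to plant (>= 0).
#' @param spacer_plan Optional list with one `c(gap1, gap2)` pair per
#'   finger (gap1 in 2-4, gap2 in 2-8); drawn at random when `NULL`.
#' @param linker_len Residues between (and flanking) fingers (default 20).
#' @param seed RNG seed.
#' @param id Sequence id for the record.
#' @return List with `record` (a protein [sequence_record()]) and `truth`
#'   (list with `planted_finger_positions`: data frame `sequence_id`,
#'   `start`, `end`, `gap1_len`, `gap2_len`, 1-based inclusive).
#' @export
generate_protein_with_fingers <- function(n_fingers, spacer_plan = NULL,
                                          linker_len = 20L, seed = 1L,
                                          id = "synthetic_protein") {
  stopifnot(n_fingers >= 0, linker_len >= 0)
  set.seed(seed)
  if (is.null(spacer_plan)) {
    spacer_plan <- replicate(n_fingers,
                             c(sample(2:4, 1), sample(2:8, 1)),
                             simplify = FALSE)
  }
  if (length(spacer_plan) != n_fingers) {
    stop("spacer_plan must have one (gap1, gap2) entry per finger",
         call. = FALSE)
  }
  for (sp in spacer_plan) {
    if (length(sp) != 2L || sp[1] < 2 || sp[1] > 4 || sp[2] < 2 || sp[2] > 8) {
      stop("spacer values out of range: gap1 must be 2-4, gap2 2-8",
           call. = FALSE)
    }
  }
  draw <- function(n) paste(sample(AA_NON_ANCHOR, n, replace = TRUE),
                            collapse = "")
  pieces <- character(0)
  pos <- 0L
  truth <- list()
  add <- function(s) {
    pieces[[length(pieces) + 1L]] <<- s
    pos <<- pos + nchar(s)
  }
  add(draw(linker_len))
  for (i in seq_len(n_fingers)) {
    g1 <- spacer_plan[[i]][1]; g2 <- spacer_plan[[i]][2]
    finger <- paste0(draw(2), "C", draw(g1), "C", draw(12), "H", draw(g2), "H")
    start <- pos + 1L
    add(finger)
    truth[[i]] <- data.frame(sequence_id = id, start = start, end = pos,
                             gap1_len = g1, gap2_len = g2)
    if (i < n_fingers) add(draw(linker_len))
  }
  if (n_fingers > 0) add(draw(linker_len))
  positions <- if (length(truth)) do.call(rbind, truth) else {
    data.frame(sequence_id = character(), start = integer(),
               end = integer(), gap1_len = integer(), gap2_len = integer(),
               stringsAsFactors = FALSE)
  }
  list(record = sequence_record(id, paste(pieces, collapse = ""), "protein"),
       truth = list(planted_finger_positions = positions))
}

#' Generate a codon-aligned paralog pair with controlled divergence
#'
#' Starts from a stop-free random (or supplied) codon sequence and applies
#' exactly `n_syn` synonymous and `n_nonsyn` nonsynonymous single-
#' nucleotide substitutions in random order, each in its own codon (which
#' is why `n_codons >= n_syn + n_nonsyn` is required); no change ever
#' creates a stop codon, so the planted counts are exactly recoverable.
#'
#' @param n_codons Codon count (>= n_syn + n_nonsyn).
#' @param n_syn,n_nonsyn Planted synonymous / nonsynonymous differences.
#' @param seed RNG seed.
#' @param ancestor Optional ancestral nucleotide string (length 3*n_codons,
#'   stop-free); random sense codons when `NULL`.
#' @param max_tries Bounded retries per substitution before a generation
#'   error is raised.
#' @return List with `record_a` (ancestor), `record_b` (derived) and
#'   `truth` (list with `n_syn`, `n_nonsyn`, `true_ks`, `true_ka`: the
#'   Jukes-Cantor-corrected planted per-site fractions, using the
#'   ancestor's NG86 site counts).
#' @export
generate_paralog_pair <- function(n_codons, n_syn, n_nonsyn, seed = 1L,
                                  ancestor = NULL, max_tries = 2000L) {
  stopifnot(n_codons >= 1, n_syn >= 0, n_nonsyn >= 0)
  if (n_codons < n_syn + n_nonsyn) {
    stop("n_codons must be >= n_syn + n_nonsyn", call. = FALSE)
  }
  set.seed(seed)
  sense <- sense_codons()
  if (is.null(ancestor)) {
    codons_a <- sample(sense, n_codons, replace = TRUE)
  } else {
    rec <- sequence_record("anc", ancestor, "nucleotide")
    codons_a <- split_codons(rec)
    if (length(codons_a) != n_codons) {
      stop("ancestor length does not match n_codons", call. = FALSE)
    }
    if (any(codons_a %in% STOP_CODONS)) {
      stop("ancestor contains stop codons", call. = FALSE)
    }
  }
  codons_b <- codons_a
  bases <- c("A", "C", "G", "T")
  kinds <- sample(c(rep("syn", n_syn), rep("nonsyn", n_nonsyn)))
  # each substitution occupies its own codon (hence the n_codons
  # precondition), so the planted counts are exactly what NG86 sees
  available <- seq_len(n_codons)
  for (kind in kinds) {
    placed <- FALSE
    for (try in seq_len(max_tries)) {
      i <- available[sample.int(length(available), 1)]
      pos <- sample(3, 1)
      cur <- codons_b[i]
      b <- sample(setdiff(bases, substr(cur, pos, pos)), 1)
      cand <- cur
      substr(cand, pos, pos) <- b
      aa_cand <- codon_aa(cand)
      if (aa_cand == "*") next
      is_syn <- aa_cand == codon_aa(cur)
      if ((kind == "syn") == is_syn) {
        codons_b[i] <- cand
        available <- setdiff(available, i)
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      stop("could not place a ", kind, " substitution after ", max_tries,
           " tries", call. = FALSE)
    }
  }
  S0 <- sum(vapply(codons_a, memo_syn_sites, numeric(1)))
  N0 <- 3 * n_codons - S0
  list(
    record_a = sequence_record("paralog_a", paste(codons_a, collapse = ""),
                               "nucleotide"),
    record_b = sequence_record("paralog_b", paste(codons_b, collapse = ""),
                               "nucleotide"),
    truth = list(n_syn = n_syn, n_nonsyn = n_nonsyn,
                 syn_sites_ancestor = S0, nonsyn_sites_ancestor = N0,
                 true_ks = if (n_syn == 0) 0 else jukes_cantor(n_syn / S0),
                 true_ka = if (n_nonsyn == 0) 0 else jukes_cantor(n_nonsyn / N0))
  )
}

#' Generate an expression matrix with a planted co-expressed module
#'
#' Family transcripts share a latent factor with loading
#' sqrt(module_correlation) (so their expected pairwise Pearson correlation
#' is `module_correlation`); background transcripts are independent. The
#' Gaussian values are shifted and scaled to a nonnegative TPM-like range
#' (`baseline + scale * z`, clipped at 0); the affine transform preserves
#' correlations.
#'
#' @param n_family,n_background Transcript counts.
#' @param samples Sample labels, or a single count (>= 3).
#' @param module_correlation Target within-family pairwise correlation,
#'   strictly in (0, 1).
#' @param seed RNG seed.
#' @param baseline,scale Affine transform to the expression scale.
#' @return List with `matrix` (rows `fam_*` then `bg_*`) and `truth`
#'   (list with `true_module_members`, `true_module_correlation`).
#' @export
generate_expression_matrix <- function(n_family, n_background, samples = 42L,
                                       module_correlation = 0.9, seed = 1L,
                                       baseline = 50, scale = 10) {
  if (length(samples) == 1L && is.numeric(samples)) {
    samples <- sprintf("S%02d", seq_len(samples))
  }
  n_s <- length(samples)
  if (n_s < 3L) stop("at least 3 samples are required", call. = FALSE)
  if (!(module_correlation > 0 && module_correlation < 1)) {
    stop("module_correlation must be strictly between 0 and 1",
         call. = FALSE)
  }
  stopifnot(n_family >= 0, n_background >= 0)
  set.seed(seed)
  fam_ids <- if (n_family) sprintf("fam_%03d", seq_len(n_family)) else character(0)
  bg_ids <- if (n_background) sprintf("bg_%03d", seq_len(n_background)) else character(0)
  latent <- rnorm(n_s)
  fam <- if (n_family) {
    t(vapply(seq_len(n_family), function(i) {
      sqrt(module_correlation) * latent +
        sqrt(1 - module_correlation) * rnorm(n_s)
    }, numeric(n_s)))
  } else matrix(numeric(0), 0, n_s)
  bg <- if (n_background) {
    matrix(rnorm(n_background * n_s), nrow = n_background)
  } else matrix(numeric(0), 0, n_s)
  m <- rbind(fam, bg)
  m <- pmax(baseline + scale * m, 0)
  dimnames(m) <- list(c(fam_ids, bg_ids), samples)
  list(matrix = m,
       truth = list(true_module_members = fam_ids,
                    true_module_correlation = module_correlation))
}

#' Generate a qPCR CT table with known fold changes
#'
#' Each gene gets a baseline CT; in condition `c` its CT is shifted by
#' `-log2(fold_changes[gene, c])` plus i.i.d. Gaussian replicate noise, so
#' the expected ddCt of a gene relative to the reference and a calibrator
#' condition with fold 1 is `-log2(fold)`.
#'
#' @param genes Gene labels (the reference gene is added if absent).
#' @param conditions Condition labels; the first is conventionally the
#'   calibrator and every gene's fold there should be 1.
#' @param fold_changes Numeric matrix genes x conditions of positive fold
#'   changes. The reference gene's row must be 1 everywhere (it is filled
#'   in if missing).
#' @param reference_gene Reference gene label (default `"CYP"`).
#' @param n_reps Replicates per gene/condition (>= 2, default 3).
#' @param noise_sd Replicate CT noise standard deviation (cycles).
#' @param seed RNG seed.
#' @return List with `table` (data frame `gene`, `condition`, `replicate`,
#'   `ct`) and `truth` (`true_fold_changes` matrix).
#' @export
generate_qpcr_table <- function(genes, conditions, fold_changes,
                                reference_gene = "CYP", n_reps = 3L,
                                noise_sd = 0.1, seed = 1L) {
  stopifnot(n_reps >= 2L, noise_sd >= 0)
  if (!is.matrix(fold_changes)) {
    stop("fold_changes must be a genes x conditions matrix", call. = FALSE)
  }
  if (!reference_gene %in% genes) genes <- c(genes, reference_gene)
  if (!reference_gene %in% rownames(fold_changes)) {
    fold_changes <- rbind(fold_changes,
                          matrix(1, 1, ncol(fold_changes),
                                 dimnames = list(reference_gene, NULL)))
  }
  colnames(fold_changes) <- conditions[seq_len(ncol(fold_changes))]
  if (!setequal(rownames(fold_changes), genes) ||
      ncol(fold_changes) != length(conditions)) {
    stop("fold_changes must cover every gene and condition", call. = FALSE)
  }
  if (any(fold_changes <= 0)) stop("fold changes must be > 0", call. = FALSE)
  if (any(fold_changes[reference_gene, ] != 1)) {
    stop("reference gene must have fold change 1 in every condition",
         call. = FALSE)
  }
  set.seed(seed)
  base_ct <- setNames(runif(length(genes), 18, 26), genes)
  rows <- expand.grid(replicate = seq_len(n_reps), condition = conditions,
                      gene = genes, stringsAsFactors = FALSE)
  rows <- rows[, c("gene", "condition", "replicate")]
  rows$ct <- base_ct[rows$gene] -
    log2(fold_changes[cbind(rows$gene, rows$condition)]) +
    rnorm(nrow(rows), 0, noise_sd)
  rownames(rows) <- NULL
  list(table = rows,
       truth = list(true_fold_changes = fold_changes,
                    reference_gene = reference_gene))
}

#' Generate an alignment table realizing a known presence map
#'
#' Genes present in an assembly receive a record passing the
#' within-species profile (identity >= 99, length >= 200,
#' e-value <= 1e-100); absent genes receive either no record or a decoy
#' record failing at least one threshold. Filtering the output at the
#' within-species profile therefore recovers exactly the presence map.
#'
#' @param gene_ids Gene universe.
#' @param presence Named list: assembly label -> character vector of
#'   present genes (subsets of `gene_ids`).
#' @param seed RNG seed.
#' @return List with `table` (BLAST outfmt-6 style data frame; `query_id`
#'   is the gene, `subject_id` the assembly) and `truth`
#'   (`presence_matrix`: logical genes x assemblies).
#' @export
generate_alignment_table <- function(gene_ids, presence, seed = 1L) {
  stopifnot(is.list(presence), length(names(presence)) == length(presence))
  extra <- setdiff(unlist(presence), gene_ids)
  if (length(extra)) {
    stop("presence refers to unknown genes: ",
         paste(extra, collapse = ", "), call. = FALSE)
  }
  set.seed(seed)
  assemblies <- names(presence)
  truth <- matrix(FALSE, length(gene_ids), length(assemblies),
                  dimnames = list(gene_ids, assemblies))
  rows <- list()
  mk_row <- function(gene, asm, identity, len, evalue) {
    qs <- sample(1:500, 1)
    data.frame(query_id = gene, subject_id = asm,
               identity = identity, align_length = len,
               mismatches = round(len * (100 - identity) / 100),
               gap_opens = 0L,
               query_start = qs, query_end = qs + len - 1L,
               subject_start = 1000L, subject_end = 1000L + len - 1L,
               evalue = evalue, bitscore = round(len * 1.8),
               stringsAsFactors = FALSE)
  }
  for (asm in assemblies) {
    for (gene in gene_ids) {
      if (gene %in% presence[[asm]]) {
        truth[gene, asm] <- TRUE
        rows[[length(rows) + 1L]] <- mk_row(
          gene, asm,
          identity = round(runif(1, 99, 100), 2),
          len = sample(200:1200, 1),
          evalue = 10^(-runif(1, 110, 180)))
      } else if (runif(1) < 0.5) {
        # decoy failing at least one within-species threshold
        mode <- sample(1:3, 1)
        identity <- if (mode == 1) round(runif(1, 80, 98.9), 2) else round(runif(1, 99, 100), 2)
        len <- if (mode == 2) sample(40:199, 1) else sample(200:1200, 1)
        evalue <- if (mode == 3) 10^(-runif(1, 10, 90)) else 10^(-runif(1, 110, 180))
        rows[[length(rows) + 1L]] <- mk_row(gene, asm, identity, len, evalue)
      }
    }
  }
  table <- if (length(rows)) do.call(rbind, rows) else empty_alignment_table()
  list(table = table, truth = list(presence_matrix = truth))
}
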