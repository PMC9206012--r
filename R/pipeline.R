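# Pipeline orchestration: a validated configuration object, a one-call
# synthetic input bundle writer, and run_pipeline() chaining the stages
# identify -> properties -> pancore -> kaks -> motifs -> cisscan -> GO ->
# network -> tendency -> ddct, with per-stage TSV outputs and a
# machine-readable JSON summary.

#' Build and validate a pipeline configuration
#'
#' All numeric parameters are validated against their documented ranges at
#' construction time, before any stage runs. Paths set to `NULL` disable
#' the corresponding stage.
#'
#' @param proteins_fasta Protein FASTA of candidate transcripts.
#' @param cds_fasta Codon-aligned CDS FASTA; consecutive records form
#'   duplicate pairs.
#' @param alignments_tsv BLAST outfmt-6 table of genes vs assemblies.
#' @param family_expression_tsv,background_expression_tsv Expression TSVs
#'   (first column transcript id).
#' @param go_annotations_tsv GO table (`transcript_id`,
#'   `primary_category`, `level2_subcategory`).
#' @param go_background_tsv Background subcategory counts (`subcategory`,
#'   `count`).
#' @param promoters_fasta Promoter FASTA (1500-bp upstream windows).
#' @param ct_table_tsv qPCR CT table (`gene`, `condition`, `replicate`,
#'   `ct`).
#' @param cis_catalog_tsv Cis-element catalog; `NULL` for the bundled one.
#' @param out_dir Output directory.
#' @param profile Alignment threshold profile name.
#' @param lambda_rate Synonymous substitution rate (> 0).
#' @param min_fingers Membership threshold for the finger count.
#' @param network_p_cutoff Cutoff for the reported network (default 0.05).
#' @param cutoffs Tendency-test cutoff series, all in (0, 1).
#' @param n_reps Tendency-test replicates (>= 2).
#' @param tendency_subsample Transcripts per tendency draw; `NULL` for the
#'   full family.
#' @param reference_gene,calibrator_condition ddCt parameters.
#' @param seed Integer seed recorded in every output.
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(proteins_fasta = NULL, cds_fasta = NULL,
                            alignments_tsv = NULL,
                            family_expression_tsv = NULL,
                            background_expression_tsv = NULL,
                            go_annotations_tsv = NULL,
                            go_background_tsv = NULL,
                            promoters_fasta = NULL, ct_table_tsv = NULL,
                            cis_catalog_tsv = NULL, out_dir = tempfile("famscan_"),
                            profile = "within_species",
                            lambda_rate = 6.5e-9, min_fingers = 1L,
                            network_p_cutoff = 0.05,
                            cutoffs = DEFAULT_CUTOFFS, n_reps = 20L,
                            tendency_subsample = NULL,
                            reference_gene = "CYP",
                            calibrator_condition = NULL, seed = 1L) {
  if (!is.numeric(lambda_rate) || lambda_rate <= 0) {
    stop("lambda_rate must be > 0", call. = FALSE)
  }
  if (!all(cutoffs > 0 & cutoffs < 1)) {
    stop("cutoffs must lie in (0, 1)", call. = FALSE)
  }
  if (network_p_cutoff <= 0 || network_p_cutoff >= 1) {
    stop("network_p_cutoff must lie in (0, 1)", call. = FALSE)
  }
  if (n_reps < 2L) stop("n_reps must be >= 2", call. = FALSE)
  if (min_fingers < 1L) stop("min_fingers must be >= 1", call. = FALSE)
  seed <- as.integer(seed)
  if (is.na(seed)) stop("seed must be an integer", call. = FALSE)
  profile <- match.arg(profile, c("within_species", "cross_species"))
  structure(as.list(environment()), class = "pipeline_config")
}

#' Write a full synthetic input bundle with a truth sidecar
#'
#' Generates every input the pipeline consumes (proteins with planted
#' fingers, codon pairs, an alignment table realizing a known presence
#' map, expression matrices with a planted module, GO annotations and
#' background counts, promoters with planted cis-elements, a noise-free CT
#' table) under one seed, writes them to `dir` plus a `truth.json`
#' sidecar of exactly recoverable counts, and returns a ready
#' [pipeline_config()].
#'
#' @param dir Output directory (created if needed).
#' @param seed RNG seed controlling the whole bundle.
#' @param n_members,n_nonmembers Proteins with / without planted fingers.
#' @param n_family,n_background Expression matrix row counts.
#' @param n_samples Expression sample count.
#' @param n_reps Tendency replicates stored in the returned config.
#' @return A `pipeline_config` pointing at the written files.
#' @export
simulate_inputs <- function(dir, seed = 1L, n_members = 18L,
                            n_nonmembers = 6L, n_family = 24L,
                            n_background = 48L, n_samples = 42L,
                            n_reps = 5L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  set.seed(seed)
  sub_seeds <- sample.int(1e6, 64)
  k <- 0L
  next_seed <- function() { k <<- k + 1L; sub_seeds[k] }

  # proteins: members carry 1-6 planted fingers, non-members none
  proteins <- list(); truth_fingers <- 0L
  for (i in seq_len(n_members)) {
    g <- generate_protein_with_fingers(((i - 1L) %% 6L) + 1L,
                                       seed = next_seed(),
                                       id = sprintf("member_%02d", i))
    truth_fingers <- truth_fingers + nrow(g$truth$planted_finger_positions)
    proteins[[length(proteins) + 1L]] <- g$record
  }
  for (i in seq_len(n_nonmembers)) {
    g <- generate_protein_with_fingers(0L, linker_len = 120L,
                                       seed = next_seed(),
                                       id = sprintf("nonmember_%02d", i))
    proteins[[length(proteins) + 1L]] <- g$record
  }
  write_fasta(proteins, p("proteins.fasta"))

  # codon-aligned duplicate pairs
  pair_spec <- data.frame(n_syn = c(2, 5, 8, 12, 4, 9),
                          n_nonsyn = c(1, 2, 4, 3, 6, 2))
  cds <- list()
  for (i in seq_len(nrow(pair_spec))) {
    pr <- generate_paralog_pair(150L, pair_spec$n_syn[i],
                                pair_spec$n_nonsyn[i], seed = next_seed())
    pr$record_a$id <- sprintf("dup%02d_a", i)
    pr$record_b$id <- sprintf("dup%02d_b", i)
    cds <- c(cds, list(pr$record_a, pr$record_b))
  }
  write_fasta(cds, p("cds_pairs.fasta"))

  # presence map over three assemblies
  genes <- sprintf("g%02d", 1:20)
  presence <- list(
    AsmA = genes[c(1:6, 9:12, 15)],
    AsmB = genes[c(1:6, 7:8, 13:14)],
    AsmC = genes[c(1:6, 10, 13, 16:18)]
  )
  aln <- generate_alignment_table(genes, presence, seed = next_seed())
  write_alignment_table(aln$table, p("alignments.tsv"))
  pc_truth <- pan_core(aln$truth$presence_matrix)

  # expression with a planted module
  fam <- generate_expression_matrix(n_family, 0L, n_samples,
                                    module_correlation = 0.9,
                                    seed = next_seed())
  bg <- generate_expression_matrix(0L, n_background, n_samples,
                                   module_correlation = 0.5,
                                   seed = next_seed())
  write_expression_matrix(fam$matrix, p("family_expression.tsv"), seed = seed)
  write_expression_matrix(bg$matrix, p("background_expression.tsv"), seed = seed)

  # GO annotations: simple controlled proportions
  tx <- rownames(fam$matrix)
  cats <- rep(c("MF", "BP", "CC"), length.out = length(tx))
  subs <- rep(c("binding", "catalytic activity", "metabolic process",
                "cell part"), length.out = length(tx))
  go <- data.frame(transcript_id = tx, primary_category = cats,
                   level2_subcategory = subs, stringsAsFactors = FALSE)
  extra <- data.frame(transcript_id = tx[seq_len(min(8, length(tx)))],
                      primary_category = "MF",
                      level2_subcategory = "binding",
                      stringsAsFactors = FALSE)
  go <- rbind(go, extra)
  go <- go[!duplicated(go[, c("transcript_id", "primary_category",
                              "level2_subcategory")]), ]
  write_tsv(go, p("go_annotations.tsv"), seed = seed)
  bg_counts <- data.frame(
    subcategory = c("binding", "catalytic activity", "metabolic process",
                    "cell part"),
    count = c(400L, 1600L, 900L, 700L), stringsAsFactors = FALSE)
  write_tsv(bg_counts, p("go_background.tsv"), seed = seed)

  # promoters with planted ABRE sites
  promoters <- list()
  for (i in 1:6) {
    base <- paste(sample(c("A", "C", "G", "T"), 1500, replace = TRUE),
                  collapse = "")
    for (at in c(200, 700, 1200)) {
      substr(base, at, at + 4L) <- "ACGTG"  # ABRE consensus
    }
    promoters[[i]] <- sequence_record(sprintf("prom_%02d", i), base,
                                      "nucleotide")
  }
  write_fasta(promoters, p("promoters.fasta"))

  # noise-free CT table so planted folds are exactly recoverable
  qgenes <- c("zfp31", "zfp78", "zfp38", "zfp39")
  qconds <- c("0mM", "20mM", "40mM", "80mM")
  folds <- matrix(c(1, 1.4, 2.5, 4,
                    1, 1.2, 2.0, 3.2,
                    1, 1.1, 1.8, 2.6,
                    1, 1.3, 2.2, 3.6),
                  nrow = 4, byrow = TRUE,
                  dimnames = list(qgenes, qconds))
  q <- generate_qpcr_table(qgenes, qconds, folds, reference_gene = "CYP",
                           n_reps = 3L, noise_sd = 0, seed = next_seed())
  write_tsv(q$table, p("ct_table.tsv"), seed = seed)

  truth <- list(
    n_proteins = length(proteins),
    n_members = n_members,
    n_fingers_total = truth_fingers,
    pan = pc_truth$pan, core = pc_truth$core,
    dispensable = pc_truth$dispensable,
    n_cds_pairs = nrow(pair_spec),
    module_size = n_family,
    planted_fold_changes = as.data.frame(as.table(folds),
                                         stringsAsFactors = FALSE)
  )
  jsonlite::write_json(truth, p("truth.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)

  pipeline_config(
    proteins_fasta = p("proteins.fasta"), cds_fasta = p("cds_pairs.fasta"),
    alignments_tsv = p("alignments.tsv"),
    family_expression_tsv = p("family_expression.tsv"),
    background_expression_tsv = p("background_expression.tsv"),
    go_annotations_tsv = p("go_annotations.tsv"),
    go_background_tsv = p("go_background.tsv"),
    promoters_fasta = p("promoters.fasta"),
    ct_table_tsv = p("ct_table.tsv"),
    out_dir = file.path(dir, "out"),
    n_reps = n_reps, tendency_subsample = min(n_family, 20L),
    calibrator_condition = "0mM", seed = seed
  )
}

#' Run the full analysis pipeline
#'
#' Executes every stage whose inputs are configured, writes per-stage TSVs
#' and a `summary.json` into `config$out_dir`, and returns the summary
#' list. Deterministic given `config$seed`; any stage error aborts with
#' the stage name.
#'
#' @param config A [pipeline_config()].
#' @return The summary list, invisibly.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$out_dir, f)
  summ <- list(seed = config$seed)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  if (!is.null(config$proteins_fasta)) {
    stage("identify", {
      proteins <- read_fasta(config$proteins_fasta)
      cls <- lapply(proteins, classify_family_member,
                    min_fingers = config$min_fingers)
      members <- vapply(cls, `[[`, logical(1), "is_member")
      hits <- do.call(rbind, lapply(cls, `[[`, "hits"))
      write_tsv(hits, out("finger_hits.tsv"), seed = config$seed)
      member_recs <- proteins[members]
      props <- lapply(member_recs, function(r) {
        pp <- suppressWarnings(protein_properties(r))
        data.frame(sequence_id = r$id, length = pp$length,
                   molecular_weight = pp$molecular_weight,
                   isoelectric_point = pp$isoelectric_point,
                   gravy = pp$gravy,
                   instability_index = pp$instability_index,
                   aliphatic_index = pp$aliphatic_index,
                   is_hydrophilic = pp$is_hydrophilic,
                   is_unstable = pp$is_unstable, stringsAsFactors = FALSE)
      })
      props <- do.call(rbind, props)
      write_tsv(props, out("protein_properties.tsv"), seed = config$seed)
      motif_hits <- do.call(rbind, lapply(member_recs, scan_named_motifs))
      write_tsv(motif_hits, out("named_motifs.tsv"), seed = config$seed)
      summ$n_proteins <- length(proteins)
      summ$n_members <- sum(members)
      summ$n_fingers_total <- nrow(hits)
      summ$n_named_motif_hits <- nrow(motif_hits)
      summ$n_hydrophilic <- sum(props$is_hydrophilic)
    })
  }

  if (!is.null(config$alignments_tsv)) {
    stage("pancore", {
      aln <- read_alignment_table(config$alignments_tsv)
      filt <- filter_alignments(aln, threshold_profile(config$profile))
      presence <- presence_from_alignments(
        filt, genes = sort(unique(aln$query_id)),
        assemblies = sort(unique(aln$subject_id)))
      pc <- pan_core(presence)
      write_tsv(data.frame(gene = rownames(presence), presence,
                           check.names = FALSE),
                out("presence_matrix.tsv"), seed = config$seed)
      summ$pan <- pc$pan
      summ$core <- pc$core
      summ$dispensable <- pc$dispensable
    })
  }

  if (!is.null(config$cds_fasta)) {
    stage("kaks", {
      cds <- read_fasta(config$cds_fasta)
      if (length(cds) %% 2 != 0) {
        stop("cds_fasta must contain an even number of records (pairs)")
      }
      res <- lapply(seq(1, length(cds), by = 2), function(i) {
        kk <- ng86_kaks(cds[[i]], cds[[i + 1]],
                        lambda_rate = config$lambda_rate)
        data.frame(pair = paste(cds[[i]]$id, cds[[i + 1]]$id, sep = "|"),
                   ka = kk$ka, ks = kk$ks,
                   ratio = ifelse(is.na(kk$ratio), NA, kk$ratio),
                   syn_sites = kk$syn_sites, nonsyn_sites = kk$nonsyn_sites,
                   syn_diffs = kk$syn_diffs, nonsyn_diffs = kk$nonsyn_diffs,
                   divergence_time_mya = kk$divergence_time_mya,
                   selection_mode = kk$selection_mode,
                   stringsAsFactors = FALSE)
      })
      res <- do.call(rbind, res)
      write_tsv(res, out("kaks.tsv"), seed = config$seed)
      summ$n_cds_pairs <- nrow(res)
      summ$selection_modes <- as.list(table(res$selection_mode))
    })
  }

  if (!is.null(config$promoters_fasta)) {
    stage("cisscan", {
      catalog <- cis_element_catalog(config$cis_catalog_tsv)
      promoters <- read_fasta(config$promoters_fasta)
      scans <- lapply(promoters, scan_cis_elements, catalog = catalog)
      hits <- do.call(rbind, lapply(scans, `[[`, "hits"))
      write_tsv(hits, out("cis_elements.tsv"), seed = config$seed)
      tallies <- Reduce(`+`, lapply(scans, `[[`, "class_tallies"))
      summ$n_cis_hits <- nrow(hits)
      summ$cis_class_tallies <- as.list(tallies)
    })
  }

  if (!is.null(config$go_annotations_tsv)) {
    stage("go", {
      go <- read_tsv(config$go_annotations_tsv)
      venn <- go_venn(go)
      summ$go_regions <- as.list(venn$regions)
      summ$go_totals <- as.list(venn$totals)
      if (!is.null(config$go_background_tsv)) {
        bg <- read_tsv(config$go_background_tsv)
        obs_tab <- table(unique(go[, c("transcript_id",
                                       "level2_subcategory")])$level2_subcategory)
        observed <- setNames(as.integer(obs_tab), names(obs_tab))
        background <- setNames(bg$count, bg$subcategory)
        enr <- chi_square_enrichment(observed,
                                     background[names(observed)])
        write_tsv(enr, out("go_enrichment.tsv"), seed = config$seed)
        summ$n_enriched_p05 <- sum(enr$significance != "ns")
      }
    })
  }

  if (!is.null(config$family_expression_tsv)) {
    stage("network", {
      fam <- read_expression_matrix(config$family_expression_tsv)
      recs <- correlation_pvalues(fam)
      net <- build_network(recs, config$network_p_cutoff)
      write_edge_list(net, out("network_edges.tsv"))
      hubs <- hub_genes(recs)
      write_tsv(hubs, out("hub_genes.tsv"), seed = config$seed)
      summ$network_nodes <- net$n_nodes
      summ$network_edges <- net$n_edges
      summ$network_components <-
        connected_components(net)$n_components
      summ$n_hubs <- nrow(hubs)
      if (!is.null(config$background_expression_tsv)) {
        bg <- read_expression_matrix(config$background_expression_tsv)
        sub <- config$tendency_subsample
        if (is.null(sub)) sub <- nrow(fam)
        tt <- tendency_test(fam, bg, subsample_size = sub,
                            cutoffs = config$cutoffs,
                            n_reps = config$n_reps, seed = config$seed)
        write_tsv(tt$edge_tests, out("tendency_edge_tests.tsv"),
                  seed = config$seed)
        write_tsv(tt$node_tests, out("tendency_node_tests.tsv"),
                  seed = config$seed)
        summ$tendency_max_edge_p <- max(tt$edge_tests$p_value)
      }
    })
  }

  if (!is.null(config$ct_table_tsv)) {
    stage("ddct", {
      ct <- read_tsv(config$ct_table_tsv)
      if (is.null(config$calibrator_condition)) {
        stop("calibrator_condition must be set for the ddct stage")
      }
      rel <- ddct(ct, config$reference_gene, config$calibrator_condition)
      write_tsv(rel, out("relative_expression.tsv"), seed = config$seed)
      summ$n_ddct_rows <- nrow(rel)
      up <- rel$gene != config$reference_gene &
        rel$condition != config$calibrator_condition &
        rel$fold_change > 1
      summ$n_upregulated <- sum(up)
    })
  }

  jsonlite::write_json(summ, out("summary.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(summ)
}
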