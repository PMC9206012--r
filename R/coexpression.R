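# Co-expression networks: pairwise Pearson correlation with exact t-based
# p-values, thresholded network construction, connected components, hub
# genes, and the randomized-control network-formation tendency test.

#' Pairwise Pearson correlations with t-distribution p-values
#'
#' For every unordered transcript pair, Pearson r, the t statistic
#' t = r * sqrt((n-2)/(1-r^2)) and its two-sided p-value with n-2 degrees
#' of freedom. Pairs with |r| = 1 get p = 0. Zero-variance rows are dropped
#' with a warning.
#'
#' @param matrix Numeric expression matrix, transcripts in rows (>= 3
#'   sample columns), with unique rownames.
#' @return Data frame with `id_a`, `id_b` (id_a < id_b), `r`, `t_stat`,
#'   `p_value`, `n`.
#' @export
correlation_pvalues <- function(matrix) {
  stopifnot(is.matrix(matrix), is.numeric(matrix))
  if (is.null(rownames(matrix)) || anyDuplicated(rownames(matrix))) {
    stop("matrix must have unique rownames", call. = FALSE)
  }
  n <- ncol(matrix)
  if (n < 3L) stop("at least 3 samples are required", call. = FALSE)
  vars <- apply(matrix, 1, stats::var)
  if (any(vars == 0)) {
    warning("dropping ", sum(vars == 0), " zero-variance row(s): ",
            paste(head(rownames(matrix)[vars == 0], 5), collapse = ", "))
    matrix <- matrix[vars > 0, , drop = FALSE]
  }
  m <- nrow(matrix)
  if (m < 2L) {
    return(data.frame(id_a = character(), id_b = character(), r = numeric(),
                      t_stat = numeric(), p_value = numeric(), n = integer(),
                      stringsAsFactors = FALSE))
  }
  cm <- cor(t(matrix))
  idx <- which(upper.tri(cm), arr.ind = TRUE)
  ids <- rownames(matrix)
  a <- ids[idx[, 1]]; b <- ids[idx[, 2]]
  swap <- a > b
  tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
  r <- cm[idx]
  r <- pmin(pmax(r, -1), 1)
  t_stat <- ifelse(abs(r) == 1, sign(r) * Inf,
                   r * sqrt((n - 2) / (1 - r^2)))
  p <- ifelse(abs(r) == 1, 0, 2 * pt(-abs(t_stat), df = n - 2))
  out <- data.frame(id_a = a, id_b = b, r = r, t_stat = t_stat,
                    p_value = p, n = n, stringsAsFactors = FALSE)
  out[order(out$id_a, out$id_b), , drop = FALSE]
}

#' Build a co-expression network at a p-value cutoff
#'
#' An edge joins two transcripts when their correlation p-value is <= the
#' cutoff. Nodes are the transcripts incident to at least one edge, so the
#' node count varies with the cutoff; isolated transcripts are excluded.
#'
#' @param records Correlation table from [correlation_pvalues()].
#' @param p_cutoff Edge inclusion threshold in (0, 1) (inclusive compare).
#' @return Object of class `coexpression_network`: list with `nodes`,
#'   `edges` (data frame `id_a`, `id_b`, `r`, `p_value`), `degree` (named),
#'   `components` (named labels), `n_nodes`, `n_edges`, `p_cutoff`.
#' @export
build_network <- function(records, p_cutoff) {
  stopifnot(is.data.frame(records),
            all(c("id_a", "id_b", "p_value") %in% names(records)),
            length(p_cutoff) == 1L, p_cutoff > 0, p_cutoff < 1)
  keep <- records$p_value <= p_cutoff
  edges <- records[keep, intersect(c("id_a", "id_b", "r", "p_value"),
                                   names(records)), drop = FALSE]
  nodes <- sort(unique(c(edges$id_a, edges$id_b)))
  degree <- setNames(integer(length(nodes)), nodes)
  if (nrow(edges)) {
    tab <- table(c(edges$id_a, edges$id_b))
    degree[names(tab)] <- as.integer(tab)
  }
  net <- structure(list(nodes = nodes, edges = edges, degree = degree,
                        components = NULL,
                        n_nodes = length(nodes), n_edges = nrow(edges),
                        p_cutoff = p_cutoff),
                   class = "coexpression_network")
  net$components <- connected_components(net)$labels
  net
}

#' @export
print.coexpression_network <- function(x, ...) {
  cat(sprintf("<coexpression_network> %d nodes, %d edges (P <= %g), %d component(s)\n",
              x$n_nodes, x$n_edges, x$p_cutoff,
              length(unique(x$components))))
  invisible(x)
}

#' Connected components of a co-expression network
#'
#' Standard undirected connected components; each component is labelled by
#' its lexicographically smallest member id, making labels deterministic.
#'
#' @param network A `coexpression_network` from [build_network()].
#' @return List with `labels` (named character vector node -> component
#'   label) and `n_components`.
#' @export
connected_components <- function(network) {
  stopifnot(inherits(network, "coexpression_network"))
  if (length(network$nodes) == 0L) {
    return(list(labels = setNames(character(0), character(0)),
                n_components = 0L))
  }
  g <- igraph::graph_from_data_frame(
    network$edges[, c("id_a", "id_b")], directed = FALSE,
    vertices = data.frame(name = network$nodes))
  comp <- igraph::components(g)
  membership <- comp$membership[network$nodes]
  labels <- vapply(split(network$nodes, membership), min, character(1))
  out <- setNames(labels[as.character(membership)], network$nodes)
  list(labels = out, n_components = comp$no)
}

#' Hub-gene criteria
#'
#' Defaults follow the standard hub definition for family co-expression
#' networks: network built at P <= 0.001, connectivity (degree) >= 30, and
#' hubs capped at 5% of the network's nodes.
#'
#' @param network_p_cutoff Network construction cutoff (default 0.001).
#' @param min_connectivity Minimum degree (default 30).
#' @param max_hub_fraction Maximum hub share of network nodes (default
#'   0.05).
#' @return List of criteria.
#' @export
hub_criteria <- function(network_p_cutoff = 0.001, min_connectivity = 30L,
                         max_hub_fraction = 0.05) {
  stopifnot(network_p_cutoff > 0, min_connectivity > 0,
            max_hub_fraction > 0, max_hub_fraction <= 1)
  list(network_p_cutoff = network_p_cutoff,
       min_connectivity = min_connectivity,
       max_hub_fraction = max_hub_fraction)
}

#' Identify hub genes of a co-expression network
#'
#' Builds the network at `criteria$network_p_cutoff`; candidate hubs are
#' nodes with degree >= `min_connectivity`. If candidates exceed
#' `max_hub_fraction` of the network's nodes, the top
#' `floor(fraction * n_nodes)` by degree are kept, ties broken by
#' lexicographic id. The result is sorted by degree descending.
#'
#' @param records Correlation table from [correlation_pvalues()].
#' @param criteria From [hub_criteria()].
#' @return Data frame with `id` and `connectivity`.
#' @export
hub_genes <- function(records, criteria = hub_criteria()) {
  net <- build_network(records, criteria$network_p_cutoff)
  deg <- net$degree
  cand <- deg[deg >= criteria$min_connectivity]
  cand <- cand[order(-cand, names(cand))]
  cap <- floor(criteria$max_hub_fraction * net$n_nodes)
  if (length(cand) > cap) cand <- cand[seq_len(cap)]
  data.frame(id = names(cand), connectivity = as.integer(cand),
             row.names = NULL, stringsAsFactors = FALSE)
}

DEFAULT_CUTOFFS <- c(5e-2, 1e-2, 1e-3, 1e-4, 1e-5, 1e-6, 1e-7, 1e-8)

# Equal-variance two-sample t that tolerates constant groups.
safe_ttest <- function(x, y, var_equal = TRUE) {
  if (sd(x) == 0 && sd(y) == 0) {
    if (mean(x) == mean(y)) return(c(t = 0, p = 1))
    return(c(t = sign(mean(x) - mean(y)) * Inf, p = 0))
  }
  tt <- t.test(x, y, var.equal = var_equal)
  c(t = unname(tt$statistic), p = tt$p.value)
}

#' Network-formation tendency test against randomized controls
#'
#' Per replicate, `subsample_size` transcripts are drawn without
#' replacement from the family matrix and the same number from the
#' background matrix; for each p-value cutoff both subsets are built into
#' networks and their node and edge counts recorded. Per cutoff, family vs
#' control counts are compared with a two-sided two-sample Student's
#' t-test (equal variance by default; set `var_equal = FALSE` for Welch),
#' separately for node and edge counts.
#'
#' @param family_matrix,background_matrix Expression matrices sharing the
#'   same sample columns, transcripts in rows.
#' @param subsample_size Transcripts drawn per replicate from each matrix;
#'   defaults to the full family size.
#' @param cutoffs Descending p-value cutoffs (default 5e-2 .. 1e-8).
#' @param n_reps Replicates per cutoff (default 20).
#' @param seed RNG seed.
#' @param var_equal Equal-variance t-test (default TRUE).
#' @return Object of class `tendency_test`: list with `cutoffs`,
#'   `family_node_counts`, `family_edge_counts`, `control_node_counts`,
#'   `control_edge_counts` (replicate x cutoff matrices), and per-cutoff
#'   `t_stats`/`p_values` data frames for nodes and edges.
#' @export
tendency_test <- function(family_matrix, background_matrix,
                          subsample_size = nrow(family_matrix),
                          cutoffs = DEFAULT_CUTOFFS, n_reps = 20L,
                          seed = 1L, var_equal = TRUE) {
  stopifnot(is.matrix(family_matrix), is.matrix(background_matrix),
            ncol(family_matrix) == ncol(background_matrix))
  if (subsample_size > nrow(family_matrix) ||
      subsample_size > nrow(background_matrix)) {
    stop("subsample_size exceeds available transcripts", call. = FALSE)
  }
  if (subsample_size < 2L) stop("subsample_size must be >= 2", call. = FALSE)
  cutoffs <- sort(cutoffs, decreasing = TRUE)
  set.seed(seed)
  count_mat <- function() matrix(0L, nrow = n_reps, ncol = length(cutoffs),
                                 dimnames = list(NULL, format(cutoffs)))
  fam_nodes <- count_mat(); fam_edges <- count_mat()
  ctl_nodes <- count_mat(); ctl_edges <- count_mat()
  counts_at_cutoffs <- function(m) {
    recs <- suppressWarnings(correlation_pvalues(m))
    vapply(cutoffs, function(ct) {
      keep <- recs$p_value <= ct
      c(nodes = length(unique(c(recs$id_a[keep], recs$id_b[keep]))),
        edges = sum(keep))
    }, c(nodes = 0, edges = 0))
  }
  for (rep in seq_len(n_reps)) {
    fi <- sample(nrow(family_matrix), subsample_size)
    bi <- sample(nrow(background_matrix), subsample_size)
    fc <- counts_at_cutoffs(family_matrix[fi, , drop = FALSE])
    cc <- counts_at_cutoffs(background_matrix[bi, , drop = FALSE])
    fam_nodes[rep, ] <- fc["nodes", ]; fam_edges[rep, ] <- fc["edges", ]
    ctl_nodes[rep, ] <- cc["nodes", ]; ctl_edges[rep, ] <- cc["edges", ]
  }
  test_per_cutoff <- function(fam, ctl) {
    res <- vapply(seq_along(cutoffs), function(j) {
      safe_ttest(fam[, j], ctl[, j], var_equal)
    }, c(t = 0, p = 0))
    data.frame(cutoff = cutoffs, t_stat = res["t", ], p_value = res["p", ],
               row.names = NULL)
  }
  structure(list(
    cutoffs = cutoffs,
    family_node_counts = fam_nodes, family_edge_counts = fam_edges,
    control_node_counts = ctl_nodes, control_edge_counts = ctl_edges,
    node_tests = test_per_cutoff(fam_nodes, ctl_nodes),
    edge_tests = test_per_cutoff(fam_edges, ctl_edges),
    n_reps = n_reps, subsample_size = subsample_size, seed = seed
  ), class = "tendency_test")
}

#' @export
print.tendency_test <- function(x, ...) {
  cat(sprintf("<tendency_test> %d replicates x %d cutoffs, subsample %d\n",
              x$n_reps, length(x$cutoffs), x$subsample_size))
  cat("edge-count tests:\n")
  print(x$edge_tests, digits = 3)
  invisible(x)
}

#' Write a network edge list as TSV
#' @param network A `coexpression_network`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(network, path) {
  write_tsv(network$edges, path,
            extra = paste0("# p_cutoff: ", network$p_cutoff))
}
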