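test_that("correlation p-values follow the exact t-distribution null", {
  set.seed(51)
  m <- matrix(rnorm(4 * 10), 4, dimnames = list(paste0("t", 1:4), NULL))
  m <- rbind(m, dup = m[1, ])
  rownames(m) <- c(paste0("t", 1:4), "dup")
  recs <- correlation_pvalues(m)
  dup_row <- recs[(recs$id_a == "dup" & recs$id_b == "t1") |
                    (recs$id_a == "t1" & recs$id_b == "dup"), ]
  expect_equal(dup_row$r, 1)
  expect_equal(dup_row$p_value, 0)

  anti <- matrix(c(1:10, -(1:10), rnorm(10)), 3, byrow = TRUE,
                 dimnames = list(c("x", "negx", "z"), NULL))
  recs2 <- correlation_pvalues(anti)
  expect_equal(recs2$r[recs2$id_a == "negx" & recs2$id_b == "x"], -1)

  # agreement with cor.test on a generic pair
  pair <- recs[recs$id_a == "t1" & recs$id_b == "t2", ]
  ct <- cor.test(m["t1", ], m["t2", ])
  expect_equal(pair$p_value, ct$p.value, tolerance = 1e-12)
  expect_equal(pair$r, unname(ct$estimate), tolerance = 1e-12)

  expect_error(correlation_pvalues(matrix(1:4, 2,
                                          dimnames = list(c("a", "b"), NULL))),
               "3 samples")
  expect_warning(
    correlation_pvalues(rbind(m, flat = rep(1, 10))), "zero-variance")
})

test_that("networks are nested across cutoffs with consistent degrees", {
  set.seed(52)
  g <- generate_expression_matrix(10, 20, 30, 0.8, seed = 52)
  recs <- correlation_pvalues(g$matrix)
  cutoffs <- c(5e-2, 1e-3, 1e-5, 1e-8)
  nets <- lapply(cutoffs, function(ct) build_network(recs, ct))
  for (i in seq_along(nets)) {
    net <- nets[[i]]
    expect_equal(sum(net$degree), 2 * net$n_edges)
    if (i > 1) {
      prev <- nets[[i - 1]]
      key <- function(n) paste(n$edges$id_a, n$edges$id_b)
      expect_true(all(key(net) %in% key(prev)))
      expect_lte(net$n_nodes, prev$n_nodes)
    }
  }
})

test_that("a planted module survives stringent cutoffs without background", {
  g <- generate_expression_matrix(8, 30, 42, 0.9, seed = 53)
  recs <- correlation_pvalues(g$matrix)
  net <- build_network(recs, 1e-8)
  fam <- g$truth$true_module_members
  fam_edges <- net$edges$id_a %in% fam & net$edges$id_b %in% fam
  expect_equal(sum(fam_edges), choose(length(fam), 2))
  expect_equal(sum(!fam_edges), 0)
})

test_that("connected components are labelled by smallest member", {
  tri <- function(ids) data.frame(id_a = ids[c(1, 1, 2)],
                                  id_b = ids[c(2, 3, 3)],
                                  r = 1, p_value = 0,
                                  stringsAsFactors = FALSE)
  recs <- rbind(tri(c("a1", "a2", "a3")), tri(c("b1", "b2", "b3")))
  net <- build_network(recs, 0.05)
  comp <- connected_components(net)
  expect_equal(comp$n_components, 2)
  expect_equal(unname(comp$labels[c("a2", "b3")]), c("a1", "b1"))

  empty <- build_network(recs[0, ], 0.05)
  expect_equal(connected_components(empty)$n_components, 0)
})

test_that("independent planted modules split into that many components", {
  mats <- lapply(1:3, function(k) {
    g <- generate_expression_matrix(5, 0, 42, 0.95, seed = 60 + k)
    m <- g$matrix
    rownames(m) <- sprintf("mod%d_%s", k, rownames(m))
    m
  })
  recs <- correlation_pvalues(do.call(rbind, mats))
  net <- build_network(recs, 1e-10)
  expect_equal(connected_components(net)$n_components, 3)
})

test_that("hub detection applies degree threshold, cap and tie-breaks", {
  # star: center connected to 40 leaves
  star <- data.frame(id_a = "center", id_b = sprintf("leaf%02d", 1:40),
                     r = 0.99, p_value = 1e-6, stringsAsFactors = FALSE)
  hubs <- hub_genes(star, hub_criteria())
  expect_equal(hubs$id, "center")
  expect_equal(hubs$connectivity, 40)

  # all degrees below the threshold -> empty
  weak <- data.frame(id_a = c("a", "b"), id_b = c("b", "c"),
                     r = 0.9, p_value = 1e-6, stringsAsFactors = FALSE)
  expect_equal(nrow(hub_genes(weak)), 0)

  # 10 candidates of degree 35 in a 100-node network, 5% cap -> 5 hubs
  hubs_ids <- sprintf("hub%02d", 1:10)
  others <- sprintf("n%03d", 1:90)
  # connect each hub to 35 distinct non-hub nodes
  edges <- do.call(rbind, lapply(seq_along(hubs_ids), function(i) {
    partners <- others[(((i - 1) * 35):((i - 1) * 35 + 34) %% 90) + 1]
    data.frame(id_a = hubs_ids[i], id_b = unique(partners), r = 0.9,
               p_value = 1e-6, stringsAsFactors = FALSE)
  }))
  net <- build_network(edges, 0.001)
  stopifnot(net$n_nodes == 100)
  deg <- net$degree[hubs_ids]
  stopifnot(all(deg >= 30))
  capped <- hub_genes(edges, hub_criteria())
  expect_equal(nrow(capped), 5)
  expect_true(all(capped$id %in% hubs_ids))
  # order invariance of the input records
  shuffled <- edges[rev(seq_len(nrow(edges))), ]
  expect_equal(hub_genes(shuffled, hub_criteria()), capped)
})

test_that("tendency test flags a planted module at every cutoff", {
  fam <- generate_expression_matrix(60, 0, 42, 0.9, seed = 71)$matrix
  bg <- generate_expression_matrix(0, 120, 42, 0.5, seed = 72)$matrix
  tt <- tendency_test(fam, bg, subsample_size = 40, n_reps = 10, seed = 73)
  expect_true(all(tt$edge_tests$p_value <= 0.01))
  expect_true(all(tt$family_edge_counts >= tt$control_edge_counts))
  # determinism
  tt2 <- tendency_test(fam, bg, subsample_size = 40, n_reps = 10, seed = 73)
  expect_identical(tt, tt2)
  expect_error(tendency_test(fam, bg, subsample_size = 500), "exceeds")
})

test_that("replicate count tables have the declared shape", {
  fam <- generate_expression_matrix(12, 0, 20, 0.8, seed = 81)$matrix
  bg <- generate_expression_matrix(0, 30, 20, 0.5, seed = 82)$matrix
  tt <- tendency_test(fam, bg, subsample_size = 8,
                      cutoffs = c(5e-2, 1e-3), n_reps = 4, seed = 83)
  expect_equal(dim(tt$family_edge_counts), c(4, 2))
  expect_equal(tt$cutoffs, c(5e-2, 1e-3))
})
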