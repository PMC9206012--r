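mk_record <- function(identity, len, evalue, q = "q", s = "s") {
  data.frame(query_id = q, subject_id = s, identity = identity,
             align_length = len, mismatches = 0L, gap_opens = 0L,
             query_start = 1L, query_end = len, subject_start = 1L,
             subject_end = len, evalue = evalue, bitscore = len * 1.8,
             stringsAsFactors = FALSE)
}

test_that("alignment filter applies inclusive boundaries", {
  prof <- threshold_profile("within_species")
  expect_equal(nrow(filter_alignments(mk_record(99.0, 200L, 1.0e-100),
                                      prof)), 1)
  expect_equal(nrow(filter_alignments(mk_record(98.99, 500L, 0), prof)), 0)
  expect_equal(nrow(filter_alignments(mk_record(99.5, 199L, 0), prof)), 0)
  expect_equal(nrow(filter_alignments(mk_record(99.5, 300L, 1.1e-100),
                                      prof)), 0)
  cross <- threshold_profile("cross_species")
  expect_equal(cross$min_identity, 75)
  expect_equal(cross$min_cover_length, 80)
  expect_equal(cross$max_evalue, 1.0e-10)
})

test_that("filter is idempotent, a subset, and monotone in thresholds", {
  set.seed(31)
  tab <- do.call(rbind, lapply(1:60, function(i) {
    mk_record(runif(1, 70, 100), sample(50:400, 1), 10^(-runif(1, 5, 150)),
              q = sprintf("q%02d", i))
  }))
  prof <- threshold_profile("within_species")
  once <- filter_alignments(tab, prof)
  expect_identical(filter_alignments(once, prof), once)
  expect_true(all(once$query_id %in% tab$query_id))
  loose <- list(min_identity = 90, min_cover_length = 100,
                max_evalue = 1e-50, name = "loose")
  expect_true(all(once$query_id %in%
                    filter_alignments(tab, loose)$query_id))
})

test_that("pan/core follows set semantics with Venn regions summing to pan", {
  m <- matrix(FALSE, 3, 3, dimnames = list(c("g1", "g2", "g3"),
                                           c("A", "B", "C")))
  m["g1", "A"] <- TRUE; m["g2", c("A", "B", "C")] <- TRUE
  m["g3", "B"] <- TRUE
  pc <- pan_core(m)
  expect_equal(pc$pan, 3)
  expect_equal(pc$core, 1)
  expect_equal(pc$dispensable, 2)
  expect_equal(sum(pc$per_region_counts), pc$pan)

  same <- matrix(TRUE, 4, 3, dimnames = list(paste0("g", 1:4), c("A", "B", "C")))
  pc2 <- pan_core(same)
  expect_equal(pc2$pan, pc2$core)

  single <- matrix(c(TRUE, FALSE, TRUE), 3, 1,
                   dimnames = list(paste0("g", 1:3), "A"))
  pc3 <- pan_core(single)
  expect_equal(pc3$pan, 2)
  expect_equal(pc3$core, 2)

  expect_error(pan_core(matrix(logical(0), 0, 0)), "non-empty")
  # pan >= every per-assembly count >= core
  expect_true(all(pc$per_assembly <= pc$pan & pc$per_assembly >= pc$core))
})

test_that("NG86 reproduces hand-worked values on glycine codons", {
  same <- ng86_kaks(sequence_record("a", "GGGGGG", "nucleotide"),
                    sequence_record("b", "GGGGGG", "nucleotide"))
  expect_equal(same$ka, 0)
  expect_equal(same$ks, 0)
  expect_true(is.na(same$ratio))
  expect_equal(same$selection_mode, "undefined")

  gly <- ng86_kaks(sequence_record("a", "GGGGGG", "nucleotide"),
                   sequence_record("b", "GGAGGG", "nucleotide"))
  expect_equal(gly$syn_sites, 2)
  expect_equal(gly$nonsyn_sites, 4)
  expect_equal(gly$syn_diffs, 1)
  expect_equal(gly$nonsyn_diffs, 0)
  expect_equal(gly$ks, -0.75 * log(1 / 3), tolerance = 1e-12)
  expect_equal(gly$ka, 0)

  # fourfold-degenerate codons: one synonymous site per codon exactly
  ffd <- paste(rep(c("GGT", "CCT", "GCT", "ACT"), 5), collapse = "")
  res <- ng86_kaks(sequence_record("a", ffd, "nucleotide"),
                   sequence_record("b", ffd, "nucleotide"))
  expect_equal(res$syn_sites, 20)
  expect_equal(res$syn_sites + res$nonsyn_sites, 3 * 20)
})

test_that("NG86 input validation catches the documented error cases", {
  expect_error(ng86_kaks(sequence_record("a", "GGGGGG", "nucleotide"),
                         sequence_record("b", "GGG", "nucleotide")),
               "length")
  expect_error(ng86_kaks(sequence_record("a", "GGGG", "nucleotide"),
                         sequence_record("b", "GGGG", "nucleotide")),
               "multiple of 3")
  expect_error(ng86_kaks(sequence_record("a", "TAAGGG", "nucleotide"),
                         sequence_record("b", "GGGGGG", "nucleotide")),
               "stop")
  # shared terminal stop codons are tolerated and dropped
  ok <- ng86_kaks(sequence_record("a", "GGGTAA", "nucleotide"),
                  sequence_record("b", "GGGTAA", "nucleotide"))
  expect_equal(ok$syn_sites + ok$nonsyn_sites, 3)
})

test_that("pathway-averaged diff counts match the brute-force oracle", {
  set.seed(41)
  for (i in 1:300) {
    a <- random_sense_codons(1)
    b <- random_sense_codons(1)
    got <- famscan:::memo_pair_diffs(a, b)
    want <- oracle_pathway_diffs(a, b)
    expect_equal(unname(got), unname(want), tolerance = 1e-12,
                 info = paste(a, b))
  }
})

test_that("planted substitution counts are recovered on generated pairs", {
  pr <- generate_paralog_pair(300, 5, 2, seed = 5)
  kk <- ng86_kaks(pr$record_a, pr$record_b)
  expect_equal(kk$syn_diffs, 5, tolerance = 0.2)
  expect_equal(kk$nonsyn_diffs, 2, tolerance = 0.2)
})

test_that("Jukes-Cantor correction saturates at p >= 3/4", {
  expect_error(famscan:::jukes_cantor(0.75), "saturated")
  expect_equal(famscan:::jukes_cantor(0), 0)
})

test_that("divergence time is the closed form Ks / 2 lambda", {
  expect_equal(divergence_time(0), 0)
  expect_equal(divergence_time(0.234), 18.0)
  expect_equal(divergence_time(0.5291), 40.7, tolerance = 0.01)
  expect_error(divergence_time(-0.1), ">= 0")
  # linear in ks, inverse in lambda
  expect_equal(divergence_time(0.4), 2 * divergence_time(0.2))
  expect_equal(divergence_time(0.2, 1.3e-8), divergence_time(0.2) / 2)
})

test_that("selection classification uses the inclusive 1.0 +/- 0.1 band", {
  expect_equal(classify_selection(0.3), "purifying")
  expect_equal(classify_selection(0.9), "neutral")
  expect_equal(classify_selection(1.05), "neutral")
  expect_equal(classify_selection(1.1), "neutral")
  expect_equal(classify_selection(1.1000001), "positive")
  expect_equal(classify_selection(0.8999999), "purifying")
  expect_equal(classify_selection(NA_real_), "undefined")
})

test_that("best reciprocal pairing honours the tie-break order", {
  tab <- rbind(mk_record(99, 300, 1e-120, q = "q1", s = "s1"),
               mk_record(95, 300, 1e-110, q = "q1", s = "s2"),
               mk_record(99, 300, 1e-120, q = "q2", s = "s1"),
               mk_record(99.5, 300, 1e-120, q = "q2", s = "s2"))
  brp <- best_reciprocal_pairs(tab)
  expect_equal(brp$query_id, c("q1", "q2"))
  expect_equal(brp$subject_id, c("s1", "s2"))
})
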