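test_that("scan_c2h2 matches the pattern by hand-checkable rules", {
  hit <- scan_c2h2(sequence_record("t", "MKCAACLLLLLLLLLLLLHAAH", "protein"))
  expect_equal(nrow(hit), 1)
  expect_equal(hit$start, 1)
  expect_equal(hit$end, 22)
  expect_equal(hit$gap1_len, 2)
  expect_equal(hit$gap2_len, 2)

  expect_equal(nrow(scan_c2h2(sequence_record("e", "AAAA", "protein"))), 0)
  expect_error(scan_c2h2(sequence_record("n", "ACGT", "nucleotide")),
               "protein")
})

test_that("every reported hit re-validates residue by residue", {
  set.seed(11)
  for (s in sample.int(1e5, 25)) {
    g <- generate_protein_with_fingers(sample(0:6, 1), seed = s)
    hits <- scan_c2h2(g$record)
    tr <- g$truth$planted_finger_positions
    expect_equal(nrow(hits), nrow(tr))
    if (nrow(hits)) {
      expect_equal(hits$start, tr$start)
      expect_equal(hits$end, tr$end)
      for (i in seq_len(nrow(hits))) {
        expect_true(revalidate_c2h2_hit(g$record$sequence, hits$start[i],
                                        hits$end[i], hits$gap1_len[i],
                                        hits$gap2_len[i]))
      }
    }
  }
})

test_that("hits are non-overlapping and resume after the second histidine", {
  # two back-to-back minimal fingers with no linker between them
  g <- generate_protein_with_fingers(2, spacer_plan = list(c(2, 2), c(2, 2)),
                                     linker_len = 0, seed = 1)
  hits <- scan_c2h2(g$record)
  expect_equal(nrow(hits), 2)
  expect_equal(hits$start[2], hits$end[1] + 1)
})

test_that("classify_family_member thresholds on finger count", {
  one <- generate_protein_with_fingers(1, seed = 2)
  res <- classify_family_member(one$record)
  expect_true(res$is_member)
  expect_equal(res$n_fingers, 1)
  expect_true(res$in_expected_range)

  none <- generate_protein_with_fingers(0, linker_len = 80, seed = 3)
  res0 <- classify_family_member(none$record)
  expect_false(res0$is_member)
  expect_equal(nrow(res0$hits), 0)

  six <- generate_protein_with_fingers(6, seed = 4)
  res6 <- classify_family_member(six$record)
  expect_true(res6$is_member)
  expect_equal(res6$n_fingers, 6)
  expect_true(res6$in_expected_range)
})

test_that("find_orfs locates ATG..stop spans on both strands", {
  fwd <- find_orfs(sequence_record("x", "ATGGGGTAA", "nucleotide"),
                   min_protein_len = 1)
  expect_equal(nrow(fwd), 1)
  expect_equal(fwd$frame, 1)
  expect_equal(fwd$protein, "MG")
  expect_equal(c(fwd$start, fwd$end), c(1, 9))
  expect_false(fwd$partial)

  expect_equal(nrow(find_orfs(sequence_record("c", "CCCCCC", "nucleotide"),
                              min_protein_len = 1)), 0)

  # same ORF embedded on the minus strand
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString("ATGGGGTAA")))
  rev <- find_orfs(sequence_record("y", paste0("CCC", rc, "CCC"),
                                   "nucleotide"), min_protein_len = 2)
  expect_equal(nrow(rev), 1)
  expect_lt(rev$frame, 0)
  expect_equal(rev$protein, "MG")

  # longest ORF first
  two <- find_orfs(sequence_record("z", "ATGAAACCCGGGTAAATGAAATAA",
                                   "nucleotide"), min_protein_len = 1)
  expect_equal(two$protein[1], "MKPG")
  expect_true(all(diff(nchar(two$protein)) <= 0))
})

test_that("N codons are skipped as starts and translated as X", {
  withN <- find_orfs(sequence_record("n", "ATGAANGGGTAA", "nucleotide"),
                     min_protein_len = 1)
  expect_equal(withN$protein[1], "MXG")
  # ATN is not a start codon
  expect_equal(nrow(find_orfs(sequence_record("n2", "ATNGGGTAA",
                                              "nucleotide"),
                              min_protein_len = 1)), 0)
})

test_that("protein properties reproduce closed-form reference values", {
  gg <- protein_properties(sequence_record("gg", "GG", "protein"))
  expect_equal(gg$molecular_weight, 132.12, tolerance = 1e-3)

  ii <- protein_properties(sequence_record("ii", "II", "protein"))
  expect_equal(ii$gravy, 4.5)
  expect_false(ii$is_hydrophilic)

  a4 <- protein_properties(sequence_record("a4", "AAAA", "protein"))
  expect_equal(a4$aliphatic_index, 100)
  expect_equal(a4$instability_index, 7.5)  # (10/4) * 3 * DIWV(A,A)
  expect_false(a4$is_unstable)

  expect_error(protein_properties(sequence_record("e", "", "protein")),
               "empty")
})

test_that("pI is a root of the net-charge curve and flags are consistent", {
  set.seed(21)
  for (i in 1:10) {
    aa <- paste(sample(famscan:::AA_STANDARD, 60, replace = TRUE),
                collapse = "")
    p <- protein_properties(sequence_record(paste0("p", i), aa, "protein"))
    expect_gt(p$isoelectric_point, 0)
    expect_lt(p$isoelectric_point, 14)
    chars <- strsplit(aa, "")[[1]]
    counts <- as.list(table(factor(chars, levels = famscan:::AA_STANDARD)))
    q <- famscan:::peptide_charge(p$isoelectric_point, counts,
                                  chars[1], chars[length(chars)])
    expect_lt(abs(q), 1e-3)
    expect_identical(p$is_hydrophilic, p$gravy < 0)
    expect_identical(p$is_unstable, p$instability_index > 40)
  }
})

test_that("X residues disable pI/instability with a warning", {
  expect_warning(p <- protein_properties(sequence_record("x", "AAXAA",
                                                         "protein")),
                 "X")
  expect_true(is.na(p$isoelectric_point))
  expect_true(is.na(p$instability_index))
  expect_false(is.na(p$molecular_weight))
})
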