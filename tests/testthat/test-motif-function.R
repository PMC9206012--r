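test_that("named motifs and their variants are found at the right offsets", {
  hits <- scan_named_motifs(sequence_record("m", "AAQALGGHAA", "protein"))
  expect_equal(nrow(hits), 1)
  expect_equal(hits$motif, "QALGGH")
  expect_equal(hits$start, 3)

  variant <- scan_named_motifs(sequence_record("v", "KALGGH", "protein"))
  expect_equal(variant$match, "KALGGH")
  expect_equal(variant$start, 1)

  ear <- scan_named_motifs(sequence_record("e", "FDLNLAP", "protein"))
  expect_equal(ear$motif, "EAR")
  expect_equal(ear$start, 1)

  lbox <- scan_named_motifs(sequence_record("l", "GGEAEKKAKCLMMLGG",
                                            "protein"))
  expect_equal(lbox$motif, "L-box")
  expect_equal(lbox$start, 3)

  none <- scan_named_motifs(sequence_record("n", "GGGGGG", "protein"))
  expect_equal(nrow(none), 0)
})

test_that("within-motif matches are greedy and non-overlapping", {
  tandem <- scan_named_motifs(sequence_record("t", "QALGGHQALGGH",
                                              "protein"))
  expect_equal(tandem$start, c(1, 7))
  # invalid motif patterns are rejected
  expect_error(motif_definition("bad", "QA L"), "invalid")
})

test_that("cis-element scanning is IUPAC-aware and strand-deduplicated", {
  catalog <- cis_element_catalog()
  # poly-A background cannot match any catalog consensus; plant 3 ABRE
  base <- strrep("A", 600)
  for (at in c(100, 300, 500)) substr(base, at, at + 4) <- "ACGTG"
  res <- scan_cis_elements(sequence_record("p", base, "nucleotide"),
                           catalog, expected_window = 1500)
  expect_equal(nrow(res$hits), 3)
  expect_true(all(res$hits$element == "ABRE"))
  expect_equal(unname(res$class_tallies["hormone"]), 3)
  expect_equal(sum(res$class_tallies), nrow(res$hits))

  # palindromic G-box (CACGTG) is counted once per genomic span
  pal <- paste0(strrep("A", 20), "CACGTG", strrep("A", 20))
  res2 <- scan_cis_elements(sequence_record("g", pal, "nucleotide"), catalog)
  gbox <- res2$hits[res2$hits$element == "G-box", ]
  expect_equal(nrow(gbox), 1)

  # empty catalog -> no hits
  res3 <- scan_cis_elements(sequence_record("p2", base, "nucleotide"),
                            catalog[0, ])
  expect_equal(nrow(res3$hits), 0)

  expect_warning(
    scan_cis_elements(sequence_record("long", strrep("A", 40), "nucleotide"),
                      catalog, expected_window = 30),
    "window")
})

test_that("reverse-strand hits are reported in forward coordinates", {
  catalog <- cis_element_catalog()
  # plant the reverse complement of ABRE (CACGT) in a poly-A background
  base <- paste0(strrep("A", 50), "CACGT", strrep("A", 50))
  res <- scan_cis_elements(sequence_record("r", base, "nucleotide"), catalog)
  abre <- res$hits[res$hits$element == "ABRE", ]
  expect_equal(nrow(abre), 1)
  expect_equal(abre$strand, "-")
  expect_equal(c(abre$start, abre$end), c(51, 55))
})

# Builds an annotation table realizing given exclusive Venn region counts.
annotations_from_regions <- function(regions) {
  rows <- list(); n <- 0L
  for (reg in names(regions)) {
    cats <- strsplit(reg, "&", fixed = TRUE)[[1]]
    for (i in seq_len(regions[[reg]])) {
      n <- n + 1L
      rows[[n]] <- data.frame(transcript_id = sprintf("t%04d", n),
                              primary_category = cats,
                              level2_subcategory = "unused",
                              stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

test_that("go_venn partitions transcripts and reconstructs category totals", {
  regions <- c("MF" = 27, "BP" = 3, "CC" = 6, "MF&BP" = 13, "MF&CC" = 17,
               "BP&CC" = 2, "MF&BP&CC" = 31)
  venn <- go_venn(annotations_from_regions(regions))
  expect_equal(venn$regions[names(regions)], regions,
               ignore_attr = FALSE)
  expect_equal(unname(venn$totals["MF"]), 88)
  expect_equal(unname(venn$totals["BP"]), 49)
  expect_equal(unname(venn$totals["CC"]), 56)
  expect_equal(venn$n_annotated, sum(regions))

  single <- go_venn(data.frame(transcript_id = "t1", primary_category = "MF",
                               stringsAsFactors = FALSE))
  expect_equal(unname(single$regions["MF"]), 1)
  expect_equal(sum(single$regions), 1)

  expect_error(go_venn(data.frame(transcript_id = "t1",
                                  primary_category = "XX",
                                  stringsAsFactors = FALSE)),
               "unknown GO")
})

test_that("chi-square enrichment matches the closed form and chisq.test", {
  # equal proportions: no signal
  flat <- chi_square_enrichment(c(a = 10, b = 30), c(a = 100, b = 300))
  expect_equal(flat$chi_square, c(0, 0), tolerance = 1e-12)
  expect_equal(flat$p_value, c(1, 1))
  expect_true(all(flat$direction == "none"))

  # family 50/100 vs background 10/100: 2x2 Pearson chi-square
  enr <- chi_square_enrichment(c(hit = 50, other = 50),
                               c(hit = 10, other = 90))
  row <- enr[enr$subcategory == "hit", ]
  n <- 200
  closed <- n * (50 * 90 - 50 * 10)^2 / (100 * 100 * 60 * 140)
  expect_equal(row$chi_square, closed, tolerance = 1e-12)
  ref <- suppressWarnings(
    chisq.test(matrix(c(50, 50, 10, 90), 2, byrow = TRUE), correct = FALSE))
  expect_equal(row$chi_square, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(row$p_value, ref$p.value, tolerance = 1e-12)
  expect_equal(row$direction, "up")
  expect_lt(row$p_value, 0.01)
  expect_equal(row$significance, "p01")

  # zero observed in a background-present subcategory
  zero <- chi_square_enrichment(c(a = 0, b = 20), c(a = 50, b = 50))
  expect_equal(zero$direction[zero$subcategory == "a"], "down")
})

test_that("enrichment direction flips and p is invariant under swap", {
  obs <- c(x = 30, y = 70)
  bg <- c(x = 10, y = 90)
  fwd <- chi_square_enrichment(obs, bg)
  rev <- chi_square_enrichment(bg, obs)
  expect_equal(fwd$p_value, rev$p_value, tolerance = 1e-12)
  flip <- c(up = "down", down = "up", none = "none")
  expect_equal(unname(flip[fwd$direction]), rev$direction)
})
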