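test_that("registry geometry: recognition, overhang length and polarity", {
  reg <- enzyme_registry()
  expect_true(all(c("BtsI", "BsrDI", "SapI", "BspQI", "BsaI", "BbsI",
                    "BsmBI") %in% names(reg)))
  sap <- get_enzyme("SapI")
  expect_identical(sap$overhang_length, 3L)
  expect_identical(sap$polarity, "five_prime")
  bts <- get_enzyme("BtsI")
  expect_identical(bts$overhang_length, 2L)
  expect_identical(bts$polarity, "three_prime")
  bsm <- get_enzyme("BsmBI")
  expect_identical(bsm$overhang_length, 4L)
  expect_identical(bsm$polarity, "five_prime")
  # BspQI is an isoschizomer of SapI with identical geometry
  bsp <- get_enzyme("BspQI")
  expect_identical(bsp$recognition, sap$recognition)
  expect_identical(bsp$cut_top, sap$cut_top)
  expect_error(get_enzyme("EcoRI"), "not in the registry")
})

test_that("site finding reports both strands with correct scissile coordinates", {
  m <- dna_molecule("x", "AAAGCAGTGCATTTTTTTT")
  s <- find_sites(m, "BtsI")
  expect_identical(nrow(s), 1L)
  expect_identical(s$strand, "+")
  expect_identical(s$rec_start, 3L)
  expect_identical(s$rec_end, 9L)
  expect_identical(s$scissile_top, 11L)
  expect_identical(s$scissile_bottom, 9L)

  m2 <- dna_molecule("y", "AAGCTCTTCTATGCCCGGG")
  s2 <- find_sites(m2, "SapI")
  expect_identical(s2$scissile_top, 10L)
  expect_identical(s2$scissile_bottom, 13L)

  expect_identical(nrow(find_sites(dna_molecule("z", "AAAAAA"), "BtsI")), 0L)

  # minus-strand site mirrors to a plus-strand site on the reverse complement
  m3 <- dna_molecule("w", paste0("TTTT", revcomp("GCAGTGAAAA"), "CCCC"))
  s3 <- find_sites(m3, "BtsI")
  expect_identical(s3$strand, "-")
  n <- nchar(m3$sequence)
  s3rc <- find_sites(dna_molecule("wrc", revcomp(m3$sequence)), "BtsI")
  expect_identical(s3rc$strand, "+")
  expect_identical(s3rc$rec_start, n - s3$rec_end)

  # origin-spanning site on a circular molecule
  circ <- dna_molecule("c", paste0("GTGAAAAAAAAAAAGCA"), topology = "circular")
  expect_identical(nrow(find_sites(circ, "BtsI")), 1L)
})

test_that("digestion produces the documented fragments with reconstructible ends", {
  m <- dna_molecule("x", "AAAGCAGTGCATTTTTTTT")
  fr <- digest(m, "BtsI")
  expect_length(fr, 2L)
  expect_identical(fragment_top_strand(fr[[1]]), "AAAGCAGTGCA")
  expect_identical(fr[[1]]$right_end$polarity, "three_prime")
  expect_identical(fr[[1]]$right_end$overhang, "CA")
  expect_identical(fr[[2]]$left_end$overhang, "TG")
  expect_identical(fragment_top_strand(fr[[2]]), "TTTTTTTT")
  expect_true(ends_compatible(fr[[1]]$right_end, fr[[2]]$left_end))
  # outermost ends of a linear digest are blunt
  expect_identical(fr[[1]]$left_end$polarity, "blunt")
  # stored sticky ends can be re-derived from the sequence
  for (f in fr) {
    re <- ezlink:::fragment_rederive_ends(f)
    expect_identical(re$left$overhang, f$left_end$overhang)
    expect_identical(re$right$overhang, f$right_end$overhang)
  }
})

test_that("digest conserves length and respects strand symmetry on circular input", {
  pz <- test_pz0()
  fr <- digest(pz, c("SapI", "BsaI"))
  expect_length(fr, 2L)
  expect_identical(sum(vapply(fr, fragment_footprint, integer(1))),
                   nchar(pz$sequence))
  # single-cut circular molecule: one fragment, footprint = length
  one <- digest(pz, "SapI")
  expect_length(one, 1L)
  expect_identical(fragment_footprint(one[[1]]), nchar(pz$sequence))
  expect_identical(one[[1]]$left_end$polarity, "five_prime")
  expect_identical(nchar(one[[1]]$left_end$overhang), 3L)
  # strand symmetry: fragments of revcomp(m) = flipped fragments of m
  rc <- dna_molecule("rc", revcomp(pz$sequence), topology = "circular")
  fr_rc <- digest(rc, c("SapI", "BsaI"))
  expect_setequal(
    vapply(fr_rc, function(f) fragment_top_strand(f), character(1)),
    vapply(fr, function(f) fragment_top_strand(ezlink:::flip_fragment(f)),
           character(1)))
})

test_that("uncut molecules, non-cleavable sites and scissile clashes are handled", {
  un <- digest(dna_molecule("u", "ACGTACGTACGT", topology = "circular"), "SapI")
  expect_true(isTRUE(attr(un, "uncut")))
  # recognition too close to a linear end to be cleaved
  short <- dna_molecule("s", "AAGCAGTG")
  expect_warning(fr <- digest(short, "BtsI"), "cannot be cleaved")
  expect_true(isTRUE(attr(fr, "uncut")))
  # overlapping scissile regions from two sites are a design error
  clash <- dna_molecule("cl", "GCAGTGACACTGC")
  expect_error(digest(clash, "BtsI"), "overlapping scissile")
})

test_that("analytical digest reports sizes descending and flags uncut input", {
  pz <- test_pz0()
  ad <- analytical_digest(pz, c("SapI", "BsaI"))
  expect_identical(ad$size_bp, sort(ad$size_bp, decreasing = TRUE))
  expect_identical(sum(ad$size_bp), nchar(pz$sequence))
  expect_false(any(ad$uncut))
  un <- analytical_digest(dna_molecule("u", strrep("ACGT", 1000),
                                       topology = "circular"), "SapI")
  expect_identical(un$size_bp, 4000L)
  expect_true(un$uncut)
})
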