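test_that("reverse complement is correct, an involution, and rejects ambiguity codes", {
  expect_identical(revcomp("GCAGTG"), "CACTGC")
  expect_identical(revcomp(""), "")
  expect_identical(revcomp("attgc"), "GCAAT")
  expect_error(revcomp("ATGN"), "non-ACGT")
  set.seed(7)
  for (i in 1:25) {
    s <- paste(sample(c("A", "C", "G", "T"), sample(1:40, 1), replace = TRUE),
               collapse = "")
    expect_identical(revcomp(revcomp(s)), s)
    expect_identical(nchar(revcomp(s)), nchar(s))
  }
})

test_that("translation uses the standard code, drops partial codons, renders stops", {
  expect_identical(translate_dna("ATGGGTGGTTCT"), "MGGS")
  expect_identical(translate_dna("TAA"), "*")
  expect_identical(translate_dna("ATGA"), "M")
  expect_identical(translate_dna("AATGGGT", frame = 1), "MG")
  expect_error(translate_dna("AT"), "complete codon")
})

test_that("canonical rotation matches brute-force enumeration and is invariant", {
  # independent oracle: enumerate every rotation of both strands, take min
  brute <- function(s) {
    rots <- function(x) vapply(seq_len(nchar(x)) - 1L, function(k) {
      paste0(substr(x, k + 1, nchar(x)), substr(x, 1, k))
    }, character(1))
    min(c(rots(s), rots(revcomp(s))))
  }
  expect_identical(rotate_canonical("TTAA"), "AATT")
  expect_identical(rotate_canonical("TTAA"), brute("TTAA"))
  expect_identical(rotate_canonical("AAAA"), "AAAA")
  set.seed(11)
  for (i in 1:20) {
    s <- paste(sample(c("A", "C", "G", "T"), sample(3:30, 1), replace = TRUE),
               collapse = "")
    can <- rotate_canonical(s)
    expect_identical(can, brute(s))
    # rotation- and flip-invariance, idempotence
    k <- sample(nchar(s), 1)
    rot <- paste0(substr(s, k + 1, nchar(s)), substr(s, 1, k))
    expect_identical(rotate_canonical(rot), can)
    expect_identical(rotate_canonical(revcomp(s)), can)
    expect_identical(rotate_canonical(can), can)
  }
  m <- dna_molecule("p", "TTAA", topology = "circular")
  expect_identical(rotate_canonical(m)$sequence, "AATT")
  expect_error(rotate_canonical(dna_molecule("l", "TTAA")), "circular")
})

test_that("sticky-end compatibility needs same polarity, same length, revcomp overhangs", {
  five <- function(o) sticky_end("five_prime", o)
  three <- function(o) sticky_end("three_prime", o)
  expect_true(ends_compatible(five("ATG"), five("CAT")))
  expect_false(ends_compatible(five("ATG"), three("CAT")))
  expect_true(ends_compatible(three("CA"), three("TG")))
  expect_false(ends_compatible(five("ATG"), five("ATG")))
  expect_false(ends_compatible(five("ATG"), five("CA")))
  expect_false(ends_compatible(sticky_end("blunt"), sticky_end("blunt")))
  # symmetry over random end pairs
  set.seed(3)
  for (i in 1:40) {
    a <- sticky_end(sample(c("five_prime", "three_prime"), 1),
                    paste(sample(c("A", "C", "G", "T"), sample(1:4, 1),
                                 replace = TRUE), collapse = ""))
    b <- sticky_end(sample(c("five_prime", "three_prime"), 1),
                    paste(sample(c("A", "C", "G", "T"), sample(1:4, 1),
                                 replace = TRUE), collapse = ""))
    expect_identical(ends_compatible(a, b), ends_compatible(b, a))
  }
})

test_that("molecule construction validates alphabet, topology and feature bounds", {
  expect_error(dna_molecule("x", ""), "non-empty")
  expect_error(dna_molecule("x", "ACGTN"), "non-ACGT")
  f <- feature_table("cds", "orf", 0L, 12L, "+")
  expect_error(dna_molecule("x", "ACGTACGT", features = f), "bounds")
  m <- dna_molecule("x", "ACGTACGTACGTACGT", features = f)
  expect_identical(m$features$key, "cds")
  # circular features may wrap once
  mw <- dna_molecule("x", "ACGTACGT", topology = "circular",
                     features = feature_table("site", "wrap", 6L, 10L, "+"))
  expect_identical(mw$features$end, 10L)
  expect_error(feature_table("marker", "m", 0L, 5L, "+"),
               "resistance")
  expect_error(feature_table("promoter", "p", 0L, 5L, "+"), "unknown feature key")
})
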