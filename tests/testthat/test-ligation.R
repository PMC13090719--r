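mk_frag <- function(id, region, lp, lo, rp, ro) {
  ezlink:::new_fragment(id, region, sticky_end(lp, lo), sticky_end(rp, ro))
}

test_that("joining re-creates the pre-digestion sequence and rejects bad ends", {
  m <- dna_molecule("x", "AAAGCAGTGCATTTTTTTT")
  fr <- digest(m, "BtsI")
  j <- join_fragments(fr[[1]], fr[[2]])
  expect_identical(fragment_top_strand(j), m$sequence)
  expect_identical(j$left_end$polarity, "blunt")
  # 5' overhang join carries the annealed bases exactly once; the bottom
  # strand's protruding ATG appears on a's region as its top-sense tail
  a <- mk_frag("a", paste0("GGGGGGCGC", "ATG"), "blunt", "",
               "five_prime", revcomp("ATG"))
  b <- mk_frag("b", paste0("ATG", "CCCCCCGTT"), "five_prime", "ATG",
               "blunt", "")
  jj <- join_fragments(a, b)
  expect_identical(jj$region, "GGGGGGCGCATGCCCCCCGTT")
  expect_identical(lengths(regmatches(jj$region,
                                      gregexpr("ATG", jj$region))), 1L)
  bad <- mk_frag("c", paste0("ATG", "CCCCCCGTT"), "five_prime", "GGG",
                 "blunt", "")
  expect_error(join_fragments(a, bad), "incompatible ends")
})

test_that("circular enumeration finds exactly the formable products", {
  # one fragment with mutually compatible ends self-circularises
  f1 <- mk_frag("s", paste0("ATG", strrep("C", 10), "ATG"),
                "five_prime", "ATG", "five_prime", revcomp("ATG"))
  prods <- enumerate_circular(ligation_pool(list(f1)), max_fragments = 2)
  expect_length(prods, 1L)
  expect_identical(nchar(prods[[1]]$molecule$sequence), 13L)
  # incompatible ends: no product
  f2 <- mk_frag("n", paste0("ATG", strrep("C", 10), "CCC"),
                "five_prime", "ATG", "five_prime", revcomp("GGG"))
  expect_length(enumerate_circular(ligation_pool(list(f2)), 2), 0L)
  # two fragments whose ends only chain pairwise: exactly one product
  a <- mk_frag("A", paste0("ATG", strrep("C", 8), "GCT"),
               "five_prime", "ATG", "five_prime", revcomp("GCT"))
  b <- mk_frag("B", paste0("GCT", strrep("T", 8), "ATG"),
               "five_prime", "GCT", "five_prime", revcomp("ATG"))
  prods <- enumerate_circular(ligation_pool(list(a, b)), 2)
  expect_length(prods, 1L)
  expect_identical(prods[[1]]$composition$fragment, c("A", "B"))
  # junction conservation: product length = sum of member footprints
  expect_identical(nchar(prods[[1]]$molecule$sequence),
                   fragment_footprint(a) + fragment_footprint(b))
})

test_that("enumeration is orientation-stable and blunt-only pools are rejected", {
  pz <- test_pz0()
  fr <- digest(pz, c("SapI", "BsaI"))
  canon <- function(ps) sort(vapply(ps, `[[`, character(1), "canonical_form"))
  p1 <- enumerate_circular(ligation_pool(fr), max_fragments = 2)
  flipped <- lapply(fr, ezlink:::flip_fragment)
  p2 <- enumerate_circular(ligation_pool(flipped), max_fragments = 2)
  expect_identical(canon(p1), canon(p2))
  blunt <- mk_frag("b", "ACGTACGT", "blunt", "", "blunt", "")
  expect_error(ligation_pool(list(blunt)), "blunt-only")
})

test_that("the enumeration frontier guard trips on explosive pools", {
  # many mutually compatible fragments under a tiny bound
  frs <- lapply(1:8, function(i) {
    mk_frag(paste0("f", i), paste0("ATG", strrep("C", 6), "ATG"),
            "five_prime", "ATG", "five_prime", revcomp("ATG"))
  })
  expect_error(enumerate_circular(ligation_pool(frs), max_fragments = 8,
                                  frontier_bound = 10),
               "frontier bound")
})

test_that("every reference fixture religates back to itself", {
  cfg <- test_cfg()
  plan <- test_plan9()
  expect_true(religation_check(plan$pz0, c("SapI", "BsaI")))
  expect_true(religation_check(plan$donors[[1]], c("SapI", "BbsI")))
  expect_true(religation_check(plan$donors[[2]], c("BtsI", "BsaI")))
  tu <- test_tu_set()
  expect_true(religation_check(tu$tus[[1]], "BsmBI"))
  expect_true(religation_check(tu$acceptor, "BsmBI"))
  expect_error(religation_check(dna_molecule("l", "ACGT"), "SapI"), "circular")
})
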