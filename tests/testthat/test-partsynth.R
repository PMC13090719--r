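test_that("random CDS generation is deterministic, site-free and stop-free", {
  spec <- synth_spec(1, n_residues = 240)
  a <- random_cds(spec)
  b <- random_cds(synth_spec(1, n_residues = 240))
  expect_identical(a$cds, b$cds)
  expect_identical(nchar(a$cds), 720L)
  m <- dna_molecule(a$id, a$cds)
  expect_true(all(count_sites(m) == 0L))
  expect_false(grepl("*", translate_dna(a$cds), fixed = TRUE))
  gcf <- ezlink:::gc_fraction(a$cds)
  expect_true(gcf >= 0.35 && gcf <= 0.65)
  expect_false(identical(random_cds(synth_spec(2, n_residues = 240))$cds,
                         a$cds))
})

test_that("domestication removes a planted BsaI site with one minimal synonymous edit", {
  cds <- "ATGGGTCTCAAA"   # ATG GGT CTC AAA with GGTCTC spanning codons 1-2
  res <- domesticate(cds)
  expect_identical(nrow(res$edits), 1L)
  expect_identical(res$edits$old_codon, "GGT")
  expect_identical(res$edits$new_codon, "GGA")   # lexicographically smallest fix
  expect_identical(translate_dna(res$sequence), translate_dna(cds))
  expect_identical(nrow(ezlink:::scan_forbidden(res$sequence,
                                                names(enzyme_registry()))), 0L)
  # identity on clean input, idempotence
  clean <- domesticate("ATGAAACCCGGG")
  expect_identical(clean$sequence, "ATGAAACCCGGG")
  expect_identical(nrow(clean$edits), 0L)
  expect_identical(domesticate(res$sequence)$sequence, res$sequence)
  expect_error(domesticate("ATGGGTCTCAA"), "divisible by 3")
})

test_that("domestication preserves translation over 1000 seeded coding sequences", {
  enz <- names(enzyme_registry())
  codons <- ezlink:::SENSE_CODONS
  n_changed <- 0L
  for (seed in 1:1000) {
    s <- ezlink:::with_seed(seed, paste(sample(codons, 25, replace = TRUE),
                                        collapse = ""))
    res <- tryCatch(domesticate(s, enz), error = function(e) NULL)
    if (is.null(res)) next   # stuck site: legitimately reported, rare
    expect_identical(translate_dna(res$sequence), translate_dna(s))
    expect_identical(nrow(ezlink:::scan_forbidden(res$sequence, enz)), 0L)
    if (!identical(res$sequence, s)) n_changed <- n_changed + 1L
  }
  expect_gt(n_changed, 50L)   # the property was exercised, not vacuous
})

test_that("linker coding sequences translate to the designed repeats", {
  g3 <- linker_cds("GGS", 3)
  expect_identical(g3$protein, "GGSGGSGGS")
  expect_identical(nchar(g3$cds), 27L)
  t4 <- linker_cds("TP_T", 4)
  expect_identical(t4$protein, "TPTPTPTPT")
  expect_identical(nchar(t4$cds), 27L)
  g1 <- linker_cds("GGS", 1)
  expect_identical(g1$protein, "GGS")
  expect_identical(nchar(g1$cds), 9L)
})

test_that("part constructor enforces frame and stop invariants", {
  expect_error(new_part("x", "ATGAA", role = "domain"), "divisible by 3")
  expect_error(new_part("x", "ATGTAAGGG", role = "domain"), "stop codon")
  p <- new_part("x", "ATGGCA", role = "domain")
  expect_identical(p$protein, "MA")
  # auxiliary roles skip frame bookkeeping
  expect_silent(new_part("r", "AGGAGGT", role = "rbs"))
})

test_that("the fixture set is reproducible, consistent and clean", {
  td1 <- withr::local_tempdir()
  td2 <- withr::local_tempdir()
  fx1 <- make_fixture_set(5, td1)
  fx2 <- make_fixture_set(5, td2)
  expect_identical(basename(fx1$paths), basename(fx2$paths))
  for (i in seq_along(fx1$paths)) {
    expect_identical(readLines(fx1$paths[i]), readLines(fx2$paths[i]))
  }
  # every fixture round-trips through the GenBank reader
  for (p in fx1$paths) {
    m <- read_genbank(p)
    expect_s3_class(m, "dna_molecule")
    expect_identical(m$topology, "circular")
  }
  # no recognition sites outside the designed cassettes anywhere
  for (m in c(list(fx1$plan$pz0), fx1$plan$donors, fx1$tus,
              list(fx1$acceptor))) {
    expect_identical(nrow(find_stray_sites(m)), 0L)
  }
})
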