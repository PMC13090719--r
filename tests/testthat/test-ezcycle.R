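test_that("cycle specs enforce distinct enzyme roles", {
  expect_error(cycle_spec("BsaI", "BsaI", "SapI", "resA"), "must differ")
  expect_error(cycle_spec("BsaI", "BbsI", "BsaI", "resA"), "cannot double")
  sp <- cycle_spec_for(1, test_cfg())
  expect_identical(sp$pz_backbone_enzyme, "BsaI")
  expect_identical(sp$donor_backbone_enzyme, "BbsI")
  expect_identical(sp$junction_enzyme, "SapI")
  expect_identical(sp$expected_marker, "resB")
  sp2 <- cycle_spec_for(2, test_cfg())
  expect_identical(sp2$pz_backbone_enzyme, "BbsI")
  expect_identical(sp2$junction_enzyme, "BtsI")
  expect_identical(sp2$expected_marker, "resA")
})

test_that("the reference pZ digests into keeper (origin+ORF) and discard (marker)", {
  cfg <- test_cfg()
  pz <- test_pz0()
  expect_identical(unname(count_sites(pz)[c("SapI", "BsaI", "BtsI", "BbsI",
                                            "BsmBI")]),
                   c(1L, 1L, 0L, 0L, 0L))
  fr <- digest(pz, c("SapI", "BsaI"))
  expect_length(fr, 2L)
  keeper <- fr[[which(vapply(fr, function(f) any(f$features$key == "origin"),
                             logical(1)))]]
  discard <- fr[[which(vapply(fr, function(f) any(f$features$key == "marker"),
                              logical(1)))]]
  expect_true(any(keeper$features$key == "cds"))
  expect_false(any(keeper$features$key == "marker"))
  expect_false(any(discard$features$key == "origin"))
  expect_false(any(pz$features$key == "ccdb"))
  # empty-frame pZ has exactly one junction and one backbone site
  expect_identical(nrow(analytical_digest(pz, c("SapI", "BsaI"))), 2L)
})

test_that("donor keeper chains onto the pZ keeper and religates to the donor", {
  cfg <- test_cfg()
  plan <- test_plan9()
  pz <- plan$pz0
  donor <- plan$donors[[1]]
  fr_pz <- digest(pz, c("SapI", "BsaI"))
  fr_do <- digest(donor, c("SapI", "BbsI"))
  pzk <- fr_pz[[which(vapply(fr_pz, function(f)
    any(f$features$key == "origin"), logical(1)))]]
  dok <- fr_do[[which(vapply(fr_do, function(f)
    any(f$features$key == "part"), logical(1)))]]
  expect_true(ends_compatible(pzk$right_end, dok$left_end))
  expect_true(ends_compatible(dok$right_end, pzk$left_end))
  # the donor discard carries the counterselection toxin
  dod <- fr_do[[which(vapply(fr_do, function(f)
    any(f$features$key == "ccdb"), logical(1)))]]
  expect_false(any(dod$features$key == "marker"))
})

test_that("a cycle yields a unique survivor: marker switched, no ccdB, ORF extended in frame", {
  cfg <- test_cfg()
  plan <- test_plan9()
  res <- run_cycle(plan$pz0, plan$donors[[1]], cycle_spec_for(1, cfg), cfg)
  expect_identical(res$status, "ok")
  expect_identical(res$diagnostics$n_survivors, 1L)
  out <- res$output_pz
  mk <- out$features[out$features$key == "marker", ]
  expect_identical(unname(mk$qualifiers[[1]]["resistance"]), "resB")
  expect_false(any(out$features$key == "ccdb"))
  orf <- ezlink:::orf_sequence(out)
  expect_identical(orf, paste0("ATG", plan$parts[[1]]$cds))
  expect_identical(translate_dna(orf),
                   paste0("M", plan$parts[[1]]$protein))
  # oracle containment: the designed output is in the full enumeration
  pool <- c(digest(plan$pz0, c("SapI", "BsaI")),
            digest(plan$donors[[1]], c("SapI", "BbsI")))
  prods <- enumerate_circular(ligation_pool(pool), max_fragments = 2)
  expect_true(rotate_canonical(out$sequence) %in%
                vapply(prods, `[[`, character(1), "canonical_form"))
})

test_that("without ligase no product survives on valid fixtures, and broken designs are flagged", {
  cfg <- test_cfg()
  plan <- test_plan9()
  sp <- cycle_spec_for(1, cfg)
  expect_identical(as.integer(no_ligase_control(plan$pz0, plan$donors[[1]],
                                                sp, cfg)), 0L)
  # donor lacking ccdB escapes counterselection
  d <- plan$donors[[1]]
  broken <- dna_molecule(d$id, d$sequence, "circular",
                         d$features[d$features$key != "ccdb", ])
  expect_gt(as.integer(no_ligase_control(plan$pz0, broken, sp, cfg)), 0L)
  # pZ already carrying the expected marker cannot be selected against
  sp_bad <- cycle_spec("BsaI", "BbsI", "SapI", expected_marker = "resA")
  expect_gt(as.integer(no_ligase_control(plan$pz0, plan$donors[[1]],
                                         sp_bad, cfg)), 0L)
})

test_that("the regenerated output accepts the complementary next cycle", {
  cfg <- test_cfg()
  plan <- test_plan9()
  res1 <- run_cycle(plan$pz0, plan$donors[[1]], cycle_spec_for(1, cfg), cfg)
  res2 <- run_cycle(res1$output_pz, plan$donors[[2]], cycle_spec_for(2, cfg),
                    cfg)
  expect_identical(res2$status, "ok")
  orf <- ezlink:::orf_sequence(res2$output_pz)
  expect_identical(orf, paste0("ATG", plan$parts[[1]]$cds, "GGT",
                               plan$parts[[2]]$cds))
  # marker alternation
  mk <- function(m) {
    f <- m$features[m$features$key == "marker", ]
    unname(f$qualifiers[[1]]["resistance"])
  }
  expect_identical(mk(res1$output_pz), "resB")
  expect_identical(mk(res2$output_pz), "resA")
})
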