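test_that("plans alternate markers, backbones and junction enzymes with period 2", {
  plan <- test_plan9()
  expect_identical(nrow(plan$steps), 9L)
  expect_identical(plan$marker_schedule,
                   rep(c("resB", "resA"), length.out = 9))
  expect_true(all(plan$steps$marker[-1] != plan$steps$marker[-9]))
  expect_identical(plan$steps$junction_enzyme,
                   rep(c("SapI", "BtsI"), length.out = 9))
  expect_identical(plan$steps$pz_backbone_enzyme,
                   rep(c("BsaI", "BbsI"), length.out = 9))
  expect_true(all(plan$steps$pz_backbone_enzyme !=
                    plan$steps$donor_backbone_enzyme))
  expect_error(plan_build(list(), test_cfg()), "non-empty")
})

test_that("a single-part build predicts the part's translation with no scar", {
  cfg <- test_cfg()
  plan <- plan_build(list(test_domain()), cfg)
  expect_identical(nrow(plan$steps), 1L)
  expect_identical(plan$final_orf, paste0("ATG", plan$parts[[1]]$cds))
  expect_identical(plan$final_protein,
                   paste0("M", plan$parts[[1]]$protein))
  expect_length(plan$scar_positions, 0L)
  res <- simulate_build(plan, cfg)
  expect_identical(res$scar_report$n_junctions, 0L)
  expect_identical(res$scar_report$scar_count_per_junction, 0L)
})

test_that("a two-part fusion carries exactly one single-residue scar at the junction", {
  cfg <- test_cfg()
  plan <- plan_build(list(test_domain(), test_linker()), cfg)
  res <- simulate_build(plan, cfg)
  rep_ <- res$scar_report
  expect_identical(rep_$n_junctions, 1L)
  expect_identical(rep_$scar_count_per_junction, 1L)
  expect_identical(rep_$junctions$scar_residue, "G")
  # independent expectation: concatenate translations around the scar codon
  expect_identical(rep_$protein,
                   paste0("M", plan$parts[[1]]$protein, "G",
                          plan$parts[[2]]$protein))
  expect_identical(rep_$junctions$protein_position,
                   2L + nchar(plan$parts[[1]]$protein))
})

test_that("the nine-cycle build yields five tandem domain copies with unique survivors", {
  plan <- test_plan9()
  res <- test_build9()
  orf <- ezlink:::orf_sequence(res$final_plasmid)
  expect_identical(orf, plan$final_orf)
  dom_cds <- plan$parts[[1]]$cds
  hits <- gregexpr(dom_cds, orf, fixed = TRUE)[[1]]
  expect_identical(length(hits), 5L)
  lnk_cds <- plan$parts[[2]]$cds
  expect_identical(length(gregexpr(lnk_cds, orf, fixed = TRUE)[[1]]), 4L)
  expect_identical(res$scar_report$n_junctions, 8L)
  expect_true(all(res$scar_report$junctions$scar_residue == "G"))
})

test_that("planned intermediates agree with the simulated ones (static vs pipeline)", {
  cfg <- test_cfg()
  plan <- test_plan9()
  res <- test_build9()
  for (i in seq_len(9)) {
    expect_identical(plan$predicted_intermediates[[i]],
                     res$qc_tables[[i]]$size_bp)
    # full sequence identity up to rotation/flip
    stat <- build_reference_pz(plan$parts[seq_len(i)], plan$steps$marker[i],
                               cfg)
    expect_identical(rotate_canonical(stat$sequence),
                     rotate_canonical(res$intermediates[[i]]$sequence))
  }
  # virtual-gel ladder: the ORF-bearing band grows strictly, by each part
  keeper <- vapply(res$qc_tables, function(q) max(q$size_bp), integer(1))
  expect_true(all(diff(keeper) > 0L))
  # net growth over matching band parities: one scar codon plus CDS per part
  expect_identical(sum(diff(keeper)),
                   sum(vapply(plan$parts[-1], function(p) nchar(p$cds),
                              integer(1))) + 8L * 3L)
})

test_that("verify_orf reports frameshifts introduced at a junction", {
  res <- test_build9()
  final <- res$final_plasmid
  f <- final$features
  oi <- which(f$key == "cds" & f$label == "orf")
  # delete one base inside the first part: frame lost
  cut <- f$start[oi] + 10L
  corrupt_seq <- paste0(substr(final$sequence, 1, cut),
                        substr(final$sequence, cut + 2, nchar(final$sequence)))
  f$end[oi] <- f$end[oi] - 1L
  f <- f[f$start < nchar(corrupt_seq) & f$end <= nchar(corrupt_seq), ]
  corrupt <- dna_molecule("bad", corrupt_seq, "circular", f)
  expect_error(verify_orf(corrupt, test_plan9()$parts),
               "frameshift")
  expect_error(verify_orf(final, test_plan9()$parts[1:3]),
               "mismatch|beyond")
})

test_that("identical generator inputs reproduce identical plans", {
  cfg <- test_cfg()
  p1 <- plan_build(list(test_domain(), test_linker()), cfg)
  p2 <- plan_build(list(test_domain(), test_linker()), cfg)
  expect_identical(p1$final_orf, p2$final_orf)
  expect_identical(p1$donors[[1]]$sequence, p2$donors[[1]]$sequence)
  expect_identical(p1$pz0$sequence, p2$pz0$sequence)
})
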