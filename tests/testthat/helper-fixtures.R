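# shared fixtures, built once per test run and memoised
.fx <- new.env(parent = emptyenv())

memo <- function(name, expr) {
  if (is.null(.fx[[name]])) .fx[[name]] <- force(expr)
  .fx[[name]]
}

test_cfg <- function() memo("cfg", ez_config(1))

test_domain <- function() memo("dom", fp_standin(ezlink:::sub_seed(1, 11), id = "FPdom"))
test_linker <- function() memo("lnk", linker_cds("GGS", 3))

test_parts9 <- function() rep(list(test_domain(), test_linker()), length.out = 9)

test_plan9 <- function() memo("plan9", plan_build(test_parts9(), test_cfg()))
test_build9 <- function() memo("build9", simulate_build(test_plan9(), test_cfg()))

test_pz0 <- function() test_plan9()$pz0

test_tu_set <- function() {
  memo("tus", {
    cfg <- test_cfg()
    fps <- lapply(1:4, function(i) {
      fp_standin(ezlink:::sub_seed(1, 20 + i), id = sprintf("FPtu%d", i))
    })
    tus <- lapply(1:4, function(i) {
      orf <- paste0("ATG", fps[[i]]$cds)
      tu_orf <- dna_molecule(fps[[i]]$id, orf, "linear",
                             feature_table("cds", fps[[i]]$id, 0L,
                                           nchar(orf), "+"))
      attach_adaptors(tu_orf,
                      adaptor_module("head", cfg$fusion_sites[i],
                                     payload = cfg$blocks$rbs),
                      adaptor_module("tail", cfg$fusion_sites[i + 1],
                                     payload = cfg$blocks$stop),
                      cfg)
    })
    list(tus = tus,
         acceptor = build_gg_acceptor(cfg$fusion_sites[1],
                                      cfg$fusion_sites[5], cfg))
  })
}

# 60-bp linear duplex holding a single recognition site with ample flanks
site_duplex <- function(recognition) {
  flank_l <- strrep("AT", 12)
  n_r <- nchar(recognition)
  flank_r <- substr(strrep("CT", 18), 1, 60 - 24 - n_r)
  dna_molecule(paste0("duplex_", recognition),
               paste0(flank_l, recognition, flank_r))
}
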