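# Run configuration: enzyme schedule, fixed cassette constants, and the
# seeded random sequence blocks (origins, promoter, placeholder marker /
# ccdB / RBS modules) shared by every reference molecule of a run.
#
# Blocks are generated site-free and then cross-validated: every boundary
# context the reference architectures create (block|cassette, block|block,
# origin wrap) is assembled and scanned, and any recognition pattern arising
# across a boundary is removed by a deterministic single-base edit inside
# the adjacent random block. The finished configuration therefore yields
# reference molecules whose only recognition sites are the designed ones,
# for any part set (part-adjacent boundaries are handled per-plan by
# synonymous edits, see plan_build()).

.config_cache <- new.env(parent = emptyenv())

#' Assembly-run configuration
#'
#' Deterministic in `seed`. Holds the enzyme schedule (junction enzymes
#' alternate SapI/BtsI, backbones BsaI/BbsI, markers resA/resB with period
#' 2), the fixed junction constants (scar codon GGT, constant backbone
#' fusion overhang, ATG start overhang), the Golden Gate layer constants
#' (BsmBI, acceptor marker, default fusion-site list), enumeration bounds,
#' and the generated sequence blocks.
#'
#' @param seed integer seed for block generation.
#' @param marker_alphabet two alternating resistance labels.
#' @param max_fragments per-product fragment bound used by [run_cycle()].
#' @param frontier_bound combinatorial guard for enumeration.
#' @return an `ez_config` list.
#' @export
ez_config <- function(seed = 1L, marker_alphabet = c("resA", "resB"),
                      max_fragments = 2L, frontier_bound = 1e6) {
  key <- paste(seed, paste(marker_alphabet, collapse = ","), max_fragments)
  if (!is.null(.config_cache[[key]])) return(.config_cache[[key]])
  stopifnot(length(marker_alphabet) == 2L,
            marker_alphabet[1] != marker_alphabet[2])
  cfg <- structure(list(
    seed = as.integer(seed),
    marker_alphabet = marker_alphabet,
    gg_marker = "resC",
    junction_enzymes = c("SapI", "BtsI"),
    backbone_enzymes = c("BsaI", "BbsI"),
    gg_enzyme = "BsmBI",
    backbone_overhang = "CGCT",
    scar_codon = "GGT",
    start_overhang = "ATG",
    junction_spacer = "A",
    btsi_completion = "T",
    fusion_sites = c("AATG", "GCTT", "CGAA", "TCCG", "ACTA"),
    max_fragments = as.integer(max_fragments),
    frontier_bound = frontier_bound,
    allow_stray = FALSE,
    blocks = NULL), class = "ez_config")
  sizes <- c(ori_z = 150L, prom = 60L, ori_d = 150L, ori_acc = 150L,
             ccdb = 90L, rbs = 21L)
  blocks <- lapply(seq_along(sizes), function(i) {
    random_dna(sizes[[i]], sub_seed(seed, 100L + i))
  })
  names(blocks) <- names(sizes)
  blocks$stop <- "TAATAA"
  markers <- c(marker_alphabet, cfg$gg_marker)
  blocks$markers <- lapply(seq_along(markers), function(i) {
    random_dna(120L, sub_seed(seed, 200L + i))
  })
  names(blocks$markers) <- markers
  cfg$blocks <- blocks
  cfg <- validate_config_blocks(cfg)
  .config_cache[[key]] <- cfg
  cfg
}

#' @export
print.ez_config <- function(x, ...) {
  cat(sprintf("<ez_config> seed %d; junctions %s; backbones %s; markers %s\n",
              x$seed, paste(x$junction_enzymes, collapse = "/"),
              paste(x$backbone_enzymes, collapse = "/"),
              paste(c(x$marker_alphabet, x$gg_marker), collapse = "/")))
  invisible(x)
}

# the reference molecules whose boundaries must be clean for any part set;
# a fixed benign linker-like CDS stands in for the (per-plan) parts
config_shells <- function(cfg) {
  cfg$allow_stray <- TRUE
  dummy <- new_part("dummy", strrep("GGTGGCTCT", 10L), role = "linker")
  shells <- list(
    build_reference_pz(list(), cfg$marker_alphabet[1], cfg),
    build_reference_pz(list(dummy), cfg$marker_alphabet[2], cfg),
    build_reference_pz(list(dummy, dummy), cfg$marker_alphabet[1], cfg),
    build_reference_donor(dummy, cfg$marker_alphabet[2], "pL", cfg, cycle = 1L),
    build_reference_donor(dummy, cfg$marker_alphabet[1], "pL", cfg, cycle = 2L),
    build_reference_donor(dummy, cfg$marker_alphabet[2], "pL", cfg, cycle = 3L))
  tu_orf <- dna_molecule("dummyFP", paste0("ATG", dummy$cds), "linear",
                         feature_table("cds", "dummyFP", 0L,
                                       3L + nchar(dummy$cds), "+"))
  shells <- c(shells, list(
    attach_adaptors(tu_orf,
                    adaptor_module("head", cfg$fusion_sites[1],
                                   payload = cfg$blocks$rbs),
                    adaptor_module("tail", cfg$fusion_sites[2],
                                   payload = cfg$blocks$stop),
                    cfg),
    build_gg_acceptor(cfg$fusion_sites[1], cfg$fusion_sites[5], cfg)))
  shells
}

# map a free segment name to its slot in cfg$blocks
block_slot <- function(name) {
  if (startsWith(name, "marker_")) {
    c("markers", sub("^marker_", "", name))
  } else name
}

get_block <- function(cfg, slot) {
  if (length(slot) == 2L) cfg$blocks[[slot[1]]][[slot[2]]] else
    cfg$blocks[[slot]]
}

set_block <- function(cfg, slot, value) {
  if (length(slot) == 2L) cfg$blocks[[slot[1]]][[slot[2]]] <- value else
    cfg$blocks[[slot]] <- value
  cfg
}

next_base <- function(b) {
  DNA_ALPHABET[(match(b, DNA_ALPHABET) %% 4L) + 1L]
}

# deterministic repair loop: rebuild all shell molecules, find recognition
# occurrences not contained in designed cassettes, and edit one base of an
# adjacent random block until everything is clean
validate_config_blocks <- function(cfg, max_iter = 300L) {
  for (iter in seq_len(max_iter)) {
    shells <- config_shells(cfg)
    repaired <- FALSE
    for (m in shells) {
      segmap <- attr(m, "segmap")
      stray <- find_stray_sites(m)
      if (nrow(stray) == 0L) next
      n <- seq_len_mol(m)
      for (si in seq_len(nrow(stray))) {
        h <- stray[si, ]
        # pieces of the hit in molecule coordinates (wrap-aware)
        pieces <- list(c(h$start, min(h$end, n)))
        if (h$end > n) pieces <- c(pieces, list(c(0L, h$end - n)))
        for (pc in pieces) {
          ov <- which(segmap$type == "free" & segmap$start < pc[2] &
                        segmap$end > pc[1])
          if (!length(ov)) next
          sgi <- ov[1]
          pos <- max(pc[1], segmap$start[sgi])       # absolute, 0-based
          off <- pos - segmap$start[sgi]             # offset in block
          slot <- block_slot(segmap$name[sgi])
          blk <- get_block(cfg, slot)
          b <- substr(blk, off + 1L, off + 1L)
          substr(blk, off + 1L, off + 1L) <- next_base(b)
          cfg <- set_block(cfg, slot, blk)
          repaired <- TRUE
          break
        }
        if (repaired) break
      }
      if (repaired) break
    }
    if (!repaired) {
      # no repairable stray anywhere; only dummy-part-adjacent hits may
      # remain, and those are resolved per-plan by synonymous edits
      leftovers <- unlist(lapply(shells, function(m) {
        st <- find_stray_sites(m)
        st$segments[!grepl("part|tu_orf|scar|atg", st$segments)]
      }))
      if (length(leftovers)) {
        stop("block validation could not clean boundary sites in: ",
             paste(leftovers, collapse = ", "), call. = FALSE)
      }
      return(cfg)
    }
  }
  stop("block validation did not converge", call. = FALSE)
}
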