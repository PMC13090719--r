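# Deterministic synthetic parts and fixtures: seeded random domesticated
# CDSs, linkers, placeholder markers/toxin/origin blocks, and the
# domestication algorithm (synonymous removal of internal recognition
# sites). Everything is a pure function of its seed, so the whole pipeline
# is testable with no external data.

# run code under a fixed seed without disturbing the caller's RNG stream
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# deterministic sub-seed derivation, kept inside 32-bit integer range
sub_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + k * 16807) %% 2147483629)
}

# codons by amino acid, each vector sorted lexicographically
codons_by_aa <- function() {
  gc <- Biostrings::GENETIC_CODE
  lapply(split(names(gc), unname(gc)), sort)
}

SENSE_CODONS <- sort(names(Biostrings::GENETIC_CODE)[Biostrings::GENETIC_CODE != "*"])

#' Specification for a synthetic coding sequence
#'
#' Identical specs yield bit-identical output.
#'
#' @param seed integer seed.
#' @param n_residues number of residues (>= 10).
#' @param gc_bounds length-2 numeric, admissible GC fraction.
#' @param forbidden_enzymes registry names whose sites must be absent.
#' @export
synth_spec <- function(seed, n_residues = 236L,
                       gc_bounds = c(0.35, 0.65),
                       forbidden_enzymes = names(enzyme_registry())) {
  stopifnot(n_residues >= 10L, length(gc_bounds) == 2L,
            gc_bounds[1] < gc_bounds[2])
  structure(list(seed = as.integer(seed), n_residues = as.integer(n_residues),
                 gc_bounds = as.numeric(gc_bounds),
                 forbidden_enzymes = forbidden_enzymes),
            class = "synth_spec")
}

gc_fraction <- function(s) {
  n <- nchar(s)
  if (n == 0L) return(NA_real_)
  (n - nchar(gsub("[GC]", "", s))) / n
}

forbidden_patterns <- function(enzymes) {
  recs <- unique(vapply(resolve_enzymes(as.list(enzymes)),
                        function(e) e$recognition, character(1)))
  unique(c(recs, vapply(recs, revcomp, character(1))))
}

scan_forbidden <- function(s, enzymes) {
  pats <- forbidden_patterns(enzymes)
  hits <- list()
  for (p in pats) {
    occ <- find_occurrences(s, p, circular = FALSE)
    for (o in occ) {
      hits[[length(hits) + 1L]] <- data.frame(start = o, end = o + nchar(p),
                                              pattern = p,
                                              stringsAsFactors = FALSE)
    }
  }
  if (!length(hits)) {
    return(data.frame(start = integer(), end = integer(),
                      pattern = character(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, hits)
  out[order(out$start, out$pattern), , drop = FALSE]
}

#' Count recognition sites of the registry enzymes on a molecule
#'
#' Both strands; used to assert that constructed plasmids carry exactly the
#' designed sites and nothing else.
#'
#' @param m a [dna_molecule()].
#' @param enzymes enzyme names (default: whole registry).
#' @return named integer vector of site counts.
#' @export
count_sites <- function(m, enzymes = names(enzyme_registry())) {
  vapply(enzymes, function(en) nrow(find_sites(m, en)), integer(1))
}

#' Random DNA free of forbidden recognition sites
#'
#' Uniform random bases, regenerated (bounded retries) until no forbidden
#' enzyme recognises the sequence on either strand. Deterministic in `seed`.
#'
#' @param n length in nt.
#' @param seed integer seed.
#' @param forbidden_enzymes registry names.
#' @export
random_dna <- function(n, seed, forbidden_enzymes = names(enzyme_registry())) {
  for (attempt in 0:199) {
    s <- with_seed(sub_seed(seed, attempt), {
      paste(sample(DNA_ALPHABET, n, replace = TRUE), collapse = "")
    })
    if (nrow(scan_forbidden(s, forbidden_enzymes)) == 0L) return(s)
  }
  stop("could not generate site-free random DNA", call. = FALSE)
}

#' Remove forbidden recognition sites from a CDS by synonymous substitution
#'
#' Greedy left-to-right scan: for the leftmost forbidden occurrence (either
#' strand), the codons overlapping the site are tried left to right; the
#' first codon with a synonymous alternative that destroys the occurrence is
#' edited, taking the lexicographically smallest such replacement codon. The
#' scan repeats until the sequence is clean. Translation is preserved by
#' construction; a site no synonymous change can destroy raises an error.
#'
#' @param cds DNA string, length divisible by 3.
#' @param forbidden registry enzyme names.
#' @return list with `sequence` (domesticated CDS) and `edits` (data.frame of
#'   `codon_index` (0-based), `old_codon`, `new_codon`, `site_pattern`,
#'   `site_start`).
#' @export
domesticate <- function(cds, forbidden = names(enzyme_registry())) {
  cds <- check_dna(cds, "cds")
  if (nchar(cds) %% 3L != 0L) {
    stop("CDS length must be divisible by 3", call. = FALSE)
  }
  syn <- codons_by_aa()
  edits <- list()
  max_iter <- nrow(scan_forbidden(cds, forbidden)) * 10L + 50L
  for (iter in seq_len(max_iter)) {
    hits <- scan_forbidden(cds, forbidden)
    if (nrow(hits) == 0L) break
    hit <- hits[1L, ]
    first_codon <- hit$start %/% 3L
    last_codon <- (hit$end - 1L) %/% 3L
    last_codon <- min(last_codon, nchar(cds) %/% 3L - 1L)
    fixed <- FALSE
    for (ci in first_codon:last_codon) {
      old <- substr(cds, 3L * ci + 1L, 3L * ci + 3L)
      aa <- unname(Biostrings::GENETIC_CODE[old])
      alts <- setdiff(syn[[aa]], old)   # already lexicographic
      for (alt in alts) {
        cand <- paste0(substr(cds, 1L, 3L * ci), alt,
                       substr(cds, 3L * ci + 4L, nchar(cds)))
        # the replacement must destroy this occurrence without creating a
        # new one elsewhere (one synonymous codon can turn one enzyme's
        # site into another's, e.g. His-Cys CATTGC <-> CACTGC)
        ok <- substr(cand, hit$start + 1L, hit$end) != hit$pattern &&
          nrow(scan_forbidden(cand, forbidden)) < nrow(hits)
        if (ok) {
          edits[[length(edits) + 1L]] <- data.frame(
            codon_index = ci, old_codon = old, new_codon = alt,
            site_pattern = hit$pattern, site_start = hit$start,
            stringsAsFactors = FALSE)
          cds <- cand
          fixed <- TRUE
          break
        }
      }
      if (fixed) break
    }
    if (!fixed) {
      stop(sprintf("site %s at position %d cannot be destroyed by any synonymous substitution",
                   hit$pattern, hit$start), call. = FALSE)
    }
  }
  if (nrow(scan_forbidden(cds, forbidden)) > 0L) {
    stop("domestication did not converge", call. = FALSE)
  }
  list(sequence = cds,
       edits = if (length(edits)) do.call(rbind, edits) else
         data.frame(codon_index = integer(), old_codon = character(),
                    new_codon = character(), site_pattern = character(),
                    site_start = integer(), stringsAsFactors = FALSE))
}

#' A protein-coding or auxiliary part
#'
#' Domain and linker parts must be in frame (length divisible by 3) with no
#' internal stop codon; their translation is derived automatically. `rbs`,
#' `stop` and `adaptor` parts sit outside the reading-frame bookkeeping.
#'
#' @param id text label.
#' @param cds DNA string.
#' @param role one of domain, linker, rbs, stop, adaptor.
#' @export
new_part <- function(id, cds, role = c("domain", "linker", "rbs", "stop",
                                       "adaptor")) {
  role <- match.arg(role)
  cds <- check_dna(cds, "part cds")
  protein <- NA_character_
  if (role %in% c("domain", "linker")) {
    if (nchar(cds) %% 3L != 0L) {
      stop("domain/linker part CDS length must be divisible by 3", call. = FALSE)
    }
    protein <- translate_dna(cds)
    if (grepl("*", protein, fixed = TRUE)) {
      stop("domain/linker part contains an internal stop codon", call. = FALSE)
    }
  }
  structure(list(id = as.character(id), role = role, cds = cds,
                 protein = protein), class = "ez_part")
}

#' @export
print.ez_part <- function(x, ...) {
  cat(sprintf("<part> %s (%s): %d nt\n", x$id, x$role, nchar(x$cds)))
  invisible(x)
}

#' Random domesticated coding sequence
#'
#' Codons drawn uniformly from the 61 sense codons, then domesticated against
#' the forbidden enzymes; drawn again if the GC fraction leaves the requested
#' bounds. Deterministic in the spec's seed.
#'
#' @param spec a [synth_spec()].
#' @param id part label.
#' @param role part role.
#' @return an [new_part()] object.
#' @export
random_cds <- function(spec, id = sprintf("cds_seed%d", spec$seed),
                       role = "domain") {
  stopifnot(inherits(spec, "synth_spec"))
  for (attempt in 0:99) {
    s <- with_seed(sub_seed(spec$seed, 1000L + attempt), {
      paste(sample(SENSE_CODONS, spec$n_residues, replace = TRUE),
            collapse = "")
    })
    s <- tryCatch(domesticate(s, spec$forbidden_enzymes)$sequence,
                  error = function(e) NULL)   # stuck site: redraw
    if (is.null(s)) next
    gcf <- gc_fraction(s)
    if (gcf >= spec$gc_bounds[1] && gcf <= spec$gc_bounds[2] &&
        !grepl("*", translate_dna(s), fixed = TRUE)) {
      return(new_part(id, s, role = role))
    }
  }
  stop("could not generate a CDS within the GC bounds", call. = FALSE)
}

#' Linker coding sequence
#'
#' Flexible glycine-serine `(GGS)n` or semi-rigid proline-threonine `(TP)nT`
#' linkers with a fixed, documented codon choice (G=GGT/GGC alternating
#' within a repeat is avoided: GGT GGC TCT per GGS repeat, ACT CCG per TP
#' repeat, final T = ACT), then domesticated.
#'
#' @param kind `"GGS"` or `"TP_T"`.
#' @param repeats number of repeats (>= 1).
#' @return an [new_part()] with role `"linker"`.
#' @export
linker_cds <- function(kind = c("GGS", "TP_T"), repeats = 3L) {
  kind <- match.arg(kind)
  stopifnot(repeats >= 1L)
  s <- if (kind == "GGS") {
    strrep("GGTGGCTCT", repeats)
  } else {
    paste0(strrep("ACTCCG", repeats), "ACT")
  }
  s <- domesticate(s)$sequence
  id <- if (kind == "GGS") sprintf("GGSx%d", repeats) else
    sprintf("TPx%dT", repeats)
  new_part(id, s, role = "linker")
}

#' Fluorescent-protein stand-in part
#'
#' Random domesticated CDS of the size class of a fluorescent protein
#' (~236 residues). The framework's guarantees are sequence-agnostic, so
#' synthetic stand-ins replace the real FP sequences; real CDSs can be
#' supplied via FASTA instead.
#'
#' @param seed integer seed.
#' @param id part label.
#' @export
fp_standin <- function(seed, id = sprintf("FP%d", seed)) {
  random_cds(synth_spec(seed, n_residues = 236L), id = id, role = "domain")
}

#' Generate the complete reference fixture set
#'
#' Writes, as GenBank files under `out_dir`: the empty reference pZ; the
#' nine donors of the five-domain / four-linker iterative build (one
#' FP stand-in domain alternating with a (GGS)3 linker); four
#' adaptor-flanked TU plasmids (stand-ins for four spectrally distinct FPs)
#' and the Golden Gate acceptor. All files are mutually consistent with the
#' default cycle schedule and byte-reproducible from the seed.
#'
#' @param seed integer seed.
#' @param out_dir output directory (created if needed).
#' @return named list with the build plan, TU plasmids, acceptor and file
#'   paths, invisibly.
#' @export
make_fixture_set <- function(seed, out_dir) {
  cfg <- ez_config(seed)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  dom <- fp_standin(sub_seed(seed, 11L), id = "FPdom")
  lnk <- linker_cds("GGS", 3L)
  parts <- rep(list(dom, lnk), length.out = 9L)
  plan <- plan_build(parts, cfg)
  paths <- character()
  wr <- function(m, name) {
    p <- file.path(out_dir, paste0(name, ".gb"))
    write_genbank(m, p)
    paths[[length(paths) + 1L]] <<- p
  }
  wr(plan$pz0, "pZ0")
  for (i in seq_along(plan$donors)) {
    wr(plan$donors[[i]], sprintf("donor_%02d", i))
  }
  fp_seeds <- vapply(1:4, function(i) sub_seed(seed, 20L + i), integer(1))
  fps <- lapply(seq_along(fp_seeds), function(i) {
    fp_standin(fp_seeds[i], id = sprintf("FPtu%d", i))
  })
  tus <- lapply(seq_along(fps), function(i) {
    orf <- paste0("ATG", fps[[i]]$cds)
    tu_orf <- dna_molecule(fps[[i]]$id, orf, "linear",
                           feature_table("cds", fps[[i]]$id, 0L, nchar(orf), "+"))
    attach_adaptors(tu_orf,
                    adaptor_module("head", cfg$fusion_sites[i],
                                   payload = cfg$blocks$rbs),
                    adaptor_module("tail", cfg$fusion_sites[i + 1L],
                                   payload = cfg$blocks$stop),
                    cfg)
  })
  for (i in seq_along(tus)) wr(tus[[i]], sprintf("TU_%d", i))
  acceptor <- build_gg_acceptor(cfg$fusion_sites[1], cfg$fusion_sites[5], cfg)
  wr(acceptor, "acceptor")
  invisible(list(config = cfg, plan = plan, tus = tus, acceptor = acceptor,
                 paths = unlist(paths)))
}
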