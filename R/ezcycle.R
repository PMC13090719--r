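# The elementary assembly cycle: reference destination (pZ) and donor
# (pD/pL) architectures, the digestion-ligation-selection pipeline, and the
# no-ligase control.
#
# Architecture (period-2 regenerative schedule):
#   cycle i odd:  junction SapI, pZ backbone BsaI, donor backbone BbsI
#   cycle i even: junction BtsI, pZ backbone BbsI, donor backbone BsaI
# The junction enzyme is the only enzyme active during the combined
# digestion-ligation step (the backbone pre-digests are heat-inactivated), so
# the donor may safely deliver the *other* junction enzyme's site for the
# next cycle. The donor likewise delivers the next cycle's backbone site:
# its recognition stays on the keeper side of the donor backbone cut and is
# reconstituted over the constant backbone fusion overhang upon ligation.
# Every junction inserts the scar codon GGT (Gly): as the 3-nt overhang
# itself under SapI, or as the designed GG overhang plus a fixed T completion
# base under BtsI. The very first junction uses the ORF's ATG start codon as
# the overhang, so the first part fuses scar-free.

junction_for_cycle <- function(cycle, config) {
  config$junction_enzymes[((cycle - 1L) %% 2L) + 1L]
}
pz_backbone_for_cycle <- function(cycle, config) {
  config$backbone_enzymes[((cycle - 1L) %% 2L) + 1L]
}
donor_backbone_for_cycle <- function(cycle, config) {
  config$backbone_enzymes[(cycle %% 2L) + 1L]
}
marker_for_cycle <- function(cycle, config) {
  config$marker_alphabet[(cycle %% 2L) + 1L]
}

# cassette strings ------------------------------------------------------------
# pZ-side junction cassette, placed right after the ORF: the overhang region
# (ORF-terminal bases) followed by the inward-pointing recognition.
pz_junction_cassette <- function(junction, overhang, config) {
  e <- get_enzyme(junction)
  if (e$name %in% c("SapI", "BspQI")) {
    stopifnot(nchar(overhang) == 3L)
    paste0(overhang, config$junction_spacer, revcomp(e$recognition))
  } else if (e$name == "BtsI") {
    stopifnot(nchar(overhang) == 2L)
    paste0(overhang, revcomp(e$recognition))
  } else stop("unsupported junction enzyme: ", e$name, call. = FALSE)
}

# donor-side head cassette, placed right before the part CDS
donor_head_cassette <- function(junction, overhang, config) {
  e <- get_enzyme(junction)
  if (e$name %in% c("SapI", "BspQI")) {
    stopifnot(nchar(overhang) == 3L)
    paste0(e$recognition, config$junction_spacer, overhang)
  } else if (e$name == "BtsI") {
    stopifnot(nchar(overhang) == 2L)
    paste0(e$recognition, overhang, config$btsi_completion)
  } else stop("unsupported junction enzyme: ", e$name, call. = FALSE)
}

# backbone cassette (shared by pZ and donors): recognition, spacer, constant
# fusion overhang; the recognition stays with the marker (discard) on pZ and
# with the keeper on donors, regenerating the site at the ligation junction.
backbone_cassette <- function(backbone, config) {
  e <- get_enzyme(backbone)
  spacer <- strrep("A", e$cut_top)
  paste0(e$recognition, spacer, config$backbone_overhang)
}

scar_overhang_for <- function(junction, config) {
  e <- get_enzyme(junction)
  if (e$overhang_length == 3L) config$scar_codon
  else substr(config$scar_codon, 1L, 2L)
}

# segment assembler ------------------------------------------------------------
# Builds a circular molecule from named segments, recording a segment map
# (used for stray-site auditing) and features.
assemble_segments <- function(id, segments) {
  seqs <- vapply(segments, `[[`, character(1), "seq")
  ends <- cumsum(nchar(seqs))
  starts <- c(0L, ends[-length(ends)])
  segmap <- data.frame(
    name = vapply(segments, `[[`, character(1), "name"),
    type = vapply(segments, `[[`, character(1), "type"),
    start = as.integer(starts), end = as.integer(ends),
    stringsAsFactors = FALSE)
  feats <- list()
  for (i in seq_along(segments)) {
    sg <- segments[[i]]
    if (!is.null(sg$feature)) {
      f <- sg$feature
      feats[[length(feats) + 1L]] <- feature_table(
        key = f$key, label = f$label, start = starts[i], end = ends[i],
        strand = "+",
        qualifiers = list(if (is.null(f$qualifiers)) character() else f$qualifiers))
    }
  }
  feats <- if (length(feats)) do.call(rbind, feats) else empty_features()
  m <- dna_molecule(id, paste(seqs, collapse = ""), topology = "circular",
                    features = feats)
  attr(m, "segmap") <- segmap
  m
}

seg <- function(name, seq, type, feature = NULL) {
  list(name = name, seq = seq, type = type, feature = feature)
}

#' Find recognition sites outside the designed cassettes
#'
#' Scans a constructed molecule for all registry recognition patterns (both
#' strands, origin-spanning included) and reports every occurrence that is
#' not wholly contained in a `fixed` (cassette) segment of the molecule's
#' segment map. A clean reference molecule has none.
#'
#' @param m molecule built by the reference constructors (carries a segment
#'   map attribute).
#' @param enzymes registry names to scan for.
#' @return data.frame of stray occurrences with the overlapped segments.
#' @export
find_stray_sites <- function(m, enzymes = names(enzyme_registry())) {
  segmap <- attr(m, "segmap")
  stopifnot(!is.null(segmap))
  n <- seq_len_mol(m)
  ext <- paste0(m$sequence, substr(m$sequence, 1L, 8L))
  hits <- scan_forbidden(ext, enzymes)
  hits <- hits[hits$start < n, , drop = FALSE]
  if (nrow(hits) == 0L) return(cbind(hits, segments = character()))
  seg_of <- function(h) {
    ov <- segmap$name[pmax(segmap$start, h["start"]) <
                        pmin(segmap$end, h["end"])]
    # wrap-around: also match segments at the start of the molecule
    if (h["end"] > n) {
      ov <- c(ov, segmap$name[segmap$start < (h["end"] - n)])
    }
    unique(ov)
  }
  keep <- logical(nrow(hits))
  segs <- character(nrow(hits))
  for (i in seq_len(nrow(hits))) {
    h <- c(start = hits$start[i], end = hits$end[i])
    inside_fixed <- any(segmap$type == "fixed" &
                          segmap$start <= h["start"] & segmap$end >= h["end"])
    keep[i] <- !inside_fixed
    segs[i] <- paste(seg_of(h), collapse = "+")
  }
  out <- hits[keep, , drop = FALSE]
  out$segments <- segs[keep]
  out
}

# ---- reference builders ------------------------------------------------------

orf_chain <- function(parts, config) {
  if (length(parts) == 0L) return(character())
  out <- list()
  for (j in seq_along(parts)) {
    if (j > 1L) out[[length(out) + 1L]] <- seg(sprintf("scar%d", j),
                                               config$scar_codon, "fixed")
    p <- parts[[j]]
    out[[length(out) + 1L]] <- seg(
      sprintf("part%d", j), p$cds, "cds",
      feature = list(key = "part", label = p$id,
                     qualifiers = c(part = p$id, role = p$role)))
  }
  out
}

#' Build the reference destination plasmid (pZ)
#'
#' A circular destination plasmid carrying: origin, promoter, the growing
#' open reading frame (ATG start plus the parts assembled so far, joined by
#' single-Gly scar codons), the next cycle's junction cassette cutting at
#' the ORF 3' end, the current resistance marker, and the next cycle's
#' backbone cassette positioned so that digestion splits the plasmid into a
#' keeper (origin + ORF) and a discard (marker) fragment. Contains no ccdB
#' and no recognition sites outside the designed cassettes.
#'
#' @param orf_parts_so_far list of parts already incorporated (possibly empty).
#' @param marker resistance label from the config's marker alphabet.
#' @param config an [ez_config()].
#' @return circular [dna_molecule()] with a segment-map attribute.
#' @export
build_reference_pz <- function(orf_parts_so_far, marker, config) {
  stopifnot(marker %in% names(config$blocks$markers))
  k <- length(orf_parts_so_far)
  cycle <- k + 1L
  junction <- junction_for_cycle(cycle, config)
  backbone <- pz_backbone_for_cycle(cycle, config)
  ovh <- if (k == 0L) config$start_overhang else
    scar_overhang_for(junction, config)
  segs <- c(
    list(seg("ori_z", config$blocks$ori_z, "free",
             feature = list(key = "origin", label = "oriZ")),
         seg("prom", config$blocks$prom, "free",
             feature = list(key = "site", label = "promoter"))),
    if (k == 0L) {
      # the ATG start codon doubles as the first junction overhang
      list(seg("jcass", pz_junction_cassette(junction, ovh, config), "fixed"))
    } else {
      c(list(seg("atg", "ATG", "fixed")),
        orf_chain(orf_parts_so_far, config),
        list(seg("jcass", pz_junction_cassette(junction, ovh, config), "fixed")))
    },
    list(seg(paste0("marker_", marker), config$blocks$markers[[marker]], "free",
             feature = list(key = "marker", label = marker,
                            qualifiers = c(resistance = marker))),
         seg("bcass", backbone_cassette(backbone, config), "fixed")))
  m <- assemble_segments(sprintf("pZ_%d", k), segs)
  # annotate the ORF: ATG through the end of the last part (the bare ATG
  # overhang when the frame is still empty)
  segmap <- attr(m, "segmap")
  orf_start <- if (k == 0L) segmap$start[segmap$name == "jcass"] else
    segmap$start[segmap$name == "atg"]
  orf_end <- if (k == 0L) orf_start + 3L else
    segmap$end[segmap$name == sprintf("part%d", k)]
  feats <- rbind(m$features,
                 feature_table("cds", "orf", orf_start, orf_end, "+"))
  m2 <- dna_molecule(m$id, m$sequence, "circular", feats)
  attr(m2, "segmap") <- segmap
  stray <- find_stray_sites(m2)
  if (nrow(stray) > 0L && !isTRUE(config$allow_stray)) {
    stop(sprintf("reference pZ contains stray recognition site(s): %s",
                 paste(sprintf("%s@%d(%s)", stray$pattern, stray$start,
                               stray$segments), collapse = ", ")),
         call. = FALSE)
  }
  m2
}

#' Build a reference donor plasmid (pD or pL)
#'
#' A circular donor whose keeper fragment carries, 5' to 3': the junction
#' overhang region feeding the part in frame onto the growing ORF, the part
#' CDS, the next cycle's junction cassette, the new resistance marker, and
#' the next cycle's backbone cassette (recognition on the keeper side, so the
#' site is regenerated in the assembled product). The discard fragment
#' carries the donor origin and the ccdB counterselection marker.
#'
#' @param part an [new_part()] (domain or linker).
#' @param new_marker resistance label delivered to the product.
#' @param kind `"pD"` (domain donor) or `"pL"` (linker donor); label only.
#' @param config an [ez_config()].
#' @param cycle 1-based cycle index this donor is used in (fixes the enzyme
#'   parity and, for cycle 1, the scar-free ATG head overhang).
#' @return circular [dna_molecule()] with a segment-map attribute.
#' @export
build_reference_donor <- function(part, new_marker, kind = c("pD", "pL"),
                                  config, cycle = 1L) {
  kind <- match.arg(kind)
  stopifnot(inherits(part, "ez_part"), part$role %in% c("domain", "linker"),
            new_marker %in% names(config$blocks$markers))
  junction <- junction_for_cycle(cycle, config)
  next_junction <- junction_for_cycle(cycle + 1L, config)
  backbone <- donor_backbone_for_cycle(cycle, config)
  head_ovh <- if (cycle == 1L) config$start_overhang else
    scar_overhang_for(junction, config)
  segs <- list(
    seg("ori_d", config$blocks$ori_d, "free",
        feature = list(key = "origin", label = "oriD")),
    seg("ccdb", config$blocks$ccdb, "free",
        feature = list(key = "ccdb", label = "ccdB")),
    seg("head", donor_head_cassette(junction, head_ovh, config), "fixed"),
    seg("part1", part$cds, "cds",
        feature = list(key = "part", label = part$id,
                       qualifiers = c(part = part$id, role = part$role))),
    seg("tail", pz_junction_cassette(next_junction,
                                     scar_overhang_for(next_junction, config),
                                     config), "fixed"),
    seg(paste0("marker_", new_marker), config$blocks$markers[[new_marker]],
        "free",
        feature = list(key = "marker", label = new_marker,
                       qualifiers = c(resistance = new_marker))),
    seg("bcass", backbone_cassette(backbone, config), "fixed"))
  m <- assemble_segments(sprintf("%s_%s", kind, part$id), segs)
  stray <- find_stray_sites(m)
  if (nrow(stray) > 0L && !isTRUE(config$allow_stray)) {
    stop(sprintf("donor contains stray recognition site(s): %s",
                 paste(sprintf("%s@%d(%s)", stray$pattern, stray$start,
                               stray$segments), collapse = ", ")),
         call. = FALSE)
  }
  if (!isTRUE(config$allow_stray)) {
    cuts <- digest(m, c(backbone, junction))
    if (isTRUE(attr(cuts, "uncut")) || length(cuts) != 2L) {
      stop("donor does not digest into exactly keeper + discard", call. = FALSE)
    }
    has_ccdb <- vapply(cuts, function(f) any(f$features$key == "ccdb"),
                       logical(1))
    if (sum(has_ccdb) != 1L ||
        any(vapply(cuts[has_ccdb], function(f) any(f$features$key == "marker"),
                   logical(1)))) {
      stop("donor construction error: ccdB must sit on the discard partition, apart from the marker",
           call. = FALSE)
    }
  }
  m
}

# ---- cycle spec & selection --------------------------------------------------

#' Specification of one elementary assembly cycle
#'
#' @param pz_backbone_enzyme,donor_backbone_enzyme the two (distinct)
#'   backbone enzymes, one per input plasmid.
#' @param junction_enzyme the fusion-overhang enzyme added in the combined
#'   digestion-ligation step; must differ from both backbone enzymes.
#' @param expected_marker resistance label the surviving product must carry.
#' @param forbidden_feature feature key that kills a candidate (default
#'   `"ccdb"`, the counterselection toxin).
#' @export
cycle_spec <- function(pz_backbone_enzyme, donor_backbone_enzyme,
                       junction_enzyme, expected_marker,
                       forbidden_feature = "ccdb") {
  for (e in c(pz_backbone_enzyme, donor_backbone_enzyme, junction_enzyme)) {
    get_enzyme(e)
  }
  if (pz_backbone_enzyme == donor_backbone_enzyme) {
    stop("pZ and donor backbone enzymes must differ", call. = FALSE)
  }
  if (junction_enzyme %in% c(pz_backbone_enzyme, donor_backbone_enzyme)) {
    stop("the junction enzyme cannot double as a backbone enzyme", call. = FALSE)
  }
  stopifnot(forbidden_feature %in% FEATURE_KEYS)
  structure(list(pz_backbone_enzyme = pz_backbone_enzyme,
                 donor_backbone_enzyme = donor_backbone_enzyme,
                 junction_enzyme = junction_enzyme,
                 expected_marker = expected_marker,
                 forbidden_feature = forbidden_feature),
            class = "cycle_spec")
}

#' Cycle spec for a given cycle index under the default schedule
#' @param cycle 1-based cycle index.
#' @param config an [ez_config()].
#' @export
cycle_spec_for <- function(cycle, config) {
  cycle_spec(pz_backbone_enzyme = pz_backbone_for_cycle(cycle, config),
             donor_backbone_enzyme = donor_backbone_for_cycle(cycle, config),
             junction_enzyme = junction_for_cycle(cycle, config),
             expected_marker = marker_for_cycle(cycle, config))
}

has_marker <- function(feats, resistance) {
  any(feats$key == "marker" &
        vapply(feats$qualifiers,
               function(q) identical(unname(q["resistance"]), resistance),
               logical(1)))
}

selection_verdict <- function(mol, spec) {
  if (any(mol$features$key == spec$forbidden_feature)) {
    return(sprintf("carries forbidden feature '%s'", spec$forbidden_feature))
  }
  if (!has_marker(mol$features, spec$expected_marker)) {
    return(sprintf("lacks required marker '%s'", spec$expected_marker))
  }
  "pass"
}

# extend the 'orf' feature over a part delivered adjacent to it (either
# scar-free at the ORF end, or one scar codon downstream)
extend_orf_feature <- function(mol) {
  feats <- mol$features
  oi <- which(feats$key == "cds" & feats$label == "orf")
  if (length(oi) != 1L) return(mol)
  repeat {
    oe <- feats$end[oi]
    pi <- which(feats$key == "part" & feats$start %in% c(oe, oe + 3L) &
                  feats$end > oe)
    if (length(pi) == 0L) break
    feats$end[oi] <- max(feats$end[pi])
  }
  dna_molecule(mol$id, mol$sequence, mol$topology, feats)
}

#' Run one elementary assembly cycle
#'
#' Pipeline: digest pZ with its backbone + junction enzyme, digest the donor
#' with its backbone + junction enzyme, pool all fragments, enumerate every
#' circular ligation product (at most `config$max_fragments` fragments), and
#' apply the genetic selection: only circular species are viable (the T5
#' exonuclease step removes linear DNA), the product must carry the expected
#' resistance marker, and must not carry the forbidden ccdB feature. With
#' exactly one surviving product class, that plasmid (ORF annotation
#' extended over the incorporated part) is returned as the next cycle's pZ.
#'
#' @param pz destination plasmid (circular).
#' @param donor donor plasmid (circular).
#' @param spec a [cycle_spec()].
#' @param config an [ez_config()].
#' @param ligase if `FALSE`, no joins are permitted: the only conceivable
#'   circular survivors are traces of intact input plasmid, which valid
#'   designs eliminate by selection.
#' @return `cycle_result` with `$survivors`, `$output_pz` (or `NULL`),
#'   `$status` and `$diagnostics`.
#' @export
run_cycle <- function(pz, donor, spec, config = ez_config(), ligase = TRUE) {
  stopifnot(is_dna_molecule(pz), is_dna_molecule(donor),
            inherits(spec, "cycle_spec"))
  dig_pz <- digest(pz, c(spec$pz_backbone_enzyme, spec$junction_enzyme))
  dig_do <- digest(donor, c(spec$donor_backbone_enzyme, spec$junction_enzyme))
  intact <- list()
  frags <- list()
  for (d in list(dig_pz, dig_do)) {
    if (isTRUE(attr(d, "uncut"))) intact <- c(intact, d) else frags <- c(frags, d)
  }
  candidates <- list()
  if (ligase && length(frags) > 0L) {
    candidates <- enumerate_circular(ligation_pool(frags),
                                     max_fragments = config$max_fragments,
                                     frontier_bound = config$frontier_bound)
  }
  # residual undigested circular input escapes the T5 exonuclease and is a
  # candidate regardless of ligase; valid designs remove it by selection
  for (m in intact) {
    candidates <- c(candidates, list(structure(
      list(molecule = m, composition = data.frame(fragment = m$id,
                                                  orientation = "as_is",
                                                  stringsAsFactors = FALSE),
           canonical_form = canonical_string(m$sequence)),
      class = "circular_product")))
  }
  if (!ligase) {
    for (m in list(pz, donor)) {
      candidates <- c(candidates, list(structure(
        list(molecule = m,
             composition = data.frame(fragment = paste0(m$id, ":undigested"),
                                      orientation = "as_is",
                                      stringsAsFactors = FALSE),
             canonical_form = canonical_string(m$sequence)),
        class = "circular_product")))
    }
  }
  verdicts <- vapply(candidates, function(p) selection_verdict(p$molecule, spec),
                     character(1))
  survivors <- candidates[verdicts == "pass"]
  diagnostics <- list(
    n_fragments_pz = if (isTRUE(attr(dig_pz, "uncut"))) 0L else length(dig_pz),
    n_fragments_donor = if (isTRUE(attr(dig_do, "uncut"))) 0L else length(dig_do),
    n_candidates = length(candidates),
    n_survivors = length(survivors),
    discard_reasons = data.frame(
      candidate = vapply(candidates, function(p)
        paste(p$composition$fragment, collapse = "+"), character(1)),
      size_bp = vapply(candidates, function(p)
        nchar(p$molecule$sequence), integer(1)),
      verdict = verdicts, stringsAsFactors = FALSE))
  status <- if (length(survivors) == 1L) "ok"
    else if (length(survivors) == 0L) "assembly failed"
    else "ambiguous design"
  output_pz <- NULL
  if (status == "ok") {
    out <- extend_orf_feature(survivors[[1L]]$molecule)
    output_pz <- dna_molecule(paste0("pZ+", donor$id), out$sequence,
                              "circular", out$features)
  }
  structure(list(survivors = survivors, output_pz = output_pz,
                 status = status, diagnostics = diagnostics,
                 spec = spec), class = "cycle_result")
}

#' @export
print.cycle_result <- function(x, ...) {
  cat(sprintf("<cycle_result> %s: %d candidate(s), %d survivor(s)\n",
              x$status, x$diagnostics$n_candidates, x$diagnostics$n_survivors))
  invisible(x)
}

#' Count survivors when T4 DNA ligase is omitted
#'
#' Identical pipeline with all joins disabled: no circular product can form,
#' and the undigested inputs that escape the exonuclease both fail selection
#' (pZ lacks the expected marker; the donor carries ccdB), so a valid design
#' yields zero survivors. A nonzero count flags an invalid design (e.g. a
#' donor lacking ccdB, or a pZ already carrying the expected marker).
#'
#' @inheritParams run_cycle
#' @return integer survivor count with the full `cycle_result` as attribute
#'   `result`.
#' @export
no_ligase_control <- function(pz, donor, spec, config = ez_config()) {
  res <- run_cycle(pz, donor, spec, config, ligase = FALSE)
  structure(res$diagnostics$n_survivors, result = res)
}
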