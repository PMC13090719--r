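# BsmBI Golden Gate layer: adaptor modules with 4-nt positioning overhangs
# flanking each translation unit (TU), and one-pot compilation of TUs into a
# poly-cistronic expression construct on a counterselectable acceptor.
#
# Chaining convention: the tail fusion site of TU_i equals the head fusion
# site of TU_{i+1} (the same 4-mer; the tail cut exposes its reverse
# complement on the bottom strand, so the two keepers anneal). The acceptor
# provides the outermost pair: backbone->TU_1 uses the first TU's head site,
# TU_N->backbone the last TU's tail site.

#' An adaptor module
#'
#' Carries an inward-pointing BsmBI site and the 4-nt fusion (positioning)
#' overhang exposed on digestion, optionally combined with a functional
#' payload: a ribosome binding site for head adaptors, a stop module for
#' tail adaptors.
#'
#' @param side `"head"` or `"tail"`.
#' @param fusion_site 4-nt DNA string; must not be a palindrome.
#' @param payload optional DNA string placed between the adaptor and the ORF.
#' @export
adaptor_module <- function(side = c("head", "tail"), fusion_site,
                           payload = NULL) {
  side <- match.arg(side)
  fusion_site <- check_dna(fusion_site, "fusion site")
  if (nchar(fusion_site) != 4L) {
    stop("fusion sites are exactly 4 nt", call. = FALSE)
  }
  if (fusion_site == revcomp(fusion_site)) {
    stop(sprintf("fusion site '%s' is self-complementary (palindrome)",
                 fusion_site), call. = FALSE)
  }
  if (!is.null(payload)) payload <- check_dna(payload, "payload")
  structure(list(side = side, fusion_site = fusion_site, payload = payload),
            class = "adaptor_module")
}

#' Validate a set of 4-nt fusion sites
#'
#' Flags duplicates, palindromes (self-complementary sites, which would
#' ligate to themselves), and mutually reverse-complementary pairs (which
#' would permit inverted insertion).
#'
#' @param sites character vector of 4-nt sites.
#' @return data.frame report (one row per site) with attribute `ok`.
#' @export
validate_fusion_sites <- function(sites) {
  sites <- vapply(sites, check_dna, character(1), "fusion site",
                  USE.NAMES = FALSE)
  if (any(nchar(sites) != 4L)) stop("fusion sites are exactly 4 nt", call. = FALSE)
  rc <- vapply(sites, revcomp, character(1))
  rep_df <- data.frame(
    site = sites,
    duplicate = duplicated(sites) | duplicated(sites, fromLast = TRUE),
    palindrome = sites == rc,
    revcomp_of = vapply(seq_along(sites), function(i) {
      j <- setdiff(which(sites == rc[i]), i)
      if (length(j)) paste(sites[j], collapse = ",") else ""
    }, character(1)),
    stringsAsFactors = FALSE)
  attr(rep_df, "ok") <- !any(rep_df$duplicate | rep_df$palindrome |
                               nzchar(rep_df$revcomp_of))
  rep_df
}

assert_fusion_sites <- function(sites) {
  rep_df <- validate_fusion_sites(sites)
  if (!isTRUE(attr(rep_df, "ok"))) {
    bad <- rep_df[rep_df$duplicate | rep_df$palindrome |
                    nzchar(rep_df$revcomp_of), , drop = FALSE]
    tags <- paste0(ifelse(bad$duplicate, " [duplicate]", ""),
                   ifelse(bad$palindrome, " [palindrome]", ""),
                   ifelse(nzchar(bad$revcomp_of),
                          paste0(" [revcomp of ", bad$revcomp_of, "]"), ""))
    stop("invalid fusion-site set: ",
         paste0(bad$site, tags, collapse = "; "), call. = FALSE)
  }
  invisible(rep_df)
}

gg_enzyme <- function(config) config$gg_enzyme

tu_head_cassette <- function(site, config) {
  e <- get_enzyme(gg_enzyme(config))
  paste0(e$recognition, strrep("A", e$cut_top), site)
}

tu_tail_cassette <- function(site, config) {
  e <- get_enzyme(gg_enzyme(config))
  paste0(site, strrep("A", e$cut_top), revcomp(e$recognition))
}

#' Flank a translation-unit ORF with head and tail adaptors
#'
#' Builds a circular TU plasmid: donor-side origin and marker on the
#' backbone, then head adaptor cassette (inward BsmBI site + head fusion
#' site), head payload (typically the RBS), the ORF, tail payload (typically
#' the stop module) and tail adaptor cassette. BsmBI digestion releases
#' exactly one keeper carrying the TU with the designed 4-nt overhangs.
#'
#' @param tu_orf linear [dna_molecule()] holding the ORF (its `cds` features
#'   are carried over); must not contain internal BsmBI sites.
#' @param head,tail [adaptor_module()]s with distinct fusion sites.
#' @param config an [ez_config()].
#' @param marker backbone resistance label (lands on the discard).
#' @return circular TU plasmid with a segment-map attribute.
#' @export
attach_adaptors <- function(tu_orf, head, tail, config = ez_config(),
                            marker = config$marker_alphabet[1]) {
  stopifnot(is_dna_molecule(tu_orf), inherits(head, "adaptor_module"),
            inherits(tail, "adaptor_module"),
            head$side == "head", tail$side == "tail")
  assert_fusion_sites(c(head$fusion_site, tail$fusion_site))
  ggz <- get_enzyme(gg_enzyme(config))
  internal <- find_sites(tu_orf, ggz)
  if (nrow(internal) > 0L) {
    stop(sprintf("TU ORF contains %d internal %s site(s); domesticate it first",
                 nrow(internal), ggz$name), call. = FALSE)
  }
  segs <- list(
    seg("ori_d", config$blocks$ori_d, "free",
        feature = list(key = "origin", label = "oriD")),
    seg(paste0("marker_", marker), config$blocks$markers[[marker]], "free",
        feature = list(key = "marker", label = marker,
                       qualifiers = c(resistance = marker))),
    seg("head_cass", tu_head_cassette(head$fusion_site, config), "fixed",
        feature = list(key = "adaptor", label = "head",
                       qualifiers = c(fusion_site = head$fusion_site))),
    if (!is.null(head$payload))
      seg("rbs", head$payload, "free",
          feature = list(key = "rbs", label = "rbs")),
    seg("tu_orf", tu_orf$sequence, "cds"),
    if (!is.null(tail$payload))
      seg("stopm", tail$payload, "fixed",
          feature = list(key = "stop", label = "stop")),
    seg("tail_cass", tu_tail_cassette(tail$fusion_site, config), "fixed",
        feature = list(key = "adaptor", label = "tail",
                       qualifiers = c(fusion_site = tail$fusion_site))))
  segs <- segs[!vapply(segs, is.null, logical(1))]
  m <- assemble_segments(sprintf("TU_%s", tu_orf$id), segs)
  # carry the ORF's own features over (cds etc.), shifted into place
  segmap <- attr(m, "segmap")
  off <- segmap$start[segmap$name == "tu_orf"]
  if (nrow(tu_orf$features) > 0L) {
    tf <- tu_orf$features
    tf$start <- tf$start + off
    tf$end <- tf$end + off
    m2 <- dna_molecule(m$id, m$sequence, "circular", rbind(m$features, tf))
    attr(m2, "segmap") <- segmap
    m <- m2
  }
  stray <- find_stray_sites(m, gg_enzyme(config))
  if (nrow(stray) > 0L && !isTRUE(config$allow_stray)) {
    stop("TU plasmid contains stray BsmBI site(s) at: ",
         paste(stray$start, collapse = ", "), call. = FALSE)
  }
  if (!isTRUE(config$allow_stray)) {
    frs <- digest(m, ggz)
    if (isTRUE(attr(frs, "uncut")) || length(frs) != 2L) {
      stop("TU plasmid must release exactly one keeper on BsmBI digestion",
           call. = FALSE)
    }
  }
  m
}

#' Build the Golden Gate acceptor
#'
#' MoClo-style acceptor: a backbone with its own resistance and a ccdB
#' dropout flanked by inward-pointing BsmBI sites. Digestion exposes the
#' first TU's head site and the last TU's tail site on the backbone ends.
#'
#' @param first_site head fusion site of the first TU.
#' @param last_site tail fusion site of the last TU.
#' @param config an [ez_config()].
#' @export
build_gg_acceptor <- function(first_site, last_site, config = ez_config()) {
  assert_fusion_sites(c(first_site, last_site))
  segs <- list(
    seg("ori_acc", config$blocks$ori_acc, "free",
        feature = list(key = "origin", label = "oriAcc")),
    seg(paste0("marker_", config$gg_marker),
        config$blocks$markers[[config$gg_marker]], "free",
        feature = list(key = "marker", label = config$gg_marker,
                       qualifiers = c(resistance = config$gg_marker))),
    seg("acc_tail_cass", tu_tail_cassette(first_site, config), "fixed",
        feature = list(key = "adaptor", label = "acceptor_first",
                       qualifiers = c(fusion_site = first_site))),
    seg("ccdb", config$blocks$ccdb, "free",
        feature = list(key = "ccdb", label = "ccdB")),
    seg("acc_head_cass", tu_head_cassette(last_site, config), "fixed",
        feature = list(key = "adaptor", label = "acceptor_last",
                       qualifiers = c(fusion_site = last_site))))
  m <- assemble_segments("pAcc", segs)
  stray <- find_stray_sites(m, gg_enzyme(config))
  if (nrow(stray) > 0L && !isTRUE(config$allow_stray)) {
    stop("acceptor contains stray BsmBI site(s) at: ",
         paste(stray$start, collapse = ", "), call. = FALSE)
  }
  m
}

tu_fusion_sites <- function(tu) {
  f <- tu$features
  i <- which(f$key == "adaptor")
  out <- list(head = NA_character_, tail = NA_character_)
  for (j in i) {
    q <- f$qualifiers[[j]]
    if (f$label[j] %in% c("head", "acceptor_last")) out$head <- unname(q["fusion_site"])
    if (f$label[j] %in% c("tail", "acceptor_first")) out$tail <- unname(q["fusion_site"])
  }
  out
}

#' One-pot Golden Gate compilation of translation units
#'
#' Digests every TU plasmid and the acceptor with BsmBI, enumerates all
#' circular ligation products, and applies the selection rule (acceptor
#' resistance present, no ccdB): with a valid fusion-site chain exactly one
#' product survives, containing every TU in the specified order and
#' orientation.
#'
#' @param tus ordered list of TU plasmids from [attach_adaptors()].
#' @param acceptor acceptor plasmid from [build_gg_acceptor()].
#' @param config an [ez_config()].
#' @return the surviving `circular_product`, with the junction report as
#'   attribute `junctions`; errors with a chain-gap or clash diagnostic
#'   otherwise.
#' @export
gg_assemble <- function(tus, acceptor, config = ez_config()) {
  stopifnot(is.list(tus), length(tus) >= 1L,
            all(vapply(tus, is_dna_molecule, logical(1))),
            is_dna_molecule(acceptor))
  sites <- lapply(tus, tu_fusion_sites)
  heads <- vapply(sites, `[[`, character(1), "head")
  tails <- vapply(sites, `[[`, character(1), "tail")
  assert_fusion_sites(unique(c(heads, tails)))
  # chain integrity: tail of TU_i must equal head of TU_{i+1}
  gaps <- which(tails[-length(tails)] != heads[-1L])
  acc_sites <- tu_fusion_sites(acceptor)
  ggz <- gg_enzyme(config)
  frags <- list()
  for (m in c(tus, list(acceptor))) {
    d <- digest(m, ggz)
    if (isTRUE(attr(d, "uncut"))) {
      stop(sprintf("input '%s' carries no %s site", m$id, ggz), call. = FALSE)
    }
    frags <- c(frags, d)
  }
  prods <- enumerate_circular(ligation_pool(frags),
                              max_fragments = length(tus) + 1L,
                              frontier_bound = config$frontier_bound)
  sel <- cycle_spec(pz_backbone_enzyme = config$backbone_enzymes[1],
                    donor_backbone_enzyme = config$backbone_enzymes[2],
                    junction_enzyme = ggz,
                    expected_marker = config$gg_marker)
  verdicts <- vapply(prods, function(p) selection_verdict(p$molecule, sel),
                     character(1))
  survivors <- prods[verdicts == "pass"]
  if (length(survivors) == 0L) {
    msg <- if (length(gaps)) {
      sprintf("chain gap at junction %d->%d: tail site '%s' does not match head site '%s'",
              gaps[1], gaps[1] + 1L, tails[gaps[1]], heads[gaps[1] + 1L])
    } else if (acc_sites$tail != heads[1L]) {
      sprintf("chain gap at acceptor->TU1: acceptor exposes '%s', TU1 head is '%s'",
              acc_sites$tail, heads[1L])
    } else if (acc_sites$head != tails[length(tails)]) {
      sprintf("chain gap at TU%d->acceptor: tail '%s' vs acceptor '%s'",
              length(tus), tails[length(tails)], acc_sites$head)
    } else "no surviving circular product"
    stop("Golden Gate assembly failed: ", msg, call. = FALSE)
  }
  if (length(survivors) > 1L) {
    stop("fusion-site clash: multiple surviving product classes of sizes ",
         paste(vapply(survivors, function(p) nchar(p$molecule$sequence),
                      integer(1)), collapse = ", "), call. = FALSE)
  }
  prod <- survivors[[1L]]
  # order check: CDS features must appear in the requested cyclic order
  expected <- unlist(lapply(tus, function(tu) {
    tu$features$label[tu$features$key == "cds"]
  }))
  f <- prod$molecule$features
  cds <- f[f$key == "cds", , drop = FALSE]
  cds <- cds[order(cds$start), , drop = FALSE]
  got <- cds$label
  ok_order <- length(got) == length(expected) && length(got) > 0L &&
    any(vapply(seq_along(got), function(r) {
      identical(got[c(seq_along(got), seq_len(r - 1L))[r:(r + length(got) - 1L)]],
                expected)
    }, logical(1)))
  junctions <- data.frame(
    junction = c("acceptor->TU1",
                 if (length(tus) > 1L)
                   sprintf("TU%d->TU%d", seq_len(length(tus) - 1L),
                           2:length(tus)),
                 sprintf("TU%d->acceptor", length(tus))),
    fusion_site = c(heads[1L], if (length(tus) > 1L) tails[-length(tails)],
                    tails[length(tails)]),
    overhang_length = 4L, stringsAsFactors = FALSE)
  attr(prod, "junctions") <- junctions
  attr(prod, "order_ok") <- ok_order
  prod
}
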