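# Type IIS enzymes: registry with cut-offset geometry, site finding on both
# strands of circular/linear molecules, digestion into sticky-ended
# fragments, and analytical-digest (virtual gel) reports.
#
# Geometry convention (REBASE-style "recognition(top/bottom)"): for a
# plus-strand site whose recognition occupies [r0, r1), the top strand is cut
# at r1 + cut_top and the bottom strand at r1 + cut_bottom, both expressed as
# top-strand coordinates ("cut at c" = between bases c-1 and c). Minus-strand
# sites mirror: cuts at r0 - cut_bottom (top) and r0 - cut_top (bottom).
# cut_bottom > cut_top leaves a 5' overhang, < a 3' overhang, = blunt.

.registry_env <- new.env(parent = emptyenv())

default_registry_table <- function() {
  # the shipped registry lives as an editable plain-text table; corrections
  # are config, not code
  path <- system.file("extdata", "enzymes.tsv", package = "ezlink")
  if (nzchar(path)) {
    return(validate_registry_table(utils::read.delim(path,
                                                     stringsAsFactors = FALSE)))
  }
  data.frame(
    name = c("BtsI", "BsrDI", "SapI", "BspQI", "BsaI", "BbsI", "BsmBI"),
    recognition = c("GCAGTG", "GCAATG", "GCTCTTC", "GCTCTTC", "GGTCTC",
                    "GAAGAC", "CGTCTC"),
    cut_top = c(2L, 2L, 1L, 1L, 1L, 2L, 1L),
    cut_bottom = c(0L, 0L, 4L, 4L, 5L, 6L, 5L),
    stringsAsFactors = FALSE
  )
}

validate_registry_table <- function(tab) {
  stopifnot(is.data.frame(tab),
            all(c("name", "recognition", "cut_top", "cut_bottom") %in% names(tab)))
  if (anyDuplicated(tab$name)) stop("duplicate enzyme names in registry", call. = FALSE)
  for (i in seq_len(nrow(tab))) check_dna(tab$recognition[i], "recognition")
  tab$cut_top <- as.integer(tab$cut_top)
  tab$cut_bottom <- as.integer(tab$cut_bottom)
  if (any(abs(tab$cut_bottom - tab$cut_top) > 4L)) {
    stop("overhangs longer than 4 nt are outside this framework", call. = FALSE)
  }
  tab
}

#' The type IIS enzyme registry
#'
#' Data-driven and immutable once loaded: each entry holds the recognition
#' sequence (5'->3') and the top/bottom scissile offsets downstream of the
#' recognition 3' end. The shipped table covers BtsI, BsrDI, SapI (with
#' BspQI as an isoschizomer of identical geometry), BsaI, BbsI and BsmBI;
#' offsets follow standard published enzyme geometry. A custom table with the
#' same columns may be supplied once per session via `table` (or a TSV path).
#'
#' @param table optional data.frame or TSV file path with columns
#'   `name`, `recognition`, `cut_top`, `cut_bottom`.
#' @return list of `typeiis_enzyme` objects, named by enzyme.
#' @export
enzyme_registry <- function(table = NULL) {
  if (!is.null(table)) {
    tab <- if (is.character(table)) {
      utils::read.delim(table, stringsAsFactors = FALSE)
    } else table
    tab <- validate_registry_table(tab)
    .registry_env$enzymes <- .build_registry(tab)
  }
  if (is.null(.registry_env$enzymes)) {
    .registry_env$enzymes <- .build_registry(default_registry_table())
  }
  .registry_env$enzymes
}

.build_registry <- function(tab) {
  out <- lapply(seq_len(nrow(tab)), function(i) {
    e <- list(name = tab$name[i],
              recognition = toupper(tab$recognition[i]),
              cut_top = tab$cut_top[i],
              cut_bottom = tab$cut_bottom[i])
    e$overhang_length <- abs(e$cut_bottom - e$cut_top)
    e$polarity <- if (e$cut_bottom > e$cut_top) "five_prime"
      else if (e$cut_bottom < e$cut_top) "three_prime" else "blunt"
    structure(e, class = "typeiis_enzyme")
  })
  names(out) <- tab$name
  out
}

#' @export
print.typeiis_enzyme <- function(x, ...) {
  cat(sprintf("<typeiis_enzyme> %s %s(%d/%d): %d-nt %s overhang\n",
              x$name, x$recognition, x$cut_top, x$cut_bottom,
              x$overhang_length, sub("_", " ", x$polarity)))
  invisible(x)
}

#' Look up one enzyme by name
#' @param name enzyme name as in the registry (e.g. `"SapI"`).
#' @export
get_enzyme <- function(name) {
  reg <- enzyme_registry()
  if (inherits(name, "typeiis_enzyme")) return(name)
  if (!name %in% names(reg)) {
    stop(sprintf("enzyme '%s' is not in the registry", name), call. = FALSE)
  }
  reg[[name]]
}

resolve_enzymes <- function(enzymes) {
  if (inherits(enzymes, "typeiis_enzyme")) enzymes <- list(enzymes)
  lapply(enzymes, get_enzyme)
}

# all occurrences (0-based starts) of `pat` in `s`, circular-aware
find_occurrences <- function(s, pat, circular) {
  n <- nchar(s)
  k <- nchar(pat)
  hay <- if (circular && n >= k) paste0(s, substr(s, 1L, k - 1L)) else s
  hits <- gregexpr(pat, hay, fixed = TRUE)[[1]]
  if (hits[1] == -1L) return(integer())
  as.integer(hits) - 1L
}

#' Locate all cut sites of an enzyme on a molecule
#'
#' Scans both strands (recognition on the plus strand, its reverse complement
#' on the minus strand); circular molecules include origin-spanning
#' occurrences. A site on a linear molecule whose scissile coordinates fall
#' outside the molecule cannot be cleaved: it is reported with
#' `cleavable = FALSE` and skipped by [digest()] with a warning.
#'
#' @param m a [dna_molecule()].
#' @param enzyme enzyme name or registry object.
#' @return data.frame with one row per site: `enzyme`, `strand`, `rec_start`,
#'   `rec_end`, `scissile_top`, `scissile_bottom`, `cleavable`, sorted by
#'   `rec_start`.
#' @export
find_sites <- function(m, enzyme) {
  stopifnot(is_dna_molecule(m))
  e <- get_enzyme(enzyme)
  n <- seq_len_mol(m)
  circ <- m$topology == "circular"
  plus <- find_occurrences(m$sequence, e$recognition, circ)
  minus <- find_occurrences(m$sequence, revcomp(e$recognition), circ)
  # a palindromic recognition would be reported on both strands; the shipped
  # registry has none, but dedupe defensively
  if (e$recognition == revcomp(e$recognition)) minus <- integer()
  rows <- list()
  k <- nchar(e$recognition)
  add <- function(start, strand) {
    r0 <- start; r1 <- start + k
    if (strand == "+") {
      st <- r1 + e$cut_top; sb <- r1 + e$cut_bottom
    } else {
      st <- r0 - e$cut_bottom; sb <- r0 - e$cut_top
    }
    # circular coordinates are kept raw (possibly < 0 or > n when the site
    # wraps the origin) so that the top/bottom pair stays a coherent
    # interval; reduce modulo length for positions on the circle
    cleavable <- TRUE
    if (!circ) {
      if (st < 0L || st > n || sb < 0L || sb > n) cleavable <- FALSE
    }
    data.frame(enzyme = e$name, strand = strand,
               rec_start = r0 %% if (circ) n else (n + 1L), rec_end = r1,
               scissile_top = st, scissile_bottom = sb,
               cleavable = cleavable, stringsAsFactors = FALSE)
  }
  for (p in plus) rows[[length(rows) + 1L]] <- add(p, "+")
  for (p in minus) rows[[length(rows) + 1L]] <- add(p, "-")
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(enzyme = character(), strand = character(),
               rec_start = integer(), rec_end = integer(),
               scissile_top = integer(), scissile_bottom = integer(),
               cleavable = logical(), stringsAsFactors = FALSE)
  out[order(out$rec_start, out$strand), , drop = FALSE]
}

# internal: collect cleavable cuts for a set of enzymes as a data.frame with
# the overhang interval [lo, hi) (top-sense), polarity, span
collect_cuts <- function(m, enzymes) {
  enzymes <- resolve_enzymes(enzymes)
  n <- seq_len_mol(m)
  cuts <- list()
  for (e in enzymes) {
    sites <- find_sites(m, e)
    skipped <- sites[!sites$cleavable, , drop = FALSE]
    if (nrow(skipped) > 0L) {
      warning(sprintf("%d %s site(s) on '%s' have scissile positions beyond the molecule end and cannot be cleaved",
                      nrow(skipped), e$name, m$id), call. = FALSE)
    }
    sites <- sites[sites$cleavable, , drop = FALSE]
    if (nrow(sites) == 0L) next
    lo <- pmin(sites$scissile_top, sites$scissile_bottom)
    hi <- pmax(sites$scissile_top, sites$scissile_bottom)
    if (m$topology == "circular") {
      span <- hi - lo
      lo <- ((lo %% n) + n) %% n
      hi <- lo + span
    }
    cuts[[length(cuts) + 1L]] <- data.frame(
      enzyme = e$name, lo = lo, hi = hi, span = hi - lo,
      polarity = e$polarity, stringsAsFactors = FALSE)
  }
  if (!length(cuts)) return(NULL)
  cuts <- do.call(rbind, cuts)
  cuts <- cuts[!duplicated(cuts[c("lo", "hi", "polarity")]), , drop = FALSE]
  cuts[order(cuts$lo, cuts$hi), , drop = FALSE]
}

check_cut_clashes <- function(cuts, n, circular) {
  k <- nrow(cuts)
  if (k < 2L) return(invisible())
  for (i in seq_len(k - 1L)) {
    if (cuts$hi[i] > cuts$lo[i + 1L]) {
      stop(sprintf("overlapping scissile regions: %s cut at [%d,%d) clashes with %s cut at [%d,%d)",
                   cuts$enzyme[i], cuts$lo[i], cuts$hi[i],
                   cuts$enzyme[i + 1L], cuts$lo[i + 1L], cuts$hi[i + 1L]),
           call. = FALSE)
    }
  }
  if (circular && cuts$hi[k] - n > cuts$lo[1L]) {
    stop(sprintf("overlapping scissile regions across the origin: %s cut at [%d,%d) clashes with %s cut at [%d,%d)",
                 cuts$enzyme[k], cuts$lo[k], cuts$hi[k],
                 cuts$enzyme[1L], cuts$lo[1L], cuts$hi[1L]), call. = FALSE)
  }
  invisible()
}

end_from_cut <- function(cut, bases, side) {
  if (cut$polarity == "blunt") return(sticky_end("blunt"))
  ovh <- if (side == "left") {
    if (cut$polarity == "five_prime") bases else revcomp(bases)
  } else {
    if (cut$polarity == "five_prime") revcomp(bases) else bases
  }
  sticky_end(cut$polarity, ovh)
}

# features of molecule m landing fully inside region [from, from+len) (mod n)
features_in_region <- function(m, from, len) {
  feats <- m$features
  if (nrow(feats) == 0L) return(feats)
  n <- seq_len_mol(m)
  off <- ((feats$start - from) %% n + n) %% n
  w <- feats$end - feats$start
  keep <- off + w <= len
  feats <- feats[keep, , drop = FALSE]
  if (nrow(feats) > 0L) {
    feats$end <- off[keep] + w[keep]
    feats$start <- off[keep]
  }
  feats
}

#' Digest a molecule with one or more type IIS enzymes
#'
#' Complete digestion is assumed: every cleavable site of every listed enzyme
#' is cut. A circular molecule with k cuts yields k fragments; with no cuts
#' it is returned intact and marked uncut. A linear molecule with k cuts
#' yields k+1 fragments whose outermost ends are the original (blunt) ends.
#' Two cuts whose single-stranded scissile regions overlap make the design
#' invalid and raise an error identifying the clash.
#'
#' Fragments inherit every source feature that lies fully inside them;
#' features severed by a cut are destroyed (dropped), which is what makes
#' marker/toxin selection on ligation products meaningful.
#'
#' @param m a [dna_molecule()].
#' @param enzymes enzyme name(s) or registry objects.
#' @return list of fragments (or a length-1 list holding the molecule itself,
#'   flagged with attribute `uncut`, when no enzyme cuts).
#' @export
digest <- function(m, enzymes) {
  stopifnot(is_dna_molecule(m))
  n <- seq_len_mol(m)
  circ <- m$topology == "circular"
  cuts <- collect_cuts(m, enzymes)
  if (is.null(cuts) || nrow(cuts) == 0L) {
    out <- list(m)
    attr(out, "uncut") <- TRUE
    return(out)
  }
  check_cut_clashes(cuts, n, circ)
  k <- nrow(cuts)
  frags <- list()
  if (circ) {
    for (i in seq_len(k)) {
      j <- if (i == k) 1L else i + 1L
      from <- cuts$lo[i]
      len <- ((cuts$lo[j] - cuts$lo[i]) %% n)
      if (len == 0L && k == 1L) len <- n
      len <- len + cuts$span[j]
      region <- circ_substr(m$sequence, from, len)
      left <- end_from_cut(cuts[i, ], substr(region, 1L, cuts$span[i]), "left")
      right <- end_from_cut(cuts[j, ],
                            substr(region, len - cuts$span[j] + 1L, len), "right")
      frags[[i]] <- new_fragment(
        sprintf("%s.f%d", m$id, i), region, left, right,
        features = features_in_region(m, from, len),
        provenance = list(list(source = m$id, start = from, length = len)))
    }
  } else {
    bounds <- rbind(data.frame(lo = 0L, hi = 0L, span = 0L,
                               polarity = "blunt", enzyme = "",
                               stringsAsFactors = FALSE),
                    cuts[, c("lo", "hi", "span", "polarity", "enzyme")],
                    data.frame(lo = n, hi = n, span = 0L, polarity = "blunt",
                               enzyme = "", stringsAsFactors = FALSE))
    for (i in seq_len(nrow(bounds) - 1L)) {
      from <- bounds$lo[i]
      to <- bounds$hi[i + 1L]
      region <- substr(m$sequence, from + 1L, to)
      left <- end_from_cut(bounds[i, ], substr(region, 1L, bounds$span[i]), "left")
      right <- end_from_cut(bounds[i + 1L, ],
                            substr(region, nchar(region) - bounds$span[i + 1L] + 1L,
                                   nchar(region)), "right")
      frags[[i]] <- new_fragment(
        sprintf("%s.f%d", m$id, i), region, left, right,
        features = features_in_region(m, from, to - from),
        provenance = list(list(source = m$id, start = from, length = to - from)))
    }
  }
  frags
}

#' Predicted fragment sizes (virtual gel)
#'
#' The analytical-digest report used to verify construct identity against
#' expected band sizes: fragment footprints in bp, sorted descending. An
#' uncut molecule reports its full length flagged `uncut`.
#'
#' @param m a [dna_molecule()].
#' @param enzymes enzyme name(s).
#' @return data.frame with columns `fragment_id`, `size_bp`, `left_polarity`,
#'   `left_overhang`, `right_polarity`, `right_overhang`, `uncut`, sorted by
#'   decreasing size.
#' @export
analytical_digest <- function(m, enzymes) {
  frags <- digest(m, enzymes)
  if (isTRUE(attr(frags, "uncut"))) {
    return(data.frame(fragment_id = m$id, size_bp = seq_len_mol(m),
                      left_polarity = NA_character_, left_overhang = NA_character_,
                      right_polarity = NA_character_, right_overhang = NA_character_,
                      uncut = TRUE, stringsAsFactors = FALSE))
  }
  out <- data.frame(
    fragment_id = vapply(frags, function(f) f$id, character(1)),
    size_bp = vapply(frags, fragment_footprint, integer(1)),
    left_polarity = vapply(frags, function(f) f$left_end$polarity, character(1)),
    left_overhang = vapply(frags, function(f) f$left_end$overhang, character(1)),
    right_polarity = vapply(frags, function(f) f$right_end$polarity, character(1)),
    right_overhang = vapply(frags, function(f) f$right_end$overhang, character(1)),
    uncut = FALSE, stringsAsFactors = FALSE)
  out[order(-out$size_bp), , drop = FALSE]
}
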