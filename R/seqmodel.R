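# Core representations: annotated DNA molecules, sticky-ended fragments, and
# the string primitives (reverse complement, translation, circular rotation)
# that every other layer of the simulator builds on.
#
# Coordinates are 0-based, half-open everywhere. Circular molecules reduce
# indices modulo length.

DNA_ALPHABET <- c("A", "C", "G", "T")

#' Validate a DNA string
#'
#' Accepts only upper- or lower-case A/C/G/T; ambiguity codes are rejected at
#' ingest because every sequence handled by the simulator is fully specified.
#'
#' @param s character scalar.
#' @param what label used in error messages.
#' @return the upper-cased sequence, invisibly usable.
#' @keywords internal
check_dna <- function(s, what = "sequence") {
  if (!is.character(s) || length(s) != 1L || is.na(s)) {
    stop(sprintf("%s must be a single character string", what), call. = FALSE)
  }
  s <- toupper(s)
  if (nchar(s) > 0L && grepl("[^ACGT]", s)) {
    bad <- unique(strsplit(gsub("[ACGT]", "", s), "")[[1]])
    stop(sprintf("%s contains non-ACGT characters: %s (ambiguity codes are not supported)",
                 what, paste(bad, collapse = ", ")), call. = FALSE)
  }
  s
}

#' Reverse complement of a DNA string
#'
#' @param s DNA string over ACGT (case-insensitive). The empty string is its
#'   own reverse complement.
#' @return reverse complement, upper case.
#' @examples
#' revcomp("GCAGTG")  # "CACTGC"
#' @export
revcomp <- function(s) {
  s <- check_dna(s)
  if (nchar(s) == 0L) return(s)
  paste(rev(strsplit(chartr("ACGT", "TGCA", s), "", fixed = TRUE)[[1]]),
        collapse = "")
}

#' Translate a DNA string with the standard genetic code
#'
#' Complete codons from `frame` onward are translated; a trailing partial
#' codon is ignored. Stop codons render as `*`.
#'
#' @param s DNA string.
#' @param frame 0-based offset of the first codon.
#' @return amino-acid string.
#' @examples
#' translate_dna("ATGGGTGGTTCT")  # "MGGS"
#' @export
translate_dna <- function(s, frame = 0L) {
  s <- check_dna(s)
  if (nchar(s) - frame < 3L) {
    stop("need at least one complete codon after the frame offset", call. = FALSE)
  }
  n_codon <- (nchar(s) - frame) %/% 3L
  starts <- frame + 3L * (seq_len(n_codon) - 1L) + 1L
  codons <- substring(s, starts, starts + 2L)
  aa <- unname(Biostrings::GENETIC_CODE[codons])
  if (anyNA(aa)) stop("untranslatable codon encountered", call. = FALSE)
  paste(aa, collapse = "")
}

# Booth's least-rotation algorithm; returns the 0-based rotation offset of the
# lexicographically smallest rotation of s.
least_rotation_offset <- function(s) {
  n <- nchar(s)
  if (n == 0L) return(0L)
  b <- utf8ToInt(paste0(s, s))
  f <- rep.int(-1L, 2L * n)
  k <- 0L
  for (j in seq.int(2L, 2L * n)) {
    sj <- b[j]
    i <- f[j - k - 1L]
    while (i != -1L && sj != b[k + i + 2L]) {
      if (sj < b[k + i + 2L]) k <- j - i - 2L
      i <- f[i + 1L]
    }
    if (sj != b[k + i + 2L]) {
      if (sj < b[k + 1L]) k <- j - 1L
      f[j - k] <- -1L
    } else {
      f[j - k] <- i + 1L
    }
  }
  k %% n
}

rotate_string <- function(s, k) {
  n <- nchar(s)
  if (n == 0L) return(s)
  k <- ((k %% n) + n) %% n
  if (k == 0L) return(s)
  paste0(substr(s, k + 1L, n), substr(s, 1L, k))
}

#' Canonical form of a circular sequence
#'
#' The canonical form is the lexicographically smallest rotation taken over
#' both strands, so two circular molecules are equivalent (same plasmid) iff
#' their canonical forms are identical. A plasmid has no distinguished origin
#' or strand, so identity must be rotation- and flip-invariant.
#'
#' @param x a circular [dna_molecule()] or a plain DNA string understood as a
#'   circular sequence.
#' @return for a molecule input, the molecule rotated/flipped to canonical
#'   form (features dropped); for a string input, the canonical string.
#' @export
rotate_canonical <- function(x) {
  if (is_dna_molecule(x)) {
    if (x$topology != "circular") {
      stop("rotate_canonical() requires a circular molecule", call. = FALSE)
    }
    can <- canonical_string(x$sequence)
    return(dna_molecule(x$id, can, topology = "circular"))
  }
  canonical_string(check_dna(x))
}

canonical_string <- function(s) {
  if (nchar(s) == 0L) return(s)
  rc <- revcomp(s)
  a <- rotate_string(s, least_rotation_offset(s))
  b <- rotate_string(rc, least_rotation_offset(rc))
  if (a <= b) a else b
}

#' Construct a sticky end
#'
#' `overhang` is read 5'->3' on the protruding strand. Blunt ends carry an
#' empty overhang; sticky overhangs in this framework are 1-4 nt.
#'
#' @param polarity one of `"five_prime"`, `"three_prime"`, `"blunt"`.
#' @param overhang DNA string (empty iff blunt).
#' @export
sticky_end <- function(polarity = c("blunt", "five_prime", "three_prime"),
                       overhang = "") {
  polarity <- match.arg(polarity)
  overhang <- check_dna(overhang, "overhang")
  if (polarity == "blunt" && nchar(overhang) != 0L) {
    stop("blunt ends carry no overhang", call. = FALSE)
  }
  if (polarity != "blunt" && !(nchar(overhang) %in% 1:4)) {
    stop("sticky overhangs must be 1-4 nt in this framework", call. = FALSE)
  }
  structure(list(polarity = polarity, overhang = overhang),
            class = "sticky_end")
}

#' Can two sticky ends ligate?
#'
#' True iff both ends have the same polarity, the same nonzero length, and
#' the overhangs are reverse complements (antiparallel annealing). Blunt ends
#' never ligate in this simulator: the junctions of the modelled assembly
#' chemistry are exclusively sticky.
#'
#' @param a,b [sticky_end()] objects.
#' @return logical scalar; symmetric in its arguments.
#' @export
ends_compatible <- function(a, b) {
  stopifnot(inherits(a, "sticky_end"), inherits(b, "sticky_end"))
  if (a$polarity == "blunt" || b$polarity == "blunt") return(FALSE)
  a$polarity == b$polarity &&
    nchar(a$overhang) == nchar(b$overhang) &&
    a$overhang == revcomp(b$overhang)
}

# ---- features ---------------------------------------------------------------

FEATURE_KEYS <- c("marker", "ccdb", "cds", "rbs", "stop", "adaptor", "site",
                  "origin", "part")

#' Build a feature table
#'
#' A data.frame with one row per feature: `key` (controlled vocabulary),
#' `label`, `start`/`end` (0-based half-open), `strand` (`"+"`/`"-"`), and a
#' `qualifiers` list-column of named character vectors. Marker features must
#' carry a `resistance` qualifier naming the antibiotic-resistance label.
#'
#' @param key,label,start,end,strand,qualifiers per-feature vectors.
#' @export
feature_table <- function(key = character(), label = character(),
                          start = integer(), end = integer(),
                          strand = character(), qualifiers = NULL) {
  n <- length(key)
  if (is.null(qualifiers)) qualifiers <- rep(list(character()), n)
  stopifnot(length(label) == n, length(start) == n, length(end) == n,
            length(strand) == n, length(qualifiers) == n)
  if (n > 0L && !all(key %in% FEATURE_KEYS)) {
    stop("unknown feature key(s): ",
         paste(setdiff(key, FEATURE_KEYS), collapse = ", "), call. = FALSE)
  }
  bad <- key == "marker" &
    !vapply(qualifiers, function(q) "resistance" %in% names(q), logical(1))
  if (any(bad)) {
    stop("marker features must carry a 'resistance' qualifier", call. = FALSE)
  }
  df <- data.frame(key = as.character(key), label = as.character(label),
                   start = as.integer(start), end = as.integer(end),
                   strand = as.character(strand), stringsAsFactors = FALSE)
  df$qualifiers <- qualifiers
  df
}

empty_features <- function() feature_table()

#' Construct an annotated DNA molecule
#'
#' The universal substrate of the simulator: a double-stranded molecule
#' represented by its top strand (5'->3'), a topology flag and a feature
#' table. Circular spans may wrap the origin once (`end` then exceeds the
#' length; positions are interpreted modulo length).
#'
#' @param id text label.
#' @param sequence top strand over ACGT; non-empty.
#' @param topology `"circular"` or `"linear"`.
#' @param features a [feature_table()].
#' @export
dna_molecule <- function(id, sequence, topology = c("linear", "circular"),
                         features = empty_features()) {
  topology <- match.arg(topology)
  sequence <- check_dna(sequence)
  if (nchar(sequence) == 0L) stop("sequence must be non-empty", call. = FALSE)
  n <- nchar(sequence)
  if (nrow(features) > 0L) {
    if (any(features$start < 0L) || any(features$start >= n)) {
      stop("feature start out of bounds", call. = FALSE)
    }
    lim <- if (topology == "circular") 2L * n else n
    if (any(features$end > lim) || any(features$end <= features$start)) {
      stop("feature end out of bounds", call. = FALSE)
    }
  }
  structure(list(id = as.character(id), sequence = sequence,
                 topology = topology, features = features),
            class = "dna_molecule")
}

#' @export
is_dna_molecule <- function(x) inherits(x, "dna_molecule")

#' @export
print.dna_molecule <- function(x, ...) {
  cat(sprintf("<dna_molecule> %s: %d bp, %s, %d feature(s)\n",
              x$id, nchar(x$sequence), x$topology, nrow(x$features)))
  invisible(x)
}

seq_len_mol <- function(m) nchar(m$sequence)

# Circular-aware substring: extract len bases starting at 0-based `from`.
circ_substr <- function(s, from, len) {
  n <- nchar(s)
  from <- ((from %% n) + n) %% n
  if (len > n + 4L && len > 2L * n) stop("substring longer than molecule")
  ss <- if (from + len <= n) substr(s, from + 1L, from + len) else
    paste0(substr(s, from + 1L, n),
           substr(paste0(s, s), n + 1L, from + len))
  ss
}

# ---- fragments --------------------------------------------------------------

# A fragment is stored in "region" form: `region` is the top-strand-sense
# sequence over the fragment's full extent, from the leftmost scissile
# position to the rightmost, including both overhang regions regardless of
# which strand protrudes. The spec-facing `seq` (the physical top strand) is
# derived by stripping bottom-strand-only overhang regions:
#   left end:  five_prime protrudes on top, three_prime on bottom;
#   right end: three_prime protrudes on top, five_prime on bottom.

new_fragment <- function(id, region, left_end, right_end,
                         features = empty_features(), provenance = list()) {
  region <- check_dna(region, "fragment region")
  ll <- nchar(left_end$overhang)
  rl <- nchar(right_end$overhang)
  if (nchar(region) - ll - rl < 1L) {
    stop("fragment duplex core must be at least 1 bp", call. = FALSE)
  }
  structure(list(id = as.character(id), region = region,
                 left_end = left_end, right_end = right_end,
                 features = features, provenance = provenance),
            class = "fragment")
}

#' @export
print.fragment <- function(x, ...) {
  cat(sprintf("<fragment> %s: %d bp footprint, left (%s, %s), right (%s, %s)\n",
              x$id, fragment_footprint(x),
              x$left_end$polarity, x$left_end$overhang,
              x$right_end$polarity, x$right_end$overhang))
  invisible(x)
}

# Overhang bases live on the top strand at this end?
ovh_on_top <- function(end, side) {
  if (end$polarity == "blunt") return(FALSE)
  if (side == "left") end$polarity == "five_prime" else
    end$polarity == "three_prime"
}

#' Physical top strand of a fragment
#'
#' The top-strand string 5'->3', including overhang bases where the top
#' strand protrudes and excluding regions covered only by the bottom strand.
#'
#' @param f a fragment.
#' @export
fragment_top_strand <- function(f) {
  from <- if (ovh_on_top(f$left_end, "left")) 0L else nchar(f$left_end$overhang)
  to <- nchar(f$region) -
    (if (ovh_on_top(f$right_end, "right")) 0L else nchar(f$right_end$overhang))
  substr(f$region, from + 1L, to)
}

#' Fragment footprint in bp
#'
#' Length of the physical top strand. Footprints of the fragments of a
#' digest sum exactly to the length of the parent molecule (each junction
#' overhang is on the top strand of exactly one of its two fragments).
#'
#' @param f a fragment.
#' @export
fragment_footprint <- function(f) nchar(fragment_top_strand(f))

# Reverse-complement a fragment (swap strands and ends). Overhang strings are
# invariant under the flip: the protruding strand is the same physical
# strand, still read 5'->3'.
flip_fragment <- function(f) {
  n <- nchar(f$region)
  feats <- f$features
  if (nrow(feats) > 0L) {
    new_start <- n - feats$end
    new_end <- n - feats$start
    feats$start <- new_start
    feats$end <- new_end
    feats$strand <- ifelse(feats$strand == "+", "-", "+")
  }
  new_fragment(f$id, revcomp(f$region),
               left_end = f$right_end, right_end = f$left_end,
               features = feats,
               provenance = lapply(rev(f$provenance), function(p) {
                 p$flipped <- !isTRUE(p$flipped); p
               }))
}

# Re-derive the overhang strings of a fragment from its region sequence; used
# by invariant tests (stored sticky ends must be reconstructible).
fragment_rederive_ends <- function(f) {
  mk <- function(end, side) {
    L <- nchar(end$overhang)
    if (end$polarity == "blunt") return(sticky_end("blunt"))
    bases <- if (side == "left") substr(f$region, 1L, L) else
      substr(f$region, nchar(f$region) - L + 1L, nchar(f$region))
    ovh <- if (ovh_on_top(end, side)) bases else revcomp(bases)
    sticky_end(end$polarity, ovh)
  }
  list(left = mk(f$left_end, "left"), right = mk(f$right_end, "right"))
}
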