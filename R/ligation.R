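# Overhang-directed joining of fragments and exhaustive enumeration of
# circular ligation products. The enumeration is the brute-force oracle that
# every designed assembly is checked against: a designed product must be an
# element of the enumeration over the same fragment pool.

#' Collect fragments into a ligation pool
#'
#' Every fragment must carry at least one sticky (non-blunt) end: blunt-only
#' fragments can never circularise in this simulator. Fragment multiplicity
#' defaults to one use per product; to explore tandem-insert artifacts, list
#' a fragment several times.
#'
#' @param fragments list of fragments.
#' @export
ligation_pool <- function(fragments) {
  stopifnot(is.list(fragments), length(fragments) > 0L,
            all(vapply(fragments, inherits, logical(1), "fragment")))
  ok <- vapply(fragments, function(f) {
    f$left_end$polarity != "blunt" || f$right_end$polarity != "blunt"
  }, logical(1))
  if (!all(ok)) {
    stop("ligation pool contains blunt-only fragment(s): ",
         paste(vapply(fragments[!ok], function(f) f$id, character(1)),
               collapse = ", "), call. = FALSE)
  }
  structure(list(fragments = fragments), class = "ligation_pool")
}

#' Join two fragments end-to-end
#'
#' `a`'s right end must be compatible with (oriented) `b`'s left end; the
#' junction duplex is reconstructed so the annealed overhang bases appear
#' exactly once, and the outer ends are preserved.
#'
#' @param a,b fragments.
#' @param orientation_b `"as_is"` or `"flipped"` (reverse-complement `b`
#'   before joining).
#' @export
join_fragments <- function(a, b, orientation_b = c("as_is", "flipped")) {
  orientation_b <- match.arg(orientation_b)
  stopifnot(inherits(a, "fragment"), inherits(b, "fragment"))
  if (orientation_b == "flipped") b <- flip_fragment(b)
  if (!ends_compatible(a$right_end, b$left_end)) {
    stop(sprintf("incompatible ends: right (%s, '%s') cannot ligate to left (%s, '%s')",
                 a$right_end$polarity, a$right_end$overhang,
                 b$left_end$polarity, b$left_end$overhang), call. = FALSE)
  }
  L <- nchar(a$right_end$overhang)
  na <- nchar(a$region)
  region <- paste0(a$region, substr(b$region, L + 1L, nchar(b$region)))
  feats_a <- a$features
  feats_b <- b$features
  if (nrow(feats_b) > 0L) {
    feats_b$start <- feats_b$start + na - L
    feats_b$end <- feats_b$end + na - L
  }
  new_fragment(paste0(a$id, "+", b$id), region,
               left_end = a$left_end, right_end = b$right_end,
               features = rbind(feats_a, feats_b),
               provenance = c(a$provenance, b$provenance))
}

# close a chain fragment into a circular molecule; requires
# ends_compatible(left, right). The shared overhang region is represented at
# both ends of the region string; the right-hand copy is dropped.
circularize_fragment <- function(f, id = f$id) {
  if (!ends_compatible(f$left_end, f$right_end)) {
    stop("fragment ends are not mutually compatible; cannot circularise",
         call. = FALSE)
  }
  L <- nchar(f$left_end$overhang)
  n <- nchar(f$region) - L
  seqn <- substr(f$region, 1L, n)
  feats <- f$features
  if (nrow(feats) > 0L) {
    # features living in the dropped duplicate overhang copy wrap to the start
    shift <- feats$start >= n
    feats$start[shift] <- feats$start[shift] - n
    feats$end[shift] <- feats$end[shift] - n
  }
  dna_molecule(id, seqn, topology = "circular", features = feats)
}

#' Enumerate all circular ligation products of a pool
#'
#' Exhaustive depth-first search over fragment subsets, orders and
#' orientations: every distinct circular product formable from at most
#' `max_fragments` fragments, each pool entry used at most once per product.
#' Self-circularisation of a single fragment is included when its two ends
#' are mutually compatible. Products are deduplicated by canonical form
#' (rotation- and strand-flip-invariant), so each plasmid appears once.
#' Enumeration order is deterministic: pool order, `as_is` before `flipped`.
#'
#' @param pool a [ligation_pool()] (or plain list of fragments).
#' @param max_fragments maximum fragments per product.
#' @param frontier_bound combinatorial guard: error if the number of partial
#'   chains explored exceeds this bound.
#' @return list of `circular_product` objects, each with `$molecule`,
#'   `$composition` (data.frame of fragment id + orientation) and
#'   `$canonical_form`.
#' @export
enumerate_circular <- function(pool, max_fragments = 2L,
                               frontier_bound = 1e6) {
  if (!inherits(pool, "ligation_pool")) pool <- ligation_pool(pool)
  stopifnot(max_fragments >= 1L)
  frs <- pool$fragments
  nf <- length(frs)
  products <- list()
  seen <- character()
  visited <- 0L
  emit <- function(chain, comp) {
    mol <- circularize_fragment(chain, id = paste(comp$fragment, collapse = "+"))
    can <- canonical_string(mol$sequence)
    if (can %in% seen) return()
    seen <<- c(seen, can)
    products[[length(products) + 1L]] <<- structure(
      list(molecule = mol, composition = comp, canonical_form = can),
      class = "circular_product")
  }
  extend <- function(chain, used, comp) {
    visited <<- visited + 1L
    if (visited > frontier_bound) {
      stop(sprintf("ligation enumeration exceeded the frontier bound (%g partial chains)",
                   frontier_bound), call. = FALSE)
    }
    if (ends_compatible(chain$left_end, chain$right_end)) emit(chain, comp)
    if (sum(used) >= max_fragments) return()
    # the chain's first fragment is kept minimal-index, which enumerates each
    # circular arrangement exactly once up to rotation; strand flips are
    # merged by canonical deduplication
    first <- match(TRUE, used)
    for (j in seq_len(nf)) {
      if (used[j] || j <= first) next
      for (ori in c("as_is", "flipped")) {
        fj <- if (ori == "flipped") flip_fragment(frs[[j]]) else frs[[j]]
        if (!ends_compatible(chain$right_end, fj$left_end)) next
        used2 <- used; used2[j] <- TRUE
        extend(join_fragments(chain, fj),
               used2,
               rbind(comp, data.frame(fragment = frs[[j]]$id,
                                      orientation = ori,
                                      stringsAsFactors = FALSE)))
      }
    }
  }
  for (s in seq_len(nf)) {
    for (ori in c("as_is", "flipped")) {
      fs <- if (ori == "flipped") flip_fragment(frs[[s]]) else frs[[s]]
      used <- rep(FALSE, nf); used[s] <- TRUE
      extend(fs, used,
             data.frame(fragment = frs[[s]]$id, orientation = ori,
                        stringsAsFactors = FALSE))
    }
  }
  products
}

#' @export
print.circular_product <- function(x, ...) {
  cat(sprintf("<circular_product> %d bp from %d fragment(s): %s\n",
              nchar(x$molecule$sequence), nrow(x$composition),
              paste(x$composition$fragment, collapse = " + ")))
  invisible(x)
}

#' Does a digest re-ligate back to its parent molecule?
#'
#' Digestion is invertible by ligation: the parent's canonical form must be
#' among the circular products enumerable from its own digest. Used as a
#' round-trip property check on every fixture.
#'
#' @param m circular [dna_molecule()].
#' @param enzymes enzyme name(s).
#' @return logical scalar.
#' @export
religation_check <- function(m, enzymes) {
  stopifnot(is_dna_molecule(m))
  if (m$topology != "circular") {
    stop("religation_check() requires a circular molecule", call. = FALSE)
  }
  frags <- digest(m, enzymes)
  if (isTRUE(attr(frags, "uncut"))) return(TRUE)
  prods <- enumerate_circular(ligation_pool(frags),
                              max_fragments = length(frags))
  target <- canonical_string(m$sequence)
  target %in% vapply(prods, function(p) p$canonical_form, character(1))
}
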