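# GenBank and FASTA ingest/export.
#
# The GenBank dialect written here is deliberately minimal (LOCUS, FEATURES,
# ORIGIN) but round-trips exactly: sequence preserved byte-for-byte, features
# up to qualifier ordering. Internal feature keys map to GenBank keys via the
# table below; unknown GenBank keys fall back to misc_feature on write and to
# the "site" key on read.
#
#   internal key  GenBank key    recognised on read by
#   ------------  -------------  -------------------------------------------
#   origin        rep_origin     key rep_origin
#   marker        CDS            qualifier /ez_key="marker" (or /resistance)
#   ccdb          CDS            qualifier /ez_key="ccdb" or /label="ccdB"
#   cds           CDS            plain CDS
#   part          CDS            qualifier /ez_key="part"
#   rbs           RBS            key RBS
#   stop          misc_feature   qualifier /ez_key="stop"
#   adaptor       misc_feature   qualifier /ez_key="adaptor"
#   site          misc_feature   qualifier /ez_key="site" (and fallback)

gb_key_for <- function(key) {
  switch(key,
         origin = "rep_origin",
         marker = , ccdb = , cds = , part = "CDS",
         rbs = "RBS",
         "misc_feature")
}

#' Write a molecule to a GenBank file
#'
#' Topology is recorded on the LOCUS line; features wrapping the circular
#' origin are emitted as a two-segment `join(..)` location.
#'
#' @param m a [dna_molecule()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_genbank <- function(m, path) {
  stopifnot(is_dna_molecule(m))
  n <- seq_len_mol(m)
  con <- file(path, "w")
  on.exit(close(con))
  topo <- if (m$topology == "circular") "circular" else "linear"
  writeLines(sprintf("LOCUS       %-16s %d bp    DNA     %-8s SYN",
                     substr(m$id, 1L, 16L), n, topo), con)
  writeLines(sprintf("DEFINITION  %s.", m$id), con)
  writeLines("FEATURES             Location/Qualifiers", con)
  feats <- m$features
  if (nrow(feats) > 0L) {
    for (i in seq_len(nrow(feats))) {
      s0 <- feats$start[i]; e0 <- feats$end[i]
      loc <- if (e0 <= n) sprintf("%d..%d", s0 + 1L, e0) else
        sprintf("join(%d..%d,1..%d)", s0 + 1L, n, e0 - n)
      if (feats$strand[i] == "-") loc <- sprintf("complement(%s)", loc)
      writeLines(sprintf("     %-15s %s", gb_key_for(feats$key[i]), loc), con)
      quals <- c(ez_key = feats$key[i], label = feats$label[i],
                 feats$qualifiers[[i]])
      for (qn in names(quals)) {
        writeLines(sprintf("                     /%s=\"%s\"", qn, quals[[qn]]), con)
      }
    }
  }
  writeLines("ORIGIN", con)
  s <- tolower(m$sequence)
  pos <- seq(1L, nchar(s), by = 60L)
  for (p in pos) {
    line <- substr(s, p, min(p + 59L, nchar(s)))
    blocks <- substring(line, seq(1L, nchar(line), 10L),
                        pmin(seq(10L, nchar(line) + 9L, 10L), nchar(line)))
    writeLines(sprintf("%9d %s", p, paste(blocks, collapse = " ")), con)
  }
  writeLines("//", con)
  invisible(path)
}

parse_gb_location <- function(loc, n) {
  strand <- "+"
  if (grepl("^complement\\(", loc)) {
    strand <- "-"
    loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
  }
  if (grepl("^join\\(", loc)) {
    inner <- sub("^join\\((.*)\\)$", "\\1", loc)
    parts <- strsplit(inner, ",", fixed = TRUE)[[1]]
    rng <- lapply(parts, function(p) as.integer(strsplit(p, "..", fixed = TRUE)[[1]]))
    if (length(rng) != 2L || rng[[1]][2] != n || rng[[2]][1] != 1L) {
      stop("only simple origin-wrapping join() locations are supported", call. = FALSE)
    }
    return(list(start = rng[[1]][1] - 1L, end = n + rng[[2]][2], strand = strand))
  }
  se <- as.integer(strsplit(loc, "..", fixed = TRUE)[[1]])
  list(start = se[1] - 1L, end = se[2], strand = strand)
}

gb_internal_key <- function(gbkey, quals) {
  if (!is.null(quals[["ez_key"]]) && quals[["ez_key"]] %in% FEATURE_KEYS) {
    return(quals[["ez_key"]])
  }
  if (gbkey == "rep_origin") return("origin")
  if (gbkey == "RBS") return("rbs")
  if (gbkey == "CDS") {
    if (!is.null(quals[["resistance"]])) return("marker")
    if (identical(quals[["label"]], "ccdB")) return("ccdb")
    if (!is.null(quals[["part"]])) return("part")
    return("cds")
  }
  "site"
}

#' Read a GenBank file
#'
#' Parses the LOCUS topology flag, the feature table (simple and
#' origin-wrapping `join` locations, `complement`) and the ORIGIN sequence.
#'
#' @param path GenBank file path.
#' @return a [dna_molecule()].
#' @export
read_genbank <- function(path) {
  lines <- readLines(path, warn = FALSE)
  locus <- grep("^LOCUS", lines, value = TRUE)[1]
  if (is.na(locus)) stop("not a GenBank file: no LOCUS line", call. = FALSE)
  toks <- strsplit(trimws(locus), "\\s+")[[1]]
  id <- toks[2]
  topology <- if (any(tolower(toks) == "circular")) "circular" else "linear"
  ori_i <- grep("^ORIGIN", lines)[1]
  end_i <- grep("^//", lines)[1]
  if (is.na(ori_i)) stop("no ORIGIN section", call. = FALSE)
  if (is.na(end_i)) end_i <- length(lines) + 1L
  seq_lines <- lines[(ori_i + 1L):(end_i - 1L)]
  seqn <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))
  n <- nchar(seqn)
  # feature block
  f_i <- grep("^FEATURES", lines)[1]
  feats <- empty_features()
  if (!is.na(f_i) && f_i + 1L < ori_i) {
    block <- lines[(f_i + 1L):(ori_i - 1L)]
    cur <- NULL
    rows <- list()
    flush <- function(cur) {
      if (is.null(cur)) return()
      quals <- cur$quals
      loc <- parse_gb_location(cur$loc, n)
      lab <- if (!is.null(quals[["label"]])) quals[["label"]] else ""
      key <- gb_internal_key(cur$key, quals)
      quals <- quals[setdiff(names(quals), c("ez_key", "label"))]
      rows[[length(rows) + 1L]] <<- feature_table(
        key = key, label = lab, start = loc$start, end = loc$end,
        strand = loc$strand,
        qualifiers = list(if (length(quals)) unlist(quals) else character()))
    }
    for (ln in block) {
      if (grepl("^     \\S", ln)) {
        flush(cur)
        toks <- strsplit(trimws(ln), "\\s+")[[1]]
        cur <- list(key = toks[1], loc = paste(toks[-1], collapse = ""),
                    quals = list())
      } else if (grepl("^\\s+/", ln)) {
        q <- sub("^\\s+/", "", ln)
        eq <- regexpr("=", q, fixed = TRUE)
        if (eq > 0L) {
          qn <- substr(q, 1L, eq - 1L)
          qv <- gsub("^\"|\"$", "", substr(q, eq + 1L, nchar(q)))
          cur$quals[[qn]] <- qv
        } else {
          cur$quals[[q]] <- ""
        }
      } else if (!is.null(cur) && grepl("^\\s+\\S", ln) &&
                 !grepl("/", ln, fixed = TRUE)) {
        cur$loc <- paste0(cur$loc, trimws(ln))
      }
    }
    flush(cur)
    if (length(rows)) feats <- do.call(rbind, rows)
  }
  dna_molecule(id, seqn, topology = topology, features = feats)
}

#' Read unannotated parts from a FASTA file
#'
#' Topology defaults to linear; pass `circular = TRUE` to override for all
#' records.
#'
#' @param path FASTA file path.
#' @param circular logical override flag.
#' @return list of [dna_molecule()] objects.
#' @export
read_fasta_parts <- function(path, circular = FALSE) {
  xs <- Biostrings::readDNAStringSet(path)
  lapply(seq_along(xs), function(i) {
    dna_molecule(strsplit(names(xs)[i], "\\s+")[[1]][1],
                 as.character(xs[[i]]),
                 topology = if (circular) "circular" else "linear")
  })
}
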