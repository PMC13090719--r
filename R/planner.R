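# Build planning and execution: turn an ordered part list into a validated
# multi-cycle plan, execute it in simulation, and verify reading frame and
# single-residue scars on the final ORF.
#
# The plan is a *static* predictor: predicted intermediates and the final
# ORF are computed by direct construction (build_reference_pz on part
# prefixes), independently of the cycle simulator; simulate_build() then
# executes the digestion-ligation-selection pipeline and the two routes are
# required to agree exactly.

plan_contexts <- function(parts, config) {
  cfg <- config
  cfg$allow_stray <- TRUE
  k <- length(parts)
  donors <- lapply(seq_len(k), function(i) {
    kind <- if (parts[[i]]$role == "linker") "pL" else "pD"
    build_reference_donor(parts[[i]], marker_for_cycle(i, cfg), kind, cfg,
                          cycle = i)
  })
  pz_final <- build_reference_pz(parts, marker_for_cycle(k, cfg), cfg)
  c(donors, list(pz_final))
}

# synonymous edits of part codons until no stray recognition pattern exists
# in any context a part appears in (its donor, and the assembled ORF).
# Edits are propagated to every identical copy of a part so repeated parts
# stay sequence-identical.
repair_parts_in_context <- function(parts, config, max_iter = 200L) {
  syn <- codons_by_aa()
  for (iter in seq_len(max_iter)) {
    mols <- plan_contexts(parts, config)
    fixed_any <- FALSE
    for (m in mols) {
      stray <- find_stray_sites(m)
      if (nrow(stray) == 0L) next
      segmap <- attr(m, "segmap")
      h <- stray[1L, ]
      psegs <- which(grepl("^part[0-9]+$", segmap$name) &
                       segmap$start < h$end & segmap$end > h$start)
      done <- FALSE
      for (sgi in psegs) {
        pidx <- as.integer(sub("part", "", segmap$name[sgi]))
        # donors hold the single part as 'part1'; map via molecule identity
        if (length(mols) > 1L && !identical(m$id, mols[[length(mols)]]$id) &&
            segmap$name[sgi] == "part1") {
          pidx <- match(m$id, vapply(mols[-length(mols)], `[[`, character(1),
                                     "id"))
        }
        p <- parts[[pidx]]
        seg_start <- segmap$start[sgi]
        c0 <- max(0L, (h$start - seg_start) %/% 3L)
        c1 <- min(nchar(p$cds) %/% 3L - 1L, (h$end - 1L - seg_start) %/% 3L)
        if (c1 < c0) next
        for (ci in c0:c1) {
          old <- substr(p$cds, 3L * ci + 1L, 3L * ci + 3L)
          aa <- unname(Biostrings::GENETIC_CODE[old])
          for (alt in setdiff(syn[[aa]], old)) {
            cand <- paste0(substr(p$cds, 1L, 3L * ci), alt,
                           substr(p$cds, 3L * ci + 4L, nchar(p$cds)))
            mut <- m$sequence
            substr(mut, seg_start + 3L * ci + 1L, seg_start + 3L * ci + 3L) <- alt
            if (substr(paste0(mut, substr(mut, 1L, 8L)),
                       h$start + 1L, h$end) != h$pattern) {
              newp <- new_part(p$id, cand, role = p$role)
              same <- vapply(parts, function(q) {
                identical(q$id, p$id) && identical(q$cds, p$cds)
              }, logical(1))
              parts[same] <- list(newp)
              done <- TRUE
              break
            }
          }
          if (done) break
        }
        if (done) break
      }
      if (!done) {
        stop(sprintf("stray site %s at %d (%s) in '%s' cannot be removed by synonymous edits",
                     h$pattern, h$start, h$segments, m$id), call. = FALSE)
      }
      fixed_any <- TRUE
      break
    }
    if (!fixed_any) return(parts)
  }
  stop("context repair did not converge", call. = FALSE)
}

#' Plan a multi-cycle build
#'
#' One assembly cycle per part under the period-2 schedule: junction enzymes
#' alternate SapI/BtsI, backbone enzymes BsaI/BbsI, resistance markers over
#' the two-letter alphabet. Part sequences are domesticated in context
#' (synonymous edits only) so that no reference molecule of the plan carries
#' a recognition site outside its designed cassettes. The plan predicts the
#' final ORF, the final protein with its scar residues, and the
#' analytical-digest sizes of every intermediate, all by static construction.
#'
#' @param parts non-empty ordered list of domain/linker [new_part()]s.
#' @param config an [ez_config()].
#' @return a `build_plan` with `$steps`, `$marker_schedule`, `$parts`
#'   (context-repaired), `$donors`, `$pz0`, `$predicted_intermediates`,
#'   `$final_orf`, `$final_protein`, `$scar_positions`, `$config`.
#' @export
plan_build <- function(parts, config = ez_config()) {
  if (!is.list(parts) || length(parts) == 0L) {
    stop("part list must be non-empty", call. = FALSE)
  }
  if (inherits(parts, "ez_part")) parts <- list(parts)
  stopifnot(all(vapply(parts, inherits, logical(1), "ez_part")))
  bad <- !vapply(parts, function(p) p$role %in% c("domain", "linker"), logical(1))
  if (any(bad)) {
    stop("only domain/linker parts enter the reading-frame build", call. = FALSE)
  }
  k <- length(parts)
  # junction clash check: consecutive cycles must not expose identical
  # overhangs with the same enzyme (part skipping); the default alternating
  # schedule never does
  for (i in seq_len(k - 1L)) {
    j1 <- junction_for_cycle(i, config); j2 <- junction_for_cycle(i + 1L, config)
    if (j1 == j2 &&
        scar_overhang_for(j1, config) == scar_overhang_for(j2, config)) {
      stop(sprintf("junction clash between cycles %d and %d: identical overhangs would permit part skipping",
                   i, i + 1L), call. = FALSE)
    }
  }
  parts <- repair_parts_in_context(parts, config)
  steps <- data.frame(
    cycle = seq_len(k),
    part_id = vapply(parts, `[[`, character(1), "id"),
    role = vapply(parts, `[[`, character(1), "role"),
    junction_enzyme = vapply(seq_len(k), junction_for_cycle, character(1),
                             config),
    pz_backbone_enzyme = vapply(seq_len(k), pz_backbone_for_cycle,
                                character(1), config),
    donor_backbone_enzyme = vapply(seq_len(k), donor_backbone_for_cycle,
                                   character(1), config),
    marker = vapply(seq_len(k), marker_for_cycle, character(1), config),
    stringsAsFactors = FALSE)
  donors <- lapply(seq_len(k), function(i) {
    kind <- if (parts[[i]]$role == "linker") "pL" else "pD"
    build_reference_donor(parts[[i]], steps$marker[i], kind, config, cycle = i)
  })
  pz0 <- build_reference_pz(list(), marker_for_cycle(0L, config), config)
  predicted <- lapply(seq_len(k), function(i) {
    pzi <- build_reference_pz(parts[seq_len(i)], steps$marker[i], config)
    qc <- analytical_digest(pzi, c(junction_for_cycle(i + 1L, config),
                                   pz_backbone_for_cycle(i + 1L, config)))
    qc$size_bp
  })
  cds_list <- vapply(parts, `[[`, character(1), "cds")
  final_orf <- paste0(config$start_overhang,
                      paste(cds_list, collapse = config$scar_codon))
  final_protein <- translate_dna(final_orf)
  scar_positions <- if (k > 1L) {
    1L + cumsum(nchar(cds_list[-k]) %/% 3L) + seq_len(k - 1L)
  } else integer()
  structure(list(steps = steps, marker_schedule = steps$marker,
                 parts = parts, donors = donors, pz0 = pz0,
                 predicted_intermediates = predicted,
                 final_orf = final_orf, final_protein = final_protein,
                 scar_positions = scar_positions, config = config),
            class = "build_plan")
}

#' @export
print.build_plan <- function(x, ...) {
  cat(sprintf("<build_plan> %d cycle(s): %s\n", nrow(x$steps),
              paste(sprintf("%s(%s)", x$steps$part_id, x$steps$marker),
                    collapse = " -> ")))
  invisible(x)
}

#' Execute a build plan through the cycle simulator
#'
#' Runs [run_cycle()] once per part starting from the empty reference pZ,
#' asserting a unique surviving product class at every step, then checks the
#' final ORF against the plan's static prediction, produces the per-
#' intermediate analytical-digest (virtual gel) table, and verifies scars.
#'
#' @param plan a [plan_build()] result.
#' @param config configuration (defaults to the plan's).
#' @return `build_result` with `$final_plasmid`, `$intermediates`,
#'   `$qc_tables`, `$scar_report`.
#' @export
simulate_build <- function(plan, config = plan$config) {
  stopifnot(inherits(plan, "build_plan"))
  pz <- plan$pz0
  k <- nrow(plan$steps)
  qc <- vector("list", k)
  intermediates <- vector("list", k)
  for (i in seq_len(k)) {
    res <- run_cycle(pz, plan$donors[[i]], cycle_spec_for(i, config), config)
    if (res$status != "ok") {
      stop(sprintf("build aborted at step %d (%s): %s\n%s", i,
                   plan$steps$part_id[i], res$status,
                   paste(utils::capture.output(
                     print(res$diagnostics$discard_reasons)), collapse = "\n")),
           call. = FALSE)
    }
    pz <- res$output_pz
    intermediates[[i]] <- pz
    qc[[i]] <- analytical_digest(pz, c(junction_for_cycle(i + 1L, config),
                                       pz_backbone_for_cycle(i + 1L, config)))
  }
  orf <- orf_sequence(pz)
  if (!identical(orf, plan$final_orf)) {
    stop("simulated final ORF does not match the planned ORF", call. = FALSE)
  }
  structure(list(final_plasmid = pz, intermediates = intermediates,
                 qc_tables = qc,
                 scar_report = verify_orf(pz, plan$parts, config)),
            class = "build_result")
}

orf_sequence <- function(m) {
  f <- m$features
  oi <- which(f$key == "cds" & f$label == "orf")
  if (length(oi) != 1L) {
    stop("molecule must carry exactly one ORF feature", call. = FALSE)
  }
  circ_substr(m$sequence, f$start[oi], f$end[oi] - f$start[oi])
}

#' Verify reading frame and scars of an assembled ORF
#'
#' The ORF must be a whole number of codons and its translation must
#' decompose as the interleaving of the part translations with exactly one
#' scar residue per inter-part junction (none before the first part, whose
#' fusion reuses the ATG start codon as the overhang). Any deviation is
#' reported with the first out-of-frame junction.
#'
#' @param final_plasmid assembled plasmid carrying one ORF feature.
#' @param parts the ordered parts of the build.
#' @param config optional [ez_config()]; when given, each junction is
#'   annotated with the enzyme that formed it under the schedule.
#' @return `scar_report`: list with `$junctions` (data.frame: junction
#'   index, protein position, scar residue, junction enzyme),
#'   `$scar_count_per_junction`, `$n_junctions`, `$protein`.
#' @export
verify_orf <- function(final_plasmid, parts, config = NULL) {
  orf <- orf_sequence(final_plasmid)
  if (nchar(orf) %% 3L != 0L) {
    stop(sprintf("frameshift: ORF length %d is not divisible by 3", nchar(orf)),
         call. = FALSE)
  }
  prot <- translate_dna(orf)
  if (substr(prot, 1L, 1L) != "M") {
    stop("ORF does not begin with the ATG start codon", call. = FALSE)
  }
  k <- length(parts)
  ptr <- 1L
  rows <- list()
  for (j in seq_len(k)) {
    pj <- parts[[j]]$protein
    got <- substr(prot, ptr + 1L, ptr + nchar(pj))
    if (!identical(got, pj)) {
      stop(sprintf("frameshift or part mismatch at junction %d (part '%s')",
                   j, parts[[j]]$id), call. = FALSE)
    }
    ptr <- ptr + nchar(pj)
    if (j < k) {
      rows[[j]] <- data.frame(junction = j, protein_position = ptr + 1L,
                              scar_residue = substr(prot, ptr + 1L, ptr + 1L),
                              junction_enzyme = if (is.null(config))
                                NA_character_ else
                                junction_for_cycle(j + 1L, config),
                              stringsAsFactors = FALSE)
      ptr <- ptr + 1L
    }
  }
  if (ptr != nchar(prot)) {
    stop("ORF translation extends beyond the final part", call. = FALSE)
  }
  junctions <- if (length(rows)) do.call(rbind, rows) else
    data.frame(junction = integer(), protein_position = integer(),
               scar_residue = character(), junction_enzyme = character(),
               stringsAsFactors = FALSE)
  structure(list(junctions = junctions,
                 scar_count_per_junction = if (k > 1L) 1L else 0L,
                 n_junctions = max(0L, k - 1L), protein = prot),
            class = "scar_report")
}

#' @export
print.scar_report <- function(x, ...) {
  cat(sprintf("<scar_report> %d junction(s), %d scar residue(s) each\n",
              x$n_junctions, x$scar_count_per_junction))
  if (nrow(x$junctions)) print(x$junctions)
  invisible(x)
}
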