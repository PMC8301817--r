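# Domain-architecture analysis: turn profile hits into an architecture call
# (helicase core, Domain 4 state, HTH_42, Cys-rich C-terminus, intein
# insertion), assign each protein to one of the six Lhr groups from
# architecture + taxon, extract the merged RecA1+RecA2 helicase core, and
# apply the Sfth (outgroup family) three-domain filter.

CORE_PROFILES <- c("PF00270", "PF00271")
DOMAIN4_PROFILE <- "PF08494"
HTH42_PROFILE <- "PF06224"
INTEIN_PROFILE <- "PF14890"
SFTH_PROFILES <- c("PF00270", "PF09369", "PF00271")

FAMILY_LABELS <- c("aLhr1", "aLhr2", "aLhr3", "bLhr", "bLhr-HTH",
                   "Lhr-like", "unclassified")

#' Architecture classifier parameters
#'
#' @param domain4_intact_min_coverage a Domain 4 hit covering at least this
#'   fraction of the profile counts as intact (default 0.50); hits below it
#'   count as deteriorated.
#' @param domain4_report_max_evalue hits above this E-value are ignored
#'   entirely, i.e. Domain 4 is called absent (default 1e-3).
#' @param cys_rich_window residues inspected after the Domain 4 end (or the
#'   last core-domain end when Domain 4 is absent) for the cysteine-rich
#'   motif (default 120).
#' @param cys_rich_min_count minimum cysteines in the window (default 4).
#' @return object of class `classifier_params`.
#' @export
classifier_params <- function(domain4_intact_min_coverage = 0.50,
                              domain4_report_max_evalue = 1e-3,
                              cys_rich_window = 120L,
                              cys_rich_min_count = 4L) {
  stopifnot(domain4_intact_min_coverage > 0, domain4_report_max_evalue > 0,
            cys_rich_window > 0, cys_rich_min_count > 0)
  structure(list(domain4_intact_min_coverage = domain4_intact_min_coverage,
                 domain4_report_max_evalue = domain4_report_max_evalue,
                 cys_rich_window = as.integer(cys_rich_window),
                 cys_rich_min_count = as.integer(cys_rich_min_count)),
            class = "classifier_params")
}

best_profile_hit <- function(hits, profile_id) {
  h <- hits[hits$profile_id == profile_id, , drop = FALSE]
  if (nrow(h) == 0L) return(NULL)
  o <- order(h$e_value, -h$coverage, h$q_start)
  h[o[1], , drop = FALSE]
}

#' Call the domain architecture of one protein
#'
#' @param protein one-row data.frame (or list) with `protein_id` and
#'   `sequence`.
#' @param hits profile-hit rows for this protein only.
#' @param params a [classifier_params()].
#' @return one-row data.frame: `protein_id`, `has_core`, `domain4_status`
#'   (`intact` / `deteriorated` / `absent`), `has_hth42`,
#'   `has_cys_rich_cterm`, `intein_inserted`.
#' @export
call_architecture <- function(protein, hits, params = classifier_params()) {
  pid <- protein$protein_id
  if (nrow(hits) > 0L && any(hits$protein_id != pid))
    stop_input("hits reference other proteins than ", pid)
  prof <- hits$profile_id
  has_core <- all(CORE_PROFILES %in% prof)

  d4 <- hits[hits$profile_id == DOMAIN4_PROFILE &
             hits$e_value <= params$domain4_report_max_evalue, ,
             drop = FALSE]
  if (nrow(d4) == 0L) {
    domain4_status <- "absent"
    d4_end <- NA_integer_
  } else {
    domain4_status <- if (any(d4$coverage >=
                              params$domain4_intact_min_coverage))
      "intact" else "deteriorated"
    d4_end <- max(d4$q_end)
  }

  has_hth42 <- HTH42_PROFILE %in% prof

  # cysteine-rich window starts after Domain 4 (or the last core hit)
  anchor <- if (!is.na(d4_end)) d4_end else {
    core <- hits[hits$profile_id %in% CORE_PROFILES, , drop = FALSE]
    if (nrow(core) > 0L) max(core$q_end) else 0L
  }
  seqlen <- nchar(protein$sequence)
  cys <- 0L
  if (anchor < seqlen && anchor >= 0L) {
    win <- substr(protein$sequence, anchor + 1L,
                  min(seqlen, anchor + params$cys_rich_window))
    cys <- lengths(regmatches(win, gregexpr("C", win, fixed = TRUE)))
  }
  has_cys <- cys >= params$cys_rich_min_count

  # intein: an insertion-domain hit nested inside a core-domain interval
  intein <- FALSE
  it <- hits[hits$profile_id == INTEIN_PROFILE, , drop = FALSE]
  if (nrow(it) > 0L) {
    core <- hits[hits$profile_id %in% CORE_PROFILES, , drop = FALSE]
    for (r in seq_len(nrow(it))) {
      if (any(it$q_start[r] >= core$q_start & it$q_end[r] <= core$q_end)) {
        intein <- TRUE
        break
      }
    }
  }

  data.frame(protein_id = pid, has_core = has_core,
             domain4_status = domain4_status, has_hth42 = has_hth42,
             has_cys_rich_cterm = has_cys, intein_inserted = intein,
             stringsAsFactors = FALSE)
}

#' Architecture calls for a whole protein table
#' @param proteins data.frame with `protein_id`, `sequence`.
#' @param hits profile-hit data.frame.
#' @param params a [classifier_params()].
#' @return data.frame, one architecture call per protein.
#' @export
call_architectures <- function(proteins, hits,
                               params = classifier_params()) {
  out <- lapply(seq_len(nrow(proteins)), function(i) {
    p <- proteins[i, , drop = FALSE]
    call_architecture(p, hits[hits$protein_id == p$protein_id, ,
                              drop = FALSE], params)
  })
  do.call(rbind, out)
}

#' Assign a protein to one of the six Lhr groups
#'
#' Decision rules over (Domain 4 state, taxon, HTH_42, Cys-rich):
#' no helicase core: unclassified; Domain 4 absent: Lhr-like (any taxon);
#' Bacteria with intact Domain 4: bLhr-HTH if HTH_42 else bLhr; Bacteria
#' with deteriorated Domain 4: Lhr-like; Archaea/Asgard with intact
#' Domain 4: aLhr1 if Cys-rich else aLhr2 (HTH_42 permitted); Archaea/
#' Asgard with deteriorated Domain 4: aLhr3. Total over all valid calls.
#'
#' @param call one-row architecture call ([call_architecture()]).
#' @param taxon_group `Archaea`, `Bacteria` or `Asgard`.
#' @param cluster_id optional cluster index carried into the output.
#' @return one-row data.frame: `protein_id`, `label`, `cluster_id` plus the
#'   evidence columns of the call.
#' @export
classify_family <- function(call, taxon_group, cluster_id = NA_integer_) {
  stopifnot(taxon_group %in% c("Archaea", "Bacteria", "Asgard"))
  archaeal <- taxon_group %in% c("Archaea", "Asgard")
  label <- if (!call$has_core) {
    "unclassified"
  } else if (call$domain4_status == "absent") {
    "Lhr-like"
  } else if (!archaeal) {
    if (call$domain4_status == "intact") {
      if (call$has_hth42) "bLhr-HTH" else "bLhr"
    } else "Lhr-like"
  } else {
    if (call$domain4_status == "intact") {
      if (call$has_cys_rich_cterm) "aLhr1" else "aLhr2"
    } else "aLhr3"
  }
  out <- call
  out$label <- label
  out$taxon_group <- taxon_group
  out$cluster_id <- cluster_id
  out[, c("protein_id", "label", "taxon_group", "cluster_id",
          setdiff(names(call), "protein_id"))]
}

#' Family assignments for a whole protein table
#'
#' Default mode applies the per-protein rules. In cluster-consensus mode
#' (`consensus = TRUE` and `cluster_of` given) every cluster is labeled by
#' the majority per-protein label of its members (ties: alphabetically
#' first) and members inherit it.
#'
#' @param proteins data.frame with `protein_id`, `sequence`, `taxon_group`.
#' @param hits profile-hit data.frame.
#' @param params a [classifier_params()].
#' @param cluster_of optional named cluster map carried into the output.
#' @param consensus use cluster-majority labels (requires `cluster_of`).
#' @return data.frame of assignments.
#' @export
classify_families <- function(proteins, hits, params = classifier_params(),
                              cluster_of = NULL, consensus = FALSE) {
  calls <- call_architectures(proteins, hits, params)
  rows <- lapply(seq_len(nrow(calls)), function(i) {
    cl <- if (is.null(cluster_of)) NA_integer_ else
      unname(cluster_of[calls$protein_id[i]])
    classify_family(calls[i, , drop = FALSE],
                    proteins$taxon_group[i], cl)
  })
  out <- do.call(rbind, rows)
  if (consensus) {
    if (is.null(cluster_of)) stop_input("consensus mode needs cluster_of")
    for (k in unique(out$cluster_id)) {
      idx <- which(out$cluster_id == k)
      tab <- sort(table(out$label[idx]), decreasing = TRUE)
      maj <- sort(names(tab)[tab == max(tab)])[1]
      out$label[idx] <- maj
    }
  }
  rownames(out) <- NULL
  out
}

#' Extract the merged RecA1+RecA2 helicase core
#'
#' Takes the best (lowest E-value; ties by coverage then position) hit of
#' each core profile, merges overlapping intervals, and concatenates the
#' covered subsequences in protein coordinate order.
#'
#' @param protein one-row data.frame (or list) with `protein_id`,
#'   `sequence`.
#' @param hits profile-hit rows for this protein.
#' @return the merged core sequence (character scalar).
#' @export
extract_helicase_core <- function(protein, hits) {
  b1 <- best_profile_hit(hits, CORE_PROFILES[1])
  b2 <- best_profile_hit(hits, CORE_PROFILES[2])
  if (is.null(b1) || is.null(b2))
    stop_input("protein ", protein$protein_id,
               " lacks a core-domain hit (PF00270/PF00271)")
  iv <- interval_union(c(b1$q_start, b2$q_start), c(b1$q_end, b2$q_end))
  paste(vapply(seq_len(nrow(iv)), function(r)
    substr(protein$sequence, iv[r, 1], iv[r, 2]), character(1)),
    collapse = "")
}

#' Merged-core sequences for many proteins
#' @param proteins data.frame with `protein_id`, `sequence`.
#' @param hits profile-hit data.frame.
#' @return named character vector of merged cores.
#' @export
extract_helicase_cores <- function(proteins, hits) {
  out <- vapply(seq_len(nrow(proteins)), function(i) {
    p <- proteins[i, , drop = FALSE]
    extract_helicase_core(p, hits[hits$protein_id == p$protein_id, ,
                                  drop = FALSE])
  }, character(1))
  setNames(out, proteins$protein_id)
}

#' Sfth outgroup filter: require the three diagnostic domains
#'
#' Retains proteins carrying hits to all of PF00270 (DEAD), PF09369
#' (DUF1998) and PF00271 (Helicase_C) — the architecture of the Sfth
#' helicase family (COG1205), the closest relative of Lhr used as the
#' outgroup.
#'
#' @param proteins data.frame with `protein_id`.
#' @param hits profile-hit data.frame.
#' @return sorted character vector of retained protein ids.
#' @export
filter_sfth <- function(proteins, hits) {
  ok <- vapply(proteins$protein_id, function(id) {
    prof <- hits$profile_id[hits$protein_id == id]
    all(SFTH_PROFILES %in% prof)
  }, logical(1))
  sort(proteins$protein_id[ok])
}

#' Per-genome family paralog counts
#'
#' @param assignments data.frame with `protein_id`, `label`.
#' @param genomes named character vector mapping protein_id to genome id.
#' @return data.frame, one row per genome, one column per family label
#'   (all of [FAMILY_LABELS] except `unclassified` unless present), row
#'   sums equal the genome's classified protein count.
#' @export
tabulate_paralog_counts <- function(assignments, genomes) {
  g <- unname(genomes[assignments$protein_id])
  labs <- sort(unique(assignments$label))
  tab <- table(factor(g, levels = sort(unique(g))),
               factor(assignments$label, levels = labs))
  df <- as.data.frame.matrix(tab)
  df <- cbind(genome_id = rownames(df), df, stringsAsFactors = FALSE)
  rownames(df) <- NULL
  df
}

#' Write family assignments and an iTOL-ready architecture table
#'
#' @param assignments data.frame from [classify_families()].
#' @param path TSV path.
#' @return the path, invisibly.
#' @export
write_assignments_tsv <- function(assignments, path) {
  write.table(assignments, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
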