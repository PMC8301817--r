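# Gene-neighborhood microsynteny: genes within a base-pair window of a
# focal gene, conservation of neighbor annotations across genomes, and
# co-occurrence contingency between two focal families.

#' Context parameters
#' @param window_bp neighborhood window in bp (default 4000): a gene is a
#'   neighbor when fewer than `window_bp` bases separate its interval from
#'   the focal gene's (0 for overlapping or bookended intervals).
#' @return object of class `context_params`.
#' @export
context_params <- function(window_bp = 4000L) {
  if (window_bp <= 0) stop_input("window_bp must be positive")
  structure(list(window_bp = as.integer(window_bp)),
            class = "context_params")
}

interval_gap <- function(s1, e1, s2, e2) {
  pmax(0L, pmax(s1, s2) - pmin(e1, e2) - 1L)
}

#' Gene neighborhood of a focal feature
#'
#' Returns the features on the focal gene's contig (excluding itself) whose
#' interval lies less than `window_bp` bases away (gap 0 for overlap),
#' annotated with the side relative to the focal gene's strand (`upstream`
#' = 5' of the focal gene on its own strand) and the orientation of the
#' neighbor (`same` / `reverse`).
#'
#' @param features data.frame of gene features (columns `genome_id`,
#'   `contig_id`, `feature_id`, `start`, `end`, `strand`,
#'   `product_profile`).
#' @param focal_id `feature_id` of the focal gene (must be present).
#' @param params a [context_params()].
#' @return subset of `features` with added `gap_bp`, `side`, `orientation`
#'   columns, sorted by `gap_bp`.
#' @export
neighborhood <- function(features, focal_id, params = context_params()) {
  idx <- which(features$feature_id == focal_id)
  if (length(idx) != 1L)
    stop_input("focal feature not found (or ambiguous): ", focal_id)
  f <- features[idx, ]
  cand <- features[features$contig_id == f$contig_id &
                   features$feature_id != focal_id, , drop = FALSE]
  if (nrow(cand) == 0L) {
    out <- cand
    out$gap_bp <- integer(0); out$side <- character(0)
    out$orientation <- character(0)
    return(out)
  }
  gap <- interval_gap(cand$start, cand$end, f$start, f$end)
  keep <- gap < params$window_bp
  out <- cand[keep, , drop = FALSE]
  out$gap_bp <- gap[keep]
  left <- out$end < f$start  # 5' side in contig coordinates
  side_plus <- ifelse(left, "upstream",
                      ifelse(out$start > f$end, "downstream", "overlap"))
  if (f$strand == "-") {
    side_plus <- ifelse(side_plus == "upstream", "downstream",
                        ifelse(side_plus == "downstream", "upstream",
                               side_plus))
  }
  out$side <- side_plus
  out$orientation <- ifelse(out$strand == f$strand, "same", "reverse")
  out <- out[order(out$gap_bp, out$feature_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Cross-genome conservation of neighbor annotations
#'
#' For every (focal family, neighbor profile) pair, counts the genomes in
#' which at least one focal gene of that family has a neighbor carrying the
#' profile in-window, over the genomes carrying the family at all, with
#' side and orientation breakdowns.
#'
#' @param features gene-feature data.frame over all genomes.
#' @param focal_family_of named vector mapping focal `feature_id` to a
#'   family label; features absent from the map are treated as non-focal.
#' @param params a [context_params()].
#' @return data.frame with one row per (family, neighbor profile):
#'   `family`, `neighbor_profile`, `n_genomes_with_neighbor`,
#'   `n_genomes_with_family`, `fraction`, `n_upstream`, `n_downstream`,
#'   `n_same_strand`, `n_reverse_strand`; sorted by family then fraction
#'   descending.
#' @export
conservation_profile <- function(features, focal_family_of,
                                 params = context_params()) {
  focal_ids <- intersect(names(focal_family_of), features$feature_id)
  rows <- list()
  for (fid in focal_ids) {
    fam <- unname(focal_family_of[fid])
    genome <- features$genome_id[features$feature_id == fid][1]
    nb <- neighborhood(features, fid, params)
    if (nrow(nb) > 0L) {
      profs <- strsplit(nb$product_profile, ",", fixed = TRUE)
      for (i in seq_len(nrow(nb))) {
        for (pr in profs[[i]]) {
          rows[[length(rows) + 1L]] <- data.frame(
            family = fam, genome_id = genome, neighbor_profile = pr,
            side = nb$side[i], orientation = nb$orientation[i],
            stringsAsFactors = FALSE)
        }
      }
    }
    rows[[length(rows) + 1L]] <- data.frame(
      family = fam, genome_id = genome, neighbor_profile = NA_character_,
      side = NA_character_, orientation = NA_character_,
      stringsAsFactors = FALSE)
  }
  long <- do.call(rbind, rows)
  if (is.null(long)) {
    return(data.frame(family = character(), neighbor_profile = character(),
                      n_genomes_with_neighbor = integer(),
                      n_genomes_with_family = integer(),
                      fraction = numeric(), n_upstream = integer(),
                      n_downstream = integer(), n_same_strand = integer(),
                      n_reverse_strand = integer(),
                      stringsAsFactors = FALSE))
  }
  out <- list()
  for (fam in sort(unique(long$family))) {
    sub <- long[long$family == fam, , drop = FALSE]
    total <- length(unique(sub$genome_id))
    obs <- sub[!is.na(sub$neighbor_profile), , drop = FALSE]
    for (pr in sort(unique(obs$neighbor_profile))) {
      ss <- obs[obs$neighbor_profile == pr, , drop = FALSE]
      out[[length(out) + 1L]] <- data.frame(
        family = fam, neighbor_profile = pr,
        n_genomes_with_neighbor = length(unique(ss$genome_id)),
        n_genomes_with_family = total,
        fraction = length(unique(ss$genome_id)) / total,
        n_upstream = sum(ss$side == "upstream"),
        n_downstream = sum(ss$side == "downstream"),
        n_same_strand = sum(ss$orientation == "same"),
        n_reverse_strand = sum(ss$orientation == "reverse"),
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L) {
    return(data.frame(family = character(), neighbor_profile = character(),
                      n_genomes_with_neighbor = integer(),
                      n_genomes_with_family = integer(),
                      fraction = numeric(), n_upstream = integer(),
                      n_downstream = integer(), n_same_strand = integer(),
                      n_reverse_strand = integer(),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res <- res[order(res$family, -res$fraction, res$neighbor_profile), ,
             drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Genome-level co-occurrence of a neighbor profile near two families
#'
#' Builds the 2x2 contingency over genomes carrying both focal families:
#' neighbor in-window near family A only, near B only, near both, near
#' neither. The mutual-exclusivity flag is set when the `both` cell is 0
#' while both exclusive cells are non-zero.
#'
#' @param features gene-feature data.frame.
#' @param focal_family_of named family map as in [conservation_profile()].
#' @param family_a,family_b the two family labels.
#' @param neighbor_profile profile id of the neighbor gene.
#' @param params a [context_params()].
#' @return list with `counts` (named vector `A_only`, `B_only`, `both`,
#'   `neither`), `n_genomes`, and a `mutually_exclusive` flag.
#' @export
cooccurrence_summary <- function(features, focal_family_of, family_a,
                                 family_b, neighbor_profile,
                                 params = context_params()) {
  has_profile_near <- function(fid) {
    nb <- neighborhood(features, fid, params)
    if (nrow(nb) == 0L) return(FALSE)
    any(vapply(strsplit(nb$product_profile, ",", fixed = TRUE),
               function(p) neighbor_profile %in% p, logical(1)))
  }
  focal_ids <- intersect(names(focal_family_of), features$feature_id)
  gmap <- setNames(features$genome_id[match(focal_ids,
                                            features$feature_id)],
                   focal_ids)
  fams <- focal_family_of[focal_ids]
  genomes_a <- unique(gmap[fams == family_a])
  genomes_b <- unique(gmap[fams == family_b])
  genomes <- intersect(genomes_a, genomes_b)
  near <- function(genome, fam) {
    ids <- focal_ids[fams == fam & gmap == genome]
    any(vapply(ids, has_profile_near, logical(1)))
  }
  a_near <- vapply(genomes, near, logical(1), fam = family_a)
  b_near <- vapply(genomes, near, logical(1), fam = family_b)
  counts <- c(A_only = sum(a_near & !b_near), B_only = sum(!a_near & b_near),
              both = sum(a_near & b_near),
              neither = sum(!a_near & !b_near))
  list(counts = counts, n_genomes = length(genomes),
       mutually_exclusive = counts[["both"]] == 0 &&
         counts[["A_only"]] > 0 && counts[["B_only"]] > 0)
}

#' Write the conservation table as TSV
#' @param table output of [conservation_profile()].
#' @param path file path.
#' @return the path, invisibly.
#' @export
write_conservation_tsv <- function(table, path) {
  write.table(table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export gene neighborhoods as an iTOL DATASET_DOMAINS-style file
#'
#' One line per genome: the focal gene and its in-window neighbors drawn as
#' boxes along a genome-coordinate axis, keyed by genome id so the dataset
#' attaches to a species tree.
#'
#' @param features gene-feature data.frame.
#' @param focal_family_of named family map; only these focal genes are
#'   drawn.
#' @param path file path.
#' @param params a [context_params()].
#' @return the path, invisibly.
#' @export
export_context_itol <- function(features, focal_family_of, path,
                                params = context_params()) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("DATASET_DOMAINS", "SEPARATOR TAB",
               "DATASET_LABEL\tgene_neighborhoods", "COLOR\t#1f78b4",
               "DATA"), con)
  focal_ids <- intersect(names(focal_family_of), features$feature_id)
  for (fid in sort(focal_ids)) {
    f <- features[features$feature_id == fid, ]
    nb <- neighborhood(features, fid, params)
    all_feats <- rbind(f, nb[, names(features), drop = FALSE])
    lo <- min(all_feats$start)
    shapes <- sprintf("RE|%d|%d|%s|%s",
                      all_feats$start - lo, all_feats$end - lo,
                      ifelse(all_feats$feature_id == fid, "#e31a1c",
                             "#33a02c"),
                      all_feats$product_profile)
    writeLines(paste(c(f$genome_id, max(all_feats$end) - lo, shapes),
                     collapse = "\t"), con)
  }
  invisible(path)
}
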