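# Candidate filtering and best-bidirectional-hit (BBH) graph construction:
# profile-hit E-value/coverage filter, one-strain-per-species dedup, per-
# (query, species) best hits, and the reciprocal-best edge graph weighted by
# the average -log10 E-value of the two directed hits.

#' Candidate-filter parameters
#'
#' Candidates are proteins hitting the required search profile with E-value
#' at most `max_evalue` and the hit covering at least `min_profile_coverage`
#' of the profile.
#'
#' @param max_evalue E-value cutoff (default 1e-4).
#' @param min_profile_coverage minimum fraction of the profile covered
#'   (default 0.30).
#' @param required_profile_id profile id the filter keys on (default the
#'   Lhr-like helicase profile stand-in `COG1201`).
#' @return object of class `candidate_filter_params`.
#' @export
candidate_filter_params <- function(max_evalue = 1e-4,
                                    min_profile_coverage = 0.30,
                                    required_profile_id = "COG1201") {
  if (max_evalue <= 0) stop_input("max_evalue must be positive")
  if (min_profile_coverage <= 0 || min_profile_coverage > 1)
    stop_input("min_profile_coverage must be in (0, 1]")
  structure(list(max_evalue = max_evalue,
                 min_profile_coverage = min_profile_coverage,
                 required_profile_id = required_profile_id),
            class = "candidate_filter_params")
}

#' Filter profile hits to candidate protein ids
#'
#' @param hits profile-hit data.frame (columns `protein_id`, `profile_id`,
#'   `e_value`, `coverage`).
#' @param params a [candidate_filter_params()].
#' @return sorted character vector of retained protein ids.
#' @export
filter_candidates <- function(hits, params = candidate_filter_params()) {
  if (nrow(hits) == 0L) return(character(0))
  if (any(hits$coverage < 0 | hits$coverage > 1))
    stop_input("coverage must lie in [0, 1]")
  keep <- hits$profile_id == params$required_profile_id &
    hits$e_value <= params$max_evalue &
    hits$coverage >= params$min_profile_coverage
  sort(unique(hits$protein_id[keep]))
}

#' Retain one strain per species
#'
#' For each species the lexicographically smallest `strain_key` is kept and
#' all proteins from other strains are dropped; deterministic.
#'
#' @param proteins data.frame with `species_key` and `strain_key` columns.
#' @return subset of `proteins`, original ordering preserved.
#' @export
dedupe_strains <- function(proteins) {
  if (nrow(proteins) == 0L) return(proteins)
  chosen <- tapply(proteins$strain_key, proteins$species_key,
                   function(x) min(x))
  keep <- proteins$strain_key == chosen[proteins$species_key]
  out <- proteins[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-(query, target-species) best hits
#'
#' Keeps, for every query protein and every other species, the single
#' subject with the smallest E-value (ties: higher bit score, then
#' lexicographically smaller subject id). Same-species pairs are dropped.
#'
#' @param hits directed pairwise-hit data.frame ([all_vs_all()] output).
#' @param proteins data.frame mapping `protein_id` to `species_key`.
#' @return data.frame of directed best hits with a `subject_species` column.
#' @export
best_hits_per_species <- function(hits, proteins) {
  if (nrow(hits) == 0L) return(cbind(hits, subject_species = character(0)))
  sp <- setNames(proteins$species_key, proteins$protein_id)
  h <- hits
  h$query_species <- unname(sp[h$query_id])
  h$subject_species <- unname(sp[h$subject_id])
  h <- h[!is.na(h$query_species) & !is.na(h$subject_species) &
         h$query_species != h$subject_species, , drop = FALSE]
  if (nrow(h) == 0L) return(h[, setdiff(names(h), "query_species")])
  o <- order(h$query_id, h$subject_species, h$e_value, -h$bit_score,
             h$subject_id)
  h <- h[o, , drop = FALSE]
  first <- !duplicated(h[, c("query_id", "subject_species")])
  out <- h[first, setdiff(names(h), "query_species"), drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build the best-bidirectional-hit similarity graph
#'
#' An edge (a, b) exists iff b is a's best hit in b's species AND a is b's
#' best hit in a's species. Edge weight is the mean of -log10 E-value over
#' the two directed hits (E-values floored at 1e-180); `identity_pct` is the
#' mean of the two directions.
#'
#' @param directed output of [best_hits_per_species()].
#' @param nodes optional character vector of node ids to include (isolated
#'   candidates become singleton nodes); defaults to ids seen in `directed`.
#' @return undirected igraph with `weight` and `identity_pct` edge
#'   attributes; no self-loops; edges only between different species.
#' @export
build_bbh_graph <- function(directed, nodes = NULL) {
  if (is.null(nodes)) {
    nodes <- sort(unique(c(directed$query_id, directed$subject_id)))
  } else {
    nodes <- sort(unique(nodes))
  }
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, length(nodes), name = nodes)
  if (nrow(directed) == 0L) return(g)
  key <- paste(directed$query_id, directed$subject_id, sep = "\r")
  rkey <- paste(directed$subject_id, directed$query_id, sep = "\r")
  has_recip <- rkey %in% key
  fwd <- directed[has_recip & directed$query_id < directed$subject_id, ,
                  drop = FALSE]
  if (nrow(fwd) == 0L) return(g)
  idx_rev <- match(paste(fwd$subject_id, fwd$query_id, sep = "\r"), key)
  rev <- directed[idx_rev, , drop = FALSE]
  w <- (-log10(pmax(fwd$e_value, EVALUE_FLOOR)) +
        -log10(pmax(rev$e_value, EVALUE_FLOOR))) / 2
  ident <- (fwd$identity_pct + rev$identity_pct) / 2
  g <- igraph::add_edges(g, rbind(fwd$query_id, fwd$subject_id),
                         weight = w, identity_pct = ident)
  g
}
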