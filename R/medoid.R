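# Sample reduction: prune the similarity graph at an identity threshold,
# re-cluster the pruned graph with MCL to find tight groups, represent each
# multi-member group by its medoid (minimum average dissimilarity, length
# near the group median), re-insert keep-list sequences, and drop
# representatives lacking the helicase core domains.

#' Reduction parameters
#'
#' @param min_identity_pct identity threshold (percent) below which graph
#'   edges are pruned before grouping (default 70; 55 for the Sfth outgroup
#'   reduction).
#' @param length_tolerance medoid candidates must have length within this
#'   fraction of the group's median length (default 0.10); if no member
#'   qualifies, the members nearest the median are used.
#' @param keep_list protein ids force-retained after medoid selection.
#' @param required_core_profiles profiles every representative must hit
#'   (default the RecA1/RecA2 helicase-core pair).
#' @return object of class `reduction_params`.
#' @export
reduction_params <- function(min_identity_pct = 70, length_tolerance = 0.10,
                             keep_list = character(0),
                             required_core_profiles = c("PF00270", "PF00271")) {
  if (min_identity_pct <= 0 || min_identity_pct > 100)
    stop_input("min_identity_pct must be in (0, 100]")
  if (length_tolerance < 0) stop_input("length_tolerance must be >= 0")
  structure(list(min_identity_pct = min_identity_pct,
                 length_tolerance = length_tolerance,
                 keep_list = keep_list,
                 required_core_profiles = required_core_profiles),
            class = "reduction_params")
}

#' Remove graph edges below an identity threshold
#'
#' @param graph igraph with an `identity_pct` edge attribute.
#' @param min_identity_pct percent threshold; edges with
#'   `identity_pct < min_identity_pct` are removed, nodes are kept.
#' @return pruned igraph on the same node set.
#' @export
prune_graph_by_identity <- function(graph, min_identity_pct = 70) {
  if (igraph::ecount(graph) == 0L) return(graph)
  drop <- which(igraph::E(graph)$identity_pct < min_identity_pct)
  igraph::delete_edges(graph, drop)
}

#' Pairwise dissimilarity matrix from directed hits
#'
#' Dissimilarity = 100 - identity_pct, averaged over the two directions;
#' pairs with no significant alignment get 100; the diagonal is 0.
#'
#' @param hits directed pairwise-hit data.frame.
#' @param ids node ids defining matrix order.
#' @return symmetric numeric matrix with zero diagonal.
#' @export
dissimilarity_from_hits <- function(hits, ids) {
  n <- length(ids)
  D <- matrix(100, n, n, dimnames = list(ids, ids))
  diag(D) <- 0
  h <- hits[hits$query_id %in% ids & hits$subject_id %in% ids, ,
            drop = FALSE]
  if (nrow(h) > 0L) {
    i <- match(h$query_id, ids); j <- match(h$subject_id, ids)
    D[cbind(i, j)] <- 100 - h$identity_pct
  }
  (D + t(D)) / 2
}

#' Medoid of a group under a length constraint
#'
#' Candidates are members whose length is within `length_tolerance` of the
#' group's median length (if none qualifies, the members with minimal
#' |length - median| are used). Among candidates, the member minimizing the
#' mean dissimilarity to all other group members is returned; ties go to
#' the lexicographically smallest id.
#'
#' @param ids group member ids.
#' @param lengths named lengths (must cover `ids`).
#' @param dissimilarity symmetric matrix with zero diagonal whose dimnames
#'   cover `ids`.
#' @param length_tolerance fraction of the median (default 0.10).
#' @return the medoid's id.
#' @export
compute_medoid <- function(ids, lengths, dissimilarity,
                           length_tolerance = 0.10) {
  stopifnot(length(ids) >= 1L)
  if (length(ids) == 1L) return(ids)
  D <- dissimilarity[ids, ids, drop = FALSE]
  if (max(abs(D - t(D))) > 1e-8) stop_input("dissimilarity must be symmetric")
  len <- lengths[ids]
  med <- median(len)
  dev <- abs(len - med)
  cand <- ids[dev <= length_tolerance * med]
  if (length(cand) == 0L) cand <- ids[dev == min(dev)]
  avg <- rowSums(D[cand, , drop = FALSE]) / (length(ids) - 1L)
  best <- cand[avg == min(avg)]
  sort(best)[1]
}

#' Reduce a dataset to representatives via medoid grouping
#'
#' Groups are the MCL clusters of the identity-pruned graph; singleton
#' groups contribute themselves, multi-member groups their medoid. Members
#' of `keep_list` absent from the representative set are then added back as
#' their own representatives.
#'
#' @param pruned_graph identity-pruned igraph ([prune_graph_by_identity()]).
#' @param lengths named protein lengths covering all graph nodes.
#' @param dissimilarity symmetric dissimilarity matrix covering all nodes.
#' @param params a [reduction_params()].
#' @param mcl_params_ MCL parameters used to cluster the pruned graph; by
#'   default the same inflation as the main clustering run.
#' @return object of class `representative_set`: list with
#'   `representatives` (sorted ids), `member_of` (named map id ->
#'   representative id), `is_medoid` (named logical over representatives),
#'   `n_singletons`, `n_medoid_groups`, `groups` (list of member vectors
#'   keyed by representative).
#' @export
reduce_dataset <- function(pruned_graph, lengths, dissimilarity,
                           params = reduction_params(),
                           mcl_params_ = mcl_params()) {
  ids <- igraph::V(pruned_graph)$name
  if (!all(params$keep_list %in% ids))
    stop_input("keep_list contains ids absent from the graph")
  part <- mcl(pruned_graph, mcl_params_)
  cl <- part$cluster_of
  groups <- split(names(cl), cl)
  member_of <- setNames(character(length(ids)), ids)
  reps <- character(0); is_med <- logical(0)
  n_single <- 0L; n_multi <- 0L
  rep_groups <- list()
  for (g in groups) {
    if (length(g) == 1L) {
      r <- g
      n_single <- n_single + 1L
      is_med[r] <- FALSE
    } else {
      r <- compute_medoid(g, lengths, dissimilarity,
                          params$length_tolerance)
      n_multi <- n_multi + 1L
      is_med[r] <- TRUE
    }
    reps <- c(reps, r)
    member_of[g] <- r
    rep_groups[[r]] <- sort(g)
  }
  # keep-list re-insertion: already-selected ids leave the set unchanged
  for (k in params$keep_list) {
    if (!(k %in% reps)) {
      reps <- c(reps, k)
      is_med[k] <- FALSE
      member_of[k] <- k
      rep_groups[[k]] <- k
    }
  }
  o <- order(reps)
  structure(list(representatives = reps[o],
                 member_of = member_of,
                 is_medoid = is_med[reps[o]],
                 n_singletons = n_single,
                 n_medoid_groups = n_multi,
                 groups = rep_groups[reps[o]]),
            class = "representative_set")
}

#' Drop representatives lacking required core-domain hits
#'
#' Removes every representative without at least one profile hit to each of
#' the required core profiles. Keep-list members are only exempt when
#' `exempt_keep_list = TRUE` (default: they are filtered like everyone
#' else).
#'
#' @param repset a `representative_set`.
#' @param profile_hits profile-hit data.frame covering the representatives.
#' @param required_core_profiles character vector of required profile ids.
#' @param keep_list ids exempt from removal when `exempt_keep_list`.
#' @param exempt_keep_list logical (default FALSE).
#' @return filtered `representative_set` (members of removed
#'   representatives are dropped from `member_of`).
#' @export
discard_missing_core <- function(repset, profile_hits,
                                 required_core_profiles = c("PF00270",
                                                            "PF00271"),
                                 keep_list = character(0),
                                 exempt_keep_list = FALSE) {
  has_all <- vapply(repset$representatives, function(id) {
    prof <- profile_hits$profile_id[profile_hits$protein_id == id]
    all(required_core_profiles %in% prof)
  }, logical(1))
  keep <- has_all
  if (exempt_keep_list) keep <- keep | repset$representatives %in% keep_list
  kept <- repset$representatives[keep]
  member_of <- repset$member_of[repset$member_of %in% kept]
  structure(list(representatives = kept,
                 member_of = member_of,
                 is_medoid = repset$is_medoid[kept],
                 n_singletons = sum(keep & !repset$is_medoid),
                 n_medoid_groups = sum(keep & repset$is_medoid),
                 groups = repset$groups[kept]),
            class = "representative_set")
}

#' Write a representative set as a TSV
#'
#' Columns: `protein_id`, `representative_id`, `is_medoid` (of the
#' representative), `group_size`.
#'
#' @param repset a `representative_set`.
#' @param path file path.
#' @return the path, invisibly.
#' @export
write_representatives_tsv <- function(repset, path) {
  ids <- names(repset$member_of)
  rep_id <- unname(repset$member_of)
  gsize <- vapply(repset$groups, length, integer(1))
  df <- data.frame(protein_id = ids, representative_id = rep_id,
                   is_medoid = unname(repset$is_medoid[rep_id]),
                   group_size = unname(gsize[rep_id]),
                   stringsAsFactors = FALSE)
  df <- df[order(df$protein_id), , drop = FALSE]
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
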