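# Markov Clustering (MCL) on the weighted similarity graph, implemented
# from scratch on sparse matrices: alternate expansion (matrix power) and
# inflation (entrywise power + column renormalization) with threshold
# pruning, then read clusters off the converged matrix. Includes the
# inflation-factor scan with an ARI-based stability criterion.

#' MCL parameters
#'
#' @param inflation inflation factor (> 1); granularity dial.
#' @param expansion matrix-power used in the expansion step (>= 2).
#' @param add_self_loops add a self-loop per node before normalization
#'   (default TRUE). Loop weight is the node's maximum incident edge weight
#'   (1 for isolated nodes) so loops live on the same scale as the
#'   -log10-E edge weights.
#' @param prune_threshold entries below this are zeroed after each
#'   inflation (then columns are renormalized).
#' @param max_iterations iteration cap.
#' @param convergence_eps stop when the largest entrywise change over one
#'   full iteration falls below this.
#' @return object of class `mcl_params`.
#' @export
mcl_params <- function(inflation = 4, expansion = 2L,
                       add_self_loops = TRUE, prune_threshold = 1e-6,
                       max_iterations = 200L, convergence_eps = 1e-8) {
  if (inflation <= 1) stop_input("inflation must be > 1")
  if (expansion < 2L) stop_input("expansion must be >= 2")
  structure(list(inflation = inflation, expansion = as.integer(expansion),
                 add_self_loops = add_self_loops,
                 prune_threshold = prune_threshold,
                 max_iterations = as.integer(max_iterations),
                 convergence_eps = convergence_eps),
            class = "mcl_params")
}

col_normalize <- function(M) {
  cs <- Matrix::colSums(M)
  cs[cs == 0] <- 1
  M %*% Matrix::Diagonal(x = 1 / cs)
}

#' Markov Clustering of a weighted graph
#'
#' Canonical MCL iteration over the column-stochastic transition matrix of
#' the weighted adjacency (with self-loops): expansion = matrix power,
#' inflation = entrywise power followed by column renormalization, pruning
#' of entries below `prune_threshold`. Clusters are the weakly connected
#' components of the non-zero pattern of the converged matrix; nodes are
#' processed in sorted-id order so the result is deterministic.
#'
#' @param graph igraph with a `weight` edge attribute (missing weights
#'   default to 1), or a symmetric adjacency matrix with dimnames.
#' @param params an [mcl_params()] object.
#' @return object of class `lhr_partition`: list with `cluster_of` (named
#'   integer vector, cluster indices ordered by decreasing size then by
#'   smallest member id), `sizes`, `converged`, `iterations`,
#'   `params_used`.
#' @export
mcl <- function(graph, params = mcl_params()) {
  A <- adjacency_from(graph)
  n <- nrow(A)
  if (n == 0L) stop_input("graph must be non-empty")
  ids <- rownames(A)
  if (params$add_self_loops) {
    mx <- apply(as.matrix(A), 2, max)
    loop <- ifelse(mx > 0, mx, 1)
    Matrix::diag(A) <- loop
  }
  M <- col_normalize(Matrix::Matrix(A, sparse = TRUE))
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(params$max_iterations)) {
    M_prev <- M
    Mx <- M
    for (e in seq_len(params$expansion - 1L)) Mx <- Mx %*% M
    M <- Mx
    M <- M ^ params$inflation
    M <- col_normalize(M)
    M <- Matrix::drop0(M * (M >= params$prune_threshold))
    M <- col_normalize(M)
    if (max(abs(M - M_prev)) < params$convergence_eps) {
      converged <- TRUE
      break
    }
  }
  partition_from_matrix(M, ids, params, converged, iter)
}

adjacency_from <- function(graph) {
  if (inherits(graph, "igraph")) {
    has_w <- "weight" %in% igraph::edge_attr_names(graph)
    A <- igraph::as_adjacency_matrix(graph,
                                     attr = if (has_w) "weight" else NULL,
                                     sparse = TRUE)
    A <- Matrix::Matrix(A, sparse = TRUE) * 1
  } else {
    A <- Matrix::Matrix(graph, sparse = TRUE) * 1
  }
  if (is.null(rownames(A))) {
    rownames(A) <- colnames(A) <- as.character(seq_len(nrow(A)))
  }
  o <- order(rownames(A))
  A[o, o, drop = FALSE]
}

partition_from_matrix <- function(M, ids, params, converged, iterations) {
  P <- ((M > 0) | Matrix::t(M > 0)) * 1
  gg <- igraph::graph_from_adjacency_matrix(P, mode = "undirected",
                                            diag = FALSE)
  comp <- igraph::components(gg)$membership
  names(comp) <- ids
  relabel_partition(comp, params, converged, iterations)
}

# Renumber clusters by decreasing size (ties: smallest member id) and wrap.
relabel_partition <- function(membership, params = NULL, converged = TRUE,
                              iterations = 0L) {
  membership <- membership[order(names(membership))]
  sizes <- table(membership)
  rep_id <- tapply(names(membership), membership, min)
  o <- order(-as.integer(sizes), rep_id[names(sizes)])
  new_idx <- setNames(seq_along(o), names(sizes)[o])
  cl <- unname(new_idx[as.character(membership)])
  names(cl) <- names(membership)
  structure(list(cluster_of = cl,
                 sizes = sort(as.integer(table(cl)), decreasing = TRUE),
                 n_clusters = length(unique(cl)),
                 converged = converged, iterations = iterations,
                 params_used = params),
            class = "lhr_partition")
}

#' @method print lhr_partition
#' @export
print.lhr_partition <- function(x, ...) {
  cat("MCL partition:", length(x$cluster_of), "nodes in", x$n_clusters,
      "clusters\n")
  cat("sizes:", paste(utils::head(x$sizes, 15), collapse = " "),
      if (length(x$sizes) > 15) "...\n" else "\n")
  if (!x$converged) cat("WARNING: iteration did not converge\n")
  invisible(x)
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement; 1 for identical partitions, ~0 for
#' independent ones.
#'
#' @param p1,p2 `lhr_partition` objects (or named cluster vectors) over the
#'   same node set.
#' @return numeric in [-1, 1].
#' @export
compare_partitions <- function(p1, p2) {
  c1 <- if (inherits(p1, "lhr_partition")) p1$cluster_of else p1
  c2 <- if (inherits(p2, "lhr_partition")) p2$cluster_of else p2
  if (!setequal(names(c1), names(c2)))
    stop_input("partitions cover different node sets")
  c2 <- c2[names(c1)]
  ari <- mclust::adjustedRandIndex(c1, c2)
  if (is.nan(ari)) {
    # degenerate marginals (e.g. two all-singleton partitions); identical
    # partitions score 1 by convention
    g1 <- lapply(split(names(c1), c1), sort)
    g2 <- lapply(split(names(c2), c2), sort)
    ari <- if (setequal(g1, g2)) 1 else 0
  }
  ari
}

#' Scan MCL inflation factors and find the stability point
#'
#' Runs [mcl()] at each inflation value and reports, per value, the number
#' of clusters and the ARI against the previous value's partition. The
#' minimal stable inflation is the smallest value from which all larger
#' scanned values give pairwise ARI >= 0.999 and identical cluster counts;
#' `NA` if no such value exists.
#'
#' @param graph as in [mcl()].
#' @param inflation_values ascending numeric vector (default 2:6).
#' @param params base [mcl_params()]; its `inflation` is overridden.
#' @return object of class `mcl_stability_report`: list with `partitions`
#'   (one per inflation), `summary` data.frame (`inflation`, `n_clusters`,
#'   `ari_vs_previous`), and `min_stable_inflation`.
#' @export
scan_inflation <- function(graph, inflation_values = 2:6,
                           params = mcl_params()) {
  if (is.unsorted(inflation_values))
    stop_input("inflation_values must be ascending")
  parts <- lapply(inflation_values, function(i) {
    p <- params; p$inflation <- i
    mcl(graph, p)
  })
  names(parts) <- as.character(inflation_values)
  k <- vapply(parts, function(p) p$n_clusters, integer(1))
  ari_prev <- c(NA_real_, vapply(seq_along(parts)[-1], function(i)
    compare_partitions(parts[[i - 1]], parts[[i]]), numeric(1)))
  min_stable <- NA_real_
  for (i in seq_along(parts)) {
    tail_idx <- seq.int(i, length(parts))
    stable <- TRUE
    for (a in tail_idx) for (b in tail_idx) {
      if (b <= a) next
      if (k[a] != k[b] ||
          compare_partitions(parts[[a]], parts[[b]]) < 0.999) {
        stable <- FALSE
        break
      }
    }
    if (stable) {
      min_stable <- inflation_values[i]
      break
    }
  }
  structure(list(
    partitions = parts,
    summary = data.frame(inflation = inflation_values, n_clusters = k,
                         ari_vs_previous = ari_prev),
    min_stable_inflation = min_stable
  ), class = "mcl_stability_report")
}

#' @method print mcl_stability_report
#' @export
print.mcl_stability_report <- function(x, ...) {
  cat("MCL inflation scan\n")
  print(x$summary, row.names = FALSE)
  cat("min stable inflation:", x$min_stable_inflation, "\n")
  invisible(x)
}

#' Write a partition as MCL-style cluster lines plus a TSV
#'
#' @param partition an `lhr_partition`.
#' @param path_clusters one-line-per-cluster text file (members
#'   tab-separated), clusters in index order.
#' @param path_tsv optional TSV (`protein_id`, `cluster`) with header.
#' @return invisibly, the cluster-lines path.
#' @export
write_partition <- function(partition, path_clusters, path_tsv = NULL) {
  cl <- partition$cluster_of
  lines <- vapply(sort(unique(cl)), function(k)
    paste(sort(names(cl)[cl == k]), collapse = "\t"), character(1))
  writeLines(lines, path_clusters)
  if (!is.null(path_tsv)) {
    write.table(data.frame(protein_id = names(cl), cluster = unname(cl)),
                path_tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path_clusters)
}
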