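# Independent reference implementations used as oracles. These are written
# against the definitions directly (dense matrices, explicit loops,
# closed-form combinatorics) and share no code with the package paths they
# check.

# ---- affine-gap local alignment, full Gotoh recursion ---------------------
# Gap of length L costs gap_open + L * gap_extend (both negative).
oracle_local_score <- function(a, b, mat, gap_open = -11, gap_extend = -1) {
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  NEG <- -1e9
  H <- matrix(0, n + 1, m + 1)
  E <- matrix(NEG, n + 1, m + 1)
  F_ <- matrix(NEG, n + 1, m + 1)
  best <- 0
  for (i in seq_len(n) + 1L) {
    for (j in seq_len(m) + 1L) {
      E[i, j] <- max(H[i, j - 1] + gap_open + gap_extend,
                     E[i, j - 1] + gap_extend)
      F_[i, j] <- max(H[i - 1, j] + gap_open + gap_extend,
                      F_[i - 1, j] + gap_extend)
      H[i, j] <- max(0,
                     H[i - 1, j - 1] + mat[A[i - 1], B[j - 1]],
                     E[i, j], F_[i, j])
      if (H[i, j] > best) best <- H[i, j]
    }
  }
  best
}

# ---- dense-matrix MCL reference -------------------------------------------
oracle_mcl_partition <- function(W, inflation, expansion = 2L,
                                 prune = 1e-6, eps = 1e-8,
                                 max_iter = 200L) {
  ids <- rownames(W)
  o <- order(ids)
  W <- W[o, o, drop = FALSE]
  ids <- ids[o]
  mx <- apply(W, 2, max)
  diag(W) <- ifelse(mx > 0, mx, 1)
  normalize <- function(M) {
    cs <- colSums(M)
    cs[cs == 0] <- 1
    sweep(M, 2, cs, "/")
  }
  M <- normalize(W)
  for (it in seq_len(max_iter)) {
    Mp <- M
    Mx <- M
    for (e in seq_len(expansion - 1L)) Mx <- Mx %*% M
    M <- Mx ^ inflation
    M <- normalize(M)
    M[M < prune] <- 0
    M <- normalize(M)
    if (max(abs(M - Mp)) < eps) break
  }
  P <- (M > 0) | t(M > 0)
  # connected components by hand (BFS)
  n <- length(ids)
  comp <- rep(NA_integer_, n)
  k <- 0L
  for (s in seq_len(n)) {
    if (!is.na(comp[s])) next
    k <- k + 1L
    queue <- s
    comp[s] <- k
    while (length(queue) > 0L) {
      v <- queue[1]; queue <- queue[-1]
      nb <- which(P[v, ] & is.na(comp))
      comp[nb] <- k
      queue <- c(queue, nb)
    }
  }
  setNames(comp, ids)
}

# partitions equal up to cluster relabeling
same_partition <- function(c1, c2) {
  c2 <- c2[names(c1)]
  g1 <- split(names(c1), c1)
  g2 <- split(names(c2), c2)
  setequal(lapply(g1, sort), lapply(g2, sort))
}

# ---- adjusted Rand index, contingency-table closed form -------------------
oracle_ari <- function(x, y) {
  tab <- table(x, y)
  a <- sum(choose(tab, 2))
  b <- sum(choose(rowSums(tab), 2))
  cc <- sum(choose(colSums(tab), 2))
  tot <- choose(length(x), 2)
  expected <- b * cc / tot
  maximum <- (b + cc) / 2
  if (maximum == expected) return(1)
  (a - expected) / (maximum - expected)
}

# ---- brute-force medoid honoring the length window ------------------------
oracle_medoid <- function(ids, lengths, D, tol = 0.10) {
  if (length(ids) == 1L) return(ids)
  med <- stats::median(lengths[ids])
  dev <- abs(lengths[ids] - med)
  cand <- ids[dev <= tol * med]
  if (length(cand) == 0L) cand <- ids[dev == min(dev)]
  avg <- vapply(cand, function(i)
    sum(D[i, setdiff(ids, i)]) / (length(ids) - 1L), numeric(1))
  sort(cand[avg == min(avg)])[1]
}

# ---- interval-union length ------------------------------------------------
oracle_union_length <- function(starts, ends) {
  covered <- logical(max(ends))
  for (i in seq_along(starts)) covered[starts[i]:ends[i]] <- TRUE
  sum(covered)
}

# ---- brute-force gene neighborhood ----------------------------------------
oracle_neighborhood_ids <- function(features, focal_id, window) {
  f <- features[features$feature_id == focal_id, ]
  out <- character(0)
  for (i in seq_len(nrow(features))) {
    g <- features[i, ]
    if (g$feature_id == focal_id) next
    if (g$contig_id != f$contig_id) next
    gap <- if (g$end >= f$start && g$start <= f$end) 0L else
      max(f$start, g$start) - min(f$end, g$end) - 1L
    if (gap < window) out <- c(out, g$feature_id)
  }
  sort(out)
}

# ---- subtree-enumeration minimal-removal oracle ---------------------------
oracle_min_removals <- function(tree, labels, cl) {
  tips <- tree$tip.label
  members <- tips[labels[tips] == cl]
  mono_after_removal <- function(rm) {
    rem <- setdiff(members, rm)
    if (length(rem) == 0L) return(FALSE)
    keep <- setdiff(tips, rm)
    if (length(rem) == length(keep)) return(TRUE)
    pruned <- if (length(rm) == 0L) tree else ape::drop.tip(tree, rm)
    if (length(rem) == 1L) return(TRUE)
    ape::is.monophyletic(pruned, rem)
  }
  for (k in 0:(length(members) - 1L)) {
    for (rm in utils::combn(tips, k, simplify = FALSE)) {
      if (mono_after_removal(rm)) return(k)
    }
  }
  length(members)
}

# ---- random weighted graph fixture ----------------------------------------
random_weighted_graph <- function(n, p_edge = 0.4, wmax = 30) {
  ids <- sprintf("n%02d", seq_len(n))
  W <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1)) {
    for (j in seq.int(i + 1, n)) {
      if (stats::runif(1) < p_edge) {
        w <- stats::runif(1, 1, wmax)
        W[i, j] <- W[j, i] <- w
      }
    }
  }
  W
}

graph_from_weight_matrix <- function(W) {
  igraph::graph_from_adjacency_matrix(W, mode = "undirected",
                                      weighted = TRUE)
}

random_peptide <- function(len) {
  paste(sample(c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M",
                 "N", "P", "Q", "R", "S", "T", "V", "W", "Y"),
               len, replace = TRUE), collapse = "")
}
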