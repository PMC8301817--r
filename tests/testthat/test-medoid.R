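random_symmetric_D <- function(ids) {
  n <- length(ids)
  D <- matrix(runif(n * n, 0, 100), n, n, dimnames = list(ids, ids))
  D <- (D + t(D)) / 2
  diag(D) <- 0
  D
}

test_that("identity pruning keeps nodes and drops exactly the weak edges", {
  withr::local_seed(21)
  W <- random_weighted_graph(8)
  g <- graph_from_weight_matrix(W)
  igraph::E(g)$identity_pct <- runif(igraph::ecount(g), 40, 100)
  ident <- igraph::E(g)$identity_pct
  pruned <- prune_graph_by_identity(g, 70)
  expect_equal(igraph::vcount(pruned), igraph::vcount(g))
  expect_equal(igraph::ecount(pruned), sum(ident >= 70))
  expect_true(all(igraph::E(pruned)$identity_pct >= 70))
  # extremes: keep-all and drop-all
  expect_equal(igraph::ecount(prune_graph_by_identity(g, 1)),
               igraph::ecount(g))
  none <- prune_graph_by_identity(g, 100.0)
  expect_equal(igraph::ecount(none), sum(ident >= 100))
  expect_equal(igraph::vcount(none), igraph::vcount(g))
})

test_that("compute_medoid honors ties, length windows, and the oracle", {
  expect_equal(compute_medoid("only", c(only = 100),
                              matrix(0, 1, 1, dimnames = list("only",
                                                              "only"))),
               "only")
  # three equidistant members, equal lengths: lexicographic tie-break
  ids <- c("b", "a", "c")
  D <- matrix(10, 3, 3, dimnames = list(ids, ids)); diag(D) <- 0
  expect_equal(compute_medoid(ids, setNames(rep(100, 3), ids), D), "a")
  # asymmetric matrix rejected
  Dbad <- D; Dbad[1, 2] <- 99
  expect_error(compute_medoid(ids, setNames(rep(100, 3), ids), Dbad),
               "symmetric")
  # random groups against the brute-force oracle
  withr::local_seed(31)
  for (rep in 1:25) {
    k <- sample(2:8, 1)
    ids <- sprintf("m%02d", seq_len(k))
    D <- random_symmetric_D(ids)
    lens <- setNames(sample(80:120, k, replace = TRUE), ids)
    expect_equal(compute_medoid(ids, lens, D),
                 oracle_medoid(ids, lens, D))
  }
})

test_that("reduction bookkeeping: representatives = singletons + medoids", {
  ds <- default_dataset()
  hits <- default_hits()
  g <- default_graph()
  pruned <- prune_graph_by_identity(g, 70)
  lens <- setNames(ds$proteins$length, ds$proteins$protein_id)
  D <- dissimilarity_from_hits(hits, igraph::V(pruned)$name)
  rs <- reduce_dataset(pruned, lens, D)
  expect_equal(length(rs$representatives),
               rs$n_singletons + rs$n_medoid_groups)
  # member_of is a projection (idempotent) and reps map to themselves
  expect_true(all(rs$member_of[rs$representatives] == rs$representatives))
  expect_equal(unname(rs$member_of[unname(rs$member_of)]),
               unname(rs$member_of))
  # every >=70%-identity group sits inside one truth family
  for (grp in rs$groups) {
    expect_equal(length(unique(ds$truth_clusters[grp])), 1L)
  }
  # keep-list: re-adding an existing representative changes nothing
  keep1 <- reduce_dataset(pruned, lens, D,
                          reduction_params(keep_list = rs$representatives[1]))
  expect_setequal(keep1$representatives, rs$representatives)
  # keep-list: a swallowed member comes back as its own representative
  swallowed <- setdiff(names(rs$member_of),
                       rs$representatives)[1]
  if (!is.na(swallowed)) {
    keep2 <- reduce_dataset(pruned, lens, D,
                            reduction_params(keep_list = swallowed))
    expect_true(swallowed %in% keep2$representatives)
    expect_equal(unname(keep2$member_of[swallowed]), swallowed)
  }
  expect_error(reduce_dataset(pruned, lens, D,
                              reduction_params(keep_list = "nonexistent")),
               "keep_list")
})

test_that("raising the identity threshold only refines the grouping", {
  g <- default_graph()
  lens <- setNames(default_dataset()$proteins$length,
                   default_dataset()$proteins$protein_id)
  D <- dissimilarity_from_hits(default_hits(), igraph::V(g)$name)
  prev_groups <- NULL
  for (thr in c(55, 70, 85)) {
    rs <- reduce_dataset(prune_graph_by_identity(g, thr), lens, D)
    groups <- rs$groups
    if (!is.null(prev_groups)) {
      # each tighter group is contained in one looser group
      for (grp in groups) {
        holders <- vapply(prev_groups, function(p) all(grp %in% p),
                          logical(1))
        expect_equal(sum(holders), 1L)
      }
    }
    prev_groups <- groups
  }
})

test_that("core-domain filtering removes exactly the coreless proteins", {
  ds <- default_dataset()
  g <- default_graph()
  lens <- setNames(ds$proteins$length, ds$proteins$protein_id)
  D <- dissimilarity_from_hits(default_hits(), igraph::V(g)$name)
  rs <- reduce_dataset(prune_graph_by_identity(g, 70), lens, D)
  # everyone in the synthetic set has the core: identity transform
  kept <- discard_missing_core(rs, ds$profile_hits)
  expect_setequal(kept$representatives, rs$representatives)
  # strip the PF00271 hits of two representatives: exactly those drop out
  victims <- rs$representatives[1:2]
  hits2 <- ds$profile_hits[!(ds$profile_hits$protein_id %in% victims &
                             ds$profile_hits$profile_id == "PF00271"), ]
  kept2 <- discard_missing_core(rs, hits2)
  expect_setequal(setdiff(rs$representatives, kept2$representatives),
                  victims)
  # keep-list exemption retains them when asked
  kept3 <- discard_missing_core(rs, hits2, keep_list = victims,
                                exempt_keep_list = TRUE)
  expect_setequal(kept3$representatives, rs$representatives)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_representatives_tsv(kept2, path)
  tab <- read.delim(path)
  expect_equal(sort(unique(tab$representative_id)),
               sort(kept2$representatives))
})
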