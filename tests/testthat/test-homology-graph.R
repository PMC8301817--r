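mk_profile_hit <- function(id, e, cov, profile = "COG1201") {
  data.frame(protein_id = id, profile_id = profile, e_value = e,
             bit_score = 50, q_start = 1L, q_end = 100L,
             profile_len = 100L, coverage = cov, stringsAsFactors = FALSE)
}

test_that("candidate filter applies the E-value and coverage rules", {
  hits <- rbind(mk_profile_hit("keep", 1e-5, 0.40),
                mk_profile_hit("lowcov", 1e-5, 0.29),
                mk_profile_hit("highE", 1e-3, 0.40),
                mk_profile_hit("wrongprof", 1e-9, 0.9, "PF00270"))
  expect_equal(filter_candidates(hits), "keep")
  expect_equal(filter_candidates(empty_profile_hits()), character(0))
  bad <- mk_profile_hit("x", 1e-5, 1.4)
  expect_error(filter_candidates(bad), "coverage")
  expect_error(candidate_filter_params(max_evalue = -1), "positive")
})

test_that("strain dedup keeps one deterministic strain per species", {
  ds <- generate_family_dataset(
    synth_params(n_families = 1L, family_sizes = 15L, n_species = 3L,
                 strains_per_species = 2L, seed = 3L))
  expect_equal(nrow(ds$proteins), 30L)
  kept <- dedupe_strains(ds$proteins)
  expect_equal(nrow(kept), 15L)
  expect_true(all(kept$strain_key == "A01"))
  # all-distinct species: identity transform
  solo <- ds$proteins[ds$proteins$strain_key == "A02", ]
  rownames(solo) <- NULL
  expect_equal(dedupe_strains(solo), solo)
})

test_that("best hits per species equal the exhaustive argmin oracle", {
  withr::local_seed(7)
  ids <- sprintf("p%02d", 1:10)
  prot <- data.frame(protein_id = ids,
                     species_key = rep(sprintf("S%d", 1:5), each = 2),
                     stringsAsFactors = FALSE)
  hits <- data.frame(
    query_id = sample(ids, 40, replace = TRUE),
    subject_id = sample(ids, 40, replace = TRUE),
    e_value = 10 ^ -sample(5:50, 40, replace = TRUE),
    bit_score = round(runif(40, 20, 200)),
    identity_pct = runif(40, 20, 100), stringsAsFactors = FALSE)
  hits <- hits[hits$query_id != hits$subject_id, ]
  best <- best_hits_per_species(hits, prot)
  sp <- setNames(prot$species_key, prot$protein_id)
  # no same-species rows
  expect_true(all(sp[best$query_id] != sp[best$subject_id]))
  # oracle: exhaustive per (query, species) argmin with tie-breaks
  for (q in unique(hits$query_id)) {
    for (s in unique(sp)) {
      cand <- hits[hits$query_id == q & sp[hits$subject_id] == s &
                   sp[q] != s, , drop = FALSE]
      got <- best[best$query_id == q & best$subject_species == s, ]
      if (nrow(cand) == 0L) {
        expect_equal(nrow(got), 0L)
      } else {
        cand <- cand[order(cand$e_value, -cand$bit_score,
                           cand$subject_id), ]
        expect_equal(nrow(got), 1L)
        expect_equal(got$subject_id, cand$subject_id[1])
      }
    }
  }
})

test_that("BBH edges require reciprocity and average the two directions", {
  prot <- data.frame(protein_id = c("a", "b", "c"),
                     species_key = c("S1", "S2", "S3"),
                     stringsAsFactors = FALSE)
  directed <- data.frame(
    query_id = c("a", "b"), subject_id = c("b", "a"),
    subject_species = c("S2", "S1"),
    e_value = c(1e-20, 1e-40), bit_score = c(80, 120),
    identity_pct = c(60, 64), stringsAsFactors = FALSE)
  g <- build_bbh_graph(directed)
  expect_equal(igraph::ecount(g), 1L)
  expect_equal(igraph::E(g)$weight, 30)        # (20 + 40) / 2
  expect_equal(igraph::E(g)$identity_pct, 62)
  # drop one direction: edge disappears
  g1 <- build_bbh_graph(directed[1, ], nodes = c("a", "b"))
  expect_equal(igraph::ecount(g1), 0L)
  expect_equal(igraph::vcount(g1), 2L)
  # non-reciprocal chain a->b, b->c gives no edges
  chain <- data.frame(query_id = c("a", "b"), subject_id = c("b", "c"),
                      subject_species = c("S2", "S3"),
                      e_value = 1e-10, bit_score = 50,
                      identity_pct = 50, stringsAsFactors = FALSE)
  expect_equal(igraph::ecount(build_bbh_graph(chain)), 0L)
})

test_that("on a well-separated fixture every BBH edge is within-family", {
  ds <- generate_family_dataset(small_params())
  hits <- all_vs_all(ds$proteins)
  bh <- best_hits_per_species(hits, ds$proteins)
  g <- build_bbh_graph(bh, nodes = ds$proteins$protein_id)
  el <- igraph::as_edgelist(g)
  expect_gt(nrow(el), 0)
  expect_true(all(ds$truth_clusters[el[, 1]] == ds$truth_clusters[el[, 2]]))
  # edge-list round trip preserves weights and node set
  path <- withr::local_tempfile(fileext = ".tsv")
  write_edgelist_tsv(g, path)
  g2 <- read_edgelist_tsv(path, nodes = igraph::V(g)$name)
  expect_setequal(igraph::V(g2)$name, igraph::V(g)$name)
  expect_equal(sort(igraph::E(g2)$weight), sort(igraph::E(g)$weight),
               tolerance = 1e-9)
})
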