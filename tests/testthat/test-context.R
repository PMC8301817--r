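mk_feat <- function(id, start, end, contig = "c1", genome = "g1",
                    strand = "+", profile = "COG1201") {
  data.frame(genome_id = genome, contig_id = contig, feature_id = id,
             start = as.integer(start), end = as.integer(end),
             strand = strand, product_id = id, product_profile = profile,
             stringsAsFactors = FALSE)
}

test_that("the neighborhood window includes near genes and excludes far", {
  feats <- rbind(mk_feat("focal", 10000, 11000),
                 mk_feat("near", 8900, 9899),       # 100 bp upstream
                 mk_feat("far", 11001 + 4500, 17000),
                 mk_feat("touch", 11001, 12000),     # bookended: gap 0
                 mk_feat("othercontig", 10000, 11000, contig = "c2"))
  nb <- neighborhood(feats, "focal")
  expect_setequal(nb$feature_id, c("near", "touch"))
  expect_equal(nb$side[nb$feature_id == "near"], "upstream")
  expect_equal(nb$side[nb$feature_id == "touch"], "downstream")
  expect_equal(nb$gap_bp[nb$feature_id == "near"], 100L)
  # focal alone on its contig
  solo <- mk_feat("lonely", 5, 10, contig = "c9")
  expect_equal(nrow(neighborhood(rbind(feats, solo), "lonely")), 0L)
  expect_error(neighborhood(feats, "missing"), "not found")
})

test_that("side and orientation follow the focal gene's strand", {
  feats <- rbind(mk_feat("f", 5000, 6000, strand = "-"),
                 mk_feat("left", 3000, 4000, strand = "+"),
                 mk_feat("right", 7000, 8000, strand = "-"))
  nb <- neighborhood(feats, "f")
  # on a minus-strand focal gene, the left gene is downstream
  expect_equal(nb$side[nb$feature_id == "left"], "downstream")
  expect_equal(nb$side[nb$feature_id == "right"], "upstream")
  expect_equal(nb$orientation[nb$feature_id == "left"], "reverse")
  expect_equal(nb$orientation[nb$feature_id == "right"], "same")
})

test_that("neighborhood matches the brute-force oracle and is symmetric", {
  withr::local_seed(71)
  for (rep in 1:6) {
    n <- 12
    starts <- sort(sample(1:40000, n))
    feats <- do.call(rbind, lapply(seq_len(n), function(i)
      mk_feat(sprintf("g%02d", i), starts[i], starts[i] +
                sample(200:1500, 1))))
    for (fid in feats$feature_id[c(1, 5, 12)]) {
      got <- sort(neighborhood(feats, fid)$feature_id)
      expect_equal(got, oracle_neighborhood_ids(feats, fid, 4000L))
    }
    # window symmetry
    for (i in c(2, 7)) for (j in c(3, 9)) {
      a <- feats$feature_id[i]; b <- feats$feature_id[j]
      expect_equal(b %in% neighborhood(feats, a)$feature_id,
                   a %in% neighborhood(feats, b)$feature_id)
    }
  }
})

test_that("conservation fractions are exact in the degenerate cases", {
  for (p in c(0, 1)) {
    ds <- generate_family_dataset(
      synth_params(n_families = 1L, family_sizes = 12L, n_species = 12L,
                   neighbor_conservation_prob = p, seed = 5L))
    fam_of <- setNames(ds$truth_labels, names(ds$truth_labels))
    tab <- conservation_profile(ds$features, fam_of)
    planted <- tab[tab$neighbor_profile == "TIGR0024", ]
    if (p == 0) {
      expect_equal(nrow(planted), 0L)
    } else {
      expect_equal(planted$fraction, 1.0)
      expect_equal(planted$n_genomes_with_family, 12L)
    }
  }
})

test_that("co-occurrence detects XOR-planted mutual exclusivity", {
  ds <- generate_family_dataset(
    synth_params(n_families = 2L, family_sizes = c(5L, 5L), n_species = 5L,
                 neighbor_conservation_prob = c(1, 0), seed = 9L))
  fam_of <- setNames(ds$truth_labels, names(ds$truth_labels))
  # family 1 (aLhr2) gets the neighbor with probability 1, aLhr1 never
  fams <- c("aLhr2", "aLhr1")
  cc <- cooccurrence_summary(ds$features, fam_of, fams[1], fams[2],
                             "TIGR0024")
  expect_equal(unname(cc$counts[["both"]]), 0L)
  expect_equal(unname(cc$counts[["A_only"]]), 5L)
  # one-sided planting is not mutual exclusivity: that needs both
  # exclusive cells occupied
  expect_false(cc$mutually_exclusive)
  # hand-built two-sided fixture: neighbor near A in g1, near B in g2
  two_sided <- rbind(
    mk_feat("a1", 1, 1000, contig = "g1c", genome = "g1"),
    mk_feat("a1n", 1200, 1800, contig = "g1c", genome = "g1",
            profile = "TIGR0024"),
    mk_feat("b1", 20000, 21000, contig = "g1c", genome = "g1"),
    mk_feat("a2", 1, 1000, contig = "g2c", genome = "g2"),
    mk_feat("b2", 20000, 21000, contig = "g2c", genome = "g2"),
    mk_feat("b2n", 21500, 22000, contig = "g2c", genome = "g2",
            profile = "TIGR0024"))
  fam2 <- c(a1 = "A", b1 = "B", a2 = "A", b2 = "B")
  cc2 <- cooccurrence_summary(two_sided, fam2, "A", "B", "TIGR0024")
  expect_equal(unname(cc2$counts), c(1L, 1L, 0L, 0L))
  expect_true(cc2$mutually_exclusive)
  # neighbor near none: no exclusivity signal
  ds0 <- generate_family_dataset(
    synth_params(n_families = 2L, family_sizes = c(5L, 5L), n_species = 5L,
                 neighbor_conservation_prob = 0, seed = 9L))
  cc0 <- cooccurrence_summary(ds0$features,
                              setNames(ds0$truth_labels,
                                       names(ds0$truth_labels)),
                              fams[1], fams[2], "TIGR0024")
  expect_equal(unname(cc0$counts[["A_only"]]), 0L)
  expect_false(cc0$mutually_exclusive)
})

test_that("GFF3 features round-trip and the iTOL context export parses", {
  ds <- generate_family_dataset(small_params())
  path <- withr::local_tempfile(fileext = ".gff3")
  write_gff3(ds$features, path)
  back <- read_gff3(path)
  expect_equal(back, ds$features)
  itol <- withr::local_tempfile(fileext = ".txt")
  fam_of <- setNames(ds$truth_labels, names(ds$truth_labels))
  export_context_itol(ds$features, fam_of, itol)
  lines <- readLines(itol)
  expect_equal(lines[1], "DATASET_DOMAINS")
  expect_equal(sum(grepl("^SP", lines)), nrow(ds$proteins))
})
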