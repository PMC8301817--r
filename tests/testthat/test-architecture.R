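mk_hit <- function(id, profile, qs, qe, e = 1e-20, plen = 100L, cov = 0.9) {
  data.frame(protein_id = id, profile_id = profile, e_value = e,
             bit_score = 50, q_start = as.integer(qs), q_end = as.integer(qe),
             profile_len = as.integer(plen), coverage = cov,
             stringsAsFactors = FALSE)
}

mk_prot <- function(id, seq) {
  data.frame(protein_id = id, sequence = seq, stringsAsFactors = FALSE)
}

test_that("architecture calls implement the threshold rules", {
  p <- mk_prot("p1", strrep("A", 600))
  full <- rbind(mk_hit("p1", "PF00270", 1, 200),
                mk_hit("p1", "PF00271", 221, 370),
                mk_hit("p1", "PF08494", 381, 500, cov = 0.9))
  call <- call_architecture(p, full)
  expect_true(call$has_core)
  expect_equal(call$domain4_status, "intact")
  expect_false(call$has_hth42)
  # deteriorated: hit below the 50% coverage default
  det <- full; det$coverage[3] <- 0.3
  expect_equal(call_architecture(p, det)$domain4_status, "deteriorated")
  # absent: either no hit, or a hit above the reporting floor
  expect_equal(call_architecture(p, full[1:2, ])$domain4_status, "absent")
  weak <- full; weak$e_value[3] <- 0.5
  expect_equal(call_architecture(p, weak)$domain4_status, "absent")
  # one core domain only
  expect_false(call_architecture(p, full[1, , drop = FALSE])$has_core)
  # wrong protein's hits rejected
  expect_error(call_architecture(p, mk_hit("other", "PF00270", 1, 100)),
               "other")
})

test_that("cysteine-rich and intein flags read the sequence and intervals", {
  tail_cys <- paste0(strrep("A", 500), strrep("CA", 10), strrep("A", 80))
  p <- mk_prot("p1", tail_cys)
  hits <- rbind(mk_hit("p1", "PF00270", 1, 200),
                mk_hit("p1", "PF00271", 221, 370),
                mk_hit("p1", "PF08494", 381, 500, cov = 0.9))
  expect_true(call_architecture(p, hits)$has_cys_rich_cterm)
  # same sequence, Domain 4 absent: window starts after PF00271 at 370,
  # covering 371-490, which holds no cysteines
  expect_false(call_architecture(p, hits[1:2, ])$has_cys_rich_cterm)
  # intein only counts when nested inside a core-domain interval
  nested <- rbind(hits, mk_hit("p1", "PF14890", 50, 150))
  outside <- rbind(hits, mk_hit("p1", "PF14890", 510, 560))
  expect_true(call_architecture(p, nested)$intein_inserted)
  expect_false(call_architecture(p, outside)$intein_inserted)
})

test_that("architecture calls equal a hand re-derivation on the fixture", {
  ds <- default_dataset()
  params <- classifier_params()
  calls <- call_architectures(ds$proteins, ds$profile_hits, params)
  for (i in seq_len(nrow(ds$proteins))) {
    pid <- ds$proteins$protein_id[i]
    h <- ds$profile_hits[ds$profile_hits$protein_id == pid, ]
    d4 <- h[h$profile_id == "PF08494" & h$e_value <= 1e-3, ]
    status <- if (nrow(d4) == 0L) "absent" else
      if (any(d4$coverage >= 0.5)) "intact" else "deteriorated"
    anchor <- if (nrow(d4) > 0L) max(d4$q_end) else
      max(h$q_end[h$profile_id %in% c("PF00270", "PF00271")])
    win <- substr(ds$proteins$sequence[i], anchor + 1, anchor + 120)
    expect_equal(calls$domain4_status[i], status, label = pid)
    expect_equal(calls$has_core[i],
                 all(c("PF00270", "PF00271") %in% h$profile_id))
    expect_equal(calls$has_hth42[i], "PF06224" %in% h$profile_id)
    expect_equal(calls$has_cys_rich_cterm[i],
                 lengths(regmatches(win, gregexpr("C", win))) >= 4,
                 label = pid)
  }
})

test_that("family assignment is total and matches the group rules", {
  combos <- expand.grid(has_core = c(TRUE, FALSE),
                        domain4_status = c("intact", "deteriorated",
                                           "absent"),
                        has_hth42 = c(TRUE, FALSE),
                        has_cys_rich_cterm = c(TRUE, FALSE),
                        taxon = c("Archaea", "Bacteria", "Asgard"),
                        stringsAsFactors = FALSE)
  for (i in seq_len(nrow(combos))) {
    call <- data.frame(protein_id = "x", has_core = combos$has_core[i],
                       domain4_status = combos$domain4_status[i],
                       has_hth42 = combos$has_hth42[i],
                       has_cys_rich_cterm = combos$has_cys_rich_cterm[i],
                       intein_inserted = FALSE, stringsAsFactors = FALSE)
    out <- classify_family(call, combos$taxon[i])
    expect_equal(length(out$label), 1L)
    expect_true(out$label %in% c("aLhr1", "aLhr2", "aLhr3", "bLhr",
                                 "bLhr-HTH", "Lhr-like", "unclassified"))
    if (!combos$has_core[i]) expect_equal(out$label, "unclassified")
  }
  # canonical instances
  mk <- function(core, d4, hth, cys)
    data.frame(protein_id = "x", has_core = core, domain4_status = d4,
               has_hth42 = hth, has_cys_rich_cterm = cys,
               intein_inserted = FALSE, stringsAsFactors = FALSE)
  expect_equal(classify_family(mk(TRUE, "intact", FALSE, TRUE),
                               "Archaea")$label, "aLhr1")
  expect_equal(classify_family(mk(TRUE, "intact", TRUE, FALSE),
                               "Bacteria")$label, "bLhr-HTH")
  expect_equal(classify_family(mk(TRUE, "intact", FALSE, FALSE),
                               "Bacteria")$label, "bLhr")
  expect_equal(classify_family(mk(TRUE, "absent", FALSE, FALSE),
                               "Archaea")$label, "Lhr-like")
  expect_equal(classify_family(mk(TRUE, "deteriorated", FALSE, FALSE),
                               "Asgard")$label, "aLhr3")
  expect_equal(classify_family(mk(TRUE, "intact", TRUE, FALSE),
                               "Archaea")$label, "aLhr2")
})

test_that("helicase-core extraction merges intervals correctly", {
  seq <- paste(rep(c("A", "C", "D", "E", "F"), 80), collapse = "")
  p <- mk_prot("p1", seq)
  h <- rbind(mk_hit("p1", "PF00270", 10, 100),
             mk_hit("p1", "PF00271", 150, 300))
  core <- extract_helicase_core(p, h)
  expect_equal(nchar(core), 242L)
  expect_equal(core, paste0(substr(seq, 10, 100), substr(seq, 150, 300)))
  hov <- rbind(mk_hit("p1", "PF00270", 10, 100),
               mk_hit("p1", "PF00271", 90, 200))
  expect_equal(nchar(extract_helicase_core(p, hov)), 191L)
  expect_equal(extract_helicase_core(p, hov), substr(seq, 10, 200))
  expect_error(extract_helicase_core(p, h[1, , drop = FALSE]), "lacks")
  # the best (lowest-E) hit per profile is the one extracted
  h2 <- rbind(mk_hit("p1", "PF00270", 10, 100, e = 1e-40),
              mk_hit("p1", "PF00270", 200, 260, e = 1e-10),
              mk_hit("p1", "PF00271", 300, 350))
  expect_equal(nchar(extract_helicase_core(p, h2)), 91L + 51L)
})

test_that("extracted cores are more alignable within families than full
           sequences are across families", {
  ds <- generate_family_dataset(small_params())
  cores <- extract_helicase_cores(ds$proteins, ds$profile_hits)
  expect_true(all(nchar(cores) > 0))
  # cores of one family member vs its ancestor-mates align at higher
  # identity than full-length cross-family pairs
  fam1 <- names(ds$truth_clusters[ds$truth_clusters == 1])
  fam2 <- names(ds$truth_clusters[ds$truth_clusters == 2])
  seqs <- setNames(ds$proteins$sequence, ds$proteins$protein_id)
  within_core <- align_local(cores[[fam1[1]]], cores[[fam1[2]]])
  across_full <- align_local(seqs[[fam1[1]]], seqs[[fam2[1]]])
  expect_gt(within_core$identity_pct, across_full$identity_pct)
})

test_that("the Sfth three-domain rule keeps exactly the Sfth architecture", {
  prot <- data.frame(protein_id = sprintf("p%d", 1:10),
                     stringsAsFactors = FALSE)
  hits <- do.call(rbind, c(
    lapply(sprintf("p%d", 1:5), function(id)
      rbind(mk_hit(id, "PF00270", 1, 100), mk_hit(id, "PF09369", 120, 200),
            mk_hit(id, "PF00271", 220, 300))),
    lapply(sprintf("p%d", 6:10), function(id)
      rbind(mk_hit(id, "PF00270", 1, 100), mk_hit(id, "PF00271", 220, 300),
            mk_hit(id, "PF08494", 320, 400)))))
  expect_setequal(filter_sfth(prot, hits), sprintf("p%d", 1:5))
})

test_that("paralog counts equal a direct group-by", {
  ds <- default_dataset()
  assign <- classify_families(ds$proteins, ds$profile_hits)
  genomes <- setNames(paste(ds$proteins$species_key, ds$proteins$strain_key,
                            sep = "_"), ds$proteins$protein_id)
  tab <- tabulate_paralog_counts(assign, genomes)
  expect_equal(sum(tab[, -1]), nrow(assign))
  for (r in sample(nrow(tab), 5)) {
    gid <- tab$genome_id[r]
    in_g <- assign$label[genomes[assign$protein_id] == gid]
    for (lab in setdiff(names(tab), "genome_id")) {
      expect_equal(tab[r, lab], sum(in_g == lab))
    }
  }
})
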