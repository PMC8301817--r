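#!/usr/bin/env Rscript
# Step 2 — candidate filtering and all-against-all comparison.
#
# Keeps proteins hitting the Lhr-like search profile (COG1201) at
# E <= 1e-4 with >= 30% profile coverage, retains one strain per species,
# then runs exact affine-gap Smith-Waterman over every pair, reporting
# blastp-style hits with Karlin-Altschul E-values (outfmt-6 layout).

library(lhrfam)

ds <- read_fixture_bundle("results/fixture")
candidates <- filter_candidates(ds$profile_hits)
message(sprintf("candidate filter: %d of %d proteins pass",
                length(candidates), nrow(ds$proteins)))

prot <- dedupe_strains(ds$proteins[ds$proteins$protein_id %in% candidates, ])
message(sprintf("one strain per species: %d proteins retained", nrow(prot)))

hits <- all_vs_all(prot)
write_hits_tsv(hits, "results/hits.tsv")
write.table(prot[, c("protein_id", "species_key", "strain_key",
                     "taxon_group", "length")],
            "results/proteins_kept.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

same <- ds$truth_clusters[hits$query_id] == ds$truth_clusters[hits$subject_id]
message(sprintf(
  "%d directed hits; mean identity %.1f%% within families, %.1f%% between",
  nrow(hits), mean(hits$identity_pct[same]),
  mean(hits$identity_pct[!same])))
message("wrote results/hits.tsv, results/proteins_kept.tsv")
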