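#!/usr/bin/env Rscript
# Step 5 — domain-architecture calls and family assignment.
#
# Calls each protein's architecture (helicase core, Domain 4 state, HTH_42,
# Cys-rich C-terminus), assigns the six Lhr group labels from architecture
# plus taxon, tabulates per-genome paralog counts, and extracts the merged
# RecA1+RecA2 helicase cores (the input an external aligner would consume).

library(lhrfam)
library(Biostrings)

ds <- read_fixture_bundle("results/fixture")
clusters <- read.delim("results/clusters.tsv")
cluster_of <- setNames(clusters$cluster, clusters$protein_id)

assign <- classify_families(ds$proteins, ds$profile_hits,
                            cluster_of = cluster_of)
write_assignments_tsv(assign, "results/assignments.tsv")

acc <- mean(assign$label == ds$truth_labels[assign$protein_id])
message(sprintf("family assignment: %.1f%% agreement with planted truth",
                100 * acc))
print(table(assign$label))

genomes <- setNames(paste(ds$proteins$species_key, ds$proteins$strain_key,
                          sep = "_"), ds$proteins$protein_id)
paralogs <- tabulate_paralog_counts(assign, genomes)
write.table(paralogs, "results/paralog_counts.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

cores <- extract_helicase_cores(ds$proteins, ds$profile_hits)
writeXStringSet(AAStringSet(cores), "results/helicase_cores.fasta")
message(sprintf("merged helicase cores: %d sequences, lengths %d-%d",
                length(cores), min(nchar(cores)), max(nchar(cores))))
message("wrote results/assignments.tsv, paralog_counts.tsv, helicase_cores.fasta")
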