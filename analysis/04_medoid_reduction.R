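#!/usr/bin/env Rscript
# Step 4 — identity pruning and medoid dereplication.
#
# Removes graph edges below 70% identity, re-clusters the pruned graph
# with MCL to find tight groups, and represents each multi-member group by
# its medoid (minimal average dissimilarity, length near the group
# median). Writes the representative map and the reduced FASTA.

library(lhrfam)
library(Biostrings)

ds <- read_fixture_bundle("results/fixture")
prot <- read.delim("results/proteins_kept.tsv")
hits <- read_hits_tsv("results/hits.tsv")
graph <- read_edgelist_tsv("results/graph_edges.tsv",
                           nodes = prot$protein_id)

pruned <- prune_graph_by_identity(graph, 70)
message(sprintf("identity pruning at 70%%: %d of %d edges kept",
                igraph::ecount(pruned), igraph::ecount(graph)))

lens <- setNames(prot$length, prot$protein_id)
D <- dissimilarity_from_hits(hits, prot$protein_id)
rs <- reduce_dataset(pruned, lens, D)
message(sprintf(
  "%d representatives: %d unique sequences + %d medoids of tight groups",
  length(rs$representatives), rs$n_singletons, rs$n_medoid_groups))

rs2 <- discard_missing_core(rs, ds$profile_hits)
message(sprintf("core-domain filter: %d representatives retained",
                length(rs2$representatives)))

write_representatives_tsv(rs2, "results/representatives.tsv")
seqs <- setNames(ds$proteins$sequence, ds$proteins$protein_id)
writeXStringSet(AAStringSet(seqs[rs2$representatives]),
                "results/representatives.fasta")
message("wrote results/representatives.tsv, representatives.fasta")
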