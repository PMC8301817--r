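#!/usr/bin/env Rscript
# Step 8 — tree vs cluster concordance.
#
# Builds a neighbor-joining tree from the pairwise dissimilarities (a
# desk-scale stand-in for the externally inferred ML tree), roots it on
# the branch separating the most divergent groups (Lhr-like plus aLhr3
# against the rest, the rooting used for the family tree), and checks the
# concordance between subtrees and MCL classes.

library(lhrfam)
library(ape)

ds <- read_fixture_bundle("results/fixture")
prot <- read.delim("results/proteins_kept.tsv")
hits <- read_hits_tsv("results/hits.tsv")
assign <- read.delim("results/assignments.tsv")
clusters <- read.delim("results/clusters.tsv")

D <- dissimilarity_from_hits(hits, prot$protein_id)
nj_tree <- ape::nj(as.dist(D))
write.tree(nj_tree, "results/nj_tree.nwk")

labels <- setNames(assign$label, assign$protein_id)[nj_tree$tip.label]
outgroup <- names(labels)[labels %in% c("Lhr-like", "aLhr3")]
rooted <- tryCatch(
  root_between(nj_tree, outgroup, setdiff(nj_tree$tip.label, outgroup)),
  error = function(e) {
    message("no clean separating edge for the outgroup; midpoint rooting: ",
            conditionMessage(e))
    phytools::midpoint.root(nj_tree)
  })
write.tree(rooted, "results/nj_tree_rooted.nwk")

rep_fam <- class_concordance(rooted, labels)
message("concordance of subtrees with family labels:")
print(rep_fam)

mcl_labels <- setNames(paste0("class", clusters$cluster),
                       clusters$protein_id)[rooted$tip.label]
rep_mcl <- class_concordance(rooted, mcl_labels)
message(sprintf("fraction concordant with MCL classes: %.3f",
                rep_mcl$fraction_concordant))

export_itol_colorstrip(labels, "results/itol_families.txt",
                       dataset_label = "family",
                       tree_ids = rooted$tip.label)
export_itol_colorstrip(
  setNames(ds$proteins$taxon_group, ds$proteins$protein_id),
  "results/itol_taxa.txt", dataset_label = "taxon",
  tree_ids = rooted$tip.label)
message("wrote results/nj_tree.nwk, nj_tree_rooted.nwk, itol_families.txt, itol_taxa.txt")
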