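#!/usr/bin/env Rscript
# Step 7 — gene-neighborhood microsynteny.
#
# Collects the genes within 4 kb of every focal gene, tabulates how often
# each neighbor annotation recurs across the genomes carrying each family,
# and checks whether the planted neighbor's presence near two families is
# mutually exclusive at the genome level.

library(lhrfam)

ds <- read_fixture_bundle("results/fixture")
assign <- read.delim("results/assignments.tsv")
fam_of <- setNames(assign$label, assign$protein_id)

tab <- conservation_profile(ds$features, fam_of)
write_conservation_tsv(tab, "results/context_conservation.tsv")
message("neighbor conservation by family (top rows):")
print(head(tab, 8))

planted <- tab[tab$neighbor_profile == "TIGR0024", ]
if (nrow(planted) > 0) {
  message(sprintf(
    "planted neighbor (TIGR0024): conserved in %.0f%% of genomes on average",
    100 * mean(planted$fraction)))
}

cc <- cooccurrence_summary(ds$features, fam_of, "aLhr1", "aLhr2",
                           "TIGR0024")
message("aLhr1/aLhr2 neighbor co-occurrence over shared genomes: ",
        paste(names(cc$counts), cc$counts, sep = "=", collapse = " "))

export_context_itol(ds$features, fam_of, "results/context_itol.txt")
message("wrote results/context_conservation.tsv, context_itol.txt")
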