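# lhrfam — phylogenomic classification of Lhr-type SF2 helicases

Lhr ("large helicase related") proteins are superfamily-2 helicases
found across Archaea and Bacteria, built around a conserved core of two
RecA-like ATPase domains (Pfam PF00270 + PF00271), a winged-helix motif
and the Lhr-specific Domain 4 (PF08494). They split into six
phylogenetic groups — aLhr1, aLhr2, aLhr3 in Archaea and bLhr,
bLhr-HTH, Lhr-like mostly in Bacteria — distinguished by whether
Domain 4 is intact, deteriorated or absent, and by C-terminal
decorations (a Cys-rich Zn-finger-like motif, an HTH_42 domain).

`lhrfam` is an R package plus a numbered analysis workflow that
implements the classification pipeline end to end, for people who want
to reproduce, audit, or adapt this kind of protein-family analysis at
desk scale:

* candidate filtering from profile hits (E ≤ 1e-4, ≥ 30% profile
  coverage; one strain per species);
* exact affine-gap Smith–Waterman all-against-all comparison (BLOSUM62,
  gap −11/−1) with Karlin–Altschul E-values, *E* = *K·m·n·*e^(−λS);
* best-bidirectional-hit (BBH) graph, edges between species weighted by
  the average −log10 E-value;
* from-scratch Markov Clustering (MCL) with an inflation scan (IF 2–6)
  and an adjusted-Rand stability criterion;
* sample reduction: 70%-identity edge pruning, re-clustering, medoid
  representatives (minimal average dissimilarity, length near the group
  median), keep-list re-insertion, core-domain filtering, plus the Sfth
  outgroup filter (PF00270 + PF09369 + PF00271);
* domain-architecture calls and the six-group labeling rules;
* merged RecA1+RecA2 helicase-core extraction, gap-threshold column
  trimming (trimal `-gt` analog) and supermatrix concatenation;
* gene-neighborhood microsynteny within 4 kb, conservation and
  co-occurrence tables;
* newick tree rooting on a named bipartition and subtree-vs-class
  concordance, with iTOL annotation export.

A synthetic-data module generates datasets with planted families,
architectures and gene neighborhoods under a single master seed, so the
whole pipeline is verifiable against known truth without downloading
genomes. External heavy tools (blastp/hmmscan themselves, mafft,
iq-tree…) are out of scope: the package consumes their input/output
formats (FASTA, domtblout-like TSV, outfmt-6 TSV, GFF3, newick) and
emits the files they would consume.

## Worked example

The numbered scripts under `analysis/` run the whole study on the
standard synthetic dataset (6 families of sizes 20/12/8/4/3/2, 49
proteins over 25 species, seed 7):

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_all_vs_all.R
# ... through analysis/08_tree_concordance.R
```

What they print (abridged):

```
01  simulated 49 proteins in 6 families over 20 species
02  candidate filter: 49 of 49 proteins pass
    2352 directed hits; mean identity 72.2% within families, 28.3% between
03  BBH graph: 49 nodes, 294 edges
    minimal stable inflation: 2
    stable partition: 6 clusters, ARI vs planted truth 1.000
04  identity pruning at 70%: 272 of 294 edges kept
    6 representatives: 0 unique sequences + 6 medoids of tight groups
05  family assignment: 100.0% agreement with planted truth
    merged helicase cores: 49 sequences, lengths 350-350
06  supermatrix: 20 species x 2100 columns from 6 markers
07  planted neighbor (TIGR0024): conserved in 76% of genomes on average
08  fraction of concordant leaves: 0.959
```

Reading this: the planted families are recovered exactly by the
BBH+MCL stage (adjusted Rand index 1.0 against the planted truth, with
the partition already stable at inflation 2 because the families are
well separated); every protein gets its true group label back from the
architecture rules; the 70%-identity medoid step collapses each tight
family to one representative; the neighbor-gene conservation fraction
estimates the 0.6 planting probability within binomial error; and a
neighbor-joining tree built from the pairwise dissimilarities is
concordant with the families except for two stragglers among the
smallest, most divergent groups (fraction 0.959).

Intermediate tables land in `results/` (hit tables, edge lists, cluster
files, representative maps, conservation tables, iTOL annotation
files).

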