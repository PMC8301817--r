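---
title: "Classifying Lhr-type SF2 helicases: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying Lhr-type SF2 helicases: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Lhr ("large helicase related") proteins are superfamily-2 helicases built
around a conserved core: two RecA-like ATPase domains (Pfam PF00270
"DEAD" and PF00271 "Helicase_C"), a winged-helix motif, and an
Lhr-specific C-terminal-side domain of unknown function, Domain 4
(PF08494). Archaeal and bacterial Lhr proteins fall into six groups that
differ in the state of Domain 4 (intact, highly deteriorated, or absent)
and in C-terminal decorations: a cysteine-rich Zn-finger-like motif
(aLhr1), an appended helix-turn-helix domain HTH_42/PF06224 (bLhr-HTH and
some aLhr2), or nothing beyond the core (bLhr, Lhr-like). `lhrfam`
implements the phylogenomic pipeline that produces this classification —
candidate detection, similarity-graph clustering, sample reduction,
architecture-based labeling, microsynteny, and tree/cluster concordance —
as tested, deterministic R code that runs at desk scale.

Genome-scale inputs (thousands of proteomes, profile searches against
CDD/Pfam) are deliberately out of scope: profile hits arrive as a
domtblout-like table and pairwise hits as an outfmt-6-like table, the
formats the external tools emit. A synthetic-data module generates inputs
with planted ground truth so that every stage can be verified end to end
without downloads.

# Pipeline model and assumptions

1. **Candidate filter.** A protein is an Lhr candidate when it hits the
   family search profile (the COG1201 stand-in) with E-value at most
   `1e-4` and the hit covers at least 30% of the profile. One strain is
   kept per species (lexicographically smallest strain key — the original
   procedure does not say how the strain was chosen, so we use the
   deterministic, auditable rule).
2. **All-against-all comparison.** Exact affine-gap Smith–Waterman under
   BLOSUM62 with gap open −11, gap extend −1 (a gap of length *L* costs
   11 + *L*), delegated to `Biostrings::pairwiseAlignment`. Percent
   identity follows the blastp `pident` convention (identical columns
   over alignment length, gap columns included) because the 70%/55%
   thresholds downstream were applied to blastp-style identities.
   E-values use the Karlin–Altschul closed form
   *E* = *K·m·n·*exp(−λ*S*) with the classical ungapped BLOSUM62
   constants λ = 0.267, *K* = 0.041; *m* is the query length and *n* the
   summed length of the other proteins. Composition-based statistics and
   search-space corrections are omitted: the scorer is a reproducible
   stand-in, not a numerical clone of any blastp build. E-values are
   floored at 1e-180 so that −log10 *E* edge weights stay finite.
3. **BBH graph.** A directed best hit is kept per (query, target
   species); an edge exists only when both directions are reciprocal
   best hits, weighted by the mean −log10 E-value of the two directions,
   with the mean identity as an edge attribute. Edges never join two
   proteins of the same species.
4. **Markov Clustering.** Canonical MCL: column-normalize the weighted
   adjacency with self-loops, then alternate expansion (matrix square)
   and inflation (entrywise power *r*, renormalize), pruning entries
   below 1e-6, until the largest entrywise change drops below 1e-8 or
   200 iterations. Clusters are weakly connected components of the
   converged matrix's non-zero pattern; nodes are processed in sorted-id
   order, so results are deterministic. Self-loops get the node's
   maximum incident edge weight rather than the classical 1: the
   −log10-E weights here routinely exceed 100, and a unit loop would be
   invisible next to them. The inflation factor is scanned (2–6 by
   default) and the partitioning is called stable from the smallest
   value whose partition agrees with every larger scanned value at
   adjusted Rand index ≥ 0.999 with an equal cluster count — an
   operational reading of "stable classes" that the source procedure
   leaves qualitative. Two identical degenerate partitions (for example
   two all-singleton partitions, where the ARI formula is 0/0) score 1
   by convention.
5. **Medoid reduction.** Graph edges with identity below 70% are removed
   (55% in Sfth outgroup mode), the pruned graph is re-clustered with
   MCL at the same inflation as the main run, and each multi-member
   group is represented by its medoid: the member minimizing the mean
   dissimilarity (100 − identity; 100 for pairs with no significant
   alignment) to the rest of its group, restricted to members whose
   length is within ±10% of the group's median length ("close to the
   median length" is not quantified in the source; if no member
   qualifies, the members nearest the median are used, so a medoid
   always exists). Keep-list sequences are re-inserted afterwards, and
   representatives lacking PF00270 and/or PF00271 are discarded.
6. **Architecture calls and labels.** Domain 4 is *intact* when a
   PF08494 hit passes the reporting floor (E ≤ 1e-3) and covers at
   least 50% of the profile, *deteriorated* when hits exist only below
   that coverage, *absent* otherwise. "Highly deteriorated" has no
   stated threshold in the source; 50% coverage is our quantification
   and is exposed in `classifier_params()`. The cysteine-rich call
   counts cysteines (≥ 4 by default) in the 120 residues after the
   Domain 4 end (after the last core-domain end when Domain 4 is
   absent); this count-in-window rule is likewise a stand-in for an
   annotation whose original basis is unstated. Labels follow the group
   rules: no core → unclassified; Domain 4 absent → Lhr-like;
   Bacteria/intact → bLhr-HTH or bLhr by HTH_42; Archaea or
   Asgard/intact → aLhr1 if Cys-rich else aLhr2 (HTH_42 permitted, as
   in Methanomassiliicoccales); Archaea or Asgard/deteriorated → aLhr3.
   An optional cluster-consensus mode labels each MCL class by its
   majority architecture, mirroring how groups are named per subtree;
   per-protein rules are the default.
7. **Core extraction, trimming, concatenation.** The merged helicase
   core is the concatenation of the sub-sequences covered by the best
   (lowest-E) PF00270 and PF00271 hits, overlapping intervals merged
   first. Alignment columns are trimmed by the gap-threshold rule
   (keep a column when its non-gap fraction is ≥ `gt`, default 0.1 —
   trimal's documented `-gt` semantics, adopted to resolve the
   qualitative "high deletion frequency"). Marker alignments
   concatenate into a supermatrix with all-gap blocks for missing taxa
   and a RAxML-style partition table.
8. **Microsynteny.** Neighbors are genes on the focal gene's contig
   whose interval lies less than 4000 bp away, distance measured
   between nearest interval boundaries (the most permissive natural
   reading of "less than 4000 bp"; gene starts would be an
   alternative). Upstream/downstream is defined relative to the focal
   gene's strand. Conservation is reported per (family, neighbor
   profile) as the fraction of family-carrying genomes with the
   neighbor in-window; co-occurrence between two families is a
   genome-level 2×2 table whose mutual-exclusivity flag requires an
   empty "both" cell with both exclusive cells occupied. Contigs are
   linear; circular chromosomes are not modeled.
9. **Tree concordance.** Externally inferred trees are consumed as
   newick. `root_between()` places the root on the single edge
   separating two named leaf sets (midpoint of that edge when branch
   lengths exist). Monophyly is judged against the rooted topology, and
   the number of leaves whose removal would make a class monophyletic
   is computed exactly as the minimum over clades *v* of (non-members
   inside *v*) + (members outside *v*); this clade-cost minimum equals
   the enumeration answer and is cheap at any size, so no greedy
   fallback is needed. The concordant-leaf fraction is
   1 − Σ removals / leaves.

# The synthetic generator

`synth_params()` defaults define the standard study dataset used by the
test suite and the analysis scripts: 6 families of sizes 20/12/8/4/3/2
(49 proteins), 25 species × 1 strain, one family per architecture row of
`default_architectures()` (aLhr2, aLhr1, bLhr, bLhr-HTH, aLhr3,
Lhr-like), `within_identity = 0.85`, `between_identity = 0.25`, helicase
core of 350 residues, a conserved neighbor gene (profile `TIGR0024`, the
metallophosphoesterase stand-in) planted immediately upstream of focal
genes with probability 0.6, and master seed 7.

Design points worth knowing before trusting a passing test:

* **Identity is the dial, not realism.** Members are mutated to the
  target identity *relative to their family ancestor*, substitutions
  drawn uniformly over the 19 alternative residues, no indels. Realized
  pairwise identity between two members is therefore lower than the
  dial (about 0.72 when the dial is 0.85); between families it is near
  the random floor. The planted separation is intentionally wide — the
  recovery tests demonstrate correctness of the pipeline mechanics, not
  its resolution on hard, realistically noisy families.
* **Architecture realization is guaranteed.** Profile-hit rows are
  written directly from the family's architecture spec (a deteriorated
  Domain 4 is a hit covering 30% of the profile, safely below the 50%
  intactness threshold; an absent one has no hit), and the C-terminal
  window is rewritten after mutation (eight cysteines planted for
  Cys-rich families, stray cysteines replaced by serine otherwise) so
  that random substitutions cannot flip the classifier call. Generator
  and classifier are co-designed to be separated; the 100%
  label-recovery check validates the rule plumbing, not classifier
  robustness near its thresholds.
* **Gene layout.** One contig per genome, focal genes on the plus
  strand. The planted neighbor sits `window_gene_spacing` (200 bp)
  upstream of its focal gene; successive focal-gene blocks are 5000 bp
  apart — beyond the 4 kb window — so a planted neighbor is in exactly
  one focal gene's neighborhood and conservation fractions estimate the
  planting probability without bleed-through.
* **Determinism.** All randomness derives from the master seed by
  stable hashing of record ids, so generation is independent of
  insertion order and two runs produce byte-identical fixture bundles.
* Not emulated: indel processes, rate heterogeneity among sites,
  substitution-matrix-biased mutation, multi-contig or circular
  genomes, paralog birth within a genome, annotation noise in profile
  hits. Conclusions about the pipeline's behavior on such data cannot
  be drawn from these fixtures.

# Numerical choices and degenerate inputs

* MCL uses sparse matrices (`Matrix`), pruning at 1e-6 and convergence
  at 1e-8, both exposed in `mcl_params()`; column stochasticity is
  maintained to ~1e-9 per step. Ties everywhere in the pipeline break
  lexicographically (best hits, medoids, cluster numbering), which is
  what makes reruns byte-identical.
* Empty-edge graphs cluster into singletons; an empty hit table gives an
  empty candidate set; a trimmed alignment may legitimately have zero
  columns; `compute_medoid` of a singleton group is that member.
* The local aligner returns an explicit empty hit (score 0) when no
  positive-scoring local alignment exists, and `all_vs_all` simply
  omits such pairs.

# Problem sizes

The test suite and the acceptance script run the full pipeline on the
49-protein standard dataset (about 1,200 exact pairwise alignments of
~400–600-residue sequences, around a minute), 50 random ≤ 12-node graphs
for the MCL/dense-reference equivalence, 100 random groups for the
medoid oracle, 200 random hit configurations for core extraction, 100
random peptide pairs for the alignment DP oracle, and 50-genome
neighborhoods for conservation recovery. These sizes were chosen so the
whole verification cycle completes in a few minutes on one CPU while
still exercising every rule at non-trivial scale.

# Known limitations

* The pairwise scorer reproduces blastp's conventions, not its numbers:
  no composition-based statistics, no effective-search-space length
  correction, fixed ungapped λ/K. Graph weights are therefore
  internally consistent but not comparable to a real blastp run.
* The original genome snapshot (4,055 complete genomes plus 75 Asgard
  proteomes) and the external tools it was processed with (rpsblast,
  hmmscan, mafft, divvier, trimal, modeltest-ng, iq-tree, t-coffee's
  TCS filter) are out of scope; headline counts that depend on that
  snapshot (candidate totals, class sizes, medoid counts) are not
  recomputable here and are not claimed.
* Monophyly is assessed on the rooted topology only; branch support is
  carried through rooting but not used in concordance.
* The Asgard proteomes' lower annotation quality is represented only as
  a taxon tag; no quality weighting is applied anywhere.
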