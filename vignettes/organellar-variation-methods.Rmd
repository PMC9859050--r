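---
title: "Methods: intraspecific organellar variation analysis with organvar"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: intraspecific organellar variation analysis with organvar}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(organvar)
```

# Scope

`organvar` analyses intraspecific variation in organellar genomes from
multiple alignments of complete plastomes and of single-copy mitogenome
regions: alignment-based SNP and InDel discovery, annotation against a GFF
feature set, mutation-spectrum and hotspot statistics, haplotype collapsing,
indel-block distances, randomized minimum-spanning-tree (RMST) haplotype
networks, bootstrapped neighbour-joining (NJ) trees with JC/HKY model
selection, and comparison of the plastid and mitochondrial topologies.
Alignments are consumed, not produced: the package starts where an aligner
(e.g. MAFFT) stops. A synthetic organellar-population simulator with exact
truth tables makes every stage testable without sequence downloads.

# Variant model

## SNPs

A SNP is an alignment column carrying at least two distinct bases among
A/C/G/T. Gaps, `N` and IUPAC ambiguity codes are missing data: they are
excluded from allele counts and never called as alternate alleles. A
multiallelic column yields a single variant record with all alternate
alleles retained; the alternate count is taken against the majority base
(ties resolved in favour of the reference sample's base, then
alphabetically). The default reporting floor is `min_alt_count = 1`:
read-mapping-style frequency and p-value filters are designed for piles of
sequencing reads, and in a 16-sequence alignment a 10% frequency floor would
erase exactly the singleton private alleles that distinguish individuals. A
frequency threshold remains available as an option.

## InDel blocks

InDels are scored as events, not columns: an InDel event is a maximal run of
contiguous columns with an identical per-sample gap/base pattern ("simple
indel coding"). A 7-bp deletion shared by three samples is one event; two
overlapping deletions with different sample sets are two events, split where
the pattern changes. Each sample is scored present/absent for the block, and
an event contributes one unit to all downstream statistics and distances
regardless of its length. Columns that are gapped in every sample are
rejected as malformed input. Whether a multiallelic column is one or several
SNPs is a convention; one variant per column is used here, with allele
multiplicity kept in the record.

## Coordinates and IR trimming

All coordinates are 1-based inclusive (the GFF3 convention); alignment
columns are projected onto a designated reference sample by counting its
non-gap characters, and columns where the reference is gapped map to the
preceding reference base. Plastomes carry two identical inverted-repeat
copies; the later-starting copy is removed before calling so repeat-resident
variation is counted once. Exactly 0 or 2 IR features are accepted — a
single IR annotation is an error, not a guess.

# Annotation

The reference is tiled completely into exon segments, introns (within-gene
gaps between exon segments) and intergenic spacers named
`"geneA--geneB"` from the flanking genes in forward-strand order (`ter`
stands in for the molecule ends). Coding SNPs are classified
synonymous/nonsynonymous by translating the reference and alternate codons
of the spliced CDS (exons concatenated, minus-strand genes
reverse-complemented) — plastid CDS under NCBI translation table 11, plant
mitochondrial CDS under table 1, both overridable. RNA editing is ignored,
which is a known limitation for mitochondrial effect calls. Variants in
tRNA/rRNA genes have exon context but effect "noncoding": translating them
would be meaningless. InDel blocks straddling a region boundary are assigned
to the region containing their first reference base.

# Summary statistics

The substitution spectrum assigns each biallelic SNP to one of six unordered
pair classes (transitions A&harr;G, C&harr;T; transversions A&harr;C,
A&harr;T, G&harr;C, G&harr;T); a multiallelic SNP contributes one unit split
equally over its alternate alleles' classes, so classes always sum to the
SNP count. Regional variability is reported under *both* metrics in
circulation — share-of-total, (SNP+InDel)/total mutations, and per-bp
density, (SNP+InDel)/region length — because published figures mix the two
(spacer shares like 20.63% are share-of-total; intron figures like 0.44% are
per-bp). Within-population polymorphism counts a position (or InDel event)
for a population iff its members carry at least two distinct non-missing
alleles there; single-member populations are structurally monomorphic and
flagged. The overall density `changes_per_bp` takes its denominator as an
explicit argument since the genome-length convention (full circle with both
IRs vs trimmed alignment) is itself a reporting choice.

# Haplotypes and networks

Individuals sharing identical characters at every variant position (SNP
alleles plus InDel presence/absence) collapse into one haplotype, labelled
by its first member. Exact identity, not a distance threshold, defines the
classes — this reproduces the behaviour of whole-population haplotype
tables where, e.g., an entire population shares one haplotype.

The indel-block distance between two gapped sequences is the number of
substitution differences at co-present sites plus the number of maximal gap
blocks present in exactly one of the two (a shared identical block
contributes 0; any block contributes 1 regardless of length). On gap-free
pairs it reduces to the Hamming distance.

The RMST network repeats Kruskal's algorithm with the edge order randomly
permuted before a stable sort by weight, so ties among equal-weight edges
break uniformly at random; the union over iterations is the network, each
edge's support is its inclusion fraction, and support &lt; 1 flags an
"alternative pathway". The iteration count is a free parameter; the default
of 200 is empirically sufficient for networks of &le; 16 haplotypes to
reach the exhaustive all-MST union, which the test suite verifies at 2000
iterations against a C++ oracle that enumerates every labelled spanning
tree via Pruefer sequences (refused above 8 nodes, where enumeration stops
being exhaustive-in-seconds).

# Trees and models

NJ follows Saitou–Nei with the standard Q-criterion. Ties in Q break
deterministically by cluster label order (a cluster is labelled by its
alphabetically first leaf); negative branch-length estimates are clamped to
zero with the deficit moved to the sister branch, preserving the joined
path length. On additive matrices the algorithm recovers the generating
tree exactly, which the tests assert on random trees up to 12 taxa.

Distance corrections: JC uses the closed form `-(3/4) log(1 - 4p/3)`
(saturated at p &ge; 0.75); the "HKY" pairwise distance is the closed form
of the TN93 family with the two transition classes kept separate, since no
simple exact pairwise formula exists at the single-kappa constraint. It
reduces to JC exactly when frequencies are equal and transitions occur at
the transversion rate.

Bootstrap supports resample alignment columns with replacement, rebuild the
NJ tree per replicate, and map the percentage of replicates containing each
internal bipartition of the full-data tree onto that tree (mapping, not
consensus). Replicates whose distances saturate are redrawn.

Model selection fits JC and HKY on the fixed NJ topology by Felsenstein
pruning, maximizing over a single global branch-length scale (and, for HKY,
kappa) by coordinate golden-section search to tolerance 1e-6, with
empirical base frequencies, and chooses by `AIC = 2k - 2 logL` with k = 0
(JC) and 4 (HKY: kappa + 3 free frequencies). Optimizing one global scale
rather than every branch is a deliberate simplification: the object of
interest is the model choice, not branch lengths. Because frequencies are
plugged in empirically rather than ML-optimized, the HKY likelihood can in
principle fall a hair below the JC likelihood on data with exactly uniform
composition; with any real compositional skew the empirical frequencies pay
for themselves and the nested-model inequality holds.

Rooting places the root at the midpoint of the outgroup's pendant edge.
Tree comparison reports the Robinson–Foulds distance plus a leaf
association table for tanglegram-style display; no graphical rotation
optimization is attempted.

# The simulator

`build_reference("plastome")` lays down a molecule with the canonical
LSC | IRa | SSC | IRb architecture (IRb an exact reverse complement of
IRa), genes with real plastid names — some intron-containing, some
minus-strand — and named spacers including the hotspot spacers
`ndhD--ccsA`, `rps4--rps16` and `trnL(UAG)--ndhF`.
`build_reference("mitogenome")` emits 14 unlinked single-copy regions on
three chromosomes (8 on chMt1, 4 on chMt2, 2 on chMt3). The default scale
is a deliberately down-scaled ~20 kb plastome and ~26 kb region set: every
structural element of the full-size molecules is present, and the `scale`
argument restores any size. Mutation rates are set per region class so the
default plastome yields on the order of 64 SNPs and 96 InDels and the
mitogenome set ~8 SNPs and ~16 InDels — the yields observed in the study
system — concentrated in non-coding DNA, with hotspot spacers boosted 8x/3x/2x
and the nad2 intron 6x.

Mutations are planted site-wise: SNP alternate bases are transitions with
probability `kappa/(kappa+2)` (default kappa 0.9, i.e. a transversion-rich
spectrum with transition share 0.31); InDel events draw geometric lengths
(p = 0.5) and are split evenly between deletions and insertions; InDels are
confined to non-coding regions by default so CDS frames stay intact and
effect annotation remains well-posed. Each mutation is carried by one
uniformly chosen population, each member independently with probability
0.8 — a simple, stated stand-in for mixed private/shared haplotypes. On
top, each population receives Poisson-distributed population-fixed
mutations (`population_divergence`, default mean 1), and a single divergent
outgroup individual (default label P22-6, ~25 private mutations) is
included for rooting. Both IR copies are held invariant, emulating the
concerted evolution and low mutability of the repeat; trimming therefore
never removes planted variation.

Events never overlap and keep at least one untouched site between them, so
the true alignment — emitted directly from the planted events, with no
aligner involved — supports *exact* recovery: calling variants on it
reproduces the truth table with recall = precision = 1, the central
acceptance property of the pipeline. Keeping an aligner out of the loop is
deliberate: aligner nondeterminism would otherwise leak into every
downstream assertion.

What the simulator does **not** model: coalescent genealogies,
recombination, selection, RNA editing, plastid-derived insertions (MTPT),
sequencing error, or alignment error. Passing tests therefore demonstrate
the correctness of the pipeline's logic on ideal alignments, not robustness
to misalignment — on real data, InDel block boundaries can shift with
aligner choice, which perturbs block counts but not the SNP calls.

# Numerical choices and problem sizes

* Distance corrections raise errors ("saturated") instead of returning NaN;
  bootstrap replicates that saturate are redrawn.
* Transition probabilities come from the eigendecomposition of the
  symmetrized rate matrix, normalized to one expected substitution per unit
  branch length; tiny negative entries from round-off are clamped to zero.
* Site patterns are compressed before pruning; the 4x4 eigendecomposition
  is cached per model object.
* Branch-scale and kappa optimization run on log scale over [1e-4, 100] and
  [0.02, 500] respectively, tolerance 1e-6, at most 200 coordinate rounds
  (non-convergence is flagged, not hidden).
* All stochastic stages take explicit seeds; one master seed is split
  deterministically into per-stage streams, so a fixed configuration is
  byte-reproducible and changing the seed can never alter variant calls on
  a fixed alignment.
* Test and acceptance problem sizes: truth recovery uses 100 simulated
  ~20 kb plastome datasets; RMST-vs-oracle uses 50 random matrices of 4-8
  nodes at 2000 iterations; NJ recovery uses 100 random additive matrices
  (&le; 12 taxa); model-selection recovery uses 50 replicates per
  generating model on 16-taxon trees — the size of the study sample —
  with 1.2 kb alignments, where AIC recovers the generating model in ~97%
  of replicates. Six-taxon harnesses were rejected because there the
  JC-recovery rate sits exactly at the AIC asymptote
  (P(&chi;&sup2;&#8324; &gt; 8) &asymp; 9%), making any fixed 90% threshold
  a coin flip rather than a property check.

# Known limitations

* Effect annotation trusts the input gene models; pseudogenes are whatever
  the annotation says they are.
* The within-population polymorphism rule (&ge; 2 distinct alleles among
  members) is one of several possible conventions; published per-population
  counts based on different attribution rules can differ by one or two.
* The "HKY" distance is the TN93 closed form, and model selection compares
  JC against HKY only — no Gamma rates, no GTR.
* Mitochondrial RNA editing is ignored when classifying coding SNPs.
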