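---
title: "Methods: stratified pan-genome analysis of Streptomyces-like collections"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: stratified pan-genome analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its methods: the models and
procedures each stage implements, the tunable parameters and why their
defaults are what they are, what the synthetic-data generator does and
does not emulate, and the numerical and design decisions taken where the
problem left room.

# The analysis pipeline

## Species demarcation: ANI + Markov clustering

Bacterial species are demarcated at the conventional 95 % genome-wide
average nucleotide identity (ANI) boundary. `ani()` implements a
seeded-fragment approximation: the chromosome (defined throughout as the
longest replicon) of genome A is cut into non-overlapping 1000-nt
fragments; each fragment's best window in genome B is located by exact
15-mer diagonal voting, strand-aware (the better-supported of the forward
and reverse-complement orientation wins); the contiguous seeded span of
the fragment is then aligned with a banded semi-global nucleotide
alignment (match +1, mismatch −1, gap open 3, extend 1, band half-width
12 nt). A fragment *qualifies* when its alignment identity is ≥ 0.70 over
≥ 0.50 of the fragment length; ANI is the mean identity of qualifying
fragments, symmetrized as the mean of the two directions. If either
direction has fewer than 5 qualifying fragments the ANI is *undefined*
(`NA`) — never 0 — and contributes no edge to the species graph, which
avoids spurious cluster splits from unalignable pairs.

Aligning only the contiguous seeded span (with coverage still measured
against the whole fragment) matters for accuracy: fragments that straddle
gene-content breakpoints otherwise mix homologous and non-homologous
sequence into one identity value near the qualifying boundary. With the
span rule such fragments either contribute their homologous part at
reduced coverage or drop out, and realized ANI tracks the true sequence
divergence. Seeds are sampled every 3 nt; this halves sensitivity only
near the 0.70 qualifying floor, far below the 0.95 decision boundary.

Genomes with ANI ≥ 0.95 are connected (edge weight = raw ANI; the paper
trail gives no transformation, so none is applied) and partitioned with
`mcl()`, a from-scratch Markov Cluster implementation on sparse matrices:
add self-loops at the maximum incident weight (making the partition
invariant to uniform weight scaling), column-normalize, then alternate
expansion (matrix squaring) and inflation (elementwise power 2.0,
renormalization) with pruning of entries below 1e−6 until the matrix
changes by less than 1e−8; clusters are the connected components of the
converged matrix. Inflation 2.0 is the community default; the clustering
here separates near-cliques split by a hard threshold, so the result is
insensitive to it (tests verify equality with connected components on
uniform-weight clique graphs for inflations 1.3–4).

Cluster ids are `C0, C1, …` by decreasing size; each cluster's
representative is its lexicographically smallest complete-assembly
genome. `flag_misannotations()` reports annotation labels split across
clusters and clusters mixing labels; `check_monophyly()` tests a cluster
against a supplied rooted tree (via ape).

## Protein homology

`align_proteins()` is a semi-global ("overlap") Gotoh alignment with free
terminal gaps in both sequences, BLOSUM62 (taken from Biostrings) and
affine gaps (open 11, extend 1). Identity is matches over aligned
columns, excluding terminal-gap columns; `X` is tolerated but never
counted as a match; coverage is the aligned-span fraction of each
protein. Tie-breaking is fully deterministic (diagonal over gap-in-a over
gap-in-b on equal score; end cell chosen by a fixed scan order), which is
what lets the test suite demand *exact* equality with an independently
written textbook dynamic-programming oracle — with co-optimal alignments,
identity is only well-defined once the tie-break is pinned down.

All-vs-all searches (orthogroup graph construction) use a shared-k-mer
prefilter (5-mers, ≥ 4 shared, deduplicated per sequence) to skip
hopeless pairs before alignment; the cross-species close-homolog screen
uses a more permissive setting (5-mers, ≥ 2 shared). The prefilter is a
heuristic: at the 50 % identity / 50 % length homolog rule a true hit
shares several 5-mers in expectation, and an `exhaustive = TRUE` mode
exists on every search so the heuristic can be (and is, in the tests)
verified against the full search. Within-genome searches — the paralog
identity-bin profile and singleton detection — are always exhaustive.

The singleton criterion is deterministic rather than E-value-based: a
protein is a singleton when it has no within-genome hit at ≥ 30 % identity
over ≥ 50 % of the shorter protein. This stands in for a
database-size-dependent E-value cutoff and is configurable; bins for the
best within-genome hit are the five classes 51–60 … 91–100 %, half-open
(lower-exclusive, upper-inclusive) so that a best hit of exactly 0.60
falls in 51–60 and no value belongs to two bins.

## Orthogroups and the pan-genome strata

`build_orthogroups()` clusters the protein homology graph (edges at
≥ 50 % identity over ≥ 50 % of the shorter protein, weighted by identity)
with MCL; unclustered proteins become singleton orthogroups, and ids are
assigned by decreasing member count so the construction is invariant to
genome input order.

Because sequencing effort is strongly biased toward a few species,
`normalize_dataset()` caps each species at 5 genomes, selecting complete
assemblies first, then drafts, each in lexicographic id order, and logs
every decision. Core membership is by *presence* (≥ 1 member gene; copy
number is ignored), and presence fractions are compared with exact
integer arithmetic (`count * 100 >= t_hundredths * total`) so that 19 of
20 genomes meets the 0.95 threshold without floating-point boundary
accidents. Hard (100 %) and soft (95 %, 90 %) cores are nested by
construction and asserted at run time.

A *relaxed fingerprint* of a species is an orthogroup present in all of
its selected genomes and in zero genomes of any other species — evaluated
against all genomes of the other species in the normalized dataset, not
only representatives, which is the strongest reading of "absent from all
other species". A *strict* fingerprint additionally has no cross-species
close homolog: its representative protein (the member in the species'
representative genome) finds no hit at ≥ 50 % identity over ≥ 50 % of its
length among other species' proteins. Species with fewer than two
selected genomes are processed but flagged low-confidence.

## Chromosome geography

The linear chromosome is split into left arm `[0, L/4)`, centre
`[L/4, 3L/4)` and right arm `[3L/4, L)`; a gene's zone is decided by its
midpoint (integer division), so genes spanning a boundary are not split
and the assignment is order-independent; a midpoint exactly on a boundary
belongs to the right-closed interval that starts there. Circular
replicons are rejected — the arm/centre geometry presumes linearity — and
plasmids (non-longest replicons) are excluded from all per-chromosome
statistics, mirroring the restriction to chromosomally encoded proteins.

Enrichment of a gene set in the arms (jointly) or the centre is an exact
hypergeometric test with the universe being that genome's chromosome
genes. Both tails are always reported; the verdict applies the dual rule:
*over* iff `p_over < 0.05` *and* the observed frequency exceeds the
background by ≥ 5 percentage points (absolute; a `relative = TRUE` switch
implements the reading "≥ 5 % of the background frequency"). The absolute
reading is the default because the rule is applied to frequencies around
0.25–0.75, where a relative 5 % would be a much weaker filter than the
significance test itself. No multiple-testing correction is applied
across genomes or sets by default, matching per-genome usage; a
Benjamini–Hochberg pass can be applied downstream to the reported
p-values.

## TTA codons

`scan_tta()` reads whole codons in frame 0 of the coding-strand CDS
(`cds` is stored coding-strand oriented from the moment of I/O, so strand
never enters codon analysis); a TTA substring spanning a codon boundary
does not count. Codon 1 is the initiator; the terminal stop codon can
never match. Genes whose CDS length is not divisible by 3 (draft-assembly
realism) are kept in pan-genome analyses but excluded from scanning.

Orthogroup-level conservation uses one representative member per species
(from the species' representative genome). The *any-position* fraction is
the share of orthogroup-carrying species whose member has ≥ 1 TTA.
Position-specific conservation maps each member's TTA codons to reference
coordinates through the pairwise alignment of the member protein to the
orthogroup reference member (the member from the lexicographically
smallest species cluster); a reference site is *conserved* when ≥ 50 % of
the species with the orthogroup have a TTA mapped to it. Pairwise mapping
to a single reference, rather than a full multiple alignment, is a
deliberate interpretation: it is deterministic, cheap, and exact whenever
the proteins align confidently; members aligning below 0.3 coverage are
excluded from position mapping (but kept in the any-position fraction)
and logged. COG-category enrichment of TTA-bearing genes is the same
hypergeometric machinery with the universe restricted to categorized
chromosome genes.

## Shared statistics

Exact hypergeometric tails come from `stats::phyper` (log-gamma
arithmetic) and are verified against full enumeration for every feasible
configuration with N ≤ 30 to 1e−12. Benjamini–Hochberg adjustment
delegates to `stats::p.adjust`; note that the step-up transform is not
idempotent (re-adjusting an adjusted vector changes it), so validity is
asserted as adjusted ∈ [p, 1] and rank-monotonicity. Z-score outliers use
the sample (n−1) standard deviation of the reference group and a strict
|z| > 2 rule; a boundary value of exactly 2 is not flagged. Jaccard
distance is `1 − |A∩B|/|A∪B|` with d(∅, ∅) = 0; intra-species feature
variability is the mean pairwise distance over complete genomes only
(draft assemblies cannot guarantee that multi-gene features such as
biosynthetic gene clusters are intact), and species with fewer than two
complete genomes are skipped with a log entry.

Species accumulation counts distinct species as genomes accrue, either in
a supplied release order or averaged over random orderings under a seed.
The saturation curve *y = a·(1 − e^(−x/b))* (a: asymptotic species count;
b: scale in genomes) is fitted by least squares with multi-start
Nelder-Mead on a fixed grid (a ∈ max(y)·{1, 2, 4, 8},
b ∈ max(x)·{0.1, 0.3, 1, 3}), optimizing log a and log b to enforce
positivity; the deterministic grid replaces a spreadsheet-solver fit with
the same objective, and the returned optimum's SSE is asserted to be no
worse than every start. Pearson correlations use the exact t-transform
with n − 2 degrees of freedom, BH-corrected across all pairs tested in
one call; constant columns yield undefined correlations and leave the BH
family.

# The synthetic pan-genome generator

The generator is the package's test bed: it produces strain collections
whose statistical structure matches what the analyses assume, with a
machine-readable truth key for every plant. Defaults are the package's
reference study conditions: 10 species × 5 strains, 300 gene families
(40 genus-core, 8 species-core and 5 fingerprint families per species,
130 accessory), 300-aa mean proteins, within-species protein identity
0.98 and ANI 0.97, between-species identity and ANI 0.85 for shared
families, GC 0.72, arm bias 0.8, seed-fixed to the byte. These sizes run
the full pipeline in minutes on one CPU while leaving every downstream
decision (95 % ANI cutoff, 50 %/50 % homology rules, 50 % conservation,
the zone dual rule) with a comfortable planted margin.

**Family stratification.** Genus-core families occur in every genome.
Species-core families occur in all strains of their species *and* in at
least one foreign genome (scattered accessory-style) — without that
guarantee a species-core family would be structurally indistinguishable
from a fingerprint. Fingerprint families are unique ancestors confined to
their species. Accessory families scatter with per-genome presence
probability 0.25; any scattered family that would by chance cover every
strain of a species is resampled out of one strain, so planted classes
remain operationally recoverable exactly.

**Sequence evolution.** Each family has an ancestral protein (length
N(300, 45), floor 60; high-GC proteome-like amino-acid composition) and
an ancestral codon template drawn from GC-weighted codon usage
(weights ∝ exp(γ·GC), with γ solved so expected coding GC matches the
target; TTA is excluded from the usable codon set so the only TTA codons
in a genome are the planted ones). Evolution is a star phylogeny:
species templates derive from the family ancestor and strains from their
species template. Amino-acid substitution is per-site with replacement
uniform over the 20 letters, at per-branch rates solved in closed form
from the pairwise identity targets (for a star pair at branch rate r,
expected identity is (1−r)² + 2r(1−r)/20 + r²/20; cross-species pairs
compose branch survival probabilities). Nucleotide divergence on top of
the protein process comes from synonymous codon resampling at a
per-branch probability solved by root-finding against an *exact*
enumeration of the lineage codon distribution (so genic pairwise
nucleotide identity hits the ANI target analytically, not by trial), plus
intergenic substitution at a rate solved from the same target. The
generator measures realized ANI on a sampled within- and between-species
pair and warns if more than a point off target.

**Chromosome layout.** Each species draws a layout: per family a zone
(volatile families — fingerprints, accessory, TTA-planted — go to an arm
with probability `arm_bias`; core-class families with probability
`1 − arm_bias`), a strand, an order within the zone and intergenic
spacers (100–200 nt). Zone capacities are padded with filler sequence at
each zone start so arms and centre occupy exactly 25/50/25 % of the
chromosome; strains of one species share the layout (so within-species
pairs are collinear up to accessory presence), while species differ in
order and strand (so between-species ANI is carried by gene-interior
fragments, as in real rearranged genomes). The symmetric placement rule
is important: at `arm_bias = 0.5` *every* gene is placed uniformly, which
makes the positional null exact — if core families were pinned to the
centre unconditionally, any volatile gene set would be arm-enriched
relative to the whole-genome background even with no planted signal, and
a false-positive rate could never be measured.

**TTA plants.** A fraction (default 0.2) of genus-core families get one
planted TTA: a leucine site in the ancestor is frozen against
substitution, and all strains of a configured species subset (default
half the species, i.e. site conservation 0.5) carry TTA there while all
other members carry CTG. `plant_tta()` applies the same operation post
hoc to any family, updating CDS, protein and chromosome consistently.
Category labels are drawn per family from class-specific COG-letter
weights (core families lean toward housekeeping letters, fingerprints
and accessory toward unknown function, TTA families toward regulatory
and secondary-metabolism letters); smBGC-type and CAZyme-family labels
are attached to volatile families with probability 0.25 each.

**What the generator does not emulate** — and therefore what passing
tests do not show about real data: gene-content evolution along a real
phylogeny (birth–death, HGT), recombination, indels within coding
sequences (alignment-free identity equals alignment identity here),
codon-usage structure beyond GC bias and TTA control, rate variation
across sites and lineages, assembly fragmentation (drafts differ only by
label), and paralogy beyond optional planted tandem duplicates. Results
on real *Streptomyces* data will be noisier in exactly these dimensions;
the tests establish correctness of the machinery, not field performance.

# Numerical choices and degenerate inputs

* Internal coordinates are 0-based half-open; GFF3 I/O converts at a
  single point (1-based inclusive), tested as a bijection.
* Presence thresholds use exact integer arithmetic (see above); identity
  and coverage comparisons are plain floating point — thresholds sit far
  from data under the study conditions.
* Undefined ANI is `NA`, never 0; missing edges, not weak ones.
* MCL non-convergence (cap 200 iterations) is an error carrying the
  iteration trace; in practice clique-like graphs converge in < 20.
* Empty gene sets, circular chromosomes, genomes with one protein,
  species with one genome, σ = 0 reference groups, all-zero saturation
  curves and infeasible hypergeometric configurations are explicit,
  tested error or flagged-result paths.
* All tables written by `write_tables()` are sorted on all columns, so
  byte-identical reruns are a tested invariant.

# Problem sizes used in the tests

The shipped test-and-verification runs use the reference conditions
(10 × 5 genomes, 300 families) for the end-to-end recovery checks; 20 and
40 single-strain species for the positional power and null runs (the null
uses more genomes because a false-positive *rate* needs a larger
denominator than a near-certain power check); 3 × 3 genomes for module
unit tests; 100 random pairs for alignment-oracle equivalence; 1000
random CDS for scanner-oracle equivalence; all feasible hypergeometric
configurations with N ≤ 30; and 100 noisy replicates for the
saturation-fit study. These sizes were chosen once as the package's
desk-scale reference conditions.

# Known limitations

* The ANI routine is a deliberately simple seeded-fragment approximation;
  it tracks true divergence on collinear-to-moderately-rearranged genomes
  but is not a reimplementation of any published ANI tool, and its
  absolute values should not be compared across tools at high precision.
* Fingerprint strictness screens only the representative protein of each
  fingerprint orthogroup; a family whose members straddle the homology
  threshold could in principle be classified differently under a
  different representative choice.
* Position-specific TTA conservation maps through pairwise alignments to
  one reference; for deeply diverged orthogroups a profile or MSA-based
  mapping would be more sensitive.
* E-value statistics are intentionally absent; the singleton floor is an
  identity/coverage rule and is documented as such wherever it stands in
  for an E-value cutoff.
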