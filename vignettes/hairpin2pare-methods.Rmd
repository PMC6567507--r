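---
title: "Methods: miRNA discovery, differential expression and degradome validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: miRNA discovery, differential expression and degradome validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hairpin2pare)
```

# Overview

`hairpin2pare` implements an interlaced small-RNA + degradome (PARE)
analysis for plant miRNAs: collapse sequencing reads to distinct tags,
ascertain mature miRNAs and isomiRs from hairpin-precursor evidence with
miRNA-star prediction, test differential expression across a
two-treatment (control/heat) by three-timepoint (0, 1, 4 days after
treatment) design with four biological replicates, and validate
miRNA-guided cleavage targets from degradome 5'-end profiles. Because
every stage makes statistical assumptions, the package also ships a
synthetic-data generator that plants precursors, isomiRs, fold changes
and cleavage peaks with a complete ground-truth table; the test suite
exercises the pipeline end-to-end against that truth.

# Tag processing

Reads are trimmed at the leftmost occurrence of the longest matching
3' adapter prefix (minimum overlap 7 nt, exact matching); reads without
adapter evidence carry no insert-size information and are rejected and
counted in the run manifest. Retained inserts are size-selected to
18–24 nt for small RNA (19–21 nt for degradome tags), collapsed to
distinct tags with per-library counts, and filtered on reads-per-million:
a tag is kept when it reaches 10 RPM in at least one library. The RPM
denominator is the library's retained (post size-selection) read total —
the filter operates on the retained tag universe, so that is the
universe it should be normalised against.

# Hairpin folding model

Precursor evidence is judged on predicted secondary structure. The
built-in folder is a Nussinov-style dynamic program over nested
structures with hairpin loops of at least 3 nt and additive per-pair
energies (GC −3.0, AU −2.0, GU −1.0 kcal/mol). This model is exactly
checkable: the test suite verifies the DP against exhaustive enumeration
of all nested structures for hundreds of short sequences. The traceback
is deterministic — position *i* pairs, to its smallest admissible
partner, whenever pairing attains the optimum — so identical inputs give
identical structures.

Two consequences of the simplified model matter in practice:

* Its absolute energies are not comparable to Turner-model (RNAfold)
  energies. The retention threshold of −0.2 kcal/mol/nt is kept as the
  default because it is the field's customary cut-off, but with additive
  pair energies nearly any 100+ nt window clears it; the threshold is
  configurable and discrimination comes from structure, not energy
  (below). An adapter to an installed `RNAfold` binary
  (`fold_external()`, `folding.engine: external`) provides Turner-model
  folding through the identical interface.
* Additive energies admit many co-optimal structures. The deterministic
  traceback resolves them reproducibly, and the hairpin test is designed
  to be robust to stray co-optimal rearrangements at helix edges.

`is_hairpin()` requires the energy density below threshold **and** a
single terminal loop on the candidate path: with a mature span given, at
least `length − 4` of the span's bases must pair so that each pair
encloses exactly one and the same terminal loop. This tolerates a few
edge bases straying into flanking structure while rejecting branched
(multi-loop) placements.

# miRNA ascertainment

Filtered tags are mapped to the genome by exact full-length matching on
both strands. Placements are visited in decreasing tag abundance; each
placement not already inside a retained candidate seeds windows of
30/60/100/150 nt flanks, and the lowest energy-per-nucleotide window
passing the hairpin test is retained as a precursor candidate (supplied
BED/GFF intervals replace derived windows in annotation mode). A cheap
antisense-complementarity prescan skips folding windows in which the
seed tag has no near-complementary partner; this cannot change the final
miRNA table because ascertainment requires that duplex anyway.

A tag within a retained candidate is ascertained as a mature miRNA when
it (a) lies fully inside the window, (b) does not straddle the terminal
loop, (c) passes the single-stem pairing test above, and (d) forms a
near-ungapped duplex with its projected star: in the duplex register
implied by 2-nt 3' overhangs, at least `length − 2 − 4` positions must
be complementary (Watson–Crick or G:U). Criteria (c) and (d) are the
package's reading of the community annotation guidelines for plant
miRNAs (a mature:star duplex with only a few mismatched positions); they
are also what gives the pipeline its specificity, since the simplified
energy model alone does not separate real hairpins from
dinucleotide-shuffled decoys.

The star span is projected from the pair table: star5 = p(m3 − 2),
star3 = p(m5) + 2, which yields exactly 2-nt 3' overhangs on both duplex
ends. If an anchor base is unpaired (or pairs inconsistently with the
candidate's stem), the nearest consistent pair up to 3 nt inward is used
and the offset carried, i.e. the helix is extrapolated; the projection
is flagged when it leaves the precursor. Star presence is graded, not
filtered on: `star_evidence` is TRUE when the predicted star sequence is
itself observed among the tags, or when the geometry is exact and the
star appears in the user-supplied catalog. This mirrors practice —
published wheat annotations retain matures without star support and
report star evidence as an attribute.

Families are assigned by best ungapped catalog match (≤ 2 mismatches,
length difference ≤ 2, ties to the lexicographically smallest family;
no match ⇒ "novel"), and names follow the
`family-precursor.variant-arm` convention: precursors numbered in
genomic order within a family, variants by descending abundance, the
variant index omitted for single-variant precursors.

# Differential expression

The count matrix of ascertained miRNAs is normalised by trimmed mean of
M-values (reference = library whose upper-quartile CPM is closest to the
mean; 30%/5% M/A trims; precision weights `(N−x)/(Nx) + (Nr−xr)/(Nr·xr)`;
factors rescaled to geometric mean 1). Dispersion is estimated under the
NB variance model Var = μ + φμ² by maximising a Cox–Reid-adjusted
profile likelihood over a logarithmic grid φ ∈ [1e−4, 10], with
per-miRNA values shrunk towards the common estimate by weighted
likelihood with a prior weight equivalent to 10 observations. Per miRNA
and contrast, a negative-binomial GLM with log link and log-effective-
library-size offsets is fitted by IRLS under the full cell-means model
and a reduced model merging the contrasted cells; twice the
log-likelihood difference is referred to χ²₁, and Benjamini–Hochberg
step-up controls FDR within each contrast. The contrasts mirror the
study design: heat vs control at 0/1/4 DAT, heat 0 vs 4 DAT and control
0 vs 4 DAT.

This is deliberately a simplified stack relative to full empirical-Bayes
machinery (no trended dispersion, fixed prior weight, grid optimisation);
what is claimed — and tested — is calibration (null p-values uniform,
null FDR controlled) and parameter recovery (planted 4-fold changes
detected with ≥ 90% power at 4 replicates), not bit-compatibility with
any particular release of an existing tool. The test suite nevertheless
cross-checks the TMM factors against an independent implementation.

Summaries use log2(RPM + 1): classical (Torgerson) multidimensional
scaling of the libraries (double-centred squared Euclidean distances,
top-2 eigenvectors scaled by root eigenvalues) and agglomerative
complete-linkage clustering under the Chebyshev (maximum-coordinate)
distance, with deterministic lexicographic tie-breaking. The +1 offset
for the log transform is the package's choice; the convention in the
upstream literature is not stated beyond "normalized log2 read counts".

# Degradome validation

Degradome tags (19–21 nt) are matched exactly, sense-strand, to coding
sequences; each placement adds the tag's count to the 5'-end position,
and multi-mapping tags count at every placement (simple and conservative
for peak calling). Candidate target sites are scored with the classical
plant-targeting penalties — match 0, G:U 0.5, mismatch 1.0, penalties
doubled at miRNA positions 2–13 — over ungapped antiparallel alignments;
sites with penalty ≤ 6 are candidates. The cleavage position is the
transcript base paired to miRNA position 10. Peaks are categorised on
the standard ladder (0 unique maximum, 1 tied maximum, 2 above the
median of nonzero positions, 3 otherwise, 4 single read).

Significance uses a self-contained permutation null: the miRNA is
dinucleotide-shuffled (uniform over dinucleotide-preserving
permutations, via random Eulerian paths), each shuffle is run through
the identical search, and p = (1 + successes)/(n + 1) where a shuffle
succeeds if it attains a site at least as good as the observed hit
(score and category). Because the penalty score is discrete in 0.5
steps, ties make this p-value conservative; the test suite verifies
global near-uniformity on random miRNAs and, critically, validity (no
anti-conservatism) at the usual cutoffs. Hits are retained when
p < 0.05 and the raw cleavage-site abundance exceeds 4 (both strict);
raw rather than normalised abundance is used because the threshold acts
per library. Retained hits are exported with t-plot tables (per-position
abundance with the cleavage site flagged).

# The synthetic-data generator

The generator emulates the structure the analysis assumes, not
sequencing chemistry:

* **Design.** 24 libraries: 2 treatments × 3 timepoints × 4 replicates.
* **Precursors.** 50 planted stem-loops (the default), each a fully
  paired hairpin: 2 basal guard pairs, the mature, a loop-proximal A:U
  homopolymer extension, an all-C loop, and the exact reverse-complement
  arm, with 0–1 planted stem mismatches. The inert (mutually unpairable)
  loop/extension alphabets and the absence of a 5' flank make the
  designed stem the *unique* minimum-energy structure under the additive
  pair-energy model, so planted-truth recovery is well defined; the cost
  is that loops and extensions are compositionally artificial. Each
  precursor carries 0–3 isomiRs (end shifts of 1–3 nt, Dirichlet
  proportions fixed across libraries) and a star that is sequenced in
  70% of precursors at 2–15% of the mature level.
* **Genome.** Precursors and 50 dinucleotide-shuffled decoy
  pseudo-precursors embedded on random strands in three chromosomes of
  random sequence (800-nt spacers). Decoys are hard negatives: shuffling
  preserves the homopolymer-derived dinucleotide composition, so they
  remain hairpin-prone and genuinely test duplex-level specificity.
* **Expression.** Baseline abundances are log-uniform and scaled so
  planted reads form 70% of each library, matching the observation that
  a few miRNA families dominate retained plant sRNA reads; truth RPM is
  expressed against the expected retained total so low-dispersion
  libraries converge to it. A 20% subset is heat-responsive with
  log2 fold change ±2 at 0 DAT, halving at 1 DAT and quartering at
  4 DAT (recovery kinetics). Counts are negative-binomial with
  dispersion 0.1 (typical sRNA-seq overdispersion); background reads
  (30%) are random genomic fragments of 18–30 nt with a 24-nt mode and a
  secondary 21-nt class. Reads carry the TruSeq small-RNA 3' adapter and
  are truncated to 50 cycles.
* **Degradome.** 10 of the planted matures get perfect-complement sites
  in a 20-transcript synthetic CDS set; signal reads are 20-nt fragments
  starting exactly at the implied cleavage position with NB counts
  (mean 50), background 5' ends are uniform with geometrically decaying
  per-position counts (50% of reads), and five untargeted transcripts
  carry dinucleotide-shuffled (decoy) sites.

What passing these tests shows is that the pipeline's logic — mapping,
folding, duplex geometry, normalisation, testing, peak calling — is
correct and calibrated under the generative assumptions it encodes. It
does not show robustness to features the generator omits: sequencing
errors and quality variation, PCR duplication, rRNA/tRNA/chloroplast
contamination (an optional exact-match exclusion list is the only hook),
multi-locus miRNA families with near-identical paralogues, or
Turner-model energetics of marginal hairpins.

# Numerical choices and degenerate inputs

* Folding tie-breaks: pairing preferred, smallest partner index;
  minimum loop 3 nt.
* `max_unpaired_in_duplex = 4` governs both the single-stem pairing test
  and the star-register complementarity gate.
* Dispersion grid: 25 log-spaced points on [1e−4, 10]; IRLS: ≤ 50
  iterations, relative log-likelihood tolerance 1e−8; non-converged fits
  are flagged (p = NA) and counted, all-zero rows get p = 1 and
  log2FC = 0 by convention.
* BH: NA p-values propagate and do not count towards m.
* Clustering ties merge the lexicographically smallest pair (by smallest
  original member); MDS with effective rank < 2 zero-fills the second
  axis with a warning.
* Windows beyond chromosome ends are clipped and flagged; coordinates
  are 0-based half-open internally and 1-based inclusive in every
  report.
* The shuffle p-value's lower bound is 1/(n_shuffles + 1); miRNAs with
  fewer than 3 distinct dinucleotides cannot be shuffled and raise an
  error.

# Problem sizes

The shipped tests run the full default study (24 libraries at 2×10⁵
reads, 50 precursors + 50 decoys) once, reuse it across the discovery
and degradome checks, and use 100-shuffle p-values; the null-calibration
simulation uses 2000 tags and the folding oracle 200 sequences of up to
12 nt. The end-to-end determinism check runs the command-line `all`
subcommand twice at a reduced depth (3×10⁴ reads, 12 precursors), since
byte-identity of outputs does not depend on scale. These sizes are the
package's chosen trade-off between statistical resolution and a test
suite that stays pleasant to run.

# Known limitations

* The additive pair-energy model over-pairs random sequence; absolute
  energies and the −0.2 kcal/mol/nt threshold are only meaningful
  relative to this model (or delegate to `RNAfold`).
* Ungapped target alignment only; bulged target sites are out of scope
  (a configuration hook is reserved).
* The permutation p-value is conservative at score ties.
* Multi-mapping reads are counted at every placement, which can inflate
  degradome peaks on repetitive transcripts.
* The generator's precursors are idealised near-perfect hairpins;
  recovery rates on them are an upper bound for real, bulged precursors.
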