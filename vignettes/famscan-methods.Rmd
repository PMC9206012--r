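---
title: "Methods and design of the famscan pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design of the famscan pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(famscan)
```

# Scope

famscan characterizes a C2H2 zinc-finger protein (C2H2-ZFP) gene family
from assembled transcripts: identification by sequence pattern, protein
property profiling, family-size variation across genome assemblies
(pan/core), duplication dating by Ka/Ks, conserved-motif and promoter
cis-element scanning, GO enrichment, co-expression network analysis with a
randomized-control tendency test, and qPCR quantification of stress
responses. This vignette records the models, the parameters that matter,
the numerical choices, and the design decisions that were genuinely open.

# Family identification

## The C2H2 pattern

Membership is decided by the canonical finger pattern
X~2~-C-X~2–4~-C-X~12~-H-X~2–8~-H: two leading residues, the two
zinc-coordinating cysteines separated by a 2–4 residue spacer, a fixed
12-residue core, and the two histidines separated by a 2–8 residue spacer.
The printed pattern is taken literally — in particular the 12-residue core
is fixed, not a range. `scan_c2h2()` scans left to right; at a candidate
start it prefers the shortest valid first gap, then the shortest valid
second gap, and after a hit it resumes at the residue following the second
histidine. This makes matches greedy and non-overlapping. How overlapping
candidate fingers should be counted is not defined anywhere authoritative;
greedy-shortest is deterministic, linear-time, and agrees with how planted
fingers are laid out, so recall and precision against the generator are
exactly 100% — a property the test suite asserts on 1,000 generated
proteins.

Profile-HMM scoring (PF00096) and external domain-confirmation engines are
deliberately out of scope: the explicit pattern is the package's
classifier, with `min_fingers` (default 1) as the membership threshold.
Plant family members typically carry one to six fingers, so
`classify_family_member()` flags hit counts in that range separately from
the membership decision.

## ORFs

`find_orfs()` scans all six frames greedily: each ATG opens an ORF that
runs to the next in-frame stop; scanning resumes after the stop, so ORFs
within one frame never overlap. ORFs reaching the sequence end without a
stop are flagged partial. Codons containing N are never starts or stops
and translate as X. The default minimum protein length is 25 aa — no
authoritative value exists; 25 aa is small enough to keep genuine short
zinc-finger ORFs and large enough to suppress spurious micro-ORFs.
Coordinates are reported 1-based inclusive on the forward strand, stop
codon included.

## Protein properties

`protein_properties()` uses the parameter sets that ProtParam uses, so its
numbers are comparable with the literature: average isotopic residue
masses plus one water for molecular weight; Kyte–Doolittle hydropathy for
GRAVY (negative = hydrophilic); the Guruprasad DIWV dipeptide weights for
the instability index (threshold 40); Ikai's coefficients for the
aliphatic index; and the Bjellqvist pKa set (with residue-specific
terminal pKa values) for pI. pI is found by bisection of the net-charge
curve on pH 0–14 to |charge| < 1e-4; the curve is strictly decreasing in
pH, so bisection converges monotonically. Sequences containing X keep
their mass/hydropathy/aliphatic values (computed over non-X residues) but
return NA for pI and instability, with a warning, because both depend on
exact residue identities.

# Comparative genomics

## Threshold profiles and pan/core

Alignment records (BLAST outfmt-6 layout) are filtered with all three
boundaries inclusive: within-species identity ≥ 99%, aligned length ≥ 200
bp, e-value ≤ 1e-100; cross-species 75% / 80 bp / 1e-10. "Cover length"
is read as the alignment length in bp — the phrase could also mean query
coverage fraction, but the alignment-length reading needs no extra
denominator and matches the outfmt-6 column. The filter is idempotent,
order-preserving and monotone in its thresholds (properties under test).

`pan_core()` uses plain set semantics: pan = union, core = intersection,
dispensable = pan − core, with exclusive Venn regions reported for up to
three assemblies. Published pan/core counts for this family are not always
consistent with per-assembly sums under set semantics (instance-based
counting can differ); the package documents and implements the set
reading, and `venn_presence_matrix()` reconstructs a presence matrix from
published region counts so composition arithmetic can be re-derived.

## Ka/Ks (NG86)

`ng86_kaks()` implements classic Nei–Gojobori (1986) counting, the
citable default among the models a Ka/Ks calculator offers:

- **Sites.** Each codon position contributes the fraction of its three
  possible changes that are synonymous; a change creating a stop codon
  counts as nonsynonymous, which keeps syn + nonsyn sites = 3 × codons
  exactly (an invariant under test). Site counts are averaged over the two
  sequences.
- **Differences.** Codons differing at k positions are resolved by
  enumerating all k! orderings of single changes with equal weights;
  orderings passing through a stop codon are excluded (if every ordering
  is blocked, all are used). The test suite checks these pathway averages
  against an independently written brute-force oracle on random codon
  pairs.
- **Correction.** Proportions are corrected with Jukes–Cantor,
  d = −(3/4)·ln(1 − 4p/3); p ≥ 3/4 raises a saturation error rather than
  returning a complex number.

Inputs must be pre-aligned codon-wise: the package does not align codons,
matching a workflow where complete-CDS pairs come from an aligner. A
shared terminal stop codon is dropped; internal stops are errors.

Divergence time is T = Ks / 2λ in years (reported in MYA), with
λ = 6.5 × 10⁻⁹ synonymous substitutions per site per year — the standard
rate for this lineage. Selection modes use the inclusive neutral band
Ka/Ks ∈ [0.9, 1.1]; "< 1.0 ± 0.1" is read as < 0.9. Ks = 0 leaves the
ratio undefined rather than infinite.

Synteny detection proper is out of scope; `best_reciprocal_pairs()`
provides the reduced form (mutual best hits with identity → e-value →
lexicographic tie-breaks) that downstream dating needs.

# Motifs, cis-elements and GO

Named motifs use a small pattern language (literal residues, `[...]`
alternatives, `x` = any residue): QALGGH with its R/K first-position
variants, the EAR repression motif `[LF]DLN[LF]xP`, and the L-box
`ExExxAxCLxxL`. Matches are greedy and non-overlapping within a motif;
motifs may overlap each other.

The cis-element catalog ships as an editable TSV of ~25 canonical
PlantCARE-style consensi mapped to hormone / stress / growth / core /
other classes; published element inventories for this family run to ~53
types but are not printed in full anywhere machine-readable, so the
shipped catalog is a documented approximation. Scanning is IUPAC-aware on
both strands, all (including overlapping) occurrences, with reverse-strand
hits mapped to forward coordinates and palindromic spans counted once.
Promoters are expected to be 1500-bp upstream windows; longer input warns
and is scanned in full.

`go_venn()` places each annotated transcript in exactly one of the seven
Venn regions of {MF, BP, CC}; region counts partition the annotated set
and reconstruct per-category totals. "Level 2" subcategories are flat
labels supplied in the annotation table — ontology traversal is out of
scope. `chi_square_enrichment()` tests each subcategory with a 2×2 Pearson
chi-square (1 df), no continuity correction (expected counts in this
setting are large) and no multiple-testing correction by default,
mirroring common practice for these family surveys; Benjamini–Hochberg is
available via `adjust = "BH"`. Rows with an expected cell below 1 are
flagged unreliable but still reported.

# Co-expression networks

Pearson r maps to a p-value through the exact null for correlation:
t = r·sqrt((n−2)/(1−r²)) with n−2 df, two-sided; |r| = 1 gives p = 0. How
the original network tool maps r to P is not documented; the
t-distribution null is the standard exact choice. Edges are pairs with
p ≤ cutoff; nodes are transcripts incident to at least one edge, so node
counts vary with the cutoff. Clusters are connected components (labelled
deterministically by smallest member id); model-based clustering such as
MCL is out of scope. Hub genes: build the network at P ≤ 0.001, keep
nodes with degree ≥ 30, cap at floor(5% of nodes) by degree with
lexicographic tie-breaks.

The tendency test draws, per replicate, equal-sized subsamples from the
family and background matrices, builds both networks at each cutoff of
{5e-2, 1e-2, …, 1e-8} (the series is descending by convention; the
endpoints are fixed, the interior grid is the package default), and
compares node and edge counts per cutoff with a two-sided equal-variance
Student's t-test over 20 replicates (Welch available). Subsampling from a
fixed family pool reproduces the published design (176 of 228 transcripts
— the published motivation for subsampling rather than using the full
family is not stated; the package defaults to the full family size and
exposes `subsample_size` for the published design).

A calibration caveat the tests encode: replicate subsamples from a small
pool share rows, so replicate counts are not independent and the t-test
becomes anti-conservative when the pools are barely larger than the
subsample. With pools an order of magnitude larger than the subsample (as
in the real design, where controls come from a whole transcriptome
database), the empirical type-I rate at nominal 0.05 is close to nominal —
the acceptance suite measures it over 1,000 module-free runs and requires
0.05 ± 0.02, and separately requires edge-level type-I within 0.05 ± 0.01
over ~10,000 independent pairs at n = 42.

# qPCR quantification

`ddct()` implements 2^−ΔΔCT with amplification efficiency fixed at 2 (the
method's defining assumption; efficiency correction is out of scope).
ΔCT is computed from condition means; per-replicate ΔCT values (gene CT −
reference CT matched by replicate index) feed a two-sided equal-variance
t-test of each condition against the calibrator — replicate handling is
not standardized in the field, and condition-mean ΔΔCT with
replicate-level testing keeps the point estimate and the test consistent.
Fold changes are invariant to a per-condition additive CT offset (machine
effect), and the reference gene's own fold is 1 by construction — both
under test. Replicate count defaults to 3 in the generator (2 is the
minimum for testing).

# Synthetic data: what it emulates and what it does not

The generators are first-class, tested code, and every one is a pure
function of its seed:

- **Proteins.** Linkers and all finger X-positions are drawn from the 18
  standard residues excluding C and H, so the only C/H residues are the
  planted anchors and the scanner's recall/precision are exactly
  assertable at 100%. Real proteins of course contain non-anchor C and H;
  the exactness guarantee is a property of the generator, not of real
  data.
- **Codon pairs.** Exactly n~syn~ synonymous and n~nonsyn~ nonsynonymous
  single-nucleotide substitutions, each in its own codon (hence
  n~codons~ ≥ n~syn~ + n~nonsyn~), never creating stops. Stored truth
  (`true_ks`, `true_ka`) is the Jukes–Cantor-corrected planted per-site
  fraction using the ancestor's site counts, so the 15% recovery
  tolerance covers site-count estimation rather than raw JC bias. Real
  paralogs accumulate multiple hits per codon and indels; neither is
  emulated.
- **Expression.** Family rows share a latent Gaussian factor with loading
  sqrt(ρ), giving expected pairwise Pearson correlation exactly ρ;
  background rows are independent. Values are mapped affinely to a
  nonnegative TPM-like scale (baseline 50, scale 10, clipped at 0) —
  affine maps preserve correlation, which is the point; real TPM
  distributions are heavy-tailed and zero-inflated, and the generator
  makes no attempt at that. Sample shapes follow the study designs the
  pipeline targets (14 tissues / 4 ages / 42 genotypes); defaults use 42.
- **qPCR.** CT noise is i.i.d. Gaussian per replicate (no published
  replicate-variance model exists for this assay family); noise_sd 0.1
  cycles is a typical technical-replicate spread.
- **Alignments.** Present genes get records passing the within-species
  profile; absent genes get either nothing or a decoy failing at least
  one threshold, so filtering recovers the presence map exactly.

# Problem sizes and tolerances

The test and acceptance runs use desk-scale sizes chosen to keep every
statistical check well-powered: 1,000 generated proteins for scanner
exactness; 500 random codon pairs for the NG86 oracle; 50 pairs spanning
Ks 0.05–0.6 for recovery (15% tolerance); 20 seeds at noise 0.1 for qPCR
fold recovery (10% on the mean); 142 independent transcripts × 42 samples
(~10,000 pairs) for edge-level type-I (0.05 ± 0.01); a planted ρ = 0.9
module of 60 transcripts vs 120 background, subsample 40, for tendency
power (p ≤ 0.01 at every cutoff); and 1,000 module-free runs with pools of
200 for tendency null calibration (0.05 ± 0.02). Headline family counts
from genome-scale surveys (hundreds of genes against full assemblies)
require the original databases and are outside what synthetic desk-scale
data can reproduce; the acceptance layer instead verifies the published
arithmetic (Venn totals, pan/core composition, dating endpoints) by
recomputing it from the printed counts.

# Known limitations

- The pattern classifier will miss degenerate fingers a profile HMM would
  score; that trade was made for exactness and auditability.
- NG86 with JC correction underestimates distances at high divergence and
  ignores transition/transversion bias; model-based estimators (e.g.
  YN00-style) are out of scope.
- The shipped cis-element catalog is a curated subset, not the full
  PlantCARE inventory; tallies on real promoters will undercount rare
  element types.
- Connected components are a coarse stand-in for model-based network
  clustering.
- The tendency t-test's calibration degrades when the subsample approaches
  the pool size (see above); interpret results accordingly when the
  family is small.
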