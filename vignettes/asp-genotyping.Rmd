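---
title: "Allele-specific PCR genotyping: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Allele-specific PCR genotyping: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(asppcr)
```

This vignette is the package's account of the science it implements: the
assay model and its assumptions, the tunable parameters and their
defaults, what the simulator does and does not emulate, and the choices
made where the design was genuinely open.

## The assay model

A codominant allele-specific PCR (ASP) assay for a biallelic SNP is a
pair of amplifications sharing a reverse primer. Each forward primer is
anchored with its 3'-terminal base on the SNP, so polymerase extension
initiates efficiently only when that terminal base pairs with the
template — the allele-A primer amplifies allele-A template, the allele-B
primer allele-B template. A single terminal mismatch is often not enough
to suppress extension completely, so a second, deliberate mismatch — the
*artificial mismatch* — is placed at the third base from the 3' end of
both forward primers. Against the matching allele the primer then
carries one internal mismatch (tolerated); against the other allele it
carries two mismatches in the 3'-proximal three bases (extension
effectively blocked). `check_allele_discrimination()` verifies this
(1 vs 2) pattern for every designed assay.

Which base to substitute is an empirical question. The package ships a
4×4 specificity matrix (`mismatch_matrix()`): for each (matching base →
replacement) substitution, the fraction of ten tested primers that gave
single-band allele-specific amplification. Substitution pairs are
admitted only when both directions reach 50% — exactly the A–G
transition and the A–T, A–C and G–T transversions — and
`choose_replacement()` picks the admissible partner of maximal
specificity. Two conventions here are ours, documented because the
underlying screen does not fix them:

* *"matching base" means the primer base being replaced* (not the
  template base). This is the reading under which the admitted-pair set
  is exactly the four pairs whose two directed cells are both ≥ 50%.
* *Tie-breaking*: when two replacements tie on specificity, an optional
  Tm bias (`raise` prefers G/C, `lower` A/T) arbitrates among the tied
  candidates only, then ties fall back to alphabetical order. The choice
  is a pure function of its inputs, so designs are reproducible.

The mismatch position (third from the 3' end, with the SNP at position
one) is fixed, not configurable: alternative schemes (e.g.
penultimate-base mismatches) are out of scope. Users with their own
screen data can substitute the matrix file; the same admission and
choice rules then apply.

## Melting temperature and standardization

The point of Tm tuning is operational: many assays, one thermal
protocol (annealing 58 °C, endpoint read 75 °C). The primary Tm model is
nearest-neighbor thermodynamics with the unified dinucleotide parameter
set, duplex-initiation terms, a monovalent-salt entropy correction
(0.368·N·ln[Na⁺]) and the Tm equation at primer excess
(ΔH/(ΔS + R·ln(C/4))). Defaults: 50 mM monovalent salt, 250 nM primer.
The Wallace rule (2(A+T) + 4(G+C)) is available as a fast fallback.
`fit_length_to_tm()` extends a primer 5'-wards from its fixed 3' anchor
and returns the smallest length in [18, 30] nt whose Tm falls inside the
target window; if none does, the closest length is returned flagged
out-of-window rather than failing, because an out-of-window assay is
still usable at a marker-specific annealing temperature (the multi-sample
workflow explicitly supports per-assay annealing).

Two defaults deserve justification:

* **Target Tm 60 ± 2 °C.** No target is dictated by the protocol itself;
  60 °C, two degrees above the 58 °C annealing step, is the conventional
  choice for primers run at 58 °C and is an artifact default, exposed as
  `thermo.target_tm_C` / `thermo.tm_window_C`.
* **Mismatch handling in Tm.** The artificial mismatch perturbs duplex
  stability, but mismatch-specific nearest-neighbor tables are beyond
  this package's scope. The designed primer's Tm is computed on the
  primer:matching-template duplex with the mismatch position treated as
  non-contributing: the two base stacks involving it are each replaced by
  the mean of the stacks immediately flanking it. This is an
  approximation (it ignores the identity of the mismatched pair); it is
  consistent across assays, which is what standardization needs.

Forward primers for the two alleles are designed at a common length —
they must be identical except at the 3' terminus — and the length is
chosen so both Tm values sit in the window where possible. The shared
reverse primer is placed deterministically: product sizes are scanned
from the minimum (default 100 bp) outward, lengths smallest-first, and
the nearest placement satisfying the Tm window, the product-size bounds
(default [100, 500] bp — typical for endpoint dye detection; the
protocol itself is silent) and a simple self-complementarity screen
(longest self-reverse-complementary run ≤ 6) wins. No multi-objective
optimization is attempted; there is nothing in the assay chemistry to
optimize beyond these constraints, and determinism is worth more.
Forward design defaults to the + strand; a `-`-strand mode (3' terminus
carries the allele complement) exists as a fallback for loci whose
upstream context is unusable, off by default.

## Endpoint-fluorescence calling

After PCR, a dsDNA dye is added and one fluorescence value per well is
read at 75 °C — a temperature at which non-specific agglomerates have
melted but the specific product has not, giving signal/noise above ~6.
Intensity units are arbitrary; the read temperature is recorded as
metadata and no temperature correction is applied.

Calling is per-channel thresholding followed by the quadrant rule
(A-positive only → AA, B only → BB, both → AB, neither → no call).
Two-dimensional clustering is deliberately out of scope: endpoint PCR is
non-quantitative, so the two channels carry no usable dosage
information, and per-channel thresholds match how such data are read in
practice. Thresholds are estimated per plate and channel by exact 1-D
two-means: the optimal two-cluster partition of points on a line is an
interval split, so the split point minimizing within-cluster sum of
squares is found by enumeration (deterministic, and exactly equal to the
brute-force oracle the tests use). The threshold is the midpoint of the
two cluster centers, accepted only when the high/low center ratio
reaches `min_separation` (default 3); otherwise the method falls back to
a fixed fraction (default 0.3) of the channel maximum and flags the
fallback — a guard against plates where one genotype class is absent and
the split would cut noise in half.

## Layouts

A genotyped unit is two adjacent wells (allele-A, allele-B reaction),
filled row-major, 48 units per 96-well plate: 48 samples × 1 marker
(multi-sample) or 1 sample × 48 markers (multi-locus), with plates added
as `ceil(n/48)`. `make_layout()` emits one plate set per marker (or
sample) when several are supplied.

## F2 mapping

Between two adjacent markers, identical calls count zero crossovers,
homozygote↔heterozygote one, opposite homozygotes two. An AB↔AB pair
can conceal a double crossover in repulsion; without phase it is
undetectable and is counted zero — a documented limitation shared by any
unphased F2 analysis. `narrow_interval()` implements the
homozygous-progeny strategy: each recombinant whose progeny phenotype
establishes its causal genotype (A-type or B-type homozygote) constrains
the locus to the markers where its genotype is that homozygote; the
admissible region is the intersection across individuals, and the
reported bounds are the markers immediately flanking it. Only
homozygous-progeny phenotypes are used; heterozygote phenotyping is out
of scope. An empty intersection raises an error naming the conflicting
samples, since it signals a genotyping or phenotyping error rather than
a statistical result. Map positions are taken as given — the package
does not estimate or re-order maps, and does not convert physical to
genetic distance.

## Distances and trees

No canonical genotype distance exists for codominant calls, so the
package defines one and documents it: per locus where both lines are
determined, opposite homozygotes score 1, identical calls 0, and any
comparison with a heterozygote 0.5 (the heterozygote shares one allele
with either homozygote); the distance is the mean, requiring at least 10
shared determined loci. This is a pseudometric (verified by property
test). Neighbor joining is the standard rate-corrected agglomeration,
implemented in-package so two details the classical algorithm leaves
open are fixed: ties in the Q-criterion break by the smallest label
pair, and negative branch-length estimates are clamped to zero with a
warning. The implementation is cross-checked in the tests against
`ape::nj` and against exact recovery on additive matrices. Bootstrap
support resamples marker columns with replacement (columns taken in
sorted name order, so support is invariant to input column order for a
fixed seed) and counts, per internal edge of the full-data tree, the
replicates containing the same bipartition. Trees are `ape` `phylo`
objects; Newick export quotes labels containing metacharacters.

## The simulator

The simulator exists so every claim above is testable with known truth,
and its defaults are the study conditions the package targets:

* **Genome**: i.i.d. bases at 43% GC (a typical plant genome
  composition); SNPs assigned round-robin to chromosomes and placed
  uniformly at least 600 bp from ends and from each other — enough room
  for a full assay (max product 500 bp + max primer 30 nt).
* **Meiosis**: gametes are generated marker-to-marker with switch
  probability `haldane_r(Δd)` — Haldane's map function, i.e. no
  crossover interference; interference modeling is out of scope. An F2
  genotype is the sum of two independent gametes.
* **Fluorescence**: channel intensity is Normal(μ⁺, σ) when the
  channel's allele is present and Normal(μ⁻, σ) otherwise, truncated at
  zero, with μ⁺/μ⁻ = 10 (comfortably above the ~6 signal/noise ratio at
  which endpoint detection is reliable) and σ = μ⁻/2. Whole-sample
  dropout (no amplification anywhere, e.g. germination failure) occurs
  with probability 8/96, the rate observed in a 96-plant F2 screen.
* **Diversity panels**: a few deeply diverged homozygous founders,
  per-line divergence 5%, per-call missingness 6.4% — matching the
  ~94% call-rate regime of multi-locus arrays on diverse material.

What the simulator does *not* emulate, and hence what passing tests do
not show about real data: PCR kinetics and primer-efficiency variation,
cross-contamination, plate-position effects, partial (single-channel)
dropout, allele dropout in heterozygotes, mutations in priming sites,
and segregation distortion. The calling-accuracy results therefore
bound what clean chemistry can achieve, not what any given wet-lab run
will.

## Problem sizes and numerical choices

The test suite and the acceptance script use: 500 (tests) / 200
(acceptance script) random genome/SNP design instances on 1.5 kb
single-chromosome genomes; 96-plant × 5-marker F2 experiments over
30 cM with the causal marker central, 100 replicates; n = 10,000 plants
for the Haldane comparison (the crossover-count estimator
`r̂ = crossovers/2n` under-estimates r by r²/2 due to invisible
repulsion-phase doubles, well inside 3 binomial SE at this n); 200
random 4–8-taxon trees for neighbor-joining recovery; 1,000 bootstrap
replicates for panel trees. These sizes make every stochastic check
sharp (3σ bands) while keeping the full suite in the low minutes on one
core.

Degenerate inputs are handled explicitly rather than silently: all-equal
intensities are a `degenerate-signal` error; fewer than 4 wells per
channel cannot be two-cluster thresholded; a SNP closer to a contig end
than the design window warns and truncates; a reference base matching
neither declared allele is an error (it indicates a stale reference, not
a designable assay); duplicate (chrom, pos) markers and non-SNP VCF
records are rejected, the latter downgradeable to warnings with
`skip_invalid`.

## Known limitations

Primer design considers no secondary-structure free energies and no
mismatch-specific thermodynamic penalties; dimer screening is the
self-complementarity run length only. In-silico amplification matches
3'-terminal 12-mers (mismatch position wildcarded) and so reports
potential products, not amplification efficiencies. The genotype
distance treats all markers equally and ignores linkage. Tree-level
reproduction of any particular published phylogeny is not a goal: the
distance convention here is the package's own.
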