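---
title: "Methods: attC folding thermodynamics and replication-strand analysis"
author: "attCfold authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: attC folding thermodynamics and replication-strand analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(attCfold)
```

## The biological problem

Integron gene cassettes are excised by the integron integrase through
recombination between consecutive attC sites.  attC sites are not
recognised as double-stranded DNA: the integrase binds a folded single
strand, almost always the *bottom strand*, which must adopt a specific
imperfect hairpin — the *recombinogenic structure* — in which the L' box
pairs the L'' box and the four conserved bases 5'-YAAC-3' of R' pair the
5'-GTTR-3' of R''.  Two quantities therefore govern how often a cassette
can excise:

* **pfold** — the probability that the thermodynamic ensemble of the
  folded bottom strand contains the recombinogenic pairing; and
* **single-strandedness** — whether the bottom strand is exposed as
  ssDNA during replication, which depends on whether it serves as the
  lagging-strand template (transiently single-stranded between Okazaki
  fragments) or the leading-strand template.

This package computes both: constrained/unconstrained folding
thermodynamics of single-stranded DNA, and the replichore geometry that
classifies every attC site of a replicon by template strand.  A
synthetic-data generator with planted ground truth makes every stage
testable without any external downloads.

## Site model and coordinates

An `AttCSite` stores the top strand 5'→3'; `bottomStrand()` is its
reverse complement.  Box intervals are kept in **top-strand, 1-based,
closed** coordinates (the IRanges convention).  Because the bottom strand
is the reverse complement of the top strand, the boxes read
R'' < L'' < L' < R' along the *bottom* strand and, equivalently,
R' < L' < L'' < R'' along the *top* strand; the single coordinate
transform is `i -> L + 1 - i`.  All constraint construction and folding
happen on the bottom strand by default, with `flipConstraintStrand()`
providing the exact round trip.

The box heuristic (`locateBoxes`) exists to annotate fixtures and
screened sequences when no annotation is available; genuine survey
annotations (and the generator's planted truth) always override it.  It
anchors the two 7-bp R boxes on the conserved GTTR/YAAC motifs and scans
stem placements scoring `matches - 2 * mismatches`, with ties resolved
toward the outermost anchors, then longer stems, then tighter spacers.

## The folding model

### Reference model

The built-in `referenceEnergyModel()` is a deliberately small
nearest-neighbor model:

* structures are non-crossing sets of base pairs with a minimum hairpin
  loop of 3 unpaired bases;
* the energy of a structure is the sum of stack increments over
  *consecutive* pairs; isolated pairs, loops and initiation contribute 0,
  so the open chain has energy exactly 0;
* Watson-Crick stacks take the unified DNA nearest-neighbor
  free energies at 37 °C (kcal/mol);
* G:T wobble pairs are allowed, and any stack touching a wobble pair
  contributes a single documented constant (default −0.5 kcal/mol).

The wobble rule deserves emphasis.  With strictly Watson-Crick pairing,
every structure of a strand maps to an equal-energy structure of its
reverse complement (pair `(i, j)` maps to `(L+1-j, L+1-i)`; any
reverse-complement-symmetric stack table preserves the energy), so the
bottom-minus-top stability gap would be *identically zero* for every
site.  Allowing G:T — whose mirror image A:C is not pairable — breaks
this symmetry, exactly as the full DNA parameter tables used by folding
programs do.  It is the reason G-rich strands (with some T) fold more
stably than their complements in this model, which mirrors the
purine-stacking argument for why bottom strands of mobile-integron attC
sites are more stable.

The model exists to make every thermodynamic claim *exactly checkable*:
`enumerateStructures()` enumerates the complete structure ensemble of any
sequence up to 20 nt, and the test suite requires the dynamic programs to
match that enumeration to a relative tolerance of 1e−9, with and without
constraints.

### Dynamic programs

MFE and partition function are computed in C++ by interval dynamic
programming over three matrices per quantity (`(i,j)` paired; `i,j` not
mutually paired; either), which carries the stacking bonus exactly.  Hard
constraints mean "the structure contains every forced pair": a forced
position may neither stay unpaired nor pair anything except its
designated partner, which restricts both the minimisation and the
Boltzmann sum to the constrained sub-ensemble with no approximation.

The partition function is accumulated in plain double precision with a
guard at 300 nt: for attC-sized sequences (≤ ~150 nt) the largest
possible Boltzmann sums (~1e190) are far below double overflow, and
linear-space arithmetic keeps the implementation bit-comparable to the
enumeration oracle.

### pfold

With `E_u` the ensemble free energy (−RT ln Z) of the unconstrained fold
and `E_c` that of the constrained fold,

$$\mathrm{pfold} = e^{(E_u - E_c)/RT} = Z_c / Z_u .$$

An empty constraint set gives pfold = 1 exactly; unsatisfiable
constraints give an empty constrained ensemble and pfold = 0.  pfold is
non-increasing as forced pairs are added (each addition removes
structures from `Z_c`).  Defaults: T = 310.15 K (37 °C),
R = 1.98717 × 10⁻³ kcal/(mol K); temperature is configurable everywhere.

### DNA-parameter backend

`viennaPfold()` delegates to the `RNAfold` executable with the DNA
nearest-neighbor parameter table shipped with ViennaRNA
(`dna_mathews2004.par`), partition functions (`-p`) and enforced pair
constraints (`-C --enforceConstraint`).  This is the backend to use when
comparing against values computed with full DNA parameter tables; the
reference model is the backend for exact, self-contained testing.  The
two share the pfold definition and the constraint construction.

## Replication geometry

`gcDisparityProfile()` is the cumulative excess of G over C along the top
strand.  On a circular replicon the leading strand is G-enriched, so the
profile increases along the replichore where the fork moves toward
increasing coordinates.  `inferReplichores()` detrends the profile
(removing the replicon-wide G−C imbalance) and places oriC at the global
minimum and ter at the global maximum; a user-supplied oriC always
overrides inference.  A profile whose detrended amplitude does not exceed
`flatTol` (default 5) standard deviations of an unbiased G/C random walk
with the same number of G/C steps is treated as signal-free and reported
*indeterminate* — a plain min/max would otherwise "find" an origin in
noise.

The strand algebra is stated once and used everywhere
(`templateClass`): where the fork direction is *increasing*, the minus
strand is the leading-strand template and the plus strand the
lagging-strand template; both flips (strand, replichore) invert the
label, and the double flip is the identity.  This convention makes "attC
bottom strand on the lagging template" coincide with the bottom strand
being transiently single-stranded between Okazaki fragments, which is the
mechanistic reading of orientation effects on excision.

Arrays are aggregated at a configurable gap threshold (default 4 kb,
with 15 kb used for a few unusually sparse sedentary arrays).  An
array's orientation label is the unanimous per-site class when the sites
agree, otherwise the majority class with a `mixed` flag (ties are
labelled `mixed`): published orientation tables report one label per
integron without stating the tie rule, so the flag preserves the
information.  Cassette length is the start-to-start distance between
consecutive attC sites — each cassette carries exactly one attC — which
is the unambiguous reading of "distance between two consecutive attC
sites"; an end-to-start variant would differ by one site length.

Classification: an integron is sedentary (SCI) when present in all
sequenced strains of its species or when it carries more than 19 attC
sites; mobile (MI) when absent from more than 40% of sequenced genomes
(fraction present < 0.6), on a plasmid, or with an integrase of one of
the five mobile classes.  SCI criteria are evaluated first; if both sets
fire, the record stays SCI with a conflict flag.  A mobile integron on a
chromosome is reported as MCI.

## Statistics

* `skews()`: GC skew (G−C)/(G+C) and AT skew (A−T)/(A+T) on the strand as
  given; zero denominators are *undefined* (NA with a flag), never 0.
* `pairwiseIdentity()`: global end-to-end alignment (match +1,
  mismatch −1, gap open −2, gap extend −1); identity = 100 × matches /
  alignment columns, gaps included in the denominator; rounding to an
  integer happens only at report time.  The scoring is a documented
  default — published integer identities calibrate it, they do not
  define it.
* `rankSumTest()`: two-sided Wilcoxon/Mann-Whitney; exact enumeration
  when n₁+n₂ ≤ 12 without ties, otherwise the normal approximation with
  tie and continuity corrections.  Exhaustive comparison at 8 vs 8 shows
  the corrected approximation within ~0.011 of the exact p anywhere (the
  worst case sits near p ≈ 0.5) and within 0.005 in the separated-samples
  regime where the pipeline's comparisons live.
* `linearFit()`: ordinary least squares with the slope's p from the t
  distribution on n−2 df; a flat response is reported as slope 0,
  R² = 0.
* `cohortSummary()`: "pfold > 0.1" uses a strict inequality and the
  low-pfold band [10⁻⁷, 10⁻⁵] is a closed interval — both documented
  constants, since prose thresholds rarely state edge behaviour.

## The synthetic-data generator

`generateAttc()` builds the bottom strand as
R''(GTTR·7) · spacer(+UCS) · L'' · [EHB bulge] · VTS · L' · spacer · R'(YAAC·7),
with total length `2(7 + stem + spacer) + ucs + vts + ehb`.  Design
choices worth knowing:

* The EHB bases are planted as a bulge at the L''/VTS junction.  Real
  extrahelical bases protrude from within the stem; planting them
  mid-stem would break box contiguity and the base-by-base L'×L''
  constraint map, so the bulge is the closest annotation-preserving
  approximation.
* The two bases flanking each stem arm are set equal to their would-be
  partners (a base never pairs itself, under either pairing rule), so
  the planted stem cannot be extended by chance and heuristic box
  recovery is exact for mismatch-free sites.
* The R' pyrimidine of YAAC is drawn as the complement of the R'' purine
  of GTTR, keeping all four anchor pairs Watson-Crick.
* Low-pfold, Vibrio-SCI-like sites carry a *decoy* arm inside the VTS:
  the reverse complement of L'' plus k adjacent spacer bases.  The decoy
  competes with L' for pairing L'' and is k pairs stronger, so the
  minimum-energy fold is non-recombinogenic and pfold drops by roughly a
  Boltzmann factor per extra pair.  This realises "structured/branched
  VTS" and stands in for stem imperfections, which cannot be planted
  inside the annotated L boxes without breaking the Watson-Crick
  constraint invariant.

Cohort presets differ only in documented parameter distributions:
`MI_like` (57–83 bp, short AT-poor VTS, unpaired bottom-strand bases
drawn A .25 / C .15 / G .40 / T .20), `SCI_other_like` (intermediate) and
`SCI_vibrio_like` (120–129 bp, long decoy-bearing VTS, composition
A .25 / C .40 / G .15 / T .20).  The compositions encode the observed
skew directions (negative top-strand GC and AT skews for mobile-integron
sites; positive GC skew for Vibrio sedentary sites) and, through the
wobble rule, the corresponding stability-gap directions.  The presets
guarantee the *signs* of the cohort contrasts (pfold, length, skews,
ΔG_bs − ΔG_ts), not their magnitudes: passing tests show the machinery
measures planted structure correctly, not that real surveys would give
these numbers.

`generateReplicon()` draws a circular background with G-enrichment on
each leading strand proportional to `skewStrength` (0.3 by default; 0
yields a signal-free replicon that orientation inference correctly
refuses) and plants integron arrays alternately on the two replichores,
10% of the replicon clear of oriC and ter, with the annotated strand
chosen so each attC bottom strand lands on the requested template.  CDS
features are planted inside cassettes (shorter) and across the backbone
(longer), so cassette/CDS length partitions have a known answer.

What the generator does **not** emulate: covariance-model attC detection
(annotations are taken as given), multi-replicon genomes sharing an
origin database, pseudoknots or branched multi-strand folds, EHB
chemistry, host factors, and any excision-rate model — the package
measures substrate properties, not recombination outcomes.

## Problem sizes and determinism

The shipped tests and the acceptance script use cohorts of 200 sites,
50 + 20 seeded replicons of 21–30 kb, 200 enumeration cross-checks at
≤ 18 nt and 1000 skew draws; on one CPU the full suite runs in about a
minute and the acceptance script in well under one.  Every random
operation takes an explicit integer seed (cohorts and replicons derive
per-item seeds from it), no global RNG state leaks
(`.Random.seed` is saved and restored), and two runs with identical
configuration and seeds produce byte-identical reports — which the
acceptance suite asserts.

## Known limitations

* The reference model omits loop-length, terminal-mismatch and
  dangling-end terms; its pfold values are comparable *within* the model,
  and absolute published values should be recomputed with the
  DNA-parameter backend.
* Strand asymmetry in the reference model flows through a single wobble
  constant rather than full mismatch tables.
* `locateBoxes` is a fixture-grade heuristic; survey work should supply
  curated box annotations.
* Only circular replicons are modelled; linear replicons are refused
  rather than guessed.
* The published assay-site sequences (VCR_126 and relatives) are not
  redistributable with the package; the corresponding checks require the
  user to supply them (see `tests/testthat/test-acceptance.R`).
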