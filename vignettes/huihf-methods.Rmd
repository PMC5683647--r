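---
title: "Models and methods behind huihf"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind huihf}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(huihf)
```

# Scope

`huihf` analyses bacterial histone-like HU/IHF proteins along three axes:
their sequences on a conserved 90-column core frame, the geometry of HU
dimer models, and the thermodynamics of HU binding to straight and
distorted DNA measured by electrophoretic mobility shift assays (EMSA).
This vignette documents the models, their assumptions, the tunable
parameters, and the design decisions taken where the underlying methods
literature leaves choices open.

# The 90-column core frame

All sequence-level work happens on a fixed 90-column alignment frame that
covers the structured HU/IHF fold (helix 1, helix 2, the beta saddle with
the DNA-binding arms, helix 3). A `core_aligned_seq` decomposes a protein
into an N-terminal extension, the 90-symbol core (with `-` for deleted
columns), insertions keyed by the core column they follow, and a
C-terminal extension. The class invariant — splicing these parts back
together must reproduce the raw sequence — is enforced at construction,
so every downstream statistic operates on a lossless representation.

## Alignment onto the frame

`align_to_core()` aligns a raw sequence against a position-specific score
matrix (PSSM) with 90 columns: the profile is traversed in full (columns
may be deleted at an affine penalty), sequence residues may be inserted
between columns, and unaligned sequence ends are free, becoming the
terminal extensions. Gap penalties default to open 11, extend 1, on the
bit-score scale of the profile log-odds; the defaults mirror the
affine-penalty conventions of standard protein search tools and are
adjustable per call. Insertions are keyed to columns 1..89 by
construction, so an "insertion after column 90" is simply part of the
C-terminal extension.

## Identity with event-based indel accounting

`core_identity()` counts identical core columns, then treats indels as
*events*: a maximal run of columns gapped in one sequence but not the
other is one non-identity regardless of its length, and an insertion
present in only one sequence (or differing in content) is one
non-identity per event, with the final count floored at zero. This
matches how family curators count "one non-identic residue" per indel
when comparing cores, and makes a single-residue insertion cost exactly
one identity unit.

## Distances, embedding, profiles

`fitch_distance()` uses the Fitch (1966) residue similarity — a binary
partition of the amino acids into the classes {A,G},
{R,N,D,Q,E,H,K,S,T}, {C,I,L,M,F,W,Y,V}, {P} — averaged over columns
where neither sequence is gapped, transformed to `d = sqrt(1 - s)`.
Pairs with no gap-free overlap have no defined similarity and are
reported `NA` rather than guessed. The test suite cross-checks the
matrix against `seqinr::dist.alignment`, which implements the same
similarity.

`pca_embed()` runs centered PCA on the *rows* of the distance matrix
(each sequence described by its distances to all others); classical
principal coordinates (`cmdscale` on the distances) is available via
`method = "pcoa"`. The row-PCA reading is the default because the
distance rows are the object the clustering narrative works with; for
well-separated clades both methods give the same qualitative picture.

`build_profile()` estimates column frequencies with an additive
pseudocount (default 0.5) and scores them as log2 odds against a uniform
residue background. The gap score column uses an assumed background gap
rate of 5%. Consensus ties break to the lexicographically smallest
residue so profiles are deterministic; conservation is the fraction of
members matching the consensus. `classify_sequence()` assigns the
best-scoring profile and flags assignments whose margin over the
runner-up is below 5 bits (configurable) as ambiguous — ties are always
ambiguous.

## Indel census and terminal extensions

`indel_census()` assigns each insertion event (one per contiguous run)
and deletion event to hotspot regions of the frame. The default spans —
loop between helices 1 and 2 at columns 14–16, turn between helix 2 and
strand 1 at 38–40, arm tip at 60–68 — are calibration data, not
constants, because secondary-structure block boundaries drawn on an
alignment are themselves approximate; they can be overridden with any
non-overlapping span table. `terminal_stats()` reports extension length,
K/R/D/E counts and all (overlapping) occurrences of the lysine-rich
PAKKA repeat implicated in DNA protection.

# Dimer geometry

`read_model()` consumes a two-chain C-alpha PDB (Angstrom converted to
nm on input; nm everywhere else), `map_core()` labels residues with core
columns through a `core_aligned_seq`, and `geometry_report()` measures:
helix-1/helix-2 and helix-2/helix-3 axis angles per monomer, the cross
angle between the two helices 2, the inter-chain distance between the
helix-2 C-terminal residues, and inter-chain distances at the last three
columns of strand 2 and first three of strand 5 (columns 54–56 and 73–75
under the default spans).

Two conventions needed fixing:

* **Angle convention.** All angles are undirected, `acos(|a . b|)`, in
  [0, 90] degrees — every family-wide value reported for these measures
  falls below 90, and the undirected angle is invariant to the arbitrary
  sign of a fitted axis.
* **Axis estimation.** The principal axis of a finite helical point
  cloud is *biased by the helical phase*: for an ideal helix of 36
  residues (rise 0.15 nm, radius 0.23 nm, 100 degrees per residue) the
  total-least-squares axis is tilted about 0.4 degrees from the true
  axis, and the bias grows for shorter spans. `fit_axis()` therefore
  uses the chord second differences `p[k] - 2 p[k+1] + p[k+2]`, which
  for a helix lie exactly in the plane perpendicular to the axis; the
  axis is the null direction of that vector set (smallest right singular
  vector), which is exact for ideal helices of any length and inherits
  the rotation-equivariance of the SVD. Near-straight spans, where the
  second differences do not span a plane, fall back to the
  total-least-squares principal axis. Spans resolving fewer than five
  mapped residues yield `NA` measurements rather than fabricated values.

`superpose_rmsd()` implements Kabsch superposition (optimal rotation and
translation, determinant-corrected so reflections are excluded) over the
core columns mapped in both models; the tests verify it against an
independent quaternion-eigenvalue oracle.

# The binding model

## Finite-lattice cooperative binding

A bound HU dimer occludes `n` base pairs of a `N`-bp duplex; a
configuration with `k` bound dimers and `c` pairs of dimers in immediate
contact has statistical weight `(K L)^k omega^c`, where `L` is the free
protein concentration, `K` the intrinsic association constant and
`omega` the McGhee–von Hippel contact cooperativity. `lattice_partition()`
computes the exact occupancy distribution by a transfer-matrix recursion
over lattice positions (O(N kmax), implemented in C++ with uniform
rescaling so lattices of thousands of base pairs stay in range), and the
tests verify it against exhaustive configuration enumeration for all
N <= 15, n <= 4. `mvh_density()` provides the closed-form
infinite-lattice isotherm, solved for the binding density by bracketed
root-finding to 1e-14; the two agree within 1% at N = 3000. Nearest-
neighbour contact is the only cooperative term — no longer-range
interactions are modelled.

## Depletion and fitting

At the experimental concentrations (DNA around 200 nM, protein of the
same order) ligand depletion is never negligible, so the free
concentration is always solved from mass conservation
(`solve_free_ligand()`, monotone bisection). `fit_cooperative()` fits
(K, omega) in log space by Nelder–Mead least squares between observed
band fractions and the depletion-corrected occupancy distribution,
identifying band k with the exactly-k-ligand states; electrophoretic
smearing or dissociation during the run is not modelled. Titrations
showing essentially no binding (maximum bound fraction < 5%) or
saturation throughout (minimum bound fraction > 95%) are rejected as
non-identifiable. The omega confidence interval comes from a seeded
parametric bootstrap (Gaussian residual noise at the fitted residual SD,
rows renormalised; percentile interval).

## Site size from length ladders

`estimate_site_size()` grid-searches integer site size `n` and register
offset against the prediction `count(N) = 1 + floor((N - offset)/n)`.
The offset is confined to one period, `0..n`: the count increments every
`n` bp, the offset only fixes where in the period the steps fall, and
offsets beyond one period would imply that even the first dimer needs
nearly two site sizes of DNA. This confinement also resolves the
single-step ladders (one visible transition inside the measured length
window), which are otherwise degenerate over arbitrarily small `n`; ties
are broken toward the smaller site size, and all tied values are
reported.

## Single-site Kd and affinity profiles

Structure-specific complexes quantified as one band are fit as 1:1
binding with depletion: the complex concentration is the smaller root of
`C^2 - C (P + D + Kd) + P D = 0`. `affinity_profile()` normalises the
fitted association constants to the same protein's dsDNA value, so the
dsDNA row is exactly 1 and structure preferences read as fold changes.

# Oligonucleotide assembly

`anneal()` performs greedy maximal pairing: repeatedly add the longest
exact antiparallel reverse-complement match of at least 8 bp between
unpaired regions of two different strands. Thermodynamics is
deliberately ignored — these constructs are designed for unique,
high-stringency pairing, and an exact-match rule with deterministic
tie-breaks (strands canonicalised labeled-first, earliest match on the
first strand) reproduces the designed topologies while staying
order-invariant. It is not a general hybridisation predictor: mismatched
or near-complementary duplexes and hairpins are out of scope.
`classify_structure()` labels the result by topology (duplex, nick,
A1/A3/A7 bulges, overhang, fork, four-way junction, incomplete junction,
invasion); a nick requires zero unpaired bases at the junction, and
anything outside the recognised set falls back to `unknown` rather than
forcing a label.

# Synthetic data: what it does and does not emulate

The generators exist so that every pipeline stage is testable without
downloads, and their defaults are the study conditions:

* `generate_family()` mutates a 90-residue consensus i.i.d. per column
  at rate `1 - identity`, places one insertion event in about 10% of
  sequences with region weights 0.34/0.18/0.15/0.33 (helix-1/2 loop,
  helix-2/strand-1 turn, arm tip, elsewhere), draws 80% of inserts as
  single residues, and appends terminal extensions with exact
  composition (so a spec of 111 residues with 29 K and 5 R is met
  exactly, and planted PAKKA repeats are the only ones possible because
  filler residues exclude proline). Columns evolve independently: there
  is no phylogenetic correlation, no covariation, and no
  secondary-structure-aware substitution model, so passing tests show
  the *statistics* are recovered, not that real evolutionary structure
  is handled.
* `generate_dimer()` builds ideal-helix C-alpha traces positioned so the
  full measurement suite evaluates to the spec targets: helices are
  placed with self-calibrated axes (build, fit, rotate the fitted axis
  onto the target), the second chain is a rigid rotation of the first at
  the cross angle, and the measured strand residues of the second chain
  sit at the exact target distances. Linkers are interpolated; the
  models are measurement fixtures with realistic local helix geometry,
  not physically packed folds.
* `generate_emsa()` adds truncated Gaussian noise (default SD 0.02,
  matching careful gel quantification) to the depletion-corrected model
  fractions and renormalises each lane. `generate_ladder()` reports the
  largest stoichiometry whose probability reaches the 5% detection
  threshold; the default protein concentration (20 uM) is strongly
  saturating because near full packing the last band competes against
  the configurational entropy of the (k-1)-dimer states — at lower
  protein the fully packed state of, e.g., an 8-bp ligand on 48 bp
  stays below detection even though it is sterically allowed.
* `design_titration()` spaces 8 protein concentrations so the lattice
  *fractional saturation* (`nu * n`) spans 10–90%. Spanning saturation
  rather than the bound-DNA fraction is what makes the cooperativity
  identifiable: with `omega < 1` the multi-dimer bands that carry the
  contact signal only populate well past the point where most DNA
  molecules carry one dimer.

All generators run behind a single integer seed and are byte-reproducible.

# Problem sizes and numerical choices

The shipped analyses and tests use 48-bp lattices with site size 9 or
11, 8-point titrations at 2% noise, 100 replicates per cooperativity
value for the median re-fit, families of 20–500 sequences, and 10–20
random dimer geometries per property check; these sizes give stable
medians (re-running the acceptance computation under different seeds
moves the fitted omega medians by a few percent) while keeping each
script in the minutes range. Bisections run to 1e-12–1e-14 relative;
optimisation is restarted once from its own optimum to guard against
premature simplex collapse; the lattice recursion rescales uniformly at
1e250 to avoid overflow without changing the normalised distribution.

# Known limitations

* The classifier is a per-sequence PSSM argmax; it does not model
  mixed-clade ancestry and its scores are not calibrated probabilities.
* Gel-mobility physics (band compression, bending-dependent anomalous
  migration) is out of scope; band identity is purely stoichiometric.
* The annealing model cannot represent mismatches, gaps of one
  nucleotide at a nick, or hairpins; such constructs classify `unknown`.
* Heterodimers (e.g. mixed alpha/beta HU) are not modelled anywhere.
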