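---
title: "Quantifying stereochemistry-driven bioactivity divergence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying stereochemistry-driven bioactivity divergence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The question the package answers

Stereoisomers — molecules with identical atomic connectivity but different
spatial arrangement — can bind different protein targets, sometimes with
clinically serious consequences (one enantiomer of a drug may be therapeutic
and the other toxic). Yet the most common 2D molecular descriptors, hashed
extended-connectivity fingerprints, are blind to stereochemistry by
construction: enantiomers receive bitwise identical fingerprints, so any
model built on them must assign stereoisomers identical predicted
bioactivity.

`stereoactivity` provides a tested pipeline to quantify this problem and to
evaluate remedies:

1. **Registry** — standardize structures, compute InChIKeys, count assigned
   and potential stereocenters, and classify each molecule as achiral, fully
   defined, or partially defined (racemic/incompletely characterized).
2. **Grouping** — partition the library into stereoisomer groups: sets of
   two or more fully defined molecules sharing one constitution.
3. **Profile analysis** — compare ternary target-binding profiles (0 none,
   1 weak, 2 strong) within groups: distinct-profile counts and Jaccard
   distance distributions against random compound pairs, with Mann–Whitney
   tests.
4. **Conformers and descriptors** — one MMFF94-relaxed 3D conformer per
   molecule; a stereo-blind 2D fingerprint baseline and a chirality-aware 3D
   geometric descriptor.
5. **Benchmark** — nearest-neighbor recapitulation: how well each
   descriptor's distances recover the nearest-neighbor structure of a
   reference bioactivity space, under random or stringent (near-miss)
   negatives, scored by AUROC over subsampled repetitions.

Because curated bioactivity corpora are large, proprietary to assemble, and
unnecessary for validating the machinery, the package ships a synthetic
library generator that emulates the relevant data regime end to end.

## Stereoisomer identification

Grouping is anchored on the InChIKey: its first 14-character block hashes
the molecular connectivity, so stereoisomers of one constitution share it.
Because a 14-character hash alone could in principle merge distinct
constitutions, membership additionally requires equality of the
stereo-stripped canonical SMILES, the protonation character (the InChIKey's
final letter), and the formal charge, and excludes isotope-labeled entries —
so that any difference between group members is exclusively stereochemical.
Molecules with at least one unassigned stereocenter (including unspecified
double-bond geometry) are excluded as not exhaustively characterized: a
racemic registry entry must never masquerade as a single stereoisomer.
Exclusions carry machine-readable reasons; full-key duplicates collapse to
the lexicographically smallest identifier. When one connectivity bucket
contains inconsistent protonation or charge variants, the largest consistent
sub-bucket (ties broken lexicographically) forms the group and the rest are
excluded with the mismatching field as the reason.

A brute-force pairwise grouping (no hashing) serves as the test oracle: on
libraries of up to ~500 molecules the hash-based partition must equal it
exactly.

## Binding profiles

Profiles are ternary vectors over a shared target list. Two conventions
matter and are deliberately different:

- **Distinctness** is exact equality of the full ternary vectors, so a
  weak-versus-strong difference at a single target makes two profiles
  distinct.
- **Jaccard distances** are computed on binarized profiles (bound = value
  ≥ 1), since Jaccard over a 3-valued alphabet is undefined without an
  arbitrary weighting. A pair with two empty bound sets has distance 0 by
  convention and is flagged for exclusion; well-formed libraries contain no
  such compounds.

Binarization can only merge profiles, never split them, so the fraction of
stereoisomer pairs with positive Jaccard distance is bounded above by the
fraction with distinct ternary profiles — a property the tests assert.

## Conformer generation

Each fully defined molecule receives exactly one 3D conformer by classical
distance geometry: holonomic bounds from covalent geometry (bond lengths
from covalent radii scaled by bond order; 1–3 distances from idealized
valence angles; van der Waals lower bounds elsewhere), triangle smoothing,
seeded uniform metrization, eigenprojection of the centered Gram matrix to
three dimensions, and SMACOF majorization toward the bounds. Tetrahedral
parity is then enforced from the MDL parity flags — a wrong center is fixed
by exchanging the *directions* (bond lengths preserved) of its two
lowest-degree non-stereocenter substituents, so adjacent centers are never
disturbed — and the geometry is relaxed with the MMFF94 force field (Open
Babel, steepest descent, capped at 1000 iterations; non-convergence is
accepted). Hydrogens are present during embedding and optimization and
removed before export.

Correctness of the stereochemistry is not assumed but verified: the final
geometry is converted back to an InChIKey, which must equal the molecule's
registry key; on mismatch the molecule is re-embedded with a derived retry
seed. The whole procedure is deterministic given `embed_seed`.

One design choice deserves emphasis: the metrization stream is seeded by the
molecule's *connectivity key*, not by its position in the input. All
stereoisomers of one constitution therefore start from the same sampled
distance matrix and differ only through their stereo corrections — the
behavior of fixed-seed distance-geometry embedding on identical molecular
graphs. Without this, independent rotamer draws dominate the geometric
differences between stereoisomers and drown the configuration signal the
downstream benchmark measures. A consequence worth knowing: conformers of
stereoisomers are *related*, not independent samples of conformational
space.

If MMFF94 setup fails for a molecule (exotic elements), the embedded
geometry is kept with `optimized = FALSE` and a warning — never a silent
skip.

## Descriptors

**fp2d** — hashed extended-connectivity fingerprints (radius 2, 2048 bits by
default) computed on the stereo-stripped constitution. The stereo-blindness
is intentional and exact: the module's contract is that 100% of stereoisomer
pairs receive cosine distance exactly 0, reproducing the premise that 2D
descriptors collapse stereoisomers.

**geo3d** — a 15-component geometric descriptor of one conformer:

- components 1–12: mean, standard deviation and cube-rooted third central
  moment of the heavy-atom distance distribution from four reference points
  (centroid; atom closest to it; atom farthest from it; atom farthest from
  that). These are invariant to all rigid motions *including reflection*.
- components 13–15: mean, median and third central moment of signed
  tetrahedral volumes over heavy-atom quadruples (all quadruples when there
  are at most 5000, else a seeded sample), normalized by the mean absolute
  volume. Only odd statistics are used, so the whole block changes sign
  under reflection — this is precisely what distinguishes enantiomeric
  geometries, which plain distance-moment descriptors cannot do. (A
  standard-deviation "dispersion" term would be reflection-even and was
  deliberately replaced by odd moments so the block negates exactly under
  mirroring.)

Conformers with fewer than four heavy atoms get a zero chirality block;
descriptors of zero-length conformers are an error.

## The kNN recapitulation benchmark

A reference space (here: cosine distances between continuous bioactivity
signatures) defines nearest neighbors as pairs below the empirical
`nn_percentile` quantile of its distance distribution (percent units: 0.001
leaves tail mass 1e-5 below the cutoff, 0.1 leaves 1e-3; the quantile is
estimated from all pairwise distances, or from a seeded sample of 1e6 when
the pair set is larger). Per repetition, a subsample of compounds is drawn;
positives are its below-cutoff pairs; negatives are drawn uniformly among
the rest (*random* mode) or from the near-miss band `(cutoff, 10 x cutoff]`
(*stringent* mode — the band multiplier is a config knob; no published value
exists for "close distance", so 10 is the declared default). Classes are
balanced by downsampling the larger one; AUROC is computed by midrank
statistics (a strictly monotone transform of candidate distances cannot
change it), then averaged over repetitions. The global-quantile cutoff is
the declared interpretation of the percentile convention; a per-molecule
variant would be a straightforward extension but is not implemented.

Two sanity anchors frame every run: a candidate identical to the reference
scores AUROC 1.0 under random negatives, and i.i.d. random candidate
distances score 0.5.

## The synthetic library generator

The generator defines the study conditions; its structure mirrors the data
regime of a curated target-binding space.

**Structures.** Families are assembled as `left + spacer + k stereocenters +
right` from fixed part pools (4 left terminations x 4 right terminations x 4
spacers x 8 substituents per center), indexed by mixed-radix decomposition
of the family index, so all constitutions are distinct by construction
(capacity 512 families). Left and right terminations are disjoint under any
spacer, which guarantees every substituted backbone carbon is a genuine
tetrahedral stereocenter and no meso symmetry can occur; this was verified
exhaustively against the InChI engine for all 512 x {1,2,3}-center variants.
Isomers of a family are distinct configuration assignments; the all-`@`
assignment is the *base isomer*. A configurable fraction of molecules is
re-emitted with one stereocenter erased, standing in for racemic entries.

**Profiles.** Each family draws a sparse base profile (each target active
with probability 0.15 — giving the right-skewed Jaccard distributions seen
in curated binding data — split weak/strong by `weak_strong_ratio`; at least
one target is always active). Every other isomer mutates each target
independently with probability `stereo_sensitivity`; a mutation always
changes the ternary value. Two refinements couple bioactivity to
configuration while keeping the arithmetic exact:

- the mutated value is drawn once per (family, target) and shared by all
  isomers — a stereocenter flip perturbs binding in a consistent direction;
- mutation indicators derive from per-(target, stereocenter) uniforms: an
  isomer whose configuration differs from the base at the center set *F*
  mutates target *t* iff `min(U[t, F]) < 1 - (1 - s)^(1/|F|)`. The marginal
  mutation probability is exactly `s` for *every* isomer, so the fraction of
  base-vs-isomer pairs with distinct profiles is exactly `1 - (1 - s)^T` in
  expectation — the closed form the tests recover across
  `s in {0, 0.01, 0.1, 1}` — while isomers with overlapping flip sets have
  correlated profiles, so bioactivity divergence tracks configuration
  divergence.

With 50 targets, `s = 0.01` reproduces a ~39.6% distinct-profile pair rate,
which is the package's default regime. Note that with three ternary values,
"every pair differs at every target" under `s = 1` can only hold for pairs
involving the base isomer; the corresponding checks run on two-isomer
families, where every pair is base-vs-mutant.

**Signatures.** 128-dimensional vectors: family base (standard normal) plus
a per-isomer offset of magnitude `0.5 x (profile Hamming distance from the
base)` along the normalized sum of per-flipped-center direction vectors,
plus i.i.d. noise (sd 0.02). Profile-divergent isomers are farther from the
family base, and isomers with similar flip sets point in similar offset
directions; cross-family distances concentrate near 1 (random directions in
128 dimensions).

**Determinism.** One root seed; per-family child streams derived by a stable
multiplicative hash, so family content is independent of generation order
and two runs with the same config are byte-identical on disk.

## Study conditions and problem sizes

All sizes below are the package's declared experimental design, chosen to
make each effect measurable with comfortable statistical margins:

- default library: 150 families, 1–3 stereocenters, 2–4 isomers (capped at
  `2^k`), 50 targets, `stereo_sensitivity 0.01`, 10% undefined molecules —
  roughly 400 compounds;
- parameter-recovery checks: 250 two-isomer families (250 independent
  pairs), binomial 95% confidence bands around `1 - (1 - p)^50`;
- percentile convention: 1e6-sample distance distributions;
- benchmark (the *stereo-sensitive* regime): 120 families, 2–3
  stereocenters, 4 isomers each, `stereo_sensitivity 0.2`, no undefined
  molecules (~480 compounds), `nn_percentile 0.1`, subsamples of 380
  compounds, 10 repetitions, averaged over 5 evaluation seeds.

The benchmark regime deserves its own note. Because the per-target mutation
marginal is exactly `s` for every isomer (required for the closed-form
arithmetic above), a base-vs-isomer pair's profile divergence is independent
of *how many* centers separate the pair — so two-isomer families carry no
geometry-to-bioactivity signal at all. The signal lives in pairs of two
non-base isomers, whose profile correlation depends on flip-set overlap.
A benchmark library of four-isomer, multi-center families maximizes such
pairs; on it, the family-standardized rank correlation between geo3d
distance and signature distance is ~0.33–0.37 on non-base pairs across
generator seeds, the stringent-mode AUROC of geo3d is consistently above
the exact 0.500 of the collapsed 2D fingerprint, and random-mode AUROC is
higher still for both (near-miss negatives are harder by construction).

## What passing tests do and do not show

The generator emulates: stereoisomer families with controlled constitution
uniqueness, racemic/partially characterized entries, sparse ternary binding
profiles with tunable within-family divergence, and continuous signatures
correlated with those profiles. It does **not** emulate: real target
identities or assay provenance, assay sparsity and false-negative structure,
tautomerism or salt forms, charge/isotope variants (these are exercised by
hand-built registry cases instead), conformational ensembles, or any learned
mapping from structure to bioactivity. Passing tests therefore demonstrate
that the pipeline's logic, statistics and contracts are correct under a
controlled data regime — not that a 15-component geometric descriptor
approaches the performance of a fine-tuned neural signature model on real
chemistry, nor that real stereoisomer bioactivity divergence follows the
generator's mutation model.

## Numerical choices and degenerate inputs

- Percentile cutoffs use the linearly interpolated empirical quantile
  (R type 7); a warning is emitted when the sample is smaller than
  `1/(percentile/100)` or when nothing falls strictly below the cutoff.
- Mann–Whitney tests use the normal approximation with tie correction
  (`wilcox.test`, `exact = FALSE`).
- Cosine distances are clipped to `[0, 2]`; pairwise matrices snap values
  below 1e-12 to exactly 0 so that bitwise identical descriptors tie exactly
  in rank statistics. Zero vectors are an error.
- Reference-point ties in geo3d (e.g. two atoms equidistant from the
  centroid) break to the lowest atom index; quadruple sampling is seeded by
  the atom count, so equal-sized conformers are compared on identical
  quadruple sets.
- MMFF94 parity: the parity-1 MDL flag corresponds to a positive signed
  volume over the four neighbor atoms in ascending index order (calibrated
  against stereo-correct reference geometries and guarded at run time by the
  InChIKey round trip).
- Tautomers are never standardized away: no published rule governs it here,
  and merging tautomers could silently fuse non-stereo variants.

## Known limitations

- Double-bond (E/Z) stereochemistry counts toward the potential-stereocenter
  total and is enforced in conformers only through the InChIKey validation
  loop (retry until the embedded geometry matches), not through explicit
  distance constraints; molecules with many stereo double bonds may need
  several retries.
- The conformer builder targets small organic molecules; macrocycles and
  fused ring systems get plausible but not carefully optimized ring
  geometries (MMFF94 relaxation does the cleanup).
- The geo3d descriptor is a desk-scale geometric stand-in with a deliberate
  design point — reflection antisymmetry — not a learned bioactivity model;
  its absolute AUROCs are not comparable to published neural-network
  results.
- Signature matrices are stored as CSV (no HDF5 dependency in the R stack).
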