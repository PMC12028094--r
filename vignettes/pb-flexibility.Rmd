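---
title: "Flexibility analysis of conformational ensembles with Protein Blocks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Flexibility analysis of conformational ensembles with Protein Blocks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pbflex)
```

## The model

A conformational ensemble — typically frames saved along molecular-dynamics
trajectories, read from a multi-model PDB — is reduced to a string per frame
over the 16-letter Protein Block (PB) alphabet. Each PB prototype is a set of
8 reference backbone dihedrals covering five consecutive residues; assignment
slides this window along the chain and, for every frame and central residue
*i*, picks the prototype minimising the angular RMSD

$$\mathrm{RMSDA}(v, w) = \sqrt{\tfrac{1}{8}\sum_{k=1}^{8}
  \mathrm{wrap}(v_k - w_k)^2},$$

where the window vector is
$(\psi_{i-2}, \phi_{i-1}, \psi_{i-1}, \phi_i, \psi_i, \phi_{i+1}, \psi_{i+1},
\phi_{i+2})$ and differences are wrapped to $[-180^\circ, 180^\circ]$. The
two positions at each chain end (and any position touching an incomplete
residue) cannot host a full window and carry the unassignable label `Z`,
excluded from all downstream frequencies. All window angles are weighted
uniformly — the classic variant of the assignment; this choice is recorded
here rather than made configurable.

Per position, the frequencies $f_x$ of each PB over the non-`Z` frames define

$$N_{eq} = \exp\Big(-\sum_{x=1}^{16} f_x \ln f_x\Big), \qquad 0\ln 0 := 0,$$

the equivalent number of PBs: a positional conformational entropy on a
directly interpretable scale, 1 (one PB ever observed) to 16 (uniform). Two
systems are compared by $\Delta N_{eq} = |N_{eq}^1 - N_{eq}^2|$ and by the L1
profile distance

$$\Delta PB = \sum_{x=1}^{16} \big|f_x^1 - f_x^2\big| \in [0, 2],$$

whose half reads as the fraction of differing PB assignments. $\Delta PB$
deliberately complements $\Delta N_{eq}$: two positions can have identical
entropy with disjoint PB usage ($\Delta N_{eq} = 0$, $\Delta PB = 2$), and the
test suite constructs exactly that counterexample. Note the sum must run over
absolute differences — without the absolute value it is identically zero for
normalized rows.

Classical measures are computed on the same frames, on Cα atoms alone:
per-frame RMSD against the starting frame after optimal (Kabsch)
superposition, and per-residue RMSF about the mean position. RMSF is a global
displacement measure while $N_{eq}$ is strictly local (five residues), which
is why their correlation over positions is typically weak; `pearson()`
correlates any two per-position metrics (RMSF, $N_{eq}$, crystallographic
B-factors) with pairwise deletion of undefined positions.

## Parameters that matter

- **Alphabet** (`pb_alphabet()`): the canonical published 16 x 8 reference
  table, shipped as a versioned CSV validated against an md5 checksum, shape
  and angle-range checks at load. It is a fixed constant of the method, not a
  tuning knob.
- **RMSF fit mode** (`rmsf(fit = )`, default `TRUE`): frames are superposed
  onto the *starting frame* on Cα in one pass before fluctuations are taken
  about the mean structure; no iterative mean refitting. Whether fitting
  targets frame 1 or the average structure is a genuinely open convention
  across MD tool chains; the choice is recorded in the profile's `fit_mode`
  attribute and in `analyze_system()` metadata. Closed-form recovery tests use
  `fit = FALSE`, where the expectation is exact.
- **Flexibility bins** (`categorize()`): rigid is pinned at $N_{eq} = 1$
  within $\varepsilon = 10^{-6}$ — "exactly one PB observed" is a distinct
  statement from "low entropy" — followed by half-open bins (1,2], (2,4],
  (4,6], (6,8], (8,16]. A coarser two-threshold reading (very flexible above
  6, disordered above 8) exists in the literature; the six-bin table is what
  the package implements.
- **ΔPB flagging threshold** (`compare_systems(delta_pb_threshold = 0.4)`):
  positions above 0.4 (a fifth of the maximal profile difference) are listed
  as notable, descending; configurable per call.
- **Angle convention**: all torsions are IUPAC-signed degrees in
  $(-180, 180]$, with exactly $-180$ mapped to $+180$ so every angle has one
  representation. Exact RMSDA ties between prototypes are broken toward the
  first label in `a`–`p` order — a measure-zero event in practice, fixed for
  determinism. Degenerate four-point geometry is an error, never a silent
  `NaN`.
- **Frame usage**: all provided frames enter the statistics; stride-based
  subsampling is the caller's decision before analysis. Replicates pooled
  with `pool_ensembles()` keep a `replicate_id`, and the frequency map of a
  pooled ensemble equals the frame-count-weighted mean of per-replicate maps
  (a tested identity).

## What the synthetic generator emulates — and what it does not

`sample_dihedral_frames()` draws each frame from $K$ whole-chain $\phi/\psi$
templates with known mixture weights, plus wrapped Gaussian angular noise;
`ensemble_from_dihedrals()` materialises frames in 3D through
`build_chain()`, a sequential internal-coordinate (NeRF-style) builder with
fixed bond lengths N–CA 1.458 Å, CA–C 1.525 Å, C–N 1.329 Å, bond angles
N–CA–C 111.2°, CA–C–N 116.2°, C–N–CA 121.7° (standard Engh–Huber values) and
a trans peptide bond ($\omega = 180^\circ$); `gaussian_ensemble()` adds
isotropic positional noise to a base structure.

Mixtures are over whole-chain templates rather than independent per-position
PB draws, because overlapping five-residue windows make independent
per-position sampling geometrically inconsistent; whole-template mixtures give
exact, self-consistent ground truth. This yields three analytic oracles the
tests lean on:

- at positions where the templates map to distinct PBs, pipeline $N_{eq}$
  must equal the entropy-exponential of the realised template draws exactly
  (to $10^{-9}$) in the noise-free case, and stay close under 10° noise;
- unfitted RMSF of a $\sigma$-Gaussian ensemble converges to
  $\sigma\sqrt{3}$ (tested at $n = 2000$ frames within three standard
  errors of the Monte-Carlo estimate);
- recomputing torsions of a built chain reproduces the input dihedrals to
  below $10^{-6}$ degrees.

The generator emulates *statistical* structure, not physics: no force field,
no side chains, no solvent, no temporal autocorrelation between frames, and
ideal covalent geometry. Passing recovery tests therefore validates the
pipeline's bookkeeping and numerics — assignment, counting, entropy,
superposition — not the realism of any particular MD ensemble. Conclusions
about a real system still depend on the quality and convergence of the input
trajectories.

Ideal repetitive templates are provided (`helix_template()` at
$\phi=-57^\circ, \psi=-47^\circ$; `strand_template()` at $\phi=-120^\circ,
\psi=135^\circ$); their interior positions assign to `m` and `d`
respectively, agreeing with an independent implementation of the published
assignment procedure on the same built chains.

## Numerical and design notes

- Positions are always author (PDB) residue numbers; internal 0/1-based
  indices never appear in outputs. Analyses are single-chain; multi-chain
  files require an explicit chain selection. Alternate locations keep the
  highest-occupancy conformer; waters and heteroatoms are excluded on read.
- Models with diverging atom tables are a hard error naming the first
  divergent model; a missing backbone atom only flags the residue incomplete
  and undefines the dihedrals that touch it.
- Empty frequency rows (all frames `Z`) are flagged (`n_frames = 0`) and
  propagate as `NA`, never as `NaN` or zero.
- Profile and frequency CSVs are written with 17 significant digits and read
  back with a correctly-rounded parser, so serialised comparisons regenerate
  bit-identically — a tested invariant.
- Test and example problem sizes (chains of 5–50 residues, 50–4000 frames,
  100-series round-trip batches) were chosen so the full suite exercises
  every stage, including the 4000-frame mixture recovery, in under a minute;
  the statistics themselves are size-independent.

## Known limitations

- No statistical testing of $N_{eq}$ differences between systems, and no
  smoothing of profiles; the measures are descriptive.
- Binary trajectory formats (XTC/DCD) are not read directly; convert to
  multi-model PDB upstream, or pool several PDB files with
  `pool_ensembles()`.
- Secondary-structure assignment (DSSP), ligand-interaction profiling and
  conformer clustering are out of scope.
- The shipped JH1 region annotation marks bounds that are not fully
  established in the consulted literature as approximate (see the file's
  comments); override with `read_regions()` where exact bounds matter.
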