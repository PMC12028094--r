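# pbflex

Per-residue flexibility analysis of protein conformational ensembles with the
**Protein Block (PB) structural alphabet**.

Molecular-dynamics ensembles are usually summarised by global geometric
measures (Cα RMSD per frame, Cα RMSF per residue). Those miss *local*
backbone rearrangements: a residue can keep a small RMSF while its local
conformation hops between discrete backbone states. `pbflex` quantifies that
local dynamics by encoding every residue of every frame as one of 16 canonical
local-backbone prototypes — the Protein Blocks `a`–`p`, where `m` is the
α-helix core and `d` the central β-strand — and deriving per-position
statistics from the letter distributions. It was designed for
system-vs-system comparisons of a kinase domain (apo vs phosphorylated vs
inhibitor-bound forms of JAK2 JH1, residues 843–1131), but applies to any
single-chain ensemble.

## The method

For each frame, the 8 backbone dihedrals of the 5-residue window centred on
residue *i* — (ψ<sub>i−2</sub>, φ<sub>i−1</sub>, ψ<sub>i−1</sub>, φ<sub>i</sub>,
ψ<sub>i</sub>, φ<sub>i+1</sub>, ψ<sub>i+1</sub>, φ<sub>i+2</sub>) — are compared
to each prototype's reference angles by the angular RMSD

> RMSDA(v, w) = sqrt( (1/8) Σ<sub>k</sub> wrap(v<sub>k</sub> − w<sub>k</sub>)² )

with differences wrapped to [−180°, 180°]; the nearest prototype's letter is
assigned. Per position, the letter frequencies *f<sub>x</sub>* over frames give:

- **N<sub>eq</sub>** = exp(−Σ<sub>x</sub> *f<sub>x</sub>* ln *f<sub>x</sub>*),
  the *equivalent number of PBs*: 1 when a single PB is ever seen (rigid),
  16 for a uniform, random distribution. Positions are categorized as rigid
  (N<sub>eq</sub> = 1), quite rigid (1–2], moderate (2–4], flexible (4–6],
  extremely flexible (6–8] or disordered (8–16].
- **ΔN<sub>eq</sub>** = |N<sub>eq</sub>¹ − N<sub>eq</sub>²| between two systems
  at matched positions.
- **ΔPB** = Σ<sub>x</sub> |*f<sub>x</sub>*¹ − *f<sub>x</sub>*²|, the L1 distance
  between the two PB distributions: 0 means identical profiles, 2 maximal
  difference; ΔPB/2 reads as the fraction of PB assignments that differ.

Classical Cα RMSD (per frame, after Kabsch superposition onto the starting
frame) and Cα RMSF (about the mean position) are computed on the same frames,
and per-residue crystallographic B-factors can be carried along for metric
correlations.

Because MD trajectories are rarely shippable, the package also contains a
synthetic-ensemble generator with exact ground truth: whole-chain φ/ψ template
mixtures with known weights (known expected N<sub>eq</sub>), wrapped Gaussian
angular noise, isotropic Gaussian positional noise (known expected RMSF =
σ√3), and an internal-coordinate backbone builder whose recomputed torsions
reproduce its inputs to machine precision.

## Worked example

Two synthetic 30-residue systems: one pure α-helix ensemble, one that mixes
the helix template with a β-strand template at weights (0.75, 0.25), both with
5° angular noise over 500 frames.

```r
library(pbflex)

tmpls <- list(
  helix_template(30, start_position = 901),
  strand_template(30, start_position = 901)
)
flexible <- sample_dihedral_frames(tmpls, c(0.75, 0.25), n_frames = 500,
                                   noise_sd = 5, seed = 7)
rigid <- sample_dihedral_frames(tmpls[1], 1, n_frames = 500,
                                noise_sd = 5, seed = 8)

sys_flex  <- analyze_system(ensemble_from_dihedrals(flexible), name = "mixed")
sys_rigid <- analyze_system(ensemble_from_dihedrals(rigid), name = "helix-only")

glance(sys_flex)
#>   name  n_frames n_positions n_assignable mean_neq max_neq pct_rigid max_rmsf
#> 1 mixed      500          30           26     1.77    1.77         0     11.8
```

Every assignable position of the mixed system sits at N<sub>eq</sub> ≈ 1.77,
matching the closed-form entropy of the mixture weights,
exp(−0.75 ln 0.75 − 0.25 ln 0.25) = 1.75, up to the binomial sampling noise of
500 draws — the generator's ground truth recovered through the full pipeline.
Comparing the two systems:

```r
cmp <- compare_systems(sys_rigid, sys_flex,
  regions = tibble::tibble(name = "core", start = 910, end = 920)
)
cmp
#> <pb_comparison> helix-only vs mixed: 26 position(s) with delta-PB > 0.4
#>   position delta_neq delta_pb delta_rmsf fraction_differing
#> 1      903     0.770    0.516       8.39              0.258
#> ...
```

ΔPB ≈ 0.52 at every interior position: the helix-only system is 100% `m`
while the mixed one is ~74% `m` / ~26% `d`, so |1 − 0.74| + 0.26 ≈ 0.52, and
`fraction_differing` = ΔPB/2 ≈ 0.26 recovers the strand mixture weight. The
`regions` table aggregates mean and max ΔPB/ΔN<sub>eq</sub>/ΔRMSF per
annotated region (a default JH1 annotation ships as `jh1_regions()`).

Plots: `autoplot(sys_flex)` (N_eq/RMSF profiles), `autoplot(cmp)`
(ΔPB/ΔN_eq profiles with the flagging threshold), `plot_pb_map(...)`
(position × PB frequency heat map). Real ensembles enter through
`read_ensemble("traj.pdb")` (multi-model PDB), `read_bfactors()`,
`read_regions()`; results leave through `write_profile()`,
`write_frequency_map()` and `write_pb_fasta()`.

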