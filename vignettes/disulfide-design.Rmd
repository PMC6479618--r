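---
title: "Disulfide design scanning and ensemble stability: methods and assumptions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Disulfide design scanning and ensemble stability: methods and assumptions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dsbscan)
```

## The problem

Engineering an extra disulfide bond (DSB) into an enzyme is a classic
rational-design route to thermostability: a well-placed S–S cross-link
rigidifies the fold and raises the temperature at which the protein
retains activity. The design question is *which residue pair to mutate
to cysteine*. `dsbscan` implements the screening half of that workflow
— geometric feasibility, explicit bridge modelling, energetic scoring,
quality classification, and filter annotation — together with the
verification half: stability metrics over conformational ensembles of
the wild type and the engineered variants, and consistency checks of
the mutagenic primers used to build them.

## The scanning model

### Feasibility screen

Two residues can host a disulfide only if their β-carbons are close:
the screen keeps pairs with d(Cβ, Cβ) ≤ `max_cb_cb` (default 5 Å; the
α-carbon substitutes for glycine, which has no Cβ). A minimum sequence
separation (default 4 residues) removes i, i±1..3 pairs that cannot
form an unstrained bridge; this default is a design choice, not a hard
constraint of the screen. Proline is excluded as a mutation target
because its backbone nitrogen is substituted and cannot accommodate
the cysteine substitution cleanly.

### Bridge modelling

For each candidate pair the Sγ atom of each side is placed from the
residue's own N/Cα/Cβ frame with ideal internal coordinates — bond
Cβ–Sγ = 1.81 Å, angle Cα–Cβ–Sγ = 114.0° — as a function of the χ1
torsion (N–Cα–Cβ–Sγ). Both χ1 values are searched on a grid (default
5°, configurable; the grid must divide 360°). For every (χ1ᵢ, χ1ⱼ)
combination the S–S distance, the two Cβ–Sγ–Sγ angles and the χ3
torsion (Cβ–Sγ–Sγ–Cβ) are measured and the conformer minimising the
strain energy is returned. A grid search is used instead of continuous
minimisation because it is deterministic, reproducible, and exhaustive
over the one periodic degree of freedom per side that matters; the
suite checks that refining the grid never worsens the minimum.

### Energy surrogates

The scoring functions are explicit surrogates with documented
constants (config-overridable, echoed into every report):

- **Strain**:
  `E = k_ss (d_SS − 2.05)² + k_ang [(θᵢ − 104.15)² + (θⱼ − 104.15)²] + k_tor [1 − cos 2(χ3 − 87°)]`
  with `k_ss = 100` units/Å², `k_ang = 0.02` units/deg², `k_tor = 2`
  units. Its zero point is ideal disulfide stereochemistry (S–S
  2.05 Å, Cβ–Sγ–Sγ 104.15°, χ3 = ±87°; the torsion term has period
  180° so both chiralities of the ideal bridge score zero). The
  constants were chosen once so that badly strained geometries exceed
  the 20/40 cut-offs of the quality rule below: a 0.45 Å bond-length
  error alone (or a ~45° χ3 error combined with modest angle strain)
  crosses 20 units.
- **Interaction**:
  `ΔEi = Σ_a [k_clash max(0, 3.0 − d(Sγ, a))² − ε·1(3.5 ≤ d(Sγ, a) ≤ 6.0)]`
  summed over both Sγ atoms against every heavy atom `a` of residues
  other than the pair, with `k_clash = 50` units/Å² and `ε = 0.1`
  units. Negative values mean the modelled sulfurs sit in a pocket of
  favourable contacts; any approach under 3 Å is penalised steeply.

These surrogates score only the modelled bridge: the environment is
kept rigid (no side-chain repacking, no backbone relaxation), which is
the standard screening approximation — the screen's job is triage, not
ΔΔG prediction.

### Quality rule and ranking

Candidates classify as **Good** (ΔEi < 0 and ΔE < 20), **Bad**
(ΔEi > 40, ΔE > 40, or both > 20), or **Medium** (anything else); the
three classes partition the plane and the inequalities are strict, so
ΔEi = 0 with ΔE = 20 is Medium. Screening filters *annotate* rather
than delete — the final choice of pairs in a real campaign mixes
criteria with expert judgment:

- `near_active_site`: any atom of either residue within
  `active_site_radius` (default 10 Å — a documented default; the
  criterion "distance from the catalytic core" has no canonical
  number) of a catalytic side-chain atom;
- `involves_native_cys`: the pair touches a cysteine already engaged
  in a detected native bond (native cystines are found as Sγ pairs
  within 2.3 Å, each cysteine pairing at most once, closest first);
- `buried_i`/`buried_j`: more than 16 other Cβ atoms within 10 Å of
  the residue's Cβ — a neighbour-count proxy for burial that avoids a
  surface-area dependency and is swappable via the config;
- `in_disordered_region`: within ±2 residues of a crystallographically
  missing region.

Ranking is a stable sort by quality class, then
`e_strain + max(e_interaction, 0)` ascending, then Cβ–Cβ distance,
with candidates flagged `near_active_site` or `involves_native_cys`
demoted below unflagged ones of the same class.

## Ensemble analysis

Ensembles are multi-model PDB files — the portable, text-only stand-in
for MD trajectories. Frame times are assigned from a configured saving
interval (default 500 ps, i.e. 200 frames represent a 100-ns run)
because the PDB format carries no time records.

- **Backbone RMSD** uses the {N, Cα, C} selection (the carbonyl O is
  excluded; "backbone" conventions differ and the selection is
  configurable) after optimal rigid superposition by the Kabsch/SVD
  method with the determinant correction, so reflections are never
  returned. The reference is the first frame by default; an external
  reference structure (e.g. a minimised crystal structure, which is an
  MD-package artefact this package does not produce) can be supplied.
- **Radius of gyration** is mass-weighted with standard atomic masses
  (uniform weighting available) and needs no superposition, being a
  centre-of-mass-relative quantity.
- **S–S distances** are internal coordinates, measured without
  superposition; a bond's *retention* is the fraction of frames with
  d(Sγ, Sγ) ≤ 2.15 Å, and the bond is called stable only at retention
  1.0.
- The **instability flag** in the cross-condition summary fires when
  the mean RMSD over the final 20% of frames exceeds 1.5× the mean
  over the first 20%. The windows and ratio are documented heuristics
  chosen to detect monotone drift against a fluctuating baseline;
  single-frame ensembles report zero spread and never flag.

## The synthetic generator: what it emulates, and what it does not

`build_structure()` grows backbones (N, Cα, C, O, Cβ) by sequential
ideal-internal-coordinate placement (bond lengths N–Cα 1.458, Cα–C
1.525, C–N 1.329 Å; standard angles; trans ω) with fold-appropriate
torsions: an α-helix preset and a β-hairpin of two antiparallel
strands around a two-residue turn. For the hairpin, the turn is
positioned so a requested planted pair (i, j) lands on the same-face
cross-strand registry (i + j = 2·turn_start + 2), and two frozen
torsion presets are tried in order until the achieved Cβ–Cβ distance
verifies inside [4, 5] Å; the presets were tuned numerically, once,
so that the registry admits an unclashed χ1 conformer at near-ideal
S–S stereochemistry. Requests no preset can satisfy (turn too close to
a chain end, odd i + j, same-strand pairs) fail with an explicit
error rather than a silent approximation, and every achieved distance
is recorded in the returned truth record. `plant_disulfide()` places
real SG atoms at 2.05 ± 0.02 Å by a geometric grid-plus-refinement
search that is independent of the strain surrogate, so planted truth
does not presuppose the scorer it is used to test.

`make_ensemble()` builds frame *t* as
`Rigid_t(ref + N(0, σ²) + t·drift·field)`: i.i.d. Gaussian per-atom
fluctuation, a progressive deformation along the first principal axis
of the reference (a smooth global stretch standing in for unfolding),
and an optional random rigid rotation+translation per frame (so the
suite can prove that superposition precedes RMSD and that internal
coordinates ignore rigid motion). When `protect_ss` is on — the
stable-trajectory condition — cystine SG atoms receive neither noise
nor drift, emulating a bond that holds its geometry while the rest of
the structure fluctuates; when off, the SG atoms feel the noise and
are additionally separated along the bond axis by the drift, emulating
bond-region unfolding. The three study conditions are fixed presets:
26.85 °C (σ = 0.10 Å, no drift, protected), 70 °C (σ = 0.25 Å, no
drift, protected), 80 °C (σ = 0.30 Å, drift 0.02 Å/frame,
unprotected). All generators are pure functions of (spec, seed).

What this does **not** emulate: real force-field dynamics, solvent,
correlated motions, temperature-dependent kinetics, or partial
unfolding pathways. Passing tests on these ensembles demonstrate that
the *metrics and the pipeline* behave correctly on data with known
ground truth — flat RMSD and full retention under stationary
fluctuation, monotone RMSD growth and retention loss under drift —
not that any particular real protein is stable. Conclusions about a
real enzyme require real trajectories, which this package only
analyses, never produces.

## Numerical choices and degenerate inputs

- PDB I/O is delegated to `bio3d`; alternate locations are collapsed
  to the highest-occupancy conformer (ties broken by altloc character
  order), hydrogens are dropped (all criteria are heavy-atom based),
  and waters/ligands are stripped on read unless requested. Multi-model
  files are pre-validated so that a model with divergent atom records
  is named in the error, and coordinates outside the fixed-width
  `%8.3f` PDB field refuse to write.
- Author residue numbering is canonical everywhere, because published
  residue labels are author numbers. Gap detection against `"seqres"`
  assumes author numbering 1..len(SEQRES) per chain; when that
  assumption does not hold for a deposited structure, pass an explicit
  expected numbering vector instead.
- Superposition requires ≥ 3 non-collinear points; collinear sets and
  zero-mass Rg inputs are errors, not NaNs. The Kabsch implementation
  is cross-checked in the test suite against an independent
  quaternion-method oracle at 1e-8 on a thousand random point sets.
- The χ1 grid default of 5° bounds the S–S distance resolution of the
  modelled bridge to well under 0.1 Å for in-band pairs, which is why
  the planted-pair recovery tolerance is 0.1 Å.
- Primer-pair consistency is reported two ways: strict equality of the
  reverse primer with the reverse complement of the forward, and
  *annealing consistency* (one strand is a contiguous subsequence of
  the other's reverse complement). Published tables commonly truncate
  one strand by a base or two; such pairs anneal perfectly over their
  full overlap and are counted as consistent, while the strict verdict
  is still reported. The cysteine-codon check (TGT/TGC in the forward
  primer) is substring-based because the table does not carry the gene
  sequence, so the reading frame is unknown — a necessary weakening,
  reported as such.

## Problem sizes used in the checks

The shipped suite and the acceptance script run on a 22-residue
hairpin fixture, 200-frame ensembles (the 100-ns convention at 500-ps
saving), a thousand random point sets for the superposition oracle,
and the six-pair packaged primer table. These sizes exercise every
code path at interactive speed; all thresholds above are the same ones
a full-size protein scan would use.

## Known limitations

- The energy surrogates are screening heuristics: no repacking,
  relaxation, electrostatics, or ΔΔG calibration. Their absolute
  scale is meaningful only relative to the quality rule's cut-offs.
- The frame-agnostic cysteine-codon check can accept a TGT/TGC that is
  out of frame.
- `detect_missing_regions` cannot distinguish disorder from a chain
  break by construction — both are expected-but-absent residues.
- Multi-chain structures are supported for I/O and detection, but
  scanning enumerates within-chain pairs only (inter-chain disulfides
  are a different design problem with different criteria).
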