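---
title: "Protein Blocks trajectory analysis: model, parameters and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Protein Blocks trajectory analysis: model, parameters and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pbtraj)
```

## The model

`pbtraj` treats a conformational ensemble as a static topology plus an
ordered stack of coordinate frames (Å, ps, author residue numbering
preserved end to end). Three layers of analysis sit on top.

**Local conformation.** Backbone φ/ψ dihedrals are computed per residue
and frame (IUPAC sign convention, degrees in (−180, 180]; φ undefined at
the chain start, ψ at the end). Each residue with a complete 8-angle
window (ψ~i−2~, φ~i−1~, ψ~i−1~, φ~i~, ψ~i~, φ~i+1~, ψ~i+1~, φ~i+2~) is
assigned to one of the 16 Protein Blocks *a*…*p* by minimizing RMSDA,
`sqrt(mean(wrap(window − prototype)^2))`, with every angular difference
wrapped to the shortest arc. The prototype table is the canonical
Protein Blocks definition and is embedded as a constant; its correctness
is enforced behaviourally in the test suite (an ideal α-helix, φ = −57,
ψ = −47, assigns block *m* at every assignable position; an ideal
extended strand, φ = −120, ψ = +130, assigns *d*; every prototype's own
8-vector self-assigns). Positions without a complete window — always
the two first and two last residues of a chain — are marked `Z` and are
excluded from all frequency statistics rather than treated as a 17th
state, so the 16 frequencies of an assignable position sum to exactly 1,
which the entropy formulas assume.

**Per-position statistics.** For position *i* with block frequencies
f~x~(i) over frames: N~eq~(i) = exp(−Σ~x~ f~x~ ln f~x~) (natural
logarithm, so the exponential inverts the Shannon entropy in nats;
0·ln 0 ≡ 0). N~eq~ is 1 when one block is observed, 16 at the uniform
distribution, and is read as the effective number of local conformations
sampled. Two systems are compared position-wise by
ΔN~eq~ = |N~eq~^S1^ − N~eq~^S2^| and by the L1 divergence
ΔPB = Σ~x~ |f~x~^S1^ − f~x~^S2^| ∈ [0, 2], which distinguishes *which*
blocks are populated — two positions can share N~eq~ with disjoint block
support, and ΔPB = 2 flags exactly that.

**Geometry over time.** Cα RMSD against a reference frame and
per-residue RMSF about the time-average position, both after
least-squares rigid-body superposition (Kabsch, proper rotation
enforced via the determinant correction). Ion binding is summarized as
per-residue occupancy (fraction of frames with an ion within a cutoff
of any heavy atom of the residue), per-ion onsets under a persistence
rule, and the bound-count series. Dimers are summarized by inter-chain
Cα–Cα distances at anchor residues and classified stable/separated.

## Tunable parameters

| Parameter | Default | Units | Rationale |
|---|---|---|---|
| equilibration cut (`discard_equilibration`) | 5000 | ps | discard the first 5 ns of a production run; 0 for synthetic data |
| ion cutoff (`ion_occupancy`) | 3.0 | Å | conventional contact radius for ion fixation at a residue |
| onset persistence (`binding_onset`) | 10 | frames | 1 ns at a 100 ps stride; rejects single-frame grazing contacts |
| separation threshold (`classify_separation`) | 50 | Å | far beyond any bound-dimer contact distance, far below drift distances (hundreds of Å) |
| separation persistence | final 20 % | fraction of frames | the verdict must hold at the end of the run, not on a transient spike |
| N~eq~ report flags (`run_profile`) | >6 disordered-like, ≤2 rigid | — | reporting vocabulary only; thresholds are config keys, not hard-coded science |
| CREAC search window (`detect_creac_cysteines`) | 12 | residues | the 5-residue motif plus the 7-residue C-terminal extension that follows it in the mutant alternative reading frame |
| PB jitter (`sample_system`) | 5 | degrees | small angular noise that never flips an assignment in the validated regimes |

The classification thresholds deliberately have no physical content —
they encode reporting conventions, are recorded in every output's
provenance header, and can be overridden per run.

## Design decisions

**Trajectory interchange is multi-model PDB** (plus a plain
whitespace-separated frame table for synthetic data). Binary MD formats
are out of scope; the PDB dialect carries per-model times in a
`REMARK 6 TIME_PS` line so round trips preserve the time axis, and
falls back to the conventional 100 ps stride when absent.

**Author numbering everywhere.** Reports, profiles and comparisons are
keyed by author residue numbers (352-based for the CALR C-domain), so
positions can be read directly against the literature. Cross-system
alignment defaults to author-number identity; frameshifted tails of
unequal length are compared through an explicit user-supplied pairing
table, because no automatic pairing is defensible there.

**Two rules, not one.** Discarding early frames (a time cut) and
excluding chain-terminal positions (a window-completeness consequence)
are independent mechanisms and are implemented independently: the first
as `discard_equilibration`, the second intrinsically in PB assignment
(`Z` positions).

**RMSF scheme.** All frames are superposed onto the reference frame
(single pass), the per-atom mean position is computed post-fit, and
fluctuations are measured about that mean. An iterative mean-structure
refinement changes nothing in the validated regimes and is not
performed. A separate `fit_selection` lets the fit run on a rigid core
while the measurement covers everything — the closed-form test cases
(a displaced atom among fixed ones) require exactly this.

**Tie-breaking.** Equal RMSDA against two prototypes resolves to the
alphabetically lowest label; assignment is therefore fully
deterministic.

**Degenerate inputs.** Superposition refuses fewer than 3 points;
selections may legitimately be empty (an empty list, not an error) for
topology queries but are an error where a computation needs atoms; a
model with a deviating atom count names the offending MODEL index; an
equilibration cut that removes every frame is an error rather than an
empty trajectory.

## The synthetic generator: what it emulates, and what it does not

The generator stands in for MD in validation. It emulates, in a
statistically controlled way: rigid helix cores with mobile/disordered
termini (PB mixtures per position), scripted ion binding (an ion sits
2.0 Å from a heavy atom of its target residue while "bound", ≥15 Å from
the whole protein while not), and two-chain systems that either hold
together or separate at a scripted rate. Backbones are rebuilt from
dihedrals with ideal geometry (N–Cα 1.458 Å, Cα–C 1.525 Å, C–N 1.329 Å;
angles 111.2°, 116.6°, 121.7°; ω = 180°) by sequential NeRF
construction, so recomputing φ/ψ from the coordinates reproduces the
inputs to 1e-6°; a pseudo-Cβ gives every residue a side-chain heavy
atom for ion targeting. Jitter on the sampled (φ₀, ψ₀) is uniform for
simplicity.

It does **not** produce physics: no force field, no solvent, no
periodic boundaries (coordinates are unwrapped, and the ion module
accordingly applies no minimum-image correction), no realistic
transition kinetics, and no side chains beyond Cβ. Passing the
recovery suite therefore demonstrates that the *analysis* pipeline is
correct, not that any MD observable of a real protein is reproduced.

**Window coupling and the recoverable regime.** A PB window spans five
residues, so the assignment of a position depends on its neighbours'
dihedrals. If every position redraws its block independently each
frame, a lone strand-like draw inside a helical context is still
assigned *m* — the window is dominated by the six neighbour angles —
and high-entropy designs underestimate their target entropy after
assignment. Only blocks *m* and *d* are context-free in the sense that
a homogeneous stretch of their own central angles self-assigns. The
generator therefore offers two regimes, and the validation suite uses
each where it is meaningful:

- *independent draws* (default): produces genuinely flexible,
  high-N~eq~ ensembles with large terminal fluctuations — used for the
  RMSF rigid-vs-flexible ranking tests, where the ground truth is the
  flexibility gradient, not the exact label;
- *frame-coherent draws* (`frame_coherent = TRUE`): one draw per frame
  shared along the chain, so interior windows are conformationally
  pure; mixtures over {*m*, *d*} are then recovered exactly up to
  multinomial sampling noise — used for the mixture-recovery and
  N~eq~-recovery tests (total variation < 0.05 and |N~eq~ − exp(H)| <
  0.1 at 5000 frames, where the observed errors are an order of
  magnitude smaller).

## Sequence-level analysis

Variant records carry the CALR C-domain fragment sequences. Point
variants (substitutions, stops) are applied by notation
(`apply_simple_variant`); frameshift products are supplied as explicit
sequences, shipped as a plain-text FASTA fixture whose headers document
their provenance as transcribed reconstructions (class C contains five
junction residues that could not be independently verified and is
labelled synthetic). The net formal charge model counts K/R against
D/E, His neutral, termini ignored — under this convention the wild-type
fragment scores −26, matching its published 13-Ca²⁺ neutralization
(`ceiling(26/2)`). Helix content is computed from annotated intervals
(inclusive, non-overlapping, rounded percentage). Of the published
per-system helix percentages, only class A (interval 366–388 over 60
residues → 38 %) is reproducible from the printed helix boundaries; for
the other systems the printed boundaries and percentages disagree with
each other, a discrepancy in the source data that the package documents
rather than resolves — the shipped annotation set is therefore
illustrative except for class A.

## Problem sizes used in validation

The test systems are deliberately small: 5–32 residues, 5–600 frames
for unit and property tests, a single 9-residue × 5000-frame ensemble
for the convergence checks, and ≤13 scripted ions. These sizes put
every statistic deep in its converged regime for the scripted designs
while keeping the whole suite fast; nothing in the implementation is
specific to them, and the algorithms scale with atoms × frames.

## Known limitations

- PB frequencies are reported per position with no smoothing or
  windowing, and no significance test is attached to ΔPB or ΔN~eq~.
- Ion occupancy is binary presence per frame; multiple simultaneously
  bound ions at one residue are not counted separately.
- No periodic-boundary imaging: trajectories from wrapped simulations
  must be unwrapped upstream.
- The multi-model PDB reader expects a consistent atom list across
  models (it is a trajectory format here, not a general alternate-
  location parser).
- Frameshift variant sequences are reconstructions (see the FASTA
  headers); analyses that depend on their exact junction residues
  should supply verified sequences.
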