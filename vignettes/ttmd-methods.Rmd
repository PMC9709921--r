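---
title: "TTMD: model, parameters and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{TTMD: model, parameters and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ttmd)
```

## The model

Thermal titration molecular dynamics (TTMD) estimates the *qualitative*
stability of a protein–ligand binding mode by heating the complex through a
ladder of short MD windows and measuring how quickly the native interaction
pattern decays. The pipeline has four layers:

1. **Interaction fingerprints.** Every frame is encoded as an `r × 8` binary
   matrix: one row per protein residue (plus metal ions), one column per
   interaction channel — hydrophobic (HY), aromatic face-to-face (F2F) and
   edge-to-face (E2F), hydrogen bond with the protein as donor (HB_PD) or
   acceptor (HB_PA), salt bridge with the protein positive (SB_PP) or
   negative (SB_PN), and metal coordination (MET).
2. **IFP_CS scoring.** Each frame's fingerprint `q` is compared with the
   reference fingerprint `ref` of the last equilibration frame:
   `IFP_CS = -(q·ref)/(|q||ref|)`, ranging from −1 (native pattern intact)
   to 0 (all native interactions lost).
3. **The titration protocol.** Windows run at 300, 310, …, 450 K for 10 ns
   each; each window starts from the previous window's final coordinates.
   The run stops early at the first window whose *mean* IFP_CS is null
   (≥ −ε).
4. **The MS coefficient.** The titration profile plots the per-window mean
   IFP_CS against window temperature, prepended with the initial state
   (−1 at the starting temperature). MS is the slope of the straight line
   between the first and last profile points. Five replicates are
   trimmed-mean aggregated and classified tight/weak at 0.004 K⁻¹.

## Geometric interaction criteria

All distances are between heavy atoms, in Å (defaults of
`interaction_thresholds()`):

| Channel | Criterion |
|---|---|
| HY | apolar C/S pair ≤ 4.0 |
| F2F | ring-centroid distance ≤ 4.5 and normal angle ≤ 30° |
| E2F | centroid distance ≤ 5.5 and normal angle 60–90° |
| HB_PD / HB_PA | donor–acceptor ≤ 3.5; if the donor hydrogen is present, D–H…A angle ≥ 130° |
| SB_PP / SB_PN | any cationic-group atom within 4.0 of any anionic-group atom |
| MET | metal ion ≤ 2.8 from N/O/S ligand atom |

Aromatic rings are 5- and 6-cycles of C/N/O/S detected on the bond graph and
accepted when planar to 0.1 Å. Hydrogens are optional everywhere: when they
are absent, hydrogen bonds fall back to the distance criterion, and
donor/acceptor roles are inferred from element and bonding pattern.
Protein-side polar and ionic groups come from residue templates (backbone
N/O, side chains of SER/THR/TYR/ASN/GLN/HIS/LYS/ARG/ASP/GLU/CYS/TRP/MET);
ligand-side groups are perceived generically from the bond graph and formal
charges (|q| ≥ 0.5 marks an ion when no group pattern matches).

## Parameters and defaults

| Parameter | Default | Units | Where |
|---|---|---|---|
| ramp | 300 → 450, step 10 | K | `build_ramp()` |
| window length | 10 | ns | `build_ramp()` |
| termination tolerance ε | 1e-4 | – | `ttmd_config()` |
| scoring stride | 1 (every saved frame) | frames | `ttmd_config()` |
| replicates | 5 | – | `run_replicates()` |
| classification cutoff | 0.004 | K⁻¹ | `MS_CUTOFF` |
| protomer weights | equal (50/50) | – | `combine_protomers()` |
| water retention | ≤ 4.5 from any ligand heavy atom | Å | `read_structure()` |
| energy pair cutoff | 9 | Å | `per_residue_energy()` |
| Coulomb constant | 332.06 | kcal·Å/(mol·e²) | `per_residue_energy()` |

The per-residue energy decomposition uses 12-6 Lennard-Jones with
Lorentz–Berthelot combination and plain (unscreened) Coulomb; it is a
diagnostic decomposition of which residues hold the ligand, not a free
energy.

## What the synthetic engine emulates — and what it does not

`synthetic_engine()` implements the engine contract with scripted frames:
every frame is an independent Gaussian displacement of the reference pose
with per-coordinate σ(T) = σ₀·T/300 (σ₀ = 0.3 Å), so fingerprint decay
accelerates with temperature exactly as the protocol assumes. Scenarios
overlay discrete events: `unbinder` translates the ligand 20 Å out of the
pocket from a scripted window on; `partial_unfold` displaces half of the
backbone in the last two windows so `monitor_fold()` has something to flag.

The generator emulates *fingerprint dynamics*, not physics: there are no
forces, no inertia, no correlated motion, no solvent, and frames within a
window are independent draws rather than a time series. It exists so the
scoring, termination, aggregation and reporting layers can be validated
end-to-end deterministically. Quantitative MS values from the toy complex
say nothing about real systems; only the *contrast* between scenarios is
meaningful.

## Numerical choices

* **Superposition** uses the Kabsch algorithm via SVD of the 3×3
  cross-covariance, with the proper-rotation (determinant) correction and an
  error on degenerate (collinear or < 3 point) selections.
* **Fingerprint kernels** compare squared distances against squared
  thresholds and obtain ring normals by Newell's method, keeping per-frame
  scoring at ~2 ms for the toy complex; a candidate-residue prefilter (max
  cutoff + 3 Å around ligand atoms) bounds the pair work.
* **Determinism.** All stochastic stages draw from seeds derived as
  `derive_seed(master, index)`; RNG state is saved and restored around each
  draw, so library calls never perturb the user's RNG stream and replays are
  bit-identical.

## Interpretation choices

Places where the method description leaves room, and what this
implementation does:

* **Zero-norm query.** Cosine similarity is undefined for a frame with no
  interactions; such frames score 0, which is exactly the "all reference
  determinants lost" state. A zero-norm *reference* is a configuration
  error: the protocol is meaningless without an equilibrated contact
  pattern.
* **Initial profile point.** The profile prepends (T_start, −1). Its
  temperature equals that of the first window, so profile temperatures must
  be non-decreasing at the first gap and strictly increasing afterwards.
* **Early termination and MS.** T_end in the MS slope is the last *explored*
  temperature, so terminating at, say, 320 K with a null mean gives
  MS = 1/20 = 0.05 K⁻¹ — early loss yields a steeper slope than surviving to
  450 K with the same final mean.
* **Termination tolerance.** "Null mean IFP_CS" is evaluated as
  `mean ≥ -epsilon` with ε = 1e-4 by default, so a mean of exactly 0 always
  terminates while floating-point residue below ε cannot keep a dead run
  alive.
* **Classification boundary.** A complex exactly at the 0.004 K⁻¹ cutoff is
  classified *weak*: tight binders sit strictly below it.
* **Fingerprint rows.** Rows are the protein residues in file order followed
  by metal ions; a MET contact is recorded on the ion's own row. Waters are
  context (retained within 4.5 Å of the ligand for I/O fidelity) but carry
  no fingerprint row.
* **Trimmed mean.** Exactly one lowest and one highest replicate are
  dropped, even under ties; with the minimum of three replicates, the single
  central value remains.
* **Problem sizes.** The shipped workflow targets pocket-scale systems
  (tens of residues, ≤ a few thousand atoms per frame, hundreds of frames
  per window). The algorithms are O(pairs within cutoff) per frame and have
  no hard size limits.

## Plugging in a real engine

Implement the two functions of `ttmd_engine()` — `equilibrate(system, seed)`
and `run_window(system, start_coords, temperature, length_ns, seed)` — each
returning a `trajectory()`. Frames can be read from DCD or multi-model PDB
with `read_trajectory()`. Everything downstream (scoring, termination,
profiles, MS, aggregation, plots, CLI) is engine-agnostic.
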