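---
title: "Methods: trajectory analysis of TCR-pMHC dynamics with tcrdyn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: trajectory analysis of TCR-pMHC dynamics with tcrdyn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tcrdyn)
```

## The problem

An alpha-beta T-cell receptor (TCR) recognises a peptide presented by a
class I MHC molecule (pMHC). Crystal structures of such complexes are
space- and time-averages; questions about *dynamics* — how flexible is the
bound peptide, which interface hydrogen bonds are persistent and which
transient, how does the TCR rock or scan atop the antigen-binding cleft —
need trajectory data (typically from molecular dynamics) and a consistent
set of geometric analyses. `tcrdyn` implements those analyses:

1. **Flexibility**: per-residue root-mean-square fluctuation (RMSF) of
   Cα positions about the iteratively aligned average structure, plus
   crystallographic B-factor summaries and pairwise RMSD comparisons.
2. **Interface**: geometric hydrogen-bond detection (donor–acceptor
   distance plus donor–H–acceptor angle), heavy-atom residue contacts,
   and per-bond persistence over a trajectory.
3. **Footprint**: the accumulated set of pMHC residues contacted by the
   TCR, each interaction classified against the crystal structure as
   `crystal_and_md`, `crystal_only`, `novel_short_lived` or
   `novel_long_lived`, with a residue-level conservation comparison
   between independently simulated complexes.
4. **Motion**: rigid-body characterisation of the TCR relative to the MHC
   frame — per-frame rotation angle and axis (Kabsch superposition),
   displacement decomposition parallel/orthogonal to the cleft axis, and
   docking-angle differences between complexes.
5. **Synthetic data**: generators with exact ground truth so that every
   stage is testable without simulation data or structure downloads.

## Models and conventions

### Coordinates, topology, selections

A trajectory is an `F × N × 3` array of Cartesian coordinates in
Ångström bound to a topology (PDB-style atom naming, author residue
numbers, chains, occupancies, B-factors). Author residue numbering is
authoritative throughout, because the literature on these systems refers
to author numbers (Arg62, Gln155, peptide positions 1–13). Selections are
conjunctions of chain / residue-range / atom-name / element predicates
resolving to deterministic, topology-ordered index lists; an empty
resolution is a value, not an error (an unknown chain warns).

Chain roles (`mhc_heavy`, `b2m`, `peptide`, `tcr_alpha`, `tcr_beta`) are
configuration, never hard-coded. Defaults are shipped for the reference
accessions; the per-chain assignment inside the 2AK4 chain ranges K–P /
A–E follows deposition convention and is flagged unverified — override it
after inspecting the deposited file.

PDB input follows wwPDB v3.3 fixed columns. Alternate locations reduce to
the highest-occupancy conformer (ties toward altloc `A`), matching the
single-conformer convention of MD input preparation. Waters and
monoatomic HETATM ions are dropped by default: all analyses here concern
direct protein–protein interactions, and water-mediated bridges are out
of scope by design. Trajectories are assumed **pre-imaged** (molecules
whole); there is no periodic-boundary minimum-image logic anywhere.

### RMSF

Frames are aligned on a fit selection to the average structure, computed
by two align→mean passes (first pass referenced to frame 1). Two passes
suffice for near-rigid cores such as the MHC platform; no iteration
scheme is standard in the field, so the count is fixed and documented
rather than exposed as a convergence loop. The conventional setup fits on
the MHC core (residues 1–180, Cα) and reports Cα of both the core and the
13-residue peptide; fitting on the reported atoms themselves is available
but not the default. RMSF is mass-unweighted over the stated selection
only: `rmsf_i = sqrt(mean_f |x_i(f) − x̄_i|²)`. No time-windowing or block
averaging is applied — whole-trajectory RMSF on production frames is
assumed.

`align = FALSE` measures raw lab-frame fluctuations; the synthetic
fluctuating-chain generator defines its ground truth in that frame
(expected RMSF = √3·σ for per-coordinate noise σ).

### Hydrogen bonds

A bond is formed in a frame iff the donor-heavy to acceptor distance is
≤ 3.5 Å **and** the donor–H–acceptor angle at the central hydrogen is
within 30° of linear (≥ 150°), both boundaries inclusive. The published
criterion states a "donor/acceptor cut-off distance", which this package
reads as donor-heavy ↔ acceptor (not hydrogen ↔ acceptor); that
interpretation is recorded here because the alternative changes counts.

Donors are N/O/S heavy atoms carrying at least one attached hydrogen
(attachment = nearest heavy atom within 1.2 Å, computed from frame 1;
unmapped hydrogens are skipped with a warning). The proline backbone
nitrogen is never a donor. Acceptors come from a residue-type table
(backbone O/OXT; Asp Oδ1/2, Glu Oε1/2, Asn Oδ1, Gln Oε1, Ser Oγ, Thr Oγ1,
Tyr Oη, His Nδ1/Nε2, Met Sδ). Histidine is treated as unprotonated on
both ring nitrogens — each is an acceptor, and a donor only when it
actually carries a hydrogen; per-structure overrides are a matter of
editing the hydrogen set.

Crystal structures usually lack hydrogens. Operations that need the angle
criterion state so and fail clearly; deciding whether a bond is "in the
crystal structure" falls back to a distance-only mode (d ≤ 3.5 Å, angle
waived), and the mode is recorded on the result object.

Chemically equivalent atom pairs (Arg Nη1/Nη2, Asp Oδ1/Oδ2, Glu Oε1/Oε2)
are merged into one series by per-frame logical OR and reported with a
`1/2` suffix — the bookkeeping convention of published interface tables.
Merging is on by default and can be disabled.

### Footprint classification

Persistence is the percent of frames in which a bond is formed, reported
at integer precision (full precision retained internally). An interaction
absent from a simulation is an empty cell, distinct from 0. Novel
interactions (not in the crystal) split at 50% persistence into
short-lived and long-lived. The source convention writes "<50%" and
">50%", leaving exactly 50 unassigned; this package classifies 50 as
long-lived, which keeps classification monotone in persistence — raising
a persistence can never demote a record. Crystal bonds never seen in
simulation are `crystal_only`.

The packaged fixture `inst/extdata/table1_footprint.csv` transcribes the
published two-complex persistence table verbatim (30 interactions,
"(-)" → empty cells). Its known internal inconsistencies — a `Gln7^O1^`
atom label that is almost certainly `Oε1`, and two conflicts between the
table and its companion figure legend about which residues are
complex-A-only (Arg157 appears only in the complex B column; "Arg162" is
not in the table at all) — are documented in `table1_notes.md` next to
the fixture and deliberately not corrected: the conservation report
computes what the table implies (Arg62 A-only, Arg157 B-only, everything
else conserved) and leaves reconciliation to the reader.

### Rigid-body motion

Superposition is the Kabsch algorithm (SVD with reflection correction, so
the returned rotation always has determinant +1). Rotation angle is
`acos((trace R − 1)/2)` in [0°, 180°]; the axis sign convention makes the
first non-negligible component positive, and the zero-rotation axis is
`(1, 0, 0)` by convention.

Per-frame TCR motion: each frame is first aligned to the reference on the
MHC core Cα (so rigid motion of the whole complex cancels exactly — this
is tested), then the residual rigid transform between frame-TCR and
reference-TCR Cα gives angle and axis, and the TCR centroid displacement
is recorded in the MHC frame. The TCR atom set should be the variable
domains where the binding-orientation signal lives; the package applies
whatever selection it is given and records it.

The cleft axis is the principal axis of the peptide Cα coordinates,
oriented N→C terminus. The "plane of the MHC" is the plane orthogonal to
the third principal axis of the MHC-core Cα — a robust, selection-only
definition. Displacements are (optionally) projected into that plane and
split along/across the cleft; the parallel fraction
`Σ|d_par| / (Σ|d_par| + Σ|d_perp|)` labels the motion parallel (≥ 0.6),
orthogonal (≤ 0.4) or mixed, with an explicit `static` label for
zero-displacement series. For isotropic in-plane displacement the
expected fraction is 1/2 (E|cosθ| = E|sinθ|), which the tests verify by
Monte Carlo.

The docking-angle difference between two complexes superposes complex B
onto A by MHC-core Cα, then measures the residual rotation between the
TCR atom sets. It is symmetric to numerical precision. The published ~12°
figure for the two crystallographic conformations of the ternary complex
originates from a comparison whose exact atom set is not stated;
`scripts/accession_checks.R` reports this package's value with its
convention (all TCR-chain Cα by default) for reconciliation — exact
agreement is not claimed.

## The synthetic world

The generators state the world the tests live in:

* `gen_fluctuating_chain`: one Cα per residue on a zig-zagged extended
  chain (3.8 Å spacing), i.i.d. Gaussian noise per coordinate with
  per-residue σ. Defaults (20 residues, σ = 0.5 Å, 2000 frames for the
  acceptance run) give the closed-form expectation √3·σ ≈ 0.866 Å with
  ≈ 0.9% Monte-Carlo noise, so the 5% acceptance band tests the
  implementation, not the luck of the seed.
* `gen_hbond_system`: one donor residue (backbone N with explicit H) and
  one acceptor residue (backbone O, no hydrogens) per scripted schedule,
  pairs 25 Å apart. "On" frames place the acceptor at 2.9 Å with a
  175° angle (0.6 Å and 25° inside the criteria); "off" frames park it at
  5.0 Å. Non-participating atoms are kept ≥ 6 Å away, so the schedule is
  the *exact* oracle; Gaussian jitter up to σ = 0.1 Å leaves every margin
  intact, which is the documented composition property.
* `gen_rocking_complex`: static MHC and peptide chains, TCR rigidly
  rotated about a pivot (default: the peptide centroid, since the TCR
  pivots atop the bulged peptide) by `amplitude·sin(2πf/period)`. With
  period = frames = 100 the peak excursion equals the amplitude exactly
  at frame 26.

Noise is uncorrelated across residues and frames. That is deliberate: the
analyses under test are frame-wise statistics, and temporal correlation
would change none of their expected values — but it does mean a green
test establishes correctness of the *analysis*, not realism of the
*dynamics*. The generators do not emulate solvent, force-field physics,
anisotropic fluctuation, or the actual flexibility magnitudes of any real
pMHC system; published RMSF magnitudes (≈1–3 Å) and persistence tables
derive from 100 ns explicit-solvent simulations and are not reproducible
at desk scale, which is why the packaged persistence table is a
transcription fixture, not a reproduction target.

## Numerical choices

* Boundary values of the bond criteria are inclusive, implemented with a
  1e-9 tolerance so exact constructions (d = 3.5 Å, θ = 150°) land inside.
* Collinear point sets are rejected by the superposition (the rotation
  about the line is undetermined); planarity is fine.
* Rotation axes near 180° are taken from the +1 eigenvector (the skew
  part vanishes there).
* PDB coordinates round-trip within 5e-4 Å (`%8.3f` columns); tests allow
  1e-3.
* The average-structure iteration count is 2 by design; alignment is
  idempotent and rigid to 1e-9 Å, both property-tested.
* Equivalent-atom merging happens before persistence accounting, so a
  bond flickering between Oδ1 and Oδ2 counts as one continuously formed
  interaction — merging after accounting would undercount.

## Known limitations

* No mmCIF parsing, no structure repair, no protonation-state prediction;
  binary trajectory formats (DCD etc.) are not read — convert to
  multi-MODEL PDB upstream.
* No water-mediated bridges, π-interactions or energy-based bond scoring.
* No PBC handling: a trajectory with molecules split across the box will
  silently produce wrong distances — image it first.
* The distance-only crystal mode over-detects relative to the full
  criterion by construction; it exists to answer "could this pair bond in
  the crystal?", and every output records which mode produced it.
* Atom correspondence in pairwise comparisons is by selection order, not
  sequence alignment.
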