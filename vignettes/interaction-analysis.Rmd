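---
title: "Methods: interaction fingerprints, pose ranking and channel geometry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: interaction fingerprints, pose ranking and channel geometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lgicsa)
```

This vignette documents the models and numerical conventions behind each
analysis stage, the choices made where several defensible definitions
exist, and what the synthetic fixtures do and do not demonstrate about
real data.

## The setting

Setron-class antagonists (granisetron, tropisetron, ...) bind the
serotonin 5-HT3A receptor, a pentameric ligand-gated ion channel, at the
orthosteric site in the extracellular domain, wedged between the principal
(+) and complementary (−) faces of adjacent subunits. Characterizing such a
complex routinely involves four computations on top of the coordinates:
which residues contact the ligand and how persistently (fingerprints +
Markov probabilities over trajectory frames); which of several candidate
ligand poses is thermodynamically preferred (metadynamics post-processing);
whether the channel is conductive (pore-radius profile); and how subunit
packing responds to binding (buried interface areas). This package
implements those four stages over a plain, explicit structure container.

## Structure model and ligand topology

Coordinates are Ångström throughout; atom serials are 1-based as in PDB,
internal row indices are R's 1-based data.frame rows, and all unit or index
conversions happen at I/O boundaries only. Parsing is delegated to bio3d;
CONECT connectivity, which bio3d drops, is recovered by a supplementary
scan. Alternate locations collapse to the highest-occupancy conformer
(ties prefer `'A'`). Van der Waals (Bondi) and covalent radius tables are
bundled and versioned in the package so geometric results are reproducible
bit for bit; unknown elements fall back to a carbon-like 1.70 Å radius with
a warning.

Ligand bonds come from CONECT records when present; otherwise two heavy
atoms are bonded when closer than the sum of their covalent radii plus
0.45 Å, the common perception heuristic. Rings are **chordless** simple
cycles of length 3–8 on the bond graph: a cycle with a chord is the
envelope of two fused smaller rings (naphthalene-style) rather than a ring
itself, while bridged-bicycle envelopes, which are chord-free, are real
rings (the granisetron cage yields 6-, 6- and 8-cycles). A ring is flagged
aromatic when every member is C/N/O/S and the RMS out-of-plane deviation
from the best-fit plane is below 0.1 Å — a purely geometric criterion,
chosen because experimental coordinate files carry no aromaticity records.
On the bundled idealized granisetron coordinates (synthetic, generated from
the molecule's connectivity and energy-minimized; not deposited
coordinates) this flags exactly the fused indazole 5- and 6-rings.

Formal charges come from a bundled per-residue template (for granisetron:
+1 on the tertiary ammonium of the azabicyclic cage, which is protonated at
physiological pH; everything else 0) or a user override. The protonation
template is deliberately minimal — a single cationic center — because
nothing in a heavy-atom model distinguishes subtler states.

## The 9-bit fingerprint

For each protein residue and frame, nine bits in a fixed, documented order:
apolar; aromatic face-to-face; aromatic edge-to-face; H-bond with protein
as donor; H-bond with protein as acceptor; electrostatic with protein
positive; electrostatic with protein negative; one-water bridge; two-water
bridge. The protein side is restricted to side-chain atoms (backbone N,
CA, C, O, OXT excluded; glycine therefore never fires).

Stated cutoffs: 4.5 Å between carbons for apolar contacts ("non-polar
atoms" is implemented as carbon atoms exactly; sulfur excluded by default)
and 4 Å for aromatic and electrostatic interactions. The remaining
geometry is underdetermined by any published cutoff list and is fixed here
as explicit, config-overridable defaults (`fp_config()`):

- **Hydrogen bonds** use a heavy-atom criterion — donor-heavy to
  acceptor-heavy ≤ 3.5 Å, plus antecedent–donor–acceptor angle ≥ 90° when
  the donor's antecedent heavy atom is known (template-derived for protein
  side chains, bond-graph-derived for ligand atoms, absent for waters).
  Hydrogens are not required anywhere: cryo-EM models rarely have them,
  and a criterion that needs them would make the engine inapplicable to
  the very structures it targets. This is an explicit substitute for
  hydrogen-resolved H-bond detection; with hydrogens present a stricter
  D–H···A criterion would disagree in a small fraction of borderline
  geometries.
- **Aromatic windows**: centroid–centroid distance (not closest-atom) is
  compared against the 4 Å cutoff; the inter-normal angle, folded to
  [0°, 90°], classifies face-to-face at ≤ 30° and edge-to-face at ≥ 60°.
  Intermediate tilts set neither bit rather than being forced into a
  class.
- **Water bridges** chain the same H-bond rule: one water H-bonded to both
  a ligand polar atom and a residue side-chain polar atom sets bit 8; a
  ligand–w1–w2–residue chain with distinct waters sets bit 9. The bits are
  independent observations, not exclusive alternatives.
- **Distances compare with ≤ at the cutoff**, so boundary cases are
  reproducible across platforms; synthetic fixtures plant geometries 0.1 Å
  inside cutoffs to keep truth tables unambiguous anyway.

The pre-screen skips residues whose nearest heavy atom is beyond 6.5 Å
from any ligand heavy atom for the direct bits and 9.5 Å for the bridge
bits (H-bond cutoff + maximum two-water span: 3 × 3.5 = 10.5 would be the
worst case through fully-stretched bonds, but the residue-side polar atom
itself sits within the side chain whose nearest atom defines the distance;
9.5 Å is the bound for the nearest-atom metric). Soundness is not argued
from geometry alone: a property test compares pre-screen on/off on planted
and jittered systems and requires identical matrices.

The narrative chemistry of such complexes includes cation–π contacts
(e.g. a tryptophan face against the ligand ammonium, or an arginine
guanidinium against the indazole ring). The 9-bit scheme has no cation–π
bit, and none is added — fidelity to the scheme wins — but
`cation_pi_report()` lists charged-atom-to-ring-centroid distances ≤ 4 Å
for interpretation.

## Two-state Markov probabilities

Each residue/bit series is modelled as a stationary two-state Markov chain.
"Standard Dirichlet priors" is implemented as pseudo-count 1 per transition
cell (the flat prior; configurable). With two states each transition-matrix
row posterior is Beta, so sampling is exact: per draw,
p01 ~ Beta(c01+1, c00+1), p10 ~ Beta(c10+1, c11+1), and the reported
statistic is the stationary probability π₁ = p01/(p01+p10) — not the
empirical frequency, which is also emitted for comparison. The posterior
mean and standard deviation over `n_samples` draws (default 10 000) give
the probability ± error. Draws in which both p01 and p10 are numerically
zero (possible only under degenerate counts) fall back to the empirical
frequency and are counted. Seeds are mandatory arguments — there is no
silent global-RNG dependence — and `summarize_matrix()` derives a distinct
deterministic sub-seed per series so results do not depend on evaluation
order. All-zero series short-circuit to probability 0 ± 0 without
sampling: an interaction never observed in n frames is reported as absent,
not as a posterior centred near 1/n.

Assumptions worth stating: the chain is first-order and stationary over
the analysed window, and frames are treated as the chain's native time
step. Autocorrelation-time estimation and hidden-state models are out of
scope; the error bar quantifies posterior uncertainty under the model, not
model misfit.

## Metadynamics post-processing and pose ranking

With fixed-height Gaussian hills, the negated deposited bias estimates the
free-energy profile: F(s) = −Σᵢ hᵢ exp(−(s−cᵢ)²/(2σᵢ²)), shifted so
min F = 0. Well-tempered rescaling is deliberately not applied — the
deposition protocol this targets uses fixed-height hills (0.21 kJ/mol,
width 0.02 nm = 0.2 Å, every 4 ps, 10 ns per run). Hills files are
whitespace text with a PLUMED `#! FIELDS` comment or a plain header; CV
columns declared in nm are converted to Å at parse time (all RMSD
quantities in this package are Å).

The pose statistic is the Boltzmann-weighted average of the collective
variable, ⟨s⟩ = ∫ds·s·e^(−F/k_BT) / ∫ds·e^(−F/k_BT), with k_B =
0.0083145 kJ/mol/K bundled and T defaulting to 300 K (the simulation
thermostat temperature). Quadrature is trapezoidal on the profile's own
grid; a refined-grid oracle in the tests bounds the discretization error
(101 vs 10⁵ points agree to 10⁻³ on an asymmetric double well). The weight
is computed as e^(−(F−min F)/k_BT), which is mathematically identical (the
average is invariant under F → F + c, tested to 10⁻¹⁰) and immune to
underflow for arbitrarily deep profiles. The integration domain is the
full grid the hills cover (± 3σ), configurable; no truncation window is
applied. Degenerate one-point grids are an error, never a silent answer.

The collective variable itself is an anchored RMSD: ligand heavy atoms
plus the backbone heavy atoms of a short stable receptor stretch far from
the site ("anchor atoms", residues 209–212 of subunit A in the 5-HT3A
case) are jointly superposed onto the reference and the RMSD of that same
combined set is reported. Anchoring means rigid-body drift of the complex
cancels while ligand motion relative to the receptor does not.
Superposition is a Kabsch least-squares fit (SVD with reflection guard)
written in-package; tests cross-check it against bio3d's independent
superposition routines.

Ranking: per pose, each replicate profile yields one ⟨s⟩; the pose mean
and SEM = sd/√n over replicates (≥ 2 required) are reported and ranks
ascend with the mean — lower average anchored RMSD = more favorable pose.
Ties break by smaller SEM, then lexicographic pose id, so output is
deterministic.

## Pore profile and passability

The channel axis is taken as the largest-variance principal axis of the
Cα inertia tensor (for a pentamer, the 5-fold axis), or a user vector.
At each position z (step 0.5 Å) the pore radius is
max over in-plane centres c of minᵢ(‖c − xᵢ‖ − r_vdw,i): the largest
probe sphere centred in the perpendicular plane touching no atom. The
centre search is a coarse 0.5 Å grid over a ±5 Å in-plane box followed by
a 0.1 Å refinement around the coarse optimum (the refinement offsets are
centred on zero so a grid-perfect coarse solution is never degraded).
This is simpler than full HOLE — no Monte Carlo sphere tracing, no curved
pathways — and is validated against dense-grid 2-D searches in the tests
(agreement within 0.05 Å). Negative clearances (blocked pore) report
radius 0 with a `blocked` flag. Constrictions are local minima below a
report threshold, annotated with the nearest residue; a bundled editable
table maps 5-HT3A M2 residue numbers to prime notation (9′ = Leu260,
−1′ = Glu250). `passability()` reports contiguous segments narrower than
an ion radius, defaulting to 2.76 Å, the approximate hydrated Na⁺ radius.

## SASA and buried interfaces

Shrake–Rupley with a deterministic Fibonacci-lattice point set (default
960 points/atom, probe 1.4 Å): no RNG, so areas are bit-reproducible.
Accuracy at the defaults: an isolated sphere matches 4π(r+probe)² to well
under 0.5%, and the two-sphere analytic cap solution to under 1%. Because
the lattice is fixed in space, rotating a molecule shifts occlusion
patterns slightly: invariance under rigid motion holds to the sampling
accuracy (≈ 0.3% on a peptide at 960 points), not exactly.

Buried interface area follows the PISA convention: strip ligands, ions and
waters (hetero records), then buried = (SASA_A + SASA_B − SASA_AB)/2. Only
this geometric identity is reproduced — PISA's interface chemistry scoring
is not — and comparisons against PISA-derived published figures should
carry a ±5% tolerance: different radius tables, point densities and
stripping details each move totals by a percent or two.

## Synthetic fixtures: what they show and what they cannot

Every stage has a seeded generator with planted ground truth, written as
standard PDB/HILLS/TSV so the real parsers are exercised:

- `make_planted_complex()` spaces one ligand "site" per requested
  interaction 15 Å apart along a synthetic multi-site ligand, with one
  residue placed to satisfy exactly its own detector 0.1 Å inside the
  cutoff (aromatic sites share one all-nitrogen planar ring so that ring
  stacking cannot co-fire the apolar bit). The truth table is the identity
  pattern.
- `make_markov_series()` simulates the two-state chain it is later asked
  to recover (truth π₁ = p01/(p01+p10), start from the stationary law).
- `make_hills_set()` draws hill centres around a planted well
  (spread 0.05 Å) with a small per-replicate well jitter (0.01 Å) —
  enough replicate scatter for a meaningful SEM; with both set to zero the
  files are byte-identical and the SEM is exactly 0. Heights/widths/stride
  default to the 0.21 kJ/mol / 0.2 Å / 4 ps deposition protocol.
- `make_pore_shape()` stacks staggered 12-atom carbon rings (0.5 Å
  spacing) realizing a requested radius function; its truth is the exact
  on-axis clearance minₖ √(rₖ² + (z−zₖ)²) − r_vdw, which reduces to
  ring radius − r_vdw wherever the wall is locally cylindrical.
- `make_interface_pair()` offsets two identical Cα-trace helices;
  far-apart chains bury 0, superposed chains bury one chain's full SASA.

These fixtures validate the *computations*: detector geometry, posterior
estimation, quadrature, search and integration. They do not emulate real
data's hard parts — conformational heterogeneity, correlated frame noise,
protonation ambiguity, crystallographic disorder, or ligands whose
chemistry defeats distance-based bond perception. Passing tests therefore
certify the pipeline's arithmetic and definitions, not the biological
interpretability of any particular trajectory.

Problem sizes in the test suite and acceptance script (frame counts of
tens, chains of 10⁴ steps, 20 posterior replicates, 10⁴-point reference
grids, 960-point SASA lattices) were chosen as the smallest sizes at which
each statistical check is decisive — e.g. 3-sigma recovery bands that a
broken estimator would leave with probability ≪ 10⁻³.

## Known limitations

- Heavy-atom H-bond criteria cannot resolve donor orientation for
  hydroxyls and histidines; the templates treat them as both donor and
  acceptor.
- mmCIF is read, not written; binary trajectory formats are out of scope
  (frame series are multi-model PDB or file lists).
- The pore scan assumes a straight axis; strongly curved permeation
  pathways would need HOLE proper.
- The Markov model ignores frame autocorrelation beyond first order;
  probabilities for marginally sampled interactions carry honest but
  model-conditional error bars.
- SASA is O(n · neighbours) pure R; fine for complexes of a few thousand
  atoms, not for exhaustive per-frame SASA over long trajectories.
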