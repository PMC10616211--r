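---
title: "Restraint-driven modelling of a C2-symmetric tethering complex"
author: "tetherdock"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Restraint-driven modelling of a C2-symmetric tethering complex}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tetherdock)
```

## The problem

Mitofusin-2 (MFN2) tethers mitochondria to the endoplasmic/sarcoplasmic
reticulum; the formin DIAPH1 binds MFN2 through its inhibitory domain
(DID), and the DID--DD dimer engages two copies of the MFN2 cytosolic
fragment in an A2B2 assembly with overall two-fold (C2) symmetry. Direct
structural data for the complex are sparse, so the model is built
integratively: chemical cross-linking read out by mass spectrometry gives
residue-pair distance ceilings, NMR competition identifies an interface
region, and rigid-body docking under those restraints produces the
assembly. `tetherdock` re-implements that workflow as reusable,
deterministic components: restraint construction from cross-link
identifications, C2-symmetric restrained docking with violation analysis,
the construct-level sequence calculators used in the wet-lab workflow
(molecular weight, molar extinction at 280 nm, isoelectric point,
cross-linked-peptide masses), and the saturation-binding fit that
quantifies the interaction. A synthetic-data module generates ground-truth
complexes and simulated plates so every stage is testable end to end
without external downloads.

## Distance restraints from cross-linking chemistry

A bifunctional cross-linker covalently bridges two reactive side chains
only when their distance does not exceed the linker's spacer-arm length.
`builtin_linkers()` carries the seven reagents used for this complex: the
amine-to-amine NHS esters DSG (7.7 Å), BS3 (11.4 Å), BS(PEG)5 (21.7 Å) and
BS(PEG)9 (35.8 Å), and the amine-to-sulfhydryl reagents KMUS (16.3 Å),
SMCC (8.3 Å) and SMPB (11.6 Å). Bridge masses are derived from the
coupling chemistry (NHS-ester aminolysis releases one N-hydroxysuccinimide
per coupling, so a homobifunctional bridge is the parent diacid minus two
waters; maleimide--thiol addition conserves atoms), e.g. the DSG bridge is
C5H4O2, 96.02113 Da monoisotopic.

An identified cross-link becomes an *unambiguous interaction restraint*
(UIR): an upper bound of one spacer length between the reactive atoms
(Lys NZ, Cys SG, or the N-terminal nitrogen) of the two residues. The
lower bound is zero -- the chemistry implies no meaningful minimum.
Because the assembly holds two copies of each protein, each cross-link
spawns one restraint per chain pairing, tied into a *symmetry group*; a
group is satisfied if any pairing satisfies it (the identification cannot
tell the copies apart), while the default violation report lists every
copy separately, matching the convention under which 18 applied restraints
derive from 5 unique links.

*Ambiguous interaction restraints* (AIRs) encode "this residue is at the
interface" without naming a partner: each active residue on one side is
restrained to the pooled atoms of all active residues on the other side
through the effective distance `(sum d_ij^-6)^(-1/6)`, which is always at
or below the minimum pair distance and saturates once any pair is in
contact. The all-atom convention bounds this at 2.0 Å; for Cα-bead models
the minimum achievable pair distance is a bead contact (~3.8--4.5 Å), so
bead-resolution work should use an upper bound near 4.0 Å (the tests and
the worked examples do).

A docked model *follows* a restraint when its violation —
`max(0, d - upper, lower - d)` — is at or below the bound correction,
5 Å by default, inclusively: a violation of exactly 5.0 Å counts as
followed, 5.1 Å does not. When a named reactive atom is absent (bead
models carry only Cα), evaluation falls back to Cα with a configurable
+1 Å slack per side.

## The docking engine

`dock()` places one ligand copy relative to a receptor dimer whose
two-fold axis has been aligned with z (`prepare_receptor()` computes the
inter-chain transform, verifies its rotation is within 5° of 180°, and
re-frames the dimer). The second ligand copy is generated, not searched:
every pose is the exact C2 image of its partner, so symmetry closure is
exact by construction.

The score is a weighted sum of four terms:

* `E_restraint` — flat-bottom quadratic: the squared violation of each
  restraint group (k = 1 per Å², group evaluated by its best symmetry
  copy). Weight 10 by default so that restraints dominate packing
  differences: a 1 Å violation outweighs the burial gained by ~50
  additional contact pairs.
* `E_clash` — soft-sphere overlap `sum(max(0, c - d)^2)` over inter-body
  atom pairs with contact distance c = 4.0 Å and weight 5; together with
  the attraction this puts the packing equilibrium of Cα-bead bodies near
  3.8 Å, above the 3.5 Å clash-free floor the synthetic complexes
  guarantee.
* `E_contact` — a shallow Gaussian attraction well (depth 1 per pair,
  centred at 4.5 Å, width 1.5 Å, weight 0.2), the coarse analogue of the
  attractive van der Waals and desolvation terms of docking force fields.
  Without it every clash-free restraint-satisfying pose ties at zero and
  the ranking cannot reward interface burial.
* `E_elec` — optional screened-Coulomb (Debye–Hückel) energy over formal
  residue charges (Asp/Glu −1, Lys/Arg +1, His +0.1) with the inverse
  Debye length taken from a 0.3 M ionic strength and a solvent dielectric
  of 80. Off by default (weight 0); it exists to probe the
  electrostatic-complementarity argument for the pH dependence of the
  interaction, not to replace Poisson–Boltzmann electrostatics, which are
  out of scope.

The search is multi-start and fully seeded: uniform random orientations
(Shoemake quaternions) with translations in a shell around the receptor;
a cheap restraint-only translation prefit per start (the restraint field
is long-ranged and convex-ish, so this reliably finds the right site);
full Nelder–Mead refinement of the best 16 starts over the 6 rigid degrees
of freedom with a simplex restart; and an orientational polish of the best
three solutions (random orientation restarts at the found translation,
kept only on improvement) — rigid-body searches find the right site long
before the right orientation, and the polish closes that gap. Solutions
are clustered by single-linkage on ligand RMSD (modulo the C2 relabelling
of the two copies) at a 7.5 Å cutoff, each cluster represented by its
lowest-scoring member, ties broken by restraint energy and then a pose
hash. Reruns with the same seed and configuration are bit-identical.

## What the synthetic complexes emulate

`make_toy_tetramer()` builds Cα-bead bodies on smoothed self-avoiding
random walks (3.8 Å bonds): a receptor chain offset from the z axis with
its exact C2 image, and a ligand placed against one receptor monomer. Two
choices matter and are deliberate:

* *Topology.* Each ligand copy engages its own receptor monomer — copy 1
  touches chain A only and stays at least 8 Å from both chain B and its
  own image — reproducing the A2B2 arrangement in which the two B
  subunits sit on opposite faces of the A2 dimer (the arrangement whose
  span across the two MFN2 copies is the ~100 Å tether).
* *Energetic self-consistency.* The planted pose is not an arbitrary
  clash-free contact: candidate placements are relaxed under the same
  packing energy the docking engine scores (with a hard floor keeping the
  assembly clash-free at 3.5 Å), through a multi-start optimisation with
  a budget matching the docking search, and the global optimum becomes
  the ground truth. A native state should be the optimum of its own force
  field; without this property "recovery" would be ill-posed, since the
  search could legitimately find poses that score better than the planted
  one.

Planted cross-links are sampled from bead pairs within the spacer in the
ground truth, spread over the interface by greedy max–min selection on
link midpoints (real studies identify links at distinct sites, and
repeated hits on one residue pair carry no extra information). Decoys,
when requested, come from pairs farther than spacer + 5 Å and are
labelled. All beads are treated as lysines, so restraint evaluation uses
the Cα fallback.

What the toys do *not* emulate: real folds, side-chain packing, shape
complementarity, flexibility, or identification noise in realistic
proportions. Passing recovery tests therefore demonstrates that the
restraint logic, symmetry handling, scoring and search are correct and
self-consistent at bead resolution — not that the engine matches
atomic-resolution docking suites on real structures.

## The saturation-binding model

Plate assays are fitted with the one-site total-plus-nonspecific model

$$Y = \frac{B_{max} X}{K_d + X} + NS \cdot X + B_0,$$

with background `B0` included because blank subtraction is imperfect in
practice (it can be fixed at zero). The fit is Levenberg–Marquardt least
squares with `Kd` log-parameterised for positivity and `Bmax`, `NS`
bounded below at zero; standard errors come from the Jacobian at the
optimum, with the `Kd` error delta-method propagated from log `Kd`.
Initialisation is heuristic (Kd at the half-range signal, nonspecific
slope from the top two concentrations). Flat curves are flagged
unidentifiable rather than reported as spurious affinities. Weighting is
unweighted by default, matching common plate-fitting practice, with an
optional 1/Y² mode. A competition condition is fitted with the same model
as an apparent Kd; `cheng_prusoff_ki()` is available but not used for any
reported comparison.

The simulation defaults mirror the assay this package models: 12
log-spaced concentrations spanning the printed affinity regimes
(0.001–100 nM around the neutral-pH condition), unit `Bmax`, `NS` = 0.01
per nM, `B0` = 0.05, Gaussian noise with a standard deviation of 2% of
`Bmax`, and explicit seeds everywhere. Parameter-recovery experiments
refit 200 simulated plates per condition and compare the median fitted
`Kd` against the generating value — the published raw data are not
deposited, so recovery on simulation keyed to the printed constants is
the strongest reproduction available at a desk.

## Numerical choices and degenerate inputs

* Superposition uses the SVD (Kabsch) solution with a determinant sign
  correction, so the rotation is proper even when the unconstrained
  optimum is a reflection; collinear point sets are rejected.
* Distance boundaries are inclusive throughout (`<=` at the interface
  cutoff, at restraint bounds, and at the violation correction).
* Isoelectric points bisect the fixed-pKa (Bjellqvist/ExPASy) charge
  model on [0, 14] to 0.01 pH; the termini guarantee a sign change.
* The pI defaults are computed on untagged domain sequences (the
  electrostatic argument concerns the domains), while molecular weight is
  computed on the full tagged construct — the published 29,078 Da value
  is consistent only with the tag included. The published extinction
  coefficient 10,220 M⁻¹cm⁻¹ equals 5500 + 3×1490 + 2×125 and therefore
  uses the cystine convention; both conventions are reported.
* A cross-linked lysine blocks tryptic cleavage, so cross-linked-peptide
  searches digest with up to two missed cleavages; carbamidomethylation
  (+57.02146 Da) applies to every cysteine except a cross-linked one.
* PDB files larger than the fixed-width serial field (99,999 atoms) are
  refused rather than silently wrapped. Altlocs keep the
  highest-occupancy conformer, first on tie; insertion codes are appended
  to the residue number as a token; file numbering is never rewritten.
* Problem sizes in the shipped tests: 24-bead receptor chains, 16-bead
  ligands, 64 docking starts, 20 recovery seeds, 200 binding replicates
  per condition. These sizes make the full suite reproducible on a single
  CPU in minutes while leaving every algorithmic path exercised.

## Known limitations

* The UniProt-derived DID/MFN2 sequences are not redistributed with the
  package; the construct-constant comparisons require the user to supply
  them once (`?load_reference_constructs`). All other checks are
  self-contained.
* The docking engine is a methodological re-implementation at desk scale,
  not a parameter clone of a production docking suite: no flexible
  refinement, no desolvation term, no explicit-solvent stage, and the
  published docking protocol's exact parameter tables are not public.
* The decomposition of the published count of 18 applied restraints into
  symmetry/ambiguity copies of the 5 printed links is not recoverable
  from the main text; the package exposes both per-copy and group-min
  accounting so either convention can be reproduced.
* Interface residues are called atom-to-atom at 5 Å, not against a
  molecular surface; with all-atom inputs the two conventions can differ
  at the margin.

## A worked example

```{r example, eval = FALSE}
toy <- make_toy_tetramer(toy_complex_spec(seed = 7))
links <- plant_crosslinks(toy, planted_crosslink_spec(n_true = 4, seed = 7))
uirs <- uirs_from_crosslinks(links, list(REC = c("A", "B"),
                                         LIG = c("C", "D")))
res <- dock(toy$receptor, toy$ligand, uirs,
            docking_config(n_starts = 64, seed = 1))
best <- res$ranking[1]
interface_rmsd(toy$receptor, toy$ligand, res$poses[[best]], toy$pose)
res$violations
```

The same functions drive real inputs: read structures with
`read_structure()`, cross-links with `read_crosslinks()`, prepare the
dimer with `prepare_receptor()`, and validate any model against any
restraint set with `evaluate_restraints()`.
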