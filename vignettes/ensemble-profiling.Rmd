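---
title: "Ensemble-aware interaction and burial profiling: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ensemble-aware interaction and burial profiling: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smnprofiler)
library(dplyr)
```

`smnprofiler` asks, for every residue of an SMN-related structure, whether
its side chain is doing structural work: joining a salt bridge, joining a
hydrogen bond, or packing into a buried position. Because most SMN
structures are solution-NMR ensembles — one PDB entry, `NumMDL` alternative
models — every question is answered per model and then summarized across
the ensemble. This vignette explains the models and rules implemented, the
parameters that matter, the numerical choices, and what the synthetic
fixtures do and do not demonstrate.

## The detection criteria and their parameters

**Salt bridges.** Only the titratable residues carry charged side-chain
groups here: Asp (OD1/OD2) and Glu (OE1/OE2) negative; Lys (NZ), Arg
(NE/NH1/NH2) and His (ND1/NE2) positive. A bridge is an opposite-polarity
pair within `sb_cutoff` = 4.0 Å (inclusive). Two measurement modes exist
because ensemble reports in this field use both conventions:

* `group_center` — distance between the unweighted geometric centers of
  the two groups; one potential bridge per residue pair per model. This is
  the convention behind "bridge in *k* of *N* models at 3.50 ± 0.23 Å"
  style statements.
* `atom_pair` (default) — distance per (positive N, negative O) atom pair;
  one potential bridge per atom pair, which is how per-model interface
  tables list, say, four distinct His–Asp bridges between two residue
  pairs.

Design choices a user should know: the Arg group is the three guanidinium
nitrogens (keeping all members nitrogen nuclei; a CZ-centroid variant was
rejected), and His is treated as charged at both ring nitrogens regardless
of protonation — no pKa prediction is attempted, matching how His–Asp
bridges are reported in the SMN interface analyses this package
reimplements. Groups with some member atoms missing use the mean of the
atoms present; groups with none are skipped with a warning.

**Hydrogen bonds.** For a donor heavy atom D, its covalently bound
hydrogen H, and an acceptor A in another residue, a bond requires
*d*(D,A) ≤ `hb_da_cutoff` = 3.0 Å and ∠ADH ≤ `hb_angle_cutoff` = 30°, both
inclusive. The angle is evaluated at the donor, between the D→A and D→H
rays, so a perfectly linear D–H···A arrangement scores 0° and the cutoff
admits moderate bending. The H–A distance is reported for completeness but
is not a criterion. D–H covalency is resolved geometrically (same residue,
D–H < 1.3 Å) rather than through a connectivity dictionary; this tolerates
nomenclature variants (`HZ1` vs `1HZ`) in deposited files. Donors without
resolvable hydrogens — every donor in an X-ray structure deposited without
hydrogens — are skipped with a warning rather than guessed: hydrogen
placement is out of scope.

Acceptors default to side-chain O/N/S acceptors *plus* backbone carbonyl
oxygens (`hb_acceptor_scope = "sidechain_plus_backbone_O"`). This was a
genuinely open point: the stated protocol of the source analysis is
"side-chain nuclei only", yet its own interface tables include bonds to a
backbone O. The default follows the tables (the practice); the strict
`"sidechain_only"` switch reproduces the stated protocol literally.

**SASA and burial.** Per-atom accessible areas use the Shrake–Rupley
construction: `n_sphere_points` = 960 test points on each atom's expanded
sphere (van der Waals radius + 1.4 Å probe), the accessible fraction scaled
to the sphere area. Points are generated by a golden-section spiral, so the
calculation is deterministic — no seed, bitwise-reproducible reports. The
radii are a Chothia-style element set (C 1.87, N 1.65, O 1.40, S 1.85 Å),
chosen because the intrinsic reference areas are the NACCESS standard
values and NACCESS uses that family of radii. Hydrogens are excluded from
surface and occlusion by default so NMR models (with H) and X-ray models
(without) give comparable areas. Residue SASA is the sum over member
atoms; relative SASA divides the ensemble mean by the residue type's
standard area; burial is `ratio < 0.30`, strict, so a residue exactly at
30% counts as exposed. DSSP, the calculator used in the original SMN
analysis, is not reimplemented: Shrake–Rupley is the field-standard
algorithm for this quantity, and the burial threshold tolerates the
small systematic differences between surface algorithms.

**Ensemble statistics.** Two kinds of summary deliberately coexist.
Detection censuses (`summarize_interactions()`) pool *detected instances*:
the count of models where the pair qualifies, and mean ± sd of the
detected distances only. Geometry profiles (`summarize_hbond_pair()`,
`atom_pair_distance_series()`) measure a fixed atom pair or triple in
*every* model, detected or not. The distinction matters scientifically: a
bridge can be detected in 3 of 32 models at ~3.5 Å while the same atom
pair averages ~8 Å over the whole ensemble — the disagreement between the
two numbers is precisely the evidence that the contact is not consistently
restrained, which is what the chemical-shift audit then probes. Standard
deviations default to the population convention (divisor *n*); the
original reports do not state their convention, so it is configurable
(`sd = "sample"`), and acceptance tolerances on spreads are set wider than
the difference between the two.

## The importance rule and mutation annotation

A residue is *potentially important* if (side chain in ≥ 1 detected salt
bridge in ≥ 1 model) ∨ (side chain in ≥ 1 detected hydrogen bond) ∨
(ensemble-mean relative SASA < 0.30). "Side chain" is enforced literally:
a backbone-carbonyl acceptor does not flag the acceptor residue's side
chain, and the burial flag uses the ensemble mean, not per-model values.
Important residues are matched by sequence position against the mutation
catalogue, restricted to the chain(s) declared to carry SMN numbering —
chain roles are data, never hard-coded, since e.g. in 2leh SMN is chain B.

The impact annotation is qualitative sign logic driven by a fixed
residue-chemistry table: Asp→Val removes a negative charge
(`charge_removal`, existing attractions lost); Glu→Lys reverses negative
to positive and Gln→Glu turns an amide donor into a negative acceptor
(both `attraction_to_repulsion`); Ala→Gly removes a hydrophobic side chain
(`hydrophobic_removal`); a premature stop is `truncation`. Substitutions
outside the table's patterns (e.g. Ile→Phe, hydrophobic for hydrophobic)
are honestly `other`. No energies, ΔΔG or conservation scores are
estimated — the annotation states only the direction of the electrostatic
change implied by the wild-type residue's observed interaction roles.

## The chemical-shift audit

`find_missing_assignments()` compares an assignment table (NMR-STAR v3
assigned-chemical-shift loop, or a simple TSV) against an expected-nuclei
table listing, per residue type, the side-chain heavy atoms and hydrogens
in PDB v3 nomenclature. The packaged expectation is deliberately a
superset of what solution NMR typically assigns (carboxylate oxygens are
listed, for instance): the audit's purpose is to enumerate *unrestrained*
nuclei, and users restrict the table when a narrower definition is wanted.
Depositions sometimes number residues differently from the PDB entry; an
explicit per-call `offset` reconciles the two, and mismatching residue
types raise warnings instead of silent misalignment.

## Synthetic fixtures: what they emulate, and what they do not

The generators produce PDB text with engineered ground truth: charged
pairs at an exact group-center distance; donor/hydrogen/acceptor triples
at an exact (d, ∠ADH); a residue inside an occluding carbon shell whose
density controls burial; multi-model ensembles built by seeded isotropic
Gaussian jitter (`jitter_sd`, in Å) of a base model; assignment tables
minus an explicit drop set. Defaults mirror the scale of the real study
conditions: 20–32 model ensembles, cutoff-straddling geometry at 4.0 Å,
0.5 Å jitter (the order of side-chain coordinate spread in NMR ensembles),
and a 30% burial threshold.

One numerical subtlety: PDB text carries three decimals, so a geometry
requested exactly at an inclusive cutoff could round a hair past it. The
hydrogen-bond generator therefore compensates: it shrinks the construction
values until the geometry *recomputed from the rounded coordinates* is at
or below the request. Distances are reproduced to ~1e-3 Å; angles to
~0.03° (the precision limit of 3-decimal coordinates on a 1 Å lever arm) —
and never above the requested value, which is what boundary tests need.

What passing fixture tests does *not* show: fixtures are not physically
realistic proteins (no rotamer libraries, minimal backbones, isolated
residues), so they validate the geometry, counting and aggregation
machinery, not force-field-level plausibility. Agreement with published
per-residue SASA ratios or interaction censuses can only be checked
against the real deposited ensembles, which must be supplied by the user
(see the README); the package's SASA implementation is instead validated
against the analytic sphere, against quadrature refinement, and against an
independent Shrake–Rupley implementation on identical radii.

## Degenerate inputs and tie-breaks

Alternate locations collapse to the highest-occupancy conformer, ties
broken by file order. `HETATM` records, waters and non-standard residue
types are excluded by default (flags exist), since the analysis concerns
protein residues. A file without `MODEL` records is a one-model ensemble.
Models that disagree in atom topology trigger a warning at read time.
Interactions never pair a residue with itself. Empty results (no charged
groups, no donors, no detections) are empty tibbles, not errors.

## Problem sizes

The shipped tests and the acceptance script run on fixtures of two to a
few hundred atoms and ensembles of up to 32 models, sizes chosen so the
whole suite completes in well under a minute while still exercising every
code path; a full 2leh-scale profile (≈ 300 residues × 32 models, SASA at
960 points) completes in a few minutes on one core.
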