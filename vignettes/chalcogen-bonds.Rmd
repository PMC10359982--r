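---
title: "Detecting chalcogen bonds at disulphide bridges and scoring predicted models"
author: "chalcogenr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting chalcogen bonds at disulphide bridges and scoring predicted models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chalcogenr)
library(purrr)
```

## The interaction and its descriptors

A chalcogen bond (ChB) is a directional attraction between a nucleophile
and a group-16 atom heavier than oxygen. In folded proteins the donor of
interest is the sulfur of a disulphide bridge. Each bridge sulfur is
divalent — bonded to its own CB and to the partner SG — and along the
prolongation of either covalent bond lies an electron-poor region that an
oxygen or sulfur nucleophile can approach. Two internal coordinates fully
describe a candidate contact:

* `d`, the nucleophile–sulfur distance, and
* `α = 180° − θ`, where `θ` is the nucleophile–sulfur–partner angle; `α`
  is the angular deviation of the nucleophile from the prolongation, so
  small `α` means good alignment.

Both are invariant under rigid-body motion, which is why the whole
comparison machinery in this package works on internal coordinates and
never needs structural superposition.

A contact qualifies as a ChB when, inclusively,

* `d ≤ S + t`, with `S` the sum of the van der Waals radii of the two
  atoms and `t` a tolerance, and
* `α_min ≤ α_max`, where `α_min` is the smaller of the two per-partner
  angles.

## Tunable parameters

`chb_params()` collects every threshold. The defaults are chosen for
protein crystal structures rather than small-molecule ones:

| parameter | default | unit | why |
|---|---|---|---|
| `vdw_radii` | O 1.52, S 1.80 | Å | Bondi radii of the default acceptor elements |
| `distance_tolerance` | 0.1 | Å | allowance for macromolecular coordinate accuracy |
| `alpha_max` | 25 | deg | relaxed from the ~20° used in chemical crystallography, same reason |
| `ssbond_distance_max` | 2.5 | Å | generous vs the canonical 2.05 Å SG–SG bond so distorted model bridges still register; beyond it a bridge is *broken* |
| `acceptor_elements` | O, S | — | the nucleophiles the survey criteria address; the radii table is extensible |
| `exclude_same_residue` | TRUE | — | the donor cysteine's own backbone oxygen sits at a covalently constrained distance |
| `include_waters` | FALSE | — | solvent contacts are not the object of study |

With the defaults the O…S detection threshold is
`1.52 + 1.80 + 0.1 = 3.42` Å, and both thresholds are *inclusive*: "not
larger than" is read literally, and the boundary behaviour is pinned by
tests at ±1e-6 of each threshold.

```{r}
vdw_contact_threshold("O", "S")
```

## Detection procedure and its numerical choices

`find_disulphides()` unions SSBOND-declared pairs with geometrically
detected CYS SG pairs within the cutoff — the geometric route is essential
for predicted models, whose files carry no SSBOND records. Candidate pairs
are accepted in order of increasing SG–SG distance and each sulfur joins
at most one bridge, so a stray third cysteine cannot double-book a sulfur;
ties are broken by that explicit ordering, making output deterministic.

`detect_chbs()` then treats *both* sulfurs of every bridge as donors. A
nucleophile contacting both sulfurs of one bridge therefore counts twice —
the two contacts have genuinely different geometry. Acceptors exclude the
donor's two covalent partners always, and the donor residue's own atoms by
default. Candidate search uses a cubic cell grid at the search radius
(3.70 Å with default radii); the grid is purely an accelerator and the
test suite asserts set-wise equality with an exhaustive all-pairs scan on
random structures. Degenerate collinear placements on the partner side
give `α = 180°` and simply never pass; exactly coincident atoms raise an
error rather than producing NaNs.

## Curation and pairing

`apply_curation()` encodes the experimental-set filters: X-ray method,
resolution ≤ 1.5 Å, collection temperature in 90–110 K, single-model
refinement, and at most 5% of atoms that are neither protein nor water.
Every rule is evaluated independently so a verdict lists all failures, and
missing metadata fails the rule that needs it — conservative by design.
Bounds are inclusive at both ends. Sequence-redundancy reduction is an
*interface*: when an external clusterer (CD-HIT-style) is configured it is
invoked on a FASTA file; otherwise a documented greedy stub aligns
sequences globally (match +1, mismatch 0, gap −1; identity = matches /
alignment length, via Biostrings) and keeps, in decreasing length order,
sequences at ≤ 40% identity to everything already kept. The stub is
deterministic and idempotent but is *not* a CD-HIT reimplementation, and
says so in its log line.

Pairing keys on the sequence-database accession in DBREF records:
predicted models are single-chain and numbered 1..L in database
coordinates, so `model_resno = exp_resno − seq_begin + db_seq_begin`.
Mapped residues must agree on residue name; insertion-coded residues are
excluded because database offsets are undefined across them.

## Comparison statistics

For each experimental ChB, `match_chbs()` finds the donor SG and acceptor
atom in the model and recomputes (d, α) there with the model's own
covalent partners. The deltas are signed model-minus-experimental, and are
reported for every bond whose model geometry exists — recovered or not —
because near-misses (distances slightly beyond threshold) carry exactly
the signal of interest. Absences are categorized: `residue-unmapped`,
`atom-missing`, or `disulphide-broken` (the donor cysteine is in no bridge
of the model). The recovery fraction counts all experimental bonds in the
denominator, with the absence breakdown reported so alternative
conventions can be recomputed.

The control statistic enumerates main-chain O…N contacts shorter than
3.5 Å involving the ChB residues (donor and acceptor residues; the two
bridge cysteines can be substituted via the `chb_residues` argument),
excluding same-residue and sequence-adjacent pairs whose O…N separation is
covalently constrained and would deflate the control. Mean pLDDT of the
donor and acceptor residues is banded: `< 50` low, `> 90` high, medium
otherwise — exactly 50 and exactly 90 fall in medium by this package's
convention.

All "±" values are standard errors of the mean (n−1 variance, a single
observation giving 0 by logged convention); whether a published "±" is SEM
or SD is often ambiguous, so the output labels it explicitly. Pooling
across entries concatenates per-bond and per-contact values rather than
averaging per-entry means, keeping counts additive; per-entry rows are
retained so the other convention stays recoverable.

## The synthetic generator: what it emulates and what it does not

`build_toy_chb()` inverts the (d, α) measurement: a fixed two-cysteine
scaffold (SG–SG 2.05 Å, CB–SG 1.81 Å, 104° bond angles, 90° disulphide
dihedral) plus an acceptor fragment whose nucleophile is placed at exactly
the prescribed distance and angle off the CB–SG prolongation. Acceptor
contexts: a glycine carbonyl oxygen (default), a serine OG, or a free
cysteine SG. A fourth, distant glycine supplies one genuine non-adjacent
main-chain O…N contact at 3.0 Å so the control statistic is exercised on
fixtures. Specs that would bring non-bonded atoms within 1.5 Å are
rejected as infeasible. Fixtures carry experimental-grade metadata
(X-ray, 1.2 Å, 100 K, SSBOND, a synthetic accession — `SYNTH…`, clearly
labelled) so curation and pairing run unmodified.

`perturb_structure()` adds i.i.d. zero-mean Gaussian noise per coordinate
— the simplest model consistent with a single scalar positional standard
error — flags the result as predicted with a constant pLDDT (default 95)
and drops SSBOND records, as real predicted-model files lack them. Under
this model the distance between two atoms acquires an error of
`σ√2` (≈ 0.065 Å at σ = 0.046 Å), and |Δd| has mean `σ√2·√(2/π)`; the test
suite verifies both by Monte Carlo.

`generate_paired_dataset()` samples d uniformly on 2.90–3.35 Å and α on
0–20° by default — comfortably inside the criteria, so an unperturbed
dataset is recovered in full and recovery degrades monotonically with
noise. The nucleophile's dihedral about the prolongation axis is fixed at
0 in datasets (it is a free parameter of single fixtures) to keep the
acceptor fragment well clear of the partner sulfur across the whole
sampling range. Its truth table recomputes the perturbed geometry with
arithmetic deliberately independent of the detection module, and the
pipeline's recovery must (and does, in tests) match it exactly.

What the generator does **not** emulate: AlphaFold's actual error
structure — pLDDT-correlated, domain-rigid displacements, broken loops —
nor crystallographic artifacts (alternate conformations, lattice
contacts). Passing tests therefore demonstrate the correctness of the
measurement and comparison machinery, not any claim about real model
accuracy; real surveys need real mirrors of the PDB and of a model
database, to which the same verbs apply unchanged.

## Problem sizes

The shipped test suite and acceptance script use fixtures of ~20–500
atoms, 1,000 random specs for the generator/detector inversion, 10,000
atom pairs for the error-propagation Monte Carlo, and noise sweeps of 200
structure pairs per σ ∈ {0, 0.1, 0.3, 0.6} Å — sizes at which every
statistic above stabilizes well inside its Monte-Carlo error while the
whole suite runs in minutes on a single core.

## Known limitations

* Selenium/tellurium donors and aromatic-ring nucleophiles are out of
  scope (the radii table and acceptor set are extensible, but ring
  centroids are not implemented).
* mmCIF input is coordinates-only; curation metadata currently comes from
  PDB headers.
* Alternate locations other than blank/"A" are discarded, with a log
  line; how the original survey treated cysteine alternates is unstated,
  so single-conformer geometry is enforced for unambiguous (d, α).
* Inter-chain experimental ChBs are matched only when both chains map to
  the same accession, since predicted models are treated as single-chain.
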