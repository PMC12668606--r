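---
title: "Methods: backbone filtering, confidence scoring and campaign orchestration"
author: "binderscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: backbone filtering, confidence scoring and campaign orchestration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(binderscreen)
```

## The problem this package addresses

De novo binder design campaigns chain together a backbone generator
(an RFdiffusion-class model), a sequence designer (a ProteinMPNN-class
model) and a structure-prediction scorer (an AlphaFold2-class model run on
the binder-target complex). The generative stages run on GPUs and are slow
and expensive; everything *around* them — deciding which backbones are
worth carrying forward, turning the predictor's confidence output into hit
decisions, keeping live books on a campaign, and stopping it as soon as
enough hits exist — is ordinary computation that deserves to be testable
without a GPU. `binderscreen` implements exactly that compute side, with
the generative stages abstracted behind a three-function stage contract and
replaced, for testing, by deterministic synthetic mocks.

## Structure model and conventions

Complexes are held as a flat heavy-atom table (one row per atom, in file
order) plus the campaign's chain roles: the designed binder is chain A and
the target chain(s) follow, a convention inherited from the design tools
this package sits downstream of. Two numbering systems coexist and are
never converted implicitly:

* **author numbering** — the PDB residue numbers, used for grafting and
  renumbering. A trimmed target is conventionally renumbered to start at a
  high offset (e.g. 1018) so its indices cannot collide with the binder's
  in downstream predictors; `renumber_chain()` implements this and strips
  insertion codes (with a warning), since consecutive renumbering subsumes
  them.
* **global positional indices** — 0 offsets into the PAE matrix, always in
  binder-first chain-concatenation order, produced by
  `model_chain_spans()`.

HETATM records, waters and hydrogens are dropped on input by default:
design-pipeline structures are protein-only and heavy-atom. Alternate
locations resolve to the highest-occupancy conformer (ties to the first
record). Parsing is delegated to `bio3d`; writing is done directly so the
package controls TER/END placement and the exact round-trip of its own
model.

## Geometry

**Superposition** is the closed-form Kabsch solution via SVD of the 3x3
covariance matrix, with the reflection corrected through the sign of the
smallest singular value; collinear point sets are rejected. The test suite
checks it against an independent quaternion-eigenvalue (Horn) oracle.

**Neighbor search** (`pairs_within()`) uses a cell list with cell size
equal to the cutoff and is contract-identical to exhaustive search, with an
*inclusive* (≤) boundary. All distance rules in the package follow the
convention: the interface rule is inclusive at 10 Å, while the steric
clash rule is strict (< 0.5 Å), read directly from the phrasing "within
0.5 Å". Only heavy atoms participate in the clash rule — generated
backbones carry no hydrogens, so a hydrogen-aware rule could not be
applied uniformly anyway.

**SASA** is Shrake–Rupley with sphere points on a deterministic Fibonacci
lattice (default 960 points/atom), which makes results bit-reproducible
across platforms; a united-atom radius table (C 1.70, N 1.55, O 1.52,
S 1.80 Å) ships as plain text and can be overridden per call. Buried
surface `dsasa()` is SASA(binder) + SASA(target) − SASA(complex), which is
symmetric in the chain labels and ≈ 0 for non-interacting chains. The
tests compare totals against a Monte-Carlo estimator with random sphere
points and against the analytic area of an isolated sphere.

## Secondary structure and the topology filter

Backbones that fold as one long helix or an isolated β-hairpin express
poorly, so they are rejected before any sequence design. Secondary
structure is assigned with a reduced three-state Kabsch–Sander scheme:
amide H is placed geometrically (1.01 Å from N, anti to the preceding
carbonyl; the first residue of a chain cannot donate), the H-bond energy is

E = 0.084 · (1/d(ON) + 1/d(CH) − 1/d(OH) − 1/d(CN)) · 332 kcal/mol

with a bond below −0.5 kcal/mol. CO(i)→NH(i+4) bonds mark helix over
i+1..i+4; parallel/antiparallel bridge patterns mark strand; helix wins
conflicts. Runs below 4 (H) or 2 (E) residues are relabelled coil. The
full 8-state DSSP alphabet (G/I/T/S/B) is deliberately out of scope; 3-10
and π segments fold into H or C, which is sufficient for the two rejection
rules.

The rejection rules are: *single_helix* — exactly one segment, helical, at
least `long_helix_min` residues; *hairpin* — exactly two strand segments
and no helix at all, so mixed α/β designs are retained. `long_helix_min`
defaults to 40 residues: "long" has no published numeric definition, and
40 was chosen once as roughly two thirds of the shortest binder length a
standard campaign designs (65 residues); it is exposed in the campaign
config and was not revisited afterwards.

Filters run clash-first (cheapest), then topology, so rejected designs
never consume sequence-design or scoring effort.

## Template grafting

Backbone generation works against a cropped target for speed; scoring
wants the full-length target for context. `graft_template()` superposes
the full template onto the design's cropped target using the CA atoms of
their shared residue numbers (Kabsch), then swaps it in. Binder
coordinates are bit-identical before and after — this is asserted in the
tests. A shared-CA rmsd above 2 Å flags the graft as suspect rather than
failing it, since a user may intentionally grapple a homologous template.

## Confidence metrics

Given per-residue pLDDT and a square PAE matrix (row = aligned residue,
column = scored residue):

* `plddt_binder` — arithmetic mean pLDDT over the binder span.
* `pae_interaction` — symmetric two-block mean,
  (mean PAE[binder rows, target cols] + mean PAE[target rows, binder cols]) / 2,
  the convention of the widely used scoring scripts this metric originates
  from.
* `cutre` — the interface-restricted, pLDDT-weighted PAE:

  CUTRE = 1/(2·N_T·N_B) · ( Σ_{i∈T} Σ_{j∈B} PAE_ij·pLDDT_i/100 +
  Σ_{j∈B} Σ_{i∈T} PAE_ji·pLDDT_j/100 )

  where T and B are the target and binder interface residue sets (any atom
  within 10 Å of the opposite chain, inclusive). Lower is better. Two
  points in this formula were genuinely open and are resolved as follows.
  First, the weighting could be read as multiplying or dividing by
  pLDDT/100; multiplication is implemented, because the metric's stated
  purpose is to *discount* the PAE contribution of flexible or badly
  predicted (low-pLDDT) regions, which only multiplication achieves.
  Second, normalization uses the residue counts N_T·N_B exactly as
  printed, not the sum of the weights — so a uniformly low-pLDDT interface
  deflates CUTRE; users comparing across very different pLDDT regimes
  should be aware of this property of the printed formula. Both indices
  range over interface residues only.

An empty interface is an error, never a score: hit calling treats it as a
rejection.

## Hit calling and bookkeeping

A design is a hit iff every *enabled* metric passes its **strict**
inequality — the printed criteria are pLDDT_binder > 80 and
PAE_interaction < 10, so values exactly at a threshold fail. Only those
two metrics ship enabled; CUTRE ships disabled as an optional extra
filter, and unknown metric columns from external scorers pass through the
CSV untouched.

`Scoring_Stats.csv` is append-only: a schema-version comment line, a fixed
header, and whole rows appended under a cooperative directory lock so
concurrent batch writers cannot interleave partial rows. Numeric fields
serialize at full precision (17 significant digits); missing metrics are
empty cells, never sentinels. Radar normalization maps each metric to
value/threshold (higher-is-better) or threshold/value (lower-is-better),
so 1.0 is always "at threshold".

A `score_record` carries an optional ISO-8601 timestamp, but the campaign
engine leaves it empty by default: a fixed-seed campaign must reproduce
its CSV bit-identically, and wall-clock stamps would break that. Callers
who want stamps can set them per record.

## Campaign engine

A campaign is a sequence of batches, each an end-to-end instance:
generate → filter → design sequences → score → evaluate. Per-batch seeds
are a stable integer hash of (campaign seed, batch index), so any batch
reproduces exactly regardless of dispatch order or worker count — the
suite asserts that a 1-worker and a 2-worker run produce identical records
for the batches they share. Batches are dispatched in waves of at most
`parallel_instances`; the stop condition (cumulative hits ≥ target) is
checked between waves, so the final wave may overshoot the target — this
matches how a cluster campaign behaves, where in-flight jobs finish and
are counted. A zero-hit-rate campaign terminates at `max_batches` with
status `"exhausted"`. Conservation (generated = filtered + scored) holds
in every state snapshot.

Two refinement strategies reuse the same machinery. *Partial diffusion*
replaces backbone generation with white-noise perturbation of a validated
reference binder (Gaussian, default sd 0.5 Å per coordinate — a modest
fraction of the structural noise a generative model would re-inject;
configurable). *Sequence diversity* skips backbone generation entirely and
scores `batch_size` sequences (conventionally 200 per batch) on the fixed
reference backbone; BLOSUM62 similarity against the reference sequence
then quantifies how far sequence space has been explored.

## Synthetic fixtures: what they emulate and what they do not

`build_ideal_backbone()` constructs poly-alanine N/CA/C/O chains from
ideal internal coordinates (N–CA 1.458, CA–C 1.525, C–N 1.329 Å, ω = 180°;
helix φ/ψ = −57/−47, strand −139/135) by NeRF chain extension, with the
carbonyl O in standard sp² geometry. `make_complex()` places a binder
against a target at a controlled minimum gap (root-finding along a random
approach axis, to 0.1 Å). `synth_confidence()` builds PAE/pLDDT with
controllable per-chain-block means and truncated Gaussian noise.
`mock_stages()` wires these into a stage contract whose hit pattern is
exactly periodic (design ordinal k is a hit iff ⌊(k+1)r⌋ − ⌊kr⌋ = 1), so
campaign arithmetic is checkable in closed form.

These fixtures emulate the *interfaces* of the generative stages, not
their physics: no side chains, no rotamers, no energetics, no correlation
between geometry and confidence, and idealized secondary structure far
cleaner than real designs. Passing tests therefore demonstrate that the
filtering, scoring and orchestration logic is correct on well-defined
inputs — not that any particular generative model will produce binders.
All randomness flows through explicit seeds under a fixed generator
(Mersenne-Twister / inversion), with caller RNG state restored.

## Numerical choices and degenerate inputs

* Distance boundaries: inclusive except the clash rule (strict <), as
  discussed above; ties at exactly the cutoff are deterministic.
* Kabsch: degenerate (collinear or < 3 points) inputs error; reflections
  corrected, det(R) = +1 within 1e-6.
* SASA lattice: n_points ≥ 92 enforced; 960 default balances the ~1%
  lattice error against runtime.
* Altloc ties: first record wins, making parsing order-stable.
* Empty interface, empty binder span, zero thresholds: errors, not NaN.
* Problem sizes in the test suite (10–30-residue fixtures, 500-atom
  oracle comparisons, 100-residue round-trip proteins, 5-batch mock
  campaigns) were chosen as the smallest sizes at which each property is
  non-trivially exercised.

## Known limitations

* The reduced 3-state secondary-structure assignment differs from full
  DSSP at helix termini and isolated bridges; the topology filter only
  needs the coarse classes, but per-residue strings should not be treated
  as DSSP output.
* CUTRE's printed normalization (by residue counts, not weight sums) makes
  scores from interfaces with very different pLDDT levels incomparable in
  absolute terms.
* The campaign engine's worker pool is in-process and cooperative; it
  models the batch semantics (seeding, stop condition, bookkeeping) of a
  cluster deployment, not its scheduling.
* The shipped codon-usage weights are rounded standard values for E. coli
  K-12; for expression hosts with unusual tRNA pools, supply your own TSV.
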