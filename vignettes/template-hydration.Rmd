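---
title: "Template-based hydration: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Template-based hydration: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aquahom)
```

## The problem

Crystallographically ordered ("internal") water molecules sit in cavities
inside a protein and take part in its function: in G-protein-coupled
receptors (GPCRs) they line the transmembrane pore, coordinate the
conserved sodium site near residue D2.50, and mediate the activation
mechanism. Resolution limits mean that most deposited structures report far
fewer internal waters than are physically present, which degrades docking
and molecular-dynamics setups built on those structures.

aquahom fills a structure's internal cavities by *borrowing* waters
observed in homologous structures: a curated reference database stores the
reliable internal waters of a protein family; for a new query structure the
templates are ranked by sequence similarity, superposed, and their waters
transferred one by one subject to geometric gates. The approach is
knowledge-based — every placed water is backed by an experimental
observation in a homolog — as opposed to energy-based cavity solvation.

## Reference database curation

Each template structure is reduced to one receptor chain plus its waters
and any retained ligands (`strip_for_curation()`). Waters in multi-chain
files belong to the chain whose protein atoms are nearest; auxiliary and
fusion chains are removed by explicit user choice of the kept chain, since
no robust automatic detector of crystallisation helpers exists.

Two filters then decide which waters enter the database
(`build_template_entry()`):

* **Order.** Waters with B-factor above 45 A^2 are positionally unreliable
  and discarded. The boundary is read literally as *strictly greater*:
  B = 45.0 is kept.
* **Burial.** A water is *internal* when the circular variance (CV) of the
  unit vectors from its oxygen to the surrounding protein heavy atoms
  within 10 A is at least 0.6:
  CV = 1 − ‖Σ u_i‖ / N. A surrounded point has vectors cancelling in every
  direction (CV → 1); a surface point sees all neighbours on one side
  (CV → 0). External waters are incompatible with the membrane environment
  and are dropped.

Design choices where the method description leaves room:

* The CV neighbour set is **protein heavy atoms only** — no waters, no
  ligands, no hydrogens. Burial is burial in the protein matrix; counting
  other solvent would make the classification depend on how well-solvated
  the deposition happens to be. The unit vectors are unweighted (no
  distance kernel); CV is then exactly rigid-motion invariant, which the
  suite verifies to 1e-9.
* A water with *no* neighbour within 10 A gets CV = 0 (external) with a
  warning rather than an error: it is the limiting one-sided case.
* Sodium ions within 6 A of any atom of the user-annotated position-2.50
  residue are recorded with a `near_250` flag. The 6 A capture radius is
  deliberately generous: placement re-checks the geometry in the query
  frame, so a loose capture cannot cause a bad placement.
* The database serialises to versioned JSON-lines — one template per line,
  diffable, lossless at double precision. A schema-version mismatch is a
  hard error naming the version found.

## Template ranking

Templates are ranked by pairwise local alignment of the query chain
sequence against each template sequence: affine-gap Smith–Waterman under
BLOSUM62 with gap open 11 / extend 1 (a gap of length L costs
`open + L·ext`, the convention of common protein search tools). Raw scores
convert to bit scores via S' = (λS − ln K)/ln 2 with the gapped constants
λ = 0.267, K = 0.041, so familiar bit-score thresholds — e.g. 300 to admit
only close homologs — keep their usual meaning. Identity is reported over
aligned (non-gap) columns.

The ranking key is: functional-state match (when the user supplies
`active`/`inactive`), then bit score descending, then resolution ascending,
then entry id for determinism. Reading state "prioritisation" as a primary
sort key is the strongest of the two defensible readings; the alternative —
score first, state as tie-break — is available as
`state_priority = "tiebreak"`. Templates below `score_min` are excluded
outright; an empty result is an explicit outcome, not an exception.

## Superposition

* **Global fit** (`global_fit()`): Kabsch least-squares superposition
  (SVD with reflection correction, so the rotation is always proper) on the
  corresponded C-alpha atoms, with iterative outlier rejection — pairs
  whose residual exceeds 2× the current RMSD are dropped and the fit
  repeated, up to 5 cycles. This keeps a displaced loop from corrupting the
  core fit. Fewer than 3 usable pairs skips the template.
* **Local refinement** (`local_refine_water()`): for each candidate water,
  the template residues with any stored heavy atom within 10 A of the
  water oxygen (measured in the template frame; the method source does not
  specify the anchor, and "any atom of the residue" is the least biased
  choice) are intersected with the correspondence and their backbone atoms
  (N, CA, C, O) superposed. Backbone-only, because side chains differ
  between homologs while the correspondence here comes from sequence. The
  water is kept only if at least 3 residue pairs support the fit and the
  local RMSD is at most 2.0 A, and its position is mapped by the **local**
  transform. Mapping by the local transform (rather than using the local
  fit purely as a gate on the globally-mapped position) is the reading that
  makes the refinement actually refine; `gate_only = TRUE` restores the
  other behaviour. Waters failing the 3-pair minimum are rejected rather
  than silently falling back to the global transform.

## Placement

Templates are visited in rank order; within a template, waters in
increasing source B-factor (most reliable first), ties in source record
order. A candidate that passed the local gate is accepted iff no query
heavy atom (protein, ligand, or pre-existing water — all treated as
occupied space), no already placed water, and no placed ion lies strictly
closer than 2.4 A. The boundary is strict: a contact at exactly 2.4 A is
allowed. Accepted waters are appended as HETATM HOH on a dedicated chain
with sequential numbering and full provenance (source entry, chain, source
B-factor, local RMSD) in the report, which partitions every assessed
candidate into placed or rejected-with-reason.

The conserved sodium, when requested, is placed **before** any water. The
candidate is the near-2.50 ion of the template with the highest percent
identity (ties to best resolution), mapped by that template's global
transform, and placed only when there is no water within 2.1 A **and** no
protein atom within 1.8 A. The source phrasing ("no water molecules within
a radius of 2.1 A or protein atoms within 1.8 A") is read as this
conjunction of exclusion conditions; the literal disjunctive reading would
almost never allow an ion. Subsequently placed waters must clear the ion at
the ordinary 2.4 A cutoff.

Candidate waters are *not* re-tested for circular variance in the query
frame: burial classification is a database-build-time property.

Externally predicted waters (e.g. from an energy-based program) can be
merged afterwards: each prediction is added iff it is at least the cutoff
(default 2.4 A) from every atom already present, including previously
accepted predictions.

## Validation

`water_recovery()` matches original to placed waters one-to-one, greedily
over all pairs in ascending distance, accepting only pairs strictly below
the cutoff (default 2.0 A). Greedy matching was chosen for transparency;
the suite checks it against a permutation-exhaustive optimal matching on
instances up to 6 waters and has never observed a count difference (ties in
the matching cannot change the count at generic coordinates).

`leave_one_out()` re-derives a test structure's query from its stored
backbone, removes **the whole entry** from the database view — not just its
waters — so identical coordinates cannot leak back through a second chain
of the same deposition, hydrates, and reports per-entry recovery, mean
matched distance and waters placed. `select_test_entries()` applies the
benchmark admission rule: resolution strictly below 2.8 A and strictly more
than five internal waters. Because the database stores backbone atoms only,
clash checking inside this benchmark is against backbone; for fixtures that
*is* every atom, and the benchmark is the package's own consistency check,
not a claim about side-chain packing.

## The synthetic generator, and what it does not emulate

`generate_family()` provides ground truth for every stage: ideal
alpha-helices (phi = −57°, psi = −47°, standard bond geometry, rise about
1.5 A per residue) arranged antiparallel on a circle around a central
pore — a deliberately GPCR-like single-chain bundle (default 7 helices ×
30 residues). Cavity waters are planted on the pore axis (pairwise ≥
2.8 A, ≥ 2.6 A from protein), surface waters ≥ 4 A outside the bundle;
the generator verifies its own labels against the CV classifier with a
safety margin (internal ≥ 0.7, external ≤ 0.5) and retries a bounded
number of times, so label/classifier agreement is enforced, not assumed.
Family members mutate the ancestor sequence to a target identity (default
90%), jitter every backbone coordinate with Gaussian noise (default
0.3 A), optionally plant a sodium near a designated "2.50" residue, and
receive a random whole-body rigid motion so that superposition is never
trivial. Everything is deterministic in the spec seed.

What the fixtures do **not** model: side chains, ligands, membrane,
crystallographic noise structure in B-factors, alternate conformations,
non-conserved loop rearrangements, and real families' uneven template
coverage. Passing the suite therefore demonstrates that the *algorithm*
(filters, ranking, superposition, gates, matching) is implemented
correctly and behaves as specified in its own regime; recovery percentages
on real crystal structures depend on template availability and homology
and will be lower for sparsely covered receptors.

## Numerical choices and problem sizes

Defaults throughout are the standard operating values: B-factor 45 A^2, CV
0.6 within 10 A, local radius 10 A, local RMSD gate 2.0 A, clash 2.4 A,
sodium 2.1/1.8 A, recovery cutoff 2.0 A, BLOSUM62 11/1 with λ = 0.267,
K = 0.041. Collinearity in a fit is detected from the second singular
value; rotations are reflection-corrected; all tie-breaks (equal B-factor,
equal score, equal resolution) are deterministic, and two identical runs
produce byte-identical PDB and report files.

The shipped validation runs on 6-member families of 7×30-residue bundles
with 8 conserved pore waters — large enough that global and local fits,
clash cascades and the state/resolution sort all engage, and small enough
that every test recomputes its fixtures from code in seconds. The
benchmark script reports, per run: identity self-recovery (expected 100%
at numerically zero distance), rigid-motion self-recovery (100%;
exercises the full fitting chain), and the leave-one-out median recovery
with mean matched distance, which for these conditions sits in the
high-recovery regime with sub-angstrom matched distances.

## Known limitations

* Sequence-based correspondence: templates below the twilight zone of
  sequence identity superpose poorly; a sequence-independent structural
  aligner is out of scope.
* Waters are represented by their oxygen only; no hydrogens, no
  orientation, no hydrogen-bond network optimisation.
* The sodium logic places at most one ion, from a single best template.
* mmCIF input, symmetry-mate expansion and automatic functional-state
  detection are not implemented; state is user metadata.
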