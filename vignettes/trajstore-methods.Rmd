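---
title: "The trajstore data model and its design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The trajstore data model and its design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trajstore)
```

## The problem

Molecular simulation output is traditionally archived as binary
trajectory files plus ad hoc side files for metadata. That layout makes
data hard to find, hard to interpret without the original author, and
hard to slice (a single snapshot, a subset of atoms) without reading
entire files. `trajstore` implements a relational storage standard that
makes trajectories findable, accessible and interpretable by
construction: every coordinate row is linked to the metadata needed to
interpret it, and integrity is checkable mechanically.

## The four tiers

The model is a strict hierarchy of four tiers:

1. **Ensemble tier** (`ensembles`): one row per simulated *system*,
   identified by a human-chosen key (`ens_key`, restricted to
   alphanumerics, `_` and `-` so it can be quoted anywhere) and a
   numeric `ens_id` that is the actual linking key. `nratoms` is a
   deliberately redundant copy of the atom count used to detect
   corruption, and `residues` stores the residue sequence as an ordered
   token list, usable both as a cross-check and as a query target.
2. **Simulation tier** (`simulations`): one row per trajectory, carrying
   the sixteen metadata attributes needed to interpret its coordinates:
   counts and intervals (`nratoms`, `equilibration_steps`,
   `snap_interval`), free text (`sim_summary`, `sim_software`) and seven
   integer-coded attributes described below. Anything not covered by a
   dedicated column belongs in `sim_summary`; in particular there are
   deliberately no columns for force-field parameters or ensemble
   thermodynamic quantities (energies, temperatures), which are
   error-prone to curate and better described in free text.
3. **Atoms tier** (`atoms`): one row per atom with the annotation needed
   to regenerate structure files: PDB-style identity (`atom_name`,
   `resid_name`, `chain_seq`, `keyword`, fixed `occupancy = 1.0`),
   physical parameters (`mass`, `partial_charge`, `formal_charge`,
   solvation terms) and topology (`bound_partners`, a 0-padded list of
   covalent neighbours that must be symmetric, and a Z-matrix triple of
   reference indices plus values with a −1/0/+1 chirality indicator,
   0 meaning the third value is a dihedral).
4. **Coordinate tier**: one table per trajectory, named
   `snapshots_(sim_id)_(sim_rank)`. Each row is one snapshot: coordinates
   as an array of `(atom_seq, x, y, z)` 4-tuples in full double
   precision, a 12-element box vector (box vectors 1–3 then the origin,
   each as x, y, z), and the *backward connectivity triple*
   (`previous_id`, `previous_rank`, `previous_snap`) naming the
   geometric parent snapshot, with `(0, 0, 0)` as the no-parent
   sentinel. `snap_id` is the primary key, so retrieving snapshot *k*
   never requires scanning earlier snapshots.

## Integer code books

Seven categorical attributes are stored as fixed integer codes
(`code_books()`): box shape (1 cuboid, 2 sphere, 3 cylinder,
4 triclinic), periodicity (0 none; z, y, x, yz, xz, xy for 1–6; 7 fully
periodic — for triclinic cells the letters refer to box-vector order),
thermodynamic ensemble (1 NVT, 2 NVE, 3 NPT, 5 semigrand, 6 grand
canonical), sampler (1 Monte Carlo, 2 Newtonian, 3 stochastic,
4 Brownian, 5–7 hybrid), parallel scheme (0 none, 1 replica exchange,
2 PIGS, 3 parallel metadynamics/Wang–Landau, 4 parallel simulated
annealing, 5 other adaptive, 6 reservoir/library), united-atom model
(0 all H, 1 no aliphatic H, 2 polar H only, 3 other coarse-grained) and
deposit mode (1 while running, 2 not). Geometric admissibility is
enforced jointly: spheres must be aperiodic and cylinders periodic in
at most the one dimension along their axis.

Labels are matched case-insensitively with spaces, hyphens and
underscores interchangeable, because free-text recognition ("AMBER" vs
"Amber") is exactly the failure mode integer codes exist to avoid. The
published codes are frozen; `register_code()` adds session-local
extensions without being able to reassign a published value.

### Replica identity

Within a trajectory ensemble every member row has its **own** `sim_id`
(the tier's primary key) and a rank 0…R−1; all members, including the
parent itself, store the parent's `sim_id` in `sim_parent` (standalone
runs are their own parent). This keeps the simulation tier's key simple
while `ORDER BY sim_parent, sim_rank` groups ensembles contiguously and
rank-ordered, which is what retrieval relies on for mappable slices.

## Backends

`emit_schema()` produces the schema in two dialects. The PostgreSQL
dialect is the standard's reference target: native arrays, a composite
coordinate element type (named `atomxyz` here; the standard fixes the
field semantics, not the type name) and `TIMESTAMP`. The executable
dialect used by the bundled backend is SQLite through DBI: the package
is then fully self-contained — a database is a single file (or
`":memory:"`), which is the right trade-off for a library whose tests,
fixtures and command-line tools must run anywhere. In this dialect the
array-valued atoms columns are space-separated text (serialized with
`%.17g`, which round-trips IEEE doubles exactly) and the per-snapshot
coordinate and box payloads are binary blobs of little-endian doubles,
so the deposit–retrieve round trip is bit-identical by construction.
Column names and order match the standard in both dialects.
Coordinates are bound natively, never formatted through strings, on the
retrieval path as well.

## Deposition logic

`open_or_create_ensemble()` implements the first integrity gate: a new
key creates the ensemble and populates the atoms tier atomically; an
existing key with a field-wise identical system is a no-op returning
the existing `ens_id`; an existing key whose system has no deposited
snapshots may be overwritten in place; anything else is an integrity
error and nothing is written. `register_simulation()` implements the
second gate: re-registration against an existing simulation is allowed
only when the metadata matches field-wise, which protects trajectory
ensembles that are appended to in parallel.

`deposit_snapshot()` allocates `snap_id` as max+1 (starting at 1),
derives `sim_step = equilibration_steps + snap_interval × snap_id`
unless an explicit step is supplied (irregular saving), defaults the
backward triple to the preceding snapshot of the same table, and
verifies that an explicit parent actually exists. Every row is
committed and visible before the call returns; `deposit_trajectory()`
offers an optional batch mode (commit every N rows) for throughput,
since per-row durability is a safety default rather than a necessity.

Grand-type ensembles store a fixed superset system including
ghost/buffer particles. A particle's absence is flagged by a coordinate
shift of +L on every axis, with L twice the largest box extent. The
magnitude is this package's documented convention (the standard
prescribes shifting but not the offset); it is exactly invertible via
`is_ghost()` under the assumption that present atoms lie inside the
primary container, which deposition of wrapped trajectories guarantees.
For curved containers the 12-vector layout is also this package's
convention (sphere: radius in element 1, center in 10–12; cylinder:
radius, height, axis index in elements 1–3, center in 10–12) and is
flagged as not interoperable with other implementations' conventions.

## Retrieval and templates

Selections (`selection_spec()`) are resolved client-side into explicit,
sorted snapshot-id and atom-index lists before any query is issued, so
results are deterministic, bounded in size, and identical whether
executed jointly or per snapshot. Atom-name filtering defaults to
substring semantics, mirroring the `LIKE '%CA%'` idiom (which also
matches `CA2`); `exact_name = TRUE` gives strict matching. Summary
search uses literal substring semantics (`INSTR`), so wildcard
characters in a needle match only themselves; case-insensitivity is
opt-in.

Three template generators read the database without ever mutating it:
`pdb_template()` builds fixed-width ATOM/HETATM records (serial =
`atom_seq`; occupancy always `1.00`; temperature-factor column filled
from a selectable source such as `partial_charge`; element derived from
mass with the name only breaking near-ties, so a 40.08 "CA" is calcium
while a 12.011 "CA" stays carbon; charge column from `formal_charge`;
`TER` at molecule boundaries; no insertion codes or altlocs). The
stored 2-character `chain_seq` is truncated to PDB's single chain
column with a warning when information is lost. `zmatrix_template()`
renders the stored internal-coordinate topology and rejects forward
references; `sequence_template()` renders the residue array.

## Connectivity and demultiplexing

The backward triples form a map that is functional by construction
(one stored parent per row — forward, the history is one-to-one or
one-to-many, never many-to-one). `trace_lineage()` walks it with cycle
detection; `demultiplex()` traces every member's terminal frame of a
parallel simulation, producing one geometrically continuous trajectory
per terminal. For replica exchange the lineages must partition the
frames (a permutation at every time slice; violations are integrity
errors). For adaptive reseeding (PIGS-like schemes), lineages may share
prefixes because frames are stored once; shared frames are reported as
branch points rather than duplicated.

## Synthetic fixtures

All tests run on generated data with known ground truth:

* `make_toy_system()` builds bead chains with three backbone-like atoms
  per residue, real element masses (so element derivation is exercised
  meaningfully), symmetric bond topology and a backward-only Z-matrix
  with idealized backbone internals (N–CA 1.458 Å, CA–C 1.525 Å,
  C–N 1.329 Å and the matching angles) plus seeded dihedrals.
* `random_walk_trajectory()` produces Gaussian-increment coordinates
  wrapped into the periodic cell. The default test scale is 3 chains ×
  10 residues (90 atoms) × 100 frames for round-trip checks — small
  enough for fast, deterministic tests while covering multi-chain
  bookkeeping.
* `replica_exchange_schedule()` alternates even/odd neighbour pairings
  deterministically across swap attempts (the standard replica-exchange
  phase pattern) and accepts each candidate swap with a seeded
  probability (default 0.5). The lineage checks use 4 replicas ×
  200 frames with swaps attempted every 10 frames.

Every generator takes an explicit seed and uses a private RNG stream,
so fixtures are bit-reproducible and the caller's random state is never
touched. The fixtures emulate structure and bookkeeping only: there is
no force field, no energetics, no realistic dynamics, and the
random-walk frames are spatially featureless. Passing tests therefore
demonstrate the correctness of storage, linkage, retrieval and
connectivity logic — not anything about simulation physics, and not
performance at archive scale (millions of snapshots, very large numbers
of tables), which depends on the backing database engine.

## Validation

`validate_database()` is a read-only auditor of the standard's
redundancy: atom counts against both `nratoms` copies, atom-index
contiguity, bond symmetry, fixed occupancy, code-book membership,
shape/periodicity admissibility, existence and well-formedness of every
snapshot table (indices in range and strictly increasing, 12-element
boxes), and resolvable, acyclic backward connectivity. There is
deliberately no repair mode: curation of scientific archives is a
human decision, and an auditor that rewrites data is a liability.

## Known limitations

* Binary trajectory formats (DCD/XTC/NetCDF) are not read or written;
  multi-model PDB is the supported interchange format.
* The biotype vocabulary is stored and round-tripped opaquely; this
  package assigns no chemical perception of its own.
* The curved-container box convention and the ghost-shift magnitude are
  package conventions, documented above, not interoperable guarantees.
* Library/reservoir sampling (parallel mode 6) has no defined parenting
  rule; such snapshots carry the nil sentinel and demultiplexing
  reports them as unparented roots.
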