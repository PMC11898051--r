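# trajstore

Relational storage for molecular simulation trajectories, for people who
need their simulation archives to be findable, sliceable and
self-describing rather than a directory of binary files.

Simulation output is stored in a strict four-tier relational schema:

* **ensembles** — one row per simulated system: a human key (`ens_key`),
  the linking id (`ens_id`), a redundant atom count used for corruption
  detection, and the residue sequence;
* **simulations** — one row per trajectory: sampling interval,
  equilibration, free-text summary, and seven integer-coded attributes
  (box shape, periodicity, thermodynamic ensemble, sampler, parallel
  scheme, united-atom model, deposit mode) under fixed code books;
* **atoms** — one row per atom: PDB-grade identity, physical parameters,
  covalent topology and a Z-matrix, sufficient to regenerate annotated
  structure files;
* **snapshot tables** — one table per trajectory
  (`snapshots_<sim_id>_<sim_rank>`), one row per frame: coordinates as
  `(atom_seq, x, y, z)` 4-tuples in full double precision, a 12-element
  box descriptor, and a backward-connectivity triple naming each frame's
  geometric parent — possibly in another replica's table, which is what
  makes replica-exchange swap histories and adaptive reseeding
  reconstructable (`demultiplex()`).

The live backend is SQLite through DBI (a database is one file, or
`":memory:"`); `emit_schema()` additionally emits the schema in
PostgreSQL dialect (arrays plus a composite `atomxyz` coordinate type)
for server deployments. Deposit–retrieve round trips are bit-identical
in coordinates, boxes and metadata.

See `vignette("trajstore-methods")` for the data model, the code books,
and the design decisions (replica identity, ghost-particle convention,
curved-container box layout).

## Worked example

```r
library(trajstore)

con <- ts_connect(":memory:")

# a seeded toy system: 1 chain x 3 residues, 3 backbone atoms each
sys <- make_toy_system(n_chains = 1, chain_length = 3, seed = 42)
ens <- open_or_create_ensemble(con, "TOY_PEPTIDE", sys)

meta <- list(
  sim_summary = "toy peptide random walk in a periodic cube",
  sim_software = "trajstore-demo", snap_interval = 100,
  box_shape = "rectangular_cuboid", box_periodicity = "xyz",
  ensemble_type = "NVT", sampler_type = "stochastic",
  parallel_mode = "none", united_atom_model = "all_hydrogens",
  deposit_mode = "after_completion")
reg <- register_simulation(con, ens, meta)
reg
#>   sim_id sim_rank         table
#> 1      1        0 snapshots_1_0

box <- box_descriptor("rectangular_cuboid", c("x", "y", "z"),
                      vectors = diag(c(20, 20, 20)))
walk <- random_walk_trajectory(sys, n_frames = 5, box,
                               step_sigma = 0.3, seed = 7)
deposit_trajectory(con, reg$sim_id[1], reg$sim_rank[1], walk$frames, box)
#> [1] 1 2 3 4 5
```

Five snapshots were deposited (ids 1–5; with `snap_interval = 100` they
represent simulation steps 100–500). Retrieval is by key, with
client-side selections:

```r
list_keys(con)[, 1:3]
#>       ens_key ens_id nratoms
#> 1 TOY_PEPTIDE      1       9

fetch_metadata(con, reg$sim_id[1], 0)$labels$sampler_type
#> [1] "stochastic"

# C-alpha beads of frame 5
ca <- fetch_coordinates(con, reg$sim_id[1], 0,
                        selection_spec(ids = 5, atom_name = "CA",
                                       exact_name = TRUE))
round(ca[[1]]$coords, 3)
#>      atom_seq      x      y     z
#> [1,]        2  8.476  3.909 6.735
#> [2,]        5  5.558  1.689 0.393
#> [3,]        8 19.914 11.603 1.710
```

The atoms tier regenerates annotated structure records for any frame or
subset (serial = `atom_seq`, occupancy fixed at 1.00, element derived
from mass and name):

```r
cat(pdb_template(con, ens, ca[[1]]$coords), sep = "\n")
#> ATOM      2  CA  ALA A   1       8.476   3.909   6.735  1.00  0.00           C
#> ATOM      5  CA  THR A   2       5.558   1.689   0.393  1.00  0.00           C
#> ATOM      8  CA  ALA A   3      19.914  11.603   1.710  1.00  0.00           C
#> TER       9      ALA A   3

validate_database(con)   # zero rows: the archive is internally consistent
#> [1] tier    ens_id  object  problem
#> <0 rows> (or 0-length row.names)
```

A command-line interface (`inst/scripts/trajstore`) wraps the same
functions: `init`, `deposit` (multi-model PDB plus YAML metadata),
`extract`, `ls`, `search`, `template`, `demux` (one PDB per continuous
lineage of a replica ensemble), `validate` and `demo`.

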