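Package: trajstore
Title: Relational Storage Standard for Molecular Simulation Trajectories
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Implements a four-tier relational storage standard for
    molecular simulation trajectories: an ensemble tier identifying the
    simulated system, a simulation tier holding run metadata under fixed
    integer code books (box shape, periodicity, thermodynamic ensemble,
    sampler, parallel scheme), a per-atom annotation tier sufficient to
    regenerate annotated structure files, and a per-simulation coordinate
    tier with a backward connectivity map linking every snapshot to its
    geometric parent. Provides deposition and retrieval logic with
    integrity checks, replica-exchange swap-history demultiplexing into
    geometrically continuous trajectories, annotated PDB, Z-matrix and
    sequence template generation, a synthetic-fixture generator with
    ground-truth lineages, a database validator, and a command-line
    interface. Schema definitions are emitted in PostgreSQL dialect (the
    standard's reference target) and in an executable SQLite dialect used
    for the bundled live backend.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    DBI,
    RSQLite,
    stats,
    utils
Suggests:
    bio3d,
    jsonlite,
    yaml,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
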