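#' @importFrom DBI dbConnect dbDisconnect dbExecute dbGetQuery dbQuoteString
#'   dbExistsTable dbListTables dbListFields dbAppendTable dbWithTransaction
NULL

# column sets of the four tiers; name and order are part of the standard
.ts_columns <- list(
  ensembles = c("ens_id", "ens_key", "nratoms", "residues", "timestamp"),
  simulations = c(
    "ens_id", "sim_id", "sim_rank", "sim_parent", "sim_summary",
    "sim_software", "nratoms", "equilibration_steps", "snap_interval",
    "box_shape", "box_periodicity", "ensemble_type", "sampler_type",
    "parallel_mode", "united_atom_model", "deposit_mode"
  ),
  atoms = c(
    "ens_id", "atom_id", "atom_seq", "sys_seq", "atom_name", "resid_seq",
    "resid_name", "chain_seq", "keyword", "occupancy", "tempfactor",
    "biotype", "molecule_id", "mass", "partial_charge", "formal_charge",
    "charge_group_id", "rfos_contribution", "solvation_group_id",
    "bound_partners", "zmatrix_references", "zmatrix_values"
  ),
  snapshots = c(
    "ens_id", "snap_id", "sim_step", "previous_id", "previous_rank",
    "previous_snap", "sampler_id", "trajectories", "box"
  )
)

#' Emit the schema definition of the storage standard
#'
#' Produces the data-definition statements for the three fixed tables
#' (ensembles, simulations, atoms) and the composite coordinate element
#' type `atomxyz`. Snapshot tables are created later, one per registered
#' trajectory, by [register_simulation()]. All statements are
#' create-if-absent, so re-running them on an existing database is a no-op.
#'
#' Two dialects are emitted. `"postgres"` is the standard's reference
#' target and uses native arrays, a composite type and `TIMESTAMP`.
#' `"sqlite"` is the executable dialect used by the bundled backend:
#' array-valued atoms columns are stored as space-separated text, the
#' per-snapshot coordinate and box payloads as BLOBs of IEEE doubles, and
#' the composite type is recorded in a one-row bookkeeping table
#' (`atomxyz_type`) describing its fields. Column names and order match
#' the standard in both dialects.
#'
#' @param schema Target schema/namespace name (PostgreSQL dialect only;
#'   must be a plain identifier). Default `"public"`.
#' @param dialect `"postgres"` (default) or `"sqlite"`.
#' @return Character vector of DDL statements.
#' @export
#' @examples
#' cat(emit_schema()[1], "\n")
emit_schema <- function(schema = "public", dialect = c("postgres", "sqlite")) {
  dialect <- match.arg(dialect)
  if (!grepl("^[A-Za-z_][A-Za-z0-9_]*$", schema)) {
    stop(sprintf("invalid schema identifier '%s'", schema), call. = FALSE)
  }
  if (dialect == "postgres") {
    q <- function(tab) sprintf("%s.%s", schema, tab)
    c(
      sprintf(
        paste0(
          "DO $$ BEGIN\n",
          "  CREATE TYPE %s.atomxyz AS (atom_seq INTEGER, ",
          "x DOUBLE PRECISION, y DOUBLE PRECISION, z DOUBLE PRECISION);\n",
          "EXCEPTION WHEN duplicate_object THEN NULL;\nEND $$;"
        ), schema
      ),
      sprintf(
        paste0(
          "CREATE TABLE IF NOT EXISTS %s (\n",
          "  ens_id INTEGER PRIMARY KEY,\n",
          "  ens_key TEXT NOT NULL UNIQUE,\n",
          "  nratoms INTEGER NOT NULL,\n",
          "  residues TEXT[],\n",
          "  \"timestamp\" TIMESTAMP\n)"
        ), q("ensembles")
      ),
      sprintf(
        paste0(
          "CREATE TABLE IF NOT EXISTS %s (\n",
          "  ens_id INTEGER NOT NULL REFERENCES %s (ens_id),\n",
          "  sim_id INTEGER PRIMARY KEY,\n",
          "  sim_rank INTEGER NOT NULL,\n",
          "  sim_parent INTEGER NOT NULL,\n",
          "  sim_summary TEXT,\n  sim_software TEXT,\n",
          "  nratoms INTEGER NOT NULL,\n",
          "  equilibration_steps INTEGER NOT NULL,\n",
          "  snap_interval INTEGER NOT NULL,\n",
          "  box_shape INTEGER NOT NULL,\n",
          "  box_periodicity INTEGER NOT NULL,\n",
          "  ensemble_type INTEGER NOT NULL,\n",
          "  sampler_type INTEGER NOT NULL,\n",
          "  parallel_mode INTEGER NOT NULL,\n",
          "  united_atom_model INTEGER NOT NULL,\n",
          "  deposit_mode INTEGER NOT NULL\n)"
        ), q("simulations"), q("ensembles")
      ),
      sprintf(
        paste0(
          "CREATE TABLE IF NOT EXISTS %s (\n",
          "  ens_id INTEGER NOT NULL REFERENCES %s (ens_id),\n",
          "  atom_id BIGINT PRIMARY KEY,\n",
          "  atom_seq INTEGER NOT NULL,\n  sys_seq INTEGER NOT NULL,\n",
          "  atom_name CHAR(5),\n  resid_seq INTEGER,\n",
          "  resid_name CHAR(4),\n  chain_seq CHAR(2),\n",
          "  keyword CHAR(6),\n  occupancy DOUBLE PRECISION,\n",
          "  tempfactor DOUBLE PRECISION,\n  biotype INTEGER,\n",
          "  molecule_id INTEGER,\n  mass DOUBLE PRECISION,\n",
          "  partial_charge DOUBLE PRECISION,\n  formal_charge SMALLINT,\n",
          "  charge_group_id INTEGER,\n",
          "  rfos_contribution DOUBLE PRECISION,\n",
          "  solvation_group_id INTEGER,\n",
          "  bound_partners INTEGER[5],\n",
          "  zmatrix_references INTEGER[4],\n",
          "  zmatrix_values DOUBLE PRECISION[3]\n)"
        ), q("atoms"), q("ensembles")
      )
    )
  } else {
    c(
      paste0(
        "CREATE TABLE IF NOT EXISTS atomxyz_type (",
        "field_1 TEXT, field_2 TEXT, field_3 TEXT, field_4 TEXT)"
      ),
      paste0(
        "CREATE TABLE IF NOT EXISTS ensembles (\n",
        "  ens_id INTEGER PRIMARY KEY,\n",
        "  ens_key TEXT NOT NULL UNIQUE,\n",
        "  nratoms INTEGER NOT NULL,\n",
        "  residues TEXT,\n",
        "  \"timestamp\" TIMESTAMP\n)"
      ),
      paste0(
        "CREATE TABLE IF NOT EXISTS simulations (\n",
        "  ens_id INTEGER NOT NULL REFERENCES ensembles (ens_id),\n",
        "  sim_id INTEGER PRIMARY KEY,\n",
        "  sim_rank INTEGER NOT NULL,\n",
        "  sim_parent INTEGER NOT NULL,\n",
        "  sim_summary TEXT,\n  sim_software TEXT,\n",
        "  nratoms INTEGER NOT NULL,\n",
        "  equilibration_steps INTEGER NOT NULL,\n",
        "  snap_interval INTEGER NOT NULL,\n",
        "  box_shape INTEGER NOT NULL,\n",
        "  box_periodicity INTEGER NOT NULL,\n",
        "  ensemble_type INTEGER NOT NULL,\n",
        "  sampler_type INTEGER NOT NULL,\n",
        "  parallel_mode INTEGER NOT NULL,\n",
        "  united_atom_model INTEGER NOT NULL,\n",
        "  deposit_mode INTEGER NOT NULL\n)"
      ),
      paste0(
        "CREATE TABLE IF NOT EXISTS atoms (\n",
        "  ens_id INTEGER NOT NULL REFERENCES ensembles (ens_id),\n",
        "  atom_id INTEGER PRIMARY KEY,\n",
        "  atom_seq INTEGER NOT NULL,\n  sys_seq INTEGER NOT NULL,\n",
        "  atom_name TEXT,\n  resid_seq INTEGER,\n",
        "  resid_name TEXT,\n  chain_seq TEXT,\n",
        "  keyword TEXT,\n  occupancy REAL,\n",
        "  tempfactor REAL,\n  biotype INTEGER,\n",
        "  molecule_id INTEGER,\n  mass REAL,\n",
        "  partial_charge REAL,\n  formal_charge INTEGER,\n",
        "  charge_group_id INTEGER,\n",
        "  rfos_contribution REAL,\n",
        "  solvation_group_id INTEGER,\n",
        "  bound_partners TEXT,\n",
        "  zmatrix_references TEXT,\n",
        "  zmatrix_values TEXT\n)"
      )
    )
  }
}

# DDL for one coordinate-tier (snapshot) table
.snapshot_table_ddl <- function(table, dialect = "sqlite") {
  if (dialect == "postgres") {
    sprintf(
      paste0(
        "CREATE TABLE IF NOT EXISTS %s (\n",
        "  ens_id BIGINT NOT NULL,\n  snap_id BIGINT PRIMARY KEY,\n",
        "  sim_step BIGINT,\n  previous_id BIGINT,\n",
        "  previous_rank INTEGER,\n  previous_snap BIGINT,\n",
        "  sampler_id SMALLINT,\n  trajectories atomxyz[],\n",
        "  box DOUBLE PRECISION[12]\n)"
      ), table
    )
  } else {
    sprintf(
      paste0(
        "CREATE TABLE IF NOT EXISTS %s (\n",
        "  ens_id INTEGER NOT NULL,\n  snap_id INTEGER PRIMARY KEY,\n",
        "  sim_step INTEGER,\n  previous_id INTEGER,\n",
        "  previous_rank INTEGER,\n  previous_snap INTEGER,\n",
        "  sampler_id INTEGER,\n  trajectories BLOB,\n  box BLOB\n)"
      ), table
    )
  }
}

#' Open (and initialize) a trajectory database
#'
#' Connects to an SQLite database file (or `":memory:"`) and creates the
#' fixed tables of the standard if they are absent.
#'
#' @param path Database file path, or `":memory:"` for a transient store.
#' @return A `DBIConnection`; pass it as the first argument to the
#'   deposition/retrieval functions and close it with [ts_disconnect()].
#' @export
#' @examples
#' con <- ts_connect(":memory:")
#' ts_disconnect(con)
ts_connect <- function(path = ":memory:") {
  con <- DBI::dbConnect(RSQLite::SQLite(), path)
  DBI::dbExecute(con, "PRAGMA foreign_keys = ON")
  ts_init(con)
  con
}

#' Create the fixed tables of the standard on a connection
#'
#' Idempotent: safe to call on an already-initialized database.
#'
#' @param con A `DBIConnection` from [ts_connect()].
#' @return The connection, invisibly.
#' @export
ts_init <- function(con) {
  for (stmt in emit_schema(dialect = "sqlite")) DBI::dbExecute(con, stmt)
  if (nrow(DBI::dbGetQuery(con, "SELECT * FROM atomxyz_type")) == 0L) {
    DBI::dbExecute(con, paste0(
      "INSERT INTO atomxyz_type VALUES ",
      "('atom_seq INTEGER', 'x DOUBLE PRECISION', ",
      "'y DOUBLE PRECISION', 'z DOUBLE PRECISION')"
    ))
  }
  invisible(con)
}

#' Close a trajectory database connection
#'
#' @param con A `DBIConnection`.
#' @return Invisibly `TRUE`.
#' @export
ts_disconnect <- function(con) {
  DBI::dbDisconnect(con)
  invisible(TRUE)
}

# ---- serialization helpers (SQLite dialect) --------------------------------

# space-separated text for int/real array columns; %.17g round-trips doubles
.pack_nums <- function(x) paste(sprintf("%.17g", as.numeric(x)), collapse = " ")
.pack_ints <- function(x) paste(as.integer(x), collapse = " ")
.unpack_nums <- function(s) as.numeric(strsplit(s, " ", fixed = TRUE)[[1]])
.unpack_ints <- function(s) as.integer(strsplit(s, " ", fixed = TRUE)[[1]])

# residues array <-> single text cell (tokens contain no whitespace)
.pack_residues <- function(res) paste(res, collapse = " ")
.unpack_residues <- function(s) {
  if (is.na(s) || !nzchar(s)) character() else strsplit(s, " ", fixed = TRUE)[[1]]
}

# trajectories payload: n (int32), atom_seq[n] (int32), then x,y,z per atom
# (doubles); bit-exact round trip by construction
.pack_traj_blob <- function(atom_seqs, coords) {
  n <- length(atom_seqs)
  c(
    writeBin(as.integer(n), raw(), size = 4L, endian = "little"),
    writeBin(as.integer(atom_seqs), raw(), size = 4L, endian = "little"),
    writeBin(as.numeric(t(coords)), raw(), size = 8L, endian = "little")
  )
}

.unpack_traj_blob <- function(blob) {
  n <- readBin(blob, "integer", n = 1L, size = 4L, endian = "little")
  seqs <- readBin(blob[-(1:4)], "integer", n = n, size = 4L,
                  endian = "little")
  xyz <- readBin(blob[-(1:(4L + 4L * n))], "double", n = 3L * n, size = 8L,
                 endian = "little")
  m <- cbind(
    atom_seq = as.numeric(seqs),
    matrix(xyz, ncol = 3L, byrow = TRUE,
           dimnames = list(NULL, c("x", "y", "z")))
  )
  m
}

.pack_box_blob <- function(box12) {
  stopifnot(length(box12) == 12L)
  writeBin(as.numeric(box12), raw(), size = 8L, endian = "little")
}

.unpack_box_blob <- function(blob) {
  readBin(blob, "double", n = length(blob) %/% 8L, size = 8L,
          endian = "little")
}
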