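#' Assemble a system description for deposition
#'
#' A system couples the per-atom annotation of the atoms tier with the
#' residue listing of the ensemble tier. `atoms` carries one row per atom;
#' topology (covalent neighbours and Z-matrix) is carried as integer/real
#' matrices aligned with the rows.
#'
#' @param atoms data.frame with columns `atom_seq`, `sys_seq`, `atom_name`
#'   (<= 5 chars), `resid_seq`, `resid_name` (<= 4 chars), `chain_seq`
#'   (<= 2 chars), `keyword` ("ATOM" or "HETATM"), `occupancy` (must be 1),
#'   `tempfactor`, `biotype`, `molecule_id`, `mass`, `partial_charge`,
#'   `formal_charge`, `charge_group_id`, `rfos_contribution`,
#'   `solvation_group_id`. Missing annotation columns are filled with
#'   neutral defaults (`occupancy` 1, numeric fields 0).
#' @param residues Character vector of residue-name tokens, in chain order.
#' @param bound_partners n x 5 integer matrix of covalent neighbours as
#'   `atom_seq` values, 0-padded. Default: all zero (no topology).
#' @param zmatrix_references n x 4 integer matrix: bond, angle and torsion
#'   reference `atom_seq` values (0 if absent) plus the chirality
#'   indicator (-1, 0 or 1; 0 means the third value is a dihedral).
#' @param zmatrix_values n x 3 numeric matrix: bond length (Angstrom),
#'   bond angle (degrees), dihedral or second bond angle (degrees).
#' @return An object of class `atom_system`.
#' @export
atom_system <- function(atoms, residues,
                        bound_partners = NULL,
                        zmatrix_references = NULL,
                        zmatrix_values = NULL) {
  n <- nrow(atoms)
  if (is.null(n) || n < 1L) stop("system must contain at least one atom",
                                 call. = FALSE)
  defaults <- list(
    sys_seq = seq_len(n), resid_seq = 1L, resid_name = "UNK",
    chain_seq = "A", keyword = "ATOM", occupancy = 1.0, tempfactor = 0.0,
    biotype = 0L, molecule_id = 1L, mass = 0.0, partial_charge = 0.0,
    formal_charge = 0L, charge_group_id = 0L, rfos_contribution = 0.0,
    solvation_group_id = 0L
  )
  if (!"atom_seq" %in% names(atoms)) atoms$atom_seq <- seq_len(n)
  if (!"atom_name" %in% names(atoms)) {
    stop("atoms must have an 'atom_name' column", call. = FALSE)
  }
  for (f in names(defaults)) {
    if (!f %in% names(atoms)) atoms[[f]] <- defaults[[f]]
  }
  atoms <- atoms[, c("atom_seq", "sys_seq", "atom_name", "resid_seq",
                     "resid_name", "chain_seq", "keyword", "occupancy",
                     "tempfactor", "biotype", "molecule_id", "mass",
                     "partial_charge", "formal_charge", "charge_group_id",
                     "rfos_contribution", "solvation_group_id")]
  if (!identical(sort(atoms$atom_seq), seq_len(n)) ||
      !identical(as.integer(atoms$atom_seq), seq_len(n))) {
    stop("atom_seq must be the contiguous range 1..n in order",
         call. = FALSE)
  }
  if (any(atoms$occupancy != 1.0)) {
    stop("occupancy must be 1.0 for every atom", call. = FALSE)
  }
  if (any(nchar(atoms$atom_name) > 5L)) stop("atom_name exceeds 5 chars",
                                             call. = FALSE)
  if (any(nchar(atoms$resid_name) > 4L)) stop("resid_name exceeds 4 chars",
                                              call. = FALSE)
  if (any(nchar(atoms$chain_seq) > 2L)) stop("chain_seq exceeds 2 chars",
                                             call. = FALSE)
  if (!all(atoms$keyword %in% c("ATOM", "HETATM"))) {
    stop("keyword must be 'ATOM' or 'HETATM'", call. = FALSE)
  }
  if (is.null(bound_partners)) bound_partners <- matrix(0L, n, 5L)
  if (is.null(zmatrix_references)) zmatrix_references <- matrix(0L, n, 4L)
  if (is.null(zmatrix_values)) zmatrix_values <- matrix(0, n, 3L)
  bound_partners <- matrix(as.integer(bound_partners), n, 5L)
  zmatrix_references <- matrix(as.integer(zmatrix_references), n, 4L)
  zmatrix_values <- matrix(as.numeric(zmatrix_values), n, 3L)
  bp <- bound_partners
  if (any(bp < 0L) || any(bp > n)) {
    stop("bound_partners entries must be 0 or valid atom_seq values",
         call. = FALSE)
  }
  for (i in seq_len(n)) {
    for (j in bp[i, ][bp[i, ] > 0L]) {
      if (!i %in% bp[j, ]) {
        stop(sprintf(
          "covalent bonding must be symmetric: atom %d lists %d but not vice versa",
          i, j
        ), call. = FALSE)
      }
    }
  }
  if (!all(zmatrix_references[, 4L] %in% c(-1L, 0L, 1L))) {
    stop("chirality indicator must be -1, 0 or 1", call. = FALSE)
  }
  residues <- as.character(residues)
  if (any(grepl("[[:space:]]", residues))) {
    stop("residue tokens must not contain whitespace", call. = FALSE)
  }
  structure(
    list(atoms = atoms, residues = residues,
         bound_partners = bound_partners,
         zmatrix_references = zmatrix_references,
         zmatrix_values = zmatrix_values),
    class = "atom_system"
  )
}

#' @export
print.atom_system <- function(x, ...) {
  cat(sprintf("<atom_system> %d atoms, %d residue tokens\n",
              nrow(x$atoms), length(x$residues)))
  invisible(x)
}

# field-wise identity of two systems (the first consistency check)
.systems_identical <- function(a, b) {
  isTRUE(all.equal(a$atoms, b$atoms, check.attributes = FALSE,
                   tolerance = 0)) &&
    identical(a$residues, b$residues) &&
    identical(a$bound_partners, b$bound_partners) &&
    identical(a$zmatrix_references, b$zmatrix_references) &&
    isTRUE(all(a$zmatrix_values == b$zmatrix_values))
}

# read a stored system back from the atoms + ensembles tiers
.load_system <- function(con, ens_id) {
  at <- DBI::dbGetQuery(con, sprintf(
    "SELECT * FROM atoms WHERE ens_id = %d ORDER BY atom_seq", ens_id
  ))
  if (nrow(at) == 0L) return(NULL)
  er <- DBI::dbGetQuery(con, sprintf(
    "SELECT residues FROM ensembles WHERE ens_id = %d", ens_id
  ))
  n <- nrow(at)
  bp <- t(vapply(at$bound_partners, .unpack_ints, integer(5L)))
  zr <- t(vapply(at$zmatrix_references, .unpack_ints, integer(4L)))
  zv <- t(vapply(at$zmatrix_values, .unpack_nums, numeric(3L)))
  atoms <- at[, c("atom_seq", "sys_seq", "atom_name", "resid_seq",
                  "resid_name", "chain_seq", "keyword", "occupancy",
                  "tempfactor", "biotype", "molecule_id", "mass",
                  "partial_charge", "formal_charge", "charge_group_id",
                  "rfos_contribution", "solvation_group_id")]
  rownames(atoms) <- NULL
  atom_system(atoms, .unpack_residues(er$residues[1]),
              bound_partners = matrix(bp, n, 5L),
              zmatrix_references = matrix(zr, n, 4L),
              zmatrix_values = matrix(zv, n, 3L))
}

# do any snapshot tables of this ensemble hold data?
.ensemble_has_snapshots <- function(con, ens_id) {
  sims <- DBI::dbGetQuery(con, sprintf(
    "SELECT sim_id, sim_rank FROM simulations WHERE ens_id = %d", ens_id
  ))
  if (nrow(sims) == 0L) return(FALSE)
  for (i in seq_len(nrow(sims))) {
    tab <- snapshot_table_name(sims$sim_id[i], sims$sim_rank[i])
    if (DBI::dbExistsTable(con, tab)) {
      k <- DBI::dbGetQuery(con, sprintf("SELECT COUNT(*) AS n FROM %s", tab))
      if (k$n[1] > 0L) return(TRUE)
    }
  }
  FALSE
}

#' Create an ensemble or reuse an existing one
#'
#' Implements the first consistency check of the data-entry flow. If the
#' key is new, a fresh ensemble id is allocated and the atoms tier is
#' populated. If the key exists and the stored system is field-wise
#' identical to the deposited one, the existing id is returned and nothing
#' is written. If the key exists but no snapshots have been deposited for
#' it, the stored system is overwritten under the same id. A key whose
#' stored system differs while deposited snapshots exist is an integrity
#' error and nothing is written.
#'
#' @param con Database connection.
#' @param key Ensemble key (validated by [validate_ens_key()]).
#' @param system An [atom_system()].
#' @return The integer `ens_id`.
#' @export
open_or_create_ensemble <- function(con, key, system) {
  validate_ens_key(key)
  stopifnot(inherits(system, "atom_system"))
  row <- DBI::dbGetQuery(con, sprintf(
    "SELECT ens_id FROM ensembles WHERE ens_key = %s",
    DBI::dbQuoteString(con, key)
  ))
  n <- nrow(system$atoms)
  if (nrow(row) == 1L) {
    ens_id <- row$ens_id[1]
    stored <- .load_system(con, ens_id)
    if (!is.null(stored) && .systems_identical(stored, system)) {
      return(ens_id)
    }
    if (.ensemble_has_snapshots(con, ens_id)) {
      stop(sprintf(
        "integrity error: key '%s' already holds a different system with deposited snapshots",
        key
      ), call. = FALSE)
    }
    # empty system: overwrite in place under the same ens_id
    DBI::dbWithTransaction(con, {
      DBI::dbExecute(con, sprintf("DELETE FROM atoms WHERE ens_id = %d",
                                  ens_id))
      DBI::dbExecute(con, sprintf(
        "UPDATE ensembles SET nratoms = %d, residues = %s, \"timestamp\" = %s WHERE ens_id = %d",
        n, DBI::dbQuoteString(con, .pack_residues(system$residues)),
        DBI::dbQuoteString(con, format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
        ens_id
      ))
      .insert_atoms(con, ens_id, system)
    })
    return(ens_id)
  }
  ens_id <- DBI::dbGetQuery(
    con, "SELECT COALESCE(MAX(ens_id), 0) + 1 AS i FROM ensembles"
  )$i[1]
  DBI::dbWithTransaction(con, {
    DBI::dbExecute(con, sprintf(
      "INSERT INTO ensembles (ens_id, ens_key, nratoms, residues, \"timestamp\") VALUES (%d, %s, %d, %s, %s)",
      ens_id, DBI::dbQuoteString(con, key), n,
      DBI::dbQuoteString(con, .pack_residues(system$residues)),
      DBI::dbQuoteString(con, format(Sys.time(), "%Y-%m-%d %H:%M:%S"))
    ))
    .insert_atoms(con, ens_id, system)
  })
  ens_id
}

.insert_atoms <- function(con, ens_id, system) {
  n <- nrow(system$atoms)
  base <- DBI::dbGetQuery(
    con, "SELECT COALESCE(MAX(atom_id), 0) AS i FROM atoms"
  )$i[1]
  df <- system$atoms
  out <- data.frame(
    ens_id = ens_id,
    atom_id = base + seq_len(n),
    df,
    stringsAsFactors = FALSE
  )
  out$bound_partners <- apply(system$bound_partners, 1L, .pack_ints)
  out$zmatrix_references <- apply(system$zmatrix_references, 1L, .pack_ints)
  out$zmatrix_values <- apply(system$zmatrix_values, 1L, .pack_nums)
  out <- out[, .ts_columns$atoms]
  DBI::dbAppendTable(con, "atoms", out)
  invisible(NULL)
}

# normalize user metadata (labels or codes) into validated integer codes
.normalize_sim_meta <- function(meta, nratoms) {
  req_codes <- c("box_shape", "box_periodicity", "ensemble_type",
                 "sampler_type", "parallel_mode", "united_atom_model",
                 "deposit_mode")
  out <- list(
    sim_summary = as.character(meta$sim_summary %||% ""),
    sim_software = as.character(meta$sim_software %||% ""),
    nratoms = as.integer(nratoms),
    equilibration_steps = as.integer(meta$equilibration_steps %||% 0L),
    snap_interval = as.integer(meta$snap_interval %||% 1L)
  )
  if (out$equilibration_steps < 0L) {
    stop("equilibration_steps must be >= 0", call. = FALSE)
  }
  if (out$snap_interval < 1L) stop("snap_interval must be >= 1",
                                   call. = FALSE)
  for (f in req_codes) {
    v <- meta[[f]]
    if (is.null(v)) stop(sprintf("metadata field '%s' is required", f),
                         call. = FALSE)
    code <- if (is.character(v)) encode(f, v) else as.integer(v)
    decode(f, code) # validates the code is in the book
    out[[f]] <- code
  }
  .check_shape_periodicity(out$box_shape, out$box_periodicity)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Register a simulation (or a replica ensemble) for an ensemble
#'
#' Allocates one simulation-tier row per trajectory and creates the
#' corresponding empty snapshot table(s). For a replica ensemble, one row
#' is the parent (rank 0, `sim_parent` equal to its own `sim_id`) and the
#' replicas store the parent's `sim_id` in `sim_parent` with ranks
#' 1..n-1; every trajectory has its own `sim_id` (the primary key of the
#' simulation tier) and its snapshot table is named from its own
#' `(sim_id, sim_rank)` pair. Standalone runs are self-parents with
#' rank 0.
#'
#' Re-registering with `sim_id` set to an existing parent performs the
#' second consistency check of the data-entry flow: appending to existing
#' snapshot tables is allowed only when the supplied metadata matches the
#' stored metadata field-wise.
#'
#' @param con Database connection.
#' @param ens_id Ensemble id.
#' @param meta Named list of simulation metadata: `sim_summary`,
#'   `sim_software`, `equilibration_steps`, `snap_interval` and the seven
#'   coded attributes (`box_shape`, `box_periodicity`, `ensemble_type`,
#'   `sampler_type`, `parallel_mode`, `united_atom_model`,
#'   `deposit_mode`), each as a label or an integer code.
#' @param n_replicas Number of coupled trajectories (>= 1).
#' @param sim_id Parent `sim_id` of an already-registered simulation to
#'   append to, or `NULL` (default) to register a new one.
#' @return data.frame with columns `sim_id`, `sim_rank`, `table`.
#' @export
register_simulation <- function(con, ens_id, meta, n_replicas = 1L,
                                sim_id = NULL) {
  ens <- DBI::dbGetQuery(con, sprintf(
    "SELECT nratoms FROM ensembles WHERE ens_id = %d", as.integer(ens_id)
  ))
  if (nrow(ens) != 1L) stop(sprintf("unknown ens_id %s", ens_id),
                            call. = FALSE)
  n_replicas <- as.integer(n_replicas)
  if (n_replicas < 1L) stop("n_replicas must be >= 1", call. = FALSE)
  m <- .normalize_sim_meta(meta, ens$nratoms[1])

  if (!is.null(sim_id)) {
    sim_id <- as.integer(sim_id)
    rows <- DBI::dbGetQuery(con, sprintf(
      "SELECT * FROM simulations WHERE sim_parent = %d ORDER BY sim_rank",
      sim_id
    ))
    if (nrow(rows) == 0L) stop(sprintf("unknown parent sim_id %d", sim_id),
                               call. = FALSE)
    cmp <- c("sim_summary", "sim_software", "nratoms",
             "equilibration_steps", "snap_interval", "box_shape",
             "box_periodicity", "ensemble_type", "sampler_type",
             "parallel_mode", "united_atom_model", "deposit_mode")
    for (f in cmp) {
      if (!identical(rows[[f]][1],
                     if (is.character(rows[[f]])) as.character(m[[f]])
                     else as.integer(m[[f]]))) {
        stop(sprintf(
          "integrity error: metadata field '%s' differs from the registered simulation; appending refused",
          f
        ), call. = FALSE)
      }
    }
    return(data.frame(
      sim_id = rows$sim_id, sim_rank = rows$sim_rank,
      table = snapshot_table_name(rows$sim_id, rows$sim_rank),
      stringsAsFactors = FALSE
    ))
  }

  base <- DBI::dbGetQuery(
    con, "SELECT COALESCE(MAX(sim_id), 0) AS i FROM simulations"
  )$i[1]
  ids <- base + seq_len(n_replicas)
  ranks <- seq_len(n_replicas) - 1L
  parent <- ids[1]
  DBI::dbWithTransaction(con, {
    for (k in seq_len(n_replicas)) {
      DBI::dbExecute(con, sprintf(
        paste0(
          "INSERT INTO simulations (ens_id, sim_id, sim_rank, sim_parent, ",
          "sim_summary, sim_software, nratoms, equilibration_steps, ",
          "snap_interval, box_shape, box_periodicity, ensemble_type, ",
          "sampler_type, parallel_mode, united_atom_model, deposit_mode) ",
          "VALUES (%d, %d, %d, %d, %s, %s, %d, %d, %d, %d, %d, %d, %d, %d, %d, %d)"
        ),
        as.integer(ens_id), ids[k], ranks[k], parent,
        DBI::dbQuoteString(con, m$sim_summary),
        DBI::dbQuoteString(con, m$sim_software),
        m$nratoms, m$equilibration_steps, m$snap_interval,
        m$box_shape, m$box_periodicity, m$ensemble_type, m$sampler_type,
        m$parallel_mode, m$united_atom_model, m$deposit_mode
      ))
      DBI::dbExecute(con, .snapshot_table_ddl(
        snapshot_table_name(ids[k], ranks[k]), "sqlite"
      ))
    }
  })
  data.frame(sim_id = ids, sim_rank = ranks,
             table = snapshot_table_name(ids, ranks),
             stringsAsFactors = FALSE)
}

#' Pack atom indices and coordinates into coordinate-tier 4-tuples
#'
#' @param atom_seqs Strictly increasing integer vector of atom indices
#'   (1-based, aligned with the atoms tier). Subsets are allowed.
#' @param coords Numeric n x 3 matrix of x, y, z (Angstrom).
#' @param precision Optional number of decimals to round coordinates to
#'   before packing (reduced-precision deposition); `NULL` keeps full
#'   double precision.
#' @return n x 4 numeric matrix with columns `atom_seq`, `x`, `y`, `z`.
#' @export
pack_coordinates <- function(atom_seqs, coords, precision = NULL) {
  atom_seqs <- as.integer(atom_seqs)
  coords <- matrix(as.numeric(coords), ncol = 3L)
  if (length(atom_seqs) != nrow(coords)) {
    stop("atom_seqs and coords must have the same length", call. = FALSE)
  }
  if (length(atom_seqs) &&
      (any(atom_seqs < 1L) || any(diff(atom_seqs) <= 0L))) {
    stop("atom_seqs must be strictly increasing and >= 1", call. = FALSE)
  }
  if (!is.null(precision)) coords <- round(coords, precision)
  cbind(atom_seq = as.numeric(atom_seqs),
        matrix(coords, ncol = 3L, dimnames = list(NULL, c("x", "y", "z"))))
}

#' Unpack coordinate-tier 4-tuples
#'
#' Exact inverse of [pack_coordinates()] (at the precision packed).
#'
#' @param packed n x 4 matrix with columns `atom_seq`, `x`, `y`, `z`.
#' @return List with `atom_seqs` (integer) and `coords` (n x 3 matrix).
#' @export
unpack_coordinates <- function(packed) {
  packed <- matrix(as.numeric(packed), ncol = 4L)
  list(atom_seqs = as.integer(packed[, 1L]),
       coords = matrix(packed[, 2:4], ncol = 3L,
                       dimnames = list(NULL, c("x", "y", "z"))))
}

#' Flag absent particles by shifting their coordinates
#'
#' Grand-type ensembles are stored as a fixed superset system including
#' ghost/buffer particles; a particle's physical absence is signalled by a
#' coordinate shift. This package's convention translates absent particles
#' by +L along every axis with L = 2 x (largest box extent); present atoms
#' are assumed to lie inside the primary container, making the flag
#' exactly invertible via [is_ghost()].
#'
#' @param coords n x 3 coordinate matrix (Angstrom).
#' @param present Logical vector of length n; `FALSE` marks ghosts.
#' @param box A [box_descriptor()].
#' @return n x 3 coordinate matrix with ghosts shifted.
#' @export
mark_ghosts <- function(coords, present, box) {
  coords <- matrix(as.numeric(coords), ncol = 3L)
  if (nrow(coords) != length(present)) {
    stop("coords and present must have the same length", call. = FALSE)
  }
  L <- 2 * .box_extent(box)
  coords[!present, ] <- coords[!present, , drop = FALSE] + L
  coords
}

#' Recover the ghost flag from stored coordinates
#'
#' @param coords n x 3 coordinate matrix.
#' @param box The [box_descriptor()] used by [mark_ghosts()].
#' @return Logical vector, `TRUE` for ghosts.
#' @export
is_ghost <- function(coords, box) {
  coords <- matrix(as.numeric(coords), ncol = 3L)
  E <- .box_extent(box)
  ref <- if (box$shape_code %in% c(1L, 4L)) box$origin else box$origin
  rel <- sweep(coords, 2L, ref)
  apply(rel > E, 1L, all)
}

#' Deposit one snapshot into a coordinate-tier table
#'
#' The snapshot id is allocated as the current maximum plus one (starting
#' at 1). Unless given explicitly, `sim_step` is derived as
#' `equilibration_steps + snap_interval * snap_id`, and the backward
#' connectivity triple points at the preceding snapshot of the same table
#' (the sentinel (0,0,0) for the first). Each deposition is committed and
#' visible before the function returns.
#'
#' @param con Database connection.
#' @param sim_id,sim_rank Identify the target snapshot table.
#' @param coords n x 4 packed coordinate matrix from [pack_coordinates()]
#'   (subsets of the system's atoms are allowed).
#' @param box A [box_descriptor()] or a 12-element numeric vector.
#' @param sim_step Original simulation step; `NULL` (default) derives it.
#' @param parent A [lineage_ref()] naming the geometric parent snapshot,
#'   `lineage_ref(0, 0, 0)` to force the no-parent sentinel, or `NULL`
#'   (default) for the preceding snapshot of the same table.
#' @param sampler_id Integer sampler code for the move that produced this
#'   snapshot; defaults to the simulation's `sampler_type`.
#' @return The allocated integer `snap_id`.
#' @export
deposit_snapshot <- function(con, sim_id, sim_rank, coords, box,
                             sim_step = NULL, parent = NULL,
                             sampler_id = NULL) {
  tab <- snapshot_table_name(sim_id, sim_rank)
  if (!DBI::dbExistsTable(con, tab)) {
    stop(sprintf("unknown snapshot table %s; register the simulation first",
                 tab), call. = FALSE)
  }
  sim <- DBI::dbGetQuery(con, sprintf(
    "SELECT ens_id, nratoms, equilibration_steps, snap_interval, sampler_type FROM simulations WHERE sim_id = %d AND sim_rank = %d",
    as.integer(sim_id), as.integer(sim_rank)
  ))
  coords <- matrix(as.numeric(coords), ncol = 4L)
  seqs <- as.integer(coords[, 1L])
  if (length(seqs) > sim$nratoms[1]) {
    stop("snapshot has more coordinate tuples than the system has atoms",
         call. = FALSE)
  }
  if (any(seqs < 1L) || any(seqs > sim$nratoms[1])) {
    stop(sprintf("atom_seq out of range 1..%d", sim$nratoms[1]),
         call. = FALSE)
  }
  if (length(seqs) > 1L && any(diff(seqs) <= 0L)) {
    stop("atom_seq entries must be strictly increasing", call. = FALSE)
  }
  box12 <- if (inherits(box, "box_descriptor")) encode_box(box) else {
    as.numeric(box)
  }
  if (length(box12) != 12L) stop("box must have exactly 12 elements",
                                 call. = FALSE)
  snap_id <- DBI::dbGetQuery(con, sprintf(
    "SELECT COALESCE(MAX(snap_id), 0) + 1 AS i FROM %s", tab
  ))$i[1]
  if (is.null(sim_step)) {
    sim_step <- sim$equilibration_steps[1] + sim$snap_interval[1] * snap_id
  }
  if (is.null(parent)) {
    parent <- if (snap_id > 1L) {
      lineage_ref(sim_id, sim_rank, snap_id - 1L)
    } else {
      lineage_ref(0L, 0L, 0L)
    }
  }
  stopifnot(inherits(parent, "lineage_ref"))
  if (!is_nil_ref(parent)) {
    ptab <- snapshot_table_name(parent["sim_id"], parent["sim_rank"])
    ok <- DBI::dbExistsTable(con, ptab) && nrow(DBI::dbGetQuery(
      con, sprintf("SELECT snap_id FROM %s WHERE snap_id = %d",
                   ptab, parent["snap_id"])
    )) == 1L
    if (!ok) {
      stop(sprintf(
        "integrity error: parent snapshot (%d, %d, %d) does not exist",
        parent["sim_id"], parent["sim_rank"], parent["snap_id"]
      ), call. = FALSE)
    }
  }
  if (is.null(sampler_id)) sampler_id <- sim$sampler_type[1]
  row <- data.frame(
    ens_id = sim$ens_id[1], snap_id = snap_id,
    sim_step = as.integer(sim_step),
    previous_id = unname(parent["sim_id"]),
    previous_rank = unname(parent["sim_rank"]),
    previous_snap = unname(parent["snap_id"]),
    sampler_id = as.integer(sampler_id)
  )
  row$trajectories <- I(list(.pack_traj_blob(seqs, coords[, 2:4,
                                                          drop = FALSE])))
  row$box <- I(list(.pack_box_blob(box12)))
  DBI::dbAppendTable(con, tab, row)
  snap_id
}

#' Deposit a stream of frames into one snapshot table
#'
#' Convenience wrapper around [deposit_snapshot()]. By default every frame
#' is committed individually (each row is validated and visible after each
#' deposition); `batch` groups commits for throughput.
#'
#' @param con Database connection.
#' @param sim_id,sim_rank Target snapshot table.
#' @param frames List of n x 3 coordinate matrices (full systems) or
#'   n x 4 packed matrices (subsets).
#' @param box One [box_descriptor()]/12-vector for all frames, or a list
#'   of one per frame.
#' @param sim_steps Optional integer vector of explicit simulation steps.
#' @param parents Optional list of [lineage_ref()] parents per frame
#'   (`NULL` entries take the sequential default).
#' @param batch Commit every `batch` rows (default 1, per-row commit).
#' @param precision Optional decimal rounding applied before packing.
#' @return Integer vector of allocated snapshot ids.
#' @export
deposit_trajectory <- function(con, sim_id, sim_rank, frames, box,
                               sim_steps = NULL, parents = NULL,
                               batch = 1L, precision = NULL) {
  n <- length(frames)
  ids <- integer(n)
  boxes <- if (is.list(box) && !inherits(box, "box_descriptor")) box else {
    rep(list(box), n)
  }
  one <- function(i) {
    fr <- frames[[i]]
    packed <- if (ncol(fr) == 4L) fr else {
      pack_coordinates(seq_len(nrow(fr)), fr, precision = precision)
    }
    deposit_snapshot(
      con, sim_id, sim_rank, packed, boxes[[i]],
      sim_step = if (is.null(sim_steps)) NULL else sim_steps[i],
      parent = if (is.null(parents)) NULL else parents[[i]]
    )
  }
  batch <- max(1L, as.integer(batch))
  i <- 1L
  while (i <= n) {
    j <- min(n, i + batch - 1L)
    if (batch > 1L) {
      DBI::dbWithTransaction(con, for (k in i:j) ids[k] <- one(k))
    } else {
      for (k in i:j) ids[k] <- one(k)
    }
    i <- j + 1L
  }
  ids
}
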