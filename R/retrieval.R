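#' Describe a snapshot / atom selection
#'
#' Selections are resolved client-side into explicit, sorted id lists, so
#' a request always maps to a deterministic slice of the data.
#'
#' @param snaps `NULL` for all snapshots, a `c(start, stop)` or
#'   `c(start, stop, stride)` range (1-based, inclusive), or an explicit
#'   vector of snapshot ids via `ids`.
#' @param ids Explicit snapshot id vector (overrides `snaps`).
#' @param atom_name Pattern matched against `atom_name`; substring
#'   semantics by default (an exact match with `exact_name = TRUE`).
#' @param molecule_id Restrict to these molecule ids.
#' @param keyword Restrict to `"ATOM"` or `"HETATM"` rows.
#' @param atom_seq Explicit atom index vector.
#' @param exact_name Use exact atom-name matching instead of substring.
#' @return An object of class `selection_spec`.
#' @export
selection_spec <- function(snaps = NULL, ids = NULL, atom_name = NULL,
                           molecule_id = NULL, keyword = NULL,
                           atom_seq = NULL, exact_name = FALSE) {
  if (!is.null(snaps)) {
    if (!length(snaps) %in% 2:3 || any(snaps < 1)) {
      stop("snaps must be c(start, stop) or c(start, stop, stride), 1-based",
           call. = FALSE)
    }
  }
  structure(
    list(snaps = snaps, ids = if (is.null(ids)) NULL else {
      sort(unique(as.integer(ids)))
    },
    atom_name = atom_name, molecule_id = molecule_id,
    keyword = keyword,
    atom_seq = if (is.null(atom_seq)) NULL else {
      sort(unique(as.integer(atom_seq)))
    },
    exact_name = isTRUE(exact_name)),
    class = "selection_spec"
  )
}

# selection -> sorted snapshot id vector, given the ids present in a table
.resolve_snaps <- function(sel, present_ids) {
  if (!is.null(sel$ids)) return(sel$ids)
  if (is.null(sel$snaps)) return(sort(present_ids))
  s <- sel$snaps
  stride <- if (length(s) == 3L) s[3] else 1L
  sort(unique(as.integer(seq(s[1], s[2], by = stride))))
}

# selection -> atom_seq filter set (NULL = all atoms) using the atoms tier
.resolve_atoms <- function(con, ens_id, sel) {
  if (is.null(sel$atom_name) && is.null(sel$molecule_id) &&
      is.null(sel$keyword) && is.null(sel$atom_seq)) {
    return(NULL)
  }
  at <- DBI::dbGetQuery(con, sprintf(
    "SELECT atom_seq, atom_name, molecule_id, keyword FROM atoms WHERE ens_id = %d",
    ens_id
  ))
  keep <- rep(TRUE, nrow(at))
  if (!is.null(sel$atom_name)) {
    nm <- trimws(at$atom_name)
    keep <- keep & if (sel$exact_name) nm == sel$atom_name else {
      grepl(sel$atom_name, nm, fixed = TRUE)
    }
  }
  if (!is.null(sel$molecule_id)) keep <- keep & at$molecule_id %in%
      sel$molecule_id
  if (!is.null(sel$keyword)) keep <- keep & trimws(at$keyword) %in%
      sel$keyword
  if (!is.null(sel$atom_seq)) keep <- keep & at$atom_seq %in% sel$atom_seq
  sort(at$atom_seq[keep])
}

#' List all ensembles in the database
#'
#' @param con Database connection.
#' @return data.frame with `ens_key`, `ens_id`, `nratoms`, `timestamp`,
#'   sorted by key; zero rows on an empty database.
#' @export
list_keys <- function(con) {
  out <- DBI::dbGetQuery(con, paste0(
    "SELECT ens_key, ens_id, nratoms, \"timestamp\" AS timestamp ",
    "FROM ensembles ORDER BY ens_key"
  ))
  out
}

#' Snapshot tables associated with an ensemble key
#'
#' Table names are generated from the simulation tier as
#' `snapshots_<sim_id>_<sim_rank>` and sorted by `sim_parent` and then
#' `sim_rank`, so trajectory ensembles appear as contiguous, rank-ordered
#' blocks regardless of registration order.
#'
#' @param con Database connection.
#' @param ens_key Ensemble key.
#' @return Character vector of snapshot-table names.
#' @export
tables_for_key <- function(con, ens_key) {
  row <- DBI::dbGetQuery(con, sprintf(
    "SELECT ens_id FROM ensembles WHERE ens_key = %s",
    DBI::dbQuoteString(con, ens_key)
  ))
  if (nrow(row) != 1L) stop(sprintf("unknown ens_key '%s'", ens_key),
                            call. = FALSE)
  out <- DBI::dbGetQuery(con, sprintf(
    paste0(
      "SELECT 'snapshots_' || sim_id || '_' || sim_rank AS tab ",
      "FROM simulations WHERE ens_id = %d ",
      "ORDER BY sim_parent, sim_rank"
    ), row$ens_id[1]
  ))
  out$tab
}

#' Search free-text simulation summaries
#'
#' Performs a substring search over `sim_summary`. SQL wildcard
#' characters in the needle are escaped, so `"100%"` matches only the
#' literal text.
#'
#' @param con Database connection.
#' @param needle Nonempty search text.
#' @param ignore_case Case-insensitive matching (default `FALSE`).
#' @return data.frame with `ens_id`, `sim_id`, `sim_rank` of matches.
#' @export
search_summaries <- function(con, needle, ignore_case = FALSE) {
  if (!is.character(needle) || length(needle) != 1L || !nzchar(needle)) {
    stop("needle must be a nonempty string", call. = FALSE)
  }
  # instr() gives literal substring semantics: LIKE-pattern wildcards in
  # the needle need no escaping and match only themselves
  field <- if (ignore_case) "LOWER(sim_summary)" else "sim_summary"
  pat <- if (ignore_case) tolower(needle) else needle
  DBI::dbGetQuery(con, sprintf(
    paste0(
      "SELECT ens_id, sim_id, sim_rank FROM simulations ",
      "WHERE INSTR(%s, %s) > 0 ORDER BY sim_id, sim_rank"
    ),
    field, DBI::dbQuoteString(con, pat)
  ))
}

#' Fetch simulation metadata with decoded labels
#'
#' @param con Database connection.
#' @param sim_id,sim_rank Identify the simulation-tier row.
#' @return List with the full simulation record (`record`) and the
#'   decoded labels of its seven coded attributes (`labels`).
#' @export
fetch_metadata <- function(con, sim_id, sim_rank) {
  row <- DBI::dbGetQuery(con, sprintf(
    "SELECT * FROM simulations WHERE sim_id = %d AND sim_rank = %d",
    as.integer(sim_id), as.integer(sim_rank)
  ))
  if (nrow(row) != 1L) {
    stop(sprintf("unknown simulation (%s, %s)", sim_id, sim_rank),
         call. = FALSE)
  }
  coded <- c("box_shape", "box_periodicity", "ensemble_type",
             "sampler_type", "parallel_mode", "united_atom_model",
             "deposit_mode")
  labels <- vapply(coded, function(f) decode(f, row[[f]][1]), character(1L))
  list(record = as.list(row), labels = as.list(labels))
}

#' Fetch coordinates (and boxes) for a snapshot selection
#'
#' For each selected snapshot, in ascending `snap_id` order, returns the
#' coordinate 4-tuples matching the atom filter (ascending `atom_seq`)
#' together with the snapshot's 12-element box and step. Atom-name
#' filtering uses substring semantics by default, mirroring SQL
#' `LIKE '%CA%'` (which also matches e.g. `"CA2"`); pass
#' `exact_name = TRUE` in the selection for strict matching.
#'
#' @param con Database connection.
#' @param sim_id,sim_rank Identify the snapshot table.
#' @param selection A [selection_spec()]; default selects everything.
#' @return List of per-snapshot lists with elements `snap_id`, `sim_step`,
#'   `coords` (m x 4 matrix: atom_seq, x, y, z) and `box` (length-12
#'   numeric).
#' @export
fetch_coordinates <- function(con, sim_id, sim_rank,
                              selection = selection_spec()) {
  tab <- snapshot_table_name(sim_id, sim_rank)
  if (!DBI::dbExistsTable(con, tab)) {
    stop(sprintf("unknown snapshot table %s", tab), call. = FALSE)
  }
  sim <- DBI::dbGetQuery(con, sprintf(
    "SELECT ens_id FROM simulations WHERE sim_id = %d AND sim_rank = %d",
    as.integer(sim_id), as.integer(sim_rank)
  ))
  present <- DBI::dbGetQuery(con, sprintf(
    "SELECT snap_id FROM %s", tab
  ))$snap_id
  ids <- .resolve_snaps(selection, present)
  missing <- setdiff(ids, present)
  if (length(missing)) {
    stop(sprintf("snapshot id(s) out of range: %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  atom_set <- .resolve_atoms(con, sim$ens_id[1], selection)
  lapply(ids, function(id) {
    row <- DBI::dbGetQuery(con, sprintf(
      "SELECT sim_step, trajectories, box FROM %s WHERE snap_id = %d",
      tab, id
    ))
    m <- .unpack_traj_blob(row$trajectories[[1]])
    if (!is.null(atom_set)) {
      m <- m[m[, "atom_seq"] %in% atom_set, , drop = FALSE]
    }
    list(snap_id = id, sim_step = row$sim_step[1], coords = m,
         box = .unpack_box_blob(row$box[[1]]))
  })
}
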