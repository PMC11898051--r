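#' Address a snapshot by (sim_id, sim_rank, snap_id)
#'
#' A lineage reference is the unit of backward-connectivity traversal:
#' `sim_id` and `sim_rank` construct the snapshot-table name and `snap_id`
#' selects the row. The nil reference (0, 0, 0) marks "no geometric
#' parent".
#'
#' @param sim_id,sim_rank,snap_id Integers (all 0 for the nil reference).
#' @return Named integer vector of class `lineage_ref`.
#' @export
lineage_ref <- function(sim_id, sim_rank, snap_id) {
  out <- c(sim_id = as.integer(sim_id), sim_rank = as.integer(sim_rank),
           snap_id = as.integer(snap_id))
  if (any(is.na(out)) || any(out < 0L)) {
    stop("lineage reference components must be non-negative integers",
         call. = FALSE)
  }
  class(out) <- "lineage_ref"
  out
}

#' @export
print.lineage_ref <- function(x, ...) {
  cat(sprintf("<lineage_ref> sim %d rank %d snap %d\n",
              x["sim_id"], x["sim_rank"], x["snap_id"]))
  invisible(x)
}

#' Is a lineage reference the no-parent sentinel?
#'
#' @param ref A [lineage_ref()].
#' @return Logical scalar.
#' @export
is_nil_ref <- function(ref) {
  all(unclass(ref) == 0L)
}

# read one snapshot row's backward triple; NULL if the row is absent
.read_parent_triple <- function(con, ref) {
  tab <- snapshot_table_name(ref["sim_id"], ref["sim_rank"])
  if (!DBI::dbExistsTable(con, tab)) return(NULL)
  row <- DBI::dbGetQuery(con, sprintf(
    "SELECT previous_id, previous_rank, previous_snap FROM %s WHERE snap_id = %d",
    tab, ref["snap_id"]
  ))
  if (nrow(row) != 1L) return(NULL)
  row
}

#' Geometric parent of a snapshot
#'
#' Returns the backward-connectivity triple stored on the referenced row,
#' or `NULL` when the no-parent sentinel is stored.
#'
#' @param con Database connection.
#' @param ref A [lineage_ref()] that resolves to a stored snapshot.
#' @return A [lineage_ref()] or `NULL`.
#' @export
parent_of <- function(con, ref) {
  stopifnot(inherits(ref, "lineage_ref"))
  row <- .read_parent_triple(con, ref)
  if (is.null(row)) {
    stop(sprintf("snapshot (%d, %d, %d) does not exist",
                 ref["sim_id"], ref["sim_rank"], ref["snap_id"]),
         call. = FALSE)
  }
  p <- lineage_ref(row$previous_id, row$previous_rank, row$previous_snap)
  if (is_nil_ref(p)) return(NULL)
  if (is.null(.read_parent_triple(con, p))) {
    stop(sprintf(
      "integrity error: dangling parent (%d, %d, %d) of snapshot (%d, %d, %d)",
      p["sim_id"], p["sim_rank"], p["snap_id"],
      ref["sim_id"], ref["sim_rank"], ref["snap_id"]
    ), call. = FALSE)
  }
  p
}

#' Trace the geometric lineage of a snapshot
#'
#' Follows backward-connectivity triples from `ref` towards the origin,
#' verifying acyclicity on the way.
#'
#' @param con Database connection.
#' @param ref A [lineage_ref()].
#' @param max_depth Maximum number of ancestors to collect (default
#'   unlimited).
#' @return data.frame with columns `sim_id`, `sim_rank`, `snap_id`,
#'   ordered from the oldest collected ancestor to `ref` itself.
#' @export
trace_lineage <- function(con, ref, max_depth = Inf) {
  stopifnot(inherits(ref, "lineage_ref"))
  if (is.null(.read_parent_triple(con, ref))) {
    stop(sprintf("snapshot (%d, %d, %d) does not exist",
                 ref["sim_id"], ref["sim_rank"], ref["snap_id"]),
         call. = FALSE)
  }
  chain <- list(ref)
  seen <- new.env(parent = emptyenv())
  assign(paste(unclass(ref), collapse = "_"), TRUE, envir = seen)
  cur <- ref
  depth <- 0L
  while (depth < max_depth) {
    p <- parent_of(con, cur)
    if (is.null(p)) break
    key <- paste(unclass(p), collapse = "_")
    if (exists(key, envir = seen)) {
      stop("integrity error: cycle detected in backward connectivity map",
           call. = FALSE)
    }
    assign(key, TRUE, envir = seen)
    chain[[length(chain) + 1L]] <- p
    cur <- p
    depth <- depth + 1L
  }
  chain <- rev(chain)
  data.frame(
    sim_id = vapply(chain, `[[`, integer(1L), "sim_id"),
    sim_rank = vapply(chain, `[[`, integer(1L), "sim_rank"),
    snap_id = vapply(chain, `[[`, integer(1L), "snap_id")
  )
}

#' Demultiplex a trajectory ensemble into continuous trajectories
#'
#' For a parallel simulation (replica exchange, PIGS or other adaptive
#' sampling), the per-rank snapshot tables hold condition-ordered data:
#' after an exchange, the geometric continuation of a conformation lives
#' in a partner's table. Demultiplexing traces every member's terminal
#' frame backwards through the connectivity map, yielding one
#' geometrically continuous trajectory per terminal.
#'
#' For replica exchange the resulting lineages partition the deposited
#' frames (a permutation at each time slice); violations raise an
#' integrity error. For adaptive reseeding, lineages may share prefixes
#' (frames are stored once); shared frames are reported in the
#' `branch_points` attribute.
#'
#' @param con Database connection.
#' @param parent_sim_id `sim_id` of the ensemble parent.
#' @return Named list, one data.frame of `(sim_id, sim_rank, snap_id)` per
#'   member rank (`"traj_<rank>"`), each ordered from origin to terminal
#'   frame. Attribute `branch_points` lists frames shared between
#'   lineages (adaptive sampling only).
#' @export
demultiplex <- function(con, parent_sim_id) {
  parent_sim_id <- as.integer(parent_sim_id)
  members <- DBI::dbGetQuery(con, sprintf(
    "SELECT sim_id, sim_rank, parallel_mode FROM simulations WHERE sim_parent = %d ORDER BY sim_rank",
    parent_sim_id
  ))
  if (nrow(members) == 0L) {
    stop(sprintf("unknown parent sim_id %d", parent_sim_id), call. = FALSE)
  }
  mode <- members$parallel_mode[1]
  if (!mode %in% c(1L, 2L, 5L)) {
    stop(sprintf(
      "sim %d has parallel_mode %d (%s); demultiplexing applies to replica exchange / adaptive schemes",
      parent_sim_id, mode, decode("parallel_mode", mode)
    ), call. = FALSE)
  }
  out <- list()
  keyspace <- character()
  branch <- character()
  for (i in seq_len(nrow(members))) {
    tab <- snapshot_table_name(members$sim_id[i], members$sim_rank[i])
    if (!DBI::dbExistsTable(con, tab)) {
      stop(sprintf("missing snapshot table %s", tab), call. = FALSE)
    }
    last <- DBI::dbGetQuery(con, sprintf(
      "SELECT MAX(snap_id) AS i FROM %s", tab
    ))$i[1]
    if (is.na(last)) next # empty member
    lin <- trace_lineage(
      con, lineage_ref(members$sim_id[i], members$sim_rank[i], last)
    )
    keys <- sprintf("%d_%d_%d", lin$sim_id, lin$sim_rank, lin$snap_id)
    dup <- keys[keys %in% keyspace]
    if (length(dup)) {
      if (mode == 1L) {
        stop("integrity error: replica-exchange lineages overlap (forward map is not one-to-many)",
             call. = FALSE)
      }
      branch <- c(branch, dup)
    }
    keyspace <- c(keyspace, keys)
    out[[sprintf("traj_%d", members$sim_rank[i])]] <- lin
  }
  attr(out, "branch_points") <- unique(branch)
  out
}
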