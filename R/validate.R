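# append one violation row
.viol <- function(df, tier, ens_id, object, problem) {
  rbind(df, data.frame(tier = tier, ens_id = as.integer(ens_id),
                       object = object, problem = problem,
                       stringsAsFactors = FALSE))
}

#' Validate database integrity
#'
#' Exercises the redundancy built into the standard: cross-tier atom
#' counts, atom-index contiguity, symmetric covalent topology, occupancy,
#' code-book membership and shape/periodicity admissibility, existence
#' and well-formedness of every snapshot table (atom indices in range and
#' strictly increasing, 12-element boxes), and resolvable, acyclic
#' backward connectivity. Read-only: no repair is attempted.
#'
#' @param con Database connection.
#' @return data.frame of violations with columns `tier`, `ens_id`,
#'   `object`, `problem`; zero rows for a healthy database.
#' @export
validate_database <- function(con) {
  v <- data.frame(tier = character(), ens_id = integer(),
                  object = character(), problem = character(),
                  stringsAsFactors = FALSE)
  ens <- DBI::dbGetQuery(con, "SELECT * FROM ensembles")
  sims <- DBI::dbGetQuery(con, "SELECT * FROM simulations")

  for (i in seq_len(nrow(ens))) {
    eid <- ens$ens_id[i]
    key <- ens$ens_key[i]
    if (!grepl("^[A-Za-z0-9_-]+$", key)) {
      v <- .viol(v, "ensembles", eid, key, "ens_key contains forbidden characters")
    }
    at <- DBI::dbGetQuery(con, sprintf(
      "SELECT atom_seq, occupancy, bound_partners FROM atoms WHERE ens_id = %d ORDER BY atom_seq",
      eid
    ))
    if (nrow(at) != ens$nratoms[i]) {
      v <- .viol(v, "ensembles", eid, key, sprintf(
        "nratoms is %d but atoms tier holds %d rows",
        ens$nratoms[i], nrow(at)
      ))
    }
    if (nrow(at) && !identical(as.integer(at$atom_seq),
                               seq_len(nrow(at)))) {
      v <- .viol(v, "atoms", eid, key,
                 "atom_seq is not the contiguous range 1..nratoms")
    }
    if (nrow(at) && any(at$occupancy != 1.0)) {
      bad <- at$atom_seq[at$occupancy != 1.0]
      v <- .viol(v, "atoms", eid, sprintf("atom_seq %d", bad[1]),
                 "occupancy differs from 1.0")
    }
    if (nrow(at)) {
      bp <- t(vapply(at$bound_partners, .unpack_ints, integer(5L)))
      n <- nrow(at)
      oor <- which(apply(bp, 1L, function(r) any(r < 0L | r > n)))
      if (length(oor)) {
        v <- .viol(v, "atoms", eid, sprintf("atom_seq %d", oor[1]),
                   "bound_partners entry is not a valid atom_seq")
      } else {
        for (a in seq_len(n)) {
          for (b in bp[a, ][bp[a, ] > 0L]) {
            if (!a %in% bp[b, ]) {
              v <- .viol(v, "atoms", eid, sprintf("atom_seq %d", a),
                         sprintf("bond %d-%d is not symmetric", a, b))
            }
          }
        }
      }
    }
  }

  books <- code_books()
  for (i in seq_len(nrow(sims))) {
    sid <- sims$sim_id[i]
    rk <- sims$sim_rank[i]
    eid <- sims$ens_id[i]
    obj <- sprintf("sim (%d, %d)", sid, rk)
    e_n <- ens$nratoms[match(eid, ens$ens_id)]
    if (!is.na(e_n) && sims$nratoms[i] != e_n) {
      v <- .viol(v, "simulations", eid, obj, sprintf(
        "simulation nratoms %d differs from ensemble nratoms %d",
        sims$nratoms[i], e_n
      ))
    }
    for (f in names(books)) {
      if (f == "box_periodicity") next # admissibility checked below
      if (!sims[[f]][i] %in% books[[f]]) {
        v <- .viol(v, "simulations", eid, obj, sprintf(
          "%s code %d is outside the code book", f, sims[[f]][i]
        ))
      }
    }
    if (!shape_periodicity_ok(sims$box_shape[i], sims$box_periodicity[i])) {
      v <- .viol(v, "simulations", eid, obj, sprintf(
        "inadmissible (box_shape, box_periodicity) pair (%d, %d)",
        sims$box_shape[i], sims$box_periodicity[i]
      ))
    }
    tab <- sprintf("snapshots_%d_%d", sid, rk)
    if (!DBI::dbExistsTable(con, tab)) {
      v <- .viol(v, "coordinates", eid, obj,
                 sprintf("snapshot table %s is missing", tab))
      next
    }
    sn <- DBI::dbGetQuery(con, sprintf(
      "SELECT snap_id, previous_id, previous_rank, previous_snap, trajectories, box FROM %s ORDER BY snap_id",
      tab
    ))
    for (k in seq_len(nrow(sn))) {
      sobj <- sprintf("%s snap %d", tab, sn$snap_id[k])
      box <- .unpack_box_blob(sn$box[[k]])
      if (length(box) != 12L) {
        v <- .viol(v, "coordinates", eid, sobj,
                   sprintf("box has %d elements, not 12", length(box)))
      }
      m <- tryCatch(.unpack_traj_blob(sn$trajectories[[k]]),
                    error = function(e) NULL)
      if (is.null(m)) {
        v <- .viol(v, "coordinates", eid, sobj,
                   "trajectories payload is unreadable")
      } else {
        seqs <- as.integer(m[, "atom_seq"])
        if (length(seqs) > e_n || any(seqs < 1L) ||
            any(seqs > e_n)) {
          v <- .viol(v, "coordinates", eid, sobj,
                     "trajectories atom indices outside 1..nratoms")
        }
        if (length(seqs) > 1L && any(diff(seqs) <= 0L)) {
          v <- .viol(v, "coordinates", eid, sobj,
                     "trajectories atom indices not strictly increasing")
        }
      }
      trip <- c(sn$previous_id[k], sn$previous_rank[k], sn$previous_snap[k])
      if (!all(trip == 0L)) {
        ptab <- try(snapshot_table_name(trip[1], trip[2]), silent = TRUE)
        ok <- !inherits(ptab, "try-error") &&
          DBI::dbExistsTable(con, ptab) &&
          nrow(DBI::dbGetQuery(con, sprintf(
            "SELECT snap_id FROM %s WHERE snap_id = %d", ptab, trip[3]
          ))) == 1L
        if (!ok) {
          v <- .viol(v, "coordinates", eid, sobj, sprintf(
            "dangling backward reference (%d, %d, %d)",
            trip[1], trip[2], trip[3]
          ))
        }
      }
    }
  }

  # acyclicity of the backward map, per terminal frame
  for (i in seq_len(nrow(sims))) {
    tab <- sprintf("snapshots_%d_%d", sims$sim_id[i], sims$sim_rank[i])
    if (!DBI::dbExistsTable(con, tab)) next
    last <- DBI::dbGetQuery(con, sprintf(
      "SELECT MAX(snap_id) AS i FROM %s", tab
    ))$i[1]
    if (is.na(last)) next
    res <- tryCatch(
      trace_lineage(con, lineage_ref(sims$sim_id[i], sims$sim_rank[i],
                                     last)),
      error = function(e) e
    )
    if (inherits(res, "error") && grepl("cycle", conditionMessage(res))) {
      v <- .viol(v, "coordinates", sims$ens_id[i], tab,
                 "cycle in backward connectivity map")
    }
  }
  v
}
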