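# run expr with a private RNG stream; global .Random.seed is untouched
.with_seed <- function(seed, expr) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = env) else {
      if (exists(".Random.seed", envir = env, inherits = FALSE)) {
        rm(".Random.seed", envir = env)
      }
    }
  })
  set.seed(seed)
  expr
}

.toy_residue_pool <- c("ALA", "GLY", "SER", "VAL", "THR", "LEU")

#' Generate a toy bead-chain system
#'
#' Builds a deterministic linear polymer fixture: per residue three
#' backbone-like atoms (N, CA, C) with real element masses, globally
#' sequential residue numbering, per-chain molecule ids, symmetric
#' covalent topology (N-CA, CA-C, C-N(+1)) and a backward-only Z-matrix
#' with idealized backbone bond lengths/angles and seeded dihedrals.
#' Residue names are drawn (seeded) from a small amino-acid pool.
#'
#' @param n_chains Number of chains (>= 1).
#' @param chain_length Residues per chain (>= 1).
#' @param seed Integer seed; fixtures are bit-reproducible per seed.
#' @return An [atom_system()] with `3 * n_chains * chain_length` atoms.
#' @export
make_toy_system <- function(n_chains, chain_length, seed) {
  stopifnot(n_chains >= 1L, chain_length >= 1L)
  .with_seed(seed, {
    n_res <- n_chains * chain_length
    residues <- sample(.toy_residue_pool, n_res, replace = TRUE)
    n <- 3L * n_res
    per <- c("N", "CA", "C")
    masses <- c(N = 14.007, CA = 12.011, C = 12.011)
    chain_of_res <- rep(seq_len(n_chains), each = chain_length)
    atoms <- data.frame(
      atom_seq = seq_len(n),
      sys_seq = seq_len(n),
      atom_name = rep(per, n_res),
      resid_seq = rep(seq_len(n_res), each = 3L),
      resid_name = rep(residues, each = 3L),
      chain_seq = LETTERS[rep(chain_of_res, each = 3L)],
      keyword = "ATOM",
      occupancy = 1.0,
      tempfactor = 0.0,
      biotype = rep(1:3, n_res),
      molecule_id = rep(chain_of_res, each = 3L),
      mass = unname(masses[rep(per, n_res)]),
      partial_charge = round(stats::rnorm(n, 0, 0.2), 4L),
      formal_charge = 0L,
      charge_group_id = rep(seq_len(n_res), each = 3L),
      rfos_contribution = 0.0,
      solvation_group_id = rep(seq_len(n_res), each = 3L),
      stringsAsFactors = FALSE
    )
    mol <- atoms$molecule_id
    bp <- matrix(0L, n, 5L)
    add_bond <- function(bp, a, b) {
      for (pair in list(c(a, b), c(b, a))) {
        slot <- which(bp[pair[1], ] == 0L)[1]
        bp[pair[1], slot] <- pair[2]
      }
      bp
    }
    for (i in seq_len(n - 1L)) {
      if (mol[i] == mol[i + 1L]) bp <- add_bond(bp, i, i + 1L)
    }
    zr <- matrix(0L, n, 4L)
    zv <- matrix(0, n, 3L)
    # idealized backbone internals: N-CA 1.458, CA-C 1.525, C-N 1.329
    bond_of <- c(N = 1.329, CA = 1.458, C = 1.525)
    angle_of <- c(N = 116.6, CA = 121.9, C = 111.2)
    nm <- atoms$atom_name
    for (i in seq_len(n)) {
      anc <- i - (1:3)
      anc <- ifelse(anc >= 1L & mol[pmax(anc, 1L)] == mol[i], anc, 0L)
      zr[i, 1:3] <- anc
      if (anc[1] > 0L) zv[i, 1L] <- unname(bond_of[nm[i]])
      if (anc[2] > 0L) zv[i, 2L] <- unname(angle_of[nm[i]])
      if (anc[3] > 0L) zv[i, 3L] <- round(stats::runif(1, -180, 180), 3L)
      zr[i, 4L] <- 0L # dihedral interpretation of the third value
    }
    atom_system(atoms, residues, bound_partners = bp,
                zmatrix_references = zr, zmatrix_values = zv)
  })
}

# wrap coordinates into the primary cell along the periodic dimensions
.wrap_coords <- function(coords, box) {
  if (!box$shape_code %in% c(1L, 4L) || box$periodicity_code == 0L) {
    return(coords)
  }
  dims <- match(.periodicity_dims(box$periodicity_code), c("x", "y", "z"))
  V <- box$vectors
  rel <- sweep(coords, 2L, box$origin)
  frac <- rel %*% solve(V) # row-vector convention: point = frac %*% V
  frac[, dims] <- frac[, dims] %% 1
  sweep(frac %*% V, 2L, box$origin, `+`)
}

#' Generate a seeded random-walk trajectory for a system
#'
#' Frame 1 places every atom uniformly inside the primary cell; each
#' subsequent frame adds isotropic Gaussian displacements of standard
#' deviation `step_sigma` and wraps the result back into the cell along
#' the periodic dimensions. No physics is implied; the walk exercises
#' storage, retrieval and connectivity bookkeeping.
#'
#' @param system An [atom_system()].
#' @param n_frames Number of frames (>= 1).
#' @param box A [box_descriptor()] (cuboid or triclinic for wrapping).
#' @param step_sigma Per-step displacement standard deviation (Angstrom);
#'   0 gives identical frames.
#' @param seed Integer seed.
#' @param interval Step interval between saved frames (`sim_step` of
#'   frame k is `k * interval`).
#' @return List with `frames` (list of n x 3 matrices), `sim_steps`
#'   (integer vector) and `box`.
#' @export
random_walk_trajectory <- function(system, n_frames, box, step_sigma,
                                   seed, interval = 1L) {
  stopifnot(inherits(system, "atom_system"), n_frames >= 1L,
            step_sigma >= 0)
  n <- nrow(system$atoms)
  .with_seed(seed, {
    if (box$shape_code %in% c(1L, 4L)) {
      frac <- matrix(stats::runif(3L * n), n, 3L)
      cur <- sweep(frac %*% box$vectors, 2L, box$origin, `+`)
    } else {
      r <- box$radius * stats::runif(n)^(1 / 3)
      u <- matrix(stats::rnorm(3L * n), n, 3L)
      u <- u / sqrt(rowSums(u^2))
      cur <- sweep(u * r, 2L, box$origin, `+`)
    }
    frames <- vector("list", n_frames)
    frames[[1L]] <- .wrap_coords(cur, box)
    if (n_frames > 1L) {
      for (k in 2L:n_frames) {
        cur <- frames[[k - 1L]] +
          matrix(stats::rnorm(3L * n, 0, step_sigma), n, 3L)
        frames[[k]] <- .wrap_coords(cur, box)
      }
    }
    list(frames = frames, sim_steps = as.integer(interval) * seq_len(n_frames),
         box = box)
  })
}

#' Generate a replica-exchange swap schedule with ground-truth lineage
#'
#' At every `swap_every`-th frame a seeded set of disjoint neighbour
#' pairs exchanges conformations (each candidate pair swapping with
#' probability `swap_prob`). The schedule records, for every (frame,
#' replica), the replica whose previous frame is the geometric parent --
#' exactly what the coordinate tier's backward connectivity map stores --
#' plus the per-replica ground-truth continuous lineage used to validate
#' demultiplexing.
#'
#' @param n_replicas Number of replicas (>= 2).
#' @param n_frames Number of frames per replica (>= 1).
#' @param swap_every Attempt swaps at every `swap_every`-th frame.
#' @param seed Integer seed.
#' @param swap_prob Per-pair acceptance probability in `[0, 1]`; 0
#'   disables all swaps.
#' @return List with:
#'   * `parents`: n_frames x n_replicas integer matrix; entry (f, r) is
#'     the replica index whose frame f-1 is the parent of replica r's
#'     frame f (row 1 is 0: no parent);
#'   * `lineages`: list per replica r of the length-`n_frames` vector of
#'     replica indices traversed by the continuous trajectory ending at
#'     replica r's terminal frame;
#'   * `swaps`: data.frame of accepted exchanges (`frame`, `replica_a`,
#'     `replica_b`).
#' @export
replica_exchange_schedule <- function(n_replicas, n_frames, swap_every,
                                      seed, swap_prob = 0.5) {
  stopifnot(n_replicas >= 2L, n_frames >= 1L, swap_every >= 1L,
            swap_prob >= 0, swap_prob <= 1)
  n_replicas <- as.integer(n_replicas)
  n_frames <- as.integer(n_frames)
  swap_every <- as.integer(swap_every)
  .with_seed(seed, {
    parents <- matrix(0L, n_frames, n_replicas)
    swaps <- list()
    if (n_frames > 1L) {
      for (f in 2L:n_frames) {
        parents[f, ] <- seq_len(n_replicas)
        if (f %% swap_every == 0L && swap_prob > 0) {
          # alternate even/odd neighbour pairings across swap attempts
          offset <- (f %/% swap_every + 1L) %% 2L
          first <- if (1L + offset > n_replicas - 1L) integer(0L) else {
            seq.int(1L + offset, n_replicas - 1L, by = 2L)
          }
          for (a in first) {
            b <- a + 1L
            if (stats::runif(1) < swap_prob) {
              parents[f, a] <- b
              parents[f, b] <- a
              swaps[[length(swaps) + 1L]] <- c(f, a, b)
            }
          }
        }
      }
    }
    lineages <- lapply(seq_len(n_replicas), function(r) {
      path <- integer(n_frames)
      cur <- r
      for (f in n_frames:1L) {
        path[f] <- cur
        if (f > 1L) cur <- parents[f, cur]
      }
      path
    })
    swaps <- if (length(swaps)) {
      m <- do.call(rbind, swaps)
      data.frame(frame = m[, 1L], replica_a = m[, 2L], replica_b = m[, 3L])
    } else {
      data.frame(frame = integer(), replica_a = integer(),
                 replica_b = integer())
    }
    list(parents = parents, lineages = lineages, swaps = swaps)
  })
}

#' Deposit a synthetic replica-exchange ensemble
#'
#' Registers a replica ensemble and deposits per-replica random-walk
#' frames wired together by a [replica_exchange_schedule()], so the
#' stored backward connectivity map reflects the schedule exactly.
#'
#' @param con Database connection.
#' @param ens_id Ensemble id (from [open_or_create_ensemble()]).
#' @param meta Simulation metadata (see [register_simulation()]);
#'   `parallel_mode` should name a parallel scheme, e.g.
#'   `"replica_exchange"`.
#' @param schedule A [replica_exchange_schedule()].
#' @param trajectories List (one per replica) of lists of n x 3 frames.
#' @param box A [box_descriptor()].
#' @return The registration data.frame (`sim_id`, `sim_rank`, `table`)
#'   with the schedule attached as attribute `"schedule"`.
#' @export
deposit_replica_ensemble <- function(con, ens_id, meta, schedule,
                                     trajectories, box) {
  R <- ncol(schedule$parents)
  n_frames <- nrow(schedule$parents)
  stopifnot(length(trajectories) == R)
  reg <- register_simulation(con, ens_id, meta, n_replicas = R)
  for (f in seq_len(n_frames)) {
    for (r in seq_len(R)) {
      parent <- if (f == 1L) lineage_ref(0L, 0L, 0L) else {
        p <- schedule$parents[f, r]
        lineage_ref(reg$sim_id[p], reg$sim_rank[p], f - 1L)
      }
      fr <- trajectories[[r]][[f]]
      deposit_snapshot(
        con, reg$sim_id[r], reg$sim_rank[r],
        pack_coordinates(seq_len(nrow(fr)), fr), box, parent = parent
      )
    }
  }
  attr(reg, "schedule") <- schedule
  reg
}

#' Materialize a complete synthetic database
#'
#' Builds a small, fully populated demonstration database: one toy
#' system, a standalone simulation with a random-walk trajectory, and a
#' replica-exchange ensemble with a seeded swap schedule. Used by the
#' `demo` CLI subcommand and by tests.
#'
#' @param con Database connection (initialized).
#' @param seed Integer seed.
#' @param n_chains,chain_length Toy-system size (defaults 1 chain of 3).
#' @param n_frames Frames per trajectory (default 10).
#' @param n_replicas Replicas in the exchange ensemble (default 4).
#' @param swap_every Swap attempt period (default 2).
#' @return List with `ens_id`, `standalone` (registration), `replicas`
#'   (registration with schedule attribute) and `box`.
#' @export
build_demo_database <- function(con, seed, n_chains = 1L,
                                chain_length = 3L, n_frames = 10L,
                                n_replicas = 4L, swap_every = 2L) {
  sys <- make_toy_system(n_chains, chain_length, seed)
  box <- box_descriptor("rectangular_cuboid", c("x", "y", "z"),
                        vectors = diag(c(25, 25, 25)))
  ens <- open_or_create_ensemble(
    con, sprintf("TOY_DEMO_%d", seed), sys
  )
  meta_md <- list(
    sim_summary = "synthetic random-walk demo trajectory",
    sim_software = "trajstore-synthetic", snap_interval = 10L,
    box_shape = "rectangular_cuboid", box_periodicity = "xyz",
    ensemble_type = "nvt", sampler_type = "stochastic",
    parallel_mode = "none", united_atom_model = "all_hydrogens",
    deposit_mode = "after_completion"
  )
  reg1 <- register_simulation(con, ens, meta_md)
  walk <- random_walk_trajectory(sys, n_frames, box, 0.3, seed + 1L)
  deposit_trajectory(con, reg1$sim_id[1], reg1$sim_rank[1], walk$frames,
                     box)
  meta_re <- meta_md
  meta_re$sim_summary <- "synthetic replica-exchange demo ensemble"
  meta_re$parallel_mode <- "replica_exchange"
  sched <- replica_exchange_schedule(n_replicas, n_frames, swap_every,
                                     seed + 2L)
  trajs <- lapply(seq_len(n_replicas), function(r) {
    random_walk_trajectory(sys, n_frames, box, 0.3, seed + 10L + r)$frames
  })
  reg2 <- deposit_replica_ensemble(con, ens, meta_re, sched, trajs, box)
  list(ens_id = ens, standalone = reg1, replicas = reg2, box = box)
}
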