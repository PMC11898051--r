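test_that("ensemble creation populates exactly nratoms atom rows", {
  con <- new_db()
  sys <- make_toy_system(1, 2, seed = 7) # 6 atoms
  ens <- open_or_create_ensemble(con, "TOY_A", sys)
  expect_identical(ens, 1L)
  n <- DBI::dbGetQuery(con, "SELECT COUNT(*) AS n FROM atoms")$n
  expect_identical(n, 6L)
  stored <- DBI::dbGetQuery(con, "SELECT nratoms FROM ensembles")$nratoms
  expect_identical(stored, 6L)
})

test_that("re-depositing an identical system is an idempotent no-op", {
  con <- new_db()
  sys <- make_toy_system(1, 2, seed = 7)
  ens1 <- open_or_create_ensemble(con, "TOY_A", sys)
  before <- DBI::dbGetQuery(con, "SELECT COUNT(*) AS n FROM atoms")$n
  ens2 <- open_or_create_ensemble(con, "TOY_A", sys)
  expect_identical(ens1, ens2)
  expect_identical(DBI::dbGetQuery(con, "SELECT COUNT(*) AS n FROM atoms")$n,
                   before)
})

test_that("an empty system is overwritten, a non-empty one protected", {
  con <- new_db()
  sys <- make_toy_system(1, 2, seed = 7)
  ens <- open_or_create_ensemble(con, "TOY_A", sys)
  # no snapshots yet: replacing with a different system is allowed in place
  other <- make_toy_system(2, 2, seed = 8)
  ens2 <- open_or_create_ensemble(con, "TOY_A", other)
  expect_identical(ens2, ens)
  expect_identical(
    DBI::dbGetQuery(con, "SELECT nratoms FROM ensembles")$nratoms, 12L
  )
  # deposit one snapshot, then a modified system must be refused
  reg <- register_simulation(con, ens, std_meta())
  box <- cube_box()
  walk <- random_walk_trajectory(other, 1, box, 0.1, seed = 1)
  deposit_trajectory(con, reg$sim_id[1], 0, walk$frames, box)
  renamed <- other
  renamed$atoms$atom_name[1] <- "XX"
  expect_error(open_or_create_ensemble(con, "TOY_A", renamed),
               "integrity")
})

test_that("asymmetric covalent topology is rejected at construction", {
  sys <- make_toy_system(1, 2, seed = 7)
  bp <- sys$bound_partners
  bp[2, ] <- 0L # atom 1 still lists atom 2
  expect_error(
    atom_system(sys$atoms, sys$residues, bound_partners = bp,
                zmatrix_references = sys$zmatrix_references,
                zmatrix_values = sys$zmatrix_values),
    "symmetric"
  )
})

test_that("replica registration creates one rank-ordered table per member", {
  con <- new_db()
  sys <- make_toy_system(1, 2, seed = 7)
  ens <- open_or_create_ensemble(con, "TOY_A", sys)
  reg <- register_simulation(con, ens,
                             std_meta(parallel_mode = "replica_exchange"),
                             n_replicas = 4)
  expect_identical(reg$sim_rank, 0:3)
  expect_identical(reg$table, snapshot_table_name(reg$sim_id, 0:3))
  expect_true(all(DBI::dbGetQuery(
    con, "SELECT sim_parent FROM simulations"
  )$sim_parent == reg$sim_id[1]))
  for (tab in reg$table) expect_true(DBI::dbExistsTable(con, tab))
})

test_that("standalone runs are their own parent at rank 0", {
  con <- new_db()
  fx <- seed_plain_db(con)
  row <- DBI::dbGetQuery(con, "SELECT * FROM simulations")
  expect_identical(row$sim_rank, 0L)
  expect_identical(row$sim_parent, row$sim_id)
})

test_that("appending requires field-wise identical metadata", {
  con <- new_db()
  fx <- seed_plain_db(con)
  again <- register_simulation(con, fx$ens, std_meta(),
                               sim_id = fx$reg$sim_id[1])
  expect_identical(again$sim_id, fx$reg$sim_id)
  expect_error(
    register_simulation(con, fx$ens, std_meta(snap_interval = 99L),
                        sim_id = fx$reg$sim_id[1]),
    "integrity"
  )
  expect_error(
    register_simulation(con, fx$ens, std_meta(sampler_type = 99L)),
    "valid codes"
  )
})

test_that("box encoding places vectors then origin in a 12-vector", {
  b <- box_descriptor("rectangular_cuboid", character(),
                      vectors = diag(c(10, 12, 14)))
  expect_identical(encode_box(b),
                   c(10, 0, 0, 0, 12, 0, 0, 0, 14, 0, 0, 0))
  s <- box_descriptor("sphere", character(), radius = 7,
                      origin = c(1, 2, 3))
  expect_length(encode_box(s), 12L)
  cy <- box_descriptor("cylinder", "z", radius = 5, height = 30, axis = 3)
  expect_length(encode_box(cy), 12L)
})

test_that("box encode/decode round-trips randomized triclinic cells", {
  set.seed(42)
  for (i in 1:100) {
    V <- matrix(stats::runif(9, -15, 15), 3, 3)
    diag(V) <- abs(diag(V)) + 10
    b <- box_descriptor("triclinic", c("x", "y", "z"), vectors = V,
                        origin = stats::runif(3, -5, 5))
    b2 <- decode_box(encode_box(b), b$shape_code, b$periodicity_code)
    expect_equal(b2$vectors, b$vectors, tolerance = 0)
    expect_equal(b2$origin, b$origin, tolerance = 0)
  }
})

test_that("coordinate packing is exact and preserves subset indices", {
  expect_identical(
    unname(pack_coordinates(c(1, 2), rbind(c(0, 0, 0), c(1.5, 0, 0)))),
    unname(cbind(c(1, 2), rbind(c(0, 0, 0), c(1.5, 0, 0))))
  )
  set.seed(1)
  xyz <- matrix(stats::rnorm(3000), ncol = 3)
  p <- pack_coordinates(1:1000, xyz)
  u <- unpack_coordinates(p)
  expect_identical(u$atom_seqs, 1:1000)
  expect_true(all(u$coords == xyz))
  sub <- pack_coordinates(c(2, 5, 9), xyz[c(2, 5, 9), ])
  expect_identical(as.integer(sub[, 1]), c(2L, 5L, 9L))
  expect_error(pack_coordinates(c(2, 2), xyz[1:2, ]), "increasing")
  expect_error(pack_coordinates(1:3, xyz[1:2, ]), "same length")
})

test_that("precision-reduced packing rounds to k decimals", {
  p <- pack_coordinates(1L, matrix(c(1.23456789, 0, 0), 1), precision = 3)
  expect_identical(unname(p[1, 2]), 1.235)
})

test_that("ghost marking is the identity for present atoms and invertible", {
  box <- cube_box(20)
  set.seed(3)
  xyz <- matrix(stats::runif(30, 0, 20), ncol = 3)
  expect_identical(mark_ghosts(xyz, rep(TRUE, 10), box), xyz)
  present <- rep(TRUE, 10); present[4] <- FALSE
  marked <- mark_ghosts(xyz, present, box)
  expect_false(all(marked[4, ] == xyz[4, ]))
  expect_identical(is_ghost(marked, box), !present)
})

test_that("grand-canonical frames keep fixed length via ghosts", {
  con <- new_db()
  sys <- make_toy_system(1, 2, seed = 7)
  ens <- open_or_create_ensemble(con, "GC", sys)
  reg <- register_simulation(
    con, ens, std_meta(ensemble_type = "grand_canonical")
  )
  box <- cube_box(20)
  n <- nrow(sys$atoms)
  set.seed(9)
  for (k in 1:3) {
    present <- stats::runif(n) > 0.3 # fluctuating particle count
    xyz <- matrix(stats::runif(3 * n, 0, 20), ncol = 3)
    marked <- mark_ghosts(xyz, present, box)
    deposit_snapshot(con, reg$sim_id[1], 0,
                     pack_coordinates(1:n, marked), box)
  }
  snaps <- fetch_coordinates(con, reg$sim_id[1], 0)
  for (s in snaps) expect_identical(nrow(s$coords), n)
})

test_that("snapshot ids, steps and default parents follow the contract", {
  con <- new_db()
  sys <- make_toy_system(1, 2, seed = 7)
  ens <- open_or_create_ensemble(con, "TOY_A", sys)
  reg <- register_simulation(
    con, ens, std_meta(equilibration_steps = 500L, snap_interval = 10L)
  )
  box <- cube_box()
  xyz <- matrix(stats::runif(18, 0, 20), ncol = 3)
  id1 <- deposit_snapshot(con, reg$sim_id[1], 0,
                          pack_coordinates(1:6, xyz), box)
  id2 <- deposit_snapshot(con, reg$sim_id[1], 0,
                          pack_coordinates(1:6, xyz), box)
  expect_identical(c(id1, id2), c(1L, 2L))
  tab <- reg$table[1]
  rows <- DBI::dbGetQuery(con, sprintf(
    "SELECT snap_id, sim_step, previous_id, previous_rank, previous_snap FROM %s ORDER BY snap_id",
    tab
  ))
  expect_identical(rows$sim_step, c(510L, 520L)) # equil + interval * snap
  expect_identical(unlist(rows[1, 3:5], use.names = FALSE), c(0L, 0L, 0L))
  expect_identical(unlist(rows[2, 3:5], use.names = FALSE),
                   c(reg$sim_id[1], 0L, 1L))
  # explicit step override
  id3 <- deposit_snapshot(con, reg$sim_id[1], 0,
                          pack_coordinates(1:6, xyz), box,
                          sim_step = 123456L)
  expect_identical(DBI::dbGetQuery(con, sprintf(
    "SELECT sim_step FROM %s WHERE snap_id = %d", tab, id3
  ))$sim_step, 123456L)
})

test_that("invalid frames and parents are refused", {
  con <- new_db()
  fx <- seed_plain_db(con)
  xyz <- matrix(0, 2, 3)
  expect_error(
    deposit_snapshot(con, 99, 0, pack_coordinates(1:2, xyz), fx$box),
    "unknown snapshot table"
  )
  expect_error(
    deposit_snapshot(con, fx$reg$sim_id[1], 0,
                     pack_coordinates(c(1, 999), xyz), fx$box),
    "out of range"
  )
  expect_error(
    deposit_snapshot(con, fx$reg$sim_id[1], 0,
                     pack_coordinates(1:2, xyz), fx$box,
                     parent = lineage_ref(fx$reg$sim_id[1], 0, 999)),
    "integrity"
  )
  expect_error(
    deposit_snapshot(con, fx$reg$sim_id[1], 0,
                     pack_coordinates(1:2, xyz), rep(1, 11)),
    "12 elements"
  )
})

test_that("deposit-then-retrieve is bit-identical at full precision", {
  con <- new_db()
  fx <- seed_plain_db(con, n_chains = 3, chain_length = 4, n_frames = 6)
  snaps <- fetch_coordinates(con, fx$reg$sim_id[1], 0)
  expect_length(snaps, 6L)
  for (k in seq_along(snaps)) {
    expect_true(all(snaps[[k]]$coords[, 2:4] == fx$walk$frames[[k]]))
    expect_true(all(snaps[[k]]$box == encode_box(fx$box)))
  }
  expect_identical(nrow(validate_database(con)), 0L)
})

test_that("batched deposition yields the same rows as per-row commits", {
  con <- new_db()
  sys <- make_toy_system(1, 3, seed = 5)
  ens <- open_or_create_ensemble(con, "B", sys)
  box <- cube_box()
  walk <- random_walk_trajectory(sys, 7, box, 0.2, seed = 6)
  r1 <- register_simulation(con, ens, std_meta())
  r2 <- register_simulation(con, ens, std_meta())
  deposit_trajectory(con, r1$sim_id[1], 0, walk$frames, box, batch = 1)
  deposit_trajectory(con, r2$sim_id[1], 0, walk$frames, box, batch = 3)
  a <- fetch_coordinates(con, r1$sim_id[1], 0)
  b <- fetch_coordinates(con, r2$sim_id[1], 0)
  for (k in seq_along(a)) expect_identical(a[[k]]$coords, b[[k]]$coords)
})
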