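test_that("key listing covers all ensembles, sorted, with resolvable ids", {
  con <- new_db()
  expect_identical(nrow(list_keys(con)), 0L)
  seed_plain_db(con, key = "B_KEY", seed = 2)
  seed_plain_db(con, key = "A_KEY", seed = 3)
  keys <- list_keys(con)
  expect_identical(keys$ens_key, c("A_KEY", "B_KEY"))
  for (i in seq_len(nrow(keys))) {
    back <- DBI::dbGetQuery(con, sprintf(
      "SELECT ens_key FROM ensembles WHERE ens_id = %d", keys$ens_id[i]
    ))$ens_key
    expect_identical(back, keys$ens_key[i])
  }
})

test_that("tables_for_key enumerates rank-ordered ensemble blocks", {
  con <- new_db()
  fx <- seed_plain_db(con, key = "K")
  expect_identical(tables_for_key(con, "K"), fx$reg$table[1])
  reg2 <- register_simulation(con, fx$ens,
                              std_meta(parallel_mode = "replica_exchange"),
                              n_replicas = 4)
  got <- tables_for_key(con, "K")
  expect_length(got, 5L)
  expect_identical(got[2:5], reg2$table)
  expect_error(tables_for_key(con, "NOPE"), "unknown")
})

test_that("ordering is stable across registration order of independent sims", {
  con1 <- new_db()
  con2 <- new_db()
  sys <- make_toy_system(1, 2, seed = 7)
  # database 1: plain then replicas; database 2 reversed sim content order
  for (case in list(list(con1, c("plain", "re")),
                    list(con2, c("re", "plain")))) {
    con <- case[[1]]
    ens <- open_or_create_ensemble(con, "K", sys)
    for (kind in case[[2]]) {
      if (kind == "plain") register_simulation(con, ens, std_meta())
      else register_simulation(con, ens,
                               std_meta(parallel_mode = "replica_exchange"),
                               n_replicas = 3)
    }
  }
  t1 <- tables_for_key(con1, "K")
  t2 <- tables_for_key(con2, "K")
  # group structure: each block is contiguous and rank-ordered by parent
  ranks1 <- vapply(t1, function(x) parse_snapshot_table_name(x)[2], 0L)
  ranks2 <- vapply(t2, function(x) parse_snapshot_table_name(x)[2], 0L)
  expect_identical(sort(unname(ranks1)), sort(unname(ranks2)))
  expect_true(all(diff(match(vapply(strsplit(t1, "_"), `[`, "", 2), unique(vapply(strsplit(t1, "_"), `[`, "", 2)))) >= 0))
})

test_that("summary search is literal substring with wildcard escaping", {
  con <- new_db()
  sys <- make_toy_system(1, 2, seed = 7)
  ens <- open_or_create_ensemble(con, "K", sys)
  register_simulation(con, ens,
                      std_meta(sim_summary = "apo bromodomain in water"))
  register_simulation(con, ens,
                      std_meta(sim_summary = "holo structure, 100% occupancy"))
  register_simulation(con, ens,
                      std_meta(sim_summary = "reached 100 ns production"))
  hits <- search_summaries(con, "bromodomain")
  expect_identical(nrow(hits), 1L)
  expect_identical(nrow(search_summaries(con, "nosuchtext")), 0L)
  # '%' must not act as a wildcard
  all_sum <- DBI::dbGetQuery(con, "SELECT sim_id, sim_summary FROM simulations")
  oracle <- all_sum$sim_id[grepl("100%", all_sum$sim_summary, fixed = TRUE)]
  expect_identical(search_summaries(con, "100%")$sim_id, oracle)
  expect_identical(nrow(search_summaries(con, "BROMODOMAIN")), 0L)
  expect_identical(nrow(search_summaries(con, "BROMODOMAIN",
                                         ignore_case = TRUE)), 1L)
  expect_error(search_summaries(con, ""), "nonempty")
})

test_that("metadata fetch decodes every coded attribute consistently", {
  con <- new_db()
  fx <- seed_plain_db(con)
  md <- fetch_metadata(con, fx$reg$sim_id[1], 0)
  expect_identical(md$labels$ensemble_type, "nvt")
  expect_identical(md$labels$sampler_type, "newtonian")
  for (f in names(md$labels)) {
    expect_identical(encode(f, md$labels[[f]]), md$record[[f]])
  }
  reg2 <- register_simulation(con, fx$ens,
                              std_meta(parallel_mode = "replica_exchange"),
                              n_replicas = 2)
  md2 <- fetch_metadata(con, reg2$sim_id[2], 1)
  expect_false(md2$record$sim_parent == md2$record$sim_id)
  expect_error(fetch_metadata(con, 999, 0), "unknown")
})

test_that("coordinate fetch matches a brute-force in-memory oracle", {
  con <- new_db()
  fx <- seed_plain_db(con, n_chains = 2, chain_length = 3, n_frames = 10)
  nm <- fx$sys$atoms$atom_name

  # full selection equals deposited frames
  full <- fetch_coordinates(con, fx$reg$sim_id[1], 0)
  for (k in 1:10) {
    expect_true(all(full[[k]]$coords[, 2:4] == fx$walk$frames[[k]]))
  }

  # atom-name substring filter: oracle by grepl over the system table
  ca <- fetch_coordinates(con, fx$reg$sim_id[1], 0,
                          selection_spec(ids = 4, atom_name = "CA"))
  oracle_idx <- which(grepl("CA", nm, fixed = TRUE))
  expect_identical(as.integer(ca[[1]]$coords[, 1]), oracle_idx)
  expect_true(all(ca[[1]]$coords[, 2:4] ==
                    fx$walk$frames[[4]][oracle_idx, ]))

  # exact matching excludes superstring names by construction
  exact <- fetch_coordinates(
    con, fx$reg$sim_id[1], 0,
    selection_spec(ids = 4, atom_name = "C", exact_name = TRUE)
  )
  expect_identical(as.integer(exact[[1]]$coords[, 1]), which(nm == "C"))

  # stride selection
  st <- fetch_coordinates(con, fx$reg$sim_id[1], 0,
                          selection_spec(snaps = c(1, 10, 3)))
  expect_identical(vapply(st, `[[`, 0L, "snap_id"), c(1L, 4L, 7L, 10L))

  # molecule filter vs oracle
  mol <- fetch_coordinates(con, fx$reg$sim_id[1], 0,
                           selection_spec(ids = 1, molecule_id = 2))
  expect_identical(as.integer(mol[[1]]$coords[, 1]),
                   which(fx$sys$atoms$molecule_id == 2))

  # empty atom filter yields empty rows, not an error
  none <- fetch_coordinates(con, fx$reg$sim_id[1], 0,
                            selection_spec(ids = 1, atom_name = "ZZ"))
  expect_identical(nrow(none[[1]]$coords), 0L)

  expect_error(
    fetch_coordinates(con, fx$reg$sim_id[1], 0,
                      selection_spec(ids = 99)),
    "out of range"
  )
})

test_that("stride over 1..100 by 10 returns exactly ten frames", {
  con <- new_db()
  fx <- seed_plain_db(con, n_frames = 100, chain_length = 1)
  st <- fetch_coordinates(con, fx$reg$sim_id[1], 0,
                          selection_spec(snaps = c(1, 100, 10)))
  expect_identical(vapply(st, `[[`, 0L, "snap_id"),
                   as.integer(seq(1, 91, 10)))
})

test_that("composite and per-snapshot execution agree", {
  con <- new_db()
  fx <- seed_plain_db(con, n_frames = 6)
  sel <- selection_spec(snaps = c(2, 6, 2), atom_name = "N")
  joint <- fetch_coordinates(con, fx$reg$sim_id[1], 0, sel)
  split <- lapply(c(2L, 4L, 6L), function(id) {
    fetch_coordinates(con, fx$reg$sim_id[1], 0,
                      selection_spec(ids = id, atom_name = "N"))[[1]]
  })
  for (k in seq_along(joint)) {
    expect_identical(joint[[k]]$coords, split[[k]]$coords)
    expect_identical(joint[[k]]$snap_id, split[[k]]$snap_id)
  }
})
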