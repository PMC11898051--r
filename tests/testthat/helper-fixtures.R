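# shared fixtures: every database is built in code, in memory

new_db <- function() {
  con <- ts_connect(":memory:")
  withr::defer(ts_disconnect(con), envir = parent.frame())
  con
}

std_meta <- function(...) {
  base <- list(
    sim_summary = "toy fixture run",
    sim_software = "trajstore-test",
    equilibration_steps = 0L,
    snap_interval = 10L,
    box_shape = "rectangular_cuboid",
    box_periodicity = "xyz",
    ensemble_type = "nvt",
    sampler_type = "newtonian",
    parallel_mode = "none",
    united_atom_model = "all_hydrogens",
    deposit_mode = "after_completion"
  )
  utils::modifyList(base, list(...))
}

cube_box <- function(edge = 20) {
  box_descriptor("rectangular_cuboid", c("x", "y", "z"),
                 vectors = diag(rep(edge, 3)))
}

# one ensemble + one plain trajectory, returning the handles tests need
seed_plain_db <- function(con, seed = 11, n_chains = 1, chain_length = 2,
                          n_frames = 4, key = "TOY_A") {
  sys <- make_toy_system(n_chains, chain_length, seed)
  ens <- open_or_create_ensemble(con, key, sys)
  reg <- register_simulation(con, ens, std_meta())
  box <- cube_box()
  walk <- random_walk_trajectory(sys, n_frames, box, 0.2, seed + 1)
  deposit_trajectory(con, reg$sim_id[1], reg$sim_rank[1], walk$frames, box)
  list(sys = sys, ens = ens, reg = reg, box = box, walk = walk)
}
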