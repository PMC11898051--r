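test_that("element derivation is nearest-atomic-weight with name tie-breaks", {
  # independent oracle: brute-force nearest weight over the periodic table
  weights <- trajstore:::.element_weights
  nearest <- function(m) names(weights)[which.min(abs(weights - m))]
  expect_identical(trimws(derive_element(12.011, "CA")), nearest(12.011))
  expect_identical(trimws(derive_element(1.008, "H1")), nearest(1.008))
  expect_identical(trimws(derive_element(40.08, "CA")), nearest(40.08))
  expect_identical(trimws(derive_element(12.011, "CA")), "C")
  expect_identical(trimws(derive_element(40.08, "CA")), "Ca")
  expect_identical(nchar(derive_element(15.999, "O")), 2L)
  # no mass: fall back to the name
  expect_identical(trimws(derive_element(0, "CL")), "Cl")
  expect_error(derive_element(0, "@@"), "classif")
})

test_that("PDB records carry fixed occupancy and standard columns", {
  con <- new_db()
  fx <- seed_plain_db(con, n_chains = 2, chain_length = 2)
  snap <- fetch_coordinates(con, fx$reg$sim_id[1], 0,
                            selection_spec(ids = 1))[[1]]
  lines <- pdb_template(con, fx$ens, snap$coords)
  atom_lines <- lines[grepl("^ATOM|^HETATM", lines)]
  expect_identical(length(atom_lines), nrow(fx$sys$atoms))
  for (l in atom_lines) {
    expect_identical(substr(l, 55, 60), "  1.00")
  }
  # TER between the two chains (molecule_id change) and at the end
  expect_identical(sum(grepl("^TER", lines)), 2L)
})

test_that("records re-parse losslessly under an independent PDB reader", {
  skip_if_not_installed("bio3d")
  con <- new_db()
  fx <- seed_plain_db(con, n_chains = 2, chain_length = 2)
  snap <- fetch_coordinates(con, fx$reg$sim_id[1], 0,
                            selection_spec(ids = 1))[[1]]
  f <- withr::local_tempfile(fileext = ".pdb")
  write_pdb_frames(con, fx$ens, list(snap$coords), f)
  pdb <- bio3d::read.pdb(f)
  a <- pdb$atom
  sys <- fx$sys$atoms
  expect_identical(nrow(a), nrow(sys))
  expect_identical(a$eleno, sys$atom_seq)
  expect_identical(trimws(a$elety), sys$atom_name)
  expect_identical(trimws(a$resid), sys$resid_name)
  expect_identical(trimws(a$chain), sys$chain_seq)
  expect_identical(a$resno, sys$resid_seq)
  expect_equal(cbind(a$x, a$y, a$z),
               unname(round(snap$coords[, 2:4], 3)), tolerance = 1e-9)
  expect_true(all(a$o == 1))
  els <- vapply(seq_len(nrow(sys)),
                function(i) trimws(derive_element(sys$mass[i],
                                                  sys$atom_name[i])),
                character(1))
  expect_identical(trimws(a$elesy), els)
})

test_that("formal charges appear in the PDB charge column", {
  con <- new_db()
  sys <- make_toy_system(1, 1, seed = 4)
  sys$atoms$formal_charge <- c(-1L, 0L, 1L)
  ens <- open_or_create_ensemble(con, "CHG", sys)
  xyz <- pack_coordinates(1:3, matrix(1:9, 3, 3))
  lines <- pdb_template(con, ens, xyz)
  atom_lines <- lines[grepl("^ATOM", lines)]
  expect_identical(substr(atom_lines[1], 79, 80), "1-")
  expect_identical(substr(atom_lines[2], 79, 80), "  ")
  expect_identical(substr(atom_lines[3], 79, 80), "1+")
})

test_that("temperature-factor column source is selectable", {
  con <- new_db()
  fx <- seed_plain_db(con)
  snap <- fetch_coordinates(con, fx$reg$sim_id[1], 0,
                            selection_spec(ids = 1))[[1]]
  lines <- pdb_template(con, fx$ens, snap$coords,
                        bfactor = "partial_charge")
  atom_lines <- lines[grepl("^ATOM", lines)]
  got <- as.numeric(substr(atom_lines, 61, 66))
  expect_equal(got, round(fx$sys$atoms$partial_charge, 2),
               tolerance = 1e-9)
  expect_error(pdb_template(con, fx$ens, snap$coords, bfactor = "mass2"),
               "unsupported")
})

test_that("a subset frame renders only the requested atoms", {
  con <- new_db()
  fx <- seed_plain_db(con)
  xyz <- pack_coordinates(c(2, 5), matrix(stats::rnorm(6), 2, 3))
  lines <- pdb_template(con, fx$ens, xyz)
  atom_lines <- lines[grepl("^ATOM", lines)]
  expect_identical(as.integer(substr(atom_lines, 7, 11)), c(2L, 5L))
  expect_error(pdb_template(con, fx$ens,
                            pack_coordinates(999, matrix(0, 1, 3))),
               "not in ensemble")
})

test_that("Z-matrix listing reproduces stored topology and geometry", {
  con <- new_db()
  sys <- make_toy_system(1, 2, seed = 7) # 6-atom chain
  ens <- open_or_create_ensemble(con, "Z", sys)
  lines <- zmatrix_template(con, ens)
  tab <- attr(lines, "table")
  expect_identical(nrow(tab), 6L)
  # atom 1 of any system references (0, 0, 0)
  expect_identical(unlist(tab[1, c("ref_bond", "ref_angle", "ref_torsion")],
                          use.names = FALSE), c(0L, 0L, 0L))
  # stored bond lengths equal the generator's values exactly
  expect_identical(tab$bond_length, sys$zmatrix_values[, 1])
  expect_identical(tab$bond_angle, sys$zmatrix_values[, 2])
  expect_identical(tab$chirality, sys$zmatrix_references[, 4])
  expect_true(all(tab$chirality == 0L)) # dihedral interpretation
})

test_that("forward Z-matrix references are an integrity error", {
  con <- new_db()
  sys <- make_toy_system(1, 2, seed = 7)
  zr <- sys$zmatrix_references
  zr[2, 1] <- 5L # forward reference
  sys2 <- atom_system(sys$atoms, sys$residues,
                      bound_partners = sys$bound_partners,
                      zmatrix_references = zr,
                      zmatrix_values = sys$zmatrix_values)
  ens <- open_or_create_ensemble(con, "ZF", sys2)
  expect_error(zmatrix_template(con, ens), "forward")
})

test_that("sequence listing matches the atoms tier residue count", {
  con <- new_db()
  sys <- make_toy_system(2, 3, seed = 9)
  ens <- open_or_create_ensemble(con, "SQ", sys)
  res <- sequence_template(con, ens)
  expect_identical(res, sys$residues)
  n_resid <- length(unique(DBI::dbGetQuery(
    con, sprintf("SELECT resid_seq FROM atoms WHERE ens_id = %d", ens)
  )$resid_seq))
  expect_identical(length(res), n_resid)
})

test_that("template generation never mutates the database", {
  con <- new_db()
  fx <- seed_plain_db(con)
  snap <- fetch_coordinates(con, fx$reg$sim_id[1], 0,
                            selection_spec(ids = 1))[[1]]
  dump_all <- function() {
    tabs <- sort(DBI::dbListTables(con))
    lapply(tabs, function(t) DBI::dbGetQuery(
      con, sprintf("SELECT * FROM %s", t)
    ))
  }
  before <- dump_all()
  invisible(pdb_template(con, fx$ens, snap$coords))
  invisible(zmatrix_template(con, fx$ens))
  invisible(sequence_template(con, fx$ens))
  expect_identical(dump_all(), before)
})
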