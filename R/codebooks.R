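#' Integer code books of the storage standard
#'
#' The simulation tier stores several categorical attributes as fixed
#' integer codes. `code_books()` returns the complete registry: for each
#' category a named integer vector mapping the canonical label to its code.
#' The registry is frozen to the published standard; [register_code()] can
#' extend a category at run time without touching the published values.
#'
#' Categories and codes:
#' * `box_shape`: 1 rectangular cuboid, 2 sphere, 3 cylinder, 4 triclinic.
#' * `box_periodicity`: 0 none, then z, y, x, yz, xz, xy for 1..6,
#'   7 fully (3D) periodic. For triclinic cells the dimension labels refer
#'   to the order of the box vectors.
#' * `ensemble_type`: 1 NVT, 2 NVE, 3 NPT, 5 semigrand, 6 grand canonical.
#'   (4 is unassigned in the standard.)
#' * `sampler_type`: 1 Monte Carlo, 2 Newtonian, 3 stochastic, 4 Brownian,
#'   5-7 hybrid schemes.
#' * `parallel_mode`: 0 none (including brute-force multicopy), 1 replica
#'   exchange, 2 progress index-guided sampling (PIGS), 3 parallel
#'   metadynamics / Wang-Landau, 4 parallel simulated annealing, 5 other
#'   adaptive scheme, 6 reservoir / library sampling.
#' * `united_atom_model`: 0 all hydrogens present, 1 aliphatic hydrogens
#'   missing, 2 only polar hydrogens retained, 3 other coarse-grained.
#' * `deposit_mode`: 1 deposited while running, 2 not.
#'
#' @return Named list of named integer vectors (label -> code).
#' @seealso [encode()], [decode()], [encode_periodicity()]
#' @export
#' @examples
#' code_books()$box_shape
code_books <- function() {
  out <- .ts_codes$books
  out
}

# canonical label -> code, per category; aliases resolved in .normalize_label
.ts_base_books <- list(
  box_shape = c(
    rectangular_cuboid = 1L, sphere = 2L, cylinder = 3L, triclinic = 4L
  ),
  box_periodicity = c(
    none = 0L, z = 1L, y = 2L, x = 3L, yz = 4L, xz = 5L, xy = 6L, xyz = 7L
  ),
  ensemble_type = c(
    nvt = 1L, nve = 2L, npt = 3L, semigrand = 5L, grand_canonical = 6L
  ),
  sampler_type = c(
    monte_carlo = 1L, newtonian = 2L, stochastic = 3L, brownian = 4L,
    hybrid = 5L, hybrid_2 = 6L, hybrid_3 = 7L
  ),
  parallel_mode = c(
    none = 0L, replica_exchange = 1L, pigs = 2L,
    parallel_metadynamics = 3L, parallel_simulated_annealing = 4L,
    adaptive = 5L, reservoir = 6L
  ),
  united_atom_model = c(
    all_hydrogens = 0L, no_aliphatic_hydrogens = 1L,
    polar_hydrogens_only = 2L, coarse_grained = 3L
  ),
  deposit_mode = c(
    while_running = 1L, after_completion = 2L
  )
)

# alias -> canonical label (after normalization); keeps the published codes
# reachable under the field's usual spellings
.ts_aliases <- list(
  box_shape = c(
    cuboid = "rectangular_cuboid", rectangular = "rectangular_cuboid",
    orthorhombic = "rectangular_cuboid", cube = "rectangular_cuboid"
  ),
  box_periodicity = c(
    aperiodic = "none", zy = "yz", zx = "xz", yx = "xy",
    full = "xyz", "3d" = "xyz"
  ),
  ensemble_type = c(
    canonical = "nvt", microcanonical = "nve",
    isothermal_isobaric = "npt", muvt = "grand_canonical",
    grand = "grand_canonical"
  ),
  sampler_type = c(
    mc = "monte_carlo", md = "newtonian", newtonian_dynamics = "newtonian",
    molecular_dynamics = "newtonian", langevin = "stochastic",
    stochastic_dynamics = "stochastic", brownian_dynamics = "brownian",
    bd = "brownian", ld = "stochastic"
  ),
  parallel_mode = c(
    progress_index_guided_sampling = "pigs",
    wang_landau = "parallel_metadynamics",
    parallel_wang_landau = "parallel_metadynamics",
    metadynamics = "parallel_metadynamics",
    simulated_annealing = "parallel_simulated_annealing",
    other_adaptive = "adaptive", adaptive_sampling = "adaptive",
    library = "reservoir", reservoir_library = "reservoir",
    multicopy = "none", brute_force_multicopy = "none",
    re = "replica_exchange", remd = "replica_exchange"
  ),
  united_atom_model = c(
    all_h = "all_hydrogens", all = "all_hydrogens",
    no_aliphatic_h = "no_aliphatic_hydrogens",
    united_aliphatic = "no_aliphatic_hydrogens",
    only_polar_h = "polar_hydrogens_only",
    polar_only = "polar_hydrogens_only",
    other_coarse_grained = "coarse_grained", cg = "coarse_grained"
  ),
  deposit_mode = c(
    live = "while_running", deposited_while_running = "while_running",
    running = "while_running", post = "after_completion",
    not_while_running = "after_completion", after = "after_completion"
  )
)

# run-time registry; extensions never overwrite published codes
.ts_codes <- new.env(parent = emptyenv())
.ts_codes$books <- .ts_base_books

# labels are matched case-insensitively with '-', ' ' and '_' interchangeable
.normalize_label <- function(label) {
  x <- tolower(trimws(as.character(label)))
  gsub("[ \t/-]+", "_", x)
}

.check_category <- function(category) {
  if (length(category) != 1L || !category %in% names(.ts_codes$books)) {
    stop(sprintf(
      "unknown code category '%s'; valid categories: %s",
      paste(category, collapse = ","),
      paste(names(.ts_codes$books), collapse = ", ")
    ), call. = FALSE)
  }
  category
}

#' Encode a categorical label to its standard integer code
#'
#' Labels are matched case-insensitively, with underscores, hyphens and
#' spaces interchangeable, so `"grand canonical"`, `"Grand-Canonical"` and
#' `"grand_canonical"` are the same label. Common field aliases
#' (e.g. `"PIGS"`, `"REMD"`, `"MC"`) are accepted.
#'
#' @param category Code-book category name (see [code_books()]).
#' @param label Label text.
#' @return The integer code.
#' @export
#' @examples
#' encode("box_shape", "sphere")      # 2
#' encode("sampler_type", "Brownian") # 4
encode <- function(category, label) {
  .check_category(category)
  book <- .ts_codes$books[[category]]
  lab <- .normalize_label(label)
  ali <- .ts_aliases[[category]]
  if (!is.null(ali) && lab %in% names(ali)) lab <- unname(ali[[lab]])
  if (!lab %in% names(book)) {
    stop(sprintf(
      "unknown %s label '%s'; valid labels: %s",
      category, label, paste(names(book), collapse = ", ")
    ), call. = FALSE)
  }
  unname(book[[lab]])
}

#' Decode a standard integer code to its canonical label
#'
#' @param category Code-book category name.
#' @param code Integer code.
#' @return Canonical label text; `decode(category, encode(category, x))`
#'   returns the canonical form of `x`.
#' @export
#' @examples
#' decode("ensemble_type", 6) # "grand_canonical"
decode <- function(category, code) {
  .check_category(category)
  book <- .ts_codes$books[[category]]
  code <- as.integer(code)
  hit <- names(book)[match(code, book)]
  if (length(hit) != 1L || is.na(hit)) {
    stop(sprintf(
      "unknown %s code %s; valid codes: %s",
      category, code, paste(sort(unname(book)), collapse = ", ")
    ), call. = FALSE)
  }
  hit
}

#' Register an extension code
#'
#' The published codes are frozen; this adds a new label/code pair to a
#' category (e.g. a future sampler type) for the current session. Reusing a
#' published code or label is an error.
#'
#' @param category Code-book category name.
#' @param label New canonical label.
#' @param code New integer code, not already assigned in the category.
#' @return The code, invisibly.
#' @export
register_code <- function(category, label, code) {
  .check_category(category)
  book <- .ts_codes$books[[category]]
  lab <- .normalize_label(label)
  code <- as.integer(code)
  if (lab %in% names(book)) {
    stop(sprintf("label '%s' already defined in %s", lab, category),
         call. = FALSE)
  }
  if (code %in% book) {
    stop(sprintf("code %d already assigned in %s", code, category),
         call. = FALSE)
  }
  book[[lab]] <- code
  .ts_codes$books[[category]] <- book
  invisible(code)
}

#' Encode periodic dimensions as the standard periodicity code
#'
#' One or two periodic dimensions occupy codes 1 to 6 in the order z, y, x,
#' yz, xz, xy; 0 is aperiodic and 7 fully periodic. The shape code is
#' checked for admissibility: spheres must be aperiodic and cylinders can
#' have at most one periodic dimension (along their axis). For triclinic
#' cells the labels x, y, z refer to box vectors 1, 2, 3.
#'
#' @param periodic_dims Character vector, a subset of `c("x","y","z")`
#'   (duplicates ignored). May be empty.
#' @param shape_code Integer box-shape code (see [code_books()]).
#' @return Integer periodicity code in 0..7.
#' @export
#' @examples
#' encode_periodicity(c("x", "y", "z"), 1) # 7
#' encode_periodicity(character(), 2)      # 0
encode_periodicity <- function(periodic_dims, shape_code) {
  shape_code <- as.integer(shape_code)
  if (!shape_code %in% .ts_codes$books$box_shape) {
    stop(sprintf("invalid box_shape code %d", shape_code), call. = FALSE)
  }
  dims <- unique(tolower(as.character(periodic_dims)))
  dims <- dims[nzchar(dims)]
  if (!all(dims %in% c("x", "y", "z"))) {
    stop("periodic_dims must be a subset of {x, y, z}", call. = FALSE)
  }
  key <- paste(sort(dims), collapse = "")
  code <- if (key == "") 0L else {
    c(z = 1L, y = 2L, x = 3L, yz = 4L, xz = 5L, xy = 6L, xyz = 7L)[[key]]
  }
  .check_shape_periodicity(shape_code, code)
  code
}

# admissibility of a (shape, periodicity) pair per the standard
.check_shape_periodicity <- function(shape_code, periodicity_code) {
  if (shape_code == 2L && periodicity_code != 0L) {
    stop("spheres must be aperiodic (box_periodicity 0)", call. = FALSE)
  }
  if (shape_code == 3L && !periodicity_code %in% 0:3) {
    stop("cylinders admit at most one periodic dimension", call. = FALSE)
  }
  invisible(TRUE)
}

#' Test whether a (shape, periodicity) code pair is admissible
#'
#' @param shape_code Integer box-shape code.
#' @param periodicity_code Integer periodicity code.
#' @return Logical scalar.
#' @export
shape_periodicity_ok <- function(shape_code, periodicity_code) {
  if (!shape_code %in% .ts_codes$books$box_shape) return(FALSE)
  if (!periodicity_code %in% 0:7) return(FALSE)
  !inherits(
    tryCatch(.check_shape_periodicity(shape_code, periodicity_code),
             error = identity),
    "error"
  )
}

#' Snapshot-table naming convention
#'
#' Coordinate-tier tables are named `snapshots_(sim_id)_(sim_rank)`, one
#' table per trajectory.
#'
#' @param sim_id Simulation id (>= 1).
#' @param sim_rank Replica rank (>= 0).
#' @return Table name, e.g. `"snapshots_1_0"`.
#' @export
snapshot_table_name <- function(sim_id, sim_rank) {
  sim_id <- as.integer(sim_id)
  sim_rank <- as.integer(sim_rank)
  if (any(is.na(sim_id)) || any(sim_id < 1L)) {
    stop("sim_id must be a positive integer", call. = FALSE)
  }
  if (any(is.na(sim_rank)) || any(sim_rank < 0L)) {
    stop("sim_rank must be a non-negative integer", call. = FALSE)
  }
  sprintf("snapshots_%d_%d", sim_id, sim_rank)
}

#' Parse a snapshot-table name back into (sim_id, sim_rank)
#'
#' @param name Table name following the `snapshots_<id>_<rank>` convention.
#' @return Named integer vector with elements `sim_id`, `sim_rank`.
#' @export
parse_snapshot_table_name <- function(name) {
  m <- regmatches(name, regexec("^snapshots_([0-9]+)_([0-9]+)$", name))[[1]]
  if (length(m) != 3L) {
    stop(sprintf("'%s' is not a snapshot-table name", name), call. = FALSE)
  }
  c(sim_id = as.integer(m[2]), sim_rank = as.integer(m[3]))
}

#' Validate an ensemble key
#'
#' Keys identify systems across the database and may contain only
#' alphanumerics, underscores and hyphens.
#'
#' @param key Proposed key text.
#' @return The key, invisibly unchanged, if valid.
#' @export
#' @examples
#' validate_ens_key("Beta3S_CHARMM19")
validate_ens_key <- function(key) {
  if (length(key) != 1L || is.na(key) || !nzchar(key)) {
    stop("ens_key must be a nonempty string", call. = FALSE)
  }
  bad <- regmatches(key, gregexpr("[^A-Za-z0-9_-]", key))[[1]]
  if (length(bad)) {
    stop(sprintf(
      "ens_key '%s' contains forbidden character(s): %s",
      key, paste(sQuote(unique(bad)), collapse = ", ")
    ), call. = FALSE)
  }
  key
}
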