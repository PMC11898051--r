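# standard atomic weights (a.m.u., abridged IUPAC values)
.element_weights <- c(
  H = 1.008, He = 4.0026, Li = 6.94, Be = 9.0122, B = 10.81, C = 12.011,
  N = 14.007, O = 15.999, F = 18.998, Ne = 20.180, Na = 22.990,
  Mg = 24.305, Al = 26.982, Si = 28.085, P = 30.974, S = 32.06,
  Cl = 35.45, Ar = 39.948, K = 39.098, Ca = 40.078, Sc = 44.956,
  Ti = 47.867, V = 50.942, Cr = 51.996, Mn = 54.938, Fe = 55.845,
  Co = 58.933, Ni = 58.693, Cu = 63.546, Zn = 65.38, Ga = 69.723,
  Ge = 72.630, As = 74.922, Se = 78.971, Br = 79.904, Kr = 83.798,
  Rb = 85.468, Sr = 87.62, Y = 88.906, Zr = 91.224, Nb = 92.906,
  Mo = 95.95, Ru = 101.07, Rh = 102.91, Pd = 106.42, Ag = 107.87,
  Cd = 112.41, In = 114.82, Sn = 118.71, Sb = 121.76, Te = 127.60,
  I = 126.90, Xe = 131.29, Cs = 132.91, Ba = 137.33, La = 138.91,
  Ce = 140.12, Nd = 144.24, Sm = 150.36, Eu = 151.96, Gd = 157.25,
  Tb = 158.93, Dy = 162.50, Ho = 164.93, Er = 167.26, Yb = 173.05,
  Lu = 174.97, Hf = 178.49, Ta = 180.95, W = 183.84, Re = 186.21,
  Os = 190.23, Ir = 192.22, Pt = 195.08, Au = 196.97, Hg = 200.59,
  Tl = 204.38, Pb = 207.2, Bi = 208.98, Th = 232.04, U = 238.03
)

#' Derive an element symbol from mass and atom name
#'
#' The atoms tier stores no element symbol; it is derived. The element
#' whose standard atomic weight is nearest to `mass` wins; the atom name
#' is consulted only to break near-ties (candidates within 0.5 a.m.u. of
#' the best match), so calcium at 40.08 beats carbon for an atom named
#' "CA" while a 12.011 "CA" remains carbon. With no usable mass, the
#' leading letters of the name are matched against element symbols.
#'
#' @param mass Atomic mass (a.m.u.); values <= 0 fall back to the name.
#' @param atom_name Atom name text (optional).
#' @return Right-justified 2-character element symbol, e.g. `" C"`,
#'   `"Ca"`.
#' @export
#' @examples
#' derive_element(12.011, "CA") # " C"
#' derive_element(40.08, "CA")  # "Ca"
derive_element <- function(mass, atom_name = "") {
  sym <- NULL
  name_alpha <- toupper(gsub("[^A-Za-z]", "", as.character(atom_name)))
  if (is.finite(mass) && mass > 0) {
    d <- abs(.element_weights - mass)
    best <- min(d)
    cand <- names(.element_weights)[d <= best + 0.5]
    if (length(cand) > 1L && nzchar(name_alpha)) {
      hit <- cand[toupper(cand) == substr(name_alpha, 1L, 2L) |
                    toupper(cand) == substr(name_alpha, 1L, 1L)]
      if (length(hit)) cand <- hit
    }
    d2 <- abs(.element_weights[cand] - mass)
    sym <- cand[which.min(d2)]
  } else if (nzchar(name_alpha)) {
    two <- names(.element_weights)[
      toupper(names(.element_weights)) == substr(name_alpha, 1L, 2L)
    ]
    one <- names(.element_weights)[
      toupper(names(.element_weights)) == substr(name_alpha, 1L, 1L)
    ]
    sym <- if (length(two)) two[1] else if (length(one)) one[1] else NULL
  }
  if (is.null(sym)) {
    stop(sprintf(
      "cannot classify element from mass %s and name '%s'", mass, atom_name
    ), call. = FALSE)
  }
  sprintf("%2s", sym)
}

# PDB atom-name placement: names of 1-3 chars for 1-letter elements get a
# leading space so the element aligns on columns 13-14
.pdb_atom_name <- function(name, element) {
  name <- trimws(name)
  if (nchar(name) >= 4L) return(substr(sprintf("%-4s", name), 1L, 4L))
  if (nchar(trimws(element)) == 1L) sprintf("%-4s", paste0(" ", name)) else {
    sprintf("%-4s", name)
  }
}

.pdb_charge_field <- function(fc) {
  fc <- as.integer(fc)
  if (is.na(fc) || fc == 0L) "  " else {
    paste0(abs(fc), if (fc > 0L) "+" else "-")
  }
}

# fetch and order the atoms-tier rows backing a set of atom_seq values
.atoms_for_template <- function(con, ens_id, seqs = NULL) {
  at <- DBI::dbGetQuery(con, sprintf(
    "SELECT * FROM atoms WHERE ens_id = %d ORDER BY atom_seq",
    as.integer(ens_id)
  ))
  if (nrow(at) == 0L) stop(sprintf("unknown or empty ens_id %s", ens_id),
                           call. = FALSE)
  if (!is.null(seqs)) {
    bad <- setdiff(seqs, at$atom_seq)
    if (length(bad)) {
      stop(sprintf("atom_seq not in ensemble: %s",
                   paste(bad, collapse = ", ")), call. = FALSE)
    }
    at <- at[match(seqs, at$atom_seq), , drop = FALSE]
  }
  at
}

#' Generate annotated PDB records for one frame
#'
#' Builds fixed-width ATOM/HETATM records from the atoms tier and a set
#' of coordinates. The occupancy column is always `1.00`; the
#' temperature-factor column is filled from a selectable atoms-tier
#' column (default `tempfactor`, e.g. `partial_charge` for charge-colored
#' rendering); the element symbol is derived via [derive_element()] and
#' the trailing charge field from `formal_charge`. The atom serial is
#' `atom_seq`. No insertion codes or alternate-location identifiers are
#' emitted. `TER` records separate molecules (changes of `molecule_id`).
#'
#' The chain identifier is the first character of the stored `chain_seq`;
#' a warning is raised when a two-character chain id is truncated.
#'
#' @param con Database connection.
#' @param ens_id Ensemble id.
#' @param coords m x 4 packed coordinate matrix (`atom_seq`, x, y, z) for
#'   a subset (or all) of the ensemble's atoms.
#' @param bfactor Atoms-tier column used for the temperature-factor
#'   column (default `"tempfactor"`).
#' @return Character vector of PDB record lines (ATOM/HETATM/TER).
#' @export
pdb_template <- function(con, ens_id, coords, bfactor = "tempfactor") {
  coords <- matrix(as.numeric(coords), ncol = 4L)
  seqs <- as.integer(coords[, 1L])
  at <- .atoms_for_template(con, ens_id, seqs)
  if (!bfactor %in% c("tempfactor", "partial_charge", "occupancy", "mass",
                      "rfos_contribution")) {
    stop(sprintf("unsupported temperature-factor source '%s'", bfactor),
         call. = FALSE)
  }
  if (any(nchar(trimws(at$chain_seq)) > 1L)) {
    warning("chain_seq truncated to its first character for PDB output")
  }
  lines <- character(0L)
  for (i in seq_len(nrow(at))) {
    el <- derive_element(at$mass[i], at$atom_name[i])
    rn <- trimws(at$resid_name[i])
    rn_fld <- if (nchar(rn) > 3L) sprintf("%-4s", rn) else {
      sprintf("%3s ", rn)
    }
    line <- sprintf(
      "%-6s%5d %s %s%s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %s%s",
      trimws(at$keyword[i]), at$atom_seq[i],
      .pdb_atom_name(at$atom_name[i], el), rn_fld,
      substr(paste0(trimws(at$chain_seq[i]), " "), 1L, 1L),
      at$resid_seq[i], coords[i, 2L], coords[i, 3L], coords[i, 4L],
      1.0, at[[bfactor]][i], el, .pdb_charge_field(at$formal_charge[i])
    )
    lines <- c(lines, line)
    nxt <- if (i < nrow(at)) at$molecule_id[i + 1L] else NA
    if (is.na(nxt) || nxt != at$molecule_id[i]) {
      lines <- c(lines, sprintf(
        "TER   %5d      %s%s%4d",
        at$atom_seq[i] + 1L, rn_fld,
        substr(paste0(trimws(at$chain_seq[i]), " "), 1L, 1L),
        at$resid_seq[i]
      ))
    }
  }
  lines
}

#' Write a multi-frame annotated PDB file
#'
#' Wraps [pdb_template()] with MODEL/ENDMDL bookkeeping for multi-frame
#' export and terminates the file with END.
#'
#' @param con Database connection.
#' @param ens_id Ensemble id.
#' @param frames List of m x 4 packed coordinate matrices.
#' @param file Output path.
#' @param bfactor Temperature-factor source column.
#' @return `file`, invisibly.
#' @export
write_pdb_frames <- function(con, ens_id, frames, file,
                             bfactor = "tempfactor") {
  out <- character(0L)
  multi <- length(frames) > 1L
  for (k in seq_along(frames)) {
    if (multi) out <- c(out, sprintf("MODEL     %4d", k))
    out <- c(out, pdb_template(con, ens_id, frames[[k]], bfactor = bfactor))
    if (multi) out <- c(out, "ENDMDL")
  }
  writeLines(c(out, "END"), file)
  invisible(file)
}

#' Generate a Z-matrix listing from the atoms tier
#'
#' One line per atom in `atom_seq` order: atom index and name, the three
#' reference indices (bond, angle, torsion; 0 for absent ancestors), the
#' chirality indicator (-1/0/1, 0 meaning the third value is a dihedral),
#' and the bond length (Angstrom), bond angle and dihedral-or-second-angle
#' (degrees). A reference to an atom at or beyond the atom's own index is
#' a forward reference and an integrity error.
#'
#' @param con Database connection.
#' @param ens_id Ensemble id.
#' @return Character vector of listing lines; the parsed columns are
#'   attached as attribute `"table"` (a data.frame).
#' @export
zmatrix_template <- function(con, ens_id) {
  at <- .atoms_for_template(con, ens_id)
  zr <- t(vapply(at$zmatrix_references, .unpack_ints, integer(4L)))
  zv <- t(vapply(at$zmatrix_values, .unpack_nums, numeric(3L)))
  for (i in seq_len(nrow(at))) {
    refs <- zr[i, 1:3]
    if (any(refs >= at$atom_seq[i] & refs > 0L)) {
      stop(sprintf(
        "integrity error: atom %d has a forward Z-matrix reference",
        at$atom_seq[i]
      ), call. = FALSE)
    }
  }
  tab <- data.frame(
    atom_seq = at$atom_seq, atom_name = trimws(at$atom_name),
    ref_bond = zr[, 1L], ref_angle = zr[, 2L], ref_torsion = zr[, 3L],
    chirality = zr[, 4L], bond_length = zv[, 1L], bond_angle = zv[, 2L],
    torsion = zv[, 3L]
  )
  lines <- sprintf(
    "%5d %-5s %5d %5d %5d %2d %10.5f %10.4f %10.4f",
    tab$atom_seq, tab$atom_name, tab$ref_bond, tab$ref_angle,
    tab$ref_torsion, tab$chirality, tab$bond_length, tab$bond_angle,
    tab$torsion
  )
  attr(lines, "table") <- tab
  lines
}

#' Generate the sequence listing of an ensemble
#'
#' Renders the residue array of the ensemble tier, one token per line.
#' An empty residue array yields a warning (incomplete ensemble
#' metadata) and zero lines.
#'
#' @param con Database connection.
#' @param ens_id Ensemble id.
#' @return Character vector of residue tokens.
#' @export
sequence_template <- function(con, ens_id) {
  row <- DBI::dbGetQuery(con, sprintf(
    "SELECT residues FROM ensembles WHERE ens_id = %d", as.integer(ens_id)
  ))
  if (nrow(row) != 1L) stop(sprintf("unknown ens_id %s", ens_id),
                            call. = FALSE)
  res <- .unpack_residues(row$residues[1])
  if (!length(res)) {
    warning(sprintf("ensemble %d has an empty residues array", ens_id))
  }
  res
}
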