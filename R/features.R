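# Knowledge-vector featurization: hybrid-orbital composition, VSEPR
# electron-domain descriptors, and sigma/pi/conjugation bond decomposition.

HYBRIDIZATION_STATES <- c("UNSPECIFIED", "s", "sp", "sp2", "sp3",
                          "sp3d", "sp3d2")

#' Orbital composition of a hybridization state
#'
#' Maps a hybridization label to the counts (n_s, n_p, n_d) of atomic
#' orbitals mixed into the hybrid: sp3 is one s and three p orbitals, sp3d2
#' adds two d orbitals, and so on. `UNSPECIFIED` (non-main-group atoms or
#' degenerate geometries) maps to (0, 0, 0), a distinct "no information"
#' encoding.
#'
#' @param state one of `"UNSPECIFIED"`, `"s"`, `"sp"`, `"sp2"`, `"sp3"`,
#'   `"sp3d"`, `"sp3d2"`.
#' @return named numeric vector `c(n_s, n_p, n_d)`.
#' @examples
#' phi_hybrid("sp3")  # (1, 3, 0)
#' @export
phi_hybrid <- function(state) {
  tab <- list(
    UNSPECIFIED = c(0, 0, 0),
    s     = c(1, 0, 0),
    sp    = c(1, 1, 0),
    sp2   = c(1, 2, 0),
    sp3   = c(1, 3, 0),
    sp3d  = c(1, 3, 1),
    sp3d2 = c(1, 3, 2)
  )
  if (!is.character(state) || length(state) != 1L || !state %in% names(tab)) {
    stop(structure(
      class = c("kggraph_hybridization_error", "error", "condition"),
      list(message = paste0("unknown hybridization state: ",
                            deparse(substitute(state)), " = ",
                            paste(format(state), collapse = ", ")),
           call = NULL)
    ))
  }
  stats::setNames(tab[[state]], c("n_s", "n_p", "n_d"))
}

#' VSEPR descriptor (x, y) of an atom
#'
#' The AXxEy descriptor of VSEPR theory: `x` counts atoms bonded to the
#' central atom including hydrogens, `y` counts its lone pairs. Lone pairs
#' follow standard electron bookkeeping,
#' y = max(0, (outer-shell electrons - formal charge - total valence) / 2),
#' which gives NH3 one pair, H2O two, CH4 none.
#'
#' @param mol a [parse_smiles()] result.
#' @param atom 1-based atom index.
#' @return named numeric vector `c(x, y)`.
#' @examples
#' phi_vsepr(parse_smiles("N"), 1)  # (3, 1)
#' @export
phi_vsepr <- function(mol, atom) {
  a <- mol_atom(mol, atom)
  c(x = as.numeric(a$x), y = as.numeric(a$y))
}

#' Composite knowledge vector (n_s, n_p, n_d, x, y) of an atom
#'
#' Concatenation of [phi_hybrid()] applied to the atom's hybridization state
#' and [phi_vsepr()]; the 5-component orbital/VSEPR knowledge vector.
#'
#' @inheritParams phi_vsepr
#' @return named numeric vector of length 5.
#' @examples
#' phi_comp(parse_smiles("C"), 1)  # (1, 3, 0, 4, 0)
#' @export
phi_comp <- function(mol, atom) {
  a <- mol_atom(mol, atom)
  c(phi_hybrid(a$hybridization), phi_vsepr(mol, atom))
}

#' Bond knowledge vector (sigma, pi, delta)
#'
#' Every chemical bond carries exactly one sigma component. The pi component
#' is the lateral-overlap count: 0 for single, 1 for double, 2 for triple,
#' and 0.5 for aromatic bonds (a delocalized half pi-bond; the fractional
#' value is regressed, not classified, during pretraining). `delta` flags
#' membership in a conjugated system, aromatic rings included.
#'
#' @param mol a [parse_smiles()] result.
#' @param bond 1-based row index into `mol$bonds`, or a length-2 vector of
#'   atom indices identifying the bond.
#' @return named numeric vector `c(sigma, pi, delta)`.
#' @examples
#' bond_knowledge(parse_smiles("CC"), 1)  # (1, 0, 0)
#' @export
bond_knowledge <- function(mol, bond) {
  b <- mol_bond(mol, bond)
  c(sigma = b$sigma, pi = b$pi, delta = b$delta)
}

#' 7-component atom feature vector
#'
#' `(atomic_number, degree, n_s, n_p, n_d, x, y)`: the atomic number, the
#' heavy-atom neighbor count, and the composite knowledge vector. Note the
#' deliberate asymmetry: `degree` excludes hydrogens while the VSEPR `x`
#' includes them (methane carbon has degree 0 but x = 4).
#'
#' @inheritParams phi_vsepr
#' @return numeric vector of length 7.
#' @export
atom_features <- function(mol, atom) {
  a <- mol_atom(mol, atom)
  stats::setNames(
    c(a$atomic_number, a$degree, a$n_s, a$n_p, a$n_d, a$x, a$y),
    c("atomic_number", "degree", "n_s", "n_p", "n_d", "x", "y")
  )
}

#' 5-component bond feature vector
#'
#' `(type_code, ring_flag, sigma, pi, delta)`: an integer bond-type code
#' (see [bond_type_codes()]), a ring-membership flag, and the bond knowledge
#' vector.
#'
#' @inheritParams bond_knowledge
#' @return numeric vector of length 5.
#' @export
bond_features <- function(mol, bond) {
  b <- mol_bond(mol, bond)
  stats::setNames(
    c(b$type_code, as.numeric(b$in_ring), b$sigma, b$pi, b$delta),
    c("type_code", "ring_flag", "sigma", "pi", "delta")
  )
}

#' Full per-atom / per-bond feature tables
#'
#' One row per atom (resp. bond), suitable for CSV export via
#' [utils::write.csv()].
#'
#' @param mol a [parse_smiles()] result.
#' @return a data frame.
#' @export
atom_feature_table <- function(mol) {
  stopifnot(inherits(mol, "kgg_mol"))
  a <- mol$atoms
  data.frame(atom = a$idx, atomic_number = a$atomic_number,
             degree = a$degree, n_s = a$n_s, n_p = a$n_p, n_d = a$n_d,
             x = a$x, y = a$y)
}

#' @rdname atom_feature_table
#' @export
bond_feature_table <- function(mol) {
  stopifnot(inherits(mol, "kgg_mol"))
  b <- mol$bonds
  data.frame(i = b$i, j = b$j, type_code = b$type_code,
             ring_flag = as.numeric(b$in_ring),
             sigma = b$sigma, pi = b$pi, delta = b$delta)
}

mol_atom <- function(mol, atom) {
  stopifnot(inherits(mol, "kgg_mol"))
  if (!(is.numeric(atom) && length(atom) == 1L &&
        atom >= 1L && atom <= mol$n_atoms)) {
    stop("atom index out of range: ", paste(atom, collapse = ","),
         call. = FALSE)
  }
  mol$atoms[atom, , drop = FALSE]
}

mol_bond <- function(mol, bond) {
  stopifnot(inherits(mol, "kgg_mol"))
  b <- mol$bonds
  if (length(bond) == 2L) {
    ij <- sort(as.integer(bond))
    row <- which(b$i == ij[1L] & b$j == ij[2L])
    if (length(row) != 1L) {
      stop("no bond between atoms ", ij[1L], " and ", ij[2L], call. = FALSE)
    }
  } else if (length(bond) == 1L && bond >= 1L && bond <= nrow(b)) {
    row <- as.integer(bond)
  } else {
    stop("invalid bond selector", call. = FALSE)
  }
  b[row, , drop = FALSE]
}
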