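# SMILES -> annotated heavy-atom molecular graph.
#
# Molecules are handled with implicit hydrogens: explicit H atoms in the
# input are folded into per-atom hydrogen counts, so |V| counts heavy atoms
# only (benzene has |V| = 6). Aromaticity and ring perception come from
# OpenBabel; bond orders are Kekule orders with an aromatic flag alongside.

ELEMENT_SYMBOLS <- c(
  "H", "He", "Li", "Be", "B", "C", "N", "O", "F", "Ne", "Na", "Mg", "Al",
  "Si", "P", "S", "Cl", "Ar", "K", "Ca", "Sc", "Ti", "V", "Cr", "Mn", "Fe",
  "Co", "Ni", "Cu", "Zn", "Ga", "Ge", "As", "Se", "Br", "Kr", "Rb", "Sr",
  "Y", "Zr", "Nb", "Mo", "Tc", "Ru", "Rh", "Pd", "Ag", "Cd", "In", "Sn",
  "Sb", "Te", "I", "Xe", "Cs", "Ba", "La", "Ce", "Pr", "Nd", "Pm", "Sm",
  "Eu", "Gd", "Tb", "Dy", "Ho", "Er", "Tm", "Yb", "Lu", "Hf", "Ta", "W",
  "Re", "Os", "Ir", "Pt", "Au", "Hg", "Tl", "Pb", "Bi", "Po", "At", "Rn")

# Outer-shell (valence) electron counts for main-group elements; NA for the
# d/f blocks, whose atoms get the UNSPECIFIED hybridization sentinel.
valence_electrons <- function(z) {
  ve <- rep(NA_real_, 118)
  ve[1:2] <- c(1, 2)
  ve[3:10] <- 1:8
  ve[11:18] <- 1:8
  ve[19:20] <- 1:2
  ve[31:36] <- 3:8
  ve[37:38] <- 1:2
  ve[49:54] <- 3:8
  ve[55:56] <- 1:2
  ve[81:86] <- 3:8
  ve[z]
}

#' Parse a SMILES string into an annotated molecular graph
#'
#' Builds the heavy-atom graph G = (V, E) and attaches, per atom, the
#' orbital/VSEPR knowledge annotations (lone pairs, electron-domain
#' hybridization, orbital composition) and, per bond, the sigma/pi/
#' conjugation decomposition. Syntax failures and sanitization failures
#' (input that parses to an empty molecule) raise the condition classes
#' `kggraph_syntax_error` and `kggraph_sanitize_error`, both subclasses of
#' `kggraph_parse_error`, carrying the offending string in `$smiles`.
#'
#' @param smiles a single SMILES string.
#' @return an object of class `kgg_mol`: a list with `smiles`, `n_atoms`,
#'   `n_bonds`, and data frames `atoms` (columns `idx`, `symbol`,
#'   `atomic_number`, `charge`, `degree` heavy-atom degree, `n_h` hydrogen
#'   count, `x` bonded-atom count incl. hydrogens, `y` lone pairs,
#'   `hybridization`, `n_s`, `n_p`, `n_d`, `aromatic`, `in_ring`) and
#'   `bonds` (1-based endpoint columns `i` < `j`, `order`, `aromatic`,
#'   `in_ring`, `conjugated`, `type_code`, `sigma`, `pi`, `delta`).
#' @examples
#' mol <- parse_smiles("c1ccccc1")
#' mol$n_atoms  # 6
#' @export
parse_smiles <- function(smiles) {
  mol <- ob_parse(smiles)
  on.exit(ob_free(mol))
  ob_call("OBMol_DeleteHydrogens", mol)
  n <- ob_call("OBMol_NumAtoms", mol)
  if (n == 0L) stop(kgg_parse_error(smiles, "no heavy atoms", "sanitize"))
  nb <- ob_call("OBMol_NumBonds", mol)

  z <- integer(n); chg <- integer(n); nh <- integer(n); val <- integer(n)
  deg <- integer(n); x <- integer(n); arom <- logical(n); ring <- logical(n)
  for (i in seq_len(n)) {
    a <- ob_call("OBMol_GetAtom", mol, i)
    z[i] <- ob_call("OBAtom_GetAtomicNum", a)
    chg[i] <- ob_call("OBAtom_GetFormalCharge", a)
    nh[i] <- ob_call("OBAtom_GetImplicitHCount", a) +
      ob_call("OBAtom_ExplicitHydrogenCount", a)
    val[i] <- ob_call("OBAtom_GetTotalValence", a)
    deg[i] <- ob_call("OBAtom_GetHvyDegree", a)
    x[i] <- ob_call("OBAtom_GetTotalDegree", a)
    arom[i] <- ob_call("OBAtom_IsAromatic", a)
    ring[i] <- ob_call("OBAtom_IsInRing", a)
  }

  bi <- integer(nb); bj <- integer(nb); border <- integer(nb)
  barom <- logical(nb); bring <- logical(nb)
  for (b in seq_len(nb)) {
    bd <- ob_call("OBMol_GetBond", mol, b - 1L)
    bi[b] <- ob_call("OBBond_GetBeginAtomIdx", bd)
    bj[b] <- ob_call("OBBond_GetEndAtomIdx", bd)
    border[b] <- ob_call("OBBond_GetBondOrder", bd)
    barom[b] <- ob_call("OBBond_IsAromatic", bd)
    bring[b] <- ob_call("OBBond_IsInRing", bd)
  }
  swap <- bi > bj
  tmp <- bi[swap]; bi[swap] <- bj[swap]; bj[swap] <- tmp

  ve <- valence_electrons(z)
  y <- ifelse(is.na(ve), 0L, pmax(0, (ve - chg - val) %/% 2))
  hyb <- electron_domain_hybridization(x + y, main_group = !is.na(ve))
  orb <- t(vapply(hyb, phi_hybrid, numeric(3)))

  atoms <- data.frame(
    idx = seq_len(n),
    symbol = ELEMENT_SYMBOLS[z],
    atomic_number = z,
    charge = chg,
    degree = deg,
    n_h = nh,
    x = x,
    y = as.integer(y),
    hybridization = hyb,
    n_s = orb[, 1L],
    n_p = orb[, 2L],
    n_d = orb[, 3L],
    aromatic = arom,
    in_ring = ring,
    stringsAsFactors = FALSE
  )

  bonds <- data.frame(
    i = bi, j = bj, order = border, aromatic = barom, in_ring = bring,
    stringsAsFactors = FALSE
  )
  bonds <- bonds[order(bonds$i, bonds$j), , drop = FALSE]
  rownames(bonds) <- NULL
  bonds$conjugated <- perceive_conjugation(atoms, bonds)
  bonds$type_code <- bond_type_code(bonds$order, bonds$aromatic)
  bonds$sigma <- rep(1, nrow(bonds))
  bonds$pi <- pi_contribution(bonds$order, bonds$aromatic)
  bonds$delta <- as.numeric(bonds$conjugated)

  structure(
    list(smiles = smiles, n_atoms = n, n_bonds = nb,
         atoms = atoms, bonds = bonds),
    class = "kgg_mol"
  )
}

#' @export
print.kgg_mol <- function(x, ...) {
  cat(sprintf("<kgg_mol> %s: %d atoms, %d bonds\n",
              x$smiles, x$n_atoms, x$n_bonds))
  invisible(x)
}

# Hybridization from the electron-domain (steric) count x + y. This keeps
# the orbital composition and the VSEPR descriptor consistent by
# construction: n_s + n_p + n_d always equals the domain count for the
# specified states.
electron_domain_hybridization <- function(steric, main_group) {
  labels <- c("s", "sp", "sp2", "sp3", "sp3d", "sp3d2")
  out <- ifelse(main_group & steric >= 1 & steric <= 6,
                labels[pmax(steric, 1)], "UNSPECIFIED")
  out
}

# Conjugation perception, modeled on the usual cheminformatics rule: at any
# pi-capable atom (carries a multiple/aromatic bond or a lone pair), a pair
# of incident bonds of which at least one is multiple/aromatic and whose far
# atoms are themselves pi-capable is part of a conjugated system. An
# isolated double bond (ethene) has no such pair and stays unconjugated.
perceive_conjugation <- function(atoms, bonds) {
  nb <- nrow(bonds)
  conj <- logical(nb)
  if (nb == 0L) return(conj)
  multiple <- bonds$order >= 2 | bonds$aromatic
  has_pi <- logical(nrow(atoms))
  for (b in seq_len(nb)) {
    if (multiple[b]) has_pi[c(bonds$i[b], bonds$j[b])] <- TRUE
  }
  capable <- has_pi | atoms$y >= 1
  incident <- split(rep(seq_len(nb), 2L), c(bonds$i, bonds$j))
  for (a in which(capable)) {
    bs <- incident[[as.character(a)]]
    if (is.null(bs) || length(bs) < 2L) next
    for (p in seq_along(bs)) {
      for (q in seq_along(bs)) {
        if (p >= q) next
        b1 <- bs[p]; b2 <- bs[q]
        if (!(multiple[b1] || multiple[b2])) next
        far1 <- setdiff(c(bonds$i[b1], bonds$j[b1]), a)
        far2 <- setdiff(c(bonds$i[b2], bonds$j[b2]), a)
        if (capable[far1] && capable[far2]) conj[c(b1, b2)] <- TRUE
      }
    }
  }
  conj | bonds$aromatic
}

bond_type_code <- function(order, aromatic) {
  code <- ifelse(aromatic, 3L,
                 ifelse(order == 1L, 0L,
                        ifelse(order == 2L, 1L,
                               ifelse(order == 3L, 2L, NA_integer_))))
  if (anyNA(code)) {
    stop("unsupported bond order: ", paste(order[is.na(code)], collapse = ", "),
         call. = FALSE)
  }
  code
}

pi_contribution <- function(order, aromatic) {
  if (any(order > 3L & !aromatic)) {
    stop("unsupported bond order: ",
         paste(unique(order[order > 3L & !aromatic]), collapse = ", "),
         call. = FALSE)
  }
  ifelse(aromatic, 0.5, order - 1)
}

#' The bond-type integer code map (serialized with checkpoints)
#' @return named integer vector mapping bond kinds to codes.
#' @export
bond_type_codes <- function() {
  c(single = 0L, double = 1L, triple = 2L, aromatic = 3L)
}
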