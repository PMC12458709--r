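# Three-level hierarchical molecular graph: atoms, motifs, supernode.
#
# Motifs are the connected components left after cutting (a) BRICS link
# bonds and (b) every acyclic bond joining a ring atom to a non-ring atom
# (the ring/substituent separation rule). Cut bonds remain present in the
# atom-level edge set E; cutting affects motif membership only.

# BRICS link environments (Degen et al., ChemMedChem 3:1503-1507, 2008),
# including the later curation used by common implementations: the original
# secondary-amine environment is merged into the general amine L5, and the
# 9-13, 9-14, 14-14 and 16-16 links are admitted. Each pattern is a
# single-atom recursive SMARTS whose match is the link attachment atom.
brics_environments <- function() {
  c(
    "1"  = "[$([C;D3]([#6,#7,#8])(=O))]",
    "3"  = "[$([O;D2]-;!@[#6,#1])]",
    "4"  = "[$([C;!D1;!$(C=*)]-;!@[#6])]",
    "5"  = "[$([N;!D1;!$(N=*);!$(N-[!#6;!#16;!#1]);!$([N;R]@[C;R]=O)])]",
    "6"  = "[$([C;D3;!R](=O)-;!@[#6,#7,#8])]",
    "7"  = "[$([C;D2,D3]-[#6])]",
    "8"  = "[$([C;!R;!D1;!$(C!-*)])]",
    "9"  = "[$([n;+0;$(n(:[c,n,o,s]):[c,n,o,s])])]",
    "10" = "[$([N;R;$(N(@C(=O))@[C,N,O,S])])]",
    "11" = "[$([S;D2](-;!@[#6]))]",
    "12" = "[$([S;D4]([#6])(=O)(=O))]",
    "13" = "[$([C;$(C(-;@[C,N,O,S])-;@[N,O,S])])]",
    "14" = "[$([c;$(c(:[c,n,o,s]):[n,o,s])])]",
    "15" = "[$([C;$(C(-;@C)-;@C)])]",
    "16" = "[$([c;$(c(:c):c)])]"
  )
}

# Compatible environment pairs; every pair is a single-bond link except
# 7-7, which cuts an acyclic double bond (alkene link).
brics_pairs <- function() {
  m <- rbind(
    c(1, 3), c(1, 5), c(1, 10),
    c(3, 4), c(3, 13), c(3, 14), c(3, 15), c(3, 16),
    c(4, 5), c(4, 11),
    c(5, 12), c(5, 13), c(5, 14), c(5, 15), c(5, 16),
    c(6, 13), c(6, 14), c(6, 15), c(6, 16),
    c(8, 9), c(8, 10), c(8, 13), c(8, 14), c(8, 15), c(8, 16),
    c(9, 13), c(9, 14), c(9, 15), c(9, 16),
    c(10, 13), c(10, 14), c(10, 15), c(10, 16),
    c(11, 13), c(11, 14), c(11, 15), c(11, 16),
    c(13, 14), c(13, 15), c(13, 16),
    c(14, 14), c(14, 15), c(14, 16),
    c(15, 16),
    c(16, 16)
  )
  data.frame(a = as.character(m[, 1]), b = as.character(m[, 2]),
             bond = "-", stringsAsFactors = FALSE)
}

# Per-atom BRICS environment label sets for a molecule.
brics_labels <- function(smiles, n_atoms) {
  obmol <- ob_parse(smiles)
  on.exit(ob_free(obmol))
  ob_call("OBMol_DeleteHydrogens", obmol)
  envs <- brics_environments()
  labels <- vector("list", n_atoms)
  for (nm in names(envs)) {
    hits <- ob_smarts_match(obmol, envs[[nm]])
    for (h in hits) {
      a <- h[1L]
      labels[[a]] <- c(labels[[a]], nm)
    }
  }
  labels
}

#' Identify bonds cut by the motif decomposition rules
#'
#' @param mol a [parse_smiles()] result.
#' @return integer vector of row indices into `mol$bonds`.
#' @keywords internal
motif_cut_bonds <- function(mol) {
  b <- mol$bonds
  if (nrow(b) == 0L) return(integer(0))
  labels <- brics_labels(mol$smiles, mol$n_atoms)
  pairs <- brics_pairs()
  cut <- logical(nrow(b))
  for (k in seq_len(nrow(b))) {
    if (b$in_ring[k] || b$aromatic[k]) next
    li <- labels[[b$i[k]]]; lj <- labels[[b$j[k]]]
    if (b$order[k] == 1L && length(li) && length(lj)) {
      hit <- any((pairs$a %in% li & pairs$b %in% lj) |
                   (pairs$a %in% lj & pairs$b %in% li))
      if (hit) { cut[k] <- TRUE; next }
    }
    if (b$order[k] == 2L && "7" %in% li && "7" %in% lj) {
      cut[k] <- TRUE; next
    }
    # ring/substituent rule: acyclic bond between a ring atom and a
    # non-ring atom
    ri <- mol$atoms$in_ring[b$i[k]]; rj <- mol$atoms$in_ring[b$j[k]]
    if (xor(ri, rj)) cut[k] <- TRUE
  }
  which(cut)
}

#' Decompose a molecule into motifs
#'
#' Cuts all BRICS link bonds plus all acyclic ring/non-ring bonds; the
#' connected components of the remaining graph are the motifs. The result
#' is always a partition of the atom indices: every atom belongs to exactly
#' one motif, and a single-atom molecule yields one singleton motif.
#'
#' @param mol a [parse_smiles()] result.
#' @return list of integer vectors of atom indices, ordered by each motif's
#'   smallest atom index.
#' @examples
#' length(motif_decompose(parse_smiles("c1ccccc1")))   # 1
#' length(motif_decompose(parse_smiles("CCc1ccccc1"))) # 2
#' @export
motif_decompose <- function(mol) {
  stopifnot(inherits(mol, "kgg_mol"))
  keep <- setdiff(seq_len(nrow(mol$bonds)), motif_cut_bonds(mol))
  g <- igraph::make_empty_graph(n = mol$n_atoms, directed = FALSE)
  if (length(keep)) {
    g <- igraph::add_edges(g, rbind(mol$bonds$i[keep], mol$bonds$j[keep]))
  }
  comp <- igraph::components(g)$membership
  motifs <- unname(split(seq_len(mol$n_atoms), comp))
  motifs[order(vapply(motifs, min, integer(1)))]
}

#' Build the three-level hierarchical graph
#'
#' Augments the molecular graph with one motif node per motif and a single
#' supernode: node ids 1..|V| are atoms, |V|+1..|V|+|Vm| are motif nodes in
#' motif order, and |V|+|Vm|+1 is the supernode. Edge sets: `E` (atom-atom
#' chemical bonds), `E_m` (motif-atom membership), `E_g` (supernode-motif).
#'
#' @param mol a [parse_smiles()] result.
#' @param partition optional motif partition as from [motif_decompose()]
#'   (computed if missing). Must partition the atom indices.
#' @return an object of class `kgg_hgraph`.
#' @examples
#' hg <- build_hierarchical_graph(parse_smiles("c1ccccc1"))
#' hg$n_atoms + hg$n_motifs + 1  # 8 nodes
#' @export
build_hierarchical_graph <- function(mol, partition = NULL) {
  stopifnot(inherits(mol, "kgg_mol"))
  if (is.null(partition)) partition <- motif_decompose(mol)
  idx <- sort(unlist(partition))
  if (length(idx) != mol$n_atoms || !identical(idx, seq_len(mol$n_atoms)) ||
      any(lengths(partition) == 0L)) {
    stop(structure(
      class = c("kggraph_partition_error", "error", "condition"),
      list(message = "partition does not cover the molecule's atoms exactly once",
           call = NULL)
    ))
  }
  n <- mol$n_atoms
  m <- length(partition)
  motif_ids <- n + seq_len(m)
  super_id <- n + m + 1L
  e_m <- data.frame(
    motif = rep(motif_ids, lengths(partition)),
    atom = unlist(partition)
  )
  structure(
    list(mol = mol, motifs = partition,
         n_atoms = n, n_motifs = m,
         motif_ids = motif_ids, super_id = super_id,
         e_atom = mol$bonds[, c("i", "j")],
         e_motif = e_m,
         e_super = data.frame(super = super_id, motif = motif_ids)),
    class = "kgg_hgraph"
  )
}

#' @export
print.kgg_hgraph <- function(x, ...) {
  cat(sprintf("<kgg_hgraph> %s: %d atoms + %d motifs + supernode, |E|=%d |E_m|=%d |E_g|=%d\n",
              x$mol$smiles, x$n_atoms, x$n_motifs,
              nrow(x$e_atom), nrow(x$e_motif), nrow(x$e_super)))
  invisible(x)
}

MOTIF_SENTINEL <- 120
GRAPH_SENTINEL <- 119

#' Assemble the sentinel-initialized feature stack
#'
#' Stacks the raw 7-component atom features (zero-padded to width `d`), one
#' sentinel row `[120, 0, ...]` per motif, and the graph sentinel row
#' `[119, 0, ...]` into the (|V| + |Vm| + 1) x d input matrix. The sentinel
#' scalars sit just above the atomic-number vocabulary (<= 118), preserving
#' level identity in the shared first component. Benzene at d = 7 yields
#' the 8 x 7 stack (6 atom rows, 1 motif row, 1 graph row).
#'
#' @param hgraph a [build_hierarchical_graph()] result.
#' @param d embedding width, at least 7.
#' @return numeric matrix of shape `(n_atoms + n_motifs + 1) x d`.
#' @export
assemble_feature_stack <- function(hgraph, d = 7L) {
  stopifnot(inherits(hgraph, "kgg_hgraph"))
  if (d < 7L) stop("embedding width d must be at least 7", call. = FALSE)
  n <- hgraph$n_atoms; m <- hgraph$n_motifs
  stack <- matrix(0, nrow = n + m + 1L, ncol = d)
  af <- atom_feature_table(hgraph$mol)
  stack[seq_len(n), 1:7] <- as.matrix(af[, -1L])
  stack[n + seq_len(m), 1L] <- MOTIF_SENTINEL
  stack[n + m + 1L, 1L] <- GRAPH_SENTINEL
  stack
}

#' Export a hierarchical graph as plain-text tables
#'
#' Writes `nodes.csv` (node id, layer, first feature component),
#' `edges.csv` (endpoints plus an edge-layer column: `atom`, `motif`,
#' `super`) and `feature_stack.csv` to `dir`.
#'
#' @param hgraph a [build_hierarchical_graph()] result.
#' @param dir output directory (created if needed).
#' @param d embedding width for the feature stack.
#' @return `dir`, invisibly.
#' @export
export_hgraph <- function(hgraph, dir, d = 7L) {
  stopifnot(inherits(hgraph, "kgg_hgraph"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  n <- hgraph$n_atoms; m <- hgraph$n_motifs
  nodes <- data.frame(
    node = seq_len(n + m + 1L),
    layer = c(rep("atom", n), rep("motif", m), "super")
  )
  edges <- rbind(
    data.frame(from = hgraph$e_atom$i, to = hgraph$e_atom$j, layer = "atom"),
    data.frame(from = hgraph$e_motif$motif, to = hgraph$e_motif$atom,
               layer = "motif"),
    data.frame(from = hgraph$e_super$super, to = hgraph$e_super$motif,
               layer = "super")
  )
  utils::write.csv(nodes, file.path(dir, "nodes.csv"), row.names = FALSE)
  utils::write.csv(edges, file.path(dir, "edges.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(assemble_feature_stack(hgraph, d)),
                   file.path(dir, "feature_stack.csv"), row.names = FALSE)
  invisible(dir)
}
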