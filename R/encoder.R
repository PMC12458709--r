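# The hierarchical-graph encoder: per-component embedding sums followed by
# five GINConv layers with BatchNorm/ELU/Dropout (ELU omitted in layer 5),
# reading out the supernode embedding at layer 5 as the molecular
# fingerprint.

N_NODE_COMPONENTS <- 7L
N_EDGE_COMPONENTS <- 5L

#' Encoder configuration
#'
#' @param d embedding width (default 512, the width used for full-scale
#'   training; tests and examples use smaller widths).
#' @param n_layers number of GINConv layers (5).
#' @param dropout dropout probability applied after each layer during
#'   training.
#' @param emb_hidden hidden width of the per-component input embedding MLPs.
#' @param seed integer seed controlling weight initialization.
#' @return a list of class `kgg_encoder_config`.
#' @export
encoder_config <- function(d = 512L, n_layers = 5L, dropout = 0.1,
                           emb_hidden = 16L, seed = 1L) {
  stopifnot(d >= 1, n_layers >= 1, dropout >= 0, dropout < 1, emb_hidden >= 1)
  structure(list(d = as.integer(d), n_layers = as.integer(n_layers),
                 dropout = dropout, emb_hidden = as.integer(emb_hidden),
                 seed = as.integer(seed)),
            class = "kgg_encoder_config")
}

# Initialize encoder parameters (flat named list) and BatchNorm state.
encoder_init <- function(config) {
  set.seed(config$seed)
  d <- config$d; h <- config$emb_hidden
  p <- list()
  for (k in seq_len(N_NODE_COMPONENTS)) {
    l1 <- init_linear(h, 1L); l2 <- init_linear(d, h)
    p[[sprintf("ne%d.W1", k)]] <- l1$W; p[[sprintf("ne%d.b1", k)]] <- l1$b
    p[[sprintf("ne%d.W2", k)]] <- l2$W; p[[sprintf("ne%d.b2", k)]] <- l2$b
  }
  for (k in seq_len(N_EDGE_COMPONENTS)) {
    l1 <- init_linear(h, 1L); l2 <- init_linear(d, h)
    p[[sprintf("ee%d.W1", k)]] <- l1$W; p[[sprintf("ee%d.b1", k)]] <- l1$b
    p[[sprintf("ee%d.W2", k)]] <- l2$W; p[[sprintf("ee%d.b2", k)]] <- l2$b
  }
  state <- list()
  for (l in seq_len(config$n_layers)) {
    l1 <- init_linear(2L * d, d); l2 <- init_linear(d, 2L * d)
    p[[sprintf("gin%d.W1", l)]] <- l1$W; p[[sprintf("gin%d.b1", l)]] <- l1$b
    p[[sprintf("gin%d.W2", l)]] <- l2$W; p[[sprintf("gin%d.b2", l)]] <- l2$b
    p[[sprintf("gin%d.gamma", l)]] <- rep(1, d)
    p[[sprintf("gin%d.beta", l)]] <- rep(0, d)
    state[[sprintf("bn%d.mean", l)]] <- rep(0, d)
    state[[sprintf("bn%d.var", l)]] <- rep(1, d)
  }
  list(params = p, state = state)
}

# -- batch tensors ------------------------------------------------------------

# Per-molecule tensor pack; combined into block-diagonal batches below.
graph_tensors <- function(hgraph) {
  stopifnot(inherits(hgraph, "kgg_hgraph"))
  mol <- hgraph$mol
  n <- hgraph$n_atoms; m <- hgraph$n_motifs
  n_nodes <- n + m + 1L
  af <- as.matrix(atom_feature_table(mol)[, -1L, drop = FALSE])
  x1 <- c(af[, 1L], rep(MOTIF_SENTINEL, m), GRAPH_SENTINEL)
  bf <- as.matrix(bond_feature_table(mol)[, -(1:2), drop = FALSE])
  edges <- rbind(
    cbind(mol$bonds$i, mol$bonds$j),
    cbind(hgraph$e_motif$motif, hgraph$e_motif$atom),
    cbind(hgraph$e_super$super, hgraph$e_super$motif)
  )
  list(n_nodes = n_nodes, n_atoms = n, n_bonds = nrow(mol$bonds),
       x1 = x1, atom_comp = af[, -1L, drop = FALSE],
       bond_feat = bf, bond_i = mol$bonds$i, bond_j = mol$bonds$j,
       edges = edges)
}

# Combine per-molecule tensors into one batch with global node indices.
combine_batch <- function(tensors) {
  counts <- vapply(tensors, `[[`, integer(1), "n_nodes")
  offsets <- cumsum(c(0L, counts[-length(counts)]))
  N <- sum(counts)
  x1 <- unlist(lapply(tensors, `[[`, "x1"), use.names = FALSE)
  atom_rows <- unlist(mapply(function(t, o) o + seq_len(t$n_atoms),
                             tensors, offsets, SIMPLIFY = FALSE),
                      use.names = FALSE)
  super_rows <- offsets + counts
  atom_comp <- do.call(rbind, lapply(tensors, `[[`, "atom_comp"))
  bond_feat <- do.call(rbind, lapply(tensors, `[[`, "bond_feat"))
  bond_i <- unlist(mapply(function(t, o) o + t$bond_i, tensors, offsets,
                          SIMPLIFY = FALSE), use.names = FALSE)
  bond_j <- unlist(mapply(function(t, o) o + t$bond_j, tensors, offsets,
                          SIMPLIFY = FALSE), use.names = FALSE)
  ed <- do.call(rbind, mapply(function(t, o) t$edges + o, tensors, offsets,
                              SIMPLIFY = FALSE))
  A <- Matrix::sparseMatrix(i = c(ed[, 1L], ed[, 2L]),
                            j = c(ed[, 2L], ed[, 1L]),
                            x = 1, dims = c(N, N))
  nb <- length(bond_i)
  B <- if (nb > 0L) {
    Matrix::sparseMatrix(i = c(bond_i, bond_j), j = rep(seq_len(nb), 2L),
                         x = 1, dims = c(N, nb))
  } else {
    Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                         dims = c(N, 0L))
  }
  list(N = N, n_graphs = length(tensors), counts = counts, offsets = offsets,
       x1 = x1, atom_rows = atom_rows, super_rows = super_rows,
       atom_comp = atom_comp, bond_feat = bond_feat,
       bond_i = bond_i, bond_j = bond_j,
       n_atoms = vapply(tensors, `[[`, integer(1), "n_atoms"),
       n_bonds = vapply(tensors, `[[`, integer(1), "n_bonds"),
       A = A, B = B)
}

# -- initial embeddings -------------------------------------------------------

# h0_v = sum_k MLP_k(x_v^k). Motif and supernode rows carry only their
# sentinel scalar (120/119), routed through the first (atomic-number)
# component map; components 2..7 contribute for atom rows only.
embed_initial_forward <- function(batch, params, d) {
  N <- batch$N
  caches <- vector("list", N_NODE_COMPONENTS)
  caches[[1L]] <- mlp2_forward(matrix(batch$x1, ncol = 1L), params, "ne1")
  H0 <- caches[[1L]]$out
  for (k in 2:N_NODE_COMPONENTS) {
    ck <- mlp2_forward(matrix(batch$atom_comp[, k - 1L], ncol = 1L),
                       params, sprintf("ne%d", k))
    H0[batch$atom_rows, ] <- H0[batch$atom_rows, , drop = FALSE] + ck$out
    caches[[k]] <- ck
  }
  nb <- length(batch$bond_i)
  ecaches <- vector("list", N_EDGE_COMPONENTS)
  E0 <- matrix(0, nb, d)
  if (nb > 0L) {
    for (k in seq_len(N_EDGE_COMPONENTS)) {
      ck <- mlp2_forward(matrix(batch$bond_feat[, k], ncol = 1L),
                         params, sprintf("ee%d", k))
      E0 <- E0 + ck$out
      ecaches[[k]] <- ck
    }
  }
  list(H0 = H0, E0 = E0, node_caches = caches, edge_caches = ecaches)
}

embed_initial_backward <- function(cache, dH0, dE0, batch, params, grads) {
  res <- mlp2_backward(cache$node_caches[[1L]], dH0, params, grads)
  grads <- res$grads
  dA <- dH0[batch$atom_rows, , drop = FALSE]
  for (k in 2:N_NODE_COMPONENTS) {
    res <- mlp2_backward(cache$node_caches[[k]], dA, params, grads)
    grads <- res$grads
  }
  if (length(batch$bond_i) > 0L) {
    for (k in seq_len(N_EDGE_COMPONENTS)) {
      res <- mlp2_backward(cache$edge_caches[[k]], dE0, params, grads)
      grads <- res$grads
    }
  }
  grads
}

# -- GIN layers ---------------------------------------------------------------

gin_layer_forward <- function(H, EB, batch, params, state, l, config,
                              training) {
  S <- H + as.matrix(batch$A %*% H) + EB
  Z1 <- S %*% t(params[[sprintf("gin%d.W1", l)]]) +
    row_broadcast(params[[sprintf("gin%d.b1", l)]], batch$N)
  R <- relu(Z1)
  Z2 <- R %*% t(params[[sprintf("gin%d.W2", l)]]) +
    row_broadcast(params[[sprintf("gin%d.b2", l)]], batch$N)
  bn <- bn_forward(Z2, params[[sprintf("gin%d.gamma", l)]],
                   params[[sprintf("gin%d.beta", l)]],
                   state, sprintf("bn%d", l), training)
  state <- bn$state
  last <- l == config$n_layers
  U <- if (last) bn$out else elu(bn$out)
  if (training && config$dropout > 0) {
    mask <- matrix(
      (stats::runif(batch$N * config$d) >= config$dropout) /
        (1 - config$dropout),
      batch$N, config$d)
    out <- U * mask
  } else {
    mask <- NULL
    out <- U
  }
  list(out = out, S = S, Z1 = Z1, R = R, bn = bn, T = bn$out, U = U,
       mask = mask, last = last, state = state)
}

gin_layer_backward <- function(cache, dOut, batch, params, grads, l) {
  dU <- if (is.null(cache$mask)) dOut else dOut * cache$mask
  dT <- if (cache$last) dU else dU * ifelse(cache$T > 0, 1, cache$U + 1)
  bnb <- bn_backward(cache$bn, dT, params[[sprintf("gin%d.gamma", l)]])
  grads[[sprintf("gin%d.gamma", l)]] <-
    grads[[sprintf("gin%d.gamma", l)]] + bnb$dgamma
  grads[[sprintf("gin%d.beta", l)]] <-
    grads[[sprintf("gin%d.beta", l)]] + bnb$dbeta
  dZ2 <- bnb$dZ
  W2 <- params[[sprintf("gin%d.W2", l)]]
  W1 <- params[[sprintf("gin%d.W1", l)]]
  grads[[sprintf("gin%d.W2", l)]] <- grads[[sprintf("gin%d.W2", l)]] +
    t(dZ2) %*% cache$R
  grads[[sprintf("gin%d.b2", l)]] <- grads[[sprintf("gin%d.b2", l)]] +
    colSums(dZ2)
  dR <- dZ2 %*% W2
  dZ1 <- dR * (cache$Z1 > 0)
  grads[[sprintf("gin%d.W1", l)]] <- grads[[sprintf("gin%d.W1", l)]] +
    t(dZ1) %*% cache$S
  grads[[sprintf("gin%d.b1", l)]] <- grads[[sprintf("gin%d.b1", l)]] +
    colSums(dZ1)
  dS <- dZ1 %*% W1
  dH <- dS + as.matrix(batch$A %*% dS)
  list(dH = dH, dEB = dS, grads = grads)
}

# Full forward pass through embeddings and all GIN layers.
encoder_forward <- function(batch, params, state, config, training = FALSE) {
  emb <- embed_initial_forward(batch, params, config$d)
  EB <- if (ncol(batch$B) > 0L) as.matrix(batch$B %*% emb$E0) else
    matrix(0, batch$N, config$d)
  H <- emb$H0
  layer_caches <- vector("list", config$n_layers)
  for (l in seq_len(config$n_layers)) {
    lc <- gin_layer_forward(H, EB, batch, params, state, l, config, training)
    state <- lc$state
    H <- lc$out
    layer_caches[[l]] <- lc
  }
  list(H = H, emb = emb, EB = EB, layer_caches = layer_caches, state = state)
}

# Backward from a gradient on the final node embeddings.
encoder_backward <- function(fwd, dH, batch, params, config) {
  grads <- list()
  for (nm in names(params)) {
    p <- params[[nm]]
    grads[[nm]] <- if (is.matrix(p)) matrix(0, nrow(p), ncol(p)) else
      numeric(length(p))
  }
  dEB <- matrix(0, batch$N, config$d)
  for (l in rev(seq_len(config$n_layers))) {
    res <- gin_layer_backward(fwd$layer_caches[[l]], dH, batch, params,
                              grads, l)
    grads <- res$grads
    dH <- res$dH
    dEB <- dEB + res$dEB
  }
  dE0 <- if (ncol(batch$B) > 0L) as.matrix(Matrix::crossprod(batch$B, dEB))
    else matrix(0, 0L, config$d)
  embed_initial_backward(fwd$emb, dH, dE0, batch, params, grads)
}

# -- public encoding API ------------------------------------------------------

#' Encode hierarchical graphs into embeddings and fingerprints
#'
#' Runs the per-component input embeddings and the five GINConv layers.
#' In `"eval"` mode dropout is disabled and BatchNorm uses running
#' statistics, so encoding is deterministic for fixed weights.
#'
#' @param hgraphs a `kgg_hgraph` or list of them.
#' @param model a `kgg_model` (from [pretrain()], [finetune()] or
#'   [init_model()]).
#' @param mode `"eval"` or `"train"`.
#' @return list with `fingerprints` (n_molecules x d matrix, the layer-5
#'   supernode embeddings) and `node_embeddings` (list of per-graph
#'   matrices at layer 5).
#' @export
encode <- function(hgraphs, model, mode = c("eval", "train")) {
  mode <- match.arg(mode)
  if (inherits(hgraphs, "kgg_hgraph")) hgraphs <- list(hgraphs)
  batch <- combine_batch(lapply(hgraphs, graph_tensors))
  fwd <- encoder_forward(batch, model$params, model$state, model$config,
                         training = mode == "train")
  node_emb <- mapply(function(o, n) fwd$H[o + seq_len(n), , drop = FALSE],
                     batch$offsets, batch$counts, SIMPLIFY = FALSE)
  list(fingerprints = fwd$H[batch$super_rows, , drop = FALSE],
       node_embeddings = node_emb)
}

#' Initialize an untrained model
#'
#' @param config an [encoder_config()].
#' @return a `kgg_model` with randomly initialized weights.
#' @export
init_model <- function(config = encoder_config()) {
  enc <- encoder_init(config)
  structure(list(params = enc$params, state = enc$state, config = config,
                 heads = NULL, bond_type_codes = bond_type_codes()),
            class = "kgg_model")
}

#' @export
print.kgg_model <- function(x, ...) {
  cat(sprintf("<kgg_model> d=%d, %d GIN layers, dropout=%.2f%s\n",
              x$config$d, x$config$n_layers, x$config$dropout,
              if (is.null(x$heads)) "" else ", with pretext heads"))
  invisible(x)
}

#' Extract molecular fingerprints from SMILES
#'
#' End-to-end convenience wrapper: parse, motif-decompose, build the
#' hierarchical graph and encode in eval mode, returning the d-dimensional
#' supernode embedding per molecule. Order-preserving.
#'
#' @param smiles character vector of SMILES.
#' @param model a `kgg_model`.
#' @return numeric matrix, one row per molecule, `length(smiles)` rows.
#' @export
extract_fingerprint <- function(smiles, model) {
  hgs <- lapply(smiles, function(s) build_hierarchical_graph(parse_smiles(s)))
  encode(hgs, model, mode = "eval")$fingerprints
}
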