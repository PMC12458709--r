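# The knowledge self-supervised pretraining objective: 11 pretext heads
# (5 orbital/VSEPR classification heads on atom embeddings, 3 bond heads on
# concatenated pair embeddings, 1 adjacency head over all atom pairs, 2
# count heads on the supernode embedding) and the composite loss
# L = L_hybridization + L_bond_type + L_adj + L_atoms + L_bonds.

ATOM_HEAD_WIDTHS <- c(ns = 2L, np = 3L, nd = 4L, x = 7L, y = 7L)
N_PRETEXT_TASKS <- 11L

#' Build self-supervision targets for a molecule
#'
#' All labels are deterministic functions of the molecular graph and its
#' knowledge features: per-atom class labels for (n_s, n_p, n_d, x, y),
#' per-bond sigma/pi/delta targets, and the heavy-atom and bond counts.
#' Class-index maps match the head widths: n_s in \{0,1\} (2 classes),
#' n_p in \{1,2,3\} mapped to classes 1..3 with n_p = 0 atoms masked out,
#' n_d in \{0..3\}, and x, y in \{0..6\} with larger values clipped (with a
#' warning). Adjacency labels over all unordered atom pairs are implied by
#' the bond list and materialized at batch time.
#'
#' @param mol a [parse_smiles()] result.
#' @return list with `ns`, `np`, `nd`, `x`, `y` (1-based class indices),
#'   `np_mask`, per-bond `sigma`, `pi`, `delta`, and counts `y_atoms`,
#'   `y_bonds`.
#' @export
build_pretext_targets <- function(mol) {
  stopifnot(inherits(mol, "kgg_mol"))
  a <- mol$atoms
  clip67 <- function(v, what) {
    if (any(v > 6)) {
      warning(sprintf("%s values above 6 clipped for atoms %s of '%s'",
                      what, paste(which(v > 6), collapse = ","), mol$smiles))
      v <- pmin(v, 6)
    }
    v
  }
  bad <- a$n_s > 1 | a$n_d > 3
  if (any(bad)) {
    stop(sprintf("atom %d of '%s' has orbital counts outside the head range",
                 which(bad)[1L], mol$smiles), call. = FALSE)
  }
  list(
    ns = as.integer(a$n_s) + 1L,
    np = as.integer(a$n_p),          # classes 1..3 for values 1..3
    np_mask = a$n_p >= 1,
    nd = as.integer(a$n_d) + 1L,
    x = as.integer(clip67(a$x, "x")) + 1L,
    y = as.integer(clip67(a$y, "y")) + 1L,
    sigma = mol$bonds$sigma,
    pi = mol$bonds$pi,
    delta = mol$bonds$delta,
    y_atoms = mol$n_atoms,
    y_bonds = mol$n_bonds
  )
}

# Initialize the 11 pretext heads. Atom heads: Linear(d,d)-ReLU-Linear(d,k);
# bond/adjacency heads: Linear(2d,d)-ReLU-Linear(d,1); count heads:
# Linear(d,d/4)-Softplus-Linear(d/4,1).
heads_init <- function(d) {
  p <- list()
  add <- function(p, prefix, n_in, n_hidden, n_out) {
    l1 <- init_linear(n_hidden, n_in); l2 <- init_linear(n_out, n_hidden)
    p[[paste0(prefix, ".W1")]] <- l1$W; p[[paste0(prefix, ".b1")]] <- l1$b
    p[[paste0(prefix, ".W2")]] <- l2$W; p[[paste0(prefix, ".b2")]] <- l2$b
    p
  }
  for (nm in names(ATOM_HEAD_WIDTHS)) {
    p <- add(p, paste0("head_", nm), d, d, ATOM_HEAD_WIDTHS[[nm]])
  }
  for (nm in c("sigma", "pi", "delta", "adj")) {
    p <- add(p, paste0("head_", nm), 2L * d, d, 1L)
  }
  dq <- max(1L, d %/% 4L)
  p <- add(p, "head_atoms", d, dq, 1L)
  p <- add(p, "head_bonds", d, dq, 1L)
  p
}

n_pretext_heads <- function(head_params) {
  length(unique(sub("\\..*$", "", names(head_params))))
}

# -- loss primitives (also used as plain functions in tests) ------------------

ce_loss_forward <- function(logits, target, mask = NULL,
                            reduction = "mean") {
  if (is.null(mask)) mask <- rep(TRUE, length(target))
  rows <- which(mask)
  n <- length(rows)
  dlogits <- matrix(0, nrow(logits), ncol(logits))
  if (n == 0L) return(list(loss = 0, dlogits = dlogits))
  lg <- logits[rows, , drop = FALSE]
  mx <- apply(lg, 1L, max)
  ex <- exp(lg - mx)
  sm <- ex / rowSums(ex)
  picked <- cbind(seq_len(n), target[rows])
  loss <- -sum(log(pmax(sm[picked], 1e-12)))
  g <- sm
  g[picked] <- g[picked] - 1
  if (reduction == "mean") { loss <- loss / n; g <- g / n }
  dlogits[rows, ] <- g
  list(loss = loss, dlogits = dlogits)
}

bce_logits_forward <- function(z, y, reduction = "mean") {
  n <- length(z)
  if (n == 0L) return(list(loss = 0, dz = numeric(0)))
  loss <- sum(pmax(z, 0) - z * y + log1p(exp(-abs(z))))
  dz <- sigmoid(z) - y
  if (reduction == "mean") { loss <- loss / n; dz <- dz / n }
  list(loss = loss, dz = dz)
}

smooth_l1_forward <- function(pred, target, reduction = "mean") {
  n <- length(pred)
  if (n == 0L) return(list(loss = 0, dpred = numeric(0)))
  e <- pred - target
  ae <- abs(e)
  loss <- sum(ifelse(ae < 1, 0.5 * e^2, ae - 0.5))
  dpred <- ifelse(ae < 1, e, sign(e))
  if (reduction == "mean") { loss <- loss / n; dpred <- dpred / n }
  list(loss = loss, dpred = dpred)
}

#' Total pretraining loss from a loss breakdown
#'
#' The exact unweighted sum of the five principal components:
#' hybridization, bond type, adjacency, atom count and bond count.
#'
#' @param breakdown a named list (or one row of a loss trace) holding
#'   `L_hybridization`, `L_bond_type`, `L_adj`, `L_atoms`, `L_bonds`.
#' @return scalar total loss.
#' @export
total_loss <- function(breakdown) {
  needed <- c("L_hybridization", "L_bond_type", "L_adj", "L_atoms", "L_bonds")
  missing <- setdiff(needed, names(breakdown))
  if (length(missing)) {
    stop(structure(
      class = c("kggraph_loss_error", "error", "condition"),
      list(message = paste("missing loss components:",
                           paste(missing, collapse = ", ")), call = NULL)
    ))
  }
  # sequential addition (not sum()'s extended-precision accumulator) so the
  # total reproduces the component sum bit-exactly
  Reduce(`+`, lapply(needed, function(nm) as.numeric(breakdown[[nm]])))
}

# Materialize per-batch target vectors (including all-pairs adjacency).
batch_targets <- function(mols, batch) {
  tg <- lapply(mols, build_pretext_targets)
  pair_i <- integer(0); pair_j <- integer(0); adj <- numeric(0)
  for (g in seq_along(mols)) {
    n <- batch$n_atoms[g]
    if (n >= 2L) {
      pr <- utils::combn(n, 2L)
      o <- batch$offsets[g]
      pi_ <- pr[1L, ]; pj_ <- pr[2L, ]
      key <- paste(pi_, pj_)
      bkey <- paste(mols[[g]]$bonds$i, mols[[g]]$bonds$j)
      adj <- c(adj, as.numeric(key %in% bkey))
      pair_i <- c(pair_i, o + pi_)
      pair_j <- c(pair_j, o + pj_)
    }
  }
  list(
    ns = unlist(lapply(tg, `[[`, "ns")),
    np = unlist(lapply(tg, `[[`, "np")),
    np_mask = unlist(lapply(tg, `[[`, "np_mask")),
    nd = unlist(lapply(tg, `[[`, "nd")),
    x = unlist(lapply(tg, `[[`, "x")),
    y = unlist(lapply(tg, `[[`, "y")),
    sigma = unlist(lapply(tg, `[[`, "sigma")),
    pi = unlist(lapply(tg, `[[`, "pi")),
    delta = unlist(lapply(tg, `[[`, "delta")),
    pair_i = pair_i, pair_j = pair_j, adj = adj,
    y_atoms = vapply(tg, `[[`, numeric(1), "y_atoms"),
    y_bonds = vapply(tg, `[[`, numeric(1), "y_bonds")
  )
}

# Forward + backward through all 11 heads given layer-5 embeddings H.
# Returns the loss breakdown, head gradients, and dH.
kssp_heads_pass <- function(H, batch, targets, head_params, reduction) {
  grads <- zero_grads(head_params)
  N <- nrow(H); d <- ncol(H)
  dH <- matrix(0, N, d)
  Hatom <- H[batch$atom_rows, , drop = FALSE]
  dHatom <- matrix(0, nrow(Hatom), d)
  comp <- list()

  tmap <- list(ns = targets$ns, np = targets$np, nd = targets$nd,
               x = targets$x, y = targets$y)
  for (nm in names(ATOM_HEAD_WIDTHS)) {
    fc <- mlp2_forward(Hatom, head_params, paste0("head_", nm))
    mask <- if (nm == "np") targets$np_mask else NULL
    ls <- ce_loss_forward(fc$out, tmap[[nm]], mask, reduction)
    comp[[paste0("L_", nm)]] <- ls$loss
    bk <- mlp2_backward(fc, ls$dlogits, head_params, grads)
    grads <- bk$grads
    dHatom <- dHatom + bk$dX
  }
  dH[batch$atom_rows, ] <- dH[batch$atom_rows, , drop = FALSE] + dHatom

  pair_pass <- function(rows_i, rows_j, prefix, lossfun, grads, dH) {
    X <- cbind(H[rows_i, , drop = FALSE], H[rows_j, , drop = FALSE])
    fc <- mlp2_forward(X, head_params, prefix)
    ls <- lossfun(drop(fc$out))
    bk <- mlp2_backward(fc, matrix(ls$dz, ncol = 1L), head_params, grads)
    idx <- c(rows_i, rows_j)
    dX <- rbind(bk$dX[, seq_len(d), drop = FALSE],
                bk$dX[, d + seq_len(d), drop = FALSE])
    acc <- rowsum(dX, group = idx)
    rows <- as.integer(rownames(acc))
    dH[rows, ] <- dH[rows, , drop = FALSE] + acc
    list(loss = ls$loss, grads = bk$grads, dH = dH)
  }

  if (length(batch$bond_i) > 0L) {
    ps <- pair_pass(batch$bond_i, batch$bond_j, "head_sigma",
                    function(z) bce_logits_forward(z, targets$sigma,
                                                   reduction),
                    grads, dH)
    grads <- ps$grads; dH <- ps$dH; comp$L_sigma <- ps$loss
    pp <- pair_pass(batch$bond_i, batch$bond_j, "head_pi",
                    function(z) {
                      r <- smooth_l1_forward(z, targets$pi, reduction)
                      list(loss = r$loss, dz = r$dpred)
                    }, grads, dH)
    grads <- pp$grads; dH <- pp$dH; comp$L_pi <- pp$loss
    pd <- pair_pass(batch$bond_i, batch$bond_j, "head_delta",
                    function(z) bce_logits_forward(z, targets$delta,
                                                   reduction),
                    grads, dH)
    grads <- pd$grads; dH <- pd$dH; comp$L_delta <- pd$loss
  } else {
    comp$L_sigma <- 0; comp$L_pi <- 0; comp$L_delta <- 0
  }

  if (length(targets$pair_i) > 0L) {
    pa <- pair_pass(targets$pair_i, targets$pair_j, "head_adj",
                    function(z) bce_logits_forward(z, targets$adj, reduction),
                    grads, dH)
    grads <- pa$grads; dH <- pa$dH; comp$L_adj <- pa$loss
  } else {
    comp$L_adj <- 0
  }

  Hg <- H[batch$super_rows, , drop = FALSE]
  fa <- mlp2_forward(Hg, head_params, "head_atoms", act = "softplus")
  la <- smooth_l1_forward(drop(fa$out), targets$y_atoms, reduction)
  ba <- mlp2_backward(fa, matrix(la$dpred, ncol = 1L), head_params, grads)
  grads <- ba$grads
  fb <- mlp2_forward(Hg, head_params, "head_bonds", act = "softplus")
  lb <- smooth_l1_forward(drop(fb$out), targets$y_bonds, reduction)
  bb <- mlp2_backward(fb, matrix(lb$dpred, ncol = 1L), head_params, grads)
  grads <- bb$grads
  dH[batch$super_rows, ] <- dH[batch$super_rows, , drop = FALSE] +
    ba$dX + bb$dX
  comp$L_atoms <- la$loss
  comp$L_bonds <- lb$loss

  comp$L_hybridization <- comp$L_ns + comp$L_np + comp$L_nd +
    comp$L_x + comp$L_y
  comp$L_bond_type <- comp$L_sigma + comp$L_pi + comp$L_delta
  comp$L_total <- total_loss(comp)
  list(breakdown = comp, grads = grads, dH = dH)
}

#' Pretrain the encoder with the 11-task self-supervised objective
#'
#' Minibatch Adam on the composite loss. Unparseable corpus entries are
#' skipped and counted. Deterministic for a fixed seed and fixed thread
#' settings.
#'
#' @param smiles character vector of SMILES (the pretraining corpus).
#' @param config an [encoder_config()].
#' @param lr Adam learning rate.
#' @param batch_size minibatch size (32 for full-scale runs).
#' @param epochs passes over the corpus.
#' @param max_steps optional cap on total optimizer steps.
#' @param loss_reduction `"mean"` (each loss component averaged over its own
#'   support, so molecule size does not reweight tasks) or `"sum"` (raw
#'   summed losses).
#' @param verbose print per-epoch loss breakdowns.
#' @return a `kgg_model` with trained weights, pretext `heads`, and a
#'   per-step loss trace in `$trace` (data frame, one row per step).
#' @export
pretrain <- function(smiles, config = encoder_config(), lr = 1e-3,
                     batch_size = 32L, epochs = 1L, max_steps = Inf,
                     loss_reduction = c("mean", "sum"), verbose = FALSE) {
  loss_reduction <- match.arg(loss_reduction)
  parsed <- list(); skipped <- 0L
  for (s in smiles) {
    m <- tryCatch(parse_smiles(s), kggraph_parse_error = function(e) NULL)
    if (is.null(m)) skipped <- skipped + 1L else parsed[[length(parsed) + 1L]] <- m
  }
  if (length(parsed) == 0L) {
    stop("no valid molecules in the pretraining corpus", call. = FALSE)
  }
  hgs <- lapply(parsed, build_hierarchical_graph)
  tensors <- lapply(hgs, graph_tensors)

  enc <- encoder_init(config)
  set.seed(config$seed + 1L)
  params <- c(enc$params, heads_init(config$d))
  state <- enc$state
  opt <- adam_init(params)
  enc_names <- names(enc$params)

  n <- length(parsed)
  step <- 0L
  trace <- list()
  for (ep in seq_len(epochs)) {
    ord <- sample.int(n)
    starts <- seq(1L, n, by = batch_size)
    for (st in starts) {
      if (step >= max_steps) break
      idx <- ord[st:min(st + batch_size - 1L, n)]
      batch <- combine_batch(tensors[idx])
      targets <- batch_targets(parsed[idx], batch)
      fwd <- encoder_forward(batch, params, state, config, training = TRUE)
      state <- fwd$state
      hp <- kssp_heads_pass(fwd$H, batch, targets, params, loss_reduction)
      enc_grads <- encoder_backward(fwd, hp$dH, batch, params, config)
      grads <- hp$grads
      for (nm in enc_names) grads[[nm]] <- enc_grads[[nm]]
      if (lr > 0) {
        upd <- adam_step(params, grads, opt, lr)
        params <- upd$params; opt <- upd$opt
      }
      step <- step + 1L
      trace[[step]] <- c(step = step, epoch = ep,
                         unlist(hp$breakdown[c(
                           "L_ns", "L_np", "L_nd", "L_x", "L_y",
                           "L_sigma", "L_pi", "L_delta", "L_adj",
                           "L_atoms", "L_bonds",
                           "L_hybridization", "L_bond_type", "L_total")]))
    }
    if (verbose && step > 0L) {
      message(sprintf("epoch %d: L_total = %.4f", ep,
                      trace[[step]][["L_total"]]))
    }
    if (step >= max_steps) break
  }
  trace <- as.data.frame(do.call(rbind, trace))
  structure(
    list(params = params[enc_names],
         heads = params[setdiff(names(params), enc_names)],
         state = state, config = config, trace = trace,
         n_skipped = skipped, loss_reduction = loss_reduction,
         bond_type_codes = bond_type_codes()),
    class = "kgg_model"
  )
}

#' Evaluate the pretext loss breakdown on a set of molecules
#'
#' Runs the encoder and all 11 heads without updating weights; useful for
#' tracking the objective on held-out molecules.
#'
#' @param smiles character vector of SMILES.
#' @param model a `kgg_model` with pretext heads.
#' @param loss_reduction as in [pretrain()].
#' @return named list of loss components including `L_total`.
#' @export
pretext_losses <- function(smiles, model,
                           loss_reduction = c("mean", "sum")) {
  loss_reduction <- match.arg(loss_reduction)
  if (is.null(model$heads)) stop("model carries no pretext heads",
                                 call. = FALSE)
  parsed <- lapply(smiles, parse_smiles)
  hgs <- lapply(parsed, build_hierarchical_graph)
  batch <- combine_batch(lapply(hgs, graph_tensors))
  targets <- batch_targets(parsed, batch)
  fwd <- encoder_forward(batch, model$params, model$state, model$config,
                         training = FALSE)
  hp <- kssp_heads_pass(fwd$H, batch, targets,
                        model$heads, loss_reduction)
  hp$breakdown
}
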