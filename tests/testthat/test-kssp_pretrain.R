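# The 11-task self-supervised objective: targets, heads, losses, training.

test_that("pretext targets are deterministic functions of the structure", {
  t_me <- build_pretext_targets(parse_smiles("C"))
  expect_equal(t_me$y_atoms, 1L)
  expect_equal(t_me$y_bonds, 0L)
  t_bz <- build_pretext_targets(parse_smiles("c1ccccc1"))
  expect_equal(t_bz$y_atoms, 6L)
  expect_equal(t_bz$y_bonds, 6L)
  # class-index maps: methane carbon is sp3 -> n_s=1, n_p=3, n_d=0, x=4, y=0
  expect_equal(t_me$ns, 2L)
  expect_equal(t_me$np, 3L)
  expect_equal(t_me$nd, 1L)
  expect_equal(t_me$x, 5L)
  expect_equal(t_me$y, 1L)
  expect_true(all(build_pretext_targets(parse_smiles("CC"))$sigma == 1))
})

test_that("there are exactly 11 pretext heads with the printed widths", {
  heads <- kggraph:::heads_init(16L)
  expect_equal(kggraph:::n_pretext_heads(heads), 11L)
  widths <- c(ns = 2L, np = 3L, nd = 4L, x = 7L, y = 7L)
  for (nm in names(widths)) {
    expect_equal(nrow(heads[[paste0("head_", nm, ".W2")]]), widths[[nm]])
    expect_equal(ncol(heads[[paste0("head_", nm, ".W1")]]), 16L)
  }
  for (nm in c("sigma", "pi", "delta", "adj")) {
    expect_equal(ncol(heads[[paste0("head_", nm, ".W1")]]), 32L)  # 2d
    expect_equal(nrow(heads[[paste0("head_", nm, ".W2")]]), 1L)
  }
  expect_equal(nrow(heads[["head_atoms.W1"]]), 4L)  # d/4
  expect_equal(nrow(heads[["head_bonds.W1"]]), 4L)
})

test_that("cross-entropy has the right closed forms and limits", {
  ce <- kggraph:::ce_loss_forward
  # uniform logits over k classes -> ln k
  for (k in c(2, 3, 7)) {
    r <- ce(matrix(0, 5, k), rep(1L, 5))
    expect_equal(r$loss, log(k), tolerance = 1e-12)
  }
  # saturated-correct logits -> ~0
  logits <- matrix(-50, 4, 3); logits[cbind(1:4, c(1, 2, 3, 1))] <- 50
  expect_lt(ce(logits, c(1L, 2L, 3L, 1L))$loss, 1e-8)
  # masking removes rows from the average
  lg <- matrix(rnorm(10 * 3), 10, 3)
  tg <- sample(1:3, 10, replace = TRUE)
  mask <- c(rep(TRUE, 6), rep(FALSE, 4))
  expect_equal(ce(lg, tg, mask)$loss,
               ce(lg[1:6, ], tg[1:6])$loss, tolerance = 1e-12)
})

test_that("smooth-L1 follows the printed piecewise branches", {
  sl <- kggraph:::smooth_l1_forward
  expect_equal(sl(0.5, 0)$loss, 0.125)
  expect_equal(sl(2, 0)$loss, 1.5)
  expect_equal(sl(3, 0)$loss, 2.5)
  expect_equal(sl(-0.5, 0)$loss, 0.125)
  expect_equal(sl(c(0.5, 3), c(0, 0))$loss, (0.125 + 2.5) / 2)
})

test_that("binary cross-entropy has the right closed forms", {
  bce <- kggraph:::bce_logits_forward
  expect_equal(bce(0, 1)$loss, log(2), tolerance = 1e-12)  # p = 1/2
  expect_lt(bce(c(50, -50), c(1, 0))$loss, 1e-8)           # saturated correct
  expect_gt(bce(c(-50, 50), c(1, 0))$loss, 10)             # saturated wrong
})

test_that("each loss matches an independently coded oracle to 1e-6", {
  set.seed(42)
  # CE oracle: explicit softmax
  for (rep in 1:5) {
    k <- sample(2:7, 1)
    n <- sample(3:20, 1)
    lg <- matrix(rnorm(n * k, sd = 3), n, k)
    tg <- sample.int(k, n, replace = TRUE)
    p <- exp(lg) / rowSums(exp(lg))
    oracle <- -mean(log(p[cbind(seq_len(n), tg)]))
    expect_equal(kggraph:::ce_loss_forward(lg, tg)$loss, oracle,
                 tolerance = 1e-6)
  }
  # BCE oracle: explicit probabilities
  z <- rnorm(50, sd = 2); y <- rbinom(50, 1, 0.4)
  pr <- 1 / (1 + exp(-z))
  oracle <- -mean(y * log(pr) + (1 - y) * log(1 - pr))
  expect_equal(kggraph:::bce_logits_forward(z, y)$loss, oracle,
               tolerance = 1e-6)
  # smooth-L1 oracle: literal piecewise definition
  e <- rnorm(50, sd = 2)
  oracle <- mean(ifelse(abs(e) < 1, 0.5 * e^2, abs(e) - 0.5))
  expect_equal(kggraph:::smooth_l1_forward(e, rep(0, 50))$loss, oracle,
               tolerance = 1e-6)
})

test_that("adjacency loss matches a brute-force pairwise oracle", {
  model <- tiny_model(8)
  mol <- parse_smiles("CCc1ccccc1")
  hg <- build_hierarchical_graph(mol)
  batch <- kggraph:::combine_batch(list(kggraph:::graph_tensors(hg)))
  targets <- kggraph:::batch_targets(list(mol), batch)
  set.seed(1)
  heads <- kggraph:::heads_init(model$config$d)
  fwd <- kggraph:::encoder_forward(batch, model$params, model$state,
                                   model$config, training = FALSE)
  hp <- kggraph:::kssp_heads_pass(fwd$H, batch, targets, heads, "mean")
  # oracle: loop over all unordered atom pairs, recompute the head by hand
  H <- fwd$H
  n <- mol$n_atoms
  losses <- c()
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    xx <- c(H[i, ], H[j, ])
    z1 <- heads[["head_adj.W1"]] %*% xx + heads[["head_adj.b1"]]
    z <- drop(heads[["head_adj.W2"]] %*% pmax(z1, 0) + heads[["head_adj.b2"]])
    yy <- as.numeric(any(mol$bonds$i == i & mol$bonds$j == j))
    pr <- 1 / (1 + exp(-z))
    losses <- c(losses, -(yy * log(pr) + (1 - yy) * log(1 - pr)))
  }
  expect_equal(hp$breakdown$L_adj, mean(losses), tolerance = 1e-6)
})

test_that("the total loss is the exact sum of the five principal components", {
  model <- pretrain(toy_set()[1:10], tiny_config(3), lr = 1e-3,
                    batch_size = 5, epochs = 1)
  bd <- pretext_losses(toy_set()[1:10], model)
  expect_identical(bd$L_total,
                   bd$L_hybridization + bd$L_bond_type + bd$L_adj +
                     bd$L_atoms + bd$L_bonds)
  expect_identical(bd$L_hybridization,
                   bd$L_ns + bd$L_np + bd$L_nd + bd$L_x + bd$L_y)
  expect_identical(bd$L_bond_type, bd$L_sigma + bd$L_pi + bd$L_delta)
  comps <- unlist(bd)
  expect_true(all(comps >= 0))
  expect_equal(total_loss(list(L_hybridization = 1, L_bond_type = 1,
                               L_adj = 1, L_atoms = 1, L_bonds = 1)), 5)
  expect_equal(total_loss(list(L_hybridization = 0, L_bond_type = 0,
                               L_adj = 0, L_atoms = 0, L_bonds = 0)), 0)
  expect_error(total_loss(list(L_adj = 1)), class = "kggraph_loss_error")
})

test_that("a zero learning rate leaves the loss trace constant", {
  smi <- toy_set()[1:8]
  m <- pretrain(smi, tiny_config(9, dropout = 0), lr = 0, batch_size = 8,
                epochs = 3)
  expect_equal(length(unique(round(m$trace$L_total, 10))), 1L)
})

test_that("unparseable corpus entries are skipped and counted", {
  m <- pretrain(c("CCO", "xyz_bad", "CC"), tiny_config(1), lr = 1e-3,
                batch_size = 2, epochs = 1)
  expect_equal(m$n_skipped, 1L)
  expect_error(pretrain(c("xyz_bad"), tiny_config(1)), "no valid molecules")
})

test_that("the heads can fit a frozen corpus (hybridization accuracy > 0.95)", {
  smi <- toy_set()[1:20]
  cfg <- tiny_config(seed = 21, dropout = 0)
  model <- pretrain(smi, cfg, lr = 3e-3, batch_size = 20, epochs = 500)
  mols <- lapply(smi, parse_smiles)
  hgs <- lapply(mols, build_hierarchical_graph)
  batch <- kggraph:::combine_batch(lapply(hgs, kggraph:::graph_tensors))
  targets <- kggraph:::batch_targets(mols, batch)
  fwd <- kggraph:::encoder_forward(batch, model$params, model$state,
                                   cfg, training = FALSE)
  Hatom <- fwd$H[batch$atom_rows, , drop = FALSE]
  accs <- vapply(c("ns", "np", "nd", "x", "y"), function(nm) {
    logits <- kggraph:::mlp2_forward(Hatom, model$heads,
                                     paste0("head_", nm))$out
    pred <- max.col(logits)
    tg <- targets[[nm]]
    sel <- if (nm == "np") targets$np_mask else rep(TRUE, length(tg))
    mean(pred[sel] == tg[sel])
  }, numeric(1))
  expect_gt(mean(accs), 0.95)
})
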