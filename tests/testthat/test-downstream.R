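# Scaffold splitting, metrics, fine-tuning, and the kNN comparison harness.

test_that("Bemis-Murcko scaffolds group frameworks and drop side chains", {
  expect_equal(murcko_scaffold("Cc1ccccc1"), murcko_scaffold("CCCc1ccccc1"))
  expect_equal(murcko_scaffold("c1ccccc1"), murcko_scaffold("Cc1ccccc1"))
  expect_equal(murcko_scaffold("CCCCCC"), "")
  expect_equal(murcko_scaffold("CCO"), "")
  # multiple-bonded terminal atoms survive pruning
  expect_equal(murcko_scaffold("O=C1CCCCC1"), murcko_scaffold("CC1CCCCC1=O"))
  expect_false(murcko_scaffold("c1ccccc1") == murcko_scaffold("C1CCCCC1"))
  # linkers between rings are retained
  expect_equal(murcko_scaffold("c1ccc(CCc2ccccc2)cc1"),
               murcko_scaffold("Cc1ccc(CCc2ccccc2)cc1"))
})

test_that("scaffold splits fill 8:1:1 and never share a scaffold", {
  ten <- c("c1ccccc1", "c1ccncc1", "C1CCCCC1", "c1ccoc1", "c1ccsc1",
           "c1cc[nH]c1", "C1CCNCC1", "C1CCOC1", "c1ccc2ccccc2c1", "C1CC1")
  sp <- scaffold_split(ten, seed = 1)
  expect_equal(lengths(sp[c("train", "valid", "test")]),
               c(train = 8L, valid = 1L, test = 1L))
  smi <- generate_fixtures("aromatic-label", 40, seed = 10)$smiles
  sp2 <- scaffold_split(smi, seed = 1)
  scafs <- vapply(smi, murcko_scaffold, character(1))
  expect_length(intersect(scafs[sp2$train], scafs[sp2$test]), 0L)
  expect_length(intersect(scafs[sp2$valid], scafs[sp2$test]), 0L)
})

test_that("splits are disjoint and covering for all strategies and seeds", {
  smi <- generate_fixtures("ring-count", 50, seed = 2)$smiles
  for (strategy in c("scaffold", "random")) {
    for (seed in 1:3) {
      sp <- scaffold_split(smi, strategy = strategy, seed = seed)
      all_idx <- c(sp$train, sp$valid, sp$test)
      expect_identical(sort(all_idx), seq_along(smi))
      expect_equal(anyDuplicated(all_idx), 0L)
      if (strategy == "random") {
        expect_equal(length(sp$train), 40L)
        expect_equal(length(sp$valid), 5L)
      }
    }
  }
})

test_that("degenerate single-scaffold datasets warn and land in train", {
  same <- paste0(c("C", "CC", "CCC", "CCCC", "N", "O", "CO", "CN", "CCN",
                   "CCO"))  # all ring-free: one empty scaffold
  expect_warning(sp <- scaffold_split(same, seed = 1), "empty")
  expect_equal(length(sp$train), 10L)
  expect_error(scaffold_split(c("C", "CC")), class = "kggraph_split_error")
})

test_that("ranking metrics reproduce the imbalanced screening example", {
  labels <- c(rep(1, 100), rep(0, 9900))
  scores <- c(rep(1, 100), rep(1, 900), rep(0, 9000))
  cm <- confusion_metrics(as.numeric(scores >= 1), labels)
  expect_equal(cm$tpr, 1)
  expect_equal(cm$fpr, 900 / 9900)
  expect_equal(cm$precision, 0.10)
  expect_equal(roc_auc(scores, labels), 0.9545, tolerance = 1e-3)
  expect_equal(average_precision(scores, labels), 0.10, tolerance = 1e-6)
  expect_equal(roc_auc(c(3, 2, 1, 0), c(1, 1, 0, 0)), 1)
  expect_equal(average_precision(c(3, 2, 1, 0), c(1, 1, 0, 0)), 1)
})

test_that("MCC uses all four confusion quadrants", {
  pred <- c(rep(1, 40), rep(1, 10), rep(0, 40), rep(0, 10))
  lab <- c(rep(1, 40), rep(0, 10), rep(0, 40), rep(1, 10))
  expect_equal(mcc(pred, lab), 0.6)
  # oracle: direct formula
  expect_equal(mcc(pred, lab),
               (40 * 40 - 10 * 10) / sqrt(50 * 50 * 50 * 50))
  # symmetry: swapping classes in both arguments preserves |MCC|
  expect_equal(abs(mcc(1 - pred, 1 - lab)), abs(mcc(pred, lab)))
  expect_warning(z <- mcc(rep(1, 5), c(1, 1, 1, 0, 0)), "zero")
  expect_equal(z, 0)
})

test_that("metric guards reject degenerate inputs", {
  expect_error(roc_auc(1:5, rep(1, 5)), class = "kggraph_metric_error")
  expect_error(average_precision(1:5, rep(0, 5)),
               class = "kggraph_metric_error")
})

test_that("AUC is invariant under strictly monotone score transforms", {
  set.seed(31)
  for (r in 1:20) {
    y <- rbinom(40, 1, 0.4)
    if (length(unique(y)) < 2) next
    s <- rnorm(40)
    a1 <- roc_auc(s, y)
    expect_equal(roc_auc(exp(s), y), a1, tolerance = 1e-12)
    expect_equal(roc_auc(2 * s + 7, y), a1, tolerance = 1e-12)
  }
})

test_that("AUC agrees with a brute-force pair-counting oracle", {
  set.seed(8)
  for (r in 1:10) {
    y <- rbinom(30, 1, 0.5)
    if (length(unique(y)) < 2) next
    s <- sample(1:5, 30, replace = TRUE)  # force ties
    pos <- s[y == 1]; neg <- s[y == 0]
    cmp <- outer(pos, neg, `>`) + 0.5 * outer(pos, neg, `==`)
    expect_equal(roc_auc(s, y), mean(cmp), tolerance = 1e-12)
  }
})

test_that("RMSE dominates MAE on every residual vector", {
  set.seed(4)
  for (r in 1:20) {
    pred <- rnorm(25); y <- rnorm(25)
    expect_gte(rmse(pred, y), mae(pred, y))
    expect_gte(mae(pred, y), 0)
  }
})

test_that("fine-tuning recovers a separable synthetic task", {
  fx <- generate_fixtures("aromatic-label", 200, seed = 5)
  cfg <- tiny_config(seed = 11)
  pt <- pretrain(fx$smiles[1:80], cfg, lr = 1e-3, batch_size = 32,
                 epochs = 2)
  sp <- scaffold_split(fx$smiles, seed = 1)
  ft <- finetune(pt, fx, sp, "classification", lr = 1e-3, epochs = 10,
                 seed = 2)
  rep <- as.data.frame(ft$report)
  expect_gte(rep$roc_auc[rep$task == "average"], 0.95)
  # regression on a deterministic structural feature (the encoder saw the
  # atom-count pretext task during pretraining)
  fr <- generate_fixtures("heavy-atom-count", 150, seed = 7)
  ptr <- pretrain(fr$smiles, encoder_config(d = 32, emb_hidden = 8,
                                            dropout = 0.1, seed = 11),
                  lr = 1e-3, batch_size = 32, epochs = 5)
  spr <- scaffold_split(fr$smiles, strategy = "random", seed = 1)
  ftr <- finetune(ptr, fr, spr, "regression", lr = 1e-3, epochs = 40,
                  seed = 1)
  repr <- as.data.frame(ftr$report)
  expect_lt(repr$rmse[repr$task == "average"], 1.0)
  expect_gte(repr$rmse[repr$task == "average"],
             repr$mae[repr$task == "average"])
})

test_that("zero-epoch fine-tuning returns an untrained head report", {
  fx <- generate_fixtures("aromatic-label", 60, seed = 13)
  sp <- scaffold_split(fx$smiles, seed = 1)
  ft <- finetune(tiny_model(), fx, sp, "classification", epochs = 0)
  expect_length(ft$trace, 0L)
  expect_s3_class(ft$report, "kgg_metric_report")
})

test_that("the kNN harness compares four fingerprints on one split", {
  fx <- generate_fixtures("aromatic-label", 80, seed = 3)
  sp <- scaffold_split(fx$smiles, seed = 1)
  tab <- compare_fingerprints(tiny_model(), fx, sp, "classification")
  expect_equal(nrow(tab), 4L)
  expect_setequal(tab$fingerprint, c("kgg", "MACCS", "ECFP4", "FP2"))
  expect_true(all(tab$roc_auc >= 0 & tab$roc_auc <= 1, na.rm = TRUE))
  # leak guard
  leaky <- sp; leaky$test <- c(leaky$test, leaky$train[1])
  expect_error(compare_fingerprints(tiny_model(), fx, leaky,
                                    "classification"), "overlap")
})

test_that("multi-task reports mask missing labels per task", {
  set.seed(9)
  scores <- matrix(rnorm(40), 20, 2)
  labels <- matrix(rbinom(40, 1, 0.5), 20, 2)
  labels[1:5, 2] <- NA
  rep <- metric_report(scores, labels, "classification", c("a", "b"))
  expect_equal(nrow(rep), 3L)
  expect_equal(rep$task, c("a", "b", "average"))
  expect_true(all(is.finite(rep$roc_auc)))
})
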