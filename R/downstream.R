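# Downstream evaluation: Bemis-Murcko scaffold splitting, fine-tuning of the
# pretrained encoder with a task head, standard metrics, and the
# learned-vs-traditional fingerprint comparison harness.

#' Bemis-Murcko scaffold of a molecule
#'
#' The molecular framework left after iteratively pruning terminal atoms
#' attached by acyclic single bonds (ring systems, linkers, and atoms
#' multiple-bonded to them survive; cyclohexanone keeps its carbonyl
#' oxygen). Ring-free molecules have the empty scaffold `""`. Returned as a
#' canonical SMILES so identical frameworks compare equal as strings.
#'
#' @param smiles a single SMILES string.
#' @return canonical scaffold SMILES (possibly `""`).
#' @export
murcko_scaffold <- function(smiles) {
  mol <- parse_smiles(smiles)
  keep <- rep(TRUE, mol$n_atoms)
  b <- mol$bonds
  repeat {
    if (!any(keep)) break
    alive <- keep[b$i] & keep[b$j]
    # prunable: at most one surviving bond, and that bond is an acyclic
    # single bond (multiple-bonded terminal atoms like carbonyl O survive)
    prune <- rep(FALSE, mol$n_atoms)
    for (a in which(keep)) {
      inc <- which(alive & (b$i == a | b$j == a))
      if (length(inc) == 0L) { prune[a] <- TRUE; next }
      if (length(inc) == 1L && b$order[inc] == 1L && !b$aromatic[inc]) {
        prune[a] <- TRUE
      }
    }
    if (!any(prune)) break
    keep[prune] <- FALSE
  }
  if (!any(keep)) return("")
  scaffold_smiles(smiles, which(keep), mol)
}

# Canonical SMILES of the induced subgraph on `keep` atoms, with implicit
# hydrogens restored at attachment points.
scaffold_smiles <- function(smiles, keep, mol) {
  obmol <- ob_parse(smiles)
  on.exit(ob_free(obmol))
  ob_call("OBMol_DeleteHydrogens", obmol)
  drop <- setdiff(seq_len(mol$n_atoms), keep)
  b <- mol$bonds
  n_cut <- vapply(keep, function(a) {
    sum((b$i == a & b$j %in% drop) | (b$j == a & b$i %in% drop))
  }, numeric(1))
  for (i in sort(drop, decreasing = TRUE)) {
    ob_call("OBMol_DeleteAtom", obmol, ob_call("OBMol_GetAtom", obmol, i))
  }
  for (t in seq_along(keep)) {
    if (n_cut[t] > 0) {
      a <- ob_call("OBMol_GetAtom", obmol, t)
      ob_call("OBAtom_SetImplicitHCount", a,
              ob_call("OBAtom_GetImplicitHCount", a) + as.integer(n_cut[t]))
    }
  }
  conv <- ob_call("OBConversion")
  ob_call("OBConversion_SetOutFormat", conv, "can")
  out <- ob_call("OBConversion_WriteString", conv, obmol)
  sub("\\s.*$", "", trimws(out))
}

#' Split a dataset into train/validation/test
#'
#' Scaffold strategy: molecules are grouped by Bemis-Murcko scaffold and
#' whole groups are assigned greedily, largest first, to train, then
#' validation, then test, so no scaffold spans two subsets. Random
#' strategy: plain seeded shuffling at the same ratios.
#'
#' @param smiles character vector of SMILES.
#' @param ratios train/valid/test proportions summing to 1 (default
#'   `c(0.8, 0.1, 0.1)`).
#' @param strategy `"scaffold"` or `"random"`.
#' @param seed integer seed (used by the random strategy; recorded always).
#' @return list of class `kgg_split` with integer index vectors `train`,
#'   `valid`, `test`, plus `strategy`, `ratios`, `seed`.
#' @export
scaffold_split <- function(smiles, ratios = c(0.8, 0.1, 0.1),
                           strategy = c("scaffold", "random"), seed = 1L) {
  strategy <- match.arg(strategy)
  n <- length(smiles)
  if (n < 10L) {
    stop(structure(
      class = c("kggraph_split_error", "error", "condition"),
      list(message = sprintf("dataset too small to split (%d < 10 records)", n),
           call = NULL)
    ))
  }
  stopifnot(length(ratios) == 3L, abs(sum(ratios) - 1) < 1e-8)
  n_train <- round(ratios[1L] * n)
  n_valid <- round(ratios[2L] * n)
  if (strategy == "random") {
    set.seed(seed)
    ord <- sample.int(n)
    train <- sort(ord[seq_len(n_train)])
    valid <- sort(ord[n_train + seq_len(n_valid)])
    test <- sort(ord[-seq_len(n_train + n_valid)])
  } else {
    scaf <- vapply(smiles, murcko_scaffold, character(1), USE.NAMES = FALSE)
    groups <- split(seq_len(n), scaf)
    groups <- groups[order(-lengths(groups),
                           vapply(groups, min, integer(1)))]
    train <- integer(0); valid <- integer(0); test <- integer(0)
    n_test <- n - n_train - n_valid
    for (g in groups) {
      caps <- c(n_train - length(train), n_valid - length(valid),
                n_test - length(test))
      dest <- which(caps >= length(g))[1L]
      if (is.na(dest)) dest <- which.max(caps)  # oversized group: most room
      if (dest == 1L) train <- c(train, g)
      else if (dest == 2L) valid <- c(valid, g)
      else test <- c(test, g)
    }
    train <- sort(train); valid <- sort(valid); test <- sort(test)
    if (length(valid) == 0L || length(test) == 0L) {
      warning("scaffold split left an empty validation or test subset ",
              "(too few distinct scaffolds)")
    }
  }
  structure(list(train = train, valid = valid, test = test,
                 strategy = strategy, ratios = ratios, seed = seed),
            class = "kgg_split")
}

# -- metrics ------------------------------------------------------------------

#' Classification and regression metrics
#'
#' `roc_auc` is the rank-based area under the ROC curve with tie averaging
#' (via pROC); `average_precision` is the step-wise area under the
#' precision-recall curve; `mcc` the Matthews correlation coefficient of
#' binarized predictions (0 with a warning when a confusion-matrix margin
#' is empty); `rmse`/`mae` the usual regression errors.
#'
#' @param scores numeric prediction scores (higher = more positive).
#' @param labels 0/1 labels.
#' @return scalar metric value.
#' @export
roc_auc <- function(scores, labels) {
  check_two_classes(labels, "ROC-AUC")
  as.numeric(pROC::auc(pROC::roc(response = labels, predictor = scores,
                                 quiet = TRUE, direction = "<",
                                 levels = c(0, 1))))
}

#' @rdname roc_auc
#' @export
average_precision <- function(scores, labels) {
  check_two_classes(labels, "average precision")
  thr <- sort(unique(scores), decreasing = TRUE)
  n_pos <- sum(labels == 1)
  ap <- 0; prev_recall <- 0
  for (t in thr) {
    sel <- scores >= t
    tp <- sum(labels[sel] == 1)
    prec <- tp / sum(sel)
    rec <- tp / n_pos
    ap <- ap + (rec - prev_recall) * prec
    prev_recall <- rec
  }
  ap
}

#' @rdname roc_auc
#' @param pred 0/1 predicted classes.
#' @export
mcc <- function(pred, labels) {
  tp <- sum(pred == 1 & labels == 1); tn <- sum(pred == 0 & labels == 0)
  fp <- sum(pred == 1 & labels == 0); fn <- sum(pred == 0 & labels == 1)
  den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  if (den == 0) {
    warning("MCC denominator is zero (degenerate confusion matrix); returning 0")
    return(0)
  }
  (tp * tn - fp * fn) / den
}

#' @rdname roc_auc
#' @export
rmse <- function(pred, labels) sqrt(mean((pred - labels)^2))

#' @rdname roc_auc
#' @export
mae <- function(pred, labels) mean(abs(pred - labels))

#' Confusion-matrix summary at a decision threshold
#'
#' @param pred 0/1 predicted classes.
#' @param labels 0/1 true labels.
#' @return named list with `tp`, `fp`, `tn`, `fn`, `tpr`, `fpr`,
#'   `precision`, `mcc`.
#' @export
confusion_metrics <- function(pred, labels) {
  tp <- sum(pred == 1 & labels == 1); tn <- sum(pred == 0 & labels == 0)
  fp <- sum(pred == 1 & labels == 0); fn <- sum(pred == 0 & labels == 1)
  list(tp = tp, fp = fp, tn = tn, fn = fn,
       tpr = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
       fpr = if (fp + tn > 0) fp / (fp + tn) else NA_real_,
       precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
       mcc = suppressWarnings(mcc(pred, labels)))
}

check_two_classes <- function(labels, what) {
  if (length(unique(labels[!is.na(labels)])) < 2L) {
    stop(structure(
      class = c("kggraph_metric_error", "error", "condition"),
      list(message = paste(what, "requires both classes present"),
           call = NULL)
    ))
  }
  invisible(TRUE)
}

# -- fine-tuning --------------------------------------------------------------

#' Fine-tune a pretrained encoder on a labeled dataset
#'
#' Attaches a two-layer task head to the supernode fingerprint and trains
#' head and encoder jointly with Adam (binary cross-entropy with logits for
#' classification, smooth-L1 for regression; missing labels are masked
#' per task). The epoch with the best validation metric is kept and the
#' report is computed on the test subset.
#'
#' @param model a pretrained `kgg_model`.
#' @param data data frame with a `smiles` column and one or more label
#'   columns.
#' @param split a [scaffold_split()] result.
#' @param task_type `"classification"` (0/1 labels) or `"regression"`.
#' @param lr,epochs,batch_size optimizer settings.
#' @param seed seed for batching, dropout and head initialization.
#' @param label_cols label column names (default: all non-`smiles` columns).
#' @return list with `model` (fine-tuned, task head in `$heads`),
#'   `report` (a `kgg_metric_report`), and `trace` (per-epoch validation
#'   metric).
#' @export
finetune <- function(model, data, split, task_type = c("classification",
                                                       "regression"),
                     lr = 1e-3, epochs = 30L, batch_size = 32L, seed = 1L,
                     label_cols = NULL) {
  task_type <- match.arg(task_type)
  stopifnot(inherits(model, "kgg_model"), is.data.frame(data),
            "smiles" %in% names(data))
  if (is.null(label_cols)) label_cols <- setdiff(names(data), "smiles")
  if (length(label_cols) == 0L) stop("no label columns", call. = FALSE)
  Y <- as.matrix(data[, label_cols, drop = FALSE])
  if (task_type == "classification" &&
      !all(Y[!is.na(Y)] %in% c(0, 1))) {
    stop("classification labels must be 0/1", call. = FALSE)
  }
  cfg <- model$config
  # regression targets are standardized on the training subset (the head
  # then learns on unit scale; predictions are mapped back for reporting)
  y_mu <- rep(0, ncol(Y)); y_sd <- rep(1, ncol(Y))
  if (task_type == "regression") {
    for (t in seq_len(ncol(Y))) {
      tr <- Y[split$train, t]
      y_mu[t] <- mean(tr, na.rm = TRUE)
      s <- stats::sd(tr, na.rm = TRUE)
      y_sd[t] <- if (is.finite(s) && s > 0) s else 1
    }
    Y <- sweep(sweep(Y, 2L, y_mu), 2L, y_sd, `/`)
  }
  tensors <- lapply(data$smiles, function(s) {
    graph_tensors(build_hierarchical_graph(parse_smiles(s)))
  })
  set.seed(seed)
  n_tasks <- length(label_cols)
  hh <- max(8L, cfg$d %/% 4L)
  l1 <- init_linear(hh, cfg$d); l2 <- init_linear(n_tasks, hh)
  params <- model$params
  params[["task.W1"]] <- l1$W; params[["task.b1"]] <- l1$b
  params[["task.W2"]] <- l2$W; params[["task.b2"]] <- l2$b
  state <- model$state
  opt <- adam_init(params)

  predict_scores <- function(params, state, idx) {
    out <- matrix(NA_real_, length(idx), n_tasks)
    for (st in seq(1L, length(idx), by = 256L)) {
      sub <- idx[st:min(st + 255L, length(idx))]
      batch <- combine_batch(tensors[sub])
      fwd <- encoder_forward(batch, params, state, cfg, training = FALSE)
      fc <- mlp2_forward(fwd$H[batch$super_rows, , drop = FALSE],
                         params, "task")
      out[match(sub, idx), ] <- fc$out
    }
    out
  }
  valid_metric <- function(params, state) {
    sc <- predict_scores(params, state, split$valid)
    yv <- Y[split$valid, , drop = FALSE]
    if (task_type == "classification") {
      mean(vapply(seq_len(n_tasks), function(t) {
        ok <- !is.na(yv[, t])
        if (length(unique(yv[ok, t])) < 2L) return(NA_real_)
        roc_auc(sigmoid(sc[ok, t]), yv[ok, t])
      }, numeric(1)), na.rm = TRUE)
    } else {
      -mean(vapply(seq_len(n_tasks), function(t) {
        ok <- !is.na(yv[, t])
        rmse(sc[ok, t], yv[ok, t])
      }, numeric(1)))
    }
  }

  best <- list(metric = -Inf, params = params, state = state)
  trace <- numeric(0)
  ntr <- length(split$train)
  for (ep in seq_len(epochs)) {
    ord <- split$train[sample.int(ntr)]
    for (st in seq(1L, ntr, by = batch_size)) {
      idx <- ord[st:min(st + batch_size - 1L, ntr)]
      batch <- combine_batch(tensors[idx])
      yb <- Y[idx, , drop = FALSE]
      fwd <- encoder_forward(batch, params, state, cfg, training = TRUE)
      state <- fwd$state
      Hg <- fwd$H[batch$super_rows, , drop = FALSE]
      fc <- mlp2_forward(Hg, params, "task")
      mask <- !is.na(yb)
      z <- fc$out[mask]; yy <- yb[mask]
      ls <- if (task_type == "classification") {
        bce_logits_forward(z, yy, "mean")
      } else {
        r <- smooth_l1_forward(z, yy, "mean")
        list(loss = r$loss, dz = r$dpred)
      }
      dOut <- matrix(0, nrow(fc$out), ncol(fc$out))
      dOut[mask] <- ls$dz
      grads <- zero_grads(params)
      bk <- mlp2_backward(fc, dOut, params, grads)
      grads <- bk$grads
      dH <- matrix(0, batch$N, cfg$d)
      dH[batch$super_rows, ] <- bk$dX
      enc_grads <- encoder_backward(fwd, dH, batch, params, cfg)
      for (nm in names(enc_grads)) grads[[nm]] <- grads[[nm]] + enc_grads[[nm]]
      upd <- adam_step(params, grads, opt, lr)
      params <- upd$params; opt <- upd$opt
    }
    vm <- if (length(split$valid)) valid_metric(params, state) else NA_real_
    trace <- c(trace, vm)
    if (is.na(vm) || vm >= best$metric) {
      best <- list(metric = if (is.na(vm)) -Inf else vm,
                   params = params, state = state)
    }
  }

  sc_test <- predict_scores(best$params, best$state, split$test)
  y_test <- Y[split$test, , drop = FALSE]
  if (task_type == "regression") {
    sc_test <- sweep(sweep(sc_test, 2L, y_sd, `*`), 2L, y_mu, `+`)
    y_test <- sweep(sweep(y_test, 2L, y_sd, `*`), 2L, y_mu, `+`)
  }
  report <- metric_report(sc_test, y_test, task_type, label_cols)
  out_model <- model
  out_model$params <- best$params[names(model$params)]
  out_model$heads <- best$params[setdiff(names(best$params),
                                         names(model$params))]
  out_model$state <- best$state
  list(model = out_model, report = report, trace = trace)
}

#' Per-task metric report
#'
#' @param scores matrix of raw model outputs (logits for classification).
#' @param labels matrix of labels (NA = missing).
#' @param task_type `"classification"` or `"regression"`.
#' @param task_names column names.
#' @return data frame of class `kgg_metric_report`: one row per task plus
#'   an `average` row; columns `roc_auc`, `mcc`, `ap` or `rmse`, `mae`.
#' @export
metric_report <- function(scores, labels, task_type, task_names = NULL) {
  scores <- as.matrix(scores); labels <- as.matrix(labels)
  if (is.null(task_names)) task_names <- paste0("task", seq_len(ncol(labels)))
  rows <- lapply(seq_len(ncol(labels)), function(t) {
    ok <- !is.na(labels[, t])
    y <- labels[ok, t]; s <- scores[ok, t]
    if (task_type == "classification") {
      p <- sigmoid(s)
      data.frame(task = task_names[t],
                 roc_auc = tryCatch(roc_auc(p, y), error = function(e) NA_real_),
                 mcc = suppressWarnings(mcc(as.numeric(p > 0.5), y)),
                 ap = tryCatch(average_precision(p, y),
                               error = function(e) NA_real_))
    } else {
      data.frame(task = task_names[t], rmse = rmse(s, y), mae = mae(s, y))
    }
  })
  rep <- do.call(rbind, rows)
  avg <- rep[1L, , drop = FALSE]
  avg$task <- "average"
  for (cc in setdiff(names(rep), "task")) avg[[cc]] <- mean(rep[[cc]], na.rm = TRUE)
  structure(rbind(rep, avg), class = c("kgg_metric_report", "data.frame"))
}

# -- fingerprint comparison ---------------------------------------------------

# k-nearest-neighbor prediction (Euclidean); returns the mean train label
# of the k nearest neighbors for each test row.
knn_predict <- function(X_train, y_train, X_test, k = 3L) {
  k <- min(k, nrow(X_train))
  tr2 <- rowSums(X_train^2)
  out <- numeric(nrow(X_test))
  for (i in seq_len(nrow(X_test))) {
    d2 <- tr2 - 2 * drop(X_train %*% X_test[i, ])
    nb <- order(d2)[seq_len(k)]
    out[i] <- mean(y_train[nb])
  }
  out
}

#' Compare learned and traditional fingerprints with a kNN probe
#'
#' Evaluates k-nearest-neighbor (k = 3) prediction on the test subset using
#' four molecular representations under the identical split: the model's
#' supernode fingerprint and MACCS, ECFP4 and path-based (FP2)
#' fingerprints. Classification tasks report ROC-AUC/MCC/AP (the kNN score
#' is the positive fraction among neighbors); regression tasks report
#' RMSE/MAE.
#'
#' @param model a `kgg_model`.
#' @param data data frame with `smiles` and one label column.
#' @param split a [scaffold_split()] result; train and test must be
#'   disjoint (overlap is a documented error, the train=test leak guard).
#' @param task_type `"classification"` or `"regression"`.
#' @param k neighbor count.
#' @param label_col label column (default first non-smiles column).
#' @return data frame with one row per fingerprint type.
#' @export
compare_fingerprints <- function(model, data, split,
                                 task_type = c("classification",
                                               "regression"),
                                 k = 3L, label_col = NULL) {
  task_type <- match.arg(task_type)
  if (length(intersect(split$train, split$test)) > 0L) {
    stop("train and test subsets overlap; refusing to evaluate a leaked split",
         call. = FALSE)
  }
  if (is.null(label_col)) label_col <- setdiff(names(data), "smiles")[1L]
  y <- data[[label_col]]
  reps <- list(
    kgg = extract_fingerprint(data$smiles, model),
    MACCS = traditional_fingerprint(data$smiles, "MACCS"),
    ECFP4 = traditional_fingerprint(data$smiles, "ECFP4"),
    FP2 = traditional_fingerprint(data$smiles, "FP2")
  )
  rows <- lapply(names(reps), function(nm) {
    X <- reps[[nm]]
    pred <- knn_predict(X[split$train, , drop = FALSE], y[split$train],
                        X[split$test, , drop = FALSE], k)
    yt <- y[split$test]
    if (task_type == "classification") {
      data.frame(fingerprint = nm,
                 roc_auc = tryCatch(roc_auc(pred, yt),
                                    error = function(e) NA_real_),
                 mcc = suppressWarnings(mcc(as.numeric(pred > 0.5), yt)),
                 ap = tryCatch(average_precision(pred, yt),
                               error = function(e) NA_real_))
    } else {
      data.frame(fingerprint = nm, rmse = rmse(pred, yt),
                 mae = mae(pred, yt))
    }
  })
  do.call(rbind, rows)
}
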