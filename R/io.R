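# Repository plumbing: SMILES/CSV readers, run configuration, checkpoints.

#' Read a SMILES file (one molecule per line)
#'
#' Lines that fail to parse are skipped and counted; leading/trailing
#' whitespace and anything after the first whitespace (titles) is ignored.
#'
#' @param path file path.
#' @param validate parse every entry and drop failures (default TRUE).
#' @return character vector of SMILES with attribute `n_skipped`.
#' @export
read_smiles_file <- function(path, validate = TRUE) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- sub("\\s.*$", "", lines)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop("empty SMILES file: ", path, call. = FALSE)
  skipped <- 0L
  if (validate) {
    ok <- vapply(lines, function(s) {
      !inherits(tryCatch(parse_smiles(s), error = function(e) e), "error")
    }, logical(1), USE.NAMES = FALSE)
    skipped <- sum(!ok)
    if (skipped > 0L) {
      message(skipped, " unparseable SMILES skipped from ", path)
    }
    lines <- lines[ok]
  }
  structure(lines, n_skipped = skipped)
}

#' Read a labeled CSV dataset
#'
#' @param path CSV path with a SMILES column plus label columns.
#' @param smiles_col name of the SMILES column.
#' @return data frame with `smiles` first, malformed rows dropped and
#'   counted in attribute `n_skipped`.
#' @export
read_labeled_csv <- function(path, smiles_col = "smiles") {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!smiles_col %in% names(df)) {
    stop("column '", smiles_col, "' not found in ", path, call. = FALSE)
  }
  if (nrow(df) == 0L) stop("empty dataset: ", path, call. = FALSE)
  ok <- vapply(df[[smiles_col]], function(s) {
    !inherits(tryCatch(parse_smiles(s), error = function(e) e), "error")
  }, logical(1), USE.NAMES = FALSE)
  if (any(!ok)) message(sum(!ok), " rows with unparseable SMILES skipped")
  df <- df[ok, , drop = FALSE]
  names(df)[names(df) == smiles_col] <- "smiles"
  df <- df[, c("smiles", setdiff(names(df), "smiles")), drop = FALSE]
  rownames(df) <- NULL
  structure(df, n_skipped = sum(!ok))
}

#' Assemble and validate a run configuration
#'
#' All defaults that full-scale training would use are explicit here:
#' embedding width 512, 5 GIN layers, batch size 32, Adam at 1e-3. Unknown
#' keys are rejected.
#'
#' @param ... overrides, e.g. `encoder = list(d = 64)`,
#'   `pretrain = list(epochs = 5)`.
#' @return nested list with sections `encoder`, `pretrain`, `finetune`.
#' @export
run_config <- function(...) {
  defaults <- list(
    encoder = list(d = 512L, n_layers = 5L, dropout = 0.1,
                   emb_hidden = 16L, seed = 1L),
    pretrain = list(lr = 1e-3, batch_size = 32L, epochs = 1L,
                    loss_reduction = "mean"),
    finetune = list(lr = 1e-3, epochs = 30L, batch_size = 32L,
                    seeds = c(1L, 2L, 3L))
  )
  over <- list(...)
  bad <- setdiff(names(over), names(defaults))
  if (length(bad)) stop("unknown config section(s): ",
                        paste(bad, collapse = ", "), call. = FALSE)
  for (sec in names(over)) {
    bad <- setdiff(names(over[[sec]]), names(defaults[[sec]]))
    if (length(bad)) stop("unknown key(s) in ", sec, ": ",
                          paste(bad, collapse = ", "), call. = FALSE)
    defaults[[sec]][names(over[[sec]])] <- over[[sec]]
  }
  defaults
}

#' Save / load a model checkpoint
#'
#' The checkpoint is a single serialized weights file accompanied by a
#' JSON sidecar (`<path>.json`) recording the architecture (d, layer
#' count, dropout, seed) and the bond-type code map, so a checkpoint is
#' self-describing. Loading verifies weights against the sidecar; a
#' mismatch is an error. Round-tripping reproduces eval-mode fingerprints
#' bit-exactly.
#'
#' @param model a `kgg_model`.
#' @param path checkpoint file path.
#' @return `path` invisibly (save); the restored `kgg_model` (load).
#' @export
save_checkpoint <- function(model, path) {
  stopifnot(inherits(model, "kgg_model"))
  saveRDS(model, path)
  sidecar <- list(
    d = model$config$d, n_layers = model$config$n_layers,
    dropout = model$config$dropout, emb_hidden = model$config$emb_hidden,
    seed = model$config$seed,
    bond_type_codes = as.list(model$bond_type_codes)
  )
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  if (!file.exists(path)) stop("no such checkpoint: ", path, call. = FALSE)
  model <- readRDS(path)
  if (!inherits(model, "kgg_model")) {
    stop("not a kgg_model checkpoint: ", path, call. = FALSE)
  }
  sc_path <- paste0(path, ".json")
  if (file.exists(sc_path)) {
    sc <- jsonlite::read_json(sc_path, simplifyVector = TRUE)
    if (!identical(as.integer(sc$d), model$config$d) ||
        !identical(as.integer(sc$n_layers), model$config$n_layers)) {
      stop("checkpoint sidecar disagrees with serialized config (d/layers)",
           call. = FALSE)
    }
  }
  d <- model$config$d
  if (ncol(model$params[["ne1.W2"]]) != model$config$emb_hidden ||
      nrow(model$params[["ne1.W2"]]) != d ||
      nrow(model$params[["gin1.W1"]]) != 2L * d) {
    stop("checkpoint weights do not match their declared architecture",
         call. = FALSE)
  }
  model
}
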