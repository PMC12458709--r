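# Pretraining-corpus contamination audit: the fraction of molecules in
# downstream test splits that also occur in the pretraining corpus, by
# exact canonical-SMILES identity (set semantics; no tautomer or charge
# standardization beyond canonicalization).

#' Audit overlap between a pretraining corpus and test splits
#'
#' Canonicalizes both sides, then counts per test set (and overall, on the
#' union of test molecules) how many canonical structures also occur in the
#' pretraining corpus. Duplicates within either input do not affect the
#' counts. Unparseable entries are excluded and counted in the attributes.
#'
#' @param pretrain_smiles character vector: the pretraining corpus.
#' @param test_sets named list of character vectors: test-split SMILES per
#'   downstream dataset.
#' @return data frame of class `kgg_contamination_report` with columns
#'   `dataset`, `contaminated`, `test_size`, `ratio_percent` (one decimal),
#'   one row per dataset plus an `overall` row; attributes
#'   `n_excluded_pretrain`, `n_excluded_test`.
#' @examples
#' \donttest{
#' audit_contamination(c("CCO", "c1ccccc1"),
#'                     list(demo = c("C1=CC=CC=C1", "CCN")))
#' }
#' @export
audit_contamination <- function(pretrain_smiles, test_sets) {
  stopifnot(is.list(test_sets), length(test_sets) > 0L)
  if (is.null(names(test_sets)) || any(!nzchar(names(test_sets)))) {
    names(test_sets) <- paste0("dataset", seq_along(test_sets))
  }
  pre <- canonicalize_smiles(pretrain_smiles)
  pre_set <- unique(pre[!is.na(pre)])
  if (length(pre_set) == 0L) {
    stop("pretraining corpus is empty after canonicalization", call. = FALSE)
  }
  canon_tests <- lapply(names(test_sets), function(nm) {
    cs <- canonicalize_smiles(test_sets[[nm]])
    if (length(cs) == 0L || all(is.na(cs))) {
      stop(structure(
        class = c("kggraph_audit_error", "error", "condition"),
        list(message = paste0("test split '", nm,
                              "' is empty after canonicalization"),
             call = NULL)
      ))
    }
    cs
  })
  names(canon_tests) <- names(test_sets)
  rows <- lapply(names(test_sets), function(nm) {
    ts <- unique(canon_tests[[nm]][!is.na(canon_tests[[nm]])])
    cont <- sum(ts %in% pre_set)
    data.frame(dataset = nm, contaminated = cont, test_size = length(ts),
               ratio_percent = round(100 * cont / length(ts), 1))
  })
  all_test <- unique(unlist(lapply(canon_tests, function(cs)
    cs[!is.na(cs)]), use.names = FALSE))
  cont_all <- sum(all_test %in% pre_set)
  rows[[length(rows) + 1L]] <- data.frame(
    dataset = "overall", contaminated = cont_all,
    test_size = length(all_test),
    ratio_percent = round(100 * cont_all / length(all_test), 1))
  out <- do.call(rbind, rows)
  attr(out, "n_excluded_pretrain") <- attr(pre, "n_excluded")
  attr(out, "n_excluded_test") <-
    sum(vapply(canon_tests, function(cs) sum(is.na(cs)), numeric(1)))
  class(out) <- c("kgg_contamination_report", "data.frame")
  out
}
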