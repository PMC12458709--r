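# Low-level bridge to the OpenBabel toolkit (via ChemmineOB).
#
# ChemmineOB ships SWIG bindings for the full OpenBabel C++ API but exports
# only a handful of high-level wrappers; the per-atom/per-bond accessors and
# the SMARTS matcher used here live in its namespace unexported. All access
# is funnelled through ob_call()/ob_fun() so the dependency surface is
# explicit and greppable.

.kgg <- new.env(parent = emptyenv())

ob_fun <- function(name) {
  ns <- getNamespace("ChemmineOB")
  f <- get0(name, envir = ns, inherits = FALSE)
  if (is.null(f)) {
    stop("ChemmineOB does not provide '", name,
         "'; an incompatible OpenBabel binding is installed",
         call. = FALSE)
  }
  f
}

ob_call <- function(name, ...) ob_fun(name)(...)

#' Parse a SMILES string into an OpenBabel molecule handle
#'
#' Internal. The handle must be released with `ob_free()` once the graph has
#' been extracted. Syntax failures (characters OpenBabel cannot lex) and
#' sanitization failures (parsed but chemically empty/invalid input) raise
#' distinct condition classes, both carrying the offending string.
#'
#' @param smiles single SMILES string.
#' @return an external pointer to an OBMol.
#' @keywords internal
#' @noRd
ob_parse <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) == 1L)
  if (is.na(smiles) || !nzchar(trimws(smiles))) {
    stop(kgg_parse_error(smiles, "empty SMILES string", "syntax"))
  }
  mol <- tryCatch(
    ChemmineOB::forEachMol("SMILES", smiles, identity)[[1L]],
    error = function(e) {
      stop(kgg_parse_error(smiles, conditionMessage(e), "syntax"))
    }
  )
  if (ob_call("OBMol_NumAtoms", mol) == 0L) {
    ob_free(mol)
    stop(kgg_parse_error(smiles, "no atoms after parsing", "sanitize"))
  }
  mol
}

ob_free <- function(mol) {
  try(ob_call("delete_OBMol", mol), silent = TRUE)
  invisible(NULL)
}

kgg_parse_error <- function(smiles, message, kind = c("syntax", "sanitize")) {
  kind <- match.arg(kind)
  structure(
    class = c(paste0("kggraph_", kind, "_error"),
              "kggraph_parse_error", "error", "condition"),
    list(message = sprintf("cannot parse SMILES '%s': %s", smiles, message),
         call = NULL, smiles = smiles)
  )
}

# -- SMARTS -------------------------------------------------------------------

ob_smarts_pattern <- function(smarts) {
  if (is.null(.kgg$smarts)) .kgg$smarts <- new.env(parent = emptyenv())
  pat <- get0(smarts, envir = .kgg$smarts)
  if (is.null(pat)) {
    pat <- ob_call("OBSmartsPattern__SWIG_0")
    if (!ob_call("OBSmartsPattern_Init", pat, smarts)) {
      stop("invalid SMARTS pattern: ", smarts, call. = FALSE)
    }
    assign(smarts, pat, envir = .kgg$smarts)
  }
  pat
}

#' Match a SMARTS pattern, returning 1-based atom index vectors
#' @return list of integer vectors, one per unique match.
#' @keywords internal
#' @noRd
ob_smarts_match <- function(mol, smarts) {
  pat <- ob_smarts_pattern(smarts)
  if (!ob_call("OBSmartsPattern_Match", pat, mol)) return(list())
  res <- ob_call("OBSmartsPattern_GetUMapList", pat)
  lapply(res, as.integer)
}

# -- canonical SMILES ---------------------------------------------------------

#' Canonicalize SMILES strings
#'
#' Converts SMILES to OpenBabel's canonical form, the normalization used for
#' exact-structure equality tests (e.g. in [audit_contamination()]).
#' Unparseable entries yield `NA` and are reported via an attribute rather
#' than an error, so corpus-scale inputs degrade gracefully.
#'
#' @param smiles character vector of SMILES.
#' @return character vector of canonical SMILES, `NA` where parsing failed,
#'   with an `n_excluded` attribute giving the failure count.
#' @examples
#' canonicalize_smiles(c("C1=CC=CC=C1", "c1ccccc1"))
#' @export
canonicalize_smiles <- function(smiles) {
  stopifnot(is.character(smiles))
  n <- length(smiles)
  out <- rep(NA_character_, n)
  if (n == 0L) return(structure(out, n_excluded = 0L))
  remaining <- seq_len(n)
  # Batch conversion stops at the first bad molecule; re-batch the tail so a
  # corpus with b bad entries costs b+1 conversions, not n.
  while (length(remaining) > 0L) {
    src <- paste0(smiles[remaining], " t", remaining, collapse = "\n")
    res <- tryCatch(
      ChemmineOB::convertFormat("SMI", "CAN", paste0(src, "\n")),
      error = function(e) ""
    )
    lines <- strsplit(res, "\n", fixed = TRUE)[[1L]]
    lines <- lines[nzchar(lines)]
    got <- integer(0)
    for (ln in lines) {
      parts <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
      if (length(parts) >= 2L && grepl("^t[0-9]+$", parts[2L])) {
        idx <- as.integer(sub("^t", "", parts[2L]))
        out[idx] <- parts[1L]
        got <- c(got, idx)
      }
    }
    done <- match(got, remaining)
    k <- length(got)
    if (k == length(remaining)) break
    # entry k+1 of the remaining batch failed; skip it and continue
    remaining <- remaining[-seq_len(min(k + 1L, length(remaining)))]
  }
  structure(out, n_excluded = sum(is.na(out)))
}

# -- fingerprints -------------------------------------------------------------

#' Compute a traditional bit fingerprint for SMILES strings
#'
#' @param smiles character vector of SMILES.
#' @param type one of `"MACCS"`, `"ECFP4"`, `"FP2"` (OpenBabel's path-based
#'   fingerprint, used here as the linear/path fingerprint baseline).
#' @return numeric 0/1 matrix, one row per molecule.
#' @export
traditional_fingerprint <- function(smiles, type = c("MACCS", "ECFP4", "FP2")) {
  type <- match.arg(type)
  rows <- lapply(smiles, function(s) {
    mol <- ob_parse(s)
    on.exit(ob_free(mol))
    ChemmineOB::fingerprint_OB(list(mol), type)
  })
  do.call(rbind, rows)
}
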