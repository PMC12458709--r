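# Curated fixture pool and deterministic label recipes. The pool covers
# drug-like fragments: rings (carbo-/heterocyclic, fused), chains, all four
# bond kinds (single, double, triple, aromatic), conjugated and
# non-conjugated systems, charged groups, and every hybridization state in
# the closed set except UNSPECIFIED (s via organolithium, sp3d/sp3d2 via
# hypervalent P/S).

#' The curated fixture SMILES pool
#'
#' @return character vector of 300 valid SMILES.
#' @export
fixture_pool <- function() {
  c(
    # -- alkanes, branched and cyclic --
    "C", "CC", "CCC", "CCCC", "CCCCC", "CCCCCC", "CCCCCCC", "CCCCCCCC",
    "CC(C)C", "CC(C)(C)C", "CCC(C)C", "CC(C)CC", "CCCC(C)C", "CC(C)C(C)C",
    "C1CC1", "C1CCC1", "C1CCCC1", "C1CCCCC1", "C1CCCCCC1", "C1CCCCCCC1",
    "CC1CCCCC1", "CC1CCCC1", "CC1CC1", "C1CCC2CCCCC2C1", "C1CC2CCC1CC2",
    "CC1CCC(C)CC1", "CC1CCCCC1C", "C1CCC(CC1)C1CCCCC1",
    # -- alkenes, dienes --
    "C=C", "CC=C", "CC=CC", "CC(C)=C", "CCC=C", "C=CC=C", "CC=CC=C",
    "CC(=C)C=C", "C1=CCCCC1", "C1=CCCC1", "C1=CC=CCC1", "CC1=CCCCC1",
    "C=C1CCCCC1", "CC(C)=CCC", "C=CCC=C",
    # -- alkynes and nitriles --
    "C#C", "CC#C", "CC#CC", "CCC#C", "C#CC#C", "CC#N", "CCC#N", "N#CC#N",
    "C#CC1CCCCC1", "CC(C)C#N", "C#Cc1ccccc1", "N#Cc1ccccc1",
    # -- benzenes and substituted aromatics --
    "c1ccccc1", "Cc1ccccc1", "CCc1ccccc1", "Cc1ccccc1C", "Cc1cccc(C)c1",
    "Cc1ccc(C)cc1", "CC(C)c1ccccc1", "C=Cc1ccccc1", "c1ccc(cc1)c1ccccc1",
    "Cc1ccc(cc1)c1ccccc1", "c1ccc(cc1)Cc1ccccc1", "CCCc1ccccc1",
    "CC(C)(C)c1ccccc1", "Cc1ccccc1CC",
    # -- phenols, ethers, anilines --
    "Oc1ccccc1", "COc1ccccc1", "CCOc1ccccc1", "Oc1ccc(O)cc1",
    "COc1ccc(OC)cc1", "Nc1ccccc1", "CNc1ccccc1", "CN(C)c1ccccc1",
    "Nc1ccc(O)cc1", "Oc1ccccc1O", "COc1ccccc1O", "c1ccc(cc1)Oc1ccccc1",
    "Nc1ccc(N)cc1", "CNc1ccc(C)cc1",
    # -- halogenated --
    "Fc1ccccc1", "Clc1ccccc1", "Brc1ccccc1", "Ic1ccccc1", "Fc1ccc(F)cc1",
    "Clc1ccc(Cl)cc1", "FC(F)(F)c1ccccc1", "CCl", "CBr", "CI", "CF",
    "ClCCl", "ClC(Cl)Cl", "ClC(Cl)(Cl)Cl", "FC(F)F", "FCC(F)(F)F",
    "CCCl", "CCBr", "ClCCCl", "FC(F)(F)C(=O)O", "Clc1ccccc1Cl",
    # -- alcohols, ethers, carbonyls --
    "CO", "CCO", "CCCO", "CC(C)O", "CC(C)(C)O", "OCCO", "OCC(O)CO",
    "COC", "CCOC", "CCOCC", "C1CCOC1", "C1CCOCC1", "C1COCCO1", "COCCOC",
    "C=O", "CC=O", "CCC=O", "CC(C)=O", "CCC(C)=O", "CC(=O)C(C)=O",
    "O=C1CCCCC1", "O=C1CCCC1", "CC(=O)CC(C)=O", "O=CC=O",
    # -- acids, esters, amides --
    "OC=O", "CC(=O)O", "CCC(=O)O", "CC(C)C(=O)O", "OC(=O)CC(=O)O",
    "OC(=O)C(=O)O", "CC(=O)OC", "CC(=O)OCC", "COC(=O)C", "CCOC(=O)CC",
    "O=C1CCCCO1", "CC(=O)N", "CC(=O)NC", "CC(=O)N(C)C", "NC=O", "CNC=O",
    "CN(C)C=O", "NC(N)=O", "CNC(=O)NC", "CC(=O)NC1CCCCC1", "O=C1CCCN1",
    "O=C1CCCCN1", "CC(=O)Nc1ccccc1", "NC(=O)c1ccccc1",
    # -- amines --
    "CN", "CCN", "CCCN", "CNC", "CCNCC", "CN(C)C", "CCN(CC)CC",
    "NCCN", "NCCCN", "C1CCNC1", "C1CCNCC1", "C1CNCCN1", "C1COCCN1",
    "CN1CCCC1", "CN1CCCCC1", "CN1CCOCC1", "NC1CCCCC1", "CNC1CCCCC1",
    "NCc1ccccc1", "CNCc1ccccc1",
    # -- sulfur and phosphorus --
    "CS", "CCS", "CSC", "CCSCC", "CSSC", "CS(C)=O", "CS(C)(=O)=O",
    "CS(=O)(=O)O", "CS(=O)(=O)N", "Sc1ccccc1", "CSc1ccccc1",
    "O=S(=O)(c1ccccc1)N", "C1CCSC1", "CP(C)C", "COP(=O)(OC)OC",
    "OP(=O)(O)O", "CCP(CC)CC",
    # -- hypervalent / organometallic (sp3d, sp3d2, s states) --
    "FP(F)(F)(F)F", "FS(F)(F)(F)(F)F", "[Li]C", "[Li]CC",
    "FP(F)(F)(F)Cl", "FS(F)(F)(F)(F)Cl",
    # -- nitro, nitrile oxides, charged groups --
    "C[N+](C)(C)C", "[O-][N+](=O)C", "[O-][N+](=O)c1ccccc1",
    "[O-][N+](=O)c1ccc(C)cc1", "CC(=O)[O-]", "CC[N+](C)(C)C",
    "[NH3+]CC(=O)[O-]", "[O-]c1ccccc1",
    # -- five-membered heteroaromatics --
    "c1ccoc1", "c1ccsc1", "c1cc[nH]c1", "Cc1ccco1", "Cc1cccs1",
    "Cc1ccc[nH]1", "c1cnco1", "c1cncs1", "c1cnc[nH]1", "c1cn[nH]c1",
    "c1cnoc1", "c1cnsc1", "Cc1ncco1", "Cc1nccs1", "Cn1cccc1", "Cn1ccnc1",
    "c1cc2ccccc2o1", "c1cc2ccccc2s1", "c1cc2ccccc2[nH]1",
    # -- six-membered heteroaromatics --
    "c1ccncc1", "Cc1ccncc1", "Cc1cccnc1", "Cc1ccccn1", "c1ccnnc1",
    "c1ccncn1", "c1cncnc1", "c1cnccn1", "Nc1ccncc1", "Oc1ccncc1",
    "COc1ccncc1", "c1ccc2ncccc2c1", "c1ccc2cnccc2c1", "Cc1ccnc(C)c1",
    "Clc1ccncc1", "c1cnc2ccccc2n1",
    # -- fused aromatics --
    "c1ccc2ccccc2c1", "Cc1ccc2ccccc2c1", "c1ccc2cc3ccccc3cc2c1",
    "c1ccc2c(c1)cccc2O", "c1ccc2c(c1)ccc(N)c2",
    # -- mixed pharmacophores --
    "CC(=O)Oc1ccccc1C(=O)O", "CC(=O)Nc1ccc(O)cc1",
    "CC(C)Cc1ccc(cc1)C(C)C(=O)O", "NCCc1ccccc1", "NCCc1cc[nH]c1",
    "OCc1ccccc1", "O=Cc1ccccc1", "CC(=O)c1ccccc1", "OC(=O)c1ccccc1",
    "COC(=O)c1ccccc1", "NCC(=O)O", "CC(N)C(=O)O", "CC(O)c1ccccc1",
    "O=Cc1ccc(O)c(OC)c1", "O=CC=Cc1ccccc1", "O=C1Cc2ccccc2O1",
    "O=c1ccoc2ccccc12", "NC(=O)c1ccncc1", "Cn1cnc2c1c(=O)n(C)c(=O)n2C",
    "OCC1OC(O)C(O)C(O)C1O", "CC1CCC(C(C)C)C(O)C1",
    "CC(=O)NCCc1c[nH]c2ccccc12", "NCCc1c[nH]c2ccccc12",
    "Clc1ccccc1-c1ccccc1", "COc1cc(C=O)ccc1O", "CCOC(=O)c1ccc(N)cc1",
    "CN1CCC(CC1)c1ccccc1", "O=C(Nc1ccccc1)c1ccccc1",
    "CN(C)CCc1ccccc1", "CSCCC(N)C(=O)O", "OC(=O)CCc1ccccc1",
    "CC(C)NCC(O)c1ccccc1", "CN1CCN(CC1)c1ccccc1",
    # -- conjugated but non-aromatic systems --
    "C=CC=O", "CC=CC=O", "C=CC#N", "C=CC(=O)O", "C=CC(=O)OC",
    "CC(=C)C(=O)OC", "O=C(C=C)N", "C=CC(=O)N(C)C", "N#CC=C",
    "O=C(C=Cc1ccccc1)O", "CC=CC(=O)O", "C=C(C)C=O",
    # -- assorted saturated heterocycles --
    "C1CCOC1O", "OC1CCCCC1", "OC1CCCC1", "NC1CCNCC1", "OCC1CCCCO1",
    "C1CSCCS1", "C1COCCS1", "O=C1OCCC1", "O=C1OCCCC1", "CC1CCCO1",
    "CC1CCCN1", "CC1OCCO1", "C1CC2(CC1)CCCC2", "C1CC2(CCC1)CCOC2",
    # -- extra diversity: imines, oximes, hydrazines, azides-free N chains --
    "CC=N", "CC=NC", "CC=NO", "CC(C)=NO", "NN", "CNN", "CNNC",
    "NNc1ccccc1", "CC(=O)NN", "C1CC=NC1", "CN=C=O", "CN=C=S",
    "O=C=O", "S=C=S", "N=C=N", "CCOC=O", "COC(=O)OC", "OCC#C",
    "NCC#C", "OCC=C", "NCC=C", "ClCC=C", "OC(C#C)C=C"
  )
}

#' Generate a deterministic labeled fixture set
#'
#' Samples molecules from the curated pool (without replacement) under a
#' seed and attaches a label computed deterministically from structure:
#' `aromatic-label` (1 if any aromatic atom), `heavy-atom-count`, or
#' `ring-count` (cyclomatic number: bonds - atoms + components).
#'
#' @param recipe one of `"aromatic-label"`, `"heavy-atom-count"`,
#'   `"ring-count"`.
#' @param n number of molecules; at most the pool size.
#' @param seed integer sampling seed.
#' @return data frame of class `kgg_fixture_set` with columns `smiles`,
#'   `label`; attributes `recipe` and `seed`.
#' @export
generate_fixtures <- function(recipe = c("aromatic-label",
                                         "heavy-atom-count", "ring-count"),
                              n = 100L, seed = 1L) {
  recipe <- match.arg(recipe)
  pool <- fixture_pool()
  if (n < 1L || n > length(pool)) {
    stop(sprintf("n must be in 1..%d (pool size), got %d",
                 length(pool), n), call. = FALSE)
  }
  set.seed(seed)
  smiles <- sample(pool, n)
  label <- vapply(smiles, function(s) {
    mol <- parse_smiles(s)
    switch(recipe,
           "aromatic-label" = as.numeric(any(mol$atoms$aromatic)),
           "heavy-atom-count" = as.numeric(mol$n_atoms),
           "ring-count" = {
             g <- igraph::make_empty_graph(n = mol$n_atoms, directed = FALSE)
             if (mol$n_bonds > 0) {
               g <- igraph::add_edges(g, rbind(mol$bonds$i, mol$bonds$j))
             }
             mol$n_bonds - mol$n_atoms + igraph::components(g)$no
           })
  }, numeric(1), USE.NAMES = FALSE)
  structure(data.frame(smiles = smiles, label = label,
                       stringsAsFactors = FALSE),
            recipe = recipe, seed = seed,
            class = c("kgg_fixture_set", "data.frame"))
}
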