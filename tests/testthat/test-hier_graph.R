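# Hierarchical graph construction and the sentinel feature stack.

test_that("parsing produces the expected heavy-atom graph sizes", {
  bz <- parse_smiles("c1ccccc1")
  expect_equal(bz$n_atoms, 6L)
  expect_equal(bz$n_bonds, 6L)
  me <- parse_smiles("C")
  expect_equal(me$n_atoms, 1L)
  expect_equal(me$n_bonds, 0L)
  expect_true(all(parse_smiles("CCO")$bonds$i < parse_smiles("CCO")$bonds$j))
})

test_that("motif decomposition matches the reference fragmentations", {
  expect_length(motif_decompose(parse_smiles("c1ccccc1")), 1L)
  expect_length(motif_decompose(parse_smiles("CC")), 1L)
  expect_length(motif_decompose(parse_smiles("C")), 1L)
  # ring/substituent rule separates the ethyl group from the ring
  md <- motif_decompose(parse_smiles("CCc1ccccc1"))
  expect_equal(md, list(1:2, 3:8))
  # BRICS cuts around the amide of N-cyclohexylacetamide
  md2 <- motif_decompose(parse_smiles("CC(=O)NC1CCCCC1"))
  expect_equal(length(md2), 3L)
  expect_true(any(vapply(md2, function(m) setequal(m, 1:3), logical(1))))
})

test_that("motif partitions cover every atom exactly once", {
  smiles <- generate_fixtures("ring-count", 100, seed = 77)$smiles
  for (s in smiles) {
    mol <- parse_smiles(s)
    md <- motif_decompose(mol)
    expect_identical(sort(unlist(md)), seq_len(mol$n_atoms), info = s)
  }
})

test_that("motif decomposition is invariant under canonical round-trip", {
  for (s in c("CCc1ccccc1", "CC(=O)Nc1ccc(O)cc1", "C1CCCCC1CCO",
              "Cn1cnc2c1c(=O)n(C)c(=O)n2C", "CC(C)Cc1ccc(cc1)C(C)C(=O)O")) {
    can <- canonicalize_smiles(s)
    sizes1 <- sort(lengths(motif_decompose(parse_smiles(s))))
    sizes2 <- sort(lengths(motif_decompose(parse_smiles(can))))
    expect_identical(sizes1, sizes2, info = s)
  }
})

test_that("hierarchical graphs have the forced node and edge counts", {
  hg <- build_hierarchical_graph(parse_smiles("c1ccccc1"))
  expect_equal(hg$n_atoms, 6L)
  expect_equal(hg$n_motifs, 1L)
  expect_equal(nrow(hg$e_atom), 6L)
  expect_equal(nrow(hg$e_motif), 6L)
  expect_equal(nrow(hg$e_super), 1L)
  hg2 <- build_hierarchical_graph(parse_smiles("C"))
  expect_equal(hg2$super_id, 3L)
  hg3 <- build_hierarchical_graph(parse_smiles("CCc1ccccc1"))
  expect_equal(nrow(hg3$e_super), 2L)
  # every atom has exactly one membership edge
  expect_identical(sort(hg3$e_motif$atom), 1:8)
  # cut bonds stay in the atom-level edge set
  expect_equal(nrow(hg3$e_atom), parse_smiles("CCc1ccccc1")$n_bonds)
})

test_that("an invalid partition is rejected", {
  mol <- parse_smiles("CCO")
  expect_error(build_hierarchical_graph(mol, list(1:2)),
               class = "kggraph_partition_error")
  expect_error(build_hierarchical_graph(mol, list(1:2, 2:3)),
               class = "kggraph_partition_error")
})

test_that("the feature stack has sentinel rows and the printed shape", {
  hg <- build_hierarchical_graph(parse_smiles("c1ccccc1"))
  st <- assemble_feature_stack(hg, d = 7)
  expect_equal(dim(st), c(8L, 7L))
  expect_equal(st[7, ], c(120, 0, 0, 0, 0, 0, 0))
  expect_equal(st[8, ], c(119, 0, 0, 0, 0, 0, 0))
  expect_equal(st[1, ], unname(atom_features(hg$mol, 1)))
  st2 <- assemble_feature_stack(build_hierarchical_graph(parse_smiles("C")), 7)
  expect_equal(dim(st2), c(3L, 7L))
  # zero padding beyond component 7
  st3 <- assemble_feature_stack(hg, d = 10)
  expect_equal(dim(st3), c(8L, 10L))
  expect_true(all(st3[, 8:10] == 0))
  expect_error(assemble_feature_stack(hg, d = 6), "at least 7")
})

test_that("feature-stack row-count identity holds over the toy set", {
  for (s in toy_set()[1:25]) {
    hg <- build_hierarchical_graph(parse_smiles(s))
    st <- assemble_feature_stack(hg, 7)
    expect_equal(nrow(st), hg$n_atoms + hg$n_motifs + 1L, info = s)
  }
})

test_that("graphs export to edge-list and feature-stack text files", {
  dir <- withr::local_tempdir()
  hg <- build_hierarchical_graph(parse_smiles("CCc1ccccc1"))
  export_hgraph(hg, dir)
  edges <- read.csv(file.path(dir, "edges.csv"))
  expect_setequal(unique(edges$layer), c("atom", "motif", "super"))
  st <- read.csv(file.path(dir, "feature_stack.csv"))
  expect_equal(nrow(st), hg$n_atoms + hg$n_motifs + 1L)
})
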