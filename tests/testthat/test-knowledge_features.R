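# Orbital/VSEPR knowledge vectors and bond decompositions.

test_that("orbital composition of each hybridization state is correct", {
  expect_equal(unname(phi_hybrid("s")), c(1, 0, 0))
  expect_equal(unname(phi_hybrid("sp")), c(1, 1, 0))
  expect_equal(unname(phi_hybrid("sp2")), c(1, 2, 0))
  expect_equal(unname(phi_hybrid("sp3")), c(1, 3, 0))
  expect_equal(unname(phi_hybrid("sp3d")), c(1, 3, 1))
  expect_equal(unname(phi_hybrid("sp3d2")), c(1, 3, 2))
  expect_equal(unname(phi_hybrid("UNSPECIFIED")), c(0, 0, 0))
  expect_error(phi_hybrid("sp4"), class = "kggraph_hybridization_error")
  expect_error(phi_hybrid(3), class = "kggraph_hybridization_error")
})

test_that("VSEPR descriptors follow lone-pair electron bookkeeping", {
  # oracle: y = (outer-shell electrons - bonds to H/heavy) / 2
  expect_equal(unname(phi_vsepr(parse_smiles("C"), 1)), c(4, 0))
  expect_equal(unname(phi_vsepr(parse_smiles("N"), 1)), c(3, (5 - 3) / 2))
  expect_equal(unname(phi_vsepr(parse_smiles("O"), 1)), c(2, (6 - 2) / 2))
  # charged species: ammonium has no lone pair, oxide anion three
  expect_equal(unname(phi_vsepr(parse_smiles("[NH4+]"), 1)), c(4, 0))
  expect_equal(unname(phi_vsepr(parse_smiles("C[O-]"), 2)), c(1, 3))
})

test_that("composite knowledge vectors match the worked examples", {
  expect_equal(unname(phi_comp(parse_smiles("C"), 1)), c(1, 3, 0, 4, 0))
  expect_equal(unname(phi_comp(parse_smiles("N"), 1)), c(1, 3, 0, 3, 1))
  expect_equal(unname(phi_comp(parse_smiles("C=O"), 1)), c(1, 2, 0, 3, 0))
  # hypervalent states
  expect_equal(unname(phi_comp(parse_smiles("FP(F)(F)(F)F"), 2)),
               c(1, 3, 1, 5, 0))
  expect_equal(unname(phi_comp(parse_smiles("FS(F)(F)(F)(F)F"), 2)),
               c(1, 3, 2, 6, 0))
})

test_that("bond knowledge vectors decompose orders into sigma/pi", {
  expect_equal(unname(bond_knowledge(parse_smiles("CC"), 1)), c(1, 0, 0))
  expect_equal(unname(bond_knowledge(parse_smiles("C#C"), 1)), c(1, 2, 0))
  expect_equal(unname(bond_knowledge(parse_smiles("C=C"), 1)), c(1, 1, 0))
  bz <- parse_smiles("c1ccccc1")
  for (b in seq_len(bz$n_bonds)) {
    expect_equal(unname(bond_knowledge(bz, b)), c(1, 0.5, 1))
  }
  # selecting a bond by its endpoints; an isolated carbonyl is unconjugated
  expect_equal(unname(bond_knowledge(parse_smiles("CC=O"), c(2, 3))),
               c(1, 1, 0))
})

test_that("conjugation perception matches the reference flags", {
  expect_false(parse_smiles("C=C")$bonds$conjugated[1])       # isolated pi
  expect_true(all(parse_smiles("C=CC=C")$bonds$conjugated))   # butadiene
  am <- parse_smiles("CC(=O)N")$bonds                          # amide
  expect_true(all(am$conjugated[am$order == 2 | am$j == 4]))
  expect_false(any(parse_smiles("CC(C)=O")$bonds$conjugated)) # acetone
  expect_false(any(parse_smiles("CCOC")$bonds$conjugated))    # ether
})

test_that("atom and bond feature vectors have the documented layout", {
  expect_equal(unname(atom_features(parse_smiles("CC"), 1)),
               c(6, 1, 1, 3, 0, 4, 0))
  expect_equal(unname(atom_features(parse_smiles("c1ccccc1"), 1)),
               c(6, 2, 1, 2, 0, 3, 0))
  expect_equal(unname(bond_features(parse_smiles("C1CCCCC1"), 1)),
               c(0, 1, 1, 0, 0))
  # aromatic bond carries its own type code and ring flag
  expect_equal(unname(bond_features(parse_smiles("c1ccccc1"), 1)),
               c(3, 1, 1, 0.5, 1))
})

test_that("steric-number conservation holds across the toy set", {
  specified <- c("sp", "sp2", "sp3", "sp3d", "sp3d2")
  for (s in toy_set()) {
    mol <- parse_smiles(s)
    a <- mol$atoms
    sel <- a$hybridization %in% specified & a$charge == 0
    expect_true(all((a$n_s + a$n_p + a$n_d)[sel] == (a$x + a$y)[sel]),
                info = s)
  }
})

test_that("structural invariants hold for every atom and bond of the toy set", {
  for (s in toy_set()) {
    mol <- parse_smiles(s)
    expect_true(all(mol$bonds$sigma == 1), info = s)
    expect_true(all(mol$bonds$pi %in% c(0, 0.5, 1, 2)), info = s)
    expect_identical(mol$bonds$delta, as.numeric(mol$bonds$conjugated),
                     info = s)
    for (i in seq_len(mol$n_atoms)) {
      expect_length(atom_features(mol, i), 7L)
    }
    for (b in seq_len(mol$n_bonds)) {
      expect_length(bond_features(mol, b), 5L)
    }
  }
})

test_that("feature tables export one labeled row per atom and bond", {
  mol <- parse_smiles("CC(=O)O")
  at <- atom_feature_table(mol)
  bt <- bond_feature_table(mol)
  expect_equal(nrow(at), 4L)
  expect_equal(nrow(bt), 3L)
  expect_named(at, c("atom", "atomic_number", "degree", "n_s", "n_p",
                     "n_d", "x", "y"))
  expect_named(bt, c("i", "j", "type_code", "ring_flag", "sigma", "pi",
                     "delta"))
})

test_that("unparseable SMILES raise classed errors carrying the input", {
  err <- tryCatch(parse_smiles("not_a_smiles"), error = identity)
  expect_s3_class(err, "kggraph_parse_error")
  expect_equal(err$smiles, "not_a_smiles")
  expect_error(parse_smiles(""), class = "kggraph_parse_error")
})
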