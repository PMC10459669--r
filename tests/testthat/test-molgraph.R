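# Graph featurization: adjacency, 74-dim atom rows, 12-dim bond rows,
# 3M-column coordinate features.

test_that("adjacency reflects bond topology", {
  eth <- prep_smiles("CCO")$ensemble[[1]]
  a <- build_adjacency(eth)
  expect_equal(dim(a), c(3, 3))
  expect_true(all(a == t(a)))
  expect_true(all(diag(a) == 0))
  expect_equal(sum(a), 4)  # two undirected bonds
  expect_equal(a[1, 2] + a[2, 3], 2)

  benz <- prep_smiles("c1ccccc1")$ensemble[[1]]
  ab <- build_adjacency(benz)
  expect_true(all(rowSums(ab) == 2))  # every ring atom has two neighbors

  methane <- prep_smiles("C")$ensemble[[1]]
  expect_equal(build_adjacency(methane), matrix(0L, 1, 1))
})

test_that("atom features are 74-dimensional with the documented blocks", {
  benz <- prep_smiles("c1ccccc1")$ensemble[[1]]
  hv <- atom_feature_matrix(benz$perception$atoms)
  expect_equal(ncol(hv), 74L)
  # blocks: element 1-43, degree 44-54, implicitH 55-61, charge 62,
  # radicals 63, hybridization 64-68, aromatic 69, totalH 70-74
  carbon_slot <- match("C", equivs:::ELEMENT_VOCAB)
  expect_true(all(hv[, carbon_slot] == 1))
  expect_true(all(hv[, 69] == 1))            # aromatic flag
  expect_true(all(hv[, 63 + 2] == 1))        # SP2 slot
  expect_true(all(hv[, 44 + 2] == 1))        # degree 2

  methane <- prep_smiles("C")$ensemble[[1]]
  hm <- atom_feature_matrix(methane$perception$atoms)
  expect_equal(ncol(hm), 74L)
  expect_equal(hm[1, 44], 1)                 # degree 0 slot
  expect_equal(hm[1, 70 + 4], 1)             # total-H = 4 slot
})

test_that("out-of-vocabulary elements give a zero element block", {
  atoms <- prep_smiles("C")$ensemble[[1]]$perception$atoms
  atoms$symbol <- "Xx"
  expect_warning(hv <- atom_feature_matrix(atoms), "vocabulary")
  expect_true(all(hv[1, 1:43] == 0))
  expect_equal(ncol(hv), 74L)
})

test_that("bond features are 12-dimensional with the documented blocks", {
  benz <- prep_smiles("c1ccccc1")$ensemble[[1]]
  he <- bond_feature_matrix(benz$perception$bonds)
  expect_equal(ncol(he), 12L)
  expect_true(all(he[, 4] == 1))  # aromatic type
  expect_true(all(he[, 5] == 1))  # conjugated
  expect_true(all(he[, 6] == 1))  # in ring

  eth <- prep_smiles("CC")$ensemble[[1]]
  hb <- bond_feature_matrix(eth$perception$bonds)
  expect_equal(dim(hb), c(1, 12))
  expect_equal(hb[1, 1], 1)   # single bond
  expect_equal(hb[1, 6], 0)   # not in ring
  expect_equal(hb[1, 7], 1)   # stereo: none slot
})

test_that("assembled graphs have consistent 74/12/3M dimensions", {
  graphs <- tiny_graphs()$graph
  for (g in graphs) {
    expect_equal(ncol(g$node_features), 74L)
    expect_equal(ncol(g$edge_features), 12L)
    expect_equal(ncol(g$HC), 3L * g$M)
    expect_equal(nrow(g$edge_index), nrow(g$edge_features))
  }
  # M = 1 gives a 3-column coordinate matrix
  one <- prep_smiles("CCO", n_conformers = 1)
  g1 <- assemble_graph(one$ensemble[[1]])
  expect_equal(ncol(g1$HC), 3L)
})

test_that("HC column slices recover each conformer and re-concatenate", {
  g <- tiny_graphs()$graph[[1]]
  slices <- lapply(seq_len(g$M), function(m) conformer_coords(g, m))
  for (m in seq_len(g$M)) {
    expect_equal(slices[[m]], g$coords[[m]])
  }
  expect_equal(do.call(cbind, slices), g$HC)
})

test_that("atom permutation permutes feature rows and conjugates adjacency", {
  ens <- prep_smiles("CCOC(=O)C")$ensemble[[1]]
  n <- ens$perception$n_heavy
  set.seed(31)
  perm <- sample(n)
  g0 <- assemble_graph(ens)
  g1 <- assemble_graph(permute_ensemble(ens, perm))
  inv <- order(perm)
  expect_equal(g1$node_features, g0$node_features[inv, ])
  expect_equal(g1$A, g0$A[inv, inv])
  expect_equal(g1$HC, g0$HC[inv, ])
})

test_that("graph assembly rejects topology/coordinate mismatches", {
  ens <- prep_smiles("CCO")$ensemble[[1]]
  ens$coords[[2]] <- ens$coords[[2]][-1, , drop = FALSE]
  expect_error(assemble_graph(ens), class = "equivs_consistency_error")
  ens2 <- prep_smiles("CCO", strip = FALSE)$ensemble[[1]]
  expect_error(assemble_graph(ens2), "stripped")
})
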