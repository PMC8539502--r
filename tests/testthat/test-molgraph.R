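test_that("SMILES parsing perceives atoms, bonds and rings", {
  eth <- parse_molecule("CC")
  expect_equal(n_atoms(eth), 2L)
  expect_equal(n_bonds(eth), 1L)
  expect_false(any(eth$atoms$in_ring))
  expect_equal(eth$atoms$h_count, c(3L, 3L))

  benz <- parse_molecule("c1ccccc1")
  expect_equal(n_atoms(benz), 6L)
  expect_true(all(benz$atoms$aromatic))
  expect_equal(benz$atoms$ring_size, rep(6L, 6))
  expect_true(all(benz$bonds$order == "ar"))

  meth <- parse_molecule("C")
  expect_equal(n_atoms(meth), 1L)
  expect_equal(n_bonds(meth), 0L)
  expect_equal(meth$atoms$h_count, 4L)
})

test_that("malformed SMILES raise parse errors naming the input", {
  expect_error(parse_molecule("C("), "C\\(")
  expect_error(parse_molecule("C1CC"), "ring")
  expect_error(parse_molecule(""), "empty")
  expect_warning(
    out <- parse_molecules(c("CC", "C(", "CCO"), on_error = "drop"),
    "C\\(")
  expect_length(out, 2L)
})

test_that("formal charges are perceived and neutralization fixes protonation states", {
  acet <- parse_molecule("CC(=O)[O-]")
  expect_equal(acet$atoms$charge, c(0L, 0L, 0L, -1L))
  neut <- parse_molecule("CC(=O)[O-]", neutralize = TRUE)
  expect_equal(neut$atoms$charge, rep(0L, 4))
  expect_equal(neut$atoms$h_count[4], 1L)
  expect_equal(neut$neutralized, 1L)
  # quaternary ammonium has no removable proton and keeps its charge
  quat <- parse_molecule("C[N+](C)(C)C", neutralize = TRUE)
  expect_equal(sum(quat$atoms$charge), 1L)
})

test_that("aromaticity perception matches Hueckel expectations", {
  arom <- c("c1ccccc1", "c1cc[nH]c1", "c1ccoc1", "c1ccsc1", "c1ccncc1")
  nonarom <- c("C1CC1", "C1CCCCC1", "C1=CC=CC1", "O=C1C=CC(=O)C=C1")
  for (s in arom) {
    expect_true(all(parse_molecule(s)$atoms$aromatic), label = s)
  }
  for (s in nonarom) {
    expect_false(any(parse_molecule(s)$atoms$aromatic), label = s)
  }
})

test_that("fused rings use the smallest ring per atom", {
  naph <- parse_molecule("c1ccc2ccccc2c1")
  expect_equal(naph$atoms$ring_size, rep(6L, 10))
  indole <- parse_molecule("c1ccc2[nH]ccc2c1")
  expect_setequal(unique(indole$atoms$ring_size), c(5L, 6L))
})

test_that("ring_size_float maps 1/size with 0 for acyclic atoms", {
  expect_equal(ring_size_float(6), 1 / 6, tolerance = 1e-12)
  expect_equal(ring_size_float(3), 1 / 3)
  expect_identical(ring_size_float(0), 0)
  expect_error(ring_size_float(2), "not chemically meaningful")
  sizes <- c(0, 3:20)
  vals <- ring_size_float(sizes)
  expect_true(all(vals == 0 | (vals > 0 & vals <= 1 / 3)))
})

test_that("ring_size_onehot covers the ten instances and clamps overflow", {
  expect_equal(which(ring_size_onehot(5)[1, ] == 1), 4L)  # (0,3,4,5,...)
  expect_equal(which(ring_size_onehot(0)[1, ] == 1), 1L)
  expect_equal(which(ring_size_onehot(14)[1, ] == 1), 10L)
  m <- ring_size_onehot(c(0, 3:15))
  expect_true(all(rowSums(m) == 1))
  expect_equal(ncol(m), 10L)
})

test_that("strategy schemas obey the sharing rules", {
  s3 <- feat_strategy(3); s4 <- feat_strategy(4); s5 <- feat_strategy(5)
  s6 <- feat_strategy(6); s7 <- feat_strategy(7); s8 <- feat_strategy(8)
  expect_identical(s5$node_schema, s6$node_schema)   # 6 shares nodes of 5
  expect_identical(s5$edge_schema, s7$edge_schema)   # 7 shares edges of 5
  expect_identical(s3$node_schema, s7$node_schema)   # 7 shares nodes of 3
  expect_identical(s3$edge_schema, s6$edge_schema)   # 6 shares edges of 3
  # 3 and 4 differ only in the ring-size encoding
  expect_identical(setdiff(s3$node_schema, s4$node_schema), "ring_size_float")
  expect_identical(setdiff(s4$node_schema, s3$node_schema), "ring_size_onehot")
  expect_length(s8$node_schema, 5L)
  expect_length(s8$edge_schema, 3L)
  expect_error(feat_strategy(2), "3..8")
})

test_that("node and edge featurization are deterministic with fixed lengths", {
  mol <- parse_molecule("c1ccccc1CC(=O)[O-]")
  for (id in 3:8) {
    st <- feat_strategy(id)
    Xn <- featurize_node(mol, st)
    Xe <- featurize_edge(mol, st)
    expect_equal(dim(Xn), c(n_atoms(mol), st$d))
    expect_equal(dim(Xe), c(n_bonds(mol), st$b))
    expect_identical(Xn, featurize_node(mol, st))
  }
  # strategies 5 and 6 give identical node vectors, 5 and 7 identical edges
  expect_identical(featurize_node(mol, feat_strategy(5)),
                   featurize_node(mol, feat_strategy(6)))
  expect_identical(featurize_edge(mol, feat_strategy(5)),
                   featurize_edge(mol, feat_strategy(7)))
})

test_that("unknown elements error unless the permissive flag is set", {
  sil <- parse_molecule("C[SiH3]")
  expect_error(featurize_node(sil, feat_strategy(5)), "Si")
  expect_warning(Xn <- featurize_node(sil, feat_strategy(5), permissive = TRUE),
                 "Si")
  expect_equal(Xn[2, 11], 1)  # the "other" slot
})

test_that("build_graph creates two directed edges per bond with symmetric adjacency", {
  eth <- build_graph(parse_molecule("CC"), feat_strategy(5))
  expect_equal(eth$n, 2L)
  expect_equal(cbind(eth$src, eth$dst), cbind(c(1L, 2L), c(2L, 1L)))

  benz <- build_graph(parse_molecule("c1ccccc1"), feat_strategy(3))
  expect_equal(length(benz$src), 12L)
  expect_identical(benz$A, t(benz$A))
  expect_true(all(rowSums(benz$A) == 2))

  meth <- build_graph(parse_molecule("C"), feat_strategy(3))
  expect_equal(meth$n, 1L)
  expect_length(meth$src, 0L)
  expect_true(all(meth$A == 0))
})

test_that("directed edge pairs share features and adjacency matches the edge set", {
  set.seed(7)
  smis <- c("CCO", "c1ccncc1", "CC(C)(C)C", "C1CCOC1", "O=C=O")
  for (s in smis) {
    for (id in c(3, 5, 8)) {
      g <- build_graph(parse_molecule(s), feat_strategy(id))
      expect_equal(length(g$src), 2L * n_bonds(parse_molecule(s)))
      expect_identical(g$A, t(g$A))
      expect_identical(g$Xe, g$Xe[g$rev, , drop = FALSE])  # e_uv == e_vu
      expect_identical(which(g$A == 1),
                       which(t(sapply(seq_len(g$n), function(u)
                         seq_len(g$n) %in% g$dst[g$src == u])) == 1))
    }
  }
})

test_that("featurization is permutation covariant", {
  mol <- parse_molecule("CC(=O)c1ccccc1O")
  st <- feat_strategy(3)
  g <- build_graph(mol, st)
  set.seed(1)
  for (i in 1:5) {
    perm <- sample(g$n)
    pg <- permute_graph(g, perm)
    expect_equal(pg$Xn[perm, , drop = FALSE], g$Xn)
  }
})

test_that("graph bundles round-trip through disk", {
  graphs <- lapply(parse_molecules(c("CCO", "c1ccccc1")), build_graph,
                   strategy = feat_strategy(4))
  path <- tempfile(fileext = ".rds")
  write_graph_bundle(graphs, path)
  back <- read_graph_bundle(path)
  expect_identical(back, graphs)
  unlink(path)
})
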