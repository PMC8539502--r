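# Forward-pass semantics of the three architectures, checked against
# hand computations and the naive loop oracle.

test_that("edge initialization collapses to feature concatenation under identity weights", {
  g <- build_graph(parse_molecule("CC"), feat_strategy(5))
  p <- identity_params("dmpnn", d = g$d, b = g$b, cc = g$d + g$b, T = 1L)
  batch <- batch_graphs(list(g))
  fw <- gnn_forward(p, batch, keep_cache = TRUE)
  expect_equal(fw$cache$H0[1, ], c(g$Xn[1, ], g$Xe[1, ]))
  expect_equal(fw$cache$H0[2, ], c(g$Xn[2, ], g$Xe[2, ]))
})

test_that("zero features with ReLU give all-zero initial hidden states", {
  g <- dgin:::.molgraph(3L, c(1L, 2L), c(2L, 3L),
                        matrix(0, 3, 4), matrix(0, 2, 2))
  p <- gnn_params("dmpnn", d = 4, b = 2, hidden = 6, T = 2, tau = "relu",
                  seed = 5)
  fw <- gnn_forward(p, batch_graphs(list(g)), keep_cache = TRUE)
  expect_true(all(fw$cache$H0 == 0))
})

test_that("a two-node graph has exactly zero messages at every iteration", {
  g <- build_graph(parse_molecule("CC"), feat_strategy(5))
  p <- gnn_params("dmpnn", d = g$d, b = g$b, hidden = 8, T = 4, seed = 2)
  fw <- gnn_forward(p, batch_graphs(list(g)), keep_cache = TRUE)
  for (t in seq_len(p$T)) {
    expect_identical(max(abs(fw$cache$Ms[[t]])), 0)  # N(u)\w is empty
    # hence h^t = tau(h^0) at every t
    expect_equal(fw$cache$Hs[[t]],
                 dgin:::.tau_fns$relu$f(fw$cache$H0))
  }
})

test_that("the exclusion rule routes messages correctly on a path a-b-c", {
  # propane: edges 1:(1->2) 2:(2->1) 3:(2->3) 4:(3->2)
  g <- build_graph(parse_molecule("CCC"), feat_strategy(5))
  p <- identity_params("dmpnn", d = g$d, b = g$b, cc = g$d + g$b, T = 1L)
  fw <- gnn_forward(p, batch_graphs(list(g)), keep_cache = TRUE)
  h0 <- fw$cache$H0
  m1 <- fw$cache$Ms[[1]]
  edge <- function(u, v) which(g$src == u & g$dst == v)
  expect_equal(m1[edge(2, 3), ], h0[edge(1, 2), ])  # m_bc = h_ab
  expect_equal(m1[edge(2, 1), ], h0[edge(3, 2), ])  # m_ba = h_cb
  expect_equal(m1[edge(1, 2), ], h0[edge(1, 2), ] * 0)
})

test_that("node aggregation sums incoming final edge states", {
  set.seed(3)
  g <- random_molgraph(5, d = 3, b = 2)
  p <- gnn_params("dgin", d = 3, b = 2, hidden = 6, T = 2, T2 = 1, seed = 7)
  batch <- batch_graphs(list(g))
  fw <- gnn_forward(p, batch, keep_cache = TRUE)
  hT <- fw$cache$Hs[[p$T]]
  mn <- fw$cache$N0[, seq_len(p$c), drop = FALSE]
  for (u in seq_len(g$n)) {
    inc <- which(g$dst == u)
    expected <- if (length(inc)) colSums(hT[inc, , drop = FALSE]) else numeric(p$c)
    expect_equal(mn[u, ], expected, tolerance = 1e-12)
  }
  # double-counting identity: sum_u m_u == sum_e h^T_e
  expect_equal(colSums(mn), colSums(hT), tolerance = 1e-12)
})

test_that("an isolated node aggregates the empty sum", {
  g <- build_graph(parse_molecule("C"), feat_strategy(5))
  p <- gnn_params("dgin", d = g$d, b = g$b, hidden = 4, T = 2, T2 = 1, seed = 1)
  fw <- gnn_forward(p, batch_graphs(list(g)), keep_cache = TRUE)
  expect_identical(fw$cache$N0[1, seq_len(4)], numeric(4))
  expect_true(all(is.finite(fw$yhat)))
})

test_that("GIN update handles the epsilon limits in closed form", {
  # two connected nodes with equal state h: (1+0)h + h = 2h under identity MLP
  Xn <- matrix(c(1, 2, 1, 2), 2, 2, byrow = TRUE)
  g <- dgin:::.molgraph(2L, 1L, 2L, Xn, matrix(1, 1, 1))
  p <- identity_params("gin", d = 2, b = 1, cc = 2, T2 = 1L)
  fw <- gnn_forward(p, batch_graphs(list(g)), keep_cache = TRUE)
  expect_equal(fw$cache$Nfin, 2 * Xn)
  # epsilon = -1 cancels the self term: each node becomes its neighbour sum
  p$theta$gin1_eps <- -1
  fw <- gnn_forward(p, batch_graphs(list(g)), keep_cache = TRUE)
  expect_equal(fw$cache$Nfin, Xn[c(2, 1), ])
  # isolated node with eps = 0 and identity MLP is a fixed point
  gi <- dgin:::.molgraph(1L, integer(0), integer(0), matrix(c(3, -1), 1, 2),
                         matrix(0, 0, 1))
  p$theta$gin1_eps <- 0
  fw <- gnn_forward(p, batch_graphs(list(gi)), keep_cache = TRUE)
  expect_equal(fw$cache$Nfin, matrix(c(3, -1), 1, 2))
})

test_that("readout sum-pools nodes and a zero-weight head returns its bias", {
  g1 <- build_graph(parse_molecule("C"), feat_strategy(5))
  p <- gnn_params("dgin", d = g1$d, b = g1$b, hidden = 5, seed = 4)
  fw <- gnn_forward(p, batch_graphs(list(g1)), keep_cache = TRUE)
  expect_equal(fw$cache$HG[1, ], fw$cache$Nfin[1, ])  # singleton sum
  p$theta$ro_Wout <- p$theta$ro_Wout * 0
  p$theta$ro_bout <- 1.25
  expect_equal(gnn_predict(p, list(g1))[1, 1], 1.25)
})

test_that("vectorized forward equals the naive loop oracle on random small graphs", {
  set.seed(99)
  for (arch in c("dgin", "dmpnn", "gin")) {
    for (rep in 1:8) {
      g <- random_molgraph(sample(1:8, 1), d = 4, b = 3)
      p <- gnn_params(arch, d = 4, b = 3, hidden = 6,
                      T = sample(1:3, 1), T2 = sample(1:3, 1),
                      n_out = sample(1:3, 1), seed = rep)
      expect_equal(as.numeric(gnn_predict(p, list(g))),
                   naive_forward(p, g), tolerance = 1e-6,
                   label = sprintf("%s rep %d", arch, rep))
    }
  }
})

test_that("batched prediction equals per-graph prediction", {
  set.seed(5)
  graphs <- lapply(parse_molecules(c("CCO", "c1ccccc1", "C", "CC(C)=O")),
                   build_graph, strategy = feat_strategy(3))
  st <- feat_strategy(3)
  p <- gnn_params("dgin", d = st$d, b = st$b, hidden = 10, seed = 6)
  together <- gnn_predict(p, graphs)
  alone <- do.call(rbind, lapply(graphs, function(g) gnn_predict(p, list(g))))
  expect_equal(together, alone, tolerance = 1e-10)
})

test_that("predictions are invariant under atom relabelling", {
  set.seed(11)
  mols <- parse_molecules(c("CC(=O)c1ccccc1O", "C1CCOC1CN", "CC(C)CC(=O)O"))
  st <- feat_strategy(3)
  for (arch in c("dgin", "dmpnn", "gin")) {
    p <- gnn_params(arch, d = st$d, b = st$b, hidden = 8, seed = 13)
    for (mol in mols) {
      g <- build_graph(mol, st)
      base <- gnn_predict(p, list(g))
      for (i in 1:5) {
        pg <- permute_graph(g, sample(g$n))
        expect_equal(gnn_predict(p, list(pg)), base, tolerance = 1e-5)
      }
    }
  }
})

test_that("deterministic forward: identical inputs give identical outputs", {
  g <- build_graph(parse_molecule("CCOC"), feat_strategy(4))
  p <- gnn_params("dgin", d = g$d, b = g$b, hidden = 8, seed = 21)
  expect_identical(gnn_predict(p, list(g)), gnn_predict(p, list(g)))
})

test_that("output count follows the training strategy's property count", {
  g <- build_graph(parse_molecule("CCO"), feat_strategy(5))
  for (k in 1:3) {
    p <- gnn_params("dgin", d = g$d, b = g$b, hidden = 4, n_out = k, seed = 1)
    expect_equal(ncol(gnn_predict(p, list(g))), k)
  }
})

test_that("dimension mismatches raise configuration errors", {
  g <- build_graph(parse_molecule("CCO"), feat_strategy(5))
  p <- gnn_params("dgin", d = 99, b = g$b, hidden = 4, seed = 1)
  expect_error(gnn_predict(p, list(g)), "does not match")
})

test_that("checkpoints round-trip bit-exactly", {
  p <- gnn_params("dgin", d = 16, b = 4, hidden = 8, seed = 3)
  path <- tempfile(fileext = ".rds")
  save_checkpoint(p, path, properties = c("logd", "logp"))
  back <- load_checkpoint(path)
  expect_identical(back$params, p)
  expect_identical(back$properties, c("logd", "logp"))
  unlink(path)
})
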