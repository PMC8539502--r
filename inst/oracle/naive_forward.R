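# Naive reference implementations and small-graph generators used as
# independent oracles: every loop below follows the update equations
# edge-by-edge and node-by-node, with none of the batched sparse algebra of
# the package implementation.

tau_ref <- function(name) {
  switch(name,
    relu = function(x) pmax(x, 0),
    sigmoid = function(x) 1 / (1 + exp(-x)),
    identity = function(x) x)
}

# Loop-based forward pass for a single molgraph.
naive_forward <- function(params, graph) {
  th <- params$theta
  tau <- tau_ref(params$tau)
  n <- graph$n
  E <- length(graph$src)
  cc <- params$c

  node_states <- NULL
  if (params$architecture != "gin") {
    h0 <- vector("list", E)
    for (e in seq_len(E)) {
      z <- c(graph$Xn[graph$src[e], ], graph$Xe[e, ])
      h0[[e]] <- tau(as.numeric(th$W_init %*% z))
    }
    h <- h0
    for (t in seq_len(params$T)) {
      m <- vector("list", E)
      for (e in seq_len(E)) {
        acc <- numeric(cc)
        for (f in seq_len(E)) {
          # incoming edge k -> src(e), excluding the reverse of e
          if (graph$dst[f] == graph$src[e] && f != graph$rev[e]) {
            acc <- acc + h[[f]]
          }
        }
        m[[e]] <- acc
      }
      h_new <- vector("list", E)
      for (e in seq_len(E)) {
        h_new[[e]] <- tau(h0[[e]] + as.numeric(th$W_m %*% m[[e]]))
      }
      h <- h_new
    }
    node_states <- matrix(0, n, cc + graph$d)
    for (u in seq_len(n)) {
      acc <- numeric(cc)
      for (e in seq_len(E)) if (graph$dst[e] == u) acc <- acc + h[[e]]
      node_states[u, ] <- c(acc, graph$Xn[u, ])
    }
    if (params$architecture == "dmpnn") {
      node_states <- t(apply(node_states, 1,
                             function(v) as.numeric(th$W_agg_edge %*% v)))
      if (n == 1L) node_states <- matrix(node_states, nrow = 1)
    }
  } else {
    node_states <- graph$Xn
  }

  if (params$architecture != "dmpnn") {
    for (l in seq_len(params$T2)) {
      eps <- th[[sprintf("gin%d_eps", l)]]
      W1 <- th[[sprintf("gin%d_W1", l)]]; b1 <- th[[sprintf("gin%d_b1", l)]]
      W2 <- th[[sprintf("gin%d_W2", l)]]; b2 <- th[[sprintf("gin%d_b2", l)]]
      new_states <- matrix(0, n, params$c)
      for (u in seq_len(n)) {
        nb <- graph$dst[graph$src == u]
        s <- (1 + eps) * node_states[u, ]
        for (w in nb) s <- s + node_states[w, ]
        hid <- tau(as.numeric(W1 %*% s) + b1)
        new_states[u, ] <- tau(as.numeric(W2 %*% hid) + b2)
      }
      node_states <- new_states
    }
  }

  hg <- colSums(node_states)
  r1 <- tau(as.numeric(th$ro_W1 %*% hg) + th$ro_b1)
  r2 <- tau(as.numeric(th$ro_W2 %*% r1) + th$ro_b2)
  as.numeric(th$ro_Wout %*% r2) + th$ro_bout
}

# Random connected small graph (tree plus optional extra edges) with random
# continuous features; used for oracle-equivalence sweeps.
random_small_graph <- function(n_nodes, d = 4, b = 3, extra_edge_prob = 0.5) {
  bonds <- NULL
  if (n_nodes >= 2) {
    parent <- vapply(2:n_nodes, function(v) sample.int(v - 1L, 1L), integer(1))
    bonds <- cbind(parent, 2:n_nodes)
    if (n_nodes >= 4 && stats::runif(1) < extra_edge_prob) {
      non_adj <- which(outer(seq_len(n_nodes), seq_len(n_nodes), `<`), arr.ind = TRUE)
      keys <- paste(bonds[, 1], bonds[, 2])
      cand <- non_adj[!(paste(pmin(non_adj[, 1], non_adj[, 2]),
                              pmax(non_adj[, 1], non_adj[, 2])) %in% keys), ,
                      drop = FALSE]
      if (nrow(cand)) {
        pick <- cand[sample.int(nrow(cand), 1L), ]
        bonds <- rbind(bonds, pick)
      }
    }
  }
  nb <- if (is.null(bonds)) 0L else nrow(bonds)
  g <- dgin:::.molgraph(n_nodes,
                        if (nb) bonds[, 1] else integer(0),
                        if (nb) bonds[, 2] else integer(0),
                        matrix(stats::rnorm(n_nodes * d), n_nodes, d),
                        matrix(stats::rnorm(max(nb, 0) * b), nb, b))
  g
}

# Apply a node permutation to a molgraph (renumber atoms).
permute_small_graph <- function(graph, perm) {
  inv <- order(perm)  # node i becomes perm[i]
  nb <- length(graph$src) / 2
  a1 <- perm[graph$src[seq_len(nb) * 2 - 1]]
  a2 <- perm[graph$dst[seq_len(nb) * 2 - 1]]
  Xe_bond <- graph$Xe[seq_len(nb) * 2 - 1, , drop = FALSE]
  dgin:::.molgraph(graph$n, a1, a2, graph$Xn[inv, , drop = FALSE], Xe_bond,
                   graph$strategy_id)
}
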