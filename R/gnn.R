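# D-GIN, D-MPNN and GIN forward passes.
#
# All three architectures share one parameter container and one vectorized
# forward implementation operating on batched graphs:
#   edge phase (D-GIN, D-MPNN):
#     h0_uv = tau(W_init cat(x_u, x_e_uv))
#     for t in 1..T: m_uv = sum_{k in N(u)\v} h_ku ; h_uv = tau(h0_uv + W_m m_uv)
#     m_u = sum over incoming edges of h^T ; node state = cat(m_u, x_u)
#     (D-MPNN additionally maps it through W_agg to width c)
#   GIN phase (D-GIN, GIN):
#     h'_u = MLP_l((1 + eps_l) h_u + sum_{w in N(u)} h_w),  l = 1..T2
#   readout: h_G = sum_u h_u ; yhat = f(h_G), one output per trained property.
# Messages exclude the reverse edge, so information never immediately
# backtracks along the bond it arrived through.

.tau_fns <- list(
  relu = list(f = function(x) pmax(x, 0), grad = function(pre, post) (pre > 0) * 1),
  sigmoid = list(f = function(x) 1 / (1 + exp(-x)),
                 grad = function(pre, post) post * (1 - post)),
  identity = list(f = function(x) x, grad = function(pre, post) 1)
)

.he_init <- function(nrow, ncol) {
  matrix(stats::rnorm(nrow * ncol, sd = sqrt(2 / ncol)), nrow, ncol)
}

#' Initialize GNN parameters
#'
#' @param architecture `"dgin"`, `"dmpnn"` or `"gin"`.
#' @param d node feature length of the featurization strategy in use.
#' @param b edge feature length.
#' @param hidden hidden width `c` shared by edge states, node states and the
#'   readout layers.
#' @param T directed-edge message passing iterations (edge phase).
#' @param T2 GIN iterations (node phase).
#' @param tau nonlinearity: `"relu"` (default), `"sigmoid"` or `"identity"`.
#' @param n_out number of regression outputs (one per trained property).
#' @param seed integer seed for the weight initialization.
#' @return a `gnn_params` object; trainable arrays live in `$theta`, with one
#'   learnable epsilon scalar per GIN layer (initialized at 0).
#' @export
gnn_params <- function(architecture = c("dgin", "dmpnn", "gin"),
                       d, b, hidden = 128L, T = 3L, T2 = 2L,
                       tau = c("relu", "sigmoid", "identity"),
                       n_out = 1L, seed = 1L) {
  architecture <- match.arg(architecture)
  tau <- match.arg(tau)
  stopifnot(d >= 1L, hidden >= 1L, n_out >= 1L)
  if (architecture != "gin") stopifnot(T >= 1L, b >= 0L)
  if (architecture != "dmpnn") stopifnot(T2 >= 1L)
  c <- as.integer(hidden)
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)
  theta <- list()
  if (architecture != "gin") {
    theta$W_init <- .he_init(c, d + b)
    theta$W_m <- .he_init(c, c)
  }
  if (architecture == "dmpnn") {
    theta$W_agg_edge <- .he_init(c, c + d)
  }
  if (architecture != "dmpnn") {
    gin_in <- if (architecture == "dgin") c + d else d
    for (l in seq_len(T2)) {
      inw <- if (l == 1L) gin_in else c
      theta[[sprintf("gin%d_W1", l)]] <- .he_init(c, inw)
      theta[[sprintf("gin%d_b1", l)]] <- numeric(c)
      theta[[sprintf("gin%d_W2", l)]] <- .he_init(c, c)
      theta[[sprintf("gin%d_b2", l)]] <- numeric(c)
      theta[[sprintf("gin%d_eps", l)]] <- 0
    }
  }
  theta$ro_W1 <- .he_init(c, c)
  theta$ro_b1 <- numeric(c)
  theta$ro_W2 <- .he_init(c, c)
  theta$ro_b2 <- numeric(c)
  theta$ro_Wout <- .he_init(n_out, c)
  theta$ro_bout <- numeric(n_out)
  structure(list(architecture = architecture, d = as.integer(d),
                 b = as.integer(b), c = c, T = as.integer(T),
                 T2 = as.integer(T2), tau = tau, n_out = as.integer(n_out),
                 seed = as.integer(seed), theta = theta),
            class = "gnn_params")
}

#' @export
print.gnn_params <- function(x, ...) {
  np <- sum(vapply(x$theta, length, integer(1)))
  cat(sprintf("<gnn_params> %s: d=%d b=%d c=%d T=%d T2=%d tau=%s outputs=%d (%d parameters)\n",
              toupper(x$architecture), x$d, x$b, x$c, x$T, x$T2, x$tau,
              x$n_out, np))
  invisible(x)
}

#' Batch molecular graphs for vectorized message passing
#'
#' Concatenates graphs into one block-disconnected graph and precomputes the
#' sparse operators used by the forward/backward passes: the
#' reverse-edge-excluding incoming-edge operator (edge phase), the
#' incoming-edge-to-node aggregator, the node adjacency, and the
#' graph-membership pooling matrix.
#'
#' @param graphs list of `molgraph` objects sharing one featurization.
#' @return a `graph_batch`.
#' @export
batch_graphs <- function(graphs) {
  stopifnot(length(graphs) >= 1L,
            all(vapply(graphs, inherits, logical(1), "molgraph")))
  d <- graphs[[1]]$d; b <- graphs[[1]]$b
  ns <- vapply(graphs, function(g) g$n, integer(1))
  es <- vapply(graphs, function(g) length(g$src), integer(1))
  noff <- cumsum(c(0L, utils::head(ns, -1L)))
  eoff <- cumsum(c(0L, utils::head(es, -1L)))
  n <- sum(ns); E <- sum(es); G <- length(graphs)
  src <- unlist(Map(function(g, o) g$src + o, graphs, noff), use.names = FALSE)
  dst <- unlist(Map(function(g, o) g$dst + o, graphs, noff), use.names = FALSE)
  rev <- unlist(Map(function(g, o) g$rev + o, graphs, eoff), use.names = FALSE)
  Xn <- do.call(rbind, lapply(graphs, `[[`, "Xn"))
  Xe <- do.call(rbind, lapply(graphs, `[[`, "Xe"))
  graph_id <- rep(seq_len(G), ns)
  if (E > 0L) {
    # M_ex[e, f] = 1 iff f feeds e: dst(f) == src(e) and f is not rev(e)
    by_dst <- split(seq_len(E), dst)
    ii <- jj <- vector("list", E)
    for (e in seq_len(E)) {
      cand <- by_dst[[as.character(src[e])]]
      cand <- cand[cand != rev[e]]
      if (length(cand)) { ii[[e]] <- rep.int(e, length(cand)); jj[[e]] <- cand }
    }
    ival <- unlist(ii); jval <- unlist(jj)
    if (is.null(ival)) { ival <- integer(0); jval <- integer(0) }
    M_ex <- Matrix::sparseMatrix(i = ival, j = jval, x = rep(1, length(ival)),
                                 dims = c(E, E))
    A_in <- Matrix::sparseMatrix(i = dst, j = seq_len(E), x = 1,
                                 dims = c(n, E))
    Adj <- Matrix::sparseMatrix(i = src, j = dst, x = 1, dims = c(n, n))
  } else {
    M_ex <- Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                                 dims = c(0L, 0L))
    A_in <- Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                                 dims = c(n, 0L))
    Adj <- Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                                dims = c(n, n))
  }
  Pool <- Matrix::sparseMatrix(i = graph_id, j = seq_len(n), x = 1,
                               dims = c(G, n))
  structure(list(n = n, E = E, G = G, d = d, b = b,
                 src = src, dst = dst, rev = rev,
                 Xn = Xn, Xe = Xe,
                 M_ex = M_ex, A_in = A_in, Adj = Adj, Pool = Pool,
                 sizes = ns, graph_id = graph_id),
            class = "graph_batch")
}

.dense <- function(x) as.matrix(x)

#' GNN forward pass
#'
#' Runs the architecture selected in `params` over a batch of graphs.
#' Deterministic: no stochastic layers are involved at inference.
#'
#' @param params a `gnn_params`.
#' @param batch a `graph_batch` (or list of `molgraph`s, batched on the fly).
#' @param keep_cache keep intermediate activations for the backward pass.
#' @return list with `yhat` (`n_graphs x n_out` matrix) and, if requested,
#'   `cache`.
#' @export
gnn_forward <- function(params, batch, keep_cache = FALSE) {
  if (!inherits(batch, "graph_batch")) batch <- batch_graphs(batch)
  th <- params$theta
  tauf <- .tau_fns[[params$tau]]
  cc <- params$c
  cache <- list()
  if (params$architecture != "gin") {
    if (batch$d != params$d || batch$b != params$b) {
      stop(sprintf(
        "featurization (d=%d, b=%d) does not match model dimensions (d=%d, b=%d)",
        batch$d, batch$b, params$d, params$b), call. = FALSE)
    }
    if (batch$E > 0L) {
      Z0 <- cbind(batch$Xn[batch$src, , drop = FALSE], batch$Xe)
      P0 <- Z0 %*% t(th$W_init)
      H <- tauf$f(P0)
      H0 <- H
      Ms <- Ps <- Hs <- vector("list", params$T)
      for (t in seq_len(params$T)) {
        M <- .dense(batch$M_ex %*% H)
        P <- H0 + M %*% t(th$W_m)
        H <- tauf$f(P)
        Ms[[t]] <- M; Ps[[t]] <- P; Hs[[t]] <- H
      }
      Mn <- .dense(batch$A_in %*% H)
      cache[c("Z0", "P0", "H0", "Ms", "Ps", "Hs")] <-
        list(Z0, P0, H0, Ms, Ps, Hs)
    } else {
      Mn <- matrix(0, batch$n, cc)  # bond-free molecules: empty message sums
    }
    N0 <- cbind(Mn, batch$Xn)
    cache$N0 <- N0
    if (params$architecture == "dmpnn") {
      Nfin <- N0 %*% t(th$W_agg_edge)
    } else {
      Nfin <- N0
    }
  } else {
    if (batch$d != params$d) {
      stop(sprintf("featurization (d=%d) does not match model dimension (d=%d)",
                   batch$d, params$d), call. = FALSE)
    }
    Nfin <- batch$Xn
  }
  if (params$architecture != "dmpnn") {
    gin <- vector("list", params$T2)
    for (l in seq_len(params$T2)) {
      eps <- th[[sprintf("gin%d_eps", l)]]
      S <- .dense(batch$Adj %*% Nfin)
      Z <- (1 + eps) * Nfin + S
      pre1 <- sweep(Z %*% t(th[[sprintf("gin%d_W1", l)]]), 2,
                    th[[sprintf("gin%d_b1", l)]], `+`)
      U <- tauf$f(pre1)
      pre2 <- sweep(U %*% t(th[[sprintf("gin%d_W2", l)]]), 2,
                    th[[sprintf("gin%d_b2", l)]], `+`)
      Nout <- tauf$f(pre2)
      gin[[l]] <- list(Nin = Nfin, Z = Z, pre1 = pre1, U = U, pre2 = pre2,
                       Nout = Nout)
      Nfin <- Nout
    }
    cache$gin <- gin
  }
  HG <- .dense(batch$Pool %*% Nfin)
  preR1 <- sweep(HG %*% t(th$ro_W1), 2, th$ro_b1, `+`)
  R1 <- tauf$f(preR1)
  preR2 <- sweep(R1 %*% t(th$ro_W2), 2, th$ro_b2, `+`)
  R2 <- tauf$f(preR2)
  yhat <- sweep(R2 %*% t(th$ro_Wout), 2, th$ro_bout, `+`)
  cache[c("Nfin", "HG", "preR1", "R1", "preR2", "R2")] <-
    list(Nfin, HG, preR1, R1, preR2, R2)
  list(yhat = yhat, cache = if (keep_cache) cache else NULL)
}

#' Predict properties for a list of graphs
#'
#' @param params a `gnn_params`.
#' @param graphs list of `molgraph`s or a `graph_batch`.
#' @return an `n_graphs x n_out` matrix of predictions.
#' @export
gnn_predict <- function(params, graphs) {
  gnn_forward(params, graphs)$yhat
}

#' Graph embedding h_G (sum pooling of final node states)
#'
#' @inheritParams gnn_predict
#' @return an `n_graphs x c` matrix of graph embeddings.
#' @export
gnn_embed <- function(params, graphs) {
  if (!inherits(graphs, "graph_batch")) graphs <- batch_graphs(graphs)
  gnn_forward(params, graphs, keep_cache = TRUE)$cache$HG
}

#' Save / load a model checkpoint
#'
#' The checkpoint container holds all weight arrays (including the learnable
#' epsilons), the architecture tag, dimensions and the property list; the
#' round trip is bit-exact.
#'
#' @param params a `gnn_params`.
#' @param path file path.
#' @param properties optional character vector naming the trained properties.
#' @export
save_checkpoint <- function(params, path, properties = NULL) {
  saveRDS(list(format = "dgin-checkpoint", version = 1L,
               params = params, properties = properties), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @return `load_checkpoint` returns a list with `params` and `properties`.
#' @export
load_checkpoint <- function(path) {
  x <- readRDS(path)
  if (!identical(x$format, "dgin-checkpoint")) {
    stop("not a checkpoint file", call. = FALSE)
  }
  x[c("params", "properties")]
}

# RNG save/restore so seeded package functions do not disturb the caller's
# random stream.
.save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(NULL)
}
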