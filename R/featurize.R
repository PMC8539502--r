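# Declarative atom/bond featurization schemas and molecular graph assembly.
#
# Each featurization strategy (ids 3..8) is an ordered list of named feature
# blocks. Blocks are data, not code: a strategy is fully described by the block
# names, so alternative transcriptions can be swapped in without touching the
# featurizer.

# Fixed element vocabulary; elements outside it map to "other" (permissive mode)
# or raise an error naming the element.
.element_vocab <- c("H", "C", "N", "O", "S", "F", "Cl", "Br", "I", "P", "other")

.ring_onehot_instances <- c(0L, 3L, 4L, 5L, 6L, 7L, 8L, 9L, 10L, 11L)

.onehot <- function(idx, len) {
  m <- matrix(0, length(idx), len)
  m[cbind(seq_along(idx), idx)] <- 1
  m
}

#' Encode a smallest-ring size as a float
#'
#' Ring atoms are encoded as the reciprocal of their smallest ring size
#' (benzene carbon: 1/6); acyclic atoms as 0.
#'
#' @param size integer vector of smallest-ring sizes; 0 means not in a ring.
#' @return numeric vector in `{0} U (0, 1/3]`.
#' @export
ring_size_float <- function(size) {
  stopifnot(is.numeric(size), all(size >= 0))
  if (any(size %in% c(1, 2))) {
    stop("ring sizes 1 and 2 are not chemically meaningful", call. = FALSE)
  }
  ifelse(size == 0, 0, 1 / size)
}

#' Encode a smallest-ring size as a ten-instance one-hot vector
#'
#' Instances are, in order, 0 (acyclic) and ring sizes 3 through 11. Sizes
#' above 11 clamp to the final instance.
#'
#' @param size integer vector of smallest-ring sizes; 0 means not in a ring.
#' @return a matrix with one row per input and ten columns, each row summing
#'   to exactly 1.
#' @export
ring_size_onehot <- function(size) {
  stopifnot(is.numeric(size), all(size >= 0))
  if (any(size %in% c(1, 2))) {
    stop("ring sizes 1 and 2 are not chemically meaningful", call. = FALSE)
  }
  clamped <- pmin(size, 11L)
  idx <- match(clamped, .ring_onehot_instances)
  .onehot(idx, length(.ring_onehot_instances))
}

# Node feature blocks: each returns an n x len matrix for a molecule.
.node_blocks <- list(
  element = list(len = 11L, fn = function(mol, permissive) {
    el <- mol$atoms$element
    idx <- match(el, .element_vocab)
    if (anyNA(idx)) {
      unknown <- unique(el[is.na(idx)])
      if (!permissive) {
        stop(sprintf("element(s) outside the supported vocabulary: %s",
                     paste(unknown, collapse = ", ")), call. = FALSE)
      }
      warning(sprintf("mapping unsupported element(s) to 'other': %s",
                      paste(unknown, collapse = ", ")), call. = FALSE)
      idx[is.na(idx)] <- length(.element_vocab)
    }
    .onehot(idx, length(.element_vocab))
  }),
  formal_charge = list(len = 5L, fn = function(mol, permissive) {
    idx <- pmin(pmax(mol$atoms$charge, -2L), 2L) + 3L
    .onehot(idx, 5L)
  }),
  aromaticity = list(len = 1L, fn = function(mol, permissive) {
    matrix(as.numeric(mol$atoms$aromatic), ncol = 1)
  }),
  ring_size_float = list(len = 1L, fn = function(mol, permissive) {
    matrix(ring_size_float(mol$atoms$ring_size), ncol = 1)
  }),
  ring_size_onehot = list(len = 10L, fn = function(mol, permissive) {
    ring_size_onehot(mol$atoms$ring_size)
  }),
  degree = list(len = 6L, fn = function(mol, permissive) {
    .onehot(pmin(mol$atoms$degree, 5L) + 1L, 6L)
  }),
  h_count = list(len = 5L, fn = function(mol, permissive) {
    .onehot(pmin(mol$atoms$h_count, 4L) + 1L, 5L)
  })
)

# Edge feature blocks: each returns an nbond x len matrix.
.edge_blocks <- list(
  bond_order = list(len = 4L, fn = function(mol) {
    idx <- match(mol$bonds$order, c("1", "2", "3", "ar"))
    .onehot(idx, 4L)
  }),
  aromatic_flag = list(len = 1L, fn = function(mol) {
    matrix(as.numeric(mol$bonds$aromatic), ncol = 1)
  }),
  ring_flag = list(len = 1L, fn = function(mol) {
    matrix(as.numeric(mol$bonds$in_ring), ncol = 1)
  })
)

.full_node_schema <- c("element", "formal_charge", "aromaticity",
                       "ring_size_float", "degree", "h_count")
.minimal_node_schema <- c("element", "formal_charge")
.full_edge_schema <- c("bond_order", "aromatic_flag", "ring_flag")
.minimal_edge_schema <- "bond_order"

# Strategy table. 3 and 4 differ only in the ring-size encoding; 5 is the
# minimal two-node/one-edge-feature schema; 6 = nodes of 5 + edges of 3;
# 7 = nodes of 3 + edges of 5; 8 = the five node and three edge features kept
# after the mask-one-feature ablation, ring size among them.
.strategies <- list(
  `3` = list(node = .full_node_schema, edge = .full_edge_schema),
  `4` = list(node = replace(.full_node_schema,
                            .full_node_schema == "ring_size_float",
                            "ring_size_onehot"),
             edge = .full_edge_schema),
  `5` = list(node = .minimal_node_schema, edge = .minimal_edge_schema),
  `6` = list(node = .minimal_node_schema, edge = .full_edge_schema),
  `7` = list(node = .full_node_schema, edge = .minimal_edge_schema),
  `8` = list(node = c("element", "formal_charge", "ring_size_float",
                      "degree", "h_count"),
             edge = .full_edge_schema)
)

#' Featurization strategy descriptor
#'
#' @param id strategy id, one of 3..8.
#' @return a `feat_strategy`: the ordered node/edge block names, per-block
#'   column spans, and total vector lengths `d` (node) and `b` (edge).
#' @examples
#' feat_strategy(5)$d  # element one-hot + formal-charge one-hot
#' @export
feat_strategy <- function(id) {
  key <- as.character(id)
  if (!key %in% names(.strategies)) {
    stop("featurization strategy id must be one of 3..8", call. = FALSE)
  }
  sch <- .strategies[[key]]
  nlen <- vapply(.node_blocks[sch$node], `[[`, integer(1), "len")
  elen <- vapply(.edge_blocks[sch$edge], `[[`, integer(1), "len")
  structure(list(
    id = as.integer(id),
    node_schema = sch$node,
    edge_schema = sch$edge,
    node_cols = split(seq_len(sum(nlen)), rep(seq_along(nlen), nlen)),
    edge_cols = split(seq_len(sum(elen)), rep(seq_along(elen), elen)),
    d = sum(nlen), b = sum(elen)
  ), class = "feat_strategy")
}

#' @export
print.feat_strategy <- function(x, ...) {
  cat(sprintf("<featurization %d> node blocks [%s] (d=%d); edge blocks [%s] (b=%d)\n",
              x$id, paste(x$node_schema, collapse = ", "), x$d,
              paste(x$edge_schema, collapse = ", "), x$b))
  invisible(x)
}

#' Atom feature matrix under a featurization strategy
#'
#' @param mol a `molecule`.
#' @param strategy a `feat_strategy` or a strategy id.
#' @param permissive map unknown elements to the "other" slot with a warning
#'   instead of failing.
#' @return an `n_atoms x d` numeric matrix, rows in atom order.
#' @export
featurize_node <- function(mol, strategy, permissive = FALSE) {
  if (!inherits(strategy, "feat_strategy")) strategy <- feat_strategy(strategy)
  do.call(cbind, lapply(.node_blocks[strategy$node_schema],
                        function(bl) bl$fn(mol, permissive)))
}

#' Bond feature matrix under a featurization strategy
#'
#' Both directed edges derived from one bond share this feature vector.
#'
#' @inheritParams featurize_node
#' @return an `n_bonds x b` numeric matrix, rows in bond order.
#' @export
featurize_edge <- function(mol, strategy) {
  if (!inherits(strategy, "feat_strategy")) strategy <- feat_strategy(strategy)
  if (nrow(mol$bonds) == 0L) {
    return(matrix(0, 0L, strategy$b))
  }
  do.call(cbind, lapply(.edge_blocks[strategy$edge_schema],
                        function(bl) bl$fn(mol)))
}

# Internal constructor shared by build_graph() and synthetic topologies.
.molgraph <- function(n, a1, a2, Xn, Xe_bond, strategy_id = NA_integer_) {
  n <- as.integer(n)
  a1 <- as.integer(a1); a2 <- as.integer(a2)
  nb <- length(a1)
  if (nb > 0L) {
    src <- as.integer(rbind(a1, a2))
    dst <- as.integer(rbind(a2, a1))
    rev <- as.integer(rbind(seq_len(nb) * 2L, seq_len(nb) * 2L - 1L))
    Xe <- Xe_bond[rep(seq_len(nb), each = 2L), , drop = FALSE]
  } else {
    src <- dst <- rev <- integer(0)
    Xe <- Xe_bond
  }
  A <- matrix(0L, n, n)
  if (nb > 0L) A[cbind(src, dst)] <- 1L
  structure(list(n = n, src = src, dst = dst, rev = rev,
                 Xn = Xn, Xe = Xe, A = A,
                 d = ncol(Xn), b = ncol(Xe),
                 strategy_id = strategy_id),
            class = "molgraph")
}

#' Build a directed, featurized molecular graph
#'
#' Every chemical bond becomes two directed edges `u->v` and `v->u` carrying
#' identical feature vectors; the binary adjacency matrix is symmetric.
#'
#' @inheritParams featurize_node
#' @return a `molgraph`: node count `n`, parallel directed-edge index vectors
#'   `src`/`dst` with `rev` pointing at each edge's reverse, node features `Xn`
#'   (`n x d`), per-directed-edge features `Xe` (`2*n_bonds x b`), and binary
#'   adjacency `A`.
#' @examples
#' g <- build_graph(parse_molecule("CC"), feat_strategy(5))
#' cbind(g$src, g$dst)  # the two directed edges of ethane
#' @export
build_graph <- function(mol, strategy, permissive = FALSE) {
  if (!inherits(strategy, "feat_strategy")) strategy <- feat_strategy(strategy)
  Xn <- featurize_node(mol, strategy, permissive = permissive)
  Xe <- featurize_edge(mol, strategy)
  .molgraph(n_atoms(mol), mol$bonds$a1, mol$bonds$a2, Xn, Xe, strategy$id)
}

#' @export
print.molgraph <- function(x, ...) {
  cat(sprintf("<molgraph> %d nodes, %d directed edges, d=%d, b=%d\n",
              x$n, length(x$src), x$d, x$b))
  invisible(x)
}

#' Construct a bare topology graph with uniform features
#'
#' Used for expressiveness probes where topology must be the only signal:
#' every node and edge feature is the constant 1.
#'
#' @param n node count.
#' @param bonds two-column matrix of undirected bonds (1-based indices).
#' @return a `molgraph` with `d = b = 1` and all-ones features.
#' @export
uniform_graph <- function(n, bonds) {
  bonds <- as.matrix(bonds)
  stopifnot(ncol(bonds) == 2L, all(bonds >= 1L), all(bonds <= n),
            all(bonds[, 1] != bonds[, 2]))
  .molgraph(n, bonds[, 1], bonds[, 2],
            matrix(1, n, 1), matrix(1, nrow(bonds), 1))
}

#' Serialize / restore graph bundles
#'
#' The on-disk container (an RDS file with a format version tag) holds the
#' node/edge feature arrays and the directed edge index lists for a list of
#' graphs; layout is an internal, versioned contract.
#'
#' @param graphs list of `molgraph` objects.
#' @param path file path.
#' @return `write_graph_bundle` returns `path` invisibly; `read_graph_bundle`
#'   the restored list of graphs.
#' @export
write_graph_bundle <- function(graphs, path) {
  stopifnot(all(vapply(graphs, inherits, logical(1), "molgraph")))
  saveRDS(list(format = "dgin-graph-bundle", version = 1L, graphs = graphs),
          path)
  invisible(path)
}

#' @rdname write_graph_bundle
#' @export
read_graph_bundle <- function(path) {
  x <- readRDS(path)
  if (!identical(x$format, "dgin-graph-bundle")) {
    stop("not a graph bundle file", call. = FALSE)
  }
  x$graphs
}
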