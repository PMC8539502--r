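# Seeded synthetic molecule generator with additive ground-truth properties.
#
# The generator emulates the structure of the reference datasets just closely
# enough to exercise every pipeline stage without a download: a library of
# small heavy-atom molecules (trees over C/N/O/S with an optional single ring
# closure), and three coupled properties
#   logP = sum of per-element atom contributions + per-order bond
#          contributions + ring bonus * cycle count + N(0, sigma)
#   logD = logP - charge_penalty * (number of charged atoms)
#   logS = a * logP + b + independent N(0, sigma), a < 0
# so lipophilicity and solubility are anticorrelated and multi-task learning
# has genuine shared signal. With sigma = 0 the properties are an exact linear
# function of composition, recoverable by least squares.

#' Ground-truth parameter set for synthetic properties
#'
#' @param element numeric map of per-element atom contributions.
#' @param bond numeric map of per-bond-order contributions (names from
#'   `{"1","2","3","ar"}`).
#' @param ring_bonus contribution per independent cycle.
#' @param charge_penalty lipophilicity loss per charged atom (enters logD).
#' @param a,b coupling of synthetic logS to synthetic logP (`a < 0`).
#' @param sigma additive Gaussian noise level on logP and logS.
#' @return a `synthetic_theta` list.
#' @export
synthetic_theta <- function(element = c(C = 0.55, N = -0.35, O = -0.6, S = 0.4),
                            bond = c(`1` = 0.12, `2` = 0.16, `3` = 0.2, ar = 0.14),
                            ring_bonus = 0.3, charge_penalty = 0.8,
                            a = -1.0, b = -1.0, sigma = 0.1) {
  stopifnot(sigma >= 0, all(is.finite(c(element, bond, ring_bonus,
                                        charge_penalty, a, b))))
  structure(list(element = element, bond = bond, ring_bonus = ring_bonus,
                 charge_penalty = charge_penalty, a = a, b = b, sigma = sigma),
            class = "synthetic_theta")
}

# Maximum bonding capacity used while growing random trees.
.capacity <- c(C = 4L, N = 3L, O = 2L, S = 2L)

# Serialize a connected graph with at most one extra (ring) edge to SMILES.
.tree_to_smiles <- function(elements, edges, ring_edge = NULL) {
  n <- length(elements)
  adj <- vector("list", n)
  if (nrow(edges)) {
    for (k in seq_len(nrow(edges))) {
      i <- edges[k, 1]; j <- edges[k, 2]
      adj[[i]] <- c(adj[[i]], j)
      adj[[j]] <- c(adj[[j]], i)
    }
  }
  ring_at <- integer(0)
  if (!is.null(ring_edge)) ring_at <- ring_edge
  emit <- function(v, parent) {
    s <- elements[v]
    if (v %in% ring_at) s <- paste0(s, "1")
    kids <- setdiff(adj[[v]], parent)
    if (length(kids)) {
      inner <- vapply(kids, function(k) emit(k, v), character(1))
      branches <- if (length(inner) > 1L) {
        paste0("(", utils::head(inner, -1L), ")", collapse = "")
      } else ""
      s <- paste0(s, branches, utils::tail(inner, 1L))
    }
    s
  }
  emit(1L, 0L)
}

#' Generate a seeded library of synthetic SMILES
#'
#' Random heavy-atom trees over C/N/O/S (respecting valence capacities) with
#' an optional single ring closure, serialized to SMILES. Every output parses
#' back successfully.
#'
#' @param n number of molecules.
#' @param seed integer seed; the same seed reproduces the same library.
#' @param max_atoms largest heavy-atom count (minimum 2).
#' @param ring_prob probability of attempting one ring closure.
#' @return character vector of `n` SMILES.
#' @export
generate_library <- function(n, seed = 1L, max_atoms = 12L, ring_prob = 0.4) {
  stopifnot(n >= 1L, max_atoms >= 2L)
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)
  out <- character(n)
  for (i in seq_len(n)) {
    k <- sample(3:max_atoms, 1L)
    elements <- sample(names(.capacity), k, replace = TRUE,
                       prob = c(0.7, 0.1, 0.15, 0.05))
    deg <- integer(k)
    edges <- matrix(0L, 0L, 2L)
    for (v in 2:k) {
      open <- which(deg[seq_len(v - 1L)] < .capacity[elements[seq_len(v - 1L)]])
      if (!length(open)) { elements[v] <- NA; next }
      p <- if (length(open) == 1L) open else sample(open, 1L)
      edges <- rbind(edges, c(p, v))
      deg[p] <- deg[p] + 1L; deg[v] <- deg[v] + 1L
    }
    keep <- !is.na(elements)
    if (!all(keep)) {
      remap <- cumsum(keep)
      edges <- edges[keep[edges[, 2]], , drop = FALSE]
      edges[] <- remap[edges]
      elements <- elements[keep]
      deg <- deg[keep]
      k <- length(elements)
    }
    ring_edge <- NULL
    if (k >= 3L && stats::runif(1) < ring_prob) {
      open <- which(deg < .capacity[elements])
      adj_pairs <- paste(pmin(edges[, 1], edges[, 2]),
                         pmax(edges[, 1], edges[, 2]))
      if (length(open) >= 2L) {
        cand <- utils::combn(open, 2L)
        ok <- !(paste(cand[1, ], cand[2, ]) %in% adj_pairs)
        if (any(ok)) {
          pick <- cand[, sample(which(ok), 1L)]
          ring_edge <- as.integer(pick)
        }
      }
    }
    out[i] <- .tree_to_smiles(elements, edges, ring_edge)
  }
  out
}

#' Assign coupled synthetic properties to a molecule
#'
#' @param mol a `molecule`.
#' @param theta a [synthetic_theta()].
#' @param seed integer seed for the noise draws.
#' @return named numeric vector `c(logp, logd, logs)`.
#' @export
assign_properties <- function(mol, theta = synthetic_theta(), seed = 1L) {
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)
  base <- sum(theta$element[mol$atoms$element], na.rm = TRUE) +
    sum(theta$bond[mol$bonds$order], na.rm = TRUE) +
    theta$ring_bonus * max(0L, nrow(mol$bonds) - nrow(mol$atoms) + 1L)
  logp <- base + stats::rnorm(1, 0, theta$sigma)
  logd <- logp - theta$charge_penalty * sum(mol$atoms$charge != 0L)
  logs <- theta$a * logp + theta$b + stats::rnorm(1, 0, theta$sigma)
  c(logp = logp, logd = logd, logs = logs)
}

#' Generate a labelled synthetic dataset
#'
#' @param n number of molecules.
#' @param seed integer seed controlling both the library and the noise.
#' @param theta a [synthetic_theta()].
#' @param max_atoms passed to [generate_library()].
#' @return data frame with columns `smiles`, `logd`, `logs`, `logp`; the
#'   parsed molecules, theta and seed are attached as attributes
#'   (`"molecules"`, `"manifest"`).
#' @export
synthetic_dataset <- function(n, seed = 1L, theta = synthetic_theta(),
                              max_atoms = 12L) {
  smiles <- generate_library(n, seed = seed, max_atoms = max_atoms)
  mols <- parse_molecules(smiles)
  props <- t(vapply(seq_along(mols),
                    function(i) assign_properties(mols[[i]], theta,
                                                  seed = seed + i),
                    numeric(3)))
  df <- data.frame(smiles = smiles, logd = props[, "logd"],
                   logs = props[, "logs"], logp = props[, "logp"])
  attr(df, "molecules") <- mols
  attr(df, "manifest") <- list(n = n, seed = seed, theta = theta,
                               max_atoms = max_atoms)
  df
}

#' Write a synthetic dataset and its manifest
#'
#' Writes the standard dataset CSV consumed by the training protocol plus a
#' JSON manifest recording theta and the seed.
#'
#' @param df data frame from [synthetic_dataset()].
#' @param path CSV output path; the manifest goes to `<path>.manifest.json`.
#' @export
write_synthetic_csv <- function(df, path) {
  utils::write.csv(df[, c("smiles", "logd", "logs", "logp")], path,
                   row.names = FALSE)
  manifest <- attr(df, "manifest")
  if (!is.null(manifest)) {
    manifest$theta <- unclass(manifest$theta)
    jsonlite::write_json(manifest, paste0(path, ".manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Design matrix of composition counts for the linear recovery oracle
#'
#' Columns: per-element atom counts, per-order bond counts, cycle count.
#' With `sigma = 0` the synthetic logP is exactly `X %*% theta_vec`, so least
#' squares recovers theta to machine precision.
#'
#' @param mols list of `molecule`s.
#' @return numeric matrix with one row per molecule.
#' @export
composition_matrix <- function(mols) {
  els <- c("C", "N", "O", "S")
  ords <- c("1", "2", "3", "ar")
  t(vapply(mols, function(m) {
    c(vapply(els, function(e) sum(m$atoms$element == e), numeric(1)),
      vapply(ords, function(o) sum(m$bonds$order == o), numeric(1)),
      cycles = max(0L, nrow(m$bonds) - nrow(m$atoms) + 1L))
  }, numeric(length(els) + length(ords) + 1L)))
}

#' The topology pair motivating isomorphism-aware networks
#'
#' Returns the naphthalene skeleton (two fused hexagons sharing an edge) and
#' the 1,1-bi(cyclopentane) skeleton (two pentagons joined by one bond) as
#' uniform-feature graphs: 10 nodes, 11 bonds and identical degree multisets
#' each, differing only in topology. The two graphs are non-isomorphic yet
#' equivalent under one-dimensional Weisfeiler-Lehman colour refinement.
#'
#' @return named list of two `molgraph`s (`naphthalene`, `bicyclopentane`).
#' @export
wl_pair <- function() {
  naph <- cbind(c(1, 2, 3, 4, 5, 6, 2, 7, 8, 9, 10),
                c(2, 3, 4, 5, 6, 1, 7, 8, 9, 10, 1))
  bicp <- cbind(c(1, 2, 3, 4, 5, 6, 7, 8, 9, 10, 1),
                c(2, 3, 4, 5, 1, 7, 8, 9, 10, 6, 6))
  list(naphthalene = uniform_graph(10L, naph),
       bicyclopentane = uniform_graph(10L, bicp))
}
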