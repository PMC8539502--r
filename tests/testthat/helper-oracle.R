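# Test helpers. The naive loop-based reference implementation lives with the
# package (inst/oracle) so the acceptance script can use the same oracle.

.oracle_path <- system.file("oracle", "naive_forward.R", package = "dgin")
if (!nzchar(.oracle_path)) {  # package loaded from source, not installed
  .cand <- c("inst/oracle/naive_forward.R", "../../inst/oracle/naive_forward.R")
  .oracle_path <- .cand[file.exists(.cand)][1]
}
source(.oracle_path, local = TRUE)

random_molgraph <- random_small_graph
permute_graph <- permute_small_graph

# Identity-shaped parameters: square maps as identities, readout passthrough.
identity_params <- function(architecture, d, b, cc, T = 1L, T2 = 1L,
                            n_out = 1L) {
  p <- gnn_params(architecture, d = d, b = b, hidden = cc, T = T, T2 = T2,
                  tau = "identity", n_out = n_out, seed = 1)
  eye <- function(nr, nc) { m <- matrix(0, nr, nc); diag(m) <- 1; m }
  for (nm in names(p$theta)) {
    v <- p$theta[[nm]]
    if (grepl("eps$", nm)) { p$theta[[nm]] <- 0; next }
    if (is.matrix(v)) p$theta[[nm]] <- eye(nrow(v), ncol(v)) else p$theta[[nm]] <- v * 0
  }
  p
}
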