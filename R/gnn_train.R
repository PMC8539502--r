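# Analytic gradients, Adam optimization and the training loop with
# combined-RMSE checkpoint selection.

# Backward pass through gnn_forward(). `dY` is dL/dyhat (G x n_out).
# Returns gradients shaped like params$theta.
.gnn_backward <- function(params, batch, cache, dY) {
  th <- params$theta
  tauf <- .tau_fns[[params$tau]]
  g <- lapply(th, function(x) if (is.matrix(x)) matrix(0, nrow(x), ncol(x)) else x * 0)

  # readout
  g$ro_bout <- colSums(dY)
  g$ro_Wout <- t(dY) %*% cache$R2
  dR2 <- dY %*% th$ro_Wout
  dP2 <- dR2 * tauf$grad(cache$preR2, cache$R2)
  g$ro_b2 <- colSums(dP2)
  g$ro_W2 <- t(dP2) %*% cache$R1
  dR1 <- dP2 %*% th$ro_W2
  dP1 <- dR1 * tauf$grad(cache$preR1, cache$R1)
  g$ro_b1 <- colSums(dP1)
  g$ro_W1 <- t(dP1) %*% cache$HG
  dHG <- dP1 %*% th$ro_W1
  dN <- .dense(Matrix::t(batch$Pool) %*% dHG)

  # GIN phase (reversed)
  if (params$architecture != "dmpnn") {
    for (l in rev(seq_len(params$T2))) {
      lc <- cache$gin[[l]]
      eps <- th[[sprintf("gin%d_eps", l)]]
      W1 <- th[[sprintf("gin%d_W1", l)]]
      W2 <- th[[sprintf("gin%d_W2", l)]]
      dPo <- dN * tauf$grad(lc$pre2, lc$Nout)
      g[[sprintf("gin%d_b2", l)]] <- colSums(dPo)
      g[[sprintf("gin%d_W2", l)]] <- t(dPo) %*% lc$U
      dU <- dPo %*% W2
      dPi <- dU * tauf$grad(lc$pre1, lc$U)
      g[[sprintf("gin%d_b1", l)]] <- colSums(dPi)
      g[[sprintf("gin%d_W1", l)]] <- t(dPi) %*% lc$Z
      dZ <- dPi %*% W1
      g[[sprintf("gin%d_eps", l)]] <- sum(dZ * lc$Nin)
      dN <- (1 + eps) * dZ + .dense(Matrix::t(batch$Adj) %*% dZ)
    }
  }

  if (params$architecture == "gin") return(g)

  # node combination (Eq. 5)
  if (params$architecture == "dmpnn") {
    g$W_agg_edge <- t(dN) %*% cache$N0
    dN0 <- dN %*% th$W_agg_edge
  } else {
    dN0 <- dN
  }
  dMn <- dN0[, seq_len(params$c), drop = FALSE]

  # edge phase (reversed recursion); absent entirely for bond-free batches
  if (batch$E > 0L) {
    dH <- .dense(Matrix::t(batch$A_in) %*% dMn)
    dH0 <- matrix(0, batch$E, params$c)
    for (t in rev(seq_len(params$T))) {
      dP <- dH * tauf$grad(cache$Ps[[t]], cache$Hs[[t]])
      dH0 <- dH0 + dP
      g$W_m <- g$W_m + t(dP) %*% cache$Ms[[t]]
      dM <- dP %*% th$W_m
      dH <- .dense(Matrix::t(batch$M_ex) %*% dM)
    }
    dH0 <- dH0 + dH
    dP0 <- dH0 * tauf$grad(cache$P0, cache$H0)
    g$W_init <- t(dP0) %*% cache$Z0
  }
  g
}

#' Masked multi-task squared-error loss
#'
#' Per property: the mean squared error over records where that property is
#' observed; the loss is the sum of these per-property terms, so records
#' lacking a property contribute nothing to that property's term.
#'
#' @param preds `n x p` matrix of predictions.
#' @param targets `n x p` matrix of observed values with `NA` for missing.
#' @return list with `loss`, per-property `terms`, and the gradient `grad`
#'   (`n x p`, zero where the target is missing).
#' @export
multitask_loss <- function(preds, targets) {
  preds <- as.matrix(preds); targets <- as.matrix(targets)
  stopifnot(all(dim(preds) == dim(targets)))
  grad <- matrix(0, nrow(preds), ncol(preds))
  terms <- numeric(ncol(preds))
  for (p in seq_len(ncol(preds))) {
    obs <- which(!is.na(targets[, p]))
    if (!length(obs)) {
      warning(sprintf("no observed values for property %d in this batch", p),
              call. = FALSE)
      next
    }
    r <- preds[obs, p] - targets[obs, p]
    terms[p] <- mean(r^2)
    grad[obs, p] <- 2 * r / length(obs)
  }
  list(loss = sum(terms), terms = terms, grad = grad)
}

.adam_init <- function(theta) {
  list(m = lapply(theta, function(x) x * 0),
       v = lapply(theta, function(x) x * 0), t = 0L)
}

.adam_step <- function(theta, grads, state, lr = 1e-3, beta1 = 0.9,
                       beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(theta)) {
    gk <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * gk
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * gk^2
    theta[[nm]] <- theta[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(theta = theta, state = state)
}

#' Evaluate per-property and combined RMSE of a model on a set of graphs
#'
#' @param params a `gnn_params`.
#' @param batch a `graph_batch` (or list of graphs).
#' @param targets targets matrix with `NA` for missing values.
#' @return list with per-property `rmse` and their sum `combined`.
#' @export
gnn_evaluate <- function(params, batch, targets) {
  yhat <- gnn_predict(params, batch)
  targets <- as.matrix(targets)
  per <- vapply(seq_len(ncol(targets)), function(p) {
    obs <- !is.na(targets[, p])
    if (!any(obs)) return(NA_real_)
    rmse(yhat[obs, p], targets[obs, p])
  }, numeric(1))
  names(per) <- colnames(targets)
  list(rmse = per, combined = combined_rmse(per[!is.na(per)]))
}

#' Train a GNN with Adam and combined-RMSE checkpointing
#'
#' Runs mini-batch gradient descent on the masked multi-task loss for a fixed
#' number of epochs. After every epoch the model is evaluated on the
#' evaluation split; whenever the combined (summed per-property) evaluation
#' RMSE drops strictly below the running best, the weights are checkpointed.
#' The returned model is the checkpointed (best), not the final, iterate.
#'
#' @param params initial `gnn_params`.
#' @param graphs list of `molgraph`s for the full dataset.
#' @param targets `n x p` matrix (NA = missing), columns named by property.
#' @param split a `split_spec` from [split_dataset()].
#' @param epochs training epochs (the reference protocol uses 1600; small
#'   studies use far fewer).
#' @param batch_size mini-batch size.
#' @param lr Adam learning rate.
#' @param seed seed controlling shuffling (training is otherwise
#'   deterministic, so identical seeds give identical histories).
#' @param verbose print progress every `verbose` epochs (0 = silent).
#' @return a `gnn_fit`: `params` (best checkpoint), `history` data frame with
#'   one row per epoch (training loss, per-property and combined evaluation
#'   RMSE), `best_epoch`, `best_combined`, and the resolved `config`.
#' @export
gnn_train <- function(params, graphs, targets, split, epochs = 100L,
                      batch_size = 64L, lr = 1e-3, seed = 1L, verbose = 0L) {
  targets <- as.matrix(targets)
  stopifnot(length(graphs) == nrow(targets),
            ncol(targets) == params$n_out)
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)
  tr <- split$train
  eval_batch <- batch_graphs(graphs[split$eval])
  eval_y <- targets[split$eval, , drop = FALSE]
  # pre-batch per-epoch mini-batches lazily; graph batching dominates cost, so
  # cache the batched structures for a fixed partition of the training set
  state <- .adam_init(params$theta)
  best <- Inf
  best_theta <- params$theta
  best_epoch <- NA_integer_
  hist <- vector("list", epochs)
  batch_cache <- new.env(parent = emptyenv())
  for (ep in seq_len(epochs)) {
    ord <- sample(tr)
    nb <- ceiling(length(ord) / batch_size)
    ep_loss <- 0
    for (bi in seq_len(nb)) {
      idx <- ord[((bi - 1L) * batch_size + 1L):min(bi * batch_size, length(ord))]
      key <- paste(idx, collapse = ",")
      bt <- batch_cache[[key]]
      if (is.null(bt)) {
        bt <- batch_graphs(graphs[idx])
        batch_cache[[key]] <- bt
      }
      fw <- gnn_forward(params, bt, keep_cache = TRUE)
      ls <- multitask_loss(fw$yhat, targets[idx, , drop = FALSE])
      if (!is.finite(ls$loss)) {
        stop(sprintf("training diverged (non-finite loss at epoch %d)", ep),
             call. = FALSE)
      }
      grads <- .gnn_backward(params, bt, fw$cache, ls$grad)
      upd <- .adam_step(params$theta, grads, state, lr = lr)
      params$theta <- upd$theta
      state <- upd$state
      ep_loss <- ep_loss + ls$loss * length(idx)
    }
    ev <- gnn_evaluate(params, eval_batch, eval_y)
    if (is.finite(ev$combined) && ev$combined < best) {
      best <- ev$combined
      best_theta <- params$theta
      best_epoch <- ep
    }
    row <- data.frame(epoch = ep, train_loss = ep_loss / length(tr),
                      eval_combined = ev$combined)
    for (p in seq_along(ev$rmse)) {
      row[[paste0("eval_rmse_", colnames(targets)[p])]] <- ev$rmse[p]
    }
    hist[[ep]] <- row
    if (verbose > 0L && ep %% verbose == 0L) {
      message(sprintf("epoch %4d  loss %.4f  eval combined RMSE %.4f (best %.4f)",
                      ep, ep_loss / length(tr), ev$combined, best))
    }
  }
  params$theta <- best_theta
  structure(list(params = params,
                 history = do.call(rbind, hist),
                 best_epoch = best_epoch, best_combined = best,
                 config = list(epochs = epochs, batch_size = batch_size,
                               lr = lr, seed = seed,
                               architecture = params$architecture,
                               hidden = params$c, T = params$T, T2 = params$T2)),
            class = "gnn_fit")
}

#' @export
print.gnn_fit <- function(x, ...) {
  cat(sprintf("<gnn_fit> %s, %d epochs; best eval combined RMSE %.4f at epoch %d\n",
              toupper(x$params$architecture), nrow(x$history),
              x$best_combined, x$best_epoch))
  invisible(x)
}
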