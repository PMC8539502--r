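# Classical single-task baselines on fingerprint (+/- descriptor) features,
# and consensus averaging of two models' predictions.
#
# Circular fingerprints (radius 4) and MACCS-style structural keys come from
# the OpenBabel backend (ChemmineR::fingerprintOB); the hashed circular
# fingerprint is folded by modulo to the configured bit length. The
# descriptor block is the full numeric descriptor set of the same backend;
# its actual length is recorded in the feature metadata rather than
# hard-coded, because descriptor counts are toolkit-dependent.

.fingerprint_names <- c("ECFP-1024", "ECFP-1536", "ECFP-2048", "MACCS")

#' The eight baseline feature settings
#'
#' Four fingerprints (three circular bit lengths and MACCS keys), each with
#' or without the standardized descriptor block.
#'
#' @return data frame with columns `fingerprint` and `with_descriptors`
#'   (8 rows).
#' @export
baseline_settings <- function() {
  expand.grid(fingerprint = .fingerprint_names,
              with_descriptors = c(FALSE, TRUE),
              KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
}

.sdf_from_smiles <- function(smiles) {
  bad <- !vapply(smiles, function(s) isTRUE(smiles_syntax_check(s)), logical(1))
  if (any(bad)) {
    stop(sprintf("cannot parse SMILES '%s'", smiles[which(bad)[1]]),
         call. = FALSE)
  }
  names(smiles) <- sprintf("cmp%06d", seq_along(smiles))
  suppressWarnings(ChemmineR::smiles2sdf(smiles))
}

# Fold a wide hashed fingerprint matrix to nbits columns by index modulo.
.fold_fp <- function(m, nbits) {
  idx <- ((seq_len(ncol(m)) - 1L) %% nbits) + 1L
  folded <- t(rowsum(t(m), idx))
  (folded > 0) * 1
}

#' Fingerprint (+ descriptor) features for the baseline models
#'
#' @param smiles character vector of SMILES.
#' @param setting one row of [baseline_settings()], or a list with elements
#'   `fingerprint` and `with_descriptors`.
#' @param standardizer a standardizer fitted on the training set (see
#'   [fit_standardizer()]); required when descriptors are enabled and the
#'   features are for evaluation/test data.
#' @return numeric feature matrix, one row per molecule. Records whose
#'   descriptor computation fails are dropped with a warning; kept row
#'   indices are attached as attribute `"kept"`.
#' @export
featurize_baseline <- function(smiles, setting, standardizer = NULL) {
  stopifnot(setting$fingerprint %in% .fingerprint_names)
  sdf <- .sdf_from_smiles(smiles)
  valid <- ChemmineR::validSDF(sdf)
  if (!all(valid)) {
    warning(sprintf("dropping %d record(s) that failed feature computation",
                    sum(!valid)), call. = FALSE)
    sdf <- sdf[valid]
  }
  if (setting$fingerprint == "MACCS") {
    fp <- ChemmineR::fingerprintOB(sdf, "MACCS")@fpma
  } else {
    nbits <- as.integer(sub("ECFP-", "", setting$fingerprint))
    raw <- ChemmineR::fingerprintOB(sdf, "ECFP8")@fpma  # radius 4
    fp <- .fold_fp(raw, nbits)
  }
  colnames(fp) <- paste0("fp", seq_len(ncol(fp)))
  if (isTRUE(setting$with_descriptors)) {
    desc <- .descriptor_block(sdf)
    if (is.null(standardizer)) standardizer <- fit_standardizer(desc)
    fp <- cbind(fp, standardize_apply(standardizer, desc))
  }
  rownames(fp) <- NULL
  attr(fp, "kept") <- which(valid)
  attr(fp, "n_descriptors") <- if (isTRUE(setting$with_descriptors)) {
    ncol(fp) - sum(grepl("^fp", colnames(fp)))
  } else 0L
  fp
}

.descriptor_block <- function(sdf) {
  pr <- ChemmineR::propOB(sdf)
  num <- pr[, vapply(pr, is.numeric, logical(1)), drop = FALSE]
  as.matrix(num)
}

#' Fit / apply a per-feature standardizer
#'
#' Centres each feature at its training mean and scales to unit standard
#' deviation; constant features get deviation 1 so they pass through as
#' zeros.
#'
#' @param X numeric training feature matrix.
#' @return a `standardizer` with `$mean` and `$sd`.
#' @export
fit_standardizer <- function(X) {
  X <- as.matrix(X)
  mu <- colMeans(X)
  sd_ <- apply(X, 2, stats::sd)
  sd_[!is.finite(sd_) | sd_ == 0] <- 1
  structure(list(mean = mu, sd = sd_), class = "standardizer")
}

#' @rdname fit_standardizer
#' @param standardizer a fitted `standardizer`.
#' @export
standardize_apply <- function(standardizer, X) {
  X <- as.matrix(X)
  sweep(sweep(X, 2, standardizer$mean, `-`), 2, standardizer$sd, `/`)
}

#' Fit a classical single-task baseline regressor
#'
#' Delegates to the established implementations at their default
#' hyperparameters: [randomForest::randomForest()], [e1071::svm()] (RBF), or
#' [caret::knnreg()]. One model per property.
#'
#' @param kind `"RF"`, `"SVM"` or `"KNN"`.
#' @param X numeric feature matrix (training rows).
#' @param y numeric response.
#' @param seed integer seed (random forest fitting is stochastic).
#' @return a `baseline_model`; use `predict(model, newX)`.
#' @export
fit_baseline <- function(kind = c("RF", "SVM", "KNN"), X, y, seed = 1L) {
  kind <- match.arg(kind)
  X <- as.matrix(X)
  stopifnot(nrow(X) == length(y))
  if (nrow(X) < 2L) stop("need at least 2 training samples", call. = FALSE)
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)
  fit <- switch(kind,
    RF = randomForest::randomForest(x = X, y = y),
    SVM = e1071::svm(x = X, y = y, scale = FALSE),
    KNN = caret::knnreg(X, y)
  )
  structure(list(kind = kind, fit = fit, p = ncol(X)), class = "baseline_model")
}

#' @export
predict.baseline_model <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  stopifnot(ncol(newdata) == object$p)
  as.numeric(stats::predict(object$fit, newdata))
}

#' Consensus of two prediction vectors
#'
#' The element-wise arithmetic mean of two models' predicted log values. By
#' convexity of the L2 norm its RMSE never exceeds the mean of the two
#' component RMSEs.
#'
#' @param pred_a,pred_b equal-length numeric prediction vectors.
#' @return their element-wise mean.
#' @export
consensus <- function(pred_a, pred_b) {
  if (length(pred_a) != length(pred_b)) {
    stop("prediction vectors must have equal length", call. = FALSE)
  }
  (pred_a + pred_b) / 2
}
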