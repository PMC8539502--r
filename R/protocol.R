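# Dataset handling and the evaluation protocol: preprocessing filters,
# 81:9:10 splitting, target offsetting, RMSE metrics, bootstrap confidence
# intervals and best-of-runs selection.

.property_names <- c("logd", "logs", "logp")

#' The seven training strategies
#'
#' Multi-task strategies combine two or three of logD, logS, logP; single-task
#' strategies use one. For two-property strategies that include logP, only
#' records carrying BOTH properties are used, so that the logP-rich side never
#' imbalances the pair.
#'
#' @return named list; each element has `name` and `properties`.
#' @export
training_strategies <- function() {
  mk <- function(name, props) list(name = name, properties = props)
  list(
    `logD/P/S` = mk("logD/P/S", c("logd", "logp", "logs")),
    `logD/P`   = mk("logD/P",   c("logd", "logp")),
    `logD/S`   = mk("logD/S",   c("logd", "logs")),
    `logS/P`   = mk("logS/P",   c("logs", "logp")),
    `logD`     = mk("logD",     "logd"),
    `logS`     = mk("logS",     "logs"),
    `logP`     = mk("logP",     "logp")
  )
}

#' Select the records a training strategy may learn from
#'
#' @param records data frame with columns `logd`, `logs`, `logp` (NA =
#'   missing).
#' @param strategy a strategy name (see [training_strategies()]) or strategy
#'   object.
#' @return logical vector marking usable records. Targets outside the
#'   strategy's property set must additionally be masked by the caller (see
#'   [strategy_targets()]).
#' @export
strategy_records <- function(records, strategy) {
  if (is.character(strategy)) strategy <- training_strategies()[[strategy]]
  stopifnot(!is.null(strategy))
  props <- strategy$properties
  have <- !is.na(as.matrix(records[, props, drop = FALSE]))
  if (length(props) == 2L && "logp" %in% props) {
    rowSums(have) == 2L  # two-property strategies with logP: both required
  } else {
    rowSums(have) >= 1L
  }
}

#' Target matrix restricted to a strategy's property set
#'
#' @inheritParams strategy_records
#' @return numeric matrix with one column per strategy property (NA where
#'   missing), rows aligned with `records`.
#' @export
strategy_targets <- function(records, strategy) {
  if (is.character(strategy)) strategy <- training_strategies()[[strategy]]
  as.matrix(records[, strategy$properties, drop = FALSE])
}

#' Read a property dataset CSV
#'
#' Expected columns: `smiles` plus any of `logd`, `logs`, `logp`; empty cells
#' are missing values. Per-column presence counts are attached as the
#' `"presence"` attribute.
#'
#' @param path CSV path.
#' @return data frame with columns `smiles`, `logd`, `logs`, `logp`.
#' @export
read_property_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  names(df) <- tolower(names(df))
  if (!"smiles" %in% names(df)) stop("CSV must have a 'smiles' column", call. = FALSE)
  for (p in .property_names) {
    if (!p %in% names(df)) df[[p]] <- NA_real_
    df[[p]] <- suppressWarnings(as.numeric(df[[p]]))
  }
  out <- df[, c("smiles", .property_names)]
  attr(out, "presence") <- colSums(!is.na(out[, .property_names]))
  out
}

# Largest fragment of a dotted (multi-component) SMILES, by heavy-atom count.
.largest_fragment <- function(smiles) {
  parts <- strsplit(smiles, ".", fixed = TRUE)[[1]]
  if (length(parts) == 1L) return(smiles)
  counts <- vapply(parts, function(p) {
    stripped <- gsub("\\[[0-9]*H[0-9]*[+-]?[0-9]*\\]", "[X]", p)
    length(gregexpr("[A-IK-PR-Za-ik-pr-z]", gsub("H", "", stripped))[[1]])
  }, numeric(1))
  parts[which.max(counts)]
}

#' Preprocess a property dataset
#'
#' Applies the dataset-specific cleaning: for solubility data, multi-fragment
#' SMILES are reduced to their largest fragment (salt stripping) and records
#' with logS strictly below -10.0 or strictly above 0.0 are removed (boundary
#' values are retained); molecules in both dataset kinds are neutralized.
#' Unparsable records are dropped with a warning.
#'
#' @param records data frame from [read_property_csv()].
#' @param dataset_kind `"lipophilicity"` or `"solubility"`.
#' @return the filtered records (with canonical fragment SMILES for
#'   solubility data); a per-filter count report is attached as the
#'   `"report"` attribute and also printed via message().
#' @export
preprocess_records <- function(records,
                               dataset_kind = c("lipophilicity", "solubility")) {
  dataset_kind <- match.arg(dataset_kind)
  n_input <- nrow(records)
  n_stripped <- 0L
  if (dataset_kind == "solubility") {
    multi <- grepl(".", records$smiles, fixed = TRUE)
    n_stripped <- sum(multi)
    records$smiles[multi] <- vapply(records$smiles[multi], .largest_fragment,
                                    character(1))
  }
  mols <- suppressWarnings(
    parse_molecules(records$smiles, neutralize = TRUE, on_error = "drop"))
  kept <- as.integer(names(mols))
  n_unparsable <- n_input - length(kept)
  if (n_unparsable > 0L) {
    warning(sprintf("dropping %d unparsable record(s)", n_unparsable),
            call. = FALSE)
  }
  records <- records[kept, , drop = FALSE]
  n_neutralized <- sum(vapply(mols, function(m) m$neutralized > 0L, logical(1)))
  n_filtered <- 0L
  if (dataset_kind == "solubility") {
    bad <- !is.na(records$logs) & (records$logs < -10.0 | records$logs > 0.0)
    n_filtered <- sum(bad)
    records <- records[!bad, , drop = FALSE]
    mols <- mols[!bad]
  }
  report <- list(dataset_kind = dataset_kind, n_input = n_input,
                 n_unparsable = n_unparsable, n_salt_stripped = n_stripped,
                 n_neutralized = n_neutralized,
                 n_logs_filtered = n_filtered, n_output = nrow(records))
  message(sprintf(
    "preprocess [%s]: %d in, %d unparsable, %d salt-stripped, %d neutralized, %d outside logS [-10, 0], %d out",
    dataset_kind, n_input, n_unparsable, n_stripped, n_neutralized,
    n_filtered, nrow(records)))
  rownames(records) <- NULL
  attr(records, "report") <- report
  attr(records, "molecules") <- unname(mols)
  records
}

#' Random 81:9:10 train/evaluation/test split
#'
#' Two-stage split under a fixed seed: 10% of the records are held out as the
#' test set (floor), then 10% of the remainder becomes the evaluation set
#' (floor), leaving 81% (up to rounding) for training. The same seed always
#' yields the same partitions, so every model can be compared on identical
#' data.
#'
#' @param n number of records.
#' @param seed integer seed.
#' @param ratios target percentages, kept at `c(81, 9, 10)`.
#' @return a `split_spec`: disjoint index vectors `train`, `eval`, `test`
#'   covering `1:n`.
#' @examples
#' s <- split_dataset(100, seed = 7)
#' lengths(s[c("train", "eval", "test")])  # 81, 9, 10
#' @export
split_dataset <- function(n, seed = 1L, ratios = c(81, 9, 10)) {
  stopifnot(length(ratios) == 3L, sum(ratios) == 100)
  if (n < 3L) stop("need at least 3 records to populate all partitions",
                   call. = FALSE)
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)
  perm <- sample.int(n)
  n_test <- max(1L, floor(n * ratios[3] / 100))
  rest <- n - n_test
  n_eval <- max(1L, floor(rest * ratios[2] / (ratios[1] + ratios[2])))
  test <- sort(perm[seq_len(n_test)])
  eval_ <- sort(perm[n_test + seq_len(n_eval)])
  train <- sort(perm[(n_test + n_eval + 1L):n])
  if (!length(train)) stop("need at least 3 records to populate all partitions",
                           call. = FALSE)
  structure(list(train = train, eval = eval_, test = test,
                 n = n, seed = as.integer(seed), ratios = ratios),
            class = "split_spec")
}

#' @export
print.split_spec <- function(x, ...) {
  cat(sprintf("<split_spec> n=%d seed=%d: train %d / eval %d / test %d\n",
              x$n, x$seed, length(x$train), length(x$eval), length(x$test)))
  invisible(x)
}

#' Per-property offset transform (shift by the minimum)
#'
#' Each property is shifted by its dataset minimum so that all training
#' targets are non-negative; RMSE is invariant under the shift, so metrics on
#' either scale agree.
#'
#' @param targets numeric matrix or data frame of property values (NA =
#'   missing), columns named by property.
#' @return an `offset_transform` holding the per-property minima.
#' @export
offset_fit <- function(targets) {
  targets <- as.matrix(targets)
  offsets <- vapply(seq_len(ncol(targets)), function(j) {
    v <- targets[, j]
    if (all(is.na(v))) stop(sprintf("property '%s' has no observed values",
                                    colnames(targets)[j]), call. = FALSE)
    min(v, na.rm = TRUE)
  }, numeric(1))
  names(offsets) <- colnames(targets)
  structure(list(offsets = offsets), class = "offset_transform")
}

#' @rdname offset_fit
#' @param transform an `offset_transform`.
#' @return `offset_apply` returns shifted values (minimum maps to 0);
#'   `offset_invert` restores the original scale.
#' @export
offset_apply <- function(transform, targets) {
  targets <- as.matrix(targets)
  sweep(targets, 2, transform$offsets[colnames(targets)], `-`)
}

#' @rdname offset_fit
#' @export
offset_invert <- function(transform, targets) {
  targets <- as.matrix(targets)
  sweep(targets, 2, transform$offsets[colnames(targets)], `+`)
}

#' Root mean squared error
#'
#' @param pred,obs equal-length numeric vectors; pairs with a missing
#'   observation are dropped.
#' @return `sqrt(mean((pred - obs)^2))`.
#' @export
rmse <- function(pred, obs) {
  if (length(pred) != length(obs)) {
    stop("pred and obs must have equal length", call. = FALSE)
  }
  keep <- !is.na(obs) & !is.na(pred)
  if (!any(keep)) stop("rmse of empty vectors", call. = FALSE)
  sqrt(mean((pred[keep] - obs[keep])^2))
}

#' Combined RMSE (sum over properties)
#'
#' Model selection metric: per-property RMSEs on the evaluation set are
#' summed.
#'
#' @param per_property numeric vector (or list) of per-property RMSEs.
#' @return their sum.
#' @export
combined_rmse <- function(per_property) {
  x <- unlist(per_property)
  stopifnot(length(x) >= 1L, all(!is.na(x)))
  sum(x)
}

#' Bootstrap 95% confidence interval for the test RMSE
#'
#' Each replicate recomputes the RMSE on a random 90% subset of the test
#' pairs drawn without replacement (the default reading of "leaving out 10%");
#' classical resampling with replacement is available behind `method`.
#'
#' @param pred,obs test-set predictions and observations.
#' @param reps bootstrap replicates.
#' @param leave_out fraction left out per replicate.
#' @param seed integer seed; identical seeds give identical intervals.
#' @param method `"subsample"` (without replacement) or `"resample"`.
#' @return numeric `c(lower, upper)`, the 2.5th and 97.5th percentiles of the
#'   replicate RMSEs; the replicates are attached as attribute `"replicates"`.
#' @export
bootstrap_ci <- function(pred, obs, reps = 100L, leave_out = 0.10, seed = 1L,
                         method = c("subsample", "resample")) {
  method <- match.arg(method)
  stopifnot(length(pred) == length(obs), length(obs) >= 10L)
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)
  n <- length(obs)
  keep_n <- max(1L, floor(n * (1 - leave_out)))
  reps_rmse <- vapply(seq_len(reps), function(r) {
    idx <- if (method == "subsample") sample.int(n, keep_n)
           else sample.int(n, n, replace = TRUE)
    rmse(pred[idx], obs[idx])
  }, numeric(1))
  ci <- stats::quantile(reps_rmse, c(0.025, 0.975), names = FALSE)
  structure(c(lower = ci[1], upper = ci[2]), replicates = reps_rmse)
}

#' Pick the best of repeated runs
#'
#' @param results list of run results, each carrying a numeric
#'   `test_combined_rmse` element.
#' @return the run with the lowest test combined RMSE; ties break towards the
#'   earliest run.
#' @export
best_of_runs <- function(results) {
  stopifnot(length(results) >= 1L)
  scores <- vapply(results, function(r) r$test_combined_rmse, numeric(1))
  results[[which.min(scores)]]
}
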