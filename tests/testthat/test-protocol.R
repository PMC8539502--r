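# Preprocessing filters, splitting, offsets, metrics and bootstrap CIs.

test_that("exactly seven training strategies exist with the stated property sets", {
  ts <- training_strategies()
  expect_length(ts, 7L)
  expect_setequal(names(ts), c("logD/P/S", "logD/P", "logD/S", "logS/P",
                               "logD", "logS", "logP"))
  expect_setequal(ts[["logD/P/S"]]$properties, c("logd", "logp", "logs"))
  expect_equal(ts[["logP"]]$properties, "logp")
})

test_that("two-property strategies with logP require both properties", {
  rec <- data.frame(smiles = c("C", "CC", "CCC", "CCCC"),
                    logd = c(1, NA, 2, NA),
                    logs = c(NA, NA, 1, 2),
                    logp = c(1, 2, NA, 3))
  expect_equal(strategy_records(rec, "logD/P"), c(TRUE, FALSE, FALSE, FALSE))
  expect_equal(strategy_records(rec, "logS/P"), c(FALSE, FALSE, FALSE, TRUE))
  # without logP any record carrying one property is usable
  expect_equal(strategy_records(rec, "logD/S"), c(TRUE, FALSE, TRUE, TRUE))
  expect_equal(strategy_records(rec, "logD"), c(TRUE, FALSE, TRUE, FALSE))
})

test_that("solubility preprocessing strips salts, filters the logS range and keeps boundaries", {
  rec <- data.frame(
    smiles = c("CCO", "CC(=O)[O-].[Na+]", "CCN", "CCS", "CCC", "CCCC"),
    logd = NA_real_,
    logs = c(-5, -3, -12, 0.5, -10.0, 0.0),
    logp = 1:6)
  out <- suppressMessages(preprocess_records(rec, "solubility"))
  rep_ <- attr(out, "report")
  expect_equal(rep_$n_salt_stripped, 1L)
  expect_equal(rep_$n_logs_filtered, 2L)        # -12 and +0.5 removed
  expect_equal(rep_$n_output, 4L)
  expect_true(all(c(-10.0, 0.0) %in% out$logs))  # strict inequalities
  expect_false(any(out$logs < -10 | out$logs > 0))
  expect_equal(out$smiles[out$logp == 2], "CC(=O)[O-]")  # largest fragment kept
})

test_that("lipophilicity preprocessing only neutralizes and drops unparsable records", {
  rec <- data.frame(smiles = c("CCO", "C(", "CC(=O)[O-]"),
                    logd = c(1, 2, 3), logs = NA_real_, logp = NA_real_)
  expect_warning(out <- suppressMessages(preprocess_records(rec, "lipophilicity")),
                 "unparsable")
  rep_ <- attr(out, "report")
  expect_equal(rep_$n_unparsable, 1L)
  expect_equal(rep_$n_neutralized, 1L)
  expect_equal(rep_$n_logs_filtered, 0L)
  expect_equal(nrow(out), 2L)
})

test_that("split has 81:9:10 sizes, is seeded, disjoint and conserving", {
  sp <- split_dataset(100, seed = 7)
  expect_equal(lengths(sp[c("train", "eval", "test")]),
               c(train = 81L, eval = 9L, test = 10L))
  expect_identical(split_dataset(100, seed = 7), sp)
  expect_false(identical(split_dataset(100, seed = 8), sp))
  set.seed(31)
  for (i in 1:50) {
    n <- sample(3:500, 1)
    s <- split_dataset(n, seed = sample.int(1e6, 1))
    all_idx <- c(s$train, s$eval, s$test)
    expect_equal(sort(all_idx), seq_len(n))        # disjoint union covers 1..n
    expect_equal(length(all_idx), n)
    # two-stage flooring keeps each partition within 2 of its exact quota;
    # conservation (tested above) is the strict contract
    quotas <- c(0.81, 0.09, 0.10) * n
    sizes <- lengths(s[c("train", "eval", "test")])
    expect_true(all(abs(sizes - quotas) < 2))
  }
  expect_error(split_dataset(2), "at least 3")
})

test_that("offset transform shifts by the minimum and round-trips exactly", {
  y <- matrix(c(-2, 0, 3), 3, 1, dimnames = list(NULL, "logp"))
  tr <- offset_fit(y)
  expect_equal(unname(tr$offsets), -2)
  shifted <- offset_apply(tr, y)
  expect_equal(as.numeric(shifted), c(0, 2, 5))
  expect_identical(offset_invert(tr, shifted), y)
  # already non-negative with min 0: identity
  y0 <- matrix(c(0, 1, 4), 3, 1, dimnames = list(NULL, "logs"))
  expect_equal(offset_apply(offset_fit(y0), y0), y0)
  expect_error(offset_fit(matrix(NA_real_, 2, 1,
                                 dimnames = list(NULL, "logd"))),
               "no observed")
})

test_that("RMSE is shift invariant, homogeneous and errors on bad input", {
  expect_equal(rmse(c(1, 2), c(1, 2)), 0)
  expect_equal(rmse(c(0, 2), c(1, 1)), 1)
  set.seed(2)
  pred <- rnorm(20); obs <- rnorm(20)
  expect_equal(rmse(pred + 5, obs + 5), rmse(pred, obs))
  expect_equal(rmse(3 * pred, 3 * obs + 3 * (pred - obs) * 0),
               rmse(pred, obs) * 3, tolerance = 1e-12)
  expect_error(rmse(1:3, 1:4), "equal length")
  expect_error(rmse(numeric(0), numeric(0)), "empty")
})

test_that("combined RMSE sums the per-property values", {
  expect_equal(combined_rmse(c(logd = 0.5, logp = 0.3)), 0.8)
  expect_equal(combined_rmse(0.7), 0.7)
  set.seed(4)
  x <- runif(3)
  expect_true(all(combined_rmse(x) >= x))
})

test_that("bootstrap CI is seeded, ordered and degenerate for constant residuals", {
  set.seed(6)
  obs <- rnorm(50); pred <- obs + rnorm(50, sd = 0.3)
  ci1 <- bootstrap_ci(pred, obs, seed = 9)
  ci2 <- bootstrap_ci(pred, obs, seed = 9)
  expect_identical(ci1, ci2)
  expect_lte(ci1["lower"], ci1["upper"])
  expect_length(attr(ci1, "replicates"), 100L)
  # constant residuals: every subsample has the same RMSE
  cst <- bootstrap_ci(obs + 0.5, obs, seed = 1)
  expect_equal(unname(cst["lower"]), unname(cst["upper"]))
  expect_equal(unname(cst["lower"]), 0.5)
  # resampling variant also honours the seed
  expect_identical(bootstrap_ci(pred, obs, seed = 2, method = "resample"),
                   bootstrap_ci(pred, obs, seed = 2, method = "resample"))
})

test_that("best_of_runs picks the lowest test RMSE with earliest-wins ties", {
  runs <- list(list(id = 1, test_combined_rmse = 0.7),
               list(id = 2, test_combined_rmse = 0.6))
  expect_equal(best_of_runs(runs)$id, 2)
  expect_equal(best_of_runs(runs[1])$id, 1)
  ties <- list(list(id = "a", test_combined_rmse = 0.5),
               list(id = "b", test_combined_rmse = 0.5))
  expect_equal(best_of_runs(ties)$id, "a")
})

test_that("property CSV reader reports per-column presence", {
  path <- tempfile(fileext = ".csv")
  writeLines("smiles,logd,logs,logp\nCCO,1.2,,0.3\nCC,,,-1", path)
  df <- read_property_csv(path)
  expect_equal(attr(df, "presence"), c(logd = 1L, logs = 0L, logp = 2L))
  expect_true(is.na(df$logs[1]))
  unlink(path)
})
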