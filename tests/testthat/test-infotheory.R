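# Output feature extraction and the KSG kNN mutual-information estimator.

fake_out_traj <- function(..., dt = 1) {
  rows <- list(...)
  X <- do.call(rbind, rows)
  times <- (seq_len(ncol(X)) - 1) * dt
  structure(list(stimulus_level = 1,
                 grid = structure(list(t_end = max(times),
                                       n_samples = length(times),
                                       times = times), class = "time_grid"),
                 amounts = X),
            class = "trajectory_set")
}

test_that("features match hand computations on a tiny trajectory", {
  tr <- fake_out_traj(out = c(0, 1, 3, 3), out_i = c(0, 0, 0, 0))
  f <- extract_features(tr, c("out", "out_i"))
  expect_equal(unname(f["maxrate_out"]), 2)       # largest forward difference
  expect_equal(unname(f["maxrate_timing"]), 1)    # earliest occurrence
  expect_equal(unname(f["auc_out"]), 5.5)         # trapezoid
  # silenced channel contributes zeros
  expect_equal(unname(f["auc_out_i"]), 0)
  expect_equal(unname(f["maxrate_out_i"]), 0)
  expect_equal(unname(f["maxrate_timing_i"]), 0)
  # combined parameters obey their defining identities
  expect_equal(unname(f["auc_sum"]), unname(f["auc_out"] + f["auc_out_i"]))
  expect_equal(unname(f["maxrate_or"]),
               max(f[["maxrate_out"]], f[["maxrate_out_i"]]))
  expect_equal(unname(f["min_timing_or"]),
               min(f[["maxrate_timing"]], f[["maxrate_timing_i"]]))
  expect_error(extract_features(tr, c("out", "nope")), "lookup error")
})

test_that("the faster channel wins the OR parameters", {
  tr <- fake_out_traj(out = c(0, 2, 4), out_i = c(0, 5, 6))
  f <- extract_features(tr, c("out", "out_i"))
  expect_equal(unname(f["maxrate_or"]), 5)
  tr0 <- fake_out_traj(out = c(0, 0, 0), out_i = c(0, 0, 0))
  f0 <- extract_features(tr0, c("out", "out_i"))
  expect_true(all(f0 == 0))
})

test_that("features are homogeneous of degree one in the trajectory", {
  set.seed(3)
  y <- cumsum(runif(30)); yi <- cumsum(runif(30))
  tr1 <- fake_out_traj(out = y, out_i = yi, dt = 0.5)
  tr2 <- fake_out_traj(out = 7 * y, out_i = 7 * yi, dt = 0.5)
  f1 <- extract_features(tr1, c("out", "out_i"))
  f2 <- extract_features(tr2, c("out", "out_i"))
  amp <- c("auc_out", "auc_out_i", "maxrate_out", "maxrate_out_i",
           "auc_sum", "maxrate_or")
  tim <- c("maxrate_timing", "maxrate_timing_i", "min_timing_or")
  expect_equal(unname(f2[amp]), unname(7 * f1[amp]), tolerance = 1e-12)
  expect_equal(f2[tim], f1[tim])
})

test_that("feature table is complete over a batch", {
  net <- small_cascade()
  batch <- batch_simulate(net, c(5, 50, 500), time_grid(50, 101))
  tab <- feature_table(batch, output_ids(net))
  expect_equal(nrow(tab), 3)
  expect_equal(tab$stimulus_level, c(5, 50, 500))
  expect_false(anyNA(tab))
  expect_equal(colnames(tab)[-1], sigorg:::FEATURE_NAMES)
})

test_that("KSG estimator hits analytic Gaussian MI (quick calibration)", {
  # smaller n / fewer seeds than the full acceptance check
  errs <- vapply(1:5, function(s) {
    p <- make_known_mi_pairs("gaussian", n = 1000, seed = s, rho = 0.9)
    knn_mutual_information(p$x, p$y, k = 5, jitter_seed = s) - p$mi
  }, numeric(1))
  expect_lt(abs(mean(errs)), 0.07)

  indep <- vapply(1:5, function(s) {
    p <- make_known_mi_pairs("independent", n = 1000, seed = s)
    knn_mutual_information(p$x, p$y, k = 5, jitter_seed = s)
  }, numeric(1))
  expect_lt(mean(indep), 0.07)
})

test_that("KSG estimator is deterministic and validates inputs", {
  p <- make_known_mi_pairs("gaussian", n = 200, seed = 1, rho = 0.5)
  a <- knn_mutual_information(p$x, p$y, jitter_seed = 4)
  b <- knn_mutual_information(p$x, p$y, jitter_seed = 4)
  expect_identical(a, b)
  expect_error(knn_mutual_information(1:10, 1:9), "domain error")
  expect_error(knn_mutual_information(1:4, 1:4, k = 5), "domain error")
  expect_error(knn_mutual_information(1:10, 1:10, k = 0), "domain error")
})

test_that("MI is invariant under monotone reparameterization (approx.)", {
  p <- make_known_mi_pairs("gaussian", n = 1000, seed = 9, rho = 0.8)
  base <- knn_mutual_information(p$x, p$y, jitter_seed = 1)
  mono <- knn_mutual_information(exp(p$x), p$y^3 + 2 * p$y, jitter_seed = 1)
  expect_lt(abs(base - mono), 0.1)
})

test_that("an exact copy dominates any noisy copy at the same n", {
  p <- make_known_mi_pairs("deterministic", n = 500, seed = 2)
  exact <- knn_mutual_information(p$x, p$y, jitter_seed = 1)
  rngstate <- set.seed(33)
  noisy <- knn_mutual_information(p$x, p$y + rnorm(500, sd = 0.3),
                                  jitter_seed = 1)
  expect_gt(exact, noisy)
})

test_that("parameter ranking orders informative above uninformative", {
  set.seed(44)
  lev <- seq(1, 500, length.out = 300)
  tab <- data.frame(stimulus_level = lev,
                    informative = log1p(lev),              # monotone in level
                    noise = rnorm(300),                    # independent
                    constant = rep(1, 300))
  rk <- rank_parameters(tab, k = 5)
  expect_equal(rk$parameter[1], "informative")
  expect_lt(rk$mi[rk$parameter == "constant"], 0.05)
  expect_gt(rk$mi[rk$parameter == "informative"],
            rk$mi[rk$parameter == "noise"])
  # duplicated column gives identical MI
  tab2 <- data.frame(stimulus_level = lev, a = log1p(lev), b = log1p(lev))
  rk2 <- rank_parameters(tab2)
  expect_equal(rk2$mi[1], rk2$mi[2])
  expect_equal(rk2$parameter, c("a", "b"))  # stable sort by name on ties
})
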