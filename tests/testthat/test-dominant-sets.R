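# Dominant-set extraction by replicator dynamics, peel clustering,
# permutation chance level.

test_that("degenerate inputs yield flagged singleton sets", {
  A1 <- matrix(0, 1, 1)
  ds <- extract_dominant_set(A1)
  expect_equal(ds$members, 1L)
  expect_equal(ds$cohesiveness, 0)
  expect_true(ds$degenerate)

  A0 <- matrix(0, 4, 4)
  ds0 <- extract_dominant_set(A0)
  expect_equal(ds0$members, 1L)
  expect_true(ds0$degenerate)
})

test_that("uniform similarity keeps the barycenter as fixed point", {
  for (n in c(3, 6, 10)) {
    A <- matrix(0.5, n, n); diag(A) <- 0
    ds <- extract_dominant_set(A)
    expect_equal(sort(ds$members), 1:n)
    expect_equal(unname(ds$membership), rep(1 / n, n), tolerance = 1e-7)
    expect_equal(ds$cohesiveness, 0.5 * (n - 1) / n, tolerance = 1e-9)
  }
})

test_that("two planted cliques: the dominant set is one full block and
           matches exhaustive subset search", {
  A <- block_similarity(c(4, 4), within = 0.9, between = 0.01)
  ds <- extract_dominant_set(A)
  expect_true(identical(sort(ds$members), 1:4) ||
                identical(sort(ds$members), 5:8))
  oracle <- exhaustive_dominant_set(A)
  expect_equal(ds$cohesiveness, oracle$f, tolerance = 1e-8)
  expect_equal(sort(ds$members), oracle$subset)
})

test_that("replicator ascent of the cohesiveness is monotone", {
  set.seed(21)
  for (trial in 1:10) {
    n <- sample(5:15, 1)
    A <- matrix(runif(n * n), n); A <- (A + t(A)) / 2; diag(A) <- 0
    ds <- extract_dominant_set(A, trace = TRUE)
    f <- attr(ds, "f_trace")
    expect_true(all(diff(f) >= -1e-12))
  }
})

test_that("extraction agrees with the exhaustive oracle on random matrices", {
  set.seed(31)
  n_trials <- 40  # the full-size calibration lives in the acceptance suite
  hits <- 0
  for (trial in seq_len(n_trials)) {
    n <- sample(4:8, 1)
    A <- matrix(runif(n * n), n); A <- (A + t(A)) / 2; diag(A) <- 0
    ds <- extract_dominant_set(A)
    oracle <- exhaustive_dominant_set(A)
    if (abs(ds$cohesiveness - oracle$f) < 1e-6) hits <- hits + 1
  }
  expect_gte(hits / n_trials, 0.95)
})

test_that("peel clustering recovers planted blocks and orders by cohesiveness", {
  A <- block_similarity(c(5, 4, 3), within = 0.9, between = 0.01)
  cl <- peel_clustering(A)
  expect_length(cl$groups, 3)
  expect_true(same_partition(cl$labels, attr(A, "labels")))
  coh <- vapply(cl$groups, `[[`, numeric(1), "cohesiveness")
  expect_true(all(diff(coh) <= 0))
  # most cohesive group = largest block (higher internal average)
  expect_equal(sort(cl$groups[[1]]$members), 1:5)
  # labels cover all points, sizes sum to N
  expect_equal(sort(unique(cl$labels)), seq_along(cl$groups))
  expect_equal(sum(vapply(cl$groups, function(g) length(g$members),
                          integer(1))), 12)
})

test_that("forced outcomes: N=2 pair and all-zero similarity", {
  A <- matrix(c(0, 0.8, 0.8, 0), 2)
  cl <- peel_clustering(A)
  expect_length(cl$groups, 1)
  expect_equal(sort(cl$groups[[1]]$members), 1:2)

  cl0 <- peel_clustering(matrix(0, 3, 3))
  expect_equal(length(cl$labels), 2)
  expect_true(all(table(cl0$labels) == 1))  # falls apart into singletons
})

test_that("clustering is invariant to input point order up to relabeling", {
  A <- block_similarity(c(4, 3, 5), within = 0.8, between = 0.05)
  cl <- peel_clustering(A)
  set.seed(9)
  for (rep in 1:5) {
    perm <- sample(nrow(A))
    clp <- peel_clustering(A[perm, perm])
    expect_true(same_partition(cl$labels[perm], clp$labels))
  }
})

test_that("chance level separates structure from permutation noise", {
  # strong two-group structure with continuous similarities
  pp <- make_planted_profiles(n_groups = 2, n_per_group = 10, T = 50,
                              noise_sd = 0.03, seed = 8)
  A <- similarity_from_distances(pairwise_distances(pp$profiles))
  thr <- chance_level(A, n_perm = 200, alpha = 0.005, seed = 2)
  cl <- peel_clustering(A, chance_threshold = thr)
  expect_gte(length(cl$groups), 2)
  expect_true(same_partition(cl$labels, pp$labels))
  for (g in cl$groups[1:2]) expect_gt(g$cohesiveness, thr)
  # alpha = 1 limit: threshold collapses to the distribution minimum
  thr_all <- chance_level(A, n_perm = 100, alpha = 1 - 1e-12, seed = 2)
  expect_equal(as.numeric(thr_all), min(attr(thr_all, "distribution")),
               tolerance = 1e-6)
  expect_error(chance_level(A, n_perm = 10), "n_perm")
})

test_that("cohesiveness table reports rank, size and chance level", {
  A <- block_similarity(c(4, 4), within = 0.9, between = 0.01)
  thr <- chance_level(A, n_perm = 100, alpha = 0.05, seed = 1)
  cl <- peel_clustering(A, chance_threshold = thr)
  tab <- cohesiveness_table(cl)
  expect_equal(tab$rank, seq_len(nrow(tab)))
  expect_equal(sum(tab$size), 8)
  expect_true(all(tab$chance_level == as.numeric(thr)))
})
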