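test_that("bootstrap ensembles are reproducible and honestly re-estimated", {
  sim <- simulate_country(4, 3, n = 300, seed = 61)
  e1 <- nonparametric_bootstrap(sim$matrix, B = 5, seed = 7)
  e2 <- nonparametric_bootstrap(sim$matrix, B = 5, seed = 7)
  expect_identical(e1$weights, e2$weights)
  e3 <- nonparametric_bootstrap(sim$matrix, B = 5, seed = 8)
  expect_false(identical(e1$weights, e3$weights))
  expect_equal(dim(e1$weights), c(7, 7, 5))
})

test_that("bootstrap replicate means track a strong edge", {
  P <- matrix(0, 5, 5); P[1, 2] <- P[2, 1] <- 0.6
  m <- sample_likert(true_network(P, rep("l", 5)), 1000, seed = 62)
  ens <- nonparametric_bootstrap(m, B = 200, seed = 1)
  point <- ens$point$weights[1, 2]
  expect_lt(abs(mean(ens$weights[1, 2, ]) - point), 0.1)
})

test_that("degenerate resamples are redrawn with a message", {
  # one near-constant item: many resamples miss the single informative row
  vals <- cbind(a = rep(1:5, 4), b = rep(c(1, 5), 10), c = c(2L, rep(1L, 19)))
  cb <- codebook(c("a", "b", "c"), "lifestyle")
  m <- survey_matrix(vals, cb)
  expect_message(nonparametric_bootstrap(m, B = 3, seed = 3), "redrawn")
})

test_that("edge CIs use empirical quantiles of the replicates", {
  arr <- array(0, c(3, 3, 50))
  arr[1, 2, ] <- arr[2, 1, ] <- 0.4          # constant edge
  ens <- fake_ensemble(arr)
  ci <- edge_ci(ens)
  row <- ci[ci$item_a == "V1" & ci$item_b == "V2", ]
  expect_equal(row$lower, 0.4)
  expect_equal(row$upper, 0.4)               # zero width for constants
  expect_equal(ci$lower[ci$item_a == "V1" & ci$item_b == "V3"], 0)
  # quantile rule is type 7 on the replicate values
  arr[1, 2, ] <- arr[2, 1, ] <- seq(0, 1, length.out = 50)
  ci2 <- edge_ci(fake_ensemble(arr), level = 0.9)
  expect_equal(ci2$lower[1], quantile(seq(0, 1, length.out = 50), 0.05,
                                      type = 7, names = FALSE))
  expect_warning(edge_ci(fake_ensemble(arr[, , 1:10])), "B < 20")
})

test_that("a true-zero edge's bootstrap interval covers zero", {
  P <- matrix(0, 4, 4); P[1, 2] <- P[2, 1] <- 0.5
  m <- sample_likert(true_network(P, rep("l", 4)), 1000, seed = 63)
  ens <- nonparametric_bootstrap(m, B = 200, seed = 2)
  ci <- edge_ci(ens)
  zero_row <- ci[ci$item_a == "L3" & ci$item_b == "L4", ]
  expect_lte(zero_row$lower, 0)
  expect_gte(zero_row$upper, 0)
  strong <- ci[ci$item_a == "L1" & ci$item_b == "L2", ]
  expect_gt(strong$lower, 0)
})

test_that("case-dropping at q = 0 reproduces the full-sample centrality", {
  P <- matrix(0, 5, 5); P[1, 2] <- P[2, 1] <- 0.5
  m <- sample_likert(true_network(P, rep("l", 5)), 400, seed = 64)
  prof <- case_dropping_bootstrap(m, grid = c(0, 0.3), B = 5, seed = 5)
  at0 <- prof$correlations$correlation[prof$correlations$proportion == 0]
  expect_true(all(at0 == 1))
})

test_that("undersized subsets are skipped, CS computed on the rest", {
  sim <- simulate_country(5, 0, n = 20, n_bridge = 0, seed = 65)
  expect_warning(
    prof <- case_dropping_bootstrap(sim$matrix, B = 3, seed = 1),
    "skipped")
  expect_true(length(prof$skipped) >= 1)
  expect_true(is.numeric(cs_coefficient(prof)))
})

test_that("CS coefficient follows its definitional lattice", {
  expect_equal(cs_coefficient(fake_profile(10)), 0.75)  # all pass
  expect_equal(cs_coefficient(fake_profile(0)), 0)      # none pass
  expect_equal(cs_coefficient(fake_profile(5)), 0.36)   # 5th of 10 points
  expect_equal(cs_coefficient(fake_profile(3)), 0.21)
  # monotone rule: a later passing point cannot rescue an earlier failure
  pr <- fake_profile(2)
  good <- pr$correlations$proportion == pr$grid[6]
  pr$correlations$correlation[good] <- 0.95
  expect_equal(cs_coefficient(pr), 0.13)
})

test_that("difference tests flag dominance and respect conventions", {
  set.seed(66)
  B <- 200
  arr <- array(0, c(3, 3, B))
  # V1-V3 edge strong and variable; V2-V3 weak: V1 dominates V2 in every
  # replicate, V3 tracks V1
  w13 <- 0.45 + rnorm(B, 0, 0.03)
  w23 <- 0.10 + rnorm(B, 0, 0.03)
  arr[1, 3, ] <- arr[3, 1, ] <- w13
  arr[2, 3, ] <- arr[3, 2, ] <- w23
  ens <- fake_ensemble(arr)
  dt <- centrality_difference_test(ens)
  expect_s3_class(dt, "difference_test")
  expect_lt(dt$adjusted_p["V1", "V2"], 0.05)
  expect_true(dt$significant["V1", "V2"])
  # adjusted never below raw; matrices symmetric; diagonal unflagged
  expect_true(all(dt$adjusted_p >= dt$raw_p - 1e-15))
  expect_equal(dt$adjusted_p, t(dt$adjusted_p))
  expect_false(any(diag(dt$significant)))
  # identical replicate distributions -> p = 1 by the zero-difference rule
  arr2 <- arr; arr2[2, 3, ] <- arr2[3, 2, ] <- w13
  dt2 <- centrality_difference_test(fake_ensemble(arr2))
  expect_equal(dt2$raw_p["V1", "V2"], 1)
  expect_false(dt2$significant["V1", "V2"])
})

test_that("bridge index difference tests use the community partition", {
  set.seed(67)
  B <- 100
  arr <- array(0, c(3, 3, B))
  arr[1, 3, ] <- arr[3, 1, ] <- 0.4 + rnorm(B, 0, 0.02)  # cross edge
  arr[1, 2, ] <- arr[2, 1, ] <- 0.5 + rnorm(B, 0, 0.02)  # within edge
  ens <- fake_ensemble(arr, community = setNames(c("a", "a", "b"),
                                                 paste0("V", 1:3)))
  dt <- centrality_difference_test(ens, index = "BEI1")
  # replicate BEI of V2 is exactly zero (its only edge is within-community)
  expect_true(all(dt$replicates[, "V2"] == 0))
  expect_lt(dt$adjusted_p["V1", "V2"], 0.05)
})

test_that("full-pipeline stability run is seed-deterministic", {
  sim <- simulate_country(4, 0, n = 400, n_bridge = 0, seed = 68)
  p1 <- case_dropping_bootstrap(sim$matrix, grid = c(0.1, 0.3), B = 10,
                                seed = 9)
  p2 <- case_dropping_bootstrap(sim$matrix, grid = c(0.1, 0.3), B = 10,
                                seed = 9)
  expect_identical(p1$correlations, p2$correlations)
  expect_identical(cs_coefficient(p1), cs_coefficient(p2))
})
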