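test_that("correlation_matrix validates input and flags repairs", {
  X <- cbind(a = c(1, 2, 3, 4), b = c(2, 1, 4, 3), c = c(1, 1, 1, 1))
  expect_error(correlation_matrix(X), "zero-variance.*c")
  expect_error(correlation_matrix(X[1:2, 1:2]), "at least 3")
  # identical columns are reported as a unit correlation
  Y <- cbind(a = c(1, 2, 3, 5), b = c(1, 2, 3, 5), c = c(2, 1, 5, 3))
  S <- correlation_matrix(Y)
  expect_equal(S$matrix["a", "b"], 1)
  expect_false(S$pd_repaired)
  expect_equal(diag(S$matrix), c(a = 1, b = 1, c = 1))
  # independence at n = 20000: tiny off-diagonals
  m <- sample_likert(true_network(matrix(0, 6, 6), rep("l", 6)),
                     20000, seed = 21)
  S2 <- correlation_matrix(m)
  expect_lt(max(abs(S2$matrix[upper.tri(S2$matrix)])), 0.05)
  # listwise deletion drops incomplete rows
  m$values[1, 2] <- NA
  expect_equal(correlation_matrix(m)$n_effective, 19999)
})

test_that("lambda grid spans max|S| down by the min ratio, descending", {
  S <- diag(2); S[1, 2] <- S[2, 1] <- 0.8
  g <- lambda_grid(S, n_lambda = 2, lambda_min_ratio = 0.01)
  expect_equal(g, c(0.8, 0.008))
  g2 <- lambda_grid(S, n_lambda = 50)
  expect_length(g2, 50)
  expect_true(all(diff(g2) < 0))
  expect_warning(g0 <- lambda_grid(diag(3)), "degenerate")
  expect_equal(g0, 0)
})

test_that("glasso endpoints: saturated at 0, empty above max|S|", {
  set.seed(31)
  A <- matrix(rnorm(60), 20, 3); S <- cor(A)
  K0 <- penalised_precision(S, 0)
  expect_lt(max(abs(K0 - solve(S))), 1e-6)
  lam_max <- max(abs(S[upper.tri(S)]))
  K1 <- penalised_precision(S, lam_max + 1e-10)
  expect_true(all(K1[upper.tri(K1)] == 0))
  expect_equal(diag(K1), 1 / diag(S), ignore_attr = TRUE)
})

test_that("glasso solutions satisfy the KKT conditions", {
  set.seed(32)
  for (p in c(4, 8)) {
    B <- matrix(rnorm(300 * p), 300, p) %*% matrix(rnorm(p * p), p, p)
    S <- cor(B)
    for (lam in c(0.02, 0.1, 0.3)) {
      K <- penalised_precision(S, lam)
      expect_lt(glasso_kkt_residual(K, S, lam), 1e-6)
    }
  }
})

test_that("partial correlations match the regression-residual oracle", {
  K <- matrix(c(2, -1, -1, 2), 2, 2)
  expect_equal(to_partial_correlations(K)[1, 2], 0.5)
  expect_true(all(to_partial_correlations(diag(c(1, 2, 3))) == 0))
  expect_error(to_partial_correlations(diag(c(1, -1))), "positive")
  set.seed(33)
  for (p in 3:5) {
    A <- matrix(rnorm(p * p), p, p)
    Sigma <- crossprod(A) + diag(p)      # random PD covariance
    W <- to_partial_correlations(solve(Sigma))
    expect_lt(max(abs(W - pcor_oracle(Sigma))), 1e-8)
  }
})

test_that("EBIC follows its stated convention and edge penalty", {
  # diagonal K on identity S: L = (n/2)(logdet I - tr I) = -np/2
  n <- 100; p <- 2
  expect_equal(ebic_score(diag(p), diag(p), n, gamma = 0.5), n * p)
  # gamma = 0 reduces to the BIC penalty; the E = 1 edge costs log n
  K <- matrix(c(1, .2, .2, 1), 2, 2)
  L <- (n / 2) * (log(det(K)) - sum(diag(2) * K))
  expect_equal(ebic_score(K, diag(2), n, gamma = 0), -2 * L + log(n))
  # the extra EBIC term per edge is 4 gamma log p
  expect_equal(ebic_score(K, diag(2), n, gamma = 0.7) -
                 ebic_score(K, diag(2), n, gamma = 0),
               4 * 0.7 * log(2))
  expect_error(ebic_score(matrix(c(1, 2, 2, 1), 2, 2), diag(2), n),
               "positive definite")
})

test_that("the fitted network is deterministic and counts its edges", {
  sim <- simulate_country(5, 4, n = 600, seed = 41)
  f1 <- likert_ggm(sim$matrix)
  f2 <- likert_ggm(sim$matrix)
  expect_identical(f1$weights, f2$weights)
  expect_equal(f1$total_edges, 36)
  expect_equal(f1$nonzero_edges,
               sum(abs(f1$weights[upper.tri(f1$weights)]) > 1e-8))
  expect_true(all(abs(f1$weights) < 1))
  expect_equal(f1$weights, t(f1$weights))
  expect_equal(diag(f1$weights), setNames(rep(0, 9), f1$item_ids))
  # community labels ride along from the codebook
  expect_equal(unname(f1$community[1:5]), rep("lifestyle", 5))
  # a 15-node set has 105 possible edges
  sim15 <- simulate_country(15, 0, n = 400, n_bridge = 0, seed = 42)
  expect_equal(likert_ggm(sim15$matrix)$total_edges, 105)
})

test_that("independence data yield an empty graph, a strong edge survives", {
  m0 <- sample_likert(true_network(matrix(0, 8, 8), rep("l", 8)),
                      1000, seed = 43)
  expect_equal(likert_ggm(m0)$nonzero_edges, 0)
  P <- matrix(0, 6, 6); P[1, 2] <- P[2, 1] <- 0.6
  m1 <- sample_likert(true_network(P, rep("l", 6)), 1000, seed = 44)
  f <- likert_ggm(m1)
  expect_gt(abs(f$weights[1, 2]), 0.3)
  others <- f$weights[upper.tri(f$weights)]
  expect_equal(sum(abs(others) > 0.3), 1)
})

test_that("edge counts shrink to zero at the top of the penalty path", {
  sim <- simulate_country(6, 0, n = 500, n_bridge = 0, seed = 45)
  S <- correlation_matrix(sim$matrix)
  lams <- lambda_grid(S, n_lambda = 20)
  edges <- vapply(lams, function(l) {
    K <- penalised_precision(S, l)
    sum(abs(K[upper.tri(K)]) > 1e-8)
  }, 0)
  expect_equal(edges[1], 0)                    # largest lambda: empty
  expect_equal(edges[20], 15)                  # lambda -> 0: saturated
})

test_that("model object methods print, summarise, coerce and simulate", {
  sim <- simulate_country(4, 3, n = 500, seed = 46)
  f <- likert_ggm(sim$matrix)
  expect_output(print(f), "likert_ggm: 7 nodes")
  s <- summary(f)
  expect_output(print(s), "top edges")
  expect_identical(coef(f), f$weights)
  pdf(NULL); on.exit(dev.off())
  expect_silent(plot(f))
  sims <- simulate(f, nsim = 2, seed = 5)
  expect_length(sims, 2)
  expect_s3_class(sims[[1]], "survey_matrix")
  expect_equal(sims[[1]]$n, f$n)
})
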