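test_that("dependent-correlation statistic has its structural symmetries", {
  # equal correlations with the third variable -> Z = 0, p = 1
  r <- dependent_correlation_test(0.4, 0.4, 0.3, 50)
  expect_equal(r$z, 0)
  expect_equal(r$p, 1)
  # swapping the two correlations flips the sign, same p
  a <- dependent_correlation_test(0.8, 0.2, 0.3, 100)
  b <- dependent_correlation_test(0.2, 0.8, 0.3, 100)
  expect_equal(a$z, -b$z)
  expect_equal(a$p, b$p)
  # strongly different profiles are decisively rejected (frozen value from
  # evaluating the closed form)
  expect_gt(a$z, 6)
  expect_equal(a$z, 6.714545, tolerance = 1e-6)
  expect_lt(a$p, 0.01)
  expect_error(dependent_correlation_test(1, 0.2, 0.3, 50), "inside")
  expect_error(dependent_correlation_test(0.5, 0.2, 0.3, 3), "exceed")
})

test_that("dependent-correlation test holds its size under the null", {
  # trivariate normal with rho_az = rho_bz: empirical rejection ~ alpha
  Sig <- matrix(c(1, .5, .4, .5, 1, .4, .4, .4, 1), 3, 3)
  set.seed(202); nrep <- 5000; n <- 100
  rej <- logical(nrep)
  for (r in seq_len(nrep)) {
    X <- MASS::mvrnorm(n, rep(0, 3), Sig)
    R <- cor(X)
    rej[r] <- dependent_correlation_test(R[1, 3], R[2, 3], R[1, 2], n)$p < 0.05
  }
  se <- sqrt(0.05 * 0.95 / nrep)
  expect_lt(abs(mean(rej) - 0.05), 3 * se)
})

test_that("an exact duplicate column is flagged with zero significant share", {
  sim <- simulate_country(8, 0, n = 1000, n_bridge = 0, seed = 4)
  mm <- inject_redundant_item(sim$matrix, "L3", agreement = 1, seed = 1)
  rep <- find_redundant_pairs(mm)
  hit <- rep$bad_pairs[rep$bad_pairs$item_a == "L3" &
                       rep$bad_pairs$item_b == "L3_dup", ]
  expect_equal(nrow(hit), 1)
  expect_equal(hit$proportion_significant, 0)
})

test_that("independent items are never flagged", {
  m <- sample_likert(true_network(matrix(0, 10, 10), rep("l", 10)),
                     2000, seed = 11)
  expect_equal(nrow(find_redundant_pairs(m)$bad_pairs), 0)
  expect_error(find_redundant_pairs(m$values[, 1:2]), "at least 3")
})

test_that("exact clones are flagged and reduced in every seeded run", {
  hits <- vapply(1:10, function(s) {
    sim <- simulate_country(8, 0, n = 1000, n_bridge = 0, seed = s)
    mm <- inject_redundant_item(sim$matrix, "L3", agreement = 1,
                                seed = s + 40)
    red <- screen_redundant(mm)
    dropped <- attr(red, "dropped_items")
    # exactly one of the clone pair is dropped and maps to the other
    sum(c("L3", "L3_dup") %in% dropped) == 1 &&
      attr(red, "kept_for")[intersect(c("L3", "L3_dup"), dropped)] %in%
        c("L3", "L3_dup")
  }, NA)
  expect_true(all(hits))
})

test_that("grouped reduction collapses a clone cluster to its kept item", {
  # three exact clones of one item mimic the L15-L17 vs L18 overlap: the
  # 18-column matrix reduces to 15 once the keep-list pins the original
  # (independent background items, so the clone group is the only overlap)
  m0 <- sample_likert(true_network(matrix(0, 15, 15), rep("lifestyle", 15)),
                      800, seed = 6)
  mm <- m0
  for (k in 1:3)
    mm <- inject_redundant_item(mm, "L15", agreement = 1, seed = k,
                                clone_id = paste0("C", k))
  expect_equal(length(mm$item_ids), 18)
  rep <- find_redundant_pairs(mm)
  red <- reduce_items(mm, rep, keep = "L15")
  expect_equal(length(red$item_ids), 15)
  expect_setequal(attr(red, "dropped_items"), c("C1", "C2", "C3"))
  expect_true(all(attr(red, "kept_for") == "L15"))
  expect_error(reduce_items(mm, rep, keep = "L1"), "unflagged")
})

test_that("reduction handles empty reports and disjoint pairs", {
  sim <- simulate_country(6, 0, n = 500, n_bridge = 0, seed = 3)
  empty <- find_redundant_pairs(
    sample_likert(true_network(matrix(0, 6, 6), rep("l", 6)), 500, seed = 2))
  out <- reduce_items(sim$matrix, empty)
  expect_identical(out$item_ids, sim$matrix$item_ids)

  mm <- inject_redundant_item(sim$matrix, "L1", 1, seed = 1, clone_id = "D1")
  mm <- inject_redundant_item(mm, "L4", 1, seed = 2, clone_id = "D2")
  rep2 <- find_redundant_pairs(mm)
  red2 <- reduce_items(mm, rep2)
  expect_equal(length(attr(red2, "dropped_items")), 2)
  # never drops an item absent from the flagged pairs
  flagged <- union(rep2$bad_pairs$item_a, rep2$bad_pairs$item_b)
  expect_true(all(attr(red2, "dropped_items") %in% flagged))
})
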