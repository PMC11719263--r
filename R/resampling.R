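#' Nonparametric bootstrap of the network estimate
#'
#' Resamples respondents with replacement `B` times and re-estimates the
#' whole network (correlations -> penalty path -> EBIC selection) on each
#' replicate with the identical tuning settings as the point estimate.
#' A replicate whose resample leaves an item with zero variance is redrawn
#' (at most 10 retries per replicate).
#'
#' @param matrix a [survey_matrix()] or numeric matrix.
#' @param B replicate count (default 1000).
#' @param seed integer seed; ensembles are deterministic given it.
#' @param ... tuning arguments passed to [likert_ggm()] (`items`, `method`,
#'   `gamma`, ...).
#' @return A `bootstrap_ensemble`: `weights` (p x p x B array), `point`
#'   (the full-sample [likert_ggm()] fit), `B`, `seed`,
#'   `scheme = "nonparametric"`.
#' @export
nonparametric_bootstrap <- function(matrix, B = 1000, seed = 1, ...) {
  point <- likert_ggm(matrix, ...)
  X <- if (inherits(matrix, "survey_matrix")) matrix$values else as.matrix(matrix)
  X <- X[, point$item_ids, drop = FALSE]
  n <- nrow(X); p <- ncol(X)
  if (n < 3) stop("bootstrap needs n >= 3")
  set.seed(seed)
  weights <- array(0, c(p, p, B),
                   dimnames = list(point$item_ids, point$item_ids, NULL))
  for (b in seq_len(B)) {
    fit <- NULL
    for (try in 1:10) {
      idx <- sample.int(n, n, replace = TRUE)
      fit <- tryCatch(likert_ggm(X[idx, , drop = FALSE], ...),
                      error = function(e) NULL)
      if (!is.null(fit)) break
      message("bootstrap replicate ", b, " redrawn (degenerate resample)")
    }
    if (is.null(fit))
      stop("bootstrap replicate ", b, " failed after 10 retries")
    weights[, , b] <- fit$weights
  }
  structure(list(weights = weights, point = point, B = B, seed = seed,
                 scheme = "nonparametric"), class = "bootstrap_ensemble")
}

#' @export
print.bootstrap_ensemble <- function(x, ...) {
  cat(sprintf("bootstrap_ensemble: %s, B = %d, %d nodes (seed %d)\n",
              x$scheme, x$B, dim(x$weights)[1], x$seed))
  invisible(x)
}

#' Bootstrap confidence intervals for edge weights
#'
#' Per-edge empirical quantile intervals (type-7 interpolation) at level
#' `level` from a nonparametric ensemble.
#'
#' @param ensemble a [nonparametric_bootstrap()] result.
#' @param level coverage (default 0.95).
#' @return data frame `item_a`, `item_b`, `estimate`, `boot_mean`, `lower`,
#'   `upper` for every node pair.
#' @export
edge_ci <- function(ensemble, level = 0.95) {
  stopifnot(inherits(ensemble, "bootstrap_ensemble"),
            ensemble$scheme == "nonparametric")
  if (ensemble$B < 20)
    warning("B < 20: empirical quantiles are unreliable")
  W <- ensemble$weights
  ids <- dimnames(W)[[1]]
  p <- length(ids)
  ut <- which(upper.tri(diag(p)), arr.ind = TRUE)
  a <- (1 - level) / 2
  out <- data.frame(item_a = ids[ut[, 1]], item_b = ids[ut[, 2]],
                    estimate = ensemble$point$weights[ut],
                    stringsAsFactors = FALSE)
  qs <- t(apply(ut, 1, function(ij)
    quantile(W[ij[1], ij[2], ], c(a, 1 - a), type = 7, names = FALSE)))
  out$boot_mean <- apply(ut, 1, function(ij) mean(W[ij[1], ij[2], ]))
  out$lower <- qs[, 1]; out$upper <- qs[, 2]
  out
}

#' Case-dropping subset bootstrap of a centrality index
#'
#' For each drop proportion `q` in the grid, draws `B` subsamples without
#' replacement of size `round((1 - q) n)`, re-estimates the network and the
#' chosen index, and records the Pearson correlation with the full-sample
#' index. Subsets smaller than p + 1 rows are skipped with a warning. A
#' zero-variance index vector (e.g. an empty network) contributes
#' correlation 0, a conservative convention.
#'
#' @param matrix a [survey_matrix()] or numeric matrix.
#' @param grid drop proportions (default 10 values evenly spaced
#'   0.05-0.75).
#' @param B subsamples per proportion (default 1000).
#' @param seed integer seed.
#' @param index `"EI"` (expected influence) or `"BEI1"` (one-step bridge
#'   expected influence; needs community labels).
#' @param community per-node labels for `"BEI1"` (defaults to the survey
#'   codebook).
#' @param ... tuning arguments passed to [likert_ggm()].
#' @return A `stability_profile`: `correlations` (long data frame
#'   `proportion`, `replicate`, `correlation`), `grid`, `skipped`, `index`,
#'   `B`, `seed`, `point_index` (full-sample index vector).
#' @export
case_dropping_bootstrap <- function(matrix,
                                    grid = seq(0.05, 0.75, length.out = 10),
                                    B = 1000, seed = 1,
                                    index = c("EI", "BEI1"),
                                    community = NULL, ...) {
  index <- match.arg(index)
  point <- likert_ggm(matrix, ...)
  if (is.null(community)) community <- point$community
  idx_fun <- function(fit) {
    if (index == "EI") expected_influence(fit)
    else bridge_expected_influence(fit, community[fit$item_ids])
  }
  full <- idx_fun(point)
  X <- if (inherits(matrix, "survey_matrix")) matrix$values else as.matrix(matrix)
  X <- X[, point$item_ids, drop = FALSE]
  n <- nrow(X); p <- ncol(X)
  set.seed(seed)
  rows <- list(); skipped <- numeric()
  safe_cor <- function(a, b) {
    if (stats::sd(a) == 0 || stats::sd(b) == 0) 0 else cor(a, b)
  }
  for (q in grid) {
    m <- round((1 - q) * n)
    if (m < p + 1) {
      warning(sprintf("drop proportion %.2f leaves %d < p+1 rows; skipped",
                      q, m))
      skipped <- c(skipped, q)
      next
    }
    cors <- numeric(B)
    for (b in seq_len(B)) {
      sub <- X[sample.int(n, m), , drop = FALSE]
      fit <- tryCatch(likert_ggm(sub, ...), error = function(e) NULL)
      cors[b] <- if (is.null(fit)) 0 else safe_cor(full, idx_fun(fit))
    }
    rows[[length(rows) + 1]] <- data.frame(proportion = q,
                                           replicate = seq_len(B),
                                           correlation = cors)
  }
  structure(list(correlations = do.call(rbind, rows), grid = grid,
                 skipped = skipped, index = index, B = B, seed = seed,
                 point_index = full),
            class = "stability_profile")
}

#' Correlation-stability (CS) coefficient
#'
#' The largest drop proportion `q*` such that at every proportion
#' `q <= q*` in the grid, at least `prob` of the subsample centralities
#' correlate `>= cor_threshold` with the full-sample centrality; `0` when
#' the smallest proportion already fails. A CS value above 0.25 is
#' conventionally acceptable, above 0.5 preferable. Reported rounded to 2
#' decimals, so the default grid yields the lattice
#' \{0.05, 0.13, 0.21, 0.28, 0.36, 0.44, 0.52, 0.59, 0.67, 0.75\}.
#'
#' @param profile a [case_dropping_bootstrap()] result.
#' @param cor_threshold correlation cut-off (default 0.7).
#' @param prob required fraction of replicates above it (default 0.95).
#' @return CS coefficient (numeric scalar, 2 decimals).
#' @export
cs_coefficient <- function(profile, cor_threshold = 0.7, prob = 0.95) {
  stopifnot(inherits(profile, "stability_profile"))
  cc <- profile$correlations
  if (is.null(cc) || nrow(cc) == 0) return(0)
  qs <- sort(unique(cc$proportion))
  cs <- 0
  for (q in qs) {
    frac <- mean(cc$correlation[cc$proportion == q] >= cor_threshold)
    if (frac >= prob) cs <- q else break
  }
  round(cs, 2)
}

#' Pairwise centrality difference tests
#'
#' Paired two-sided Wilcoxon signed-rank tests on the B bootstrap replicate
#' values of a centrality index for every node pair, Holm-adjusted across
#' all p(p-1)/2 comparisons. Pairs with identical replicate values (all
#' differences zero) get p = 1 by convention.
#'
#' @param ensemble a [nonparametric_bootstrap()] result (B >= 30 advised).
#' @param index `"EI"` or `"BEI1"`.
#' @param alpha flag threshold on adjusted p-values (default 0.05).
#' @param community per-node labels for `"BEI1"`.
#' @return A `difference_test`: `raw_p`, `adjusted_p`, `significant`
#'   (symmetric node x node matrices; diagonal non-significant), `alpha`,
#'   `index`, `replicates` (B x p index matrix).
#' @export
centrality_difference_test <- function(ensemble, index = c("EI", "BEI1"),
                                       alpha = 0.05, community = NULL) {
  stopifnot(inherits(ensemble, "bootstrap_ensemble"),
            ensemble$scheme == "nonparametric")
  index <- match.arg(index)
  W <- ensemble$weights
  ids <- dimnames(W)[[1]]
  p <- length(ids); B <- ensemble$B
  if (is.null(community)) community <- ensemble$point$community
  vals <- matrix(0, B, p, dimnames = list(NULL, ids))
  for (b in seq_len(B)) {
    vals[b, ] <- if (index == "EI") rowSums(W[, , b])
    else bridge_expected_influence(W[, , b], community[ids])
  }
  raw <- matrix(1, p, p, dimnames = list(ids, ids))
  for (i in seq_len(p - 1)) for (j in (i + 1):p) {
    d <- vals[, i] - vals[, j]
    pv <- if (all(d == 0)) 1 else
      suppressWarnings(wilcox.test(vals[, i], vals[, j], paired = TRUE,
                                   exact = NULL)$p.value)
    if (is.na(pv)) pv <- 1
    raw[i, j] <- raw[j, i] <- pv
  }
  ut <- upper.tri(raw)
  adj <- raw
  adj[ut] <- p.adjust(raw[ut], method = "holm")
  adj[lower.tri(adj)] <- t(adj)[lower.tri(adj)]
  sig <- adj < alpha
  diag(sig) <- FALSE
  structure(list(raw_p = raw, adjusted_p = adj, significant = sig,
                 alpha = alpha, index = index, replicates = vals),
            class = "difference_test")
}

#' @export
print.difference_test <- function(x, ...) {
  cat(sprintf("difference_test (%s): %d significant of %d pairs at alpha = %g (Holm)\n",
              x$index, sum(x$significant[upper.tri(x$significant)]),
              sum(upper.tri(x$significant)), x$alpha))
  invisible(x)
}
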