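#' Correlation matrix of a survey item set
#'
#' Listwise-complete Pearson (default) or Spearman correlations on the
#' integer scores. A zero-variance item is an error. Should the matrix ever
#' be indefinite (possible only under future pairwise options), the negative
#' eigenvalues are clipped at zero and the result rescaled to a correlation
#' matrix, with the repair flagged.
#'
#' @param matrix a [survey_matrix()] or numeric matrix.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return A `cor_estimate`: `matrix`, `n_effective`, `method`,
#'   `pd_repaired`.
#' @export
correlation_matrix <- function(matrix, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  X <- if (inherits(matrix, "survey_matrix")) matrix$values else as.matrix(matrix)
  X <- X[complete.cases(X), , drop = FALSE]
  if (nrow(X) < 3) stop("need at least 3 complete rows")
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0))
    stop("zero-variance item(s): ",
         paste(colnames(X)[sds == 0], collapse = ", "))
  R <- cor(X, method = method)
  repaired <- FALSE
  ev <- eigen(R, symmetric = TRUE)
  if (min(ev$values) < 0) {
    vals <- pmax(ev$values, 0)
    R <- ev$vectors %*% diag(vals) %*% t(ev$vectors)
    R <- stats::cov2cor(R)
    dimnames(R) <- list(colnames(X), colnames(X))
    repaired <- TRUE
  }
  R <- (R + t(R)) / 2
  diag(R) <- 1
  structure(list(matrix = R, n_effective = nrow(X), method = method,
                 pd_repaired = repaired), class = "cor_estimate")
}

#' Penalty grid for the graphical lasso path
#'
#' `n_lambda` log-spaced values descending from
#' `lambda_max = max |off-diagonal of S|` to
#' `lambda_max * lambda_min_ratio`.
#'
#' @param S a `cor_estimate` or correlation matrix.
#' @param n_lambda grid length (default 100).
#' @param lambda_min_ratio smallest/largest penalty ratio (default 0.01).
#' @return Descending numeric vector; a degenerate all-zero off-diagonal
#'   matrix yields `0` with a warning.
#' @export
lambda_grid <- function(S, n_lambda = 100, lambda_min_ratio = 0.01) {
  stopifnot(n_lambda >= 2, lambda_min_ratio > 0, lambda_min_ratio < 1)
  R <- if (inherits(S, "cor_estimate")) S$matrix else S
  lam_max <- max(abs(R[upper.tri(R)]))
  if (lam_max == 0) {
    warning("all off-diagonal correlations are zero; degenerate single-value grid")
    return(0)
  }
  exp(seq(log(lam_max), log(lam_max * lambda_min_ratio),
          length.out = n_lambda))
}

#' Solve the graphical lasso at one penalty
#'
#' Maximises `log det K - tr(SK) - lam * sum_{i != j} |K_ij|` (diagonal not
#' penalised) by block coordinate descent.
#'
#' @param S a `cor_estimate` or PSD covariance/correlation matrix.
#' @param lam penalty >= 0.
#' @param tol convergence tolerance (default 1e-8).
#' @param maxit outer iteration cap.
#' @return Symmetric positive definite precision matrix with exact zeros.
#' @export
penalised_precision <- function(S, lam, tol = 1e-8, maxit = 1000) {
  R <- if (inherits(S, "cor_estimate")) S$matrix else as.matrix(S)
  stopifnot(lam >= 0)
  fit <- .glasso_path_cpp(R, lam, tol = tol, maxit = maxit)
  K <- fit$theta[[1]]
  dimnames(K) <- dimnames(R)
  K
}

#' Convert a precision matrix to partial correlations
#'
#' `w_ij = -K_ij / sqrt(K_ii K_jj)`, zero diagonal; exact zeros in `K` stay
#' exact zeros.
#'
#' @param K symmetric precision matrix with positive diagonal.
#' @return Symmetric partial-correlation matrix with zero diagonal.
#' @export
to_partial_correlations <- function(K) {
  d <- diag(K)
  if (any(d <= 0)) stop("precision diagonal must be positive")
  W <- -K / sqrt(outer(d, d))
  diag(W) <- 0
  (W + t(W)) / 2
}

#' Extended BIC of a fitted precision matrix
#'
#' `EBIC = -2 L + E log n + 4 E gamma log p` with
#' `L = (n/2)(log det K - tr(SK))` and `E` the number of nonzero
#' upper-triangle entries (counted with `zero_tolerance`). `gamma = 0`
#' reduces to the ordinary BIC penalty.
#'
#' @param K precision matrix (positive definite).
#' @param S a `cor_estimate` or correlation matrix.
#' @param n sample size.
#' @param gamma EBIC hyperparameter >= 0 (default 0.5).
#' @param zero_tolerance edge-count threshold (default 1e-8).
#' @return Finite numeric EBIC value.
#' @export
ebic_score <- function(K, S, n, gamma = 0.5, zero_tolerance = 1e-8) {
  R <- if (inherits(S, "cor_estimate")) S$matrix else as.matrix(S)
  p <- nrow(K)
  ld <- determinant(K, logarithm = TRUE)
  if (ld$sign <= 0) stop("precision matrix must be positive definite")
  L <- (n / 2) * (as.numeric(ld$modulus) - sum(R * K))
  E <- sum(abs(K[upper.tri(K)]) > zero_tolerance)
  -2 * L + E * log(n) + 4 * E * gamma * log(p)
}

#' Fit a sparse partial-correlation network to Likert survey items
#'
#' The package's central model fit: correlation matrix (listwise complete)
#' -> graphical lasso along a descending log-spaced penalty path (warm
#' starts) -> extended-BIC selection of the penalty -> partial-correlation
#' edge weights. Everything is deterministic given the data.
#'
#' @param x a [survey_matrix()], or a numeric matrix/data frame of scores.
#' @param items optional character vector restricting the fit to an item
#'   subset (e.g. only the lifestyle community).
#' @param method correlation type, `"pearson"` (default) or `"spearman"`.
#' @param n_lambda,lambda_min_ratio penalty-path shape (defaults 100, 0.01).
#' @param gamma EBIC hyperparameter (default 0.5).
#' @param zero_tolerance |weight| below this counts as no edge (default 1e-8).
#' @return An object of class `likert_ggm`: list with `weights` (partial
#'   correlations, zero diagonal), `precision`, `lambda`, `ebic`,
#'   `lambda_path`, `ebic_path`, `nonzero_edges`, `total_edges`, `item_ids`,
#'   `community` (when known), `n`, `cor` (the `cor_estimate`), and the
#'   tuning settings. Methods: [print.likert_ggm()], [summary.likert_ggm()],
#'   [coef.likert_ggm()], [plot.likert_ggm()], [simulate.likert_ggm()].
#' @export
likert_ggm <- function(x, items = NULL, method = c("pearson", "spearman"),
                       n_lambda = 100, lambda_min_ratio = 0.01, gamma = 0.5,
                       zero_tolerance = 1e-8) {
  method <- match.arg(method)
  community <- NULL
  if (inherits(x, "survey_matrix")) {
    community <- setNames(x$codebook$community, x$codebook$id)
    X <- x$values
  } else X <- as.matrix(x)
  if (!is.null(items)) {
    missing_items <- setdiff(items, colnames(X))
    if (length(missing_items))
      stop("unknown item(s): ", paste(missing_items, collapse = ", "))
    X <- X[, items, drop = FALSE]
  }
  p <- ncol(X)
  if (p < 2) stop("a network needs at least 2 items")
  S <- correlation_matrix(X, method = method)
  lams <- lambda_grid(S, n_lambda, lambda_min_ratio)
  path <- .glasso_path_cpp(S$matrix, lams)
  ebics <- vapply(path$theta, ebic_score, 0, S = S, n = S$n_effective,
                  gamma = gamma, zero_tolerance = zero_tolerance)
  best <- which.min(ebics)
  K <- path$theta[[best]]
  dimnames(K) <- dimnames(S$matrix)
  W <- to_partial_correlations(K)
  W[abs(W) <= zero_tolerance] <- 0
  ids <- colnames(S$matrix)
  if (!is.null(community)) community <- community[ids]
  structure(list(
    weights = W, precision = K, lambda = lams[best], lambda_index = best,
    ebic = ebics[best], lambda_path = lams, ebic_path = ebics,
    nonzero_edges = sum(abs(W[upper.tri(W)]) > zero_tolerance),
    total_edges = p * (p - 1) / 2, item_ids = ids, community = community,
    n = S$n_effective, cor = S,
    config = list(method = method, n_lambda = n_lambda,
                  lambda_min_ratio = lambda_min_ratio, gamma = gamma,
                  zero_tolerance = zero_tolerance)),
    class = "likert_ggm")
}

#' @export
print.likert_ggm <- function(x, ...) {
  cat(sprintf("likert_ggm: %d nodes, %d/%d nonzero edges (%.1f%%)\n",
              length(x$item_ids), x$nonzero_edges, x$total_edges,
              100 * x$nonzero_edges / x$total_edges))
  cat(sprintf("  n = %d, lambda = %.4g (EBIC %.1f, gamma %.2g, %s correlations)\n",
              x$n, x$lambda, x$ebic, x$config$gamma, x$config$method))
  invisible(x)
}

#' @describeIn likert_ggm top edges and expected-influence summary.
#' @param object,... method arguments.
#' @param k number of top edges to display.
#' @export
summary.likert_ggm <- function(object, k = 3, ...) {
  out <- list(fit = object, top_edges = top_edges(object, k),
              expected_influence = sort(expected_influence(object),
                                        decreasing = TRUE))
  class(out) <- "summary.likert_ggm"
  out
}

#' @export
print.summary.likert_ggm <- function(x, ...) {
  print(x$fit)
  cat("top edges by |weight|:\n")
  print(x$top_edges, row.names = FALSE)
  cat("expected influence (descending):\n")
  print(round(x$expected_influence, 3))
  invisible(x)
}

#' @describeIn likert_ggm the partial-correlation weight matrix.
#' @export
coef.likert_ggm <- function(object, ...) object$weights

#' @describeIn likert_ggm minimal circle-layout debug plot (edge width
#'   proportional to |weight|; solid = positive, dashed = negative).
#' @export
plot.likert_ggm <- function(x, ...) {
  p <- length(x$item_ids)
  th <- seq(0, 2 * pi, length.out = p + 1)[-(p + 1)]
  xs <- cos(th); ys <- sin(th)
  graphics::plot(xs, ys, type = "n", axes = FALSE, xlab = "", ylab = "",
                 xlim = c(-1.2, 1.2), ylim = c(-1.2, 1.2), asp = 1, ...)
  W <- x$weights
  for (i in seq_len(p - 1)) for (j in (i + 1):p) {
    if (W[i, j] == 0) next
    graphics::segments(xs[i], ys[i], xs[j], ys[j],
                       lwd = 4 * abs(W[i, j]) + 0.2,
                       lty = if (W[i, j] > 0) 1 else 2, col = "grey40")
  }
  graphics::text(1.12 * xs, 1.12 * ys, x$item_ids, cex = 0.8)
  invisible(x)
}

#' @describeIn likert_ggm draw ordinal datasets treating the fitted weights
#'   as the true partial-correlation structure (useful for parametric
#'   checks); returns a list of [survey_matrix()] objects.
#' @param nsim,seed as in [stats::simulate()].
#' @export
simulate.likert_ggm <- function(object, nsim = 1, seed = 1, ...) {
  truth <- true_network(object$weights,
                        community = if (is.null(object$community))
                          rep("all", length(object$item_ids))
                        else unname(object$community),
                        item_ids = object$item_ids)
  lapply(seq_len(nsim), function(s)
    sample_likert(truth, n = object$n, seed = seed + s - 1))
}

#' Karush-Kuhn-Tucker residual of a graphical lasso solution
#'
#' Maximum violation of the stationarity conditions
#' `|S - K^{-1} + lam sign(K)| = 0` on nonzero off-diagonals and
#' `|S - K^{-1}| <= lam` on zeros (diagonal unpenalised).
#'
#' @param K fitted precision matrix.
#' @param S correlation matrix or `cor_estimate` used in the fit.
#' @param lam penalty.
#' @param zero_tolerance classification threshold for zeros.
#' @return Maximum KKT violation (numeric scalar).
#' @export
glasso_kkt_residual <- function(K, S, lam, zero_tolerance = 1e-8) {
  R <- if (inherits(S, "cor_estimate")) S$matrix else as.matrix(S)
  W <- solve(K)
  G <- R - W
  p <- nrow(K)
  viol <- abs(diag(G))
  off <- upper.tri(K)
  nz <- off & abs(K) > zero_tolerance
  zz <- off & !(abs(K) > zero_tolerance)
  viol <- c(viol, abs(G[nz] + lam * sign(K[nz])), pmax(abs(G[zz]) - lam, 0))
  max(viol)
}
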