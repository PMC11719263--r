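#' Define a true partial-correlation network
#'
#' The truth is parameterised by the partial-correlation matrix of a
#' Gaussian graphical model with unit-diagonal precision: precision
#' `K = I` with off-diagonals `K[i,j] = -partial_corr[i,j]`. The implied
#' precision must be positive definite; declared zeros are exact.
#'
#' @param partial_corr p x p symmetric matrix, zero diagonal, entries in
#'   (-1, 1).
#' @param community character label per node (e.g. `"lifestyle"`/`"outcome"`).
#' @param item_ids node labels; defaults to L1..Lk / H1..Hm by community.
#' @return A `true_network` list: `partial_corr`, `precision`, `sigma`
#'   (implied latent correlation matrix), `community`, `item_ids`.
#' @export
true_network <- function(partial_corr, community, item_ids = NULL) {
  p <- nrow(partial_corr)
  stopifnot(ncol(partial_corr) == p, length(community) == p)
  if (max(abs(partial_corr - t(partial_corr))) > 1e-12)
    stop("partial_corr must be symmetric")
  if (any(diag(partial_corr) != 0)) stop("partial_corr diagonal must be zero")
  if (any(abs(partial_corr) >= 1)) stop("partial correlations must lie in (-1,1)")
  K <- diag(p) - partial_corr
  diag(K) <- 1
  ev <- eigen(K, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0)
    stop("implied precision matrix is not positive definite (min eigenvalue ",
         signif(min(ev), 3), ")")
  sigma <- stats::cov2cor(solve(K))
  if (is.null(item_ids)) {
    comm <- unique(community)
    item_ids <- character(p)
    for (ci in seq_along(comm)) {
      idx <- which(community == comm[ci])
      item_ids[idx] <- paste0(toupper(substr(comm[ci], 1, 1)), seq_along(idx))
    }
  }
  dimnames(partial_corr) <- dimnames(K) <- dimnames(sigma) <-
    list(item_ids, item_ids)
  structure(list(partial_corr = partial_corr, precision = K, sigma = sigma,
                 community = setNames(community, item_ids),
                 item_ids = item_ids),
            class = "true_network")
}

#' Generate a random sparse two-community truth
#'
#' Samples a sparse symmetric partial-correlation structure with the
#' requested within-community density (exact edge counts,
#' `round(density * pairs)`) and exactly `n_bridge` cross-community edges,
#' with weights drawn uniformly from `weight_range` (positive, as in the
#' predominantly positive empirical lifestyle/outcome networks). Positive
#' definiteness is enforced by shrinking all off-diagonals by a factor 0.9
#' until the smallest eigenvalue of the unit-diagonal precision exceeds 0.05.
#'
#' @param p_lifestyle,p_outcome nodes per community.
#' @param within_density fraction of within-community pairs that carry an
#'   edge, in \[0, 1\].
#' @param n_bridge exact number of cross-community edges.
#' @param weight_range interval inside (0, 1) for edge weights.
#' @param seed integer seed; the generator is deterministic given it.
#' @param bridge_edges optional explicit data frame (`from`, `to`, `weight`)
#'   of cross-community edges, overriding random placement.
#' @return A [true_network()].
#' @export
generate_true_network <- function(p_lifestyle, p_outcome,
                                  within_density = 0.2, n_bridge = 2,
                                  weight_range = c(0.2, 0.5), seed = 1,
                                  bridge_edges = NULL) {
  stopifnot(within_density >= 0, within_density <= 1,
            weight_range[1] > 0, weight_range[2] < 1)
  set.seed(seed)
  p <- p_lifestyle + p_outcome
  community <- c(rep("lifestyle", p_lifestyle), rep("outcome", p_outcome))
  P <- matrix(0, p, p)
  draw_w <- function(k) runif(k, weight_range[1], weight_range[2])
  add_within <- function(P, idx, density) {
    pairs <- which(upper.tri(diag(length(idx))), arr.ind = TRUE)
    k <- round(density * nrow(pairs))
    if (k > 0) {
      sel <- pairs[sample.int(nrow(pairs), k), , drop = FALSE]
      w <- draw_w(k)
      for (e in seq_len(k)) {
        i <- idx[sel[e, 1]]; j <- idx[sel[e, 2]]
        P[i, j] <- P[j, i] <- w[e]
      }
    }
    P
  }
  P <- add_within(P, seq_len(p_lifestyle), within_density)
  P <- add_within(P, p_lifestyle + seq_len(p_outcome), within_density)
  if (!is.null(bridge_edges)) {
    for (e in seq_len(nrow(bridge_edges))) {
      i <- bridge_edges$from[e]; j <- bridge_edges$to[e]
      P[i, j] <- P[j, i] <- bridge_edges$weight[e]
    }
  } else if (n_bridge > 0) {
    cross <- expand.grid(i = seq_len(p_lifestyle),
                         j = p_lifestyle + seq_len(p_outcome))
    sel <- cross[sample.int(nrow(cross), n_bridge), , drop = FALSE]
    w <- draw_w(n_bridge)
    for (e in seq_len(n_bridge))
      P[sel$i[e], sel$j[e]] <- P[sel$j[e], sel$i[e]] <- w[e]
  }
  # PD repair: global off-diagonal shrink, preserving the zero pattern
  for (try in 0:100) {
    K <- diag(p) - P
    if (min(eigen(K, symmetric = TRUE, only.values = TRUE)$values) >= 0.05)
      return(true_network(P, community))
    if (try == 100)
      stop("could not reach a positive definite precision by rescaling")
    P <- P * 0.9
  }
}

#' Discretisation thresholds for 5-point items
#'
#' Cutpoints partition each item's standard-normal latent scale into the
#' five observed categories. The default gives equal 20% category masses;
#' the `"skewed"` preset shifts each item's cutpoints so the expected
#' category mean matches `target_means` (recycled), emulating the 2.6-3.9
#' item means typical of real lifestyle-change data.
#'
#' @param p number of items.
#' @param type `"equiprobable"` or `"skewed"`.
#' @param target_means per-item expected category means for the skewed
#'   preset (default alternates between 2.7 and 3.6).
#' @return p x 4 matrix of strictly increasing cutpoints.
#' @export
likert_thresholds <- function(p, type = c("equiprobable", "skewed"),
                              target_means = c(2.7, 3.6)) {
  type <- match.arg(type)
  base <- qnorm(c(0.2, 0.4, 0.6, 0.8))
  if (type == "equiprobable")
    return(matrix(base, p, 4, byrow = TRUE))
  target_means <- rep_len(target_means, p)
  t(vapply(target_means, function(m) {
    mean_at <- function(s) {
      cuts <- base - s
      pr <- diff(c(0, pnorm(cuts), 1))
      sum(pr * 1:5)
    }
    s <- uniroot(function(s) mean_at(s) - m, c(-3, 3))$root
    base - s
  }, numeric(4)))
}

#' Sample ordinal survey data from a known truth
#'
#' Draws `n` latent vectors from the multivariate normal with the truth's
#' implied correlation structure and discretises each coordinate by its
#' cutpoints into categories 1-5.
#'
#' @param truth a [true_network()].
#' @param n respondent count (>= 1).
#' @param thresholds optional cutpoint matrix from [likert_thresholds()];
#'   default equiprobable.
#' @param seed integer seed.
#' @param country tag for the generated dataset.
#' @return A [survey_matrix()] whose codebook carries the truth's community
#'   labels.
#' @export
sample_likert <- function(truth, n, thresholds = NULL, seed = 1,
                          country = "synthetic") {
  stopifnot(inherits(truth, "true_network"), n >= 1)
  p <- length(truth$item_ids)
  if (is.null(thresholds)) thresholds <- likert_thresholds(p)
  stopifnot(nrow(thresholds) == p, ncol(thresholds) == 4,
            all(apply(thresholds, 1, function(r) all(diff(r) > 0))))
  set.seed(seed)
  Z <- MASS::mvrnorm(n, mu = rep(0, p), Sigma = truth$sigma)
  Z <- matrix(Z, nrow = n)
  vals <- matrix(NA_integer_, n, p, dimnames = list(NULL, truth$item_ids))
  for (j in seq_len(p))
    vals[, j] <- findInterval(Z[, j], thresholds[j, ]) + 1L
  cb <- codebook(truth$item_ids, community = unname(truth$community))
  survey_matrix(vals, cb, country)
}

#' Append a near-duplicate (redundant) item
#'
#' Clones `source_item` into a new column whose cells equal the source with
#' probability `agreement` and are otherwise re-drawn uniformly from the
#' item's levels. Used to validate the redundancy screen.
#'
#' @param matrix a [survey_matrix()].
#' @param source_item id of the item to clone.
#' @param agreement probability in (0, 1\] that a cell copies the source.
#' @param seed integer seed.
#' @param clone_id id for the new column (default `<source>_dup`).
#' @return A [survey_matrix()] with one extra item in the source's community.
#' @export
inject_redundant_item <- function(matrix, source_item, agreement = 0.95,
                                  seed = 1, clone_id = NULL) {
  stopifnot(inherits(matrix, "survey_matrix"),
            agreement > 0, agreement <= 1)
  j <- match(source_item, matrix$item_ids)
  if (is.na(j)) stop("unknown source item: ", source_item)
  if (is.null(clone_id)) clone_id <- paste0(source_item, "_dup")
  set.seed(seed)
  cb <- matrix$codebook
  lo <- cb$level_min[j]; hi <- cb$level_max[j]
  src <- matrix$values[, j]
  n <- length(src)
  clone <- ifelse(runif(n) <= agreement, src,
                  as.integer(sample(lo:hi, n, replace = TRUE)))
  clone[is.na(src)] <- NA_integer_
  vals <- cbind(matrix$values, clone)
  colnames(vals) <- c(matrix$item_ids, clone_id)
  cb2 <- codebook(c(cb$id, clone_id),
                  community = c(cb$community, cb$community[j]),
                  description = c(cb$description,
                                  paste0("clone of ", source_item)),
                  reverse_coded = c(cb$reverse_coded, cb$reverse_coded[j]),
                  level_min = c(cb$level_min, lo),
                  level_max = c(cb$level_max, hi))
  survey_matrix(vals, cb2, matrix$country)
}

#' Truth with a planted hub node
#'
#' A single-community sparse truth in which one node carries `n_neighbors`
#' strong edges (the hub) while the remaining structure is weak and sparse;
#' used to validate that expected-influence centrality plus difference
#' tests single out the dominant node.
#'
#' @param p node count.
#' @param hub index of the hub node.
#' @param n_neighbors number of strong hub edges.
#' @param hub_weight weight of each hub edge.
#' @param within_density,weight_range background structure (weak, sparse).
#' @param seed integer seed.
#' @param community single community label.
#' @return A [true_network()].
#' @export
planted_hub_truth <- function(p = 15, hub = 1, n_neighbors = 3,
                              hub_weight = 0.4, within_density = 0.1,
                              weight_range = c(0.15, 0.25), seed = 1,
                              community = "lifestyle") {
  set.seed(seed)
  pairs <- which(upper.tri(diag(p)), arr.ind = TRUE)
  P <- matrix(0, p, p)
  k <- round(within_density * nrow(pairs))
  if (k > 0) {
    sel <- pairs[sample.int(nrow(pairs), k), , drop = FALSE]
    w <- runif(k, weight_range[1], weight_range[2])
    for (e in seq_len(k))
      P[sel[e, 1], sel[e, 2]] <- P[sel[e, 2], sel[e, 1]] <- w[e]
  }
  nbrs <- sample(setdiff(seq_len(p), hub), n_neighbors)
  P[hub, ] <- P[, hub] <- 0
  for (j in nbrs) P[hub, j] <- P[j, hub] <- hub_weight
  for (try in 0:100) {
    if (min(eigen(diag(p) - P, symmetric = TRUE,
                  only.values = TRUE)$values) >= 0.05) break
    P <- P * 0.9
  }
  true_network(P, rep(community, p))
}
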