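#' One-step expected influence
#'
#' `EI(i) = sum_j w_ij`: signed sum of a node's edge weights (negative
#' edges stay negative, unlike strength).
#'
#' @param net a [likert_ggm()] fit or a symmetric weight matrix with zero
#'   diagonal.
#' @return Named numeric vector per node.
#' @export
expected_influence <- function(net) {
  W <- if (inherits(net, "likert_ggm")) net$weights else as.matrix(net)
  rowSums(W)
}

#' One-step bridge expected influence
#'
#' `BEI1(i) = sum over j in other communities of w_ij`: signed sum of a
#' node's edges that cross the declared community partition.
#'
#' @param net a [likert_ggm()] fit (with community labels) or weight matrix.
#' @param community per-node labels; defaults to the fit's codebook labels.
#' @return Named numeric vector per node.
#' @export
bridge_expected_influence <- function(net, community = NULL) {
  W <- if (inherits(net, "likert_ggm")) net$weights else as.matrix(net)
  if (is.null(community) && inherits(net, "likert_ggm"))
    community <- net$community
  if (is.null(community) || length(unique(community)) < 2)
    stop("bridge expected influence needs >= 2 declared communities")
  cross <- outer(community, community, `!=`)
  rowSums(W * cross)
}

#' Per-node centrality table
#'
#' @param net a [likert_ggm()] fit.
#' @return data frame with `node`, `expected_influence`, its rank
#'   (1 = highest), and - when community labels are present -
#'   `bridge_expected_influence` with its rank.
#' @export
centrality_table <- function(net) {
  ei <- expected_influence(net)
  out <- data.frame(node = names(ei), expected_influence = unname(ei),
                    ei_rank = rank(-ei, ties.method = "min"),
                    stringsAsFactors = FALSE)
  if (!is.null(net$community) && length(unique(net$community)) >= 2) {
    bei <- bridge_expected_influence(net)
    out$bridge_expected_influence <- unname(bei)
    out$bei_rank <- rank(-bei, ties.method = "min")
  }
  out
}

#' Strongest edges of a network
#'
#' The `k` edges with largest |weight|, ties broken lexicographically by
#' item ids; fewer than `k` nonzero edges yield a shorter list.
#'
#' @param net a [likert_ggm()] fit or weight matrix.
#' @param k number of edges (default 3).
#' @return data frame `item_a`, `item_b`, `weight`, `label` (weight printed
#'   to 2 decimals in the reporting convention `A-B (w)`).
#' @export
top_edges <- function(net, k = 3) {
  stopifnot(k >= 1)
  W <- if (inherits(net, "likert_ggm")) net$weights else as.matrix(net)
  ids <- colnames(W)
  ut <- which(upper.tri(W) & W != 0, arr.ind = TRUE)
  if (nrow(ut) == 0)
    return(data.frame(item_a = character(), item_b = character(),
                      weight = numeric(), label = character(),
                      stringsAsFactors = FALSE))
  w <- W[ut]
  a <- ids[ut[, 1]]; b <- ids[ut[, 2]]
  ord <- order(-abs(w), a, b)
  sel <- head(ord, k)
  data.frame(item_a = a[sel], item_b = b[sel], weight = w[sel],
             label = sprintf("%s-%s (%.2f)", a[sel], b[sel], w[sel]),
             stringsAsFactors = FALSE)
}

#' Identify the top (central or bridge) node set
#'
#' The top set is the argmax node plus every candidate whose Holm-adjusted
#' difference-test p-value against the argmax is >= 0.05 (statistically
#' indistinguishable "co-central" nodes), reported in descending index
#' order.
#'
#' @param values named per-node index (EI or BEI1).
#' @param difftest a `difference_test` from [centrality_difference_test()]
#'   covering the nodes.
#' @param candidates optional subset of nodes eligible for selection (e.g.
#'   only lifestyle nodes when picking the bridge lifestyle); the argmax and
#'   co-members are restricted to it.
#' @param alpha significance level (default 0.05).
#' @return Character vector of node ids, descending by index value.
#' @export
identify_top <- function(values, difftest, candidates = NULL, alpha = 0.05) {
  if (is.null(candidates)) candidates <- names(values)
  v <- values[candidates]
  top <- names(v)[which.max(v)]
  padj <- difftest$adjusted_p
  tied <- vapply(names(v), function(nd)
    nd == top || padj[nd, top] >= alpha, NA)
  set <- names(v)[tied]
  set[order(-v[set])]
}
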