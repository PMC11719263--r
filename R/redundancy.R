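#' Test equality of two dependent overlapping correlations
#'
#' Back-transformed-average Fisher-z statistic (Hittner-style) for
#' H0: rho(a,z) = rho(b,z) when the correlations share the variable z and
#' r(a,b) is known. With z1 = atanh(r_az), z2 = atanh(r_bz),
#' rbar = tanh((z1+z2)/2):
#' psi = r_ab (1 - 2 rbar^2) - rbar^2 (1 - 2 rbar^2 - r_ab^2) / 2,
#' c = psi / (1 - rbar^2)^2, and
#' Z = (z1 - z2) sqrt(n - 3) / sqrt(2 - 2c), two-sided normal p-value.
#'
#' @param r_az,r_bz the two correlations with the shared third variable.
#' @param r_ab correlation between the two overlapping variables.
#' @param n sample size (> 3).
#' @return list with `z` and `p`.
#' @export
dependent_correlation_test <- function(r_az, r_bz, r_ab, n) {
  if (n <= 3) stop("n must exceed 3")
  if (any(abs(c(r_az, r_bz)) >= 1))
    stop("correlations with the third variable must lie strictly inside (-1, 1)")
  if (abs(r_ab) > 1) stop("r_ab must lie in [-1, 1]")
  if (r_az == r_bz) return(list(z = 0, p = 1))   # identical profiles
  z1 <- atanh(r_az); z2 <- atanh(r_bz)
  rbar <- tanh((z1 + z2) / 2)
  psi <- r_ab * (1 - 2 * rbar^2) - 0.5 * rbar^2 * (1 - 2 * rbar^2 - r_ab^2)
  cc <- psi / (1 - rbar^2)^2
  den <- 2 - 2 * cc
  z <- if (den <= 0) sign(z1 - z2) * Inf
       else (z1 - z2) * sqrt(n - 3) / sqrt(den)
  list(z = z, p = 2 * pnorm(-abs(z)))
}

#' Screen item pairs for topological overlap (redundancy)
#'
#' For every candidate pair with |r(a,b)| >= `corr_floor`, compares the two
#' items' correlations with each of the remaining p - 2 items via
#' [dependent_correlation_test()]. A pair is flagged redundant when the
#' proportion of those comparisons significant at `alpha` falls below
#' `proportion_threshold` (the pair's correlation profiles are statistically
#' indistinguishable).
#'
#' @param matrix a [survey_matrix()] or numeric matrix.
#' @param alpha significance level for each comparison (default 0.01).
#' @param proportion_threshold flag a pair when the significant proportion is
#'   below this value (default 0.25).
#' @param corr_floor only pairs at least this correlated are candidates
#'   (default 0.5).
#' @param method correlation type, `"pearson"` (default) or `"spearman"`;
#'   pairwise-complete observations.
#' @return A `redundancy_report`: `bad_pairs` data frame
#'   (`item_a`, `item_b`, `r_ab`, `proportion_significant`), `alpha`,
#'   `proportion_threshold`, `corr_floor`, `n`.
#' @export
find_redundant_pairs <- function(matrix, alpha = 0.01,
                                 proportion_threshold = 0.25,
                                 corr_floor = 0.5,
                                 method = c("pearson", "spearman")) {
  method <- match.arg(method)
  X <- if (inherits(matrix, "survey_matrix")) matrix$values else as.matrix(matrix)
  p <- ncol(X)
  if (p < 3) stop("redundancy screening needs at least 3 items")
  ids <- colnames(X)
  R <- cor(X, use = "pairwise.complete.obs", method = method)
  n_pair <- crossprod(!is.na(X))           # complete obs per pair
  # correlations of exactly +/-1 with a third variable (true duplicates
  # elsewhere in the matrix) are clamped so the Fisher transform is finite;
  # such comparisons come out decisively significant, as they should
  Rc <- pmin(pmax(R, -1 + 1e-12), 1 - 1e-12)
  bad <- data.frame(item_a = character(), item_b = character(),
                    r_ab = numeric(), proportion_significant = numeric(),
                    stringsAsFactors = FALSE)
  for (a in seq_len(p - 1)) for (b in (a + 1):p) {
    if (is.na(R[a, b]) || abs(R[a, b]) < corr_floor) next
    zs <- setdiff(seq_len(p), c(a, b))
    sig <- vapply(zs, function(z) {
      n_eff <- min(n_pair[a, b], n_pair[a, z], n_pair[b, z])
      dependent_correlation_test(Rc[a, z], Rc[b, z], R[a, b], n_eff)$p < alpha
    }, NA)
    prop <- mean(sig)
    if (prop < proportion_threshold)
      bad <- rbind(bad, data.frame(item_a = ids[a], item_b = ids[b],
                                   r_ab = R[a, b],
                                   proportion_significant = prop,
                                   stringsAsFactors = FALSE))
  }
  structure(list(bad_pairs = bad, alpha = alpha,
                 proportion_threshold = proportion_threshold,
                 corr_floor = corr_floor, n = nrow(X),
                 correlations = R),
            class = "redundancy_report")
}

#' @export
print.redundancy_report <- function(x, ...) {
  cat(sprintf("redundancy screen: alpha = %g, proportion threshold = %g, corr floor = %g\n",
              x$alpha, x$proportion_threshold, x$corr_floor))
  if (nrow(x$bad_pairs) == 0) cat("no redundant pairs flagged\n")
  else print(x$bad_pairs)
  invisible(x)
}

#' Collapse redundant item groups to single representatives
#'
#' Connected components of the flagged pairs are collapsed to one kept item
#' each. By default the kept item is the one with the largest mean |r| to
#' all items outside its group (ties broken by lowest item id); an explicit
#' `keep` list overrides per group.
#'
#' @param matrix a [survey_matrix()].
#' @param report a `redundancy_report` from [find_redundant_pairs()].
#' @param keep optional character vector naming the item to keep in its
#'   group; each must appear in the flagged pairs.
#' @return The reduced [survey_matrix()], with attributes `dropped_items`
#'   (ordered) and `kept_for` (named map dropped -> kept).
#' @export
reduce_items <- function(matrix, report, keep = NULL) {
  stopifnot(inherits(matrix, "survey_matrix"),
            inherits(report, "redundancy_report"))
  bp <- report$bad_pairs
  if (nrow(bp) == 0) {
    attr(matrix, "dropped_items") <- character()
    attr(matrix, "kept_for") <- character()
    return(matrix)
  }
  flagged <- union(bp$item_a, bp$item_b)
  if (!all(flagged %in% matrix$item_ids))
    stop("report refers to items absent from the matrix")
  if (!is.null(keep) && !all(keep %in% flagged))
    stop("keep list names unflagged item(s): ",
         paste(setdiff(keep, flagged), collapse = ", "))
  # connected components by union-find over flagged pairs
  parent <- setNames(flagged, flagged)
  find <- function(x) { while (parent[[x]] != x) x <- parent[[x]]; x }
  for (e in seq_len(nrow(bp)))
    parent[[find(bp$item_a[e])]] <- find(bp$item_b[e])
  groups <- split(flagged, vapply(flagged, find, ""))

  R <- report$correlations
  dropped <- character(); kept_for <- character()
  for (g in groups) {
    g <- sort(g)
    chosen <- intersect(keep, g)
    if (length(chosen) > 1)
      stop("keep list names several items of one redundant group: ",
           paste(chosen, collapse = ", "))
    if (length(chosen) == 0) {
      outside <- setdiff(matrix$item_ids, g)
      score <- vapply(g, function(it)
        mean(abs(R[it, outside]), na.rm = TRUE), 0)
      chosen <- g[order(-score, g)][1]   # ties -> lowest id
    }
    drop_g <- setdiff(g, chosen)
    dropped <- c(dropped, drop_g)
    kept_for <- c(kept_for, setNames(rep(chosen, length(drop_g)), drop_g))
  }
  keep_ids <- setdiff(matrix$item_ids, dropped)
  cb <- matrix$codebook[matrix$codebook$id %in% keep_ids, , drop = FALSE]
  class(cb) <- c("likert_codebook", "data.frame")
  out <- survey_matrix(matrix$values[, keep_ids, drop = FALSE], cb,
                       matrix$country)
  attr(out, "dropped_items") <- dropped
  attr(out, "kept_for") <- kept_for
  out
}

#' One-call redundancy screen and reduction
#'
#' @inheritParams find_redundant_pairs
#' @inheritParams reduce_items
#' @return As [reduce_items()]; the report is attached as attribute `report`.
#' @export
screen_redundant <- function(matrix, alpha = 0.01,
                             proportion_threshold = 0.25, corr_floor = 0.5,
                             keep = NULL) {
  rep <- find_redundant_pairs(matrix, alpha, proportion_threshold, corr_floor)
  out <- reduce_items(matrix, rep, keep = keep)
  attr(out, "report") <- rep
  out
}
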