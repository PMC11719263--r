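#' Number of edges of a complete graph
#'
#' @param p node count (>= 1).
#' @return `p(p-1)/2`.
#' @export
complete_graph_edges <- function(p) {
  stopifnot(p >= 1)
  as.integer(p * (p - 1) / 2)
}

#' Nonzero-edge percentage in the reporting convention
#'
#' `round(100 * nonzero / total, 1)` (round-half-even, 1 decimal), the
#' convention used in cross-country summary tables.
#'
#' @param nonzero,total edge counts, `0 <= nonzero <= total`, `total > 0`.
#' @return Percentage with 1 decimal.
#' @export
percent_nonzero <- function(nonzero, total) {
  if (total <= 0) stop("total edge count must be positive")
  stopifnot(nonzero >= 0, nonzero <= total)
  round(100 * nonzero / total, 1)
}

#' Pipeline configuration
#'
#' Bundles every tuning default of the per-country analysis: network
#' estimation (Pearson correlations, 100 log-spaced penalties with min
#' ratio 0.01, EBIC gamma 0.5), bootstrap sizes (B = 1000 for difference
#' tests and for case dropping), the case-dropping grid (10 proportions
#' 0.05-0.75), the CS interpretability gate (strictly > 0.25), the
#' redundancy screen (alpha 0.01, proportion threshold 0.25, correlation
#' floor 0.5), and the reporting depth (top 3 edges).
#'
#' @param B nonparametric bootstrap replicates.
#' @param B_cs case-dropping subsamples per grid point.
#' @param cs_grid drop-proportion grid.
#' @param cs_gate interpretability threshold on the CS coefficient
#'   (strict `>`).
#' @param method,n_lambda,lambda_min_ratio,gamma,zero_tolerance estimation
#'   settings, see [likert_ggm()].
#' @param alpha significance level for difference tests.
#' @param redundancy list of screen settings (`alpha`,
#'   `proportion_threshold`, `corr_floor`).
#' @param reduction `"screen"` (run the redundancy screen per dataset),
#'   `"fixed"` (drop `drop_items` globally), or `"none"`.
#' @param drop_items item ids dropped under `reduction = "fixed"`.
#' @param keep keep-list override for the screen (see [reduce_items()]).
#' @param top_k edges reported per network.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(B = 1000, B_cs = 1000,
                            cs_grid = seq(0.05, 0.75, length.out = 10),
                            cs_gate = 0.25,
                            method = "pearson", n_lambda = 100,
                            lambda_min_ratio = 0.01, gamma = 0.5,
                            zero_tolerance = 1e-8, alpha = 0.05,
                            redundancy = list(alpha = 0.01,
                                              proportion_threshold = 0.25,
                                              corr_floor = 0.5),
                            reduction = c("screen", "fixed", "none"),
                            drop_items = character(), keep = NULL,
                            top_k = 3) {
  structure(list(B = B, B_cs = B_cs, cs_grid = cs_grid, cs_gate = cs_gate,
                 method = method, n_lambda = n_lambda,
                 lambda_min_ratio = lambda_min_ratio, gamma = gamma,
                 zero_tolerance = zero_tolerance, alpha = alpha,
                 redundancy = redundancy, reduction = match.arg(reduction),
                 drop_items = drop_items, keep = keep, top_k = top_k),
            class = "pipeline_config")
}

.fit_args <- function(config) {
  list(method = config$method, n_lambda = config$n_lambda,
       lambda_min_ratio = config$lambda_min_ratio, gamma = config$gamma,
       zero_tolerance = config$zero_tolerance)
}

.subset_items <- function(matrix, ids) {
  cb <- matrix$codebook[matrix$codebook$id %in% ids, , drop = FALSE]
  class(cb) <- c("likert_codebook", "data.frame")
  survey_matrix(matrix$values[, cb$id, drop = FALSE], cb, matrix$country)
}

# one network's full validation block: fit, bootstrap difference tests,
# case-dropping CS on the chosen index
.analyse_network <- function(matrix, config, seed, index, community) {
  fa <- .fit_args(config)
  fit <- do.call(likert_ggm, c(list(matrix), fa))
  ens <- do.call(nonparametric_bootstrap,
                 c(list(matrix, B = config$B, seed = seed), fa))
  dt <- centrality_difference_test(ens, index = index, alpha = config$alpha,
                                   community = community)
  prof <- do.call(case_dropping_bootstrap,
                  c(list(matrix, grid = config$cs_grid, B = config$B_cs,
                         seed = seed + 1L, index = index,
                         community = community), fa))
  cs <- cs_coefficient(prof)
  vals <- if (index == "EI") expected_influence(fit)
          else bridge_expected_influence(fit, community[fit$item_ids])
  list(fit = fit, ensemble = ens, difftest = dt, profile = prof, cs = cs,
       index_values = vals,
       interpretable = cs > config$cs_gate,
       nonzero_edges = fit$nonzero_edges, total_edges = fit$total_edges,
       percent_nonzero = percent_nonzero(fit$nonzero_edges,
                                         fit$total_edges),
       top_edges = top_edges(fit, config$top_k))
}

#' Run the full per-country analysis
#'
#' Orchestrates one country's pipeline: redundancy reduction on the pooled
#' item set, then three networks - within the first declared community
#' ("lifestyle"), within the second ("outcome"), and the bridge network
#' over all items - each validated by nonparametric bootstrap difference
#' tests and a case-dropping CS coefficient. Central variables (highest
#' expected influence within their network) and the bridge variable
#' (highest one-step bridge expected influence, selection restricted to the
#' lifestyle community) are reported only when the corresponding network's
#' CS exceeds the gate; otherwise they are `NA`. A sample below the
#' 3-per-parameter requirement produces a warning, not an error, since
#' stability gating is the operative safeguard.
#'
#' @param matrix a [survey_matrix()] covering all codebook items.
#' @param config a [pipeline_config()].
#' @param seed integer seed driving all bootstraps.
#' @return A `country_summary` list: `country`, `n`, `dropped_items`,
#'   per-network blocks (`lifestyle`, `outcome`, `bridge`) each with edge
#'   censuses, top edges, `cs`, `interpretable`; plus `central_lifestyle`,
#'   `central_outcome`, `bridge_lifestyle` (id vectors or `NA`) and
#'   `bridge_edge` (label or `NA`).
#' @export
run_country <- function(matrix, config = pipeline_config(), seed = 1) {
  stopifnot(inherits(matrix, "survey_matrix"))
  comms <- unique(matrix$codebook$community)
  if (length(comms) != 2)
    stop("the pipeline expects exactly 2 communities; found ",
         length(comms))
  reduced <- switch(config$reduction,
    screen = screen_redundant(matrix,
                              alpha = config$redundancy$alpha,
                              proportion_threshold = config$redundancy$proportion_threshold,
                              corr_floor = config$redundancy$corr_floor,
                              keep = config$keep),
    fixed = .subset_items(matrix,
                          setdiff(matrix$item_ids, config$drop_items)),
    none = matrix)
  dropped <- if (config$reduction == "fixed")
    intersect(matrix$item_ids, config$drop_items)
  else attr(reduced, "dropped_items") %||% character()

  cb <- reduced$codebook
  community <- setNames(cb$community, cb$id)
  items1 <- cb$id[cb$community == comms[1]]
  items2 <- cb$id[cb$community == comms[2]]
  req <- required_sample_size(length(cb$id))
  if (reduced$n < req)
    warning(sprintf("n = %d below the 3-per-parameter requirement %d for the bridge network; proceeding (stability gating applies)",
                    reduced$n, req))

  net1 <- .analyse_network(.subset_items(reduced, items1), config,
                           seed, "EI", community)
  net2 <- .analyse_network(.subset_items(reduced, items2), config,
                           seed + 100L, "EI", community)
  netb <- .analyse_network(reduced, config, seed + 200L, "BEI1", community)

  pick <- function(block, candidates = NULL) {
    if (!block$interpretable) return(NA_character_)
    identify_top(block$index_values, block$difftest,
                 candidates = candidates, alpha = config$alpha)
  }
  central1 <- pick(net1)
  central2 <- pick(net2)
  bridge <- pick(netb, candidates = items1)

  bridge_edge <- NA_character_
  if (!anyNA(bridge)) {
    node <- bridge[1]
    W <- netb$fit$weights
    cross <- names(community)[community != community[node]]
    w <- W[node, cross]
    if (any(w != 0)) {
      j <- cross[which.max(abs(w))]
      bridge_edge <- sprintf("%s-%s (%.2f)", node, j, W[node, j])
    }
  }

  structure(list(country = matrix$country, n = reduced$n,
                 dropped_items = dropped, seed = seed, config = config,
                 lifestyle = net1, outcome = net2, bridge = netb,
                 central_lifestyle = central1, central_outcome = central2,
                 bridge_lifestyle = bridge, bridge_edge = bridge_edge),
            class = "country_summary")
}

#' @export
print.country_summary <- function(x, ...) {
  fmt_set <- function(s) if (anyNA(s)) "NA" else paste(s, collapse = " = ")
  cat(sprintf("country_summary: %s (n = %d)\n", x$country, x$n))
  if (length(x$dropped_items))
    cat("  redundant items dropped:", paste(x$dropped_items, collapse = ", "),
        "\n")
  for (nm in c("lifestyle", "outcome", "bridge")) {
    b <- x[[nm]]
    cat(sprintf("  %s network: %d/%d nonzero edges (%.1f%%), CS = %.2f%s\n",
                nm, b$nonzero_edges, b$total_edges, b$percent_nonzero,
                b$cs, if (b$interpretable) "" else " [not interpretable]"))
    if (nrow(b$top_edges))
      cat("    top edges:", paste(b$top_edges$label, collapse = ", "), "\n")
  }
  cat("  central lifestyle:", fmt_set(x$central_lifestyle), "\n")
  cat("  central outcome:  ", fmt_set(x$central_outcome), "\n")
  cat("  bridge lifestyle: ", fmt_set(x$bridge_lifestyle),
      if (!is.na(x$bridge_edge)) paste0(" | bridge edge ", x$bridge_edge)
      else "", "\n")
  invisible(x)
}

#' Group countries by their central and bridge variables
#'
#' Aggregates [run_country()] summaries into the cross-country reporting
#' structure: for each of the three roles, the distinct variables
#' identified and the countries in which each was identified (a country
#' with a co-central tie contributes to every tied variable's group;
#' non-interpretable `NA` entries are excluded).
#'
#' @param summaries list of `country_summary` objects.
#' @return list with one data frame per role (`central_lifestyle`,
#'   `central_outcome`, `bridge_lifestyle`), columns `variable`,
#'   `n_countries`, `countries`, plus `n_types` counts.
#' @export
summarize_across_countries <- function(summaries) {
  stopifnot(length(summaries) >= 1)
  roles <- c("central_lifestyle", "central_outcome", "bridge_lifestyle")
  out <- list()
  for (role in roles) {
    pairs <- do.call(rbind, lapply(summaries, function(s) {
      v <- s[[role]]
      if (anyNA(v)) return(NULL)
      data.frame(variable = v, country = s$country,
                 stringsAsFactors = FALSE)
    }))
    if (is.null(pairs) || nrow(pairs) == 0) {
      out[[role]] <- data.frame(variable = character(),
                                n_countries = integer(),
                                countries = character(),
                                stringsAsFactors = FALSE)
      next
    }
    grp <- split(pairs$country, pairs$variable)
    df <- data.frame(variable = names(grp),
                     n_countries = vapply(grp, length, 0L),
                     countries = vapply(grp, function(g)
                       paste(sort(g), collapse = ", "), ""),
                     stringsAsFactors = FALSE)
    out[[role]] <- df[order(-df$n_countries, df$variable), , drop = FALSE]
    rownames(out[[role]]) <- NULL
  }
  out$n_types <- vapply(roles, function(r) nrow(out[[r]]), 0L)
  out
}

#' Simulate one synthetic country dataset
#'
#' Convenience wrapper: generates a sparse two-community truth and samples
#' an ordinal survey from it, so the whole pipeline can run with no
#' external data.
#'
#' @param p_lifestyle,p_outcome,within_density,n_bridge,weight_range,bridge_edges
#'   passed to [generate_true_network()].
#' @param n respondent count.
#' @param seed integer seed (drives both truth and sampling).
#' @param country dataset tag.
#' @param thresholds optional cutpoints, see [sample_likert()].
#' @return list with `truth` and `matrix`.
#' @export
simulate_country <- function(p_lifestyle = 15, p_outcome = 13, n = 1000,
                             within_density = 0.2, n_bridge = 2,
                             weight_range = c(0.2, 0.5), seed = 1,
                             country = "synthetic", thresholds = NULL,
                             bridge_edges = NULL) {
  truth <- generate_true_network(p_lifestyle, p_outcome, within_density,
                                 n_bridge, weight_range, seed = seed,
                                 bridge_edges = bridge_edges)
  mat <- sample_likert(truth, n = n, thresholds = thresholds,
                       seed = seed + 1L, country = country)
  list(truth = truth, matrix = mat)
}
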