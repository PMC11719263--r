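# fixtures are built in code; nothing is read from disk except files the
# helpers themselves write to tempdir()

tiny_codebook <- function(p_l = 3, p_o = 2) {
  codebook(c(paste0("L", seq_len(p_l)), paste0("H", seq_len(p_o))),
           community = c(rep("lifestyle", p_l), rep("outcome", p_o)),
           reverse_coded = c(rep(FALSE, p_l - 1), TRUE, rep(FALSE, p_o)))
}

tiny_survey_csv <- function(path, cb = tiny_codebook(), n = 3, seed = 1) {
  set.seed(seed)
  df <- as.data.frame(matrix(sample(1:5, n * nrow(cb), replace = TRUE),
                             n, nrow(cb), dimnames = list(NULL, cb$id)))
  df$country <- "Testland"
  write.csv(df, path, row.names = FALSE, na = "")
  df
}

# regression-residual oracle for partial correlations: correlate the
# residuals of each pair of variables regressed on all the others
pcor_oracle <- function(Sigma) {
  p <- nrow(Sigma)
  out <- diag(0, p)
  for (i in seq_len(p - 1)) for (j in (i + 1):p) {
    rest <- setdiff(seq_len(p), c(i, j))
    if (length(rest) == 0) {
      out[i, j] <- out[j, i] <- Sigma[i, j] / sqrt(Sigma[i, i] * Sigma[j, j])
      next
    }
    Srr <- Sigma[rest, rest, drop = FALSE]
    bi <- solve(Srr, Sigma[rest, i])
    bj <- solve(Srr, Sigma[rest, j])
    vi <- Sigma[i, i] - sum(Sigma[i, rest] * bi)
    vj <- Sigma[j, j] - sum(Sigma[j, rest] * bj)
    cij <- Sigma[i, j] - sum(Sigma[i, rest] * bj)
    out[i, j] <- out[j, i] <- cij / sqrt(vi * vj)
  }
  out
}

# manual bootstrap ensemble around a fixed point fit, for method-level tests
fake_ensemble <- function(weights_array, point_weights = NULL,
                          community = NULL) {
  p <- dim(weights_array)[1]
  ids <- dimnames(weights_array)[[1]]
  if (is.null(ids)) {
    ids <- paste0("V", seq_len(p))
    dimnames(weights_array) <- list(ids, ids, NULL)
  }
  if (is.null(point_weights)) point_weights <- weights_array[, , 1]
  point <- list(weights = point_weights, item_ids = ids,
                community = community)
  class(point) <- "likert_ggm"
  structure(list(weights = weights_array, point = point,
                 B = dim(weights_array)[3], seed = 0,
                 scheme = "nonparametric"), class = "bootstrap_ensemble")
}

fake_profile <- function(pass_upto, grid = seq(0.05, 0.75, length.out = 10),
                         B = 40) {
  rows <- do.call(rbind, lapply(seq_along(grid), function(i) {
    good <- if (i <= pass_upto) B else floor(0.5 * B)
    data.frame(proportion = grid[i], replicate = seq_len(B),
               correlation = c(rep(0.9, good), rep(0.2, B - good)))
  }))
  structure(list(correlations = rows, grid = grid, skipped = numeric(),
                 index = "EI", B = B, seed = 0,
                 point_index = rep(1, 5)),
            class = "stability_profile")
}
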