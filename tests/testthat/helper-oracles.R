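# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths (and lm/hclust) so that agreement is meaningful.

# Closed-form simple linear regression via the textbook normal equations.
ols_oracle <- function(x, y) {
  n <- length(x)
  xbar <- sum(x) / n
  ybar <- sum(y) / n
  sxx <- sum((x - xbar)^2)
  sxy <- sum((x - xbar) * (y - ybar))
  syy <- sum((y - ybar)^2)
  slope <- sxy / sxx
  intercept <- ybar - slope * xbar
  sse <- sum((y - intercept - slope * x)^2)
  s <- sqrt(sse / (n - 2))
  r <- sxy / sqrt(sxx * syy)
  list(
    intercept = intercept, slope = slope,
    se_slope = s / sqrt(sxx),
    se_intercept = s * sqrt(1 / n + xbar^2 / sxx),
    r = r, s_resid = s,
    f_stat = (n - 2) * r^2 / (1 - r^2),
    n = n
  )
}

# Normal-equation solve of the rearranged excess-retention model.
oscik_oracle <- function(x, rm, rm_org) {
  A <- cbind(1 - x, x^2 * (1 - x), x * (1 - x))
  z <- rm - x * rm_org
  beta <- solve(t(A) %*% A, t(A) %*% z)
  list(rmwo = beta[1], a = beta[2], b = beta[3])
}

# Brute-force O(n^3) agglomerative clustering via the Lance-Williams
# recurrences. Returns, per merge, the two leaf sets joined and the height,
# so comparisons are free of merge-matrix ordering conventions.
lw_cluster_oracle <- function(dmat, linkage) {
  d <- as.matrix(dmat)
  n <- nrow(d)
  clusters <- lapply(seq_len(n), identity)  # leaf index sets
  sizes <- rep(1, n)
  active <- seq_len(n)
  steps <- list()
  for (step in seq_len(n - 1)) {
    best <- c(NA, NA); bestd <- Inf
    for (ii in seq_along(active)) for (jj in seq_along(active)) {
      if (ii < jj) {
        i <- active[ii]; j <- active[jj]
        if (d[i, j] < bestd) { bestd <- d[i, j]; best <- c(i, j) }
      }
    }
    i <- best[1]; j <- best[2]
    new_set <- sort(c(clusters[[i]], clusters[[j]]))
    steps[[step]] <- list(sets = list(sort(clusters[[i]]), sort(clusters[[j]])),
                          height = bestd)
    for (k in setdiff(active, c(i, j))) {
      dk <- switch(linkage,
        single   = min(d[k, i], d[k, j]),
        complete = max(d[k, i], d[k, j]),
        average  = (sizes[i] * d[k, i] + sizes[j] * d[k, j]) / (sizes[i] + sizes[j]),
        ward     = sqrt(((sizes[i] + sizes[k]) * d[k, i]^2 +
                         (sizes[j] + sizes[k]) * d[k, j]^2 -
                         sizes[k] * d[i, j]^2) /
                        (sizes[i] + sizes[j] + sizes[k]))
      )
      d[k, i] <- d[i, k] <- dk
    }
    clusters[[i]] <- new_set
    sizes[i] <- sizes[i] + sizes[j]
    active <- setdiff(active, j)
  }
  steps
}

# Leaf sets joined at each merge of an rptlc dendrogram, for comparison
# with the oracle above.
dendrogram_merge_sets <- function(den) {
  sets <- list()
  out <- list()
  for (j in seq_along(den$height)) {
    members <- lapply(den$merge[j, ], function(child)
      if (child < 0) -child else sets[[child]])
    sets[[j]] <- sort(unlist(members))
    out[[j]] <- list(sets = lapply(members, sort), height = den$height[j])
  }
  out
}

same_merge_step <- function(a, b, tol = 1e-8) {
  hts <- abs(a$height - b$height) <= tol
  pair_eq <- (identical(a$sets[[1]], b$sets[[1]]) && identical(a$sets[[2]], b$sets[[2]])) ||
             (identical(a$sets[[1]], b$sets[[2]]) && identical(a$sets[[2]], b$sets[[1]]))
  hts && pair_eq
}
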