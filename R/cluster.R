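#' Paired t-statistic map
#'
#' Per-feature dependent-samples t statistic over units (subjects) for a
#' condition pair. Features with zero variance of the paired differences get
#' t = 0 and are flagged.
#'
#' @param a,b numeric matrices, units x features (conditions A and B), or
#'   vectors for a single feature.
#' @return numeric vector of t values (length = n features) with attribute
#'   `zero_variance` (logical vector).
#' @export
paired_t_map <- function(a, b) {
  if (is.vector(a)) a <- matrix(a, ncol = 1)
  if (is.vector(b)) b <- matrix(b, ncol = 1)
  stopifnot(identical(dim(a), dim(b)), nrow(a) >= 2)
  d <- a - b
  n <- nrow(d)
  mu <- colMeans(d)
  s <- apply(d, 2, stats::sd)
  zv <- s == 0
  t <- ifelse(zv, 0, mu / (s / sqrt(n)))
  attr(t, "zero_variance") <- zv
  t
}

# Connected suprathreshold clusters.
#  - 1-D (length-n vector mask): runs of consecutive TRUE.
#  - 2-D (matrix mask): 4-neighbourhood components (two-pass union-find).
#  - custom adjacency: list mapping feature index -> integer neighbours.
# Returns a list of integer index vectors (into the flattened mask).
find_clusters <- function(mask, adjacency = NULL) {
  if (!is.null(adjacency)) {
    idx <- which(mask)
    if (!length(idx)) return(list())
    comp <- stats::setNames(seq_along(idx), idx)
    find <- function(i) { while (comp[i] != i) i <- comp[i]; i }
    pos <- match(seq_along(mask), idx)
    for (k in seq_along(idx)) {
      for (nb in adjacency[[idx[k]]]) {
        j <- pos[nb]
        if (!is.na(j) && mask[nb]) {
          ri <- find(k); rj <- find(j)
          if (ri != rj) comp[ri] <- rj
        }
      }
    }
    roots <- vapply(seq_along(idx), find, integer(1))
    return(unname(split(idx, roots)))
  }
  if (is.matrix(mask)) {
    nr <- nrow(mask); nc <- ncol(mask)
    lab <- matrix(0L, nr, nc)
    nxt <- 0L
    parent <- integer(0)
    findp <- function(i) { while (parent[i] != i) i <- parent[i]; i }
    for (j in seq_len(nc)) for (i in seq_len(nr)) {
      if (!mask[i, j]) next
      up <- if (i > 1 && mask[i - 1, j]) lab[i - 1, j] else 0L
      lf <- if (j > 1 && mask[i, j - 1]) lab[i, j - 1] else 0L
      if (up == 0L && lf == 0L) {
        nxt <- nxt + 1L; parent[nxt] <- nxt; lab[i, j] <- nxt
      } else if (up != 0L && lf != 0L) {
        lab[i, j] <- up
        ru <- findp(up); rl <- findp(lf)
        if (ru != rl) parent[ru] <- rl
      } else {
        lab[i, j] <- max(up, lf)
      }
    }
    idx <- which(mask)
    if (!length(idx)) return(list())
    roots <- vapply(lab[idx], findp, integer(1))
    return(unname(split(idx, roots)))
  }
  r <- rle(as.logical(mask))
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
  out <- list()
  for (k in which(r$values)) out[[length(out) + 1]] <- starts[k]:ends[k]
  out
}

# Cluster masses (summed t) for one t-map: positive and negative clusters at
# +/- t_crit. Returns list(clusters = list(idx, mass, sign), max_mass).
cluster_masses <- function(tmap, t_crit, dims = NULL, adjacency = NULL) {
  shape_mask <- function(v) {
    if (!is.null(dims)) matrix(v, dims[1], dims[2]) else v
  }
  cl <- list()
  for (sgn in c(1, -1)) {
    mask <- shape_mask(sgn * tmap > t_crit)
    for (idx in find_clusters(mask, adjacency)) {
      cl[[length(cl) + 1]] <- list(idx = idx, mass = sum(tmap[idx]),
                                   sign = sgn)
    }
  }
  max_mass <- if (length(cl)) max(vapply(cl, function(c) abs(c$mass),
                                         numeric(1))) else 0
  list(clusters = cl, max_mass = max_mass)
}

#' Cluster-based permutation test for paired data
#'
#' Forms clusters of adjacent features whose dependent-samples t exceeds the
#' cluster-forming threshold (the t value with two-tailed tail probability
#' `cluster_alpha` at n-1 df), separately for each sign, and compares each
#' cluster's summed t against a sign-flip permutation null of the maximum
#' absolute cluster mass (two-tailed max-statistic correction). Monte-Carlo
#' p-values use the (b+1)/(m+1) correction, so p is never 0. When
#' `exhaustive = TRUE` (or `n_perm >= 2^n`), all 2^n sign patterns are
#' enumerated and the p-value is exact.
#'
#' @param a,b units x features matrices (paired conditions); vectors allowed.
#' @param n_perm number of random sign-flip permutations (default 1000).
#' @param cluster_alpha two-tailed p threshold forming clusters (0.025).
#' @param alpha cluster-level significance level (0.05).
#' @param dims optional c(nrow, ncol) to treat features as a 2-D grid with
#'   4-neighbourhood adjacency (e.g. frequency x time).
#' @param adjacency optional list of integer neighbour indices per feature
#'   (e.g. a sensor adjacency built from electrode distances).
#' @param exhaustive force exhaustive enumeration of all sign patterns.
#' @param seed integer seed for the permutation draws.
#' @return a `cluster_test` object: tibble `clusters` (mass, size, sign, p,
#'   significant), `t_map`, `t_crit`, `n_perm_used`, `exhaustive`.
#' @export
cluster_permutation_test <- function(a, b, n_perm = 1000,
                                     cluster_alpha = 0.025, alpha = 0.05,
                                     dims = NULL, adjacency = NULL,
                                     exhaustive = FALSE, seed = 1) {
  if (!is.matrix(a)) a <- as.matrix(a)
  if (!is.matrix(b)) b <- as.matrix(b)
  stopifnot(identical(dim(a), dim(b)), nrow(a) >= 2)
  n <- nrow(a)
  d <- a - b
  t_crit <- stats::qt(1 - cluster_alpha / 2, df = n - 1)
  tobs <- paired_t_map(a, b)
  obs <- cluster_masses(tobs, t_crit, dims, adjacency)

  if (n_perm >= 2^n) exhaustive <- TRUE
  # vectorized sign-flip t-maps: column j of signs flips unit j
  sq <- colMeans(d^2)
  tmap_for <- function(s) {
    mu <- drop(s %*% d) / n
    v <- (sq - mu^2) * n / (n - 1)
    ifelse(v <= 0, 0, mu / sqrt(v / n))
  }
  if (exhaustive) {
    grid <- as.matrix(expand.grid(rep(list(c(1, -1)), n)))
    null_max <- apply(grid, 1, function(s)
      cluster_masses(tmap_for(s), t_crit, dims, adjacency)$max_mass)
    m_used <- nrow(grid)
    pval <- function(mass) mean(null_max >= abs(mass) - 1e-12)
  } else {
    null_max <- withr::with_seed(seed, vapply(seq_len(n_perm), function(p) {
      s <- sample(c(1, -1), n, replace = TRUE)
      cluster_masses(tmap_for(s), t_crit, dims, adjacency)$max_mass
    }, numeric(1)))
    m_used <- n_perm
    pval <- function(mass) (sum(null_max >= abs(mass) - 1e-12) + 1) / (m_used + 1)
  }
  clusters <- if (length(obs$clusters)) {
    dplyr::bind_rows(lapply(obs$clusters, function(cl) {
      p <- pval(cl$mass)
      tibble::tibble(mass = cl$mass, size = length(cl$idx),
                     sign = cl$sign, p = p, significant = p <= alpha,
                     features = list(cl$idx))
    }))
  } else {
    tibble::tibble(mass = numeric(), size = integer(), sign = numeric(),
                   p = numeric(), significant = logical(), features = list())
  }
  structure(list(clusters = clusters, t_map = tobs, t_crit = t_crit,
                 n_perm_used = m_used, exhaustive = exhaustive,
                 cluster_alpha = cluster_alpha, alpha = alpha),
            class = "cluster_test")
}

#' @export
print.cluster_test <- function(x, ...) {
  cat(sprintf("<cluster_test> %d cluster(s), t_crit = %.3f, %s permutations\n",
              nrow(x$clusters), x$t_crit,
              if (x$exhaustive) sprintf("exhaustive %d", x$n_perm_used)
              else sprintf("%d Monte-Carlo", x$n_perm_used)))
  if (nrow(x$clusters)) print(x$clusters[, c("mass", "size", "sign", "p",
                                             "significant")])
  invisible(x)
}

#' Empirical family-wise type-I error of the cluster test
#'
#' Repeatedly draws exchangeable null condition pairs from `null_gen`, runs
#' the cluster permutation test, and reports the fraction of repetitions
#' with at least one significant cluster (expected to be about `alpha`).
#'
#' @param null_gen function(rep_index) returning `list(a = , b = )` of
#'   paired condition matrices with no true difference.
#' @param n_reps number of repetitions.
#' @param n_perm permutations per test.
#' @param alpha significance level under test.
#' @param seed integer seed.
#' @param ... passed to [cluster_permutation_test()].
#' @return list: `rate`, `n_reps`, `hits`.
#' @export
typeI_harness <- function(null_gen, n_reps = 500, n_perm = 200,
                          alpha = 0.05, seed = 1, ...) {
  hits <- withr::with_seed(seed, vapply(seq_len(n_reps), function(r) {
    ab <- null_gen(r)
    if (alpha <= 0) return(FALSE)
    res <- cluster_permutation_test(ab$a, ab$b, n_perm = n_perm,
                                    alpha = alpha,
                                    seed = sample.int(2147480000L, 1), ...)
    any(res$clusters$significant)
  }, logical(1)))
  list(rate = mean(hits), n_reps = n_reps, hits = hits)
}

#' Paired session summary for one metric and window
#'
#' Convenience layer over the long metrics table: extracts one metric in one
#' window for two sessions, pairs by subject, and reports per-subject
#' differences with a paired t-test.
#'
#' @param metrics long-format tibble (subject, session, window, metric,
#'   value).
#' @param metric_name metric to extract.
#' @param window_name window to extract.
#' @param sessions length-2 vector: sessions to compare (second - first).
#' @return list: `differences` (tibble subject, value_1, value_2, diff),
#'   `t`, `p`, `mean_diff`.
#' @export
window_paired_summary <- function(metrics, metric_name, window_name,
                                  sessions) {
  stopifnot(length(sessions) == 2)
  sub <- metrics[metrics$metric == metric_name &
                   metrics$window == window_name &
                   metrics$session %in% sessions, ]
  wide <- tidyr_pivot(sub)
  s1 <- paste0("s", sessions[1]); s2 <- paste0("s", sessions[2])
  if (!all(c(s1, s2) %in% names(wide)) || any(is.na(wide[[s1]])) ||
      any(is.na(wide[[s2]]))) {
    stop("unmatched subjects between sessions")
  }
  diffs <- wide[[s2]] - wide[[s1]]
  tt <- if (stats::sd(diffs) > 0) stats::t.test(diffs) else
    list(statistic = c(t = NA_real_), p.value = NA_real_)
  list(differences = tibble::tibble(subject = wide$subject,
                                    value_1 = wide[[s1]],
                                    value_2 = wide[[s2]],
                                    diff = diffs),
       t = unname(tt$statistic), p = tt$p.value, mean_diff = mean(diffs))
}

# minimal long-to-wide on (subject, session, value) without importing tidyr
tidyr_pivot <- function(sub) {
  subjects <- sort(unique(sub$subject))
  sessions <- sort(unique(sub$session))
  out <- tibble::tibble(subject = subjects)
  for (s in sessions) {
    v <- rep(NA_real_, length(subjects))
    rows <- sub[sub$session == s, ]
    v[match(rows$subject, subjects)] <- rows$value
    out[[paste0("s", s)]] <- v
  }
  out
}
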