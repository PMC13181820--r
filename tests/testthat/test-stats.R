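test_that("paired t map: identical conditions give 0, closed form and formula oracle hold", {
  a <- matrix(stats::rnorm(40), 8, 5)
  t0 <- paired_t_map(a, a)
  expect_equal(as.numeric(t0), rep(0, 5))
  expect_true(all(attr(t0, "zero_variance")))

  # constant difference d over units with known spread
  d <- c(1, 2, 3, 4, 5)
  b <- matrix(0, 5, 1)
  tt <- paired_t_map(matrix(d, 5, 1), b)
  expect_equal(as.numeric(tt), mean(d) / (stats::sd(d) / sqrt(5)))

  set.seed(11)
  x <- matrix(stats::rnorm(60), 10, 6)
  y <- matrix(stats::rnorm(60), 10, 6)
  tmap <- paired_t_map(x, y)
  for (j in 1:6) {
    expect_equal(tmap[j], unname(stats::t.test(x[, j], y[, j],
                                               paired = TRUE)$statistic))
  }
})

test_that("cluster finding handles 1-D runs, 2-D components, and custom adjacency", {
  m1 <- c(FALSE, TRUE, TRUE, FALSE, TRUE)
  cl <- betabursts:::find_clusters(m1)
  expect_equal(cl, list(2:3, 5L))

  m2 <- matrix(FALSE, 3, 4)
  m2[1, 1] <- m2[2, 1] <- m2[2, 2] <- TRUE   # L-shaped 4-connected blob
  m2[3, 4] <- TRUE                           # isolated
  cl2 <- betabursts:::find_clusters(m2)
  sizes <- sort(vapply(cl2, length, integer(1)))
  expect_equal(sizes, c(1L, 3L))

  # diagonal cells are NOT 4-neighbours
  m3 <- matrix(FALSE, 2, 2); m3[1, 1] <- m3[2, 2] <- TRUE
  expect_length(betabursts:::find_clusters(m3), 2)

  # ring adjacency joins the two ends
  adj <- lapply(1:6, function(i) c(ifelse(i == 1, 6, i - 1),
                                   ifelse(i == 6, 1, i + 1)))
  m4 <- c(TRUE, TRUE, FALSE, FALSE, FALSE, TRUE)
  cl4 <- betabursts:::find_clusters(m4, adjacency = adj)
  expect_length(cl4, 1)
  expect_setequal(cl4[[1]], c(1L, 2L, 6L))
})

test_that("identical conditions produce no clusters and p-values are never 0", {
  set.seed(21)
  a <- matrix(stats::rnorm(8 * 20), 8, 20)
  res <- cluster_permutation_test(a, a, n_perm = 50, seed = 3)
  expect_equal(nrow(res$clusters), 0)

  b <- a + 2          # strong uniform effect
  res2 <- cluster_permutation_test(a + 2, a, n_perm = 100, seed = 3)
  expect_gte(nrow(res2$clusters), 1)
  expect_true(all(res2$clusters$p > 0))
  expect_true(any(res2$clusters$significant))
})

test_that("Monte-Carlo p agrees with exhaustive enumeration at n = 6", {
  set.seed(33)
  n <- 6
  a <- matrix(stats::rnorm(n * 20), n, 20)
  b <- a
  b[, 8:12] <- b[, 8:12] - 1.2
  ex <- cluster_permutation_test(a, b, exhaustive = TRUE)
  mc <- cluster_permutation_test(a, b, n_perm = 800, seed = 5)
  expect_true(ex$exhaustive)
  expect_equal(ex$n_perm_used, 64)
  expect_gte(nrow(ex$clusters), 1)
  i_ex <- which.max(abs(ex$clusters$mass))
  i_mc <- which.max(abs(mc$clusters$mass))
  expect_equal(ex$clusters$mass[i_ex], mc$clusters$mass[i_mc])
  expect_lt(abs(ex$clusters$p[i_ex] - mc$clusters$p[i_mc]), 0.05)
})

test_that("permutation p-values are invariant to feature relabeling", {
  set.seed(44)
  n <- 8
  a <- matrix(stats::rnorm(n * 15), n, 15)
  b <- a; b[, 4:7] <- b[, 4:7] - 1
  res1 <- cluster_permutation_test(a, b, n_perm = 300, seed = 9)
  # reverse the feature axis: same clusters, same masses, same p
  res2 <- cluster_permutation_test(a[, 15:1], b[, 15:1], n_perm = 300,
                                   seed = 9)
  expect_equal(sort(res1$clusters$mass), sort(res2$clusters$mass))
  expect_equal(sort(res1$clusters$p), sort(res2$clusters$p))
})

test_that("an injected post-movement power difference is detected on the time grid", {
  # paired 'sessions': session B adds a smooth bump over features 30..45
  set.seed(55)
  n <- 14
  hits <- 0
  for (s in 1:10) {
    noise1 <- matrix(stats::rnorm(n * 60, sd = 1), n, 60)
    noise2 <- matrix(stats::rnorm(n * 60, sd = 1), n, 60)
    bump <- c(rep(0, 29), 1.4 * sin(seq(0, pi, length.out = 16)), rep(0, 15))
    bmat <- matrix(bump, n, 60, byrow = TRUE)
    res <- cluster_permutation_test(noise1 + bmat, noise2, n_perm = 300,
                                    seed = s)
    sig <- res$clusters[res$clusters$significant, ]
    if (nrow(sig) && any(vapply(sig$features, function(f)
      any(f %in% 30:45), logical(1)))) hits <- hits + 1
  }
  expect_gte(hits, 9)
})

test_that("2-D grids cluster over the 4-neighbourhood", {
  set.seed(66)
  n <- 10; nf <- 6; nt <- 12
  a <- matrix(stats::rnorm(n * nf * nt), n)
  b <- a
  grid <- matrix(0, nf, nt)
  grid[2:4, 5:8] <- 1.5
  b <- b - matrix(rep(as.vector(grid), each = n), n)
  res <- cluster_permutation_test(a, b, n_perm = 200, dims = c(nf, nt),
                                  seed = 2)
  sig <- res$clusters[res$clusters$significant, ]
  expect_gte(nrow(sig), 1)
  target <- which(as.vector(grid) > 0)
  overlap <- max(vapply(sig$features, function(f)
    length(intersect(f, target)), integer(1)))
  expect_gte(overlap, 6)
})

test_that("empirical family-wise error rate sits near alpha, and alpha 0 rejects nothing", {
  null_gen <- function(r) {
    list(a = matrix(stats::rnorm(12 * 30), 12, 30),
         b = matrix(stats::rnorm(12 * 30), 12, 30))
  }
  h <- typeI_harness(null_gen, n_reps = 200, n_perm = 150, seed = 77)
  expect_gte(h$rate, 0.01)
  expect_lte(h$rate, 0.10)
  # identical rate under the same seed
  h2 <- typeI_harness(null_gen, n_reps = 50, n_perm = 100, seed = 5)
  h3 <- typeI_harness(null_gen, n_reps = 50, n_perm = 100, seed = 5)
  expect_identical(h2$rate, h3$rate)
  expect_equal(typeI_harness(null_gen, n_reps = 20, alpha = 0, seed = 1)$rate,
               0)
})

test_that("window_paired_summary pairs subjects and matches a direct computation", {
  metrics <- tibble::tibble(
    subject = rep(1:4, times = 2),
    session = rep(c(1, 3), each = 4),
    window = "postmove", metric = "probability",
    value = c(0.10, 0.12, 0.09, 0.11, 0.14, 0.15, 0.12, 0.16))
  s <- window_paired_summary(metrics, "probability", "postmove", c(1, 3))
  expect_equal(s$differences$diff, c(0.04, 0.03, 0.03, 0.05))
  expect_equal(s$mean_diff, 0.0375)
  tt <- stats::t.test(c(0.04, 0.03, 0.03, 0.05))
  expect_equal(s$t, unname(tt$statistic))
  expect_equal(s$p, tt$p.value)

  # identical sessions: zero differences, degenerate t flagged as NA
  m2 <- metrics; m2$value[5:8] <- m2$value[1:4]
  s2 <- window_paired_summary(m2, "probability", "postmove", c(1, 3))
  expect_equal(s2$mean_diff, 0)
  expect_true(is.na(s2$t))

  # unmatched subjects error
  m3 <- metrics[-6, ]
  expect_error(window_paired_summary(m3, "probability", "postmove", c(1, 3)),
               "unmatched")
})
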