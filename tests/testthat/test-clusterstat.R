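test_that("channel adjacency follows the distance-quantile rule", {
  m <- make_montage()
  empty <- build_adjacency(m, 0)
  expect_equal(sum(lengths(empty$neighbors)), 0L)
  complete <- build_adjacency(m, 1)
  expect_equal(sum(lengths(complete$neighbors)) / 2, 64 * 63 / 2)
  adj <- build_adjacency(m)
  deg <- lengths(adj$neighbors)
  expect_true(stats::median(deg) >= 4 && stats::median(deg) <= 10)
  # neighbouring temporal electrodes are connected at the default quantile
  t7 <- match("T7", adj$labels)
  tp7 <- match("TP7", adj$labels)
  expect_true(tp7 %in% adj$neighbors[[t7]])
  # symmetry, no self edges
  for (i in seq_along(adj$neighbors)) {
    expect_false(i %in% adj$neighbors[[i]])
    for (j in adj$neighbors[[i]]) expect_true(i %in% adj$neighbors[[j]])
  }
  expect_error(build_adjacency(m, 2), "quantile")
})

test_that("pair adjacency links pairs sharing a channel with neighbouring other ends", {
  m <- subset_montage(make_montage(), c("FT7", "T7", "TP7", "C4"))
  adj <- build_adjacency(m, 0.4)
  padj <- build_pair_adjacency(adj)
  expect_equal(length(padj$labels), 6L)
  lab <- padj$labels
  # FT7-T7 and T7-TP7 share T7, and FT7 ~ TP7 is not required; the rule
  # requires the two non-shared channels to be neighbours
  i <- match("FT7-T7", lab)
  for (j in padj$neighbors[[i]]) {
    a <- strsplit(lab[i], "-")[[1]]
    b <- strsplit(lab[j], "-")[[1]]
    shared <- intersect(a, b)
    expect_equal(length(shared), 1L)
    other <- c(setdiff(a, shared), setdiff(b, shared))
    oi <- match(other, adj$labels)
    expect_true(oi[2] %in% adj$neighbors[[oi[1]]])
  }
})

test_that("identical groups give no supra-threshold clusters", {
  set.seed(33)
  x <- array(rnorm(6 * 4 * 7 * 7), c(6, 4, 7, 7))
  adj <- build_adjacency(subset_montage(make_montage(),
                                        c("FT7", "T7", "TP7", "P7")), 0.5)
  res <- cluster_test(x, x, adj, 0.001, 100, seed = 1)
  expect_equal(length(res$clusters), 0L)
})

test_that("a planted block shift is detected and localized", {
  set.seed(7)
  mont <- scaled_montage()
  adj <- build_adjacency(mont, 0.3)
  ga <- array(rnorm(16 * 8 * 11 * 11), c(16, 8, 11, 11))
  gb <- array(rnorm(16 * 8 * 11 * 11), c(16, 8, 11, 11))
  block_ch <- 3:5   # FT7, T7, TP7 (contiguous on the montage)
  ga[, block_ch, 4:8, 4:8] <- ga[, block_ch, 4:8, 4:8] + 3
  res <- cluster_test(ga, gb, adj, 0.001, 500, seed = 2)
  expect_gt(length(res$clusters), 0L)
  top <- res$clusters[[1]]
  expect_lt(top$p, 0.05)
  expect_equal(top$sign, 1)
  planted <- as.matrix(expand.grid(channel = block_ch, t1 = 4:8,
                                   t2 = 4:8))
  covered <- sum(apply(planted, 1, function(v)
    any(top$voxels[, 1] == v[1] & top$voxels[, 2] == v[2] &
          top$voxels[, 3] == v[3])))
  expect_gte(covered / nrow(planted), 0.8)
})

test_that("permutation p is invariant to common monotone rescaling", {
  set.seed(12)
  adj <- build_adjacency(subset_montage(make_montage(),
                                        c("FT7", "T7", "TP7", "P7")), 0.5)
  ga <- array(rnorm(8 * 4 * 6 * 6), c(8, 4, 6, 6)) + 1.5
  gb <- array(rnorm(8 * 4 * 6 * 6), c(8, 4, 6, 6))
  r1 <- cluster_test(ga, gb, adj, 0.01, 200, seed = 5)
  r2 <- cluster_test(3 * ga + 2, 3 * gb + 2, adj, 0.01, 200, seed = 5)
  expect_equal(vapply(r1$clusters, `[[`, 1, "p"),
               vapply(r2$clusters, `[[`, 1, "p"))
})

test_that("doubling a planted effect never increases the cluster p", {
  adj <- build_adjacency(subset_montage(make_montage(),
                                        c("FT7", "T7", "TP7", "P7")), 0.5)
  for (seed in 1:4) {
    set.seed(seed)
    base <- array(rnorm(10 * 4 * 6 * 6), c(10, 4, 6, 6))
    gb <- array(rnorm(10 * 4 * 6 * 6), c(10, 4, 6, 6))
    p_at <- function(effect) {
      ga <- base
      ga[, 2:3, 2:5, 2:5] <- ga[, 2:3, 2:5, 2:5] + effect
      res <- cluster_test(ga, gb, adj, 0.01, 300, seed = 50 + seed)
      if (!length(res$clusters)) 1 else min(vapply(res$clusters, `[[`,
                                                   1, "p"))
    }
    expect_lte(p_at(3), p_at(1.5))
  }
})

test_that("exhaustive enumeration matches the combinatorial count and bounds", {
  set.seed(14)
  adj <- build_adjacency(subset_montage(make_montage(),
                                        c("T7", "TP7")), 1)
  ga <- array(rnorm(4 * 2 * 5 * 5) + 2, c(4, 2, 5, 5))
  gb <- array(rnorm(4 * 2 * 5 * 5), c(4, 2, 5, 5))
  ex <- exhaustive_null(ga, gb, adj, 0.05)
  expect_equal(ex$n_perm, choose(8, 4))
  for (cl in ex$clusters) expect_gte(cl$p, 1 / 70)
  # cluster_test in exhaustive mode is the same enumeration
  ex2 <- cluster_test(ga, gb, adj, 0.05, permutations = "exhaustive")
  expect_equal(vapply(ex$clusters, `[[`, 1, "mass"),
               vapply(ex2$clusters, `[[`, 1, "mass"))
  expect_equal(vapply(ex$clusters, `[[`, 1, "p"),
               vapply(ex2$clusters, `[[`, 1, "p"))
  big_a <- array(rnorm(12 * 2 * 5 * 5), c(12, 2, 5, 5))
  big_b <- array(rnorm(12 * 2 * 5 * 5), c(12, 2, 5, 5))
  expect_error(exhaustive_null(big_a, big_b, adj, 0.05),
               "Monte Carlo")
})

test_that("cluster means extract the stated per-subject averages", {
  vals <- array(0, c(3, 2, 4, 5, 5))
  vals[1, 1, 2, 3, 3] <- 10
  cl <- list(voxels = cbind(channel = 2, t1 = 3, t2 = 3))
  out <- extract_cluster_means(vals, cl, conditions = 1)
  expect_equal(out$cond1, c(10, 0, 0))
  # constant map -> the constant
  vals_c <- array(7, c(3, 2, 4, 5, 5))
  cl2 <- list(voxels = cbind(channel = c(1, 4), t1 = c(2, 3),
                             t2 = c(2, 4)))
  expect_equal(extract_cluster_means(vals_c, cl2, 2)$cond2, rep(7, 3))
  # two voxels with values 1 and 3 average to 2
  vals_d <- array(0, c(1, 1, 4, 5, 5))
  vals_d[1, 1, 1, 2, 2] <- 1
  vals_d[1, 1, 2, 2, 2] <- 3
  cl3 <- list(voxels = cbind(channel = c(1, 2), t1 = 2, t2 = 2))
  expect_equal(extract_cluster_means(vals_d, cl3, 1)$cond1, 2)
})
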