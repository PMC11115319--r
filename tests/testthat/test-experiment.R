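# Grid selection and comparison statistics.

make_results_table <- function(seed = 1) {
  set.seed(seed)
  grid <- expand.grid(core = c("task_a", "task_b"),
                      layer = c("conv1", "layer1.0", "layer2.0"),
                      scale = c(7, 14), lambda = c(1, 3), seed = 1:3,
                      stringsAsFactors = FALSE)
  grid$val_score <- runif(nrow(grid))
  grid
}

test_that("grid selection maximizes the seed-averaged validation score", {
  tab <- make_results_table(4)
  single <- tab[tab$core == "task_a" & tab$layer == "conv1" &
                  tab$scale == 7 & tab$lambda == 1, ]
  sel1 <- grid_select(single)
  expect_identical(nrow(sel1), 1L)
  expect_equal(sel1$val_score, mean(single$val_score))

  # exhaustive-scan oracle over all configurations
  sel <- grid_select(tab)
  for (co in unique(tab$core)) {
    sub <- tab[tab$core == co, ]
    key <- paste(sub$layer, sub$scale, sub$lambda)
    means <- tapply(sub$val_score, key, mean)
    expect_equal(sel$val_score[sel$core == co], max(means))
  }

  # invariant to row order
  shuf <- tab[sample(nrow(tab)), ]
  expect_equal(grid_select(shuf)[order(grid_select(shuf)$core), ],
               sel[order(sel$core), ], ignore_attr = TRUE)
  expect_error(grid_select(tab[0, ]), "non-empty")
})

test_that("grid selection breaks ties by smallest lambda then earliest layer", {
  tab <- data.frame(core = "a",
                    layer = c("layer2.0", "conv1", "conv1"),
                    scale = 7, lambda = c(1, 3, 1), seed = 1,
                    val_score = 0.5)
  sel <- grid_select(tab)
  expect_identical(sel$lambda, 1)
  expect_identical(sel$layer, "conv1")
})

test_that("default lambda grids cover the per-layer protocol", {
  lg <- lambda_grid()
  expect_equal(lg$conv1, c(0.33, 1, 3))
  expect_equal(lg$layer4.0, c(6, 12))
})

test_that("cluster contrasts use paired signed-rank tests with Holm correction", {
  set.seed(7)
  n <- 30
  scores <- cbind(semantic = rnorm(n, 0.5, 0.05),
                  `2d` = rnorm(n, 0.3, 0.05),
                  `3d` = rnorm(n, 0.45, 0.05),
                  geometric = rnorm(n, 0.3, 0.05))
  res <- cluster_contrasts(scores)
  expect_identical(nrow(res), 6L)             # 4 clusters -> 6 pairs
  # Holm: the smallest raw p is multiplied by the number of comparisons
  k <- which.min(res$p)
  expect_equal(res$p_adj[k], min(1, res$p[k] * 6))
  expect_true(all(res$p_adj >= res$p))
  # monotone in the raw p values
  expect_false(is.unsorted(res$p_adj[order(res$p)]))

  # groups drawn from the same distribution: nothing significant
  set.seed(42)
  base <- rnorm(n, 0.4, 0.05)
  same <- cbind(a = base, b = base[sample(n)])
  res0 <- cluster_contrasts(same)
  expect_gt(res0$p_adj[1], 0.05)
})

test_that("signed-rank statistic and exact p match full enumeration at small n", {
  set.seed(15)
  n <- 9
  x <- rnorm(n, 0.2)
  y <- rnorm(n)
  res <- cluster_contrasts(cbind(A = x, B = y), exact = TRUE)

  d <- x - y
  rk <- rank(abs(d))
  V <- sum(rk[d > 0])
  expect_equal(res$V, V)

  # exact permutation oracle: all 2^n sign assignments
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  null_v <- signs %*% rk
  p_exact <- min(1, 2 * min(mean(null_v <= V), mean(null_v >= V)))
  expect_equal(res$p, p_exact)
})

test_that("specialization index is a variance of normalized increments", {
  # three hand-chosen scores: direct arithmetic
  s <- c(0.4, 0.5, 0.6); base <- 0.1
  inc <- s - base
  expect_equal(specialization_index(s, base)$index, var(inc / mean(inc)))
  # all equal: zero variance
  expect_equal(specialization_index(c(0.3, 0.3, 0.3), base)$index, 0)
  # the baseline never enters the variance set
  expect_identical(length(specialization_index(s, base)$normalized), 3L)
  # invariant to common positive rescaling of the increments
  expect_equal(specialization_index(base + 5 * inc, base)$index,
               specialization_index(s, base)$index)
  # plain mean-normalized variant
  expect_equal(specialization_index(s, normalize = "mean")$index,
               var(s / mean(s)))
  expect_error(specialization_index(c(0.1, 0.2)), "at least 3")
})

test_that("specialization test reports Bartlett and Levene side by side", {
  set.seed(30)
  s1 <- 0.2 + rnorm(23, 0, 0.02)             # homogeneous area
  s2 <- 0.2 + rnorm(23, 0, 0.12)             # specialized area
  out <- specialization_test(s1, s2, baseline1 = 0.05, baseline2 = 0.05,
                             fisher_z = TRUE)
  expect_identical(out$test, c("bartlett", "levene"))
  expect_true(all(out$p < 0.05))
  expect_lt(attr(out, "index1"), attr(out, "index2"))
})
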