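test_that("PCA on duplicated marker columns is rank one", {
  set.seed(5)
  a <- runif(4)
  rt <- ratio_matrix(rmat(cbind(a, a)), imputed = TRUE)
  pc <- pca_ratios(rt, n_components = 2)
  expect_equal(pc$explained[1], 1)
  expect_equal(sum(pc$explained), 1, tolerance = 1e-10)
})

test_that("explained fractions sum to one over all components", {
  rt <- random_ratios(8, 5, seed = 2)
  pc <- pca_ratios(rt)
  expect_equal(sum(pc$explained), 1, tolerance = 1e-10)
  expect_true(all(pc$explained >= 0))
  expect_true(all(diff(pc$explained) <= 1e-12))
})

test_that("scores match an independent eigendecomposition up to sign", {
  rt <- random_ratios(6, 5, seed = 13)
  pc <- pca_ratios(rt, n_components = 4)
  Z <- scale(rt$ratio)
  ev <- eigen(crossprod(Z) / (nrow(Z) - 1), symmetric = TRUE)
  oracle <- Z %*% ev$vectors[, 1:4]
  for (j in 1:4) {
    s <- sign(sum(oracle[, j] * pc$scores[, j]))
    expect_equal(unname(pc$scores[, j]), unname(s * oracle[, j]),
                 tolerance = 1e-8)
  }
})

test_that("PCA scores are invariant to marker order", {
  rt <- random_ratios(7, 9, seed = 4)
  set.seed(8)
  perm <- sample(9)
  p1 <- pca_ratios(rt, 3)
  p2 <- pca_ratios(ratio_matrix(rt$ratio[, perm], imputed = TRUE), 3)
  expect_equal(abs(p1$scores), abs(p2$scores), tolerance = 1e-8)
  expect_error(pca_ratios(rt, 10), "exceeds")
})

test_that("Ward clustering merges the tight pair first, duplicates at 0", {
  x <- rmat(matrix(c(0, 1, 10, 0, 0, 0), 3, 2))
  cl <- ward_cluster(x)
  expect_equal(sort(cl$hclust$merge[1, ]), c(-2, -1))
  x2 <- rmat(matrix(c(0.3, 0.3, 0.9, 0.1, 0.1, 0.5), 3, 2))
  cl2 <- ward_cluster(x2)
  expect_equal(cl2$hclust$height[1], 0)
  expect_equal(length(unique(cut_clusters(cl2, 2))), 2)
})

test_that("merge order equals a brute-force Lance-Williams agglomeration", {
  rt <- random_ratios(8, 6, seed = 17)
  cl <- ward_cluster(rt)
  ## exhaustive Ward.D2 agglomeration on squared Euclidean distances
  D2 <- as.matrix(dist(rt$ratio))^2
  labels <- -(1:8)
  sizes <- rep(1, 8)
  merges <- matrix(0L, 7, 2)
  heights <- numeric(7)
  for (step in 1:7) {
    k <- nrow(D2)
    best <- c(Inf, 0, 0)
    for (i in 1:(k - 1)) for (j in (i + 1):k) {
      ## Ward.D2 merge cost between current clusters
      ni <- sizes[i]; nj <- sizes[j]
      cost <- D2[i, j]
      if (cost < best[1] - 1e-12) best <- c(cost, i, j)
    }
    i <- best[2]; j <- best[3]
    heights[step] <- sqrt(best[1])
    merges[step, ] <- sort(c(labels[i], labels[j]))
    ## Lance-Williams update for Ward.D2 on squared distances
    ni <- sizes[i]; nj <- sizes[j]
    newd <- sapply(seq_len(k), function(l) {
      if (l == i || l == j) return(NA_real_)
      nl <- sizes[l]
      ((ni + nl) * D2[i, l] + (nj + nl) * D2[j, l] - nl * D2[i, j]) /
        (ni + nj + nl)
    })
    keep <- setdiff(seq_len(k), c(i, j))
    D2 <- rbind(cbind(D2[keep, keep, drop = FALSE], newd[keep]),
                c(newd[keep], 0))
    labels <- c(labels[keep], step)
    sizes <- c(sizes[keep], ni + nj)
  }
  hm <- cl$hclust$merge
  hm_sorted <- t(apply(hm, 1, sort))
  expect_equal(unname(hm_sorted), unname(merges))
  expect_equal(cl$hclust$height, heights, tolerance = 1e-10)
  expect_true(all(diff(cl$hclust$height) >= -1e-12))
})

test_that("AMOVA matches the direct centroid sums-of-squares oracle", {
  set.seed(10)
  X <- rmat(matrix(rnorm(12 * 6), 12, 6))
  g <- rep(c("A", "B"), each = 6)
  s <- rep(c("a1", "a2", "b1", "b2"), each = 3)
  X[g == "B", ] <- X[g == "B", ] + 2
  X[s %in% c("a2", "b2"), ] <- X[s %in% c("a2", "b2"), ] + 0.7
  am <- amova_two_level(X, g, s, n_perm = 0)
  expect_equal(unname(am$sigma), unname(amova_oracle(X, g, s)),
               tolerance = 1e-10)
  expect_equal(sum(am$percent), 100, tolerance = 1e-9)
  expect_equal(unname(am$phi["ST"]),
               unname((am$sigma["a"] + am$sigma["b"]) / sum(am$sigma)),
               tolerance = 1e-12)
  ## components reconstruct the total variance from the distances
  expect_equal(unname(am$ssd["total"]),
               sum(scale(X, scale = FALSE)^2), tolerance = 1e-10)
})

test_that("degenerate and ill-posed AMOVA designs are rejected or NA", {
  X <- rmat(matrix(0.5, 8, 3))
  g <- rep(c("A", "B"), each = 4)
  s <- rep(c("a1", "a2", "b1", "b2"), each = 2)
  expect_warning(am <- amova_two_level(X, g, s, n_perm = 0), "undefined")
  expect_true(all(is.na(am$phi)))
  expect_error(amova_two_level(rmat(matrix(runif(18), 6, 3)),
                               rep(c("A", "B"), each = 3),
                               c("a1", "a1", "a1", "b1", "b1", "b2")),
               ">= 2")
  expect_error(
    amova_two_level(rmat(matrix(runif(24), 8, 3)),
                    rep("A", 8), rep(c("a1", "a2"), 4), n_perm = 0),
    ">= 2 group")
})

test_that("AMOVA is invariant to passing distances instead of data", {
  set.seed(30)
  X <- rmat(matrix(rnorm(24), 12, 2))
  g <- rep(c("A", "B"), each = 6)
  s <- rep(c("a1", "a2", "b1", "b2"), each = 3)
  a1 <- amova_two_level(X, g, s, n_perm = 0)
  a2 <- amova_two_level(dist(X), g, s, n_perm = 0)
  a3 <- amova_two_level(as.matrix(dist(X))^2, g, s, n_perm = 0,
                        is_squared_dist = TRUE)
  expect_equal(a1$sigma, a2$sigma, tolerance = 1e-12)
  expect_equal(a1$sigma, a3$sigma, tolerance = 1e-12)
})
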