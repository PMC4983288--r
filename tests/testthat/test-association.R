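test_that("spaced-marker selection hits equally spaced cM targets", {
  map <- data.frame(marker = sprintf("m%03d", 0:100),
                    linkage_group = "Mrg01", position_cM = 0:100)
  sel <- select_spaced_markers(map, 3)
  expect_equal(sort(sel), c("m000", "m050", "m100"))
  expect_equal(sort(select_spaced_markers(map, 101)), sort(map$marker))
  expect_error(select_spaced_markers(map, 200), "exceeds")
})

test_that("allocation across groups follows largest-remainder arithmetic", {
  map <- rbind(
    data.frame(marker = sprintf("a%03d", 0:100), linkage_group = "Mrg01",
               position_cM = 0:100),
    data.frame(marker = sprintf("b%02d", 0:50), linkage_group = "Mrg02",
               position_cM = 0:50))
  sel <- select_spaced_markers(map, 9)
  expect_equal(sum(startsWith(sel, "a")), 6)
  expect_equal(sum(startsWith(sel, "b")), 3)
  expect_false(anyDuplicated(sel) > 0)
  expect_error(select_spaced_markers(map, 1), "below")
})

test_that("kinship is the scaled Gower double-centering of distances", {
  rt <- random_ratios(5, 8, seed = 23)
  K <- kinship_from_ratios(rt)
  ## brute-force -1/2 C D^2 C, then diagonal-mean scaling
  D2 <- as.matrix(dist(rt$ratio))^2
  n <- 5
  C <- diag(n) - matrix(1 / n, n, n)
  G <- -0.5 * C %*% D2 %*% C
  Ko <- G / mean(diag(G))
  expect_equal(unclass(K), Ko, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(unname(rowSums(K)), rep(0, n), tolerance = 1e-10)
  expect_equal(mean(diag(K)), 1, tolerance = 1e-12)
  ## duplicated samples: off-diagonal equals the diagonal entries
  m <- rt$ratio; m[2, ] <- m[1, ]
  K2 <- kinship_from_ratios(ratio_matrix(m, imputed = TRUE))
  expect_equal(K2[1, 2], K2[1, 1], tolerance = 1e-10)
  expect_equal(K2[1, 1], K2[2, 2], tolerance = 1e-10)
  expect_error(kinship_from_ratios(rt, subset = "nope"), "absent")
})

test_that("REML delta estimate matches a dense grid-search oracle", {
  set.seed(41)
  n <- 60
  rt <- random_ratios(n, 150, seed = 41)
  K <- kinship_from_ratios(rt)
  ## simulate y with h2 = 0.5 under K
  ev <- eigen(unclass(K), symmetric = TRUE)
  L <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0)))
  y <- drop(L %*% rnorm(n)) * sqrt(0.5) + rnorm(n, 0, sqrt(0.5))
  fit <- fit_null_mixed(y, K)
  ## independent oracle: brute-force 1e6-point grid over log10 delta
  X <- matrix(1, n, 1)
  Xq <- qr.Q(qr(X))
  SKS <- unclass(K) - Xq %*% crossprod(Xq, unclass(K))
  SKS <- SKS - (SKS %*% Xq) %*% t(Xq)
  es <- eigen((SKS + t(SKS)) / 2, symmetric = TRUE)
  xi <- pmax(es$values[1:(n - 1)], 0)
  eta <- drop(crossprod(es$vectors[, 1:(n - 1)], y))
  nq <- n - 1
  best <- c(-Inf, NA)
  for (chunk in split(seq(-10, 10, length.out = 1e6),
                      rep(1:100, each = 1e4))) {
    W <- outer(xi, 10^chunk, "+")
    ll <- -nq * log(colSums(eta^2 / W)) - colSums(log(W))
    i <- which.max(ll)
    if (ll[i] > best[1]) best <- c(ll[i], chunk[i])
  }
  expect_equal(log10(fit$delta), best[2], tolerance = 5e-4)
  expect_equal(fit$sigma_e2 / fit$sigma_g2, fit$delta, tolerance = 1e-10)
  ## optimum at least as good as every grid point tested
  expect_gte(fit$loglik,
             0.5 * (nq * log(nq / (2 * pi)) - nq + best[1]) - 1e-6)
})

test_that("identity kinship and vanishing genetic variance reduce to OLS", {
  ## seed chosen so the REML maximum sits at the no-genetic-variance
  ## boundary (a null trait only drives delta there about half the time)
  set.seed(2)
  n <- 50
  rt <- random_ratios(n, 40, seed = 2)
  y <- rnorm(n)
  simple <- gwas(y, rt, "simple")
  ## K = I
  KI <- structure(diag(n), class = c("kinship_matrix", "matrix"))
  a_ki <- gwas(y, rt, "kinship", K = KI)
  expect_lt(max(abs(a_ki$neg_log10_p - simple$neg_log10_p)), 1e-8)
  ## structured K but y independent of it: delta -> upper bound
  K <- kinship_from_ratios(rt)
  a_k <- gwas(y, rt, "kinship", K = K)
  fit <- attr(a_k, "fit")
  expect_gt(fit$delta, 1e9)
  expect_lt(max(abs(a_k$neg_log10_p - simple$neg_log10_p)), 1e-6)
})

test_that("zero principal components reduce the pcs model to simple", {
  rt <- random_ratios(30, 25, seed = 77)
  set.seed(77); y <- rnorm(30)
  pca <- pca_ratios(rt, 5)
  a0 <- gwas(y, rt, "pcs", pca = pca, n_pcs = 0)
  a1 <- gwas(y, rt, "simple")
  expect_equal(a0$neg_log10_p, a1$neg_log10_p, tolerance = 1e-12)
  a2 <- gwas(y, rt, "pcs", pca = pca, n_pcs = 2)
  expect_false(isTRUE(all.equal(a2$neg_log10_p, a1$neg_log10_p)))
})

test_that("perfect and orthogonal markers hit the p-value extremes", {
  set.seed(88)
  n <- 40
  y <- rnorm(n)
  m <- rmat(matrix(runif(n * 3), n, 3))
  m[, 1] <- (y - min(y)) / diff(range(y))       # marker == rescaled y
  yc <- y - mean(y)
  v <- m[, 3] - mean(m[, 3])
  m[, 2] <- 0.5 + 0.2 * (v - yc * sum(v * yc) / sum(yc^2))  # orthogonal to y
  a <- gwas(y, ratio_matrix(m, imputed = TRUE), "simple")
  expect_equal(a$neg_log10_p[1], 300)
  expect_equal(a$p[2], 1, tolerance = 1e-12)
  expect_equal(a$effect[2], 0, tolerance = 1e-12)
})

test_that("gwas is invariant to consistent sample reordering", {
  rt <- random_ratios(25, 15, seed = 91)
  set.seed(91); y <- setNames(rnorm(25), rownames(rt$ratio))
  K <- kinship_from_ratios(rt)
  a1 <- gwas(y, rt, "kinship", K = K)
  p <- sample(25)
  rt2 <- ratio_matrix(rt$ratio[p, ], imputed = TRUE)
  K2 <- kinship_from_ratios(rt2)
  a2 <- gwas(y[p], rt2, "kinship", K = K2)
  expect_equal(a1$neg_log10_p, a2$neg_log10_p, tolerance = 1e-6)
  expect_error(gwas(y[-1], rt, "simple"), "missing")
})

test_that("M_eff equals M for orthogonalized markers", {
  set.seed(19)
  n <- 40; m <- 10
  Q <- qr.Q(qr(scale(matrix(rnorm(n * m), n, m))))   # orthonormal, centered?
  Q <- scale(Q, center = TRUE, scale = FALSE)
  ## re-orthogonalize the centered columns
  Q <- qr.Q(qr(Q))[, 1:m]
  Q <- Q - matrix(colMeans(Q), n, m, byrow = TRUE)
  Q <- qr.Q(qr(cbind(1, Q)))[, -1]                   # orthogonal to 1 and each other
  rt <- ratio_matrix(rmat(0.5 + 0.2 * Q), imputed = TRUE)
  th <- lij_threshold(rt, alpha = 0.05)
  expect_equal(th$M_eff, m, tolerance = 1e-6)
  expect_equal(th$neg_log10_threshold,
               -log10(1 - 0.95^(1 / m)), tolerance = 1e-9)
})

test_that("fully duplicated marker pairs halve M_eff", {
  ## base markers orthogonalized so the correlation matrix is exactly
  ## block diagonal with {2, 0} eigenvalue pairs
  set.seed(20)
  n <- 30; m <- 6
  Q <- qr.Q(qr(cbind(1, matrix(rnorm(n * m), n, m))))[, -1]
  base <- 0.5 + 0.2 * Q
  rt <- ratio_matrix(rmat(cbind(base, base)), imputed = TRUE)
  th <- lij_threshold(rt)
  expect_equal(th$M_eff, 6, tolerance = 1e-8)
  expect_equal(th$M, 12)
})

test_that("dual and direct eigen-computations of M_eff agree", {
  set.seed(21)
  rt <- random_ratios(20, 50, seed = 21)        # m > n: dual path
  th <- lij_threshold(rt)
  lam <- eigen(cor(rt$ratio), symmetric = TRUE, only.values = TRUE)$values
  lam <- pmax(lam, 0)
  snap <- round(lam); near <- abs(lam - snap) < 1e-8; lam[near] <- snap[near]
  m_eff_direct <- sum((lam >= 1) + (lam - floor(lam)))
  expect_equal(th$M_eff, m_eff_direct, tolerance = 1e-8)
  expect_true(th$M_eff >= 1 && th$M_eff <= th$M)
})

test_that("M_eff is invariant to marker order and allele flips", {
  rt <- random_ratios(15, 25, seed = 22)
  t0 <- lij_threshold(rt)$M_eff
  set.seed(23)
  perm <- sample(25)
  flip <- sample(c(TRUE, FALSE), 25, replace = TRUE)
  m2 <- rt$ratio[, perm]
  m2[, flip[perm]] <- 1 - m2[, flip[perm]]
  t1 <- lij_threshold(ratio_matrix(m2, imputed = TRUE))$M_eff
  expect_equal(t0, t1, tolerance = 1e-8)
})

test_that("qq diagnostics recover the uniform null exactly", {
  m <- 201   # odd, so the median order statistic is exactly 1/2
  p <- seq_len(m) / (m + 1)
  qq <- qq_data(p)
  expect_equal(qq$points$observed, qq$points$expected, tolerance = 1e-12)
  expect_equal(qq$lambda_gc, 1, tolerance = 1e-9)
  qq1 <- qq_data(rep(1, 10))
  expect_true(all(qq1$points$observed == 0))
  expect_error(qq_data(c(0, 0.5)), "0, 1")
})

test_that("outlier post-filter flags minor clusters below the count floor", {
  n <- 61
  m <- rmat(cbind(c(rep(0, 60), 1),
                  c(rep(0, 30), rep(1, 31)),
                  runif(n)))
  assoc <- structure(
    data.frame(marker = colnames(m),
               effect = 1, se = 1, stat = 1, p = 1e-8,
               neg_log10_p = c(8, 8, 1), model = "simple",
               outlier_flag = NA),
    class = c("assoc_result", "data.frame"))
  out <- outlier_flag(ratio_matrix(m, imputed = TRUE), assoc,
                      threshold = 4)
  expect_true(out$outlier_flag[1])      # minor cluster of 1
  expect_false(out$outlier_flag[2])     # 30/31 split
  expect_true(is.na(out$outlier_flag[3]))  # not significant
})

test_that("single-outlier-driven associations are caught in null sims", {
  hits <- 0L
  for (seed in 1:100) {
    set.seed(seed)
    n <- 60
    y <- rnorm(n)
    j <- which.max(abs(y - mean(y)))
    marker <- rep(0.1, n); marker[j] <- 0.9   # association carried by 1 sample
    m <- rmat(cbind(marker, matrix(runif(n * 4), n, 4)))
    a <- gwas(y, ratio_matrix(m, imputed = TRUE), "simple")
    a <- outlier_flag(ratio_matrix(m, imputed = TRUE), a,
                      threshold = min(a$neg_log10_p[1], 1))
    if (isTRUE(a$outlier_flag[1])) hits <- hits + 1L
  }
  expect_gte(hits, 90)
})
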