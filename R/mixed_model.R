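#' REML fit of the null variance-component model
#'
#' Estimates the variance components of
#' `y = X beta + g + e`, `g ~ N(0, sigma_g^2 K)`,
#' `e ~ N(0, sigma_e^2 I)` by restricted maximum likelihood under the
#' no-marker null, parameterized by the ratio
#' `delta = sigma_e^2 / sigma_g^2`. The REML log-likelihood is a 1-D
#' function of delta after eigendecomposition of K projected on the
#' space orthogonal to the covariates; it is maximized over
#' `log10(delta)` in [-10, 10] by a 100-point grid followed by Brent
#' refinement (tolerance 1e-8). The wide base-10 box lets the
#' no-genetic-variance limit collapse onto ordinary least squares to
#' numerical precision. The fit caches the eigendecomposition
#' of K used to whiten the data in per-marker tests.
#'
#' @param y numeric response vector, length n.
#' @param K n x n positive semidefinite kinship matrix.
#' @param covariates optional numeric matrix of fixed covariates
#'   (without intercept; an intercept is always included).
#' @return class `mm_fit`: `delta`, `sigma_g2`, `sigma_e2`, REML
#'   `loglik`, the cached `eigK`, `n`, and the covariate matrix used.
#' @export
fit_null_mixed <- function(y, K, covariates = NULL) {
  n <- length(y)
  K <- unclass(K)
  stopifnot(is.matrix(K), nrow(K) == n, ncol(K) == n)
  X <- cbind(`(Intercept)` = rep(1, n), covariates)
  q <- qr(X)$rank
  if (q < ncol(X)) stop("covariates are rank deficient")
  if (n < ncol(X) + 2) stop("too few samples for the covariate count")
  evK <- eigen(K, symmetric = TRUE)
  if (min(evK$values) < -1e-6) stop("K is not positive semidefinite")
  ## eigendecomposition of S K S, S the projector off the column space of X
  Xq <- qr.Q(qr(X))
  SKS <- K - Xq %*% crossprod(Xq, K)
  SKS <- SKS - (SKS %*% Xq) %*% t(Xq)
  SKS <- (SKS + t(SKS)) / 2
  es <- eigen(SKS, symmetric = TRUE)
  keep <- seq_len(n - q)
  xi <- pmax(es$values[keep], 0)
  eta <- drop(crossprod(es$vectors[, keep, drop = FALSE], y))
  nq <- n - q
  reml_ll <- function(logdelta) {
    d <- 10^logdelta
    w <- xi + d
    0.5 * (nq * log(nq / (2 * pi)) - nq -
             nq * log(sum(eta^2 / w)) - sum(log(w)))
  }
  grid <- seq(-10, 10, length.out = 100)
  vals <- vapply(grid, reml_ll, 0)
  i <- which.max(vals)
  lo <- grid[max(1, i - 1)]; hi <- grid[min(length(grid), i + 1)]
  opt <- stats::optimize(reml_ll, c(lo, hi), maximum = TRUE, tol = 1e-8)
  cand <- rbind(c(opt$maximum, opt$objective), c(grid[i], vals[i]))
  best <- cand[which.max(cand[, 2]), ]
  delta <- 10^best[1]
  sigma_g2 <- sum(eta^2 / (xi + delta)) / nq
  sigma_e2 <- delta * sigma_g2
  structure(list(delta = delta, sigma_g2 = sigma_g2, sigma_e2 = sigma_e2,
                 loglik = best[2], eigK = evK, n = n, X = X),
            class = "mm_fit")
}

#' @export
print.mm_fit <- function(x, ...) {
  cat("mm_fit: sigma_g2 =", signif(x$sigma_g2, 4),
      " sigma_e2 =", signif(x$sigma_e2, 4),
      " delta =", signif(x$delta, 4),
      " REML logLik =", signif(x$loglik, 6), "\n")
  invisible(x)
}

## whitening transform rows: W y has iid errors under the null fit
.whitener <- function(fit) {
  lam <- pmax(fit$eigK$values, 0)
  U <- fit$eigK$vectors
  t(U) * (1 / sqrt(lam + fit$delta))
}

## vectorized GLS scan: y, C (covariates incl. intercept), M (markers),
## all already whitened (or raw for OLS). Wald F with 1 df.
.scan_markers <- function(yt, Ct, Mt) {
  n <- length(yt)
  q <- ncol(Ct)
  QR <- qr(Ct)
  yr <- qr.resid(QR, yt)
  Mr <- qr.resid(QR, Mt)
  mm <- colSums(Mr^2)
  my <- colSums(Mr * yr)
  dfree <- n - q - 1
  rss0 <- sum(yr^2)
  ok <- mm > 1e-12 * max(mm, 1)
  beta <- ifelse(ok, my / mm, 0)
  rss <- pmax(rss0 - ifelse(ok, my^2 / mm, 0), 0)
  sigma2 <- rss / dfree
  ## a (numerically) perfect fit underflows p; report it as Inf so the
  ## -log10 cap at 300 applies
  perfect <- ok & rss < 1e-10 * rss0
  Fstat <- ifelse(perfect, Inf,
                  ifelse(ok & sigma2 > 0, (my^2 / mm) / sigma2, 0))
  lp <- stats::pf(Fstat, 1, dfree, lower.tail = FALSE, log.p = TRUE)
  nlp <- pmin(-lp / log(10), 300)
  se <- ifelse(ok, sqrt(sigma2 / mm), NA_real_)
  data.frame(effect = beta, se = se, stat = Fstat,
             p = 10^(-nlp), neg_log10_p = nlp)
}

#' Genome-wide association scan on intensity ratios
#'
#' Tests each marker's ratio column as a fixed covariate for the trait
#' under one of four models: `simple` (no correction,
#' `y = marker + error`), `kinship` (EMMAX-style linear mixed model
#' `y = marker + genotype + error` with the polygenic effect
#' structured by K), `pcs` (principal component scores as fixed
#' covariates), or `pcs+kinship` (both). For the mixed models the
#' variance components are estimated once under the no-marker null
#' ([fit_null_mixed()]) and reused for every marker (the EMMAX
#' approximation); each marker is then tested by generalized least
#' squares in the whitened space with a 1-df Wald F test,
#' denominator df = n - rank(design). `-log10 p` is capped at 300.
#'
#' @param y named numeric vector of per-accession trait values (names
#'   must match the ratio matrix sample ids) or unnamed vector in row
#'   order.
#' @param ratios imputed [ratio_matrix()] or matrix.
#' @param model one of `"simple"`, `"kinship"`, `"pcs"`,
#'   `"pcs+kinship"`.
#' @param K kinship matrix (required for the kinship models).
#' @param pca a [pca_ratios()] result (required for the pcs models).
#' @param n_pcs number of principal components used as covariates
#'   (default 15; typical choices 10, 15, 20, 40; 0 reduces to the
#'   model without PCs).
#' @param fit optional pre-computed [fit_null_mixed()] result.
#' @return class `assoc_result`: data.frame with columns `marker`,
#'   `effect`, `se`, `stat`, `p`, `neg_log10_p`, `model`,
#'   `outlier_flag` (NA until [outlier_flag()] is applied). The null
#'   fit, when any, is attached as attribute `fit`.
#' @export
gwas <- function(y, ratios, model = c("simple", "kinship", "pcs",
                                      "pcs+kinship"),
                 K = NULL, pca = NULL, n_pcs = 15, fit = NULL) {
  model <- match.arg(model)
  rm_ <- .ratio_mat(ratios)
  n <- nrow(rm_)
  if (!is.null(names(y))) {
    missing_s <- setdiff(rownames(rm_), names(y))
    if (length(missing_s))
      stop("y is missing accessions: ",
           paste(utils::head(missing_s, 5), collapse = ", "))
    y <- y[rownames(rm_)]
  }
  if (length(y) != n) stop("length(y) != number of samples")
  if (anyNA(y)) stop("y contains missing values")
  covs <- NULL
  if (model %in% c("pcs", "pcs+kinship")) {
    if (is.null(pca)) stop("model '", model, "' requires a pca result")
    if (n_pcs > 0) {
      if (n_pcs > ncol(pca$scores))
        stop("n_pcs exceeds available components")
      covs <- pca$scores[, seq_len(n_pcs), drop = FALSE]
      colnames(covs) <- paste0("PC", seq_len(n_pcs))
    }
  }
  use_k <- model %in% c("kinship", "pcs+kinship")
  if (use_k) {
    if (is.null(K) && is.null(fit))
      stop("model '", model, "' requires a kinship matrix K")
    if (is.null(fit)) fit <- fit_null_mixed(y, K, covs)
    W <- .whitener(fit)
    yt <- drop(W %*% y)
    Ct <- W %*% cbind(`(Intercept)` = rep(1, n), covs)
    Mt <- W %*% rm_
  } else {
    yt <- as.numeric(y)
    Ct <- cbind(`(Intercept)` = rep(1, n), covs)
    Mt <- rm_
  }
  res <- .scan_markers(yt, Ct, Mt)
  out <- data.frame(marker = colnames(rm_), res, model = model,
                    outlier_flag = NA, stringsAsFactors = FALSE)
  class(out) <- c("assoc_result", "data.frame")
  attr(out, "fit") <- if (use_k) fit else NULL
  out
}

#' Per-marker full-REML association scan (reference implementation)
#'
#' Refits the variance components by REML for every marker (the marker
#' in the fixed part of its own null projection) instead of reusing
#' the no-marker null fit. Orders of magnitude slower than [gwas()];
#' intended as the exact reference against which the EMMAX
#' approximation is validated.
#'
#' @inheritParams gwas
#' @param covariates optional fixed-covariate matrix (no intercept).
#' @return an `assoc_result` data.frame (model label
#'   `"kinship-full-reml"`).
#' @export
gwas_full_reml <- function(y, ratios, K, covariates = NULL) {
  rm_ <- .ratio_mat(ratios)
  n <- nrow(rm_)
  if (!is.null(names(y))) y <- y[rownames(rm_)]
  K <- unclass(K)
  evK <- eigen(K, symmetric = TRUE)
  lam <- pmax(evK$values, 0)
  U <- evK$vectors
  res <- vector("list", ncol(rm_))
  for (j in seq_len(ncol(rm_))) {
    X <- cbind(rep(1, n), covariates, rm_[, j])
    q <- qr(X)$rank
    Xq <- qr.Q(qr(X))[, seq_len(q), drop = FALSE]
    SKS <- K - Xq %*% crossprod(Xq, K)
    SKS <- SKS - (SKS %*% Xq) %*% t(Xq)
    SKS <- (SKS + t(SKS)) / 2
    es <- eigen(SKS, symmetric = TRUE)
    keep <- seq_len(n - q)
    xi <- pmax(es$values[keep], 0)
    eta <- drop(crossprod(es$vectors[, keep, drop = FALSE], y))
    nq <- n - q
    ll <- function(logdelta) {
      w <- xi + 10^logdelta
      0.5 * (nq * log(nq / (2 * pi)) - nq -
               nq * log(sum(eta^2 / w)) - sum(log(w)))
    }
    grid <- seq(-10, 10, length.out = 100)
    vals <- vapply(grid, ll, 0)
    i <- which.max(vals)
    opt <- stats::optimize(ll, c(grid[max(1, i - 1)],
                                 grid[min(length(grid), i + 1)]),
                           maximum = TRUE, tol = 1e-8)
    delta <- 10^(if (opt$objective >= vals[i]) opt$maximum else grid[i])
    W <- t(U) * (1 / sqrt(lam + delta))
    yt <- drop(W %*% y)
    Ct <- W %*% cbind(rep(1, n), covariates)
    Mt <- W %*% rm_[, j, drop = FALSE]
    res[[j]] <- .scan_markers(yt, Ct, Mt)
  }
  out <- data.frame(marker = colnames(rm_), do.call(rbind, res),
                    model = "kinship-full-reml", outlier_flag = NA,
                    stringsAsFactors = FALSE)
  class(out) <- c("assoc_result", "data.frame")
  out
}
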