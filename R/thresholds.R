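#' Genome-wide significance threshold via the effective number of tests
#'
#' Computes the Li & Ji effective number of independent tests from the
#' eigenvalues of the marker-marker correlation matrix and converts
#' the genome-wide level `alpha` into a per-test level by the Sidak
#' formula. Each eigenvalue lambda contributes
#' `f(lambda) = 1(lambda >= 1) + (lambda - floor(lambda))`; the sum
#' over all m eigenvalues is `M_eff`. When there are more markers
#' than samples the eigenvalues are obtained from the dual n x n
#' cross-product matrix (identical nonzero spectrum, zero-padded to
#' m). Eigenvalues within 1e-8 of an integer are snapped to it so the
#' integer-boundary discontinuity of f is not hit by floating-point
#' noise.
#'
#' @param ratios imputed [ratio_matrix()] or matrix; m >= 2 markers,
#'   all with nonzero variance.
#' @param alpha genome-wide significance level (default 0.05).
#' @return class `threshold_result`: `M`, `M_eff`, `alpha`, `alpha_p`
#'   (per-test Sidak level) and `neg_log10_threshold`.
#' @export
lij_threshold <- function(ratios, alpha = 0.05) {
  rm_ <- .ratio_mat(ratios)
  n <- nrow(rm_); m <- ncol(rm_)
  if (m < 2) stop("need >= 2 markers")
  Z <- scale(rm_, center = TRUE, scale = TRUE)
  if (anyNA(Z)) stop("zero-variance or missing marker column")
  Z <- Z / sqrt(n - 1)               # corr matrix = crossprod(Z)
  lam <- if (m > n) {
    c(eigen(tcrossprod(Z), symmetric = TRUE, only.values = TRUE)$values,
      rep(0, m - n))[seq_len(m)]
  } else {
    eigen(crossprod(Z), symmetric = TRUE, only.values = TRUE)$values
  }
  snap <- round(lam)
  near <- abs(lam - snap) < 1e-8
  lam[near] <- snap[near]
  lam <- pmax(lam, 0)
  f <- as.numeric(lam >= 1) + (lam - floor(lam))
  m_eff <- sum(f)
  alpha_p <- 1 - (1 - alpha)^(1 / m_eff)
  structure(list(M = m, M_eff = m_eff, alpha = alpha, alpha_p = alpha_p,
                 neg_log10_threshold = -log10(alpha_p)),
            class = "threshold_result")
}

#' @export
print.threshold_result <- function(x, ...) {
  cat("threshold_result: M =", x$M, " M_eff =", signif(x$M_eff, 6),
      " alpha =", x$alpha,
      " -log10 threshold =", signif(x$neg_log10_threshold, 6), "\n")
  invisible(x)
}

#' Observed-vs-expected p-value diagnostics
#'
#' Pairs the sorted observed `-log10 p` with the `-log10` of the
#' uniform order statistics `i/(m+1)` expected under the global null,
#' and computes the median-based genomic inflation factor
#' `lambda_GC = median(chi2_obs) / qchisq(0.5, 1)`, where `chi2_obs`
#' are the 1-df chi-square quantiles of the observed p-values.
#' `lambda_GC` near 1 indicates well-calibrated tests; values well
#' above 1 indicate uncorrected structure confounding.
#'
#' @param pvalues numeric vector of p-values in (0, 1].
#' @return class `qq_data`: data.frame `points` with columns
#'   `expected`, `observed` (both -log10 scale, ascending), and
#'   `lambda_gc`.
#' @export
qq_data <- function(pvalues) {
  p <- pvalues[!is.na(pvalues)]
  if (any(p <= 0 | p > 1)) stop("p-values must lie in (0, 1]")
  m <- length(p)
  obs <- sort(-log10(p))
  expd <- sort(-log10(seq_len(m) / (m + 1)))
  lam <- stats::median(stats::qchisq(p, df = 1, lower.tail = FALSE)) /
    stats::qchisq(0.5, df = 1, lower.tail = FALSE)
  structure(list(points = data.frame(expected = expd, observed = obs),
                 lambda_gc = lam),
            class = "qq_data")
}

#' @export
print.qq_data <- function(x, ...) {
  cat("qq_data:", nrow(x$points), "tests; lambda_GC =",
      signif(x$lambda_gc, 4), "\n")
  invisible(x)
}

#' Flag significant markers driven by a few outlying samples
#'
#' Association from a continuous ratio column can be carried by one or
#' two aberrant samples — the continuous-data analogue of a
#' low-minor-allele-frequency artifact. For each marker at or above
#' the significance threshold this splits its sorted ratios at the
#' largest gap; the side with fewer samples is the minor cluster, and
#' the marker is flagged when that cluster holds fewer than
#' `min_minor_count` samples. Flags annotate the result, they never
#' delete rows.
#'
#' @param ratios imputed [ratio_matrix()] or matrix.
#' @param assoc an `assoc_result` from [gwas()].
#' @param threshold `-log10 p` significance threshold (e.g. from
#'   [lij_threshold()]).
#' @param min_minor_count minimum minor-cluster size (default 3).
#' @return the `assoc_result` with `outlier_flag` set (TRUE/FALSE) for
#'   significant markers, NA elsewhere.
#' @export
outlier_flag <- function(ratios, assoc, threshold, min_minor_count = 3) {
  rm_ <- .ratio_mat(ratios)
  stopifnot(inherits(assoc, "assoc_result"))
  assoc$outlier_flag <- NA
  sig <- which(assoc$neg_log10_p >= threshold)
  for (i in sig) {
    r <- sort(rm_[, assoc$marker[i]])
    n <- length(r)
    gaps <- diff(r)
    g <- which.max(gaps)           # first largest gap
    minor <- min(g, n - g)
    assoc$outlier_flag[i] <- minor < min_minor_count
  }
  assoc
}
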