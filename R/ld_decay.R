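#' Pairwise linkage disequilibrium within linkage groups
#'
#' Computes, for every pair of mapped markers on the same linkage
#' group, the classical LD (`r2`, squared Pearson correlation of
#' their ratio columns) and a structure-corrected LD (`r2_s`). The
#' correction whitens the ratio columns by the inverse square root of
#' a covariance matrix `V` between individuals (typically the kinship
#' matrix) and projects out the intercept in the whitened space, so
#' correlation generated purely by population stratification or
#' relatedness is removed before squaring. With `V = NULL` (or the
#' identity) `r2_s` equals `r2`.
#'
#' Singular `V` is handled by a pseudo-inverse square root on its
#' positive eigenspace (relative tolerance 1e-10); a double-centered
#' kinship matrix, whose null vector is the intercept, therefore
#' works unchanged.
#'
#' @param ratios imputed [ratio_matrix()] or matrix.
#' @param map marker map data.frame (`marker`, `linkage_group`,
#'   `position_cM`); unmapped markers are ignored.
#' @param V optional n x n positive semidefinite covariance matrix
#'   between individuals.
#' @return class `ld_pairs`: data.frame with `marker1`, `marker2`,
#'   `linkage_group`, `dist_cM`, `r2`, `r2_s`.
#' @export
ld_pairs <- function(ratios, map, V = NULL) {
  rm_ <- .ratio_mat(ratios)
  n <- nrow(rm_)
  mp <- map[!is.na(map$linkage_group) & !is.na(map$position_cM) &
              map$marker %in% colnames(rm_), , drop = FALSE]
  if (!nrow(mp)) stop("no mapped markers present in the ratio matrix")
  Xc <- scale(rm_[, mp$marker, drop = FALSE], center = TRUE, scale = FALSE)
  if (is.null(V)) {
    Xw <- Xc
  } else {
    V <- unclass(V)
    ev <- eigen((V + t(V)) / 2, symmetric = TRUE)
    pos <- ev$values > 1e-10 * max(ev$values)
    if (!any(pos)) stop("V has no positive eigenvalues")
    W <- t(ev$vectors[, pos, drop = FALSE]) / sqrt(ev$values[pos])
    Xw <- W %*% rm_[, mp$marker, drop = FALSE]
    one_w <- drop(W %*% rep(1, n))
    nrm <- sum(one_w^2)
    if (nrm > 1e-12)                 # project out whitened intercept
      Xw <- Xw - one_w %*% t(crossprod(Xw, one_w)) / nrm
  }
  out <- vector("list", 0)
  skipped <- 0L
  for (g in unique(mp$linkage_group)) {
    idx <- which(mp$linkage_group == g)
    if (length(idx) < 2) next
    idx <- idx[order(mp$position_cM[idx], mp$marker[idx])]
    pos <- mp$position_cM[idx]
    ids <- mp$marker[idx]
    pair <- which(upper.tri(diag(length(idx))), arr.ind = TRUE)
    ## classical r2
    cc <- stats::cor(Xc[, idx, drop = FALSE])
    r2 <- cc[pair]^2
    ## corrected r2: squared cosine of whitened, intercept-free columns
    Xg <- Xw[, idx, drop = FALSE]
    cp <- crossprod(Xg)
    d <- diag(cp)
    ok <- d > 1e-12 * max(d)
    r2s <- (cp[pair]^2) / (d[pair[, 1]] * d[pair[, 2]])
    bad <- !(ok[pair[, 1]] & ok[pair[, 2]])
    if (any(bad)) {
      skipped <- skipped + sum(bad)
      r2s[bad] <- NA_real_
    }
    df <- data.frame(marker1 = ids[pair[, 1]], marker2 = ids[pair[, 2]],
                     linkage_group = g,
                     dist_cM = abs(pos[pair[, 1]] - pos[pair[, 2]]),
                     r2 = r2, r2_s = pmin(r2s, 1),
                     stringsAsFactors = FALSE)
    df <- df[!is.na(df$r2_s), , drop = FALSE]
    out[[length(out) + 1]] <- df
  }
  if (skipped > 0)
    warning(skipped, " pair(s) skipped: zero variance after whitening")
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("ld_pairs", "data.frame")
  res
}

#' Binned-percentile LD decay curve
#'
#' Groups within-linkage-group marker pairs into distance bins of
#' `bin_width` cM (left-closed, right-open: [0,1), [1,2), ...), takes
#' the per-bin `percentile` of the corrected r2 values (type-7
#' linear-interpolation quantile), and smooths the (bin midpoint,
#' percentile) points with a penalized cubic regression spline. The
#' smoothing parameter is selected by REML (default), which is robust
#' where generalized cross-validation degenerates to interpolation on
#' short, nearly-noise-free percentile series; `method = "gcv"`
#' exposes the classical GCV-selected `smooth.spline` instead. Bins
#' with fewer than `min_pairs` pairs are reported but excluded from
#' smoothing (sparse far-distance bins otherwise make the upper
#' percentile erratic). With fewer than four usable bins the
#' percentiles are returned unsmoothed.
#'
#' @param pairs an [ld_pairs()] result.
#' @param bin_width bin width in cM (default 1).
#' @param percentile percentile summarized per bin (default 90).
#' @param min_pairs minimum pair count for a bin to enter the
#'   smoothing (default 20).
#' @param method smoothing-parameter selection: `"reml"` (penalized
#'   regression spline via [mgcv::gam()]) or `"gcv"`
#'   ([stats::smooth.spline()]).
#' @return class `ld_decay_curve`: data.frame `bins` (`lower`,
#'   `upper`, `mid`, `n_pairs`, `percentile`, `used`, `smoothed`) and
#'   the spline fit object (or NULL).
#' @export
decay_curve <- function(pairs, bin_width = 1, percentile = 90,
                        min_pairs = 20, method = c("reml", "gcv")) {
  method <- match.arg(method)
  stopifnot(nrow(pairs) > 0)
  b <- floor(pairs$dist_cM / bin_width)
  lev <- seq(0, max(b))
  cnt <- tabulate(b + 1, nbins = length(lev))
  qv <- rep(NA_real_, length(lev))
  for (i in seq_along(lev)) {
    v <- pairs$r2_s[b == lev[i]]
    if (length(v)) qv[i] <- stats::quantile(v, percentile / 100,
                                            type = 7, names = FALSE)
  }
  used <- cnt >= min_pairs
  if (!any(used)) stop("all bins hold fewer than min_pairs pairs")
  bins <- data.frame(lower = lev * bin_width,
                     upper = (lev + 1) * bin_width,
                     mid = (lev + 0.5) * bin_width,
                     n_pairs = cnt, percentile = qv, used = used)
  sm <- NULL
  bins$smoothed <- NA_real_
  xs <- bins$mid[used]; ys <- bins$percentile[used]
  if (stats::sd(ys) < 1e-12) {
    bins$smoothed[used] <- ys          # constant input: nothing to smooth
  } else if (sum(used) >= 4) {
    if (method == "reml") {
      dd <- data.frame(x = xs, y = ys)
      k <- min(10, sum(used) - 1)
      sm <- mgcv::gam(y ~ s(x, bs = "cr", k = k), data = dd,
                      method = "REML")
      bins$smoothed[used] <- as.numeric(
        mgcv::predict.gam(sm, data.frame(x = xs)))
    } else {
      sm <- stats::smooth.spline(xs, ys, cv = FALSE)  # GCV
      bins$smoothed[used] <- stats::predict(sm, xs)$y
    }
  } else {
    bins$smoothed[used] <- ys
  }
  structure(list(bins = bins, spline = sm,
                 bin_width = bin_width, percentile = percentile,
                 min_pairs = min_pairs),
            class = "ld_decay_curve")
}

#' @export
print.ld_decay_curve <- function(x, ...) {
  cat("ld_decay_curve:", nrow(x$bins), "bins of", x$bin_width, "cM;",
      sum(x$bins$used), "used for smoothing (",
      x$percentile, "th percentile)\n")
  invisible(x)
}
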