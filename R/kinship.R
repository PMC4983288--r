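#' Select equally spaced markers along the genetic map
#'
#' Picks a subset of mapped markers spread uniformly in genetic (cM)
#' distance, for use in kinship construction. The target count is
#' allocated to linkage groups proportionally to their map lengths by
#' largest-remainder rounding (every group with mapped markers gets at
#' least one); within a group, the marker nearest each of the equally
#' spaced cM targets is chosen, ties broken by marker id, and no
#' marker is chosen twice.
#'
#' @param map a marker map data.frame (columns `marker`,
#'   `linkage_group`, `position_cM`; unmapped markers have `NA`).
#' @param n_target number of markers to select (e.g. 160, 302, 520);
#'   must be at least the number of linkage groups and at most the
#'   number of mapped markers.
#' @return character vector of selected marker ids.
#' @export
select_spaced_markers <- function(map, n_target) {
  mp <- map[!is.na(map$linkage_group) & !is.na(map$position_cM), ,
            drop = FALSE]
  if (!nrow(mp)) stop("no mapped markers")
  if (n_target > nrow(mp))
    stop("n_target (", n_target, ") exceeds mapped markers (", nrow(mp), ")")
  lgs <- sort(unique(mp$linkage_group))
  if (n_target < length(lgs))
    stop("n_target (", n_target, ") below number of linkage groups (",
         length(lgs), ")")
  len <- vapply(lgs, function(g) {
    p <- mp$position_cM[mp$linkage_group == g]
    diff(range(p))
  }, 0)
  cnt <- vapply(lgs, function(g) sum(mp$linkage_group == g), 0L)
  ## largest-remainder allocation proportional to map length
  if (sum(len) == 0) {
    quota <- rep(n_target / length(lgs), length(lgs))
  } else {
    quota <- n_target * len / sum(len)
  }
  alloc <- floor(quota)
  rem <- n_target - sum(alloc)
  if (rem > 0) {
    ord <- order(quota - alloc, decreasing = TRUE)
    alloc[ord[seq_len(rem)]] <- alloc[ord[seq_len(rem)]] + 1
  }
  ## every group at least 1, and never more than it holds
  repeat {
    over <- alloc > cnt
    alloc[over] <- cnt[over]
    short <- n_target - sum(alloc)
    if (short == 0 && all(alloc >= 1)) break
    if (any(alloc == 0)) {
      i <- which(alloc == 0)[1]
      j <- which.max(alloc - 1 * (alloc <= 1))
      alloc[i] <- 1
      alloc[j] <- alloc[j] - 1
    } else if (short > 0) {
      room <- which(alloc < cnt)
      j <- room[which.max(quota[room] - alloc[room])]
      alloc[j] <- alloc[j] + 1
    } else break
  }
  picked <- character(0)
  for (i in seq_along(lgs)) {
    g <- lgs[i]
    sub <- mp[mp$linkage_group == g, , drop = FALSE]
    sub <- sub[order(sub$position_cM, sub$marker), , drop = FALSE]
    ng <- alloc[i]
    if (ng == 0) next
    lo <- min(sub$position_cM); hi <- max(sub$position_cM)
    targets <- if (ng == 1) (lo + hi) / 2 else
      seq(lo, hi, length.out = ng)
    used <- rep(FALSE, nrow(sub))
    for (t in targets) {
      d <- abs(sub$position_cM - t)
      d[used] <- Inf
      j <- which(d == min(d))
      if (length(j) > 1) j <- j[order(sub$marker[j])][1]
      used[j] <- TRUE
    }
    picked <- c(picked, sub$marker[used])
  }
  picked
}

#' Kinship matrix from Euclidean distances on intensity ratios
#'
#' Builds the covariance structure of the random polygenic effect from
#' pairwise Euclidean distances between samples' ratio profiles:
#' `K = -1/2 * C %*% D^2 %*% C` (Gower double-centering, `C` the
#' centering matrix), which for Euclidean distances equals the
#' centered cross-product matrix and is positive semidefinite. K is
#' then scaled so the mean diagonal element is 1, making the genetic
#' variance component identifiable on a common scale. A small ridge is
#' added only if floating-point error produces an eigenvalue below
#' -1e-10.
#'
#' @param ratios imputed [ratio_matrix()] or matrix.
#' @param subset optional character vector of marker ids to use (e.g.
#'   from [select_spaced_markers()]); default all markers.
#' @return class `kinship_matrix`: the n x n matrix with attributes
#'   `subset_size` and `scale`.
#' @export
kinship_from_ratios <- function(ratios, subset = NULL) {
  rm_ <- .ratio_mat(ratios)
  if (!is.null(subset)) {
    missing_m <- setdiff(subset, colnames(rm_))
    if (length(missing_m))
      stop("subset markers absent from ratios: ",
           paste(utils::head(missing_m, 5), collapse = ", "))
    rm_ <- rm_[, subset, drop = FALSE]
  }
  Xc <- scale(rm_, center = TRUE, scale = FALSE)
  G <- tcrossprod(Xc)                 # == -1/2 C D^2 C for Euclidean D
  sc <- mean(diag(G))
  if (sc <= 0) stop("degenerate kinship: all samples identical")
  K <- G / sc
  ev_min <- min(eigen(K, symmetric = TRUE, only.values = TRUE)$values)
  if (ev_min < -1e-10) K <- K + diag(-ev_min, nrow(K))
  structure(K, class = c("kinship_matrix", "matrix"),
            subset_size = ncol(rm_), scale = sc)
}
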