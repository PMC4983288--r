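#' Principal component analysis of intensity ratios
#'
#' Correlation-matrix PCA with samples as observations and markers as
#' variables: every marker is standardized to zero mean and unit
#' variance across samples before the eigendecomposition, so markers
#' contribute equally regardless of their allele-frequency scale.
#' Component signs are fixed so that each component's
#' largest-magnitude marker loading is positive.
#'
#' @param ratios an imputed [ratio_matrix()] (or plain matrix); every
#'   marker must have nonzero variance (guaranteed by the QC stage).
#' @param n_components number of components to return; at most
#'   `min(n_samples - 1, n_markers)`.
#' @return An object of class `pca_result`: list with `scores`
#'   (samples x components), `loadings` (markers x components),
#'   `explained` (variance fraction per returned component, out of the
#'   total over all components), `sdev` (all singular values / sqrt(n-1)).
#' @export
pca_ratios <- function(ratios, n_components = NULL) {
  rm_ <- .ratio_mat(ratios)
  n <- nrow(rm_); m <- ncol(rm_)
  if (anyNA(rm_)) stop("PCA requires an imputed (complete) ratio matrix")
  v <- apply(rm_, 2, stats::var)
  if (any(v == 0))
    stop("zero-variance marker(s): ",
         paste(utils::head(colnames(rm_)[v == 0], 5), collapse = ", "))
  maxc <- min(n - 1, m)
  if (is.null(n_components)) n_components <- maxc
  if (n_components > maxc)
    stop("n_components (", n_components, ") exceeds min(n-1, m) = ", maxc)
  pc <- stats::prcomp(rm_, center = TRUE, scale. = TRUE)
  ev <- pc$sdev^2
  explained_all <- ev / sum(ev)
  k <- n_components
  L <- pc$rotation[, seq_len(k), drop = FALSE]
  S <- pc$x[, seq_len(k), drop = FALSE]
  ## sign convention: largest-|loading| entry positive per component
  for (j in seq_len(k)) {
    i <- which.max(abs(L[, j]))
    if (L[i, j] < 0) { L[, j] <- -L[, j]; S[, j] <- -S[, j] }
  }
  structure(list(scores = S, loadings = L,
                 explained = explained_all[seq_len(k)],
                 sdev = pc$sdev),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  cat("pca_result:", nrow(x$scores), "samples,", ncol(x$scores),
      "components; explained:",
      paste(sprintf("%.1f%%", 100 * utils::head(x$explained, 5)),
            collapse = " "), "\n")
  invisible(x)
}

#' Ward hierarchical clustering on Euclidean ratio distances
#'
#' Agglomerates samples by Ward's minimum-variance criterion on
#' pairwise Euclidean distances between their ratio profiles. The
#' default dialect is `ward.D2` (squared-Euclidean objective on
#' Euclidean input; heights are Euclidean-scale merge costs); the
#' legacy `ward.D` dialect, which applies Ward's update to the raw
#' distances, only rescales heights, not topology, on data of this
#' kind and is exposed for comparability.
#'
#' @param ratios imputed [ratio_matrix()] or matrix with >= 2 rows.
#' @param dialect `"ward.D2"` (default) or `"ward.D"`.
#' @return class `cluster_result`: the `hclust` object plus the
#'   distance used.
#' @export
ward_cluster <- function(ratios, dialect = c("ward.D2", "ward.D")) {
  dialect <- match.arg(dialect)
  rm_ <- .ratio_mat(ratios)
  if (nrow(rm_) < 2) stop("need >= 2 samples to cluster")
  d <- stats::dist(rm_, method = "euclidean")
  hc <- stats::hclust(d, method = dialect)
  structure(list(hclust = hc, dialect = dialect, dist = d),
            class = "cluster_result")
}

#' Cut a cluster tree into k groups
#'
#' @param clust a [ward_cluster()] result.
#' @param k number of groups.
#' @return named integer vector of group labels (1..k) per sample.
#' @export
cut_clusters <- function(clust, k) {
  stopifnot(inherits(clust, "cluster_result"))
  stats::cutree(clust$hclust, k = k)
}

#' @export
print.cluster_result <- function(x, ...) {
  cat("cluster_result (", x$dialect, "): ",
      length(x$hclust$labels %||% x$hclust$order), " samples\n", sep = "")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## squared Euclidean distance matrix from samples x markers data
.sq_dist <- function(M) {
  G <- tcrossprod(M)
  d <- diag(G)
  D2 <- outer(d, d, "+") - 2 * G
  D2[D2 < 0] <- 0
  D2
}

## sum over i<j within index set of D2, divided by set size
.ssd_within <- function(D2, idx) {
  if (length(idx) < 2) return(0)
  sum(D2[idx, idx]) / (2 * length(idx))
}

.amova_components <- function(D2, groups, subgroups) {
  N <- nrow(D2)
  glev <- unique(groups)
  slev <- unique(subgroups)
  G <- length(glev); S <- length(slev)
  ss_total <- sum(D2) / (2 * N)
  ss_wg <- vapply(glev, function(g) .ssd_within(D2, which(groups == g)), 0)
  ss_ws <- vapply(slev, function(s) .ssd_within(D2, which(subgroups == s)), 0)
  SSD_WS <- sum(ss_ws)
  SSD_AS <- sum(ss_wg) - SSD_WS
  SSD_AG <- ss_total - sum(ss_wg)
  df <- c(AG = G - 1, AS = S - G, WS = N - S)
  MS <- unname(c(SSD_AG, SSD_AS, SSD_WS) / df)
  ## unbalanced-design coefficients for the expected mean squares
  n_s <- as.numeric(table(subgroups)[slev])
  N_g <- as.numeric(table(groups)[glev])
  sub_in_g <- vapply(glev, function(g)
    sum((table(subgroups[groups == g]))^2) / sum(groups == g), 0)
  n1 <- (N - sum(sub_in_g)) / (S - G)
  n2 <- (sum(sub_in_g) - sum(n_s^2) / N) / (G - 1)
  n3 <- (N - sum(N_g^2) / N) / (G - 1)
  sig_c <- MS[3]
  sig_b <- (MS[2] - sig_c) / n1
  sig_a <- (MS[1] - sig_c - n2 * sig_b) / n3
  tot <- sig_a + sig_b + sig_c
  list(ssd = c(AG = SSD_AG, AS = SSD_AS, WS = SSD_WS, total = ss_total),
       df = df, MS = MS,
       sigma = c(a = sig_a, b = sig_b, c = sig_c),
       phi = if (tot <= 0) c(CT = NA_real_, SC = NA_real_, ST = NA_real_)
             else c(CT = sig_a / tot,
                    SC = if (sig_b + sig_c > 0) sig_b / (sig_b + sig_c)
                         else NA_real_,
                    ST = (sig_a + sig_b) / tot))
}

#' Two-level analysis of molecular variance (AMOVA)
#'
#' Partitions distance-based molecular variance into between-group,
#' among-subgroup-within-group and within-subgroup components using
#' the Excoffier sums-of-squares decomposition on squared Euclidean
#' distances, with unbalanced-design coefficients when group or
#' subgroup sizes differ. Significance of each Phi statistic is
#' assessed by permutation: whole subgroups among groups for Phi_CT,
#' samples among subgroups within their group for Phi_SC, samples
#' among all subgroups for Phi_ST; p = (#\{perm >= obs\} + 1) /
#' (n_perm + 1). Negative variance-component estimates are reported
#' as-is and flagged, never truncated.
#'
#' @param x imputed [ratio_matrix()] / data matrix, or a precomputed
#'   squared-Euclidean distance matrix (`dist` or square matrix,
#'   passed with `is_squared_dist = TRUE`).
#' @param groups,subgroups vectors of labels per sample; nested design
#'   (each subgroup belongs to exactly one group). Every group needs
#'   >= 2 subgroups and every subgroup >= 2 samples.
#' @param n_perm number of permutations (default 1000).
#' @param seed RNG seed for the permutations.
#' @param is_squared_dist interpret `x` as squared distances.
#' @return class `amova_result`: variance components, percent of total,
#'   Phi statistics, permutation p-values, df and sums of squares.
#' @export
amova_two_level <- function(x, groups, subgroups, n_perm = 1000,
                            seed = NULL, is_squared_dist = FALSE) {
  if (is_squared_dist) {
    D2 <- as.matrix(x)
  } else if (inherits(x, "dist")) {
    D2 <- as.matrix(x)^2
  } else {
    D2 <- .sq_dist(.ratio_mat(x))
  }
  N <- nrow(D2)
  groups <- as.character(groups)
  subgroups <- as.character(subgroups)
  stopifnot(length(groups) == N, length(subgroups) == N)
  nest <- unique(data.frame(g = groups, s = subgroups))
  if (anyDuplicated(nest$s))
    stop("design not nested: a subgroup appears in more than one group")
  if (length(unique(groups)) < 2)
    stop("need >= 2 groups (between-group component unidentifiable)")
  if (any(table(nest$g) < 2))
    stop("every group needs >= 2 subgroups (components unidentifiable)")
  if (any(table(subgroups) < 2))
    stop("every subgroup needs >= 2 samples (components unidentifiable)")
  obs <- .amova_components(D2, groups, subgroups)
  if (all(obs$sigma == 0) || anyNA(obs$phi)) {
    if (all(abs(obs$sigma) < 1e-300))
      warning("all variance components are zero; Phi statistics undefined")
  }
  perm <- NULL
  if (n_perm > 0 && !anyNA(obs$phi)) {
    perm <- with_seed(seed, {
      sub_of <- stats::setNames(nest$g, nest$s)
      slev <- nest$s
      pge <- matrix(NA_real_, n_perm, 3,
                    dimnames = list(NULL, c("CT", "SC", "ST")))
      for (b in seq_len(n_perm)) {
        ## CT: permute whole subgroups among groups
        g_perm_map <- stats::setNames(sample(unname(sub_of)), slev)
        g_ct <- unname(g_perm_map[subgroups])
        phi_ct <- .amova_components(D2, g_ct, subgroups)$phi["CT"]
        ## SC: permute samples among subgroups within each group
        s_sc <- subgroups
        for (g in unique(groups)) {
          i <- which(groups == g)
          s_sc[i] <- subgroups[sample(i)]
        }
        phi_sc <- .amova_components(D2, groups, s_sc)$phi["SC"]
        ## ST: permute samples among all subgroups (labels follow)
        p <- sample(N)
        phi_st <- .amova_components(D2, groups[p], subgroups[p])$phi["ST"]
        pge[b, ] <- c(phi_ct, phi_sc, phi_st)
      }
      pge
    })
  }
  pval <- c(CT = NA_real_, SC = NA_real_, ST = NA_real_)
  if (!is.null(perm)) {
    for (k in c("CT", "SC", "ST"))
      pval[k] <- (sum(perm[, k] >= obs$phi[k], na.rm = TRUE) + 1) /
        (n_perm + 1)
  }
  tot <- sum(obs$sigma)
  structure(list(
    sigma = obs$sigma,
    percent = if (tot != 0) 100 * obs$sigma / tot else
      stats::setNames(rep(NA_real_, 3), names(obs$sigma)),
    phi = obs$phi, p_value = pval,
    ssd = obs$ssd, df = obs$df, MS = obs$MS,
    negative_components = names(obs$sigma)[obs$sigma < 0],
    n_perm = n_perm, seed = seed),
    class = "amova_result")
}

#' @export
print.amova_result <- function(x, ...) {
  tab <- data.frame(
    source = c("Between groups", "Among subgroups within groups",
               "Within subgroups"),
    df = as.integer(x$df),
    variance = x$sigma,
    percent = x$percent,
    phi = c(x$phi["CT"], x$phi["SC"], x$phi["ST"]),
    p = c(x$p_value["CT"], x$p_value["SC"], x$p_value["ST"]))
  print(tab, row.names = FALSE, digits = 4)
  if (length(x$negative_components))
    cat("note: negative component estimate(s):",
        paste(x$negative_components, collapse = ", "), "\n")
  invisible(x)
}
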