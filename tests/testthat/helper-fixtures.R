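## shared fixture builders; everything deterministic under the seeds
## passed by the callers

rmat <- function(m, sample_prefix = "S", marker_prefix = "M") {
  rownames(m) <- paste0(sample_prefix, seq_len(nrow(m)))
  colnames(m) <- paste0(marker_prefix, sprintf("%03d", seq_len(ncol(m))))
  m
}

## random imputed ratio matrix
random_ratios <- function(n, m, seed) {
  set.seed(seed)
  ratio_matrix(rmat(matrix(runif(n * m), n, m)), imputed = TRUE)
}

## small signal matrix with optional missing cells
random_signals <- function(n, m, seed, miss = 0) {
  set.seed(seed)
  ratio <- rmat(matrix(runif(n * m), n, m))
  R <- matrix(rgamma(n * m, 9, scale = 1.3 / 9), n, m)
  X <- R * ratio; Y <- R * (1 - ratio)
  if (miss > 0) {
    idx <- sample(n * m, miss)
    X[idx] <- NA; Y[idx] <- NA
  }
  dimnames(Y) <- dimnames(X)
  signal_matrix(X, Y)
}

## map with evenly spread markers over linkage groups
toy_map <- function(markers, lgs, lengths) {
  k <- length(markers)
  lg_idx <- rep(seq_along(lgs), length.out = k)
  pos <- unlist(lapply(seq_along(lgs), function(i) {
    ni <- sum(lg_idx == i)
    seq(0, lengths[i], length.out = max(ni, 2))[seq_len(ni)]
  }))
  data.frame(marker = markers, linkage_group = lgs[lg_idx],
             position_cM = pos, stringsAsFactors = FALSE)
}

## direct centroid-deviation AMOVA sums of squares: the independent
## oracle for the distance-based implementation
amova_oracle <- function(X, groups, subgroups) {
  N <- nrow(X)
  ss_dev <- function(M) sum(scale(M, scale = FALSE)^2)
  SS_T <- ss_dev(X)
  SS_WS <- sum(vapply(unique(subgroups), function(s)
    ss_dev(X[subgroups == s, , drop = FALSE]), 0))
  SS_WG <- sum(vapply(unique(groups), function(g)
    ss_dev(X[groups == g, , drop = FALSE]), 0))
  SS_AG <- SS_T - SS_WG
  SS_AS <- SS_WG - SS_WS
  G <- length(unique(groups)); S <- length(unique(subgroups))
  MS <- c(SS_AG / (G - 1), SS_AS / (S - G), SS_WS / (N - S))
  n_s <- table(subgroups); N_g <- table(groups)
  sub_in_g <- vapply(unique(groups), function(g)
    sum(table(subgroups[groups == g])^2) / sum(groups == g), 0)
  n1 <- (N - sum(sub_in_g)) / (S - G)
  n2 <- (sum(sub_in_g) - sum(n_s^2) / N) / (G - 1)
  n3 <- (N - sum(N_g^2) / N) / (G - 1)
  sig_c <- MS[3]
  sig_b <- (MS[2] - sig_c) / n1
  sig_a <- (MS[1] - sig_c - n2 * sig_b) / n3
  c(a = sig_a, b = sig_b, c = sig_c)
}
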