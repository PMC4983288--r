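#' Compute intensity ratios with total-intensity masking
#'
#' Converts two-channel intensities to per-cell ratios X/(X+Y) and masks
#' unreliable reactions by their total intensity R = X + Y: cells with
#' R strictly below `r_low` or strictly above `r_high` become missing,
#' as do cells with zero total or absent source data. The comparisons
#' are strict on both sides.
#'
#' @param signals a [signal_matrix()].
#' @param r_low,r_high total-intensity bounds (defaults 0.25 and 2.5).
#' @return A [ratio_matrix()] with reason codes "R_low", "R_high",
#'   "zero_total", "absent" on masked cells.
#' @export
compute_ratios <- function(signals, r_low = 0.25, r_high = 2.5) {
  stopifnot(inherits(signals, "signal_matrix"), r_low < r_high)
  R <- signals$X + signals$Y
  ratio <- signals$X / R
  reason <- matrix(NA_character_, nrow(R), ncol(R), dimnames = dimnames(R))
  absent <- is.na(signals$X) | is.na(signals$Y)
  zero <- !absent & R == 0
  low <- !absent & !zero & R < r_low
  high <- !absent & !zero & R > r_high
  reason[absent] <- "absent"
  reason[zero] <- "zero_total"
  reason[low] <- "R_low"
  reason[high] <- "R_high"
  ratio[absent | zero | low | high] <- NA_real_
  out <- ratio_matrix(ratio, reason)
  attr(out, "r_bounds") <- c(r_low = r_low, r_high = r_high)
  out
}

#' Filter markers by missingness and variance
#'
#' Applies the two marker-level quality filters, in order: (1) markers
#' whose missing fraction is strictly greater than `max_missing_frac`
#' are excluded; (2) among the survivors, markers whose sample variance
#' (denominator n - 1, non-missing cells) is strictly below
#' `min_variance` are excluded as uninformative. A marker with fewer
#' than two non-missing cells has undefined variance and is dropped
#' with its own reason.
#'
#' @param ratios a pre-imputation [ratio_matrix()].
#' @param max_missing_frac maximum tolerated missing fraction (default
#'   0.25, i.e. markers with more than 25% missing cells are excluded).
#' @param min_variance minimum informative variance (default 0.001).
#' @return A list with elements `ratios` (filtered [ratio_matrix()]) and
#'   `report` (a `qc_report` list: per-filter marker counts, masked-cell
#'   counts by reason, thresholds used, and the removed marker ids).
#' @export
filter_markers <- function(ratios, max_missing_frac = 0.25,
                           min_variance = 0.001) {
  stopifnot(inherits(ratios, "ratio_matrix"), !ratios$imputed)
  rm_ <- ratios$ratio
  n <- nrow(rm_)
  miss_frac <- colMeans(is.na(rm_))
  drop_miss <- miss_frac > max_missing_frac
  n_obs <- colSums(!is.na(rm_))
  v <- apply(rm_, 2, stats::var, na.rm = TRUE)
  drop_undef <- !drop_miss & n_obs < 2
  drop_var <- !drop_miss & !drop_undef & v < min_variance
  keep <- !(drop_miss | drop_var | drop_undef)
  mask_counts <- if (is.null(ratios$reason)) integer(0) else
    table(ratios$reason[!is.na(ratios$reason)])
  report <- structure(list(
    n_samples = n,
    n_markers_in = ncol(rm_),
    n_markers_out = sum(keep),
    masked_cells = as.list(mask_counts),
    removed_missingness = sum(drop_miss),
    removed_variance = sum(drop_var),
    removed_undefined_variance = sum(drop_undef),
    markers_removed_missingness = colnames(rm_)[drop_miss],
    markers_removed_variance = colnames(rm_)[drop_var],
    markers_removed_undefined = colnames(rm_)[drop_undef],
    thresholds = list(max_missing_frac = max_missing_frac,
                      min_variance = min_variance)),
    class = "qc_report")
  out <- ratio_matrix(rm_[, keep, drop = FALSE],
                      if (is.null(ratios$reason)) NULL else
                        ratios$reason[, keep, drop = FALSE])
  list(ratios = out, report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat("QC report:", x$n_markers_in, "->", x$n_markers_out, "markers\n")
  cat("  removed by missingness:", x$removed_missingness,
      "| by variance:", x$removed_variance,
      "| undefined variance:", x$removed_undefined_variance, "\n")
  if (length(x$masked_cells))
    cat("  masked cells:",
        paste(names(x$masked_cells), unlist(x$masked_cells),
              sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Flag heterogeneous samples by intermediate-band ratio fraction
#'
#' A pure (homogeneous) inbred bulk shows intensity ratios concentrated
#' near the homozygous extremes; a genetically heterogeneous bulk (e.g.
#' a mixture of lines, or residual heterozygosity) piles ratios in the
#' intermediate band. For each sample this computes the fraction of its
#' non-missing ratios falling inside `band` and flags samples whose
#' fraction strictly exceeds `max_band_frac`. The statistic is a
#' quantitative surrogate for visual inspection of per-sample ratio
#' histograms; removal of flagged samples is left to the caller.
#'
#' @param ratios a marker-filtered, pre-imputation [ratio_matrix()].
#' @param band numeric length-2, the intermediate ratio band (default
#'   c(0.2, 0.8), inclusive on both ends).
#' @param max_band_frac flag threshold on the band fraction (default 0.5).
#' @return A data.frame with columns `sample`, `band_frac`, `flagged`.
#' @export
flag_heterogeneous_samples <- function(ratios, band = c(0.2, 0.8),
                                       max_band_frac = 0.5) {
  rm_ <- .ratio_mat(ratios)
  stopifnot(length(band) == 2, band[1] < band[2])
  inband <- rm_ >= band[1] & rm_ <= band[2]
  frac <- rowSums(inband, na.rm = TRUE) / rowSums(!is.na(rm_))
  data.frame(sample = rownames(rm_), band_frac = unname(frac),
             flagged = unname(frac > max_band_frac),
             stringsAsFactors = FALSE)
}

#' Impute missing ratios by the per-marker mean
#'
#' Replaces every remaining missing cell with the mean of the marker's
#' non-missing ratios. Observed cells are never changed, so per-marker
#' means are preserved exactly.
#'
#' @param ratios a marker-filtered [ratio_matrix()].
#' @return An imputed [ratio_matrix()] with no missing cells.
#' @export
impute_mean <- function(ratios) {
  stopifnot(inherits(ratios, "ratio_matrix"))
  rm_ <- ratios$ratio
  if (any(colSums(!is.na(rm_)) == 0))
    stop("marker(s) with no observed cells cannot be imputed: ",
         paste(colnames(rm_)[colSums(!is.na(rm_)) == 0], collapse = ", "))
  mu <- colMeans(rm_, na.rm = TRUE)
  idx <- which(is.na(rm_), arr.ind = TRUE)
  if (nrow(idx)) rm_[idx] <- mu[idx[, 2]]
  ratio_matrix(rm_, NULL, imputed = TRUE)
}

#' Run the full signal QC pipeline
#'
#' Fixed stage order: total-intensity masking, marker missingness
#' filter, marker variance filter, sample heterogeneity flagging
#' (on observed, pre-imputation data), per-marker mean imputation.
#'
#' @inheritParams compute_ratios
#' @inheritParams filter_markers
#' @inheritParams flag_heterogeneous_samples
#' @param drop_het_samples remove flagged samples before imputation
#'   (default `FALSE`: flags annotate only).
#' @return list with `ratios` (imputed [ratio_matrix()]), `report`
#'   (`qc_report` augmented with the sample flags), `sample_flags`.
#' @export
qc_pipeline <- function(signals, r_low = 0.25, r_high = 2.5,
                        max_missing_frac = 0.25, min_variance = 0.001,
                        band = c(0.2, 0.8), max_band_frac = 0.5,
                        drop_het_samples = FALSE) {
  rr <- compute_ratios(signals, r_low, r_high)
  fl <- filter_markers(rr, max_missing_frac, min_variance)
  flags <- flag_heterogeneous_samples(fl$ratios, band, max_band_frac)
  kept <- fl$ratios
  if (drop_het_samples && any(flags$flagged)) {
    keep <- !flags$flagged
    kept <- ratio_matrix(kept$ratio[keep, , drop = FALSE],
                         if (is.null(kept$reason)) NULL else
                           kept$reason[keep, , drop = FALSE])
  }
  rep <- fl$report
  rep$flagged_samples <- flags$sample[flags$flagged]
  rep$n_flagged_samples <- sum(flags$flagged)
  rep$thresholds <- c(rep$thresholds,
                      list(r_low = r_low, r_high = r_high,
                           band = band, max_band_frac = max_band_frac))
  list(ratios = impute_mean(kept), report = rep, sample_flags = flags)
}
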