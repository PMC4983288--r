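#' Construct a two-channel signal matrix
#'
#' Container for raw allele-specific hybridization intensities from a
#' biallelic SNP array. `X` and `Y` hold the A- and B-channel intensities
#' for every (sample, marker) cell; the total intensity `R = X + Y` is the
#' per-cell reaction strength used downstream for quality masking.
#'
#' @param X numeric matrix (samples x markers) of A-channel intensities;
#'   must carry sample ids as rownames and marker ids as colnames.
#' @param Y numeric matrix of B-channel intensities, same shape and
#'   dimnames as `X`. `NA` cells mark data absent from the source file.
#' @return An object of class `signal_matrix`: a list with elements `X`,
#'   `Y`, `sample_ids`, `marker_ids`.
#' @export
signal_matrix <- function(X, Y) {
  X <- as.matrix(X)
  Y <- as.matrix(Y)
  if (!identical(dim(X), dim(Y)))
    stop("X and Y must have identical dimensions")
  if (is.null(rownames(X)) || is.null(colnames(X)))
    stop("X must carry sample ids (rownames) and marker ids (colnames)")
  if (anyDuplicated(rownames(X)))
    stop("duplicate sample ids: ",
         paste(unique(rownames(X)[duplicated(rownames(X))]), collapse = ", "))
  if (anyDuplicated(colnames(X)))
    stop("duplicate marker ids: ",
         paste(unique(colnames(X)[duplicated(colnames(X))]), collapse = ", "))
  dimnames(Y) <- dimnames(X)
  if (any(X < 0, na.rm = TRUE) || any(Y < 0, na.rm = TRUE))
    stop("negative intensities are not allowed")
  structure(
    list(X = X, Y = Y,
         sample_ids = rownames(X), marker_ids = colnames(X)),
    class = "signal_matrix")
}

#' @export
print.signal_matrix <- function(x, ...) {
  cat("signal_matrix:", length(x$sample_ids), "samples x",
      length(x$marker_ids), "markers\n")
  cat("  missing cells:", sum(is.na(x$X) | is.na(x$Y)), "\n")
  invisible(x)
}

#' Construct a ratio matrix
#'
#' The pipeline's universal genotype representation: per (sample, marker)
#' intensity ratios X/(X+Y) in [0, 1]. For a pooled (bulk) sample the
#' ratio is a continuous proxy for the bulk allele frequency rather than
#' a discrete genotype call. Missing cells are `NA` in `ratio` and carry
#' a reason code in `reason` ("R_low", "R_high", "zero_total",
#' "absent", ...).
#'
#' @param ratio numeric matrix (samples x markers) with values in [0, 1]
#'   or `NA`; dimnames required.
#' @param reason optional character matrix, same shape, non-`NA` exactly
#'   where `ratio` is missing.
#' @param imputed logical; `TRUE` once missing cells have been replaced
#'   by per-marker means.
#' @return An object of class `ratio_matrix`.
#' @export
ratio_matrix <- function(ratio, reason = NULL, imputed = FALSE) {
  ratio <- as.matrix(ratio)
  if (is.null(rownames(ratio)) || is.null(colnames(ratio)))
    stop("ratio must carry sample ids (rownames) and marker ids (colnames)")
  rng <- range(ratio, na.rm = TRUE)
  if (is.finite(rng[1]) && (rng[1] < 0 || rng[2] > 1))
    stop("ratios must lie in [0, 1]")
  if (!is.null(reason) && !identical(dim(reason), dim(ratio)))
    stop("reason matrix must match ratio dimensions")
  structure(
    list(ratio = ratio, reason = reason, imputed = isTRUE(imputed),
         sample_ids = rownames(ratio), marker_ids = colnames(ratio)),
    class = "ratio_matrix")
}

#' @export
print.ratio_matrix <- function(x, ...) {
  cat("ratio_matrix:", nrow(x$ratio), "samples x", ncol(x$ratio),
      "markers;", sum(is.na(x$ratio)), "missing;",
      if (x$imputed) "imputed" else "not imputed", "\n")
  invisible(x)
}

## internal: accept a ratio_matrix or a plain samples x markers matrix
.ratio_mat <- function(x) {
  if (inherits(x, "ratio_matrix")) return(x$ratio)
  if (is.matrix(x)) return(x)
  stop("expected a ratio_matrix or a numeric matrix")
}

## internal: run expr under a temporary RNG state; never leaks global state
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
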