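## format numerics at 6 significant digits, empty string for NA
.fmt6 <- function(x) {
  if (is.numeric(x)) ifelse(is.na(x), "", signif(x, 6)) else
    ifelse(is.na(x), "", as.character(x))
}

.write_tsv <- function(df, path) {
  out <- as.data.frame(lapply(df, .fmt6), check.names = FALSE,
                       stringsAsFactors = FALSE)
  names(out) <- names(df)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

## deterministic row order: map order (group, position), unmapped last,
## marker id as the final tie-break
.map_order <- function(markers, map = NULL) {
  if (is.null(map)) return(order(markers))
  i <- match(markers, map$marker)
  lg <- map$linkage_group[i]
  pos <- map$position_cM[i]
  unmapped <- is.na(lg) | is.na(pos)
  order(unmapped, ifelse(unmapped, "", lg),
        ifelse(unmapped, 0, pos), markers)
}

#' Write an association result table
#'
#' Fixed column order `marker`, `linkage_group`, `position_cM`,
#' `effect`, `se`, `stat`, `p`, `neg_log10_p`, `model`,
#' `outlier_flag`; floats at 6 significant digits; rows in map order
#' (linkage group, then position), unmapped markers last, marker id
#' breaking ties.
#'
#' @param assoc an `assoc_result` from [gwas()].
#' @param path output TSV path.
#' @param map optional marker map for positions and row order.
#' @return the path, invisibly.
#' @export
write_assoc <- function(assoc, path, map = NULL) {
  df <- as.data.frame(assoc)
  if (!is.null(map)) {
    i <- match(df$marker, map$marker)
    df$linkage_group <- map$linkage_group[i]
    df$position_cM <- map$position_cM[i]
  } else {
    df$linkage_group <- NA_character_
    df$position_cM <- NA_real_
  }
  df <- df[.map_order(df$marker, map),
           c("marker", "linkage_group", "position_cM", "effect", "se",
             "stat", "p", "neg_log10_p", "model", "outlier_flag")]
  .write_tsv(df, path)
}

#' Read back an association table written by [write_assoc()]
#' @param path TSV path.
#' @return an `assoc_result` data.frame.
#' @export
read_assoc <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  df$outlier_flag <- as.logical(df$outlier_flag)
  class(df) <- c("assoc_result", "data.frame")
  df
}

#' Write population-structure outputs
#'
#' Writes PCA scores plus explained-variance fractions (and, when
#' given, the cluster assignment) as one tidy TSV: one row per sample,
#' columns `sample`, `group`, `subgroup`, `PC1..PCk`; a trailing
#' comment-free header row is avoided by storing the explained
#' fractions in a sidecar `<path>.explained.tsv`.
#'
#' @param pca a [pca_ratios()] result.
#' @param path output TSV path.
#' @param groups,subgroups optional named cluster labels per sample.
#' @return the path, invisibly.
#' @export
write_structure <- function(pca, path, groups = NULL, subgroups = NULL) {
  sc <- pca$scores
  df <- data.frame(sample = rownames(sc), stringsAsFactors = FALSE)
  if (!is.null(groups)) df$group <- groups[df$sample]
  if (!is.null(subgroups)) df$subgroup <- subgroups[df$sample]
  df <- cbind(df, as.data.frame(sc))
  .write_tsv(df, path)
  .write_tsv(data.frame(component = colnames(sc),
                        explained = pca$explained),
             paste0(path, ".explained.tsv"))
  invisible(path)
}

#' Write LD pair or decay-curve tables
#'
#' @param ld an [ld_pairs()] or [decay_curve()] result.
#' @param path output TSV path.
#' @return the path, invisibly.
#' @export
write_ld <- function(ld, path) {
  if (inherits(ld, "ld_decay_curve")) {
    .write_tsv(ld$bins, path)
  } else {
    df <- as.data.frame(ld)
    df <- df[order(df$linkage_group, df$dist_cM, df$marker1, df$marker2), ]
    .write_tsv(df, path)
  }
}

#' Write a ratio matrix as TSV
#'
#' One row per sample (`sample` column first), one column per marker,
#' empty cells for missing values. Ratios are written at full
#' precision so a write/read round trip is lossless.
#'
#' @param ratios a [ratio_matrix()].
#' @param path output TSV path.
#' @return the path, invisibly.
#' @export
write_ratios <- function(ratios, path) {
  rm_ <- .ratio_mat(ratios)
  df <- data.frame(sample = rownames(rm_), stringsAsFactors = FALSE,
                   check.names = FALSE)
  for (j in colnames(rm_))
    df[[j]] <- ifelse(is.na(rm_[, j]), "",
                      format(rm_[, j], digits = 17, trim = TRUE))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' Write a two-channel signal matrix
#'
#' @param signals a [signal_matrix()].
#' @param path output TSV path.
#' @param dialect `"long"` or `"matrix"` (see [read_signal_report()]).
#' @param header write a bracketed `[Header]`/`[Data]` block first.
#' @return the path, invisibly.
#' @export
write_signal_report <- function(signals, path,
                                dialect = c("long", "matrix"),
                                header = FALSE) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(signals, "signal_matrix"))
  con <- file(path, "w")
  on.exit(close(con))
  if (header) {
    writeLines(c("[Header]",
                 "Content\tsignal export",
                 paste0("Num Samples\t", length(signals$sample_ids)),
                 paste0("Num SNPs\t", length(signals$marker_ids)),
                 "[Data]"), con)
  }
  if (dialect == "long") {
    ## absent cells are written with empty X/Y fields so the
    ## first-appearance sample/marker order survives a round trip
    idx <- cbind(rep(seq_along(signals$sample_ids),
                     each = length(signals$marker_ids)),
                 rep(seq_along(signals$marker_ids),
                     times = length(signals$sample_ids)))
    fmt <- function(v) ifelse(is.na(v), "",
                              format(v, digits = 17, trim = TRUE))
    df <- data.frame(
      `Sample ID` = signals$sample_ids[idx[, 1]],
      `SNP Name` = signals$marker_ids[idx[, 2]],
      X = fmt(signals$X[idx]),
      Y = fmt(signals$Y[idx]),
      check.names = FALSE, stringsAsFactors = FALSE)
    utils::write.table(df, con, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    df <- data.frame(`Sample ID` = signals$sample_ids,
                     check.names = FALSE, stringsAsFactors = FALSE)
    for (mk in signals$marker_ids) {
      df[[paste0(mk, ".X")]] <- format(signals$X[, mk], digits = 17,
                                       trim = TRUE)
      df[[paste0(mk, ".Y")]] <- format(signals$Y[, mk], digits = 17,
                                       trim = TRUE)
    }
    utils::write.table(df, con, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}

#' Write a long-format phenotype table
#' @param pheno data.frame (accession, trait, value, ...).
#' @param path output TSV path.
#' @return the path, invisibly.
#' @export
write_phenotypes <- function(pheno, path) {
  df <- pheno
  df$value <- format(df$value, digits = 17, trim = TRUE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}
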