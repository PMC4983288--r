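## Skip an optional GenomeStudio-style "[Header] ... [Data]" block:
## returns the number of lines to skip before the column-header row.
.data_block_skip <- function(path) {
  head_lines <- readLines(path, n = 200L, warn = FALSE)
  hit <- grep("^\\[Data\\]", head_lines)
  if (length(hit)) hit[1] else 0L
}

#' Read a final-report-like two-channel signal table
#'
#' Reads normalized per-cell A/B intensities exported from array
#' software. Two dialects are supported: `"long"` (one row per sample
#' x marker, columns `Sample ID`, `SNP Name`, `X`, `Y`) and
#' `"matrix"` (one row per sample, first column `Sample ID`, then two
#' columns `<marker>.X`, `<marker>.Y` per marker). An optional
#' bracketed header block is skipped by scanning for a `[Data]` line;
#' without one the file starts at the column-header row. Sample and
#' marker order follow first appearance in the file. Cells absent
#' from a long file are recorded as missing.
#'
#' @param path TSV file path.
#' @param dialect `"long"` (default) or `"matrix"`.
#' @return a [signal_matrix()].
#' @export
read_signal_report <- function(path, dialect = c("long", "matrix")) {
  dialect <- match.arg(dialect)
  skip <- .data_block_skip(path)
  df <- utils::read.delim(path, skip = skip, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (dialect == "long") {
    need <- c("Sample ID", "SNP Name", "X", "Y")
    miss <- setdiff(need, names(df))
    if (length(miss))
      stop("missing required column(s): ", paste(miss, collapse = ", "))
    key <- paste(df$`Sample ID`, df$`SNP Name`, sep = "\r")
    if (anyDuplicated(key)) {
      d <- key[duplicated(key)][1]
      pair <- strsplit(d, "\r", fixed = TRUE)[[1]]
      stop("duplicate record for sample '", pair[1], "', marker '",
           pair[2], "'")
    }
    if (any(df$X < 0, na.rm = TRUE) || any(df$Y < 0, na.rm = TRUE))
      stop("negative intensities are not allowed")
    samples <- unique(df$`Sample ID`)
    markers <- unique(df$`SNP Name`)
    X <- matrix(NA_real_, length(samples), length(markers),
                dimnames = list(samples, markers))
    Y <- X
    i <- cbind(match(df$`Sample ID`, samples),
               match(df$`SNP Name`, markers))
    X[i] <- df$X
    Y[i] <- df$Y
    signal_matrix(X, Y)
  } else {
    if (names(df)[1] != "Sample ID")
      stop("missing required column(s): Sample ID")
    cols <- names(df)[-1]
    xs <- grep("\\.X$", cols, value = TRUE)
    ys <- grep("\\.Y$", cols, value = TRUE)
    markers <- sub("\\.X$", "", xs)
    if (!setequal(markers, sub("\\.Y$", "", ys)))
      stop("matrix dialect needs matched <marker>.X / <marker>.Y columns")
    if (anyDuplicated(df$`Sample ID`))
      stop("duplicate record for sample '",
           df$`Sample ID`[duplicated(df$`Sample ID`)][1], "'")
    X <- as.matrix(df[paste0(markers, ".X")])
    Y <- as.matrix(df[paste0(markers, ".Y")])
    dimnames(X) <- dimnames(Y) <- list(df$`Sample ID`, markers)
    signal_matrix(X, Y)
  }
}

#' Read a marker genetic map
#'
#' TSV with columns `marker`, `linkage_group`, `position_cM`. Markers
#' with an empty linkage group or position are retained as unmapped
#' (`NA`), never dropped: unmapped markers are still tested for
#' association, they just carry no map position.
#'
#' @param path TSV file path.
#' @return data.frame of class `marker_map` with columns `marker`,
#'   `linkage_group`, `position_cM`.
#' @export
read_map <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  need <- c("marker", "linkage_group", "position_cM")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("missing required column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(df$marker))
    stop("duplicate marker in map: ",
         df$marker[duplicated(df$marker)][1])
  raw <- df$position_cM
  empty <- is.na(raw) | raw == ""
  pos <- suppressWarnings(as.numeric(raw))
  bad <- which(!empty & is.na(pos))
  if (length(bad))
    stop("non-numeric position_cM at line ", bad[1] + 1L,
         " ('", raw[bad[1]], "')")
  lg <- df$linkage_group
  lg[lg == "" | empty] <- NA_character_
  pos[empty | is.na(lg)] <- NA_real_
  out <- data.frame(marker = df$marker, linkage_group = lg,
                    position_cM = pos, stringsAsFactors = FALSE)
  class(out) <- c("marker_map", "data.frame")
  out
}

#' Read a long-format phenotype table
#'
#' TSV with at least `accession`, `trait`, `value`; optional
#' `environment`, `plant`, `condition` columns pass through.
#'
#' @param path TSV file path.
#' @return data.frame with `value` numeric.
#' @export
read_phenotypes <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("accession", "trait", "value")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("missing required column(s): ", paste(miss, collapse = ", "))
  df$value <- as.numeric(df$value)
  df
}

#' Read a ratio matrix written by [write_ratios()]
#'
#' @param path TSV file path (first column `sample`, one column per
#'   marker; empty cells are missing).
#' @return a [ratio_matrix()].
#' @export
read_ratios <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (names(df)[1] != "sample") stop("first column must be 'sample'")
  m <- as.matrix(df[-1])
  rownames(m) <- df$sample
  ratio_matrix(m, NULL, imputed = !anyNA(m))
}
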