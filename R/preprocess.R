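# Expression matrices ------------------------------------------------------
#
# Intensities are held as a plain matrix (rows = probes or transcripts,
# columns = samples) plus a sample sheet naming each column's condition
# (WT1/DR1/WT2/DR2) and replicate (1/2), and a scale flag (raw or log2).

CONDITIONS <- c("WT1", "DR1", "WT2", "DR2")

#' Construct an expression matrix
#'
#' @param values numeric matrix with row names (probe or transcript ids) and
#'   column names (sample ids).
#' @param sample_meta data frame with columns `sample_id`, `condition`
#'   (one of WT1, DR1, WT2, DR2) and `replicate`; one row per column of
#'   `values`, matched by `sample_id`.
#' @param scale `"raw"` or `"log2"`.
#' @return object of class `expr_matrix`.
#' @export
expression_matrix <- function(values, sample_meta, scale = c("raw", "log2")) {
  scale <- match.arg(scale)
  stopifnot(is.matrix(values), !is.null(rownames(values)),
            !is.null(colnames(values)))
  req <- c("sample_id", "condition", "replicate")
  if (!all(req %in% names(sample_meta))) {
    stop("sample_meta needs columns: ", paste(req, collapse = ", "))
  }
  if (anyNA(sample_meta[req])) stop("missing sample metadata")
  sample_meta <- sample_meta[match(colnames(values), sample_meta$sample_id), ]
  if (anyNA(sample_meta$sample_id)) {
    stop("sample_meta does not cover every column of the matrix")
  }
  if (!all(sample_meta$condition %in% CONDITIONS)) {
    stop("conditions must be among: ", paste(CONDITIONS, collapse = ", "))
  }
  if (scale == "raw" && any(values < 0)) stop("raw intensities must be >= 0")
  structure(list(values = values, sample_meta = sample_meta, scale = scale),
            class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat("Expression matrix (", x$scale, " scale): ", nrow(x$values), " rows x ",
      ncol(x$values), " samples\n", sep = "")
  print(table(x$sample_meta$condition))
  invisible(x)
}

#' Read an intensity matrix with sample sheet
#'
#' The reader is tolerant of GEO series-matrix-like layouts: lines starting
#' with `!` or `#` are skipped and a leading `ID_REF` (or any first) column
#' supplies row ids.
#'
#' @param matrix_path TSV with first column of row ids, remaining columns
#'   numeric intensities.
#' @param samples_path TSV sample sheet (`sample_id`, `condition`,
#'   `replicate`).
#' @param scale scale of the stored values.
#' @return an `expr_matrix`.
#' @export
read_intensity_matrix <- function(matrix_path, samples_path,
                                  scale = c("raw", "log2")) {
  tab <- read.table(matrix_path, header = TRUE, sep = "\t",
                    comment.char = "!", check.names = FALSE,
                    quote = "\"", stringsAsFactors = FALSE)
  vals <- as.matrix(tab[, -1L, drop = FALSE])
  rownames(vals) <- as.character(tab[[1L]])
  meta <- read.table(samples_path, header = TRUE, sep = "\t",
                     stringsAsFactors = FALSE)
  expression_matrix(vals, meta, match.arg(scale))
}

#' Write an expression matrix and its sample sheet
#'
#' @param m an `expr_matrix`.
#' @param matrix_path output TSV path.
#' @param samples_path optional sample-sheet TSV path.
#' @export
write_intensity_matrix <- function(m, matrix_path, samples_path = NULL) {
  tab <- data.frame(probe_id = rownames(m$values), m$values,
                    check.names = FALSE)
  write.table(tab, matrix_path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(samples_path)) {
    write.table(m$sample_meta, samples_path, sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  invisible(matrix_path)
}

#' Background-correct raw intensities
#'
#' Per column, a lower-quantile background estimate is subtracted and the
#' result floored at `offset` so every value stays positive ahead of the
#' log transform.
#'
#' @param raw an `expr_matrix` on the raw scale.
#' @param offset positive floor applied after subtraction (default 1).
#' @param bg_quantile quantile used as the per-column background estimate
#'   (default 0.05).
#' @return background-corrected `expr_matrix`, still raw scale.
#' @export
background_correct <- function(raw, offset = 1, bg_quantile = 0.05) {
  stopifnot(inherits(raw, "expr_matrix"), raw$scale == "raw")
  if (!is.numeric(offset) || offset <= 0) stop("offset must be positive")
  v <- raw$values
  bg <- apply(v, 2L, quantile, probs = bg_quantile, names = FALSE)
  v <- sweep(v, 2L, bg)
  v[v < offset] <- offset
  expression_matrix(v, raw$sample_meta, "raw")
}

#' Log2-transform a raw expression matrix
#'
#' @param m an `expr_matrix` on the raw scale with positive values.
#' @return `expr_matrix` on the log2 scale.
#' @export
log2_transform <- function(m) {
  stopifnot(inherits(m, "expr_matrix"), m$scale == "raw")
  if (any(m$values <= 0)) stop("log2 transform needs positive values; ",
                               "background-correct with a positive offset")
  expression_matrix(log2(m$values), m$sample_meta, "log2")
}

#' Quantile-normalize a log2 expression matrix
#'
#' Each column's values are replaced by the across-column mean of order
#' statistics at their ranks, forcing all samples onto one intensity
#' distribution.  Ties receive the mean of their rank-range targets.
#'
#' @param m an `expr_matrix` on the log2 scale.
#' @return normalized `expr_matrix`.
#' @export
quantile_normalize <- function(m) {
  stopifnot(inherits(m, "expr_matrix"), m$scale == "log2")
  v <- m$values
  if (ncol(v) < 2L) return(m)
  ref <- rowMeans(apply(v, 2L, sort))
  cs <- c(0, cumsum(ref))
  out <- apply(v, 2L, function(col) {
    # a tie group occupying ranks k..k+t-1 receives mean(ref[k:(k+t-1)])
    rmin <- rank(col, ties.method = "min")
    rmax <- rank(col, ties.method = "max")
    (cs[rmax + 1L] - cs[rmin]) / (rmax - rmin + 1L)
  })
  dimnames(out) <- dimnames(v)
  expression_matrix(out, m$sample_meta, "log2")
}

#' Replicate concordance between two samples
#'
#' Ordinary least-squares fit of `y` on `x` plus the Pearson correlation, as
#' a quality check that biological replicates agree.
#'
#' @param x,y numeric vectors of log2 intensities, equal length >= 3.
#' @return list with `slope`, `intercept`, `pearson_r`.
#' @export
replicate_concordance <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3L)
  if (sd(x) == 0) stop("degenerate regressor: x has zero variance")
  fit <- lm(y ~ x)
  list(slope = unname(coef(fit)[2L]), intercept = unname(coef(fit)[1L]),
       pearson_r = cor(x, y))
}

#' Summarize probe-level values to transcripts
#'
#' The chip carries up to three tiling probes per transcript; per transcript
#' and sample they are collapsed with the median (or mean).
#'
#' @param m probe-level `expr_matrix`.
#' @param probe2tx named character vector mapping probe id to transcript id.
#' @param method `"median"` or `"mean"`.
#' @return transcript-level `expr_matrix`.
#' @export
summarize_probes <- function(m, probe2tx, method = c("median", "mean")) {
  method <- match.arg(method)
  fun <- if (method == "median") median else mean
  stopifnot(inherits(m, "expr_matrix"))
  tx <- probe2tx[rownames(m$values)]
  keep <- !is.na(tx)
  groups <- split(which(keep), tx[keep])
  out <- t(vapply(groups, function(idx) {
    apply(m$values[idx, , drop = FALSE], 2L, fun)
  }, numeric(ncol(m$values))))
  colnames(out) <- colnames(m$values)
  expression_matrix(out, m$sample_meta, m$scale)
}

#' Run the full normalization chain
#'
#' Background correction, log2 transform and quantile normalization in one
#' call.
#'
#' @inheritParams background_correct
#' @return normalized log2 `expr_matrix`.
#' @export
normalize_expression <- function(raw, offset = 1, bg_quantile = 0.05) {
  quantile_normalize(log2_transform(
    background_correct(raw, offset = offset, bg_quantile = bg_quantile)))
}
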