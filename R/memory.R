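# Drought-memory taxonomy ---------------------------------------------------
#
# Over two drought/recovery cycles (WT1 -> DR1 -> WT2 -> DR2, two biological
# replicates each), a transcript is drought-induced (DIT) or -repressed (DRT)
# when its first-drought fold change exceeds the threshold in BOTH
# replicates, and carries a memory label (DIMT/DRMT) when, being already
# responsive, its second-drought level changes more than the threshold again
# relative to the first drought.  Thresholds are strict (> fold, < 1/fold).

cond_rep_cols <- function(m) {
  meta <- m$sample_meta
  need <- expand.grid(condition = CONDITIONS, replicate = 1:2)
  idx <- mapply(function(cond, rep) {
    w <- which(meta$condition == cond & meta$replicate == rep)
    if (length(w) != 1L) NA_integer_ else w
  }, need$condition, need$replicate)
  if (anyNA(idx)) {
    miss <- need[is.na(idx), ]
    stop("missing condition/replicate: ",
         paste(miss$condition, miss$replicate, sep = "/", collapse = ", "))
  }
  matrix(idx, nrow = 4L, dimnames = list(CONDITIONS, c("rep1", "rep2")))
}

# linear-scale ratio between two conditions within each replicate
replicate_ratios <- function(m, num, den) {
  cols <- cond_rep_cols(m)
  v <- m$values
  if (m$scale == "log2") {
    cbind(rep1 = 2^(v[, cols[num, 1L]] - v[, cols[den, 1L]]),
          rep2 = 2^(v[, cols[num, 2L]] - v[, cols[den, 2L]]))
  } else {
    cbind(rep1 = v[, cols[num, 1L]] / v[, cols[den, 1L]],
          rep2 = v[, cols[num, 2L]] / v[, cols[den, 2L]])
  }
}

both_pass <- function(ratios, fold, direction, mode) {
  test <- if (direction == "up") function(r) r > fold
  else function(r) r < 1 / fold
  if (mode == "both") test(ratios[, 1L]) & test(ratios[, 2L])
  else test(sqrt(ratios[, 1L] * ratios[, 2L]))
}

#' Classify first-drought response
#'
#' A transcript is labelled `DIT` when its DR1/WT1 ratio exceeds `fold` in
#' both replicates, `DRT` when it falls below `1/fold` in both, otherwise
#' `non-responsive`.  Ratios are computed on the linear scale within each
#' replicate.
#'
#' @param m normalized `expr_matrix` with all four conditions and two
#'   replicates.
#' @param fold fold-change threshold (strict; default 4).
#' @param mode `"both"` requires both replicates to pass (the default);
#'   `"mean"` tests the geometric-mean fold change instead.
#' @param detect_rel detection guard: a transcript whose linear intensity
#'   never reaches `detect_rel` times the matrix median in any sample is
#'   indistinguishable from background and stays `non-responsive` (its
#'   ratios are dominated by the background floor).  Relative to the median,
#'   so classification is invariant under rescaling all intensities.
#' @return data frame (class `memory_classification`) with `transcript_id`,
#'   `label`, a `detected` flag, the per-replicate DR1/WT1 fold changes, and
#'   placeholder memory columns.
#' @export
classify_response <- function(m, fold = 4, mode = c("both", "mean"),
                              detect_rel = 0.05) {
  mode <- match.arg(mode)
  r1 <- replicate_ratios(m, "DR1", "WT1")
  up <- both_pass(r1, fold, "up", mode)
  dn <- both_pass(r1, fold, "down", mode)
  lin <- if (m$scale == "log2") 2^m$values else m$values
  detected <- apply(lin, 1L, max) >= detect_rel * median(lin)
  label <- ifelse(up, "DIT", ifelse(dn, "DRT", "non-responsive"))
  label[!detected] <- "non-responsive"
  structure(data.frame(transcript_id = rownames(m$values), label = label,
                       detected = detected,
                       fc_DR1_WT1_rep1 = r1[, 1L], fc_DR1_WT1_rep2 = r1[, 2L],
                       memory_label = "none",
                       fc_DR2_DR1_rep1 = NA_real_, fc_DR2_DR1_rep2 = NA_real_,
                       recovered_at_WT2 = NA, is_control = FALSE,
                       row.names = NULL, stringsAsFactors = FALSE),
            class = c("memory_classification", "data.frame"))
}

#' Assign drought-memory labels
#'
#' `DIMT` requires a transcript already labelled `DIT` whose DR2/DR1 ratio
#' exceeds `fold` in both replicates; `DRMT` mirrors this for `DRT` with
#' ratios below `1/fold`.  Organellar/control rows are never memory-labelled.
#' Setting `gate = FALSE` applies the DR2-vs-DR1 screen without requiring
#' prior first-drought responsiveness.
#'
#' @param cls output of [classify_response()].
#' @param m the same `expr_matrix`.
#' @param fold fold-change threshold (strict; default 4).
#' @param gate require memory labels to be nested in response labels
#'   (default `TRUE`).
#' @param control_ids transcript ids of organellar/control rows.
#' @inheritParams classify_response
#' @return the classification with `memory_label` and DR2/DR1 fold columns
#'   filled in.
#' @export
classify_memory <- function(cls, m, fold = 4, gate = TRUE,
                            control_ids = NULL, mode = c("both", "mean")) {
  mode <- match.arg(mode)
  stopifnot(inherits(cls, "memory_classification"))
  r2 <- replicate_ratios(m, "DR2", "DR1")
  r2 <- r2[match(cls$transcript_id, rownames(m$values)), , drop = FALSE]
  up <- both_pass(r2, fold, "up", mode)
  dn <- both_pass(r2, fold, "down", mode)
  mem <- ifelse(up, "DIMT", ifelse(dn, "DRMT", "none"))
  if (gate) {
    mem[mem == "DIMT" & cls$label != "DIT"] <- "none"
    mem[mem == "DRMT" & cls$label != "DRT"] <- "none"
  }
  is_ctrl <- cls$transcript_id %in% control_ids
  mem[is_ctrl] <- "none"
  mem[!cls$detected] <- "none"
  cls$memory_label <- mem
  cls$fc_DR2_DR1_rep1 <- r2[, 1L]
  cls$fc_DR2_DR1_rep2 <- r2[, 2L]
  cls$is_control <- is_ctrl
  cls
}

#' Flag recovery at the re-watered state
#'
#' A transcript has recovered when its WT2/WT1 ratio lies within
#' `[1/tolerance_fold, tolerance_fold]` in both replicates.  This is an
#' annotation only; it never filters labels.
#'
#' @param m normalized `expr_matrix`.
#' @param tolerance_fold symmetric tolerance (default 2; `Inf` flags
#'   everything recovered).
#' @return named logical vector over transcripts.
#' @export
recovery_flag <- function(m, tolerance_fold = 2) {
  r <- replicate_ratios(m, "WT2", "WT1")
  ok <- r >= 1 / tolerance_fold & r <= tolerance_fold
  setNames(ok[, 1L] & ok[, 2L], rownames(m$values))
}

#' Classify the full drought-memory taxonomy
#'
#' Convenience wrapper running [classify_response()], [classify_memory()]
#' and [recovery_flag()] in sequence.
#'
#' @inheritParams classify_memory
#' @inheritParams recovery_flag
#' @return a `memory_classification` data frame.
#' @export
classify_drought_memory <- function(m, fold = 4, gate = TRUE,
                                    control_ids = NULL, tolerance_fold = 2,
                                    mode = c("both", "mean"),
                                    detect_rel = 0.05) {
  mode <- match.arg(mode)
  cls <- classify_response(m, fold = fold, mode = mode,
                           detect_rel = detect_rel)
  cls <- classify_memory(cls, m, fold = fold, gate = gate,
                         control_ids = control_ids, mode = mode)
  cls$recovered_at_WT2 <- unname(recovery_flag(m, tolerance_fold))
  cls
}

#' Summarize classification counts
#'
#' @param cls a `memory_classification`.
#' @param path optional directory; when given, per-category transcript-id
#'   lists and a counts table are written there as TSV.
#' @return named integer vector of counts (DIT, DRT, DIMT, DRMT,
#'   non-responsive, recovered).
#' @export
summarize_counts <- function(cls, path = NULL) {
  counts <- c(DIT = sum(cls$label == "DIT"),
              DRT = sum(cls$label == "DRT"),
              DIMT = sum(cls$memory_label == "DIMT"),
              DRMT = sum(cls$memory_label == "DRMT"),
              `non-responsive` = sum(cls$label == "non-responsive"),
              recovered = sum(cls$recovered_at_WT2, na.rm = TRUE))
  if (!is.null(path)) {
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    write.table(data.frame(category = names(counts), count = counts),
                file.path(path, "counts.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    sets <- list(DIT = cls$transcript_id[cls$label == "DIT"],
                 DRT = cls$transcript_id[cls$label == "DRT"],
                 DIMT = cls$transcript_id[cls$memory_label == "DIMT"],
                 DRMT = cls$transcript_id[cls$memory_label == "DRMT"])
    for (nm in names(sets)) {
      writeLines(sets[[nm]], file.path(path, paste0(nm, "_ids.txt")))
    }
  }
  counts
}

#' @export
print.memory_classification <- function(x, n = 6L, ...) {
  cat("Drought-memory classification of", nrow(x), "transcripts\n")
  print(summarize_counts(x))
  if (nrow(x)) {
    cat("\n")
    print(utils::head(as.data.frame(x), n))
  }
  invisible(x)
}
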