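# Moderated differential statistics ----------------------------------------
#
# Per-row residual variances from a one-way condition-means fit are shrunk
# towards a prior via
#
#   s_tilde^2 = (d0 * s0^2 + d * s^2) / (d0 + d)
#
# with the prior degrees of freedom d0 and prior variance s0^2 estimated by
# moment matching on log s^2: if z = log s^2 then
#   E[z] = log s0^2 + digamma(d/2) - log(d/2) - digamma(d0/2) + log(d0/2)
#   Var[z] = trigamma(d/2) + trigamma(d0/2)
# so trigamma(d0/2) is read off the excess spread of z and inverted
# numerically.  The moderated t for a contrast then uses d0 + d degrees of
# freedom.

estimate_prior <- function(s2, d) {
  ok <- s2 > 0
  z <- log(s2[ok])
  e <- z - digamma(d / 2) + log(d / 2)
  ev <- var(z)
  if (!is.finite(ev) || ev < 1e-12) {
    # all rows share one variance: the prior is that value itself, so the
    # shrunk variance stays at s^2 for every row
    return(list(d0 = Inf, s0_2 = exp(mean(z))))
  }
  excess <- ev - trigamma(d / 2)
  if (excess <= 1e-10) {
    # spread no larger than chi-square sampling noise: no heterogeneity
    return(list(d0 = Inf, s0_2 = exp(mean(e))))
  }
  # invert trigamma(d0/2) = excess; trigamma is decreasing on (0, Inf)
  f <- function(x) trigamma(x) - excess
  half_d0 <- tryCatch(
    uniroot(f, lower = 1e-8, upper = 1e8, tol = 1e-10)$root,
    error = function(e) Inf)
  d0 <- 2 * half_d0
  s0_2 <- exp(mean(e) + digamma(half_d0) - log(half_d0))
  list(d0 = d0, s0_2 = s0_2)
}

#' Moderated differential statistics across drought/recovery contrasts
#'
#' Fits per-row condition means on a normalized log2 matrix, shrinks the
#' per-row residual variances towards a moment-matched prior, and reports
#' moderated t-statistics, p-values and Benjamini-Hochberg adjusted
#' p-values for each requested contrast.  Per-replicate log2 fold changes
#' (replicate 1 vs replicate 1, 2 vs 2) accompany each contrast, and each
#' row carries its maximum absolute log2 level relative to the watered
#' control (WT1) across the DR1, WT2 and DR2 stages.
#'
#' @param m normalized log2 `expr_matrix` with at least 2 replicates per
#'   condition.
#' @param contrasts character vector of `"A-B"` condition contrasts; the
#'   default covers the first drought, the recovery state and the second
#'   drought versus first.
#' @param d0 optional override of the prior degrees of freedom: `0` turns
#'   shrinkage off (ordinary t), `Inf` uses the prior variance alone.
#' @param s0_2 optional override of the prior variance (used with finite or
#'   infinite `d0`); defaults to the moment-matched estimate, or the mean
#'   residual variance when `d0 = Inf` is forced without an estimate.
#' @return object of class `moderated_fit`: list with `table` (long-format
#'   data frame of per-contrast statistics), `max_abs_level` (named vector),
#'   `d0`, `s0_2`, `df_residual`.
#' @export
moderated_differential <- function(m,
                                   contrasts = c("DR1-WT1", "WT2-WT1",
                                                 "DR2-DR1"),
                                   d0 = NULL, s0_2 = NULL) {
  stopifnot(inherits(m, "expr_matrix"), m$scale == "log2")
  meta <- m$sample_meta
  v <- m$values
  conds <- unique(meta$condition)
  nrep <- table(meta$condition)
  short <- names(nrep)[nrep < 2L]
  if (length(short)) {
    stop("conditions with fewer than 2 replicates: ",
         paste(short, collapse = ", "))
  }
  cols_of <- split(seq_len(ncol(v)), meta$condition)
  means <- vapply(cols_of, function(ix) rowMeans(v[, ix, drop = FALSE]),
                  numeric(nrow(v)))
  # residual variance of the one-way condition-means fit
  resid2 <- v
  for (cn in names(cols_of)) {
    resid2[, cols_of[[cn]]] <- v[, cols_of[[cn]], drop = FALSE] -
      means[, cn]
  }
  d <- ncol(v) - length(cols_of)
  if (d < 1L) stop("no residual degrees of freedom")
  s2 <- rowSums(resid2^2) / d

  prior <- estimate_prior(s2, d)
  d0_forced <- !is.null(d0)
  if (is.null(d0)) d0 <- prior$d0
  if (is.null(s0_2)) {
    # a forced infinite prior means "use the pooled global variance"
    s0_2 <- if (d0_forced && is.infinite(d0)) mean(s2) else prior$s0_2
  }
  s2_post <- if (is.infinite(d0)) rep(s0_2, length(s2))
  else if (d0 == 0) s2
  else (d0 * s0_2 + d * s2) / (d0 + d)
  df_total <- if (is.infinite(d0)) Inf else d0 + d

  rows <- rownames(v)
  tabs <- lapply(contrasts, function(ct) {
    parts <- strsplit(ct, "-", fixed = TRUE)[[1L]]
    if (length(parts) != 2L || !all(parts %in% names(cols_of))) {
      stop("contrast '", ct, "' references unknown conditions")
    }
    a <- parts[1L]; b <- parts[2L]
    na <- length(cols_of[[a]]); nb <- length(cols_of[[b]])
    delta <- means[, a] - means[, b]
    se <- sqrt(s2_post * (1 / na + 1 / nb))
    tt <- delta / se
    p <- 2 * pt(-abs(tt), df = df_total)
    # replicate-matched fold changes
    reps <- sort(intersect(meta$replicate[meta$condition == a],
                           meta$replicate[meta$condition == b]))
    lfc_rep <- vapply(reps, function(r) {
      ca <- which(meta$condition == a & meta$replicate == r)
      cb <- which(meta$condition == b & meta$replicate == r)
      rowMeans(v[, ca, drop = FALSE]) - rowMeans(v[, cb, drop = FALSE])
    }, numeric(nrow(v)))
    colnames(lfc_rep) <- paste0("lfc_rep", reps)
    data.frame(row_id = rows, contrast = ct, lfc_rep,
               mean_lfc = delta, t = tt, p = p,
               adj_p = p.adjust(p, method = "BH"),
               row.names = NULL, stringsAsFactors = FALSE)
  })
  stages <- setdiff(intersect(CONDITIONS, colnames(means)), "WT1")
  levels_vs_ctrl <- means[, stages, drop = FALSE] - means[, "WT1"]
  max_abs_level <- apply(abs(levels_vs_ctrl), 1L, max)

  structure(list(table = do.call(rbind, tabs),
                 means = means,
                 max_abs_level = setNames(max_abs_level, rows),
                 d0 = d0, s0_2 = s0_2, df_residual = d,
                 contrasts = contrasts),
            class = "moderated_fit")
}

#' @export
print.moderated_fit <- function(x, ...) {
  cat("Moderated differential fit\n")
  cat("  rows:", length(x$max_abs_level),
      "  contrasts:", paste(x$contrasts, collapse = ", "), "\n")
  cat("  prior df (d0):", format(x$d0, digits = 4),
      "  prior variance (s0^2):", format(x$s0_2, digits = 4),
      "  residual df:", x$df_residual, "\n")
  invisible(x)
}

#' @export
coef.moderated_fit <- function(object, ...) {
  tab <- object$table
  out <- do.call(cbind, lapply(object$contrasts, function(ct) {
    tab$mean_lfc[tab$contrast == ct]
  }))
  dimnames(out) <- list(tab$row_id[tab$contrast == object$contrasts[1L]],
                        object$contrasts)
  out
}

#' @export
summary.moderated_fit <- function(object, alpha = 0.05, ...) {
  tab <- object$table
  counts <- tapply(tab$adj_p < alpha, tab$contrast, sum)
  cat("Rows with adjusted p <", alpha, "per contrast:\n")
  print(counts)
  invisible(counts)
}

#' Filter significant rows
#'
#' Keeps rows with adjusted p below `alpha` in at least one contrast and an
#' absolute log2 level versus the watered control above `level_cut` at at
#' least one stage.
#'
#' @param d a `moderated_fit`.
#' @param alpha adjusted-p cutoff (default 0.05).
#' @param level_cut log2 level cutoff versus WT1 (default 1).
#' @return character vector of retained row ids.
#' @export
filter_significant <- function(d, alpha = 0.05, level_cut = 1) {
  stopifnot(inherits(d, "moderated_fit"))
  tab <- d$table
  sig <- tapply(tab$adj_p, tab$row_id, min) < alpha
  lev <- d$max_abs_level[names(sig)] > level_cut
  names(sig)[sig & lev]
}

#' @importFrom stats uniroot
NULL
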