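test_that("background correction subtracts the column background and floors", {
  v <- matrix(c(10, 100, 1000, 20, 200, 2000), ncol = 2,
              dimnames = list(paste0("p", 1:3), c("WT1_1", "WT1_2")))
  meta <- data.frame(sample_id = c("WT1_1", "WT1_2"),
                     condition = "WT1", replicate = 1:2)
  m <- expression_matrix(v, meta, "raw")
  out <- background_correct(m, offset = 1, bg_quantile = 0)  # bg = column min
  expect_equal(unname(out$values[, 1]), c(1, 90, 990))
  expect_equal(unname(out$values[, 2]), c(1, 180, 1980))

  # all-equal column degenerates to the offset
  v2 <- v; v2[, 1] <- 50
  m2 <- expression_matrix(v2, meta, "raw")
  expect_true(all(background_correct(m2, bg_quantile = 0)$values[, 1] == 1))

  expect_error(background_correct(m, offset = 0), "positive")
})

test_that("quantile normalization follows the rank-mean algorithm by hand", {
  meta <- data.frame(sample_id = c("WT1_1", "WT1_2"),
                     condition = "WT1", replicate = 1:2)
  v <- matrix(c(1, 3, 2, 6), ncol = 2,
              dimnames = list(c("a", "b"), meta$sample_id))
  m <- expression_matrix(v, meta, "log2")
  out <- quantile_normalize(m)
  expect_equal(unname(out$values[, 1]), c(1.5, 4.5))
  expect_equal(unname(out$values[, 2]), c(1.5, 4.5))

  # identical columns are a fixed point
  v2 <- matrix(c(5, 1, 9, 5, 1, 9), ncol = 2,
               dimnames = list(c("a", "b", "c"), meta$sample_id))
  m2 <- expression_matrix(v2, meta, "log2")
  expect_equal(quantile_normalize(m2)$values, v2)

  # tie handling: tied rows share the mean of their rank-range targets
  v3 <- matrix(c(2, 2, 8, 1, 3, 9), ncol = 2,
               dimnames = list(c("a", "b", "c"), meta$sample_id))
  m3 <- expression_matrix(v3, meta, "log2")
  out3 <- quantile_normalize(m3)
  # sorted column means: (1.5, 2.5, 8.5); rows a,b occupy ranks 1-2
  expect_equal(unname(out3$values[, 1]), c(2, 2, 8.5))
  expect_equal(unname(out3$values[, 2]), c(1.5, 2.5, 8.5))
})

test_that("normalized tie-free columns share one multiset of values", {
  set.seed(31)
  ids <- paste0(rep(c("WT1", "DR1", "WT2", "DR2"), each = 2), "_", 1:2)
  v <- matrix(rnorm(200 * 8, 8, 2), ncol = 8,
              dimnames = list(paste0("t", 1:200), ids))
  meta <- data.frame(sample_id = ids,
                     condition = rep(c("WT1", "DR1", "WT2", "DR2"), each = 2),
                     replicate = rep(1:2, 4))
  out <- quantile_normalize(expression_matrix(v, meta, "log2"))
  ref <- sort(out$values[, 1])
  for (j in 2:8) expect_equal(sort(out$values[, j]), ref,
                              ignore_attr = TRUE)
  # independent cross-check against the established implementation
  skip_if_not_installed("limma")
  expect_equal(unname(out$values),
               unname(limma::normalizeQuantiles(v)), tolerance = 1e-12)
})

test_that("replicate concordance recovers exact linear relations", {
  set.seed(4)
  x <- rnorm(100, 8, 2)
  r <- replicate_concordance(x, x)
  expect_equal(r$slope, 1); expect_equal(r$intercept, 0)
  expect_equal(r$pearson_r, 1)
  r2 <- replicate_concordance(x, 2 * x + 1)
  expect_equal(r2$slope, 2); expect_equal(r2$intercept, 1)
  expect_equal(r2$pearson_r, 1)
  expect_error(replicate_concordance(rep(1, 10), rnorm(10)), "degenerate")
})

test_that("probe summarization collapses tiling probes by median", {
  meta <- data.frame(sample_id = c("WT1_1", "WT1_2"),
                     condition = "WT1", replicate = 1:2)
  v <- matrix(c(1, 2, 9, 5, 2, 4, 18, 7), ncol = 2,
              dimnames = list(c("t1_P1", "t1_P2", "t1_P3", "t2_P1"),
                              meta$sample_id))
  m <- expression_matrix(v, meta, "log2")
  p2t <- c(t1_P1 = "t1", t1_P2 = "t1", t1_P3 = "t1", t2_P1 = "t2")
  out <- summarize_probes(m, p2t)
  expect_equal(out$values["t1", ], c(WT1_1 = 2, WT1_2 = 4))
  expect_equal(out$values["t2", ], c(WT1_1 = 5, WT1_2 = 7))
  out_mean <- summarize_probes(m, p2t, method = "mean")
  expect_equal(unname(out_mean$values["t1", 1]), 4)
})

test_that("moderated t reduces to the linear-model t when shrinkage is off", {
  set.seed(12)
  conds <- rep(c("WT1", "DR1", "WT2", "DR2"), each = 2)
  ids <- paste0(conds, "_", rep(1:2, 4))
  v <- matrix(rnorm(50 * 8, 8, 1), ncol = 8,
              dimnames = list(paste0("t", 1:50), ids))
  meta <- data.frame(sample_id = ids, condition = conds,
                     replicate = rep(1:2, 4))
  m <- expression_matrix(v, meta, "log2")
  fit0 <- moderated_differential(m, contrasts = "DR1-WT1", d0 = 0)
  # oracle: per-row one-way linear model, contrast t from lm machinery
  for (i in c(1, 17, 50)) {
    lf <- lm(v[i, ] ~ 0 + factor(conds))
    s <- summary(lf)$sigma
    t_lm <- (mean(v[i, conds == "DR1"]) - mean(v[i, conds == "WT1"])) /
      (s * sqrt(1 / 2 + 1 / 2))
    expect_equal(fit0$table$t[i], t_lm, tolerance = 1e-10)
  }
  expect_equal(fit0$d0, 0)
})

test_that("moderated t limits: pooled variance at d0 = Inf, fixed point at equal variances", {
  set.seed(13)
  conds <- rep(c("WT1", "DR1"), each = 2)
  ids <- paste0(conds, "_", rep(1:2, 2))
  v <- matrix(rnorm(80 * 4, 8, 1), ncol = 4,
              dimnames = list(paste0("t", 1:80), ids))
  meta <- data.frame(sample_id = ids, condition = conds,
                     replicate = rep(1:2, 2))
  m <- expression_matrix(v, meta, "log2")
  fit_inf <- moderated_differential(m, contrasts = "DR1-WT1", d0 = Inf)
  # oracle: t with the global pooled variance
  grp <- split(seq_len(4), conds)
  s2 <- (rowSums((v[, grp$WT1] - rowMeans(v[, grp$WT1]))^2) +
           rowSums((v[, grp$DR1] - rowMeans(v[, grp$DR1]))^2)) / 2
  t_pool <- (rowMeans(v[, grp$DR1]) - rowMeans(v[, grp$WT1])) /
    sqrt(mean(s2) * (1 / 2 + 1 / 2))
  expect_equal(fit_inf$table$t, unname(t_pool), tolerance = 1e-10)
  # large finite d0 approaches the same limit
  fit_big <- moderated_differential(m, contrasts = "DR1-WT1", d0 = 1e9,
                                    s0_2 = mean(s2))
  expect_equal(fit_big$table$t, fit_inf$table$t, tolerance = 1e-6)

  # identical variance on every row: shrinkage leaves s2 untouched
  mu <- rnorm(20, 8, 1); delta <- rnorm(20, 0, 1)
  v2 <- cbind(mu + 0.1, mu - 0.1, mu + delta + 0.1, mu + delta - 0.1)
  dimnames(v2) <- list(paste0("t", 1:20), ids)
  m2 <- expression_matrix(v2, meta, "log2")
  fit_eq <- moderated_differential(m2, contrasts = "DR1-WT1")
  s2_eq <- 0.02  # every row has within-group deviations of exactly +/-0.1
  expect_equal(unname(fit_eq$table$t), unname(delta / sqrt(s2_eq)),
               tolerance = 1e-10)
})

test_that("moderated statistics agree with the established empirical-Bayes fit", {
  skip_if_not_installed("limma")
  set.seed(14)
  conds <- rep(c("WT1", "DR1", "WT2", "DR2"), each = 2)
  ids <- paste0(conds, "_", rep(1:2, 4))
  v <- matrix(rnorm(300 * 8, 8, 1) * rep(exp(rnorm(300, 0, .4)), 8),
              ncol = 8, dimnames = list(paste0("t", 1:300), ids))
  meta <- data.frame(sample_id = ids, condition = conds,
                     replicate = rep(1:2, 4))
  fit <- moderated_differential(expression_matrix(v, meta, "log2"),
                                contrasts = "DR1-WT1")
  design <- stats::model.matrix(~ 0 + factor(conds,
                                             c("WT1", "DR1", "WT2", "DR2")))
  colnames(design) <- c("WT1", "DR1", "WT2", "DR2")
  lf <- limma::lmFit(v, design)
  lf <- limma::contrasts.fit(
    lf, limma::makeContrasts(DR1 - WT1, levels = design))
  eb <- limma::eBayes(lf)
  expect_equal(fit$d0, eb$df.prior, tolerance = 0.05)
  expect_equal(fit$s0_2, eb$s2.prior, tolerance = 0.02)
  expect_equal(unname(fit$table$t), unname(eb$t[, 1]), tolerance = 1e-3)
})

test_that("planted differential rows dominate the smallest adjusted p-values", {
  set.seed(21)
  conds <- rep(c("WT1", "DR1"), each = 2)
  ids <- paste0(conds, "_", rep(1:2, 2))
  n <- 1000; planted <- 1:50
  v <- matrix(rnorm(n * 4, 8, 0.25), ncol = 4,
              dimnames = list(paste0("t", 1:n), ids))
  v[planted, conds == "DR1"] <- v[planted, conds == "DR1"] + 2
  meta <- data.frame(sample_id = ids, condition = conds,
                     replicate = rep(1:2, 2))
  fit <- moderated_differential(expression_matrix(v, meta, "log2"),
                                contrasts = "DR1-WT1")
  top <- order(fit$table$adj_p)[1:50]
  expect_gte(sum(top %in% planted) / 50, 0.9)
})

test_that("BH adjustment is monotone and significance filtering applies both gates", {
  set.seed(22)
  p <- runif(500)
  adj <- p.adjust(p, "BH")
  expect_true(all(diff(adj[order(p)]) >= -1e-15))

  fake <- structure(list(
    table = data.frame(row_id = c("a", "b", "c"), contrast = "DR1-WT1",
                       adj_p = c(0.01, 0.01, 0.06)),
    max_abs_level = c(a = 1.5, b = 0.8, c = 3)), class = "moderated_fit")
  expect_equal(filter_significant(fake), "a")   # b fails level, c fails p
})
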