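test_that("exact Mann-Whitney matches hand-derived enumerations", {
  r <- mwu_exact(c(1, 2, 3, 4), c(5, 6, 7, 8))
  expect_equal(r$U, 0)
  expect_equal(r$p, 2 / 70)
  expect_equal(mwu_exact(1, 2)$p, 1.0)
  x <- c(3, 1, 4, 1, 5)
  expect_equal(mwu_exact(x, x)$p, 1.0)
  expect_error(mwu_exact(numeric(0), 1), "nonempty")
})

test_that("exact p equals the independent pairwise-comparison oracle, ties included", {
  set.seed(19)
  for (trial in 1:60) {
    n <- sample(1:5, 1); m <- sample(1:5, 1)
    vals <- sample(1:4, n + m, replace = TRUE)  # heavy ties
    x <- vals[seq_len(n)]; y <- vals[-seq_len(n)]
    alt <- sample(c("two.sided", "greater", "less"), 1)
    got <- mwu_exact(x, y, alt)
    want <- oracle_mwu(x, y, alt)
    expect_equal(got$U, want$U, info = paste(trial, alt))
    expect_equal(got$p, want$p, info = paste(trial, alt))
  }
})

test_that("tie-free exact p agrees with wilcox.test", {
  set.seed(23)
  for (trial in 1:20) {
    x <- sample(1:1000, sample(3:5, 1))
    y <- sample(1001:2000, sample(3:5, 1)) - sample(0:900, 1)
    if (length(intersect(x, y))) next
    got <- mwu_exact(x, y, "two.sided")
    ref <- suppressWarnings(stats::wilcox.test(x, y, exact = TRUE,
                                               correct = FALSE))
    expect_equal(got$U, unname(ref$statistic))
    expect_equal(got$p, ref$p.value)
  }
})

test_that("large-sample path uses the tie-corrected normal approximation", {
  set.seed(29)
  x <- rnorm(20); y <- rnorm(25, 0.8)
  got <- mwu_exact(x, y, "two.sided")
  ref <- stats::wilcox.test(x, y, exact = FALSE, correct = FALSE)
  expect_equal(got$p, ref$p.value, tolerance = 1e-10)
})

test_that("log2 fold change is oriented treatment/control and antisymmetric", {
  expect_equal(log2_fold_change(2, 4), 1.0)
  expect_equal(log2_fold_change(3, 3), 0.0)
  expect_equal(log2_fold_change(4, 2), -log2_fold_change(2, 4))
  expect_error(log2_fold_change(0, 1), "zero-count")
})

test_that("PROMPT preset applies zero filter, exact test and thresholds", {
  m <- rbind(
    up = c(10, 10, 10, 10, 20, 22, 18, 20),
    zero = c(0, 5, 5, 5, 5, 5, 5, 5),
    flat = c(10, 11, 10, 11, 10, 11, 10, 11))
  colnames(m) <- c(paste0("noIR_rep", 1:4), paste0("IR_rep", 1:4))
  ct <- table_from_matrix(m, kind = "PROMPT")
  d <- diff_features(ct, sheet44(), preset = "prompt")
  up <- d[d$feature_id == "up", ]
  expect_equal(up$log2fc, 1.0)
  expect_equal(up$p, 2 / 70)
  expect_equal(up$status, "up")
  expect_equal(d[d$feature_id == "zero", ]$status, "filtered")
  expect_equal(d[d$feature_id == "flat", ]$status, "unchanged")
})

test_that("relabeling the conditions swaps up and down calls", {
  m <- rbind(a = c(10, 10, 10, 10, 20, 22, 18, 20),
             b = c(20, 22, 18, 20, 10, 10, 10, 10))
  colnames(m) <- c(paste0("noIR_rep", 1:4), paste0("IR_rep", 1:4))
  ct <- table_from_matrix(m, kind = "PROMPT")
  d1 <- diff_features(ct, sheet44(), preset = "prompt")
  d2 <- diff_features(ct, sheet44(), preset = "prompt",
                      ctrl = "IR", trt = "noIR")
  expect_equal(d1[d1$feature_id == "a", ]$status, "up")
  expect_equal(d2[d2$feature_id == "a", ]$status, "down")
  expect_equal(d1$log2fc, -d2$log2fc)
  expect_equal(d1$p, d2$p)
})

test_that("null 4v4 features reject at the exact attainable level, not nominal 0.05", {
  set.seed(31)
  nfeat <- 2000L
  m <- matrix(rnbinom(nfeat * 8, mu = 50, size = 50) + 1, nrow = nfeat)
  colnames(m) <- c(paste0("noIR_rep", 1:4), paste0("IR_rep", 1:4))
  rownames(m) <- paste0("f", seq_len(nfeat))
  ct <- table_from_matrix(m, kind = "PROMPT")
  d <- diff_features(ct, sheet44(), preset = "prompt")
  rate <- mean(d$p < 0.05, na.rm = TRUE)
  p0 <- 2 / 70
  ci <- 2.576 * sqrt(p0 * (1 - p0) / nfeat)
  expect_lt(abs(rate - p0), ci + 0.005)
})

test_that("gene preset uses Welch t with BH adjustment and padj thresholds", {
  set.seed(37)
  base <- matrix(rnbinom(50 * 8, mu = 400, size = 100), nrow = 50)
  base[1, 5:8] <- round(base[1, 5:8] * 3)   # strong induction
  colnames(base) <- c(paste0("noIR_rep", 1:4), paste0("IR_rep", 1:4))
  rownames(base) <- paste0("f", 1:50)
  ct <- table_from_matrix(base, kind = "GB_DE")
  d <- diff_features(ct, sheet44(), preset = "gene")
  expect_true(all(d$padj >= d$p, na.rm = TRUE))
  expect_equal(d$status[1], "up")
  # batch correction runs and leaves fold changes untouched
  db <- diff_features(ct, sheet44(), preset = "gene", batch_correct = TRUE)
  expect_equal(db$log2fc, d$log2fc)
})

test_that("distribution comparison returns exact p and proper ECDFs", {
  r <- compare_distributions(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$p, 2 / 20)
  expect_equal(compare_distributions(c(1, 2), c(1, 2))$p, 1.0)
  ec <- r$ecdf_a
  expect_equal(ec$fractions[ec$values == 2], 2 / 3)
  expect_true(all(diff(ec$fractions) >= 0))
  expect_equal(max(ec$fractions), 1)
})

test_that("PCA reports nonincreasing variance fractions and degenerate geometry", {
  m <- matrix(c(0, 0, 2, 2, 4, 4), nrow = 2,
              dimnames = list(c("f1", "f2"), c("s1", "s2", "s3")))
  ct <- table_from_matrix(m, kind = "GB_DE")
  # exact collinearity on the log scale
  lm_ <- log2(m + 1)
  pc <- prcomp(t(lm_), center = TRUE)
  res <- pca_qc(ct, kind = "GB_DE")
  expect_equal(res$variance_fraction[1], 1.0, tolerance = 1e-12)
  expect_true(all(diff(res$variance_fraction) <= 1e-12))
  expect_lte(sum(res$variance_fraction), 1 + 1e-12)
  # identical samples sit at identical coordinates
  m2 <- matrix(c(5, 9, 5, 9, 1, 7), nrow = 2,
               dimnames = list(c("f1", "f2"), c("s1", "s2", "s3")))
  res2 <- pca_qc(table_from_matrix(m2, kind = "GB_DE"), kind = "GB_DE")
  co <- res2$coordinates
  expect_equal(unlist(co[co$sample == "s1", 1:2]),
               unlist(co[co$sample == "s2", 1:2]))
  expect_error(pca_qc(table_from_matrix(m[, 1, drop = FALSE], kind = "GB_DE"),
                      kind = "GB_DE"), "2 samples")
})

test_that("the pause preset behaves like the prompt preset on PPR counts", {
  m <- rbind(up = c(10, 10, 10, 10, 20, 22, 18, 20),
             zero = c(0, 5, 5, 5, 5, 5, 5, 5))
  colnames(m) <- c(paste0("noIR_rep", 1:4), paste0("IR_rep", 1:4))
  ct <- table_from_matrix(m, kind = "PPR")
  d <- diff_features(ct, sheet44(), preset = "pause")
  expect_equal(d$kind, rep("PPR", 2))
  expect_equal(d[d$feature_id == "up", ]$p, 2 / 70)
  expect_equal(d[d$feature_id == "up", ]$status, "up")
  expect_equal(d[d$feature_id == "zero", ]$status, "filtered")
})
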