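#' Exact Mann-Whitney U test
#'
#' U is computed with midranks for ties. When `n + m <= exact_max` the
#' p-value comes from exact enumeration of all `choose(n+m, n)` group
#' assignments of the pooled values (the permutation distribution of U,
#' ties respected); the two-sided p is the probability of a U at least as
#' far from its null mean `nm/2` as observed. For larger samples a normal
#' approximation with tie correction is used (no continuity correction).
#'
#' @param x,y numeric vectors (both nonempty).
#' @param alternative `"two.sided"`, `"greater"` (x tends larger) or
#'   `"less"`.
#' @param exact_max largest `n + m` for which the permutation distribution
#'   is enumerated (default 12).
#' @return list with elements `U` (statistic for `x`) and `p`.
#' @examples
#' mwu_exact(c(1, 2, 3, 4), c(5, 6, 7, 8))  # U = 0, p = 2/70
#' @export
mwu_exact <- function(x, y, alternative = c("two.sided", "greater", "less"),
                      exact_max = 12L) {
  alternative <- match.arg(alternative)
  if (length(x) == 0L || length(y) == 0L) abort("both groups must be nonempty")
  n <- length(x); m <- length(y); N <- n + m
  pooled <- c(x, y)
  r <- rank(pooled)  # midranks
  U <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  mu <- n * m / 2
  eps <- 1e-9
  if (N <= exact_max) {
    combs <- combn(N, n)
    Us <- colSums(matrix(r[combs], nrow = n)) - n * (n + 1) / 2
    p <- switch(alternative,
      two.sided = mean(abs(Us - mu) >= abs(U - mu) - eps),
      greater = mean(Us >= U - eps),
      less = mean(Us <= U + eps))
  } else {
    ties <- table(pooled)
    tie_term <- sum(ties^3 - ties) / (N * (N - 1))
    sigma2 <- n * m / 12 * (N + 1 - tie_term)
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- (U - mu) / sqrt(sigma2)
      p <- switch(alternative,
        two.sided = min(1, 2 * pnorm(-abs(z))),
        greater = pnorm(z, lower.tail = FALSE),
        less = pnorm(z))
    }
  }
  list(U = U, p = p)
}

#' Log2 fold change of group means
#'
#' Oriented treatment over control: `log2(mean_trt / mean_ctrl)`, with
#' treatment = damage/IR, so up-regulation upon damage is positive. No
#' pseudocount — both means must be positive (the upstream zero-count
#' filter guarantees this for the PROMPT/pause presets).
#'
#' @param mean_ctrl,mean_trt positive group means.
#' @return log2 fold change.
#' @export
log2_fold_change <- function(mean_ctrl, mean_trt) {
  if (any(mean_ctrl <= 0) || any(mean_trt <= 0))
    abort("non-positive mean; apply the zero-count filter before computing log2FC")
  log2(mean_trt / mean_ctrl)
}

#' Feature-level differential testing
#'
#' Runs per-feature differential tests between two conditions with the
#' preset-specific filters and thresholds:
#'
#' * `preset = "prompt"` / `"pause"`: features with a zero count in any
#'   sample get status `filtered`; the rest are tested with the exact
#'   Mann-Whitney U test ([mwu_exact()]) on per-replicate normalized values,
#'   raw p against `p_threshold` (no multiple-testing correction).
#' * `preset = "gene"`: a Welch t-test on `log2(CPM + 1)` with
#'   Benjamini-Hochberg adjustment stands in for a count-model fit; calls
#'   use `padj`. Optional batch correction subtracts per-batch means of
#'   the log-scale values before testing.
#'
#' Status labels: `up` if significant and `log2fc > lfc_threshold`; `down`
#' if significant and `log2fc < -lfc_threshold`; `unchanged` if
#' `|log2fc| < unchanged_band` (regardless of p — this is the background
#' set for sequence-feature comparisons); otherwise `ns`.
#'
#' @param norm_table normalized [count_table()] (CPM). Zero CPM occurs iff
#'   the raw count was zero, so the zero filter operates on this table.
#' @param sample_sheet data.frame with columns `sample`, `condition` (and
#'   `batch` if `batch_correct`).
#' @param preset `"prompt"`, `"pause"` or `"gene"`.
#' @param kind region kind to test; defaults to `PROMPT`, `PPR` or `GB_DE`
#'   according to the preset.
#' @param ctrl,trt condition labels (control and treatment/damage).
#' @param p_threshold significance threshold (raw p or padj per preset).
#' @param lfc_threshold minimum |log2FC| for an up/down call.
#' @param unchanged_band half-width of the "unchanged" log2FC band.
#' @param batch_correct subtract batch means before the gene-preset test.
#' @return data.frame: `feature_id`, `kind`, `mean_ctrl`, `mean_trt`,
#'   `log2fc`, `p`, `padj` (NA except for the gene preset), `status`.
#' @export
diff_features <- function(norm_table, sample_sheet,
                          preset = c("prompt", "pause", "gene"),
                          kind = NULL, ctrl = "noIR", trt = "IR",
                          p_threshold = 0.05, lfc_threshold = 0.1,
                          unchanged_band = 0.05, batch_correct = FALSE) {
  preset <- match.arg(preset)
  stopifnot(inherits(norm_table, "count_table"))
  if (is.null(kind))
    kind <- switch(preset, prompt = "PROMPT", pause = "PPR", gene = "GB_DE")
  if (!all(c(ctrl, trt) %in% sample_sheet$condition))
    abort("sample sheet lacks condition '%s' or '%s'", ctrl, trt)
  ctrl_s <- sample_sheet$sample[sample_sheet$condition == ctrl]
  trt_s <- sample_sheet$sample[sample_sheet$condition == trt]
  if (length(ctrl_s) < 2L || length(trt_s) < 2L)
    abort("need >= 2 replicates per condition")
  m <- as_count_matrix(norm_table, kind)
  missing <- setdiff(c(ctrl_s, trt_s), colnames(m))
  if (length(missing))
    abort("samples in sheet but not in table: %s", paste(missing, collapse = ", "))

  mc <- m[, ctrl_s, drop = FALSE]
  mt <- m[, trt_s, drop = FALSE]
  nfeat <- nrow(m)
  mean_ctrl <- rowMeans(mc)
  mean_trt <- rowMeans(mt)
  has_zero <- apply(m[, c(ctrl_s, trt_s), drop = FALSE] == 0, 1L, any)

  p <- rep(NA_real_, nfeat)
  padj <- rep(NA_real_, nfeat)
  log2fc <- rep(NA_real_, nfeat)

  if (preset %in% c("prompt", "pause")) {
    ok <- !has_zero
    log2fc[ok] <- log2(mean_trt[ok] / mean_ctrl[ok])
    p[ok] <- vapply(which(ok), function(i)
      mwu_exact(mt[i, ], mc[i, ], "two.sided")$p, 0)
    sig <- !is.na(p) & p < p_threshold
  } else {
    lc <- log2(mc + 1); lt <- log2(mt + 1)
    if (batch_correct) {
      if (is.null(sample_sheet$batch)) abort("batch_correct requires a batch column")
      all_s <- c(ctrl_s, trt_s)
      lmat <- cbind(lc, lt)
      batches <- sample_sheet$batch[match(all_s, sample_sheet$sample)]
      for (b in unique(batches)) {
        cols <- which(batches == b)
        bm <- rowMeans(lmat[, cols, drop = FALSE])
        lmat[, cols] <- lmat[, cols] - bm + rowMeans(lmat)
      }
      lc <- lmat[, seq_along(ctrl_s), drop = FALSE]
      lt <- lmat[, length(ctrl_s) + seq_along(trt_s), drop = FALSE]
    }
    ok <- mean_ctrl > 0 & mean_trt > 0
    log2fc[ok] <- log2(mean_trt[ok] / mean_ctrl[ok])
    p[ok] <- vapply(which(ok), function(i) {
      if (sd(lc[i, ]) == 0 && sd(lt[i, ]) == 0)
        return(if (mean(lc[i, ]) == mean(lt[i, ])) 1 else 0)
      t.test(lt[i, ], lc[i, ])$p.value
    }, 0)
    padj[ok] <- p.adjust(p[ok], method = "BH")
    sig <- !is.na(padj) & padj < p_threshold
  }

  status <- rep("ns", nfeat)
  status[sig & !is.na(log2fc) & log2fc > lfc_threshold] <- "up"
  status[sig & !is.na(log2fc) & log2fc < -lfc_threshold] <- "down"
  band <- !is.na(log2fc) & abs(log2fc) < unchanged_band &
    !(status %in% c("up", "down"))
  status[band] <- "unchanged"
  status[if (preset == "gene") !ok else has_zero] <- "filtered"

  data.frame(feature_id = rownames(m), kind = kind,
             mean_ctrl = mean_ctrl, mean_trt = mean_trt,
             log2fc = log2fc, p = p, padj = padj, status = status,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Compare two value distributions
#'
#' Wraps [mwu_exact()] and additionally returns the two empirical
#' cumulative distribution functions (sorted values plus cumulative
#' fractions), the data behind cumulative-distribution plots of log2 fold
#' changes.
#'
#' @param a,b numeric vectors.
#' @param alternative passed to [mwu_exact()].
#' @return list of class `comparison_result`: `n_a`, `n_b`, `U`, `p`,
#'   `ecdf_a`, `ecdf_b` (each a list with `values`, `fractions`).
#' @export
compare_distributions <- function(a, b, alternative = "two.sided") {
  res <- mwu_exact(a, b, alternative)
  step <- function(v) {
    s <- sort(v)
    list(values = s, fractions = seq_along(s) / length(s))
  }
  structure(list(n_a = length(a), n_b = length(b), U = res$U, p = res$p,
                 ecdf_a = step(a), ecdf_b = step(b)),
            class = "comparison_result")
}

#' Principal component QC of samples
#'
#' PCA on `log2(CPM + 1)` with features centered; returns per-sample
#' coordinates of the first up to 4 components and the variance fraction of
#' each (nonincreasing, summing to <= 1).
#'
#' @param norm_table normalized [count_table()].
#' @param sample_sheet optional sample sheet merged onto the coordinates.
#' @param kind region kind to use (default `GB_DE`).
#' @return list: `coordinates` (data.frame sample x PCs), `variance_fraction`.
#' @export
pca_qc <- function(norm_table, sample_sheet = NULL, kind = "GB_DE") {
  m <- as_count_matrix(norm_table, kind)
  if (ncol(m) < 2L) abort("need >= 2 samples for PCA")
  lm <- log2(m + 1)
  pc <- prcomp(t(lm), center = TRUE, scale. = FALSE)
  k <- min(4L, ncol(pc$x))
  coords <- as.data.frame(pc$x[, seq_len(k), drop = FALSE])
  coords$sample <- rownames(pc$x)
  if (!is.null(sample_sheet))
    coords <- merge(coords, sample_sheet, by = "sample", sort = FALSE)
  vf <- pc$sdev^2 / sum(pc$sdev^2)
  list(coordinates = coords, variance_fraction = vf[seq_len(k)])
}
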