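#' Per-gene, per-sample pause index
#'
#' The pause index (PI) is the ratio of polymerase signal density in the
#' promoter-proximal region to the density across the gene body:
#' `PI = (ppr / |PPR|) / (gb / |GB|)` when `density_mode` (the default), or
#' the raw coverage ratio `ppr / gb` otherwise. The two modes differ per
#' gene by the constant `|GB| / |PPR|`, so differential PI is identical in
#' both. Genes with a zero count in any sample for either region, and genes
#' whose gene body is shorter than `min_gb_bp`, are excluded (ids in the
#' `"excluded"` attribute).
#'
#' @param norm_counts normalized [count_table()] containing `PPR` and
#'   `GB_PI` counts.
#' @param regions region data.frame (for region lengths and the gene-body
#'   length filter).
#' @param density_mode divide by region lengths (per-bp densities).
#' @param min_gb_bp minimum gene-body length retained (default 1000).
#' @return data.frame: `gene_id`, `sample_id`, `pi` (positive).
#' @export
pause_index_table <- function(norm_counts, regions, density_mode = TRUE,
                              min_gb_bp = 1000L) {
  stopifnot(inherits(norm_counts, "count_table"))
  for (k in c("PPR", "GB_PI"))
    if (!k %in% norm_counts$counts$kind) abort("missing region kind '%s'", k)
  reg <- as.data.table(regions)
  lens <- reg[kind %in% c("PPR", "GB_PI"),
              .(gene_id, kind, len = end - start, flagged)]
  ppr <- as_count_matrix(norm_counts, "PPR")
  gb <- as_count_matrix(norm_counts, "GB_PI")
  shared <- intersect(rownames(ppr), rownames(gb))
  ppr <- ppr[shared, , drop = FALSE]
  gb <- gb[shared, colnames(ppr), drop = FALSE]

  gb_len <- setNames(lens[kind == "GB_PI"]$len, lens[kind == "GB_PI"]$gene_id)
  ppr_len <- setNames(lens[kind == "PPR"]$len, lens[kind == "PPR"]$gene_id)
  flagged <- unique(lens[flagged == TRUE]$gene_id)

  zero <- rowSums(ppr == 0) > 0 | rowSums(gb == 0) > 0
  short <- gb_len[shared] < min_gb_bp
  drop <- zero | short | shared %in% flagged
  excluded <- data.frame(gene_id = shared[drop],
                         reason = ifelse(shared[drop] %in% shared[zero],
                                         "zero_count", "short_gb"))
  keep <- shared[!drop]
  if (length(keep) == 0L) {
    out <- data.frame(gene_id = character(), sample_id = character(),
                      pi = numeric())
    attr(out, "excluded") <- excluded
    return(out)
  }
  num <- ppr[keep, , drop = FALSE]
  den <- gb[keep, , drop = FALSE]
  if (density_mode) {
    num <- num / ppr_len[keep]
    den <- den / gb_len[keep]
  }
  pim <- num / den
  out <- data.frame(gene_id = rep(keep, ncol(pim)),
                    sample_id = rep(colnames(pim), each = length(keep)),
                    pi = as.vector(pim), stringsAsFactors = FALSE)
  attr(out, "excluded") <- excluded
  out
}

#' Differential pause index between conditions
#'
#' Per gene: `log2fc = log2(mean PI trt / mean PI ctrl)` and a two-sided
#' exact Mann-Whitney p on the per-replicate PI values.
#'
#' @param pause_records output of [pause_index_table()].
#' @param sample_sheet sample sheet with `sample`, `condition`.
#' @param ctrl,trt condition labels.
#' @return data.frame: `gene_id`, `mean_pi_ctrl`, `mean_pi_trt`,
#'   `mean_pi_all`, `log2fc`, `p`.
#' @export
diff_pause_index <- function(pause_records, sample_sheet,
                             ctrl = "noIR", trt = "IR") {
  pr <- as.data.table(pause_records)
  cond <- setNames(sample_sheet$condition, sample_sheet$sample)
  pr[, condition := cond[sample_id]]
  if (any(is.na(pr$condition))) abort("sample sheet does not cover all samples")
  nrep <- pr[, .N, by = .(gene_id, condition)]
  if (any(nrep$N < 2L)) abort("need >= 2 replicates per condition")
  out <- pr[, {
    x <- pi[condition == trt]; y <- pi[condition == ctrl]
    list(mean_pi_ctrl = mean(y), mean_pi_trt = mean(x),
         mean_pi_all = mean(pi),
         log2fc = log2(mean(x) / mean(y)),
         p = mwu_exact(x, y, "two.sided")$p)
  }, by = gene_id]
  as.data.frame(out)
}

#' Select genes with a moderate pause index
#'
#' Retains genes whose selection statistic (mean PI over all samples by
#' default) lies strictly inside `(low, high)`, sorted by that statistic —
#' the layout of the per-gene PI line plot.
#'
#' @param pause_records output of [diff_pause_index()] (or any data.frame
#'   with `gene_id` and the statistic column).
#' @param low,high strict bounds (defaults 5 and 50).
#' @param stat column used for selection.
#' @return sorted, filtered data.frame.
#' @export
select_moderate_pi <- function(pause_records, low = 5, high = 50,
                               stat = "mean_pi_all") {
  if (low >= high) abort("low must be < high")
  if (nrow(pause_records) == 0L) return(pause_records)
  v <- pause_records[[stat]]
  out <- pause_records[v > low & v < high, , drop = FALSE]
  out[order(out[[stat]]), , drop = FALSE]
}
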