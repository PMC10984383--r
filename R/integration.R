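#' Integrate gene-body, PROMPT and pause-index differential results
#'
#' Joins the three per-gene result sets and classifies each gene:
#' `repressed_concordant` iff the gene body is significantly down, the
#' PROMPT significantly up, and the PI significantly changed with positive
#' log2FC — the coupled repression signature; `incomplete` if the gene is
#' missing (or filtered) in any of the three sets; `other` otherwise.
#' "Significant change in PI" means p < `p_threshold` regardless of
#' direction; directionality enters through status labels and the PI
#' log2FC sign.
#'
#' The summary reports the printed-style contingency percentages on inner
#' joins of significant sets:
#' (a) among genes significant in both PI and gene body, the percent with
#' gene body down; (b) among genes significant in both PI and PROMPT, the
#' percent with PROMPT up; (c) among genes significant in all three, the
#' percent classified `repressed_concordant`. Percentages are returned
#' unrounded (`NA` when a denominator is 0); callers round for display.
#'
#' @param gb_diff gene-body [diff_features()] result (uses `padj` when
#'   present, raw `p` otherwise).
#' @param prompt_diff PROMPT [diff_features()] result (raw `p`).
#' @param pi_diff [diff_pause_index()] result (`gene_id`, `log2fc`, `p`).
#' @param p_threshold significance threshold for all three axes.
#' @return list with `records` (per-gene data.frame incl.
#'   `concordance_class`) and `summary` (named list of counts and
#'   percentages).
#' @export
classify_genes <- function(gb_diff, prompt_diff, pi_diff, p_threshold = 0.05) {
  for (d in list(gb_diff, prompt_diff, pi_diff)) {
    ids <- if (!is.null(d$gene_id)) d$gene_id else d$feature_id
    if (anyDuplicated(ids)) abort("duplicate gene_id within a result set")
  }
  pick <- function(d, prefix, use_padj) {
    id <- if (!is.null(d$gene_id)) d$gene_id else d$feature_id
    pval <- if (use_padj && !is.null(d$padj) && any(!is.na(d$padj))) d$padj else d$p
    out <- data.frame(gene_id = id, lfc = d$log2fc, p = pval,
                      stringsAsFactors = FALSE)
    if (!is.null(d$status)) out$status <- d$status else
      out$status <- ifelse(is.na(d$log2fc), "filtered",
                           ifelse(d$log2fc > 0, "up", "down"))
    names(out)[-1] <- paste0(prefix, "_", names(out)[-1])
    out
  }
  gb <- pick(gb_diff, "gb", use_padj = TRUE)
  pr <- pick(prompt_diff, "prompt", use_padj = FALSE)
  pi <- pick(pi_diff, "pi", use_padj = FALSE)

  rec <- merge(merge(gb, pr, by = "gene_id", all = TRUE), pi,
               by = "gene_id", all = TRUE)
  miss <- is.na(rec$gb_p) | is.na(rec$prompt_p) | is.na(rec$pi_p) |
    rec$gb_status == "filtered" | rec$prompt_status == "filtered"
  miss[is.na(miss)] <- TRUE

  gb_sig <- !miss & rec$gb_p < p_threshold
  prompt_sig <- !miss & rec$prompt_p < p_threshold
  pi_sig <- !miss & rec$pi_p < p_threshold

  concordant <- !miss & rec$gb_status == "down" & rec$prompt_status == "up" &
    pi_sig & rec$pi_lfc > 0
  rec$concordance_class <- ifelse(miss, "incomplete",
                                  ifelse(concordant, "repressed_concordant",
                                         "other"))

  pct <- function(num, den) if (den == 0L) NA_real_ else 100 * num / den
  n_pi_gb <- sum(pi_sig & gb_sig)
  n_pi_gb_down <- sum(pi_sig & gb_sig & rec$gb_status == "down")
  n_pi_prompt <- sum(pi_sig & prompt_sig)
  n_pi_prompt_up <- sum(pi_sig & prompt_sig & rec$prompt_status == "up")
  n_triple <- sum(pi_sig & gb_sig & prompt_sig)
  n_rc <- sum(concordant & gb_sig & prompt_sig)

  summary <- list(
    n_pi_gb_significant = n_pi_gb,
    n_pi_gb_down = n_pi_gb_down,
    pct_gb_down = pct(n_pi_gb_down, n_pi_gb),
    n_pi_prompt_significant = n_pi_prompt,
    n_pi_prompt_up = n_pi_prompt_up,
    pct_prompt_up = pct(n_pi_prompt_up, n_pi_prompt),
    n_triple_significant = n_triple,
    n_repressed_concordant = n_rc,
    pct_repressed_concordant = pct(n_rc, n_triple))

  list(records = rec, summary = summary)
}

#' Pearson correlation of two per-gene log2 fold-change sets
#'
#' Correlates the inner join; two-sided p from the t transform with `n - 2`
#' degrees of freedom.
#'
#' @param x,y named numeric vectors (names = gene ids) or data.frames with
#'   `gene_id`/`feature_id` and `log2fc`.
#' @return list: `r`, `p`, `n`.
#' @export
correlate_lfc <- function(x, y) {
  as_named <- function(v) {
    if (is.data.frame(v)) {
      id <- if (!is.null(v$gene_id)) v$gene_id else v$feature_id
      setNames(v$log2fc, id)
    } else v
  }
  x <- as_named(x); y <- as_named(y)
  shared <- intersect(names(x), names(y))
  xs <- x[shared]; ys <- y[shared]
  keep <- is.finite(xs) & is.finite(ys)
  xs <- xs[keep]; ys <- ys[keep]
  n <- length(xs)
  if (n < 3L) abort("need >= 3 shared genes with finite log2FC")
  if (sd(xs) == 0 || sd(ys) == 0) abort("zero variance in log2FC values")
  r <- cor(xs, ys)
  tt <- r * sqrt((n - 2) / max(1 - r^2, .Machine$double.eps))
  p <- 2 * pt(-abs(tt), df = n - 2)
  list(r = r, p = p, n = n)
}

#' PROMPT fold-change shift stratified by gene-body status
#'
#' Splits PROMPT log2 fold changes by the gene-body call of the host gene
#' (`down` vs `up`) and compares the two strata — the
#' cumulative-distribution comparison of PROMPT induction between repressed
#' and activated genes.
#'
#' @param prompt_diff PROMPT [diff_features()] result.
#' @param gb_diff gene-body [diff_features()] result.
#' @return a [compare_distributions()] result (`a` = gene-body-down
#'   stratum, `b` = gene-body-up stratum).
#' @export
stratified_prompt_shift <- function(prompt_diff, gb_diff) {
  gid <- function(d) if (!is.null(d$gene_id)) d$gene_id else d$feature_id
  gb_status <- setNames(gb_diff$status, gid(gb_diff))
  lfc <- setNames(prompt_diff$log2fc, gid(prompt_diff))
  shared <- intersect(names(lfc), names(gb_status))
  a <- lfc[shared][gb_status[shared] == "down"]
  b <- lfc[shared][gb_status[shared] == "up"]
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  if (length(a) == 0L || length(b) == 0L)
    abort("a gene-body stratum is empty")
  compare_distributions(a, b)
}
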