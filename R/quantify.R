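#' Count table container
#'
#' A light container for region-kind x gene x sample counts: a long-format
#' data.table `counts` (`kind`, `gene_id`, `sample_id`, `count`), the
#' per-sample library sizes (total retained fragments, not per-region
#' totals), and a `normalized` flag (raw integer counts vs counts per
#' million).
#'
#' @param counts long-format data.table.
#' @param library_sizes named numeric vector of totals per sample.
#' @param normalized whether values are CPM.
#' @return object of class `count_table`.
#' @export
count_table <- function(counts, library_sizes, normalized = FALSE) {
  stopifnot(all(c("kind", "gene_id", "sample_id", "count") %in% names(counts)))
  samples <- unique(counts$sample_id)
  missing <- setdiff(samples, names(library_sizes))
  if (length(missing))
    abort("library_sizes missing for sample(s): %s", paste(missing, collapse = ", "))
  if (!normalized && any(counts$count %% 1 != 0))
    abort("raw counts must be integers")
  if (any(counts$count < 0)) abort("counts must be >= 0")
  structure(list(counts = as.data.table(counts),
                 library_sizes = library_sizes,
                 normalized = normalized),
            class = "count_table")
}

#' @export
print.count_table <- function(x, ...) {
  cat(sprintf("count_table: %d kinds x %d genes x %d samples (%s)\n",
              length(unique(x$counts$kind)),
              length(unique(x$counts$gene_id)),
              length(unique(x$counts$sample_id)),
              if (x$normalized) "CPM" else "raw"))
  invisible(x)
}

#' Strand-aware overlap counting of fragments over regions
#'
#' A fragment contributes 1 to a region iff it overlaps the region by at
#' least 1 bp (half-open interval semantics, matching `bedtools multicov`)
#' and, when `same_strand = TRUE`, its strand equals the region's strand.
#' Because the PROMPT region is emitted on the strand opposite its gene,
#' sense-to-region counting is automatically antisense-to-gene counting
#' there. With `exclude_multigene`, fragments overlapping the `GB_DE`
#' regions of more than one gene contribute to no region at all. Counting
#' is order-independent; fragments on chromosomes absent from the regions
#' are skipped with a warning.
#'
#' @param regions region data.frame from [derive_regions()] (flagged empty
#'   regions are excluded and reported as zero counts).
#' @param fragments fragment data.table (multiple samples allowed).
#' @param same_strand require fragment strand == region strand.
#' @param exclude_multigene drop fragments spanning the `GB_DE` regions of
#'   more than one gene (default on when counting gene bodies).
#' @param library_sizes named totals per sample; defaults to the number of
#'   fragments per sample in `fragments`.
#' @return raw [count_table()] with one row per (kind, gene, sample),
#'   including explicit zeros.
#' @export
count_overlaps <- function(regions, fragments, same_strand = TRUE,
                           exclude_multigene = FALSE, library_sizes = NULL) {
  fragments <- as.data.table(fragments)
  reg <- copy(as.data.table(regions))
  if (is.null(reg$flagged)) reg[, flagged := FALSE]
  reg[, rid := .I]
  samples <- sort(unique(fragments$sample_id))
  if (is.null(library_sizes)) {
    library_sizes <- fragments[, .N, by = sample_id]
    library_sizes <- setNames(library_sizes$N, library_sizes$sample_id)
  }

  unknown <- setdiff(unique(fragments$chrom), unique(reg$chrom))
  if (length(unknown)) {
    warning(sprintf("skipping fragments on unknown chromosome(s): %s",
                    paste(unknown, collapse = ", ")))
    fragments <- fragments[!chrom %in% unknown]
  }

  if (exclude_multigene) {
    gb <- reg[kind == "GB_DE" & !flagged]
    if (nrow(gb)) {
      ngene <- overlap_gene_count(gb, fragments)
      fragments <- fragments[ngene <= 1L]
    }
  }

  live <- reg[flagged == FALSE]
  key_cols <- if (same_strand) c("chrom", "strand") else "chrom"
  acc <- list()
  if (nrow(fragments) && nrow(live)) {
    fr <- copy(fragments)
    groups <- unique(live[, ..key_cols])
    for (g in seq_len(nrow(groups))) {
      lr <- live[groups[g], on = key_cols, nomatch = NULL]
      ff <- fr[groups[g], on = key_cols, nomatch = NULL]
      if (nrow(ff) == 0L || nrow(lr) == 0L) next
      hits <- IRanges::findOverlaps(
        IRanges::IRanges(start = ff$start + 1L, end = ff$end),
        IRanges::IRanges(start = lr$start + 1L, end = lr$end),
        minoverlap = 1L)
      if (length(hits) == 0L) next
      tab <- data.table(rid = lr$rid[S4Vectors::subjectHits(hits)],
                        sample_id = ff$sample_id[S4Vectors::queryHits(hits)])
      acc[[length(acc) + 1L]] <- tab[, .N, by = .(rid, sample_id)]
    }
  }
  long_hits <- if (length(acc)) rbindlist(acc) else
    data.table(rid = integer(), sample_id = character(), N = integer())

  # full grid including explicit zeros and flagged regions
  grid <- CJ(rid = seq_len(nrow(reg)), sample_id = samples)
  map <- merge(grid, reg[, .(rid, kind, gene_id)], by = "rid", sort = FALSE)
  out <- merge(map, long_hits, by = c("rid", "sample_id"), all.x = TRUE)
  out[is.na(N), N := 0L]
  counts_long <- out[, .(kind, gene_id, sample_id, count = as.integer(N))]
  setorder(counts_long, kind, gene_id, sample_id)
  count_table(counts_long, library_sizes, normalized = FALSE)
}

# Internal: number of distinct genes whose (GB) regions each fragment
# overlaps (strand-aware)
overlap_gene_count <- function(gb, fragments) {
  n <- nrow(fragments)
  res <- rep(0L, n)
  fr <- copy(as.data.table(fragments))
  fr[, fid := .I]
  groups <- unique(gb[, .(chrom, strand)])
  for (g in seq_len(nrow(groups))) {
    lr <- gb[groups[g], on = c("chrom", "strand")]
    ff <- fr[groups[g], on = c("chrom", "strand"), nomatch = NULL]
    if (nrow(ff) == 0L) next
    hits <- IRanges::findOverlaps(
      IRanges::IRanges(start = ff$start + 1L, end = ff$end),
      IRanges::IRanges(start = lr$start + 1L, end = lr$end),
      minoverlap = 1L)
    if (length(hits) == 0L) next
    tab <- unique(data.table(fid = ff$fid[S4Vectors::queryHits(hits)],
                             gene_id = lr$gene_id[S4Vectors::subjectHits(hits)]))
    cnt <- tab[, .N, by = fid]
    res[cnt$fid] <- res[cnt$fid] + cnt$N
  }
  res
}

#' Depth normalization to counts per million
#'
#' With `method = "total"` (the default) each value becomes
#' `value * 1e6 / library_size` of its sample — counts per million retained
#' fragments. With `method = "median_ratio"` the per-sample scaling factor
#' is instead estimated by the median-of-ratios over gene-level features
#' (the size-factor estimator of negative-binomial DE frameworks), scaled
#' so the geometric-mean sample keeps its total library size; this is
#' robust to compositional shifts when induction is asymmetric between
#' conditions, at the cost of no longer being a literal per-million scale.
#'
#' @param table raw [count_table()].
#' @param method `"total"` or `"median_ratio"`.
#' @param sf_kind region kind used to estimate median-of-ratio factors
#'   (default `GB_DE` when present, else all kinds).
#' @return normalized `count_table`.
#' @export
normalize_depth <- function(table, method = c("total", "median_ratio"),
                            sf_kind = NULL) {
  method <- match.arg(method)
  stopifnot(inherits(table, "count_table"))
  if (table$normalized) abort("table is already normalized")
  if (any(table$library_sizes <= 0)) abort("zero library size")
  counts <- copy(table$counts)
  lib <- table$library_sizes
  eff <- lib
  if (method == "median_ratio") {
    if (is.null(sf_kind))
      sf_kind <- if ("GB_DE" %in% counts$kind) "GB_DE" else unique(counts$kind)
    sub <- counts[counts[["kind"]] %in% sf_kind]
    wide <- dcast(sub, gene_id ~ sample_id, value.var = "count",
                  fun.aggregate = sum, fill = 0)
    m <- as.matrix(wide[, -1])
    pos <- rowSums(m == 0) == 0L
    if (sum(pos) >= 10L) {
      lg <- log(m[pos, , drop = FALSE])
      ref <- rowMeans(lg)
      sf <- apply(exp(lg - ref), 2L, median)
      sf <- sf / exp(mean(log(sf)))
      eff <- exp(mean(log(lib[colnames(m)]))) * sf
      eff <- eff[names(lib)]
    } else {
      warning("too few all-positive features; falling back to total-count scaling")
    }
  }
  counts[, count := count * 1e6 / eff[sample_id]]
  count_table(counts, table$library_sizes, normalized = TRUE)
}

#' Count table as a genes x samples matrix for one region kind
#'
#' @param table a [count_table()].
#' @param kind region kind to extract.
#' @return numeric matrix, rownames gene ids, colnames sample ids.
#' @export
as_count_matrix <- function(table, kind) {
  stopifnot(inherits(table, "count_table"))
  want <- kind
  sub <- table$counts[table$counts[["kind"]] == want]
  if (nrow(sub) == 0L) abort("no counts of kind '%s'", kind)
  wide <- dcast(sub, gene_id ~ sample_id, value.var = "count", fill = 0)
  m <- as.matrix(wide[, -1])
  rownames(m) <- wide$gene_id
  m
}

#' Write a count table as long-format TSV
#'
#' @param table a [count_table()].
#' @param path output file.
#' @export
write_count_table <- function(table, path) {
  fwrite(table$counts, path, sep = "\t")
  invisible(path)
}
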