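#' Region offset configuration
#'
#' Offsets (in bp, transcript orientation) that turn a gene model into the
#' four analysis regions:
#'
#' * `GB_DE` — gene body used for differential expression, from
#'   `gb_de_start` downstream of the TSS to the TES. The default +200
#'   excludes the promoter-proximal pause peak from expression measurement.
#' * `GB_PI` — gene body used as the pause-index denominator. The literature
#'   is ambiguous between +50 and +200 for this region; both bodies default
#'   to +200 here and `gb_pi_start` is exposed rather than silently
#'   reconciled (+50 makes the body overlap the PPR).
#' * `PPR` — promoter-proximal region, `ppr_upstream` bp upstream to
#'   `ppr_downstream` bp downstream of the TSS (defaults \eqn{-50/+200}),
#'   where paused polymerase accumulates.
#' * `PROMPT` — the 500 bp window immediately upstream of the TSS on the
#'   opposite strand, where promoter upstream transcripts initiate.
#'
#' @param gb_de_start bp downstream of the TSS where the DE gene body starts.
#' @param gb_pi_start bp downstream of the TSS where the PI gene body starts.
#' @param ppr_upstream,ppr_downstream PPR extent around the TSS.
#' @param prompt_width width of the antisense PROMPT window upstream of the TSS.
#' @return A named list of offsets.
#' @export
region_config <- function(gb_de_start = 200L, gb_pi_start = 200L,
                          ppr_upstream = 50L, ppr_downstream = 200L,
                          prompt_width = 500L) {
  list(gb_de_start = as.integer(gb_de_start),
       gb_pi_start = as.integer(gb_pi_start),
       ppr_upstream = as.integer(ppr_upstream),
       ppr_downstream = as.integer(ppr_downstream),
       prompt_width = as.integer(prompt_width))
}

#' Derive analysis regions from gene models
#'
#' For each gene, derives the four regions used throughout the pipeline
#' (`GB_DE`, `GB_PI`, `PPR`, `PROMPT`), interpreting upstream/downstream in
#' the gene's transcriptional orientation. All coordinates are 0-based
#' half-open (BED convention); the TSS is the 5' boundary base (`start` on
#' `+`, `end - 1` on `-`). The PROMPT window abuts the TSS with no gap and is
#' reported on the strand opposite the gene, which is the strand its signal
#' is counted on. Coordinates are clipped at 0; a gene too short to carry a
#' gene body yields an empty, flagged `GB` region that downstream stages
#' exclude.
#'
#' @param genes data.frame of gene models with columns `gene_id`, `chrom`,
#'   `start`, `end`, `strand` (and optionally an `exons` list column).
#' @param offsets a [region_config()] list.
#' @return data.frame with columns `gene_id`, `kind`, `chrom`, `start`,
#'   `end`, `strand`, `flagged` (TRUE for empty/clipped-away gene bodies).
#' @examples
#' g <- data.frame(gene_id = "g1", chrom = "chr1", start = 10000L,
#'                 end = 20000L, strand = "+")
#' derive_regions(g)
#' @export
derive_regions <- function(genes, offsets = region_config()) {
  stopifnot(all(c("gene_id", "chrom", "start", "end", "strand") %in% names(genes)))
  check_strand(genes$strand)
  if (any(genes$start >= genes$end)) abort("gene start must be < end")

  n <- nrow(genes)
  pos <- genes$strand == "+"
  tss5 <- ifelse(pos, genes$start, genes$end)     # 5' boundary coordinate
  tes5 <- ifelse(pos, genes$end, genes$start)     # 3' boundary coordinate
  dirn <- ifelse(pos, 1L, -1L)

  # boundary arithmetic in transcript orientation: coordinate of a point
  # `k` bp downstream of the TSS boundary
  down <- function(k) tss5 + dirn * k

  # b5/b3 are the region's 5'- and 3'-most boundaries in transcript
  # orientation; an inverted pair (gene shorter than the offset) flags the
  # region as empty rather than reordering it.
  mk <- function(kind, b5, b3, strand) {
    inverted <- dirn * (b3 - b5) <= 0L
    start <- pmax(pmin(b5, b3), 0L)
    end <- pmax(pmax(b5, b3), 0L)
    start[inverted] <- end[inverted] <- pmax(pmin(b5, b3)[inverted], 0L)
    flagged <- inverted | end <= start
    data.frame(gene_id = genes$gene_id, kind = kind, chrom = genes$chrom,
               start = as.integer(start), end = as.integer(end),
               strand = strand, flagged = flagged, stringsAsFactors = FALSE)
  }

  gb_de <- mk("GB_DE", down(offsets$gb_de_start), tes5, genes$strand)
  gb_pi <- mk("GB_PI", down(offsets$gb_pi_start), tes5, genes$strand)
  ppr   <- mk("PPR", down(-offsets$ppr_upstream), down(offsets$ppr_downstream),
              genes$strand)
  prompt <- mk("PROMPT", down(-offsets$prompt_width), down(0L),
               ifelse(pos, "-", "+"))

  out <- rbind(gb_de, gb_pi, ppr, prompt)
  rownames(out) <- NULL
  out
}

#' Write regions as BED6
#'
#' The region kind is encoded in the BED name field as `<gene_id>|<kind>`.
#'
#' @param regions data.frame from [derive_regions()].
#' @param path output file.
#' @export
write_regions_bed <- function(regions, path) {
  bed <- data.table(chrom = regions$chrom, start = regions$start,
                    end = regions$end,
                    name = paste0(regions$gene_id, "|", regions$kind),
                    score = 0L, strand = regions$strand)
  fwrite(bed, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Read gene models from BED12
#'
#' BED12 blocks become the exon list; the thick fields are ignored.
#'
#' @param path BED12 file.
#' @return data.frame of gene models with an `exons` list column of 2-column
#'   matrices (0-based half-open).
#' @export
read_gene_bed12 <- function(path) {
  bed <- fread(path, header = FALSE, sep = "\t")
  if (ncol(bed) < 12L) abort("expected BED12 (12 columns), got %d", ncol(bed))
  setnames(bed, 1:12, c("chrom", "start", "end", "name", "score", "strand",
                        "thickStart", "thickEnd", "rgb", "blockCount",
                        "blockSizes", "blockStarts"))
  exons <- lapply(seq_len(nrow(bed)), function(i) {
    sizes <- as.integer(strsplit(bed$blockSizes[i], ",")[[1]])
    starts <- as.integer(strsplit(bed$blockStarts[i], ",")[[1]])
    cbind(start = bed$start[i] + starts, end = bed$start[i] + starts + sizes)
  })
  out <- data.frame(gene_id = bed$name, chrom = bed$chrom,
                    start = bed$start, end = bed$end, strand = bed$strand,
                    biotype = "protein_coding", stringsAsFactors = FALSE)
  out$exons <- exons
  out
}

#' Write gene models as BED12
#'
#' @param genes gene model data.frame (with `exons` list column; genes
#'   without exons are written as a single block).
#' @param path output file.
#' @export
write_gene_bed12 <- function(genes, path) {
  n <- nrow(genes)
  exons <- genes$exons
  if (is.null(exons)) exons <- lapply(seq_len(n), function(i)
    cbind(start = genes$start[i], end = genes$end[i]))
  sizes <- vapply(exons, function(e) paste0(paste(e[, 2] - e[, 1], collapse = ","), ","), "")
  starts <- vapply(seq_len(n), function(i)
    paste0(paste(exons[[i]][, 1] - genes$start[i], collapse = ","), ","), "")
  bed <- data.table(chrom = genes$chrom, start = genes$start, end = genes$end,
                    name = genes$gene_id, score = 0L, strand = genes$strand,
                    thickStart = genes$start, thickEnd = genes$end, rgb = "0",
                    blockCount = vapply(exons, nrow, 0L),
                    blockSizes = sizes, blockStarts = starts)
  fwrite(bed, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Write gene models as GTF
#'
#' One `gene` record plus one `exon` record per exon block, converting the
#' internal 0-based half-open coordinates to GTF 1-based inclusive.
#'
#' @param genes gene model data.frame.
#' @param path output file.
#' @param source_label value of the GTF source column.
#' @export
write_gene_gtf <- function(genes, path, source_label = "promptpause") {
  rows <- character(0)
  fmt <- function(chrom, type, start, end, strand, attrs)
    sprintf("%s\t%s\t%s\t%d\t%d\t.\t%s\t.\t%s", chrom, source_label, type,
            start + 1L, end, strand, attrs)
  for (i in seq_len(nrow(genes))) {
    at <- sprintf("gene_id \"%s\"; gene_biotype \"%s\";", genes$gene_id[i],
                  genes$biotype[i] %||% "protein_coding")
    rows <- c(rows, fmt(genes$chrom[i], "gene", genes$start[i], genes$end[i],
                        genes$strand[i], at))
    ex <- if (!is.null(genes$exons)) genes$exons[[i]] else
      cbind(start = genes$start[i], end = genes$end[i])
    att <- sprintf("gene_id \"%s\"; transcript_id \"%s.1\";",
                   genes$gene_id[i], genes$gene_id[i])
    for (j in seq_len(nrow(ex)))
      rows <- c(rows, fmt(genes$chrom[i], "exon", ex[j, 1], ex[j, 2],
                          genes$strand[i], att))
  }
  writeLines(rows, path)
  invisible(path)
}

#' Read gene models from GTF
#'
#' Exon records are grouped per gene; the TSS of a multi-transcript gene is
#' the most-5' annotated transcript start by default (`tss = "five_prime"`)
#' or taken from the longest transcript (`tss = "longest"`). GTF 1-based
#' inclusive coordinates are converted to 0-based half-open.
#'
#' @param path GTF file.
#' @param tss TSS selection rule for multi-transcript genes.
#' @return gene model data.frame as for [read_gene_bed12()].
#' @export
read_gene_gtf <- function(path, tss = c("five_prime", "longest")) {
  tss <- match.arg(tss)
  if (!requireNamespace("rtracklayer", quietly = TRUE))
    abort("reading GTF requires the rtracklayer package")
  gr <- rtracklayer::import(path, format = "gtf")
  ex <- gr[gr$type == "exon"]
  if (length(ex) == 0L) abort("no exon records in %s", path)
  gid <- as.character(ex$gene_id)
  tid <- as.character(ex$transcript_id %||% ex$gene_id)
  df <- data.table(gene_id = gid, transcript_id = tid,
                   chrom = as.character(GenomeInfoDb_seqnames(ex)),
                   start = BiocGenerics::start(ex) - 1L,
                   end = BiocGenerics::end(ex),
                   strand = as.character(BiocGenerics::strand(ex)),
                   biotype = as.character(ex$gene_biotype %||% "protein_coding"))
  tx <- df[, .(t_start = min(start), t_end = max(end)), by = .(gene_id, transcript_id, strand)]
  pick <- if (tss == "five_prime") {
    tx[, .(anchor = if (strand[1] == "+") min(t_start) else max(t_end)), by = gene_id]
  } else {
    tx[, .SD[which.max(t_end - t_start)], by = gene_id][,
       .(gene_id, anchor = ifelse(strand == "+", t_start, t_end))]
  }
  span <- df[, .(chrom = chrom[1], start = min(start), end = max(end),
                 strand = strand[1], biotype = biotype[1]), by = gene_id]
  span <- merge(span, pick, by = "gene_id", sort = FALSE)
  span[, start := ifelse(strand == "+", pmin(start, anchor), start)]
  span[, end := ifelse(strand == "-", pmax(end, anchor), end)]
  # TSS = 5' span boundary; ensure the chosen anchor is that boundary
  span[strand == "+", start := anchor]
  span[strand == "-", end := anchor]
  exons <- lapply(span$gene_id, function(g) {
    e <- as.matrix(unique(df[gene_id == g, .(start, end)])[order(start)])
    e <- merge_intervals(e)  # transcripts overlap; the gene model may not
    colnames(e) <- c("start", "end")
    e
  })
  out <- as.data.frame(span[, .(gene_id, chrom, start, end, strand, biotype)])
  out$exons <- exons
  out
}

# thin indirection so the rtracklayer/GenomicRanges generics are resolved
# lazily (both are optional dependencies)
GenomeInfoDb_seqnames <- function(x) {
  getExportedValue("GenomeInfoDb", "seqnames")(x)
}
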