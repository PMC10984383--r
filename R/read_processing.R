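#' Read stranded fragments from BED6
#'
#' @param path BED6 file (name = read id, score = mapq, strand).
#' @param sample_id sample identifier attached to every fragment.
#' @return data.table with columns `chrom`, `start`, `end`, `strand`,
#'   `mapq`, `read_id`, `sample_id` (0-based half-open intervals).
#' @export
read_fragments_bed <- function(path, sample_id = basename(path)) {
  bed <- fread(path, header = FALSE, sep = "\t",
               col.names = c("chrom", "start", "end", "name", "score", "strand"))
  data.table(chrom = bed$chrom, start = bed$start, end = bed$end,
             strand = bed$strand, mapq = as.integer(bed$score),
             read_id = bed$name, sample_id = sample_id)
}

#' Write fragments as BED6
#'
#' @param fragments fragment data.table.
#' @param path output file.
#' @export
write_fragments_bed <- function(fragments, path) {
  fwrite(data.table(chrom = fragments$chrom, start = fragments$start,
                    end = fragments$end,
                    name = paste0("r", fragments$read_id),
                    score = fragments$mapq, strand = fragments$strand),
         path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Read fragments from SAM/BAM
#'
#' Thin adapter over Rsamtools that emits the same fragment records as
#' [read_fragments_bed()]. The reference-consumed width is derived from the
#' CIGAR (M/D/N/=/X operations); unmapped reads are dropped.
#'
#' @param path SAM or BAM file (SAM is converted through [Rsamtools::asBam]
#'   semantics via `scanBam` on a BamFile; plain-text SAM is parsed
#'   directly).
#' @param sample_id sample identifier.
#' @return fragment data.table.
#' @export
read_fragments_sam <- function(path, sample_id = basename(path)) {
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    ln <- readLines(path)
    ln <- ln[!startsWith(ln, "@")]
    if (length(ln) == 0L)
      return(data.table(chrom = character(), start = integer(),
                        end = integer(), strand = character(),
                        mapq = integer(), read_id = character(),
                        sample_id = character()))
    f <- tstrsplit(ln, "\t", fixed = TRUE)
    flag <- as.integer(f[[2]])
    keep <- bitwAnd(flag, 4L) == 0L
    width <- cigar_ref_width(f[[6]])
    data.table(chrom = f[[3]], start = as.integer(f[[4]]) - 1L,
               end = as.integer(f[[4]]) - 1L + width,
               strand = ifelse(bitwAnd(flag, 16L) > 0L, "-", "+"),
               mapq = as.integer(f[[5]]), read_id = f[[1]],
               sample_id = sample_id)[keep]
  } else {
    if (!requireNamespace("Rsamtools", quietly = TRUE))
      abort("reading BAM requires the Rsamtools package")
    res <- Rsamtools::scanBam(path, param = Rsamtools::ScanBamParam(
      what = c("qname", "rname", "pos", "cigar", "strand", "mapq")))[[1]]
    keep <- !is.na(res$pos)
    data.table(chrom = as.character(res$rname),
               start = res$pos - 1L,
               end = res$pos - 1L + cigar_ref_width(res$cigar),
               strand = as.character(res$strand), mapq = res$mapq,
               read_id = res$qname, sample_id = sample_id)[keep]
  }
}

# Internal: reference-consumed width of CIGAR strings
cigar_ref_width <- function(cigar) {
  vapply(cigar, function(cg) {
    if (is.na(cg) || cg == "*") return(0L)
    ops <- gregexpr("\\d+[MIDNSHP=X]", cg)[[1]]
    toks <- regmatches(cg, gregexpr("\\d+[MIDNSHP=X]", cg))[[1]]
    w <- 0L
    for (t in toks) {
      n <- as.integer(sub("[MIDNSHP=X]$", "", t))
      op <- substr(t, nchar(t), nchar(t))
      if (op %in% c("M", "D", "N", "=", "X")) w <- w + n
    }
    w
  }, 0L, USE.NAMES = FALSE)
}

#' Filter aligned fragments
#'
#' Removes fragments below a mapping-quality threshold (the operational
#' proxy for "uniquely mapped") and, optionally, collapses fragments that
#' are identical in (chrom, start, end, strand) within a sample to a single
#' fragment — a conservative stand-in for PCR duplicate/internal-priming
#' removal, off by default. Removal counts per category are attached as the
#' `"removed"` attribute and reported via `message()`.
#'
#' @param fragments fragment data.table.
#' @param min_mapq minimum mapping quality retained (default 50).
#' @param collapse_duplicates collapse identical fragments within a sample.
#' @param verbose emit a message with removal counts.
#' @return filtered fragment data.table.
#' @export
filter_fragments <- function(fragments, min_mapq = 50L,
                             collapse_duplicates = FALSE, verbose = FALSE) {
  fragments <- as.data.table(fragments)
  n0 <- nrow(fragments)
  out <- fragments[mapq >= min_mapq]
  n_mapq <- n0 - nrow(out)
  n_dup <- 0L
  if (collapse_duplicates && nrow(out) > 0L) {
    n1 <- nrow(out)
    out <- out[!duplicated(out, by = c("sample_id", "chrom", "start", "end", "strand"))]
    n_dup <- n1 - nrow(out)
  }
  if (verbose)
    message(sprintf("filter_fragments: removed %d low-mapq, %d duplicate fragments",
                    n_mapq, n_dup))
  setattr(out, "removed", c(low_mapq = n_mapq, duplicate = n_dup))
  out[]
}

#' Extract single-nucleotide polymerase positions (3'OH ends)
#'
#' The strand-aware 3'-terminal base of each fragment marks the active-site
#' position of the transcribing polymerase: a `+` fragment `[s, e)` yields
#' position `e - 1`; a `-` fragment yields `s`. Exactly one position is
#' produced per fragment.
#'
#' @param fragments fragment data.table.
#' @return data.table with columns `chrom`, `pos` (single 0-based base),
#'   `strand`, `sample_id`.
#' @export
extract_3prime <- function(fragments) {
  fragments <- as.data.table(fragments)
  if (nrow(fragments) == 0L)
    return(data.table(chrom = character(), pos = integer(),
                      strand = character(), sample_id = character()))
  check_strand(fragments$strand)
  data.table(chrom = fragments$chrom,
             pos = ifelse(fragments$strand == "+",
                          fragments$end - 1L, fragments$start),
             strand = fragments$strand,
             sample_id = fragments$sample_id)
}

#' Remove splicing-intermediate positions at exon 3' ends
#'
#' Free 3'OH ends produced by co-transcriptional splicing (exon last bases,
#' lariat intermediates) would masquerade as paused polymerase; positions
#' lying within `window` bp of the strand-aware 3'-terminal base of any
#' annotated exon on the same strand are removed. With the default
#' `window = 0` only the exact terminal base is dropped.
#'
#' @param positions data.table from [extract_3prime()].
#' @param genes gene models with an `exons` list column.
#' @param window tolerance around the exon end (bp).
#' @param verbose message the removal count.
#' @return filtered positions; removal count in attribute `"removed"`.
#' @export
filter_splicing_intermediates <- function(positions, genes, window = 0L,
                                          verbose = FALSE) {
  positions <- as.data.table(positions)
  if (is.null(genes$exons) || all(vapply(genes$exons, is.null, TRUE))) {
    warning("genes carry no exon models; positions passed through unfiltered")
    setattr(positions, "removed", 0L)
    return(positions[])
  }
  ends <- rbindlist(lapply(seq_len(nrow(genes)), function(i) {
    e <- genes$exons[[i]]
    if (is.null(e) || nrow(e) == 0L) return(NULL)
    p <- if (genes$strand[i] == "+") e[, "end"] - 1L else e[, "start"]
    data.table(chrom = genes$chrom[i], pos = as.integer(p),
               strand = genes$strand[i])
  }))
  if (window > 0L) {
    ends <- ends[, .(pos = pos + seq.int(-window, window)),
                 by = .(chrom, strand, base = pos)][, .(chrom, pos, strand)]
  }
  ends <- unique(ends)
  n0 <- nrow(positions)
  out <- positions[!ends, on = c("chrom", "strand", "pos")]
  if (verbose)
    message(sprintf("filter_splicing_intermediates: removed %d positions",
                    n0 - nrow(out)))
  setattr(out, "removed", n0 - nrow(out))
  out[]
}

#' Write polymerase positions as width-1 BED6 intervals
#'
#' @param positions data.table from [extract_3prime()].
#' @param path output file.
#' @export
write_positions_bed <- function(positions, path) {
  fwrite(data.table(chrom = positions$chrom, start = positions$pos,
                    end = positions$pos + 1L, name = ".", score = 0L,
                    strand = positions$strand),
         path, sep = "\t", col.names = FALSE)
  invisible(path)
}
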