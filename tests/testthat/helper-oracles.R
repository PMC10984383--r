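# Independent oracles used across the suite. These deliberately avoid the
# code paths of the implementation they check.

# Brute-force per-base overlap counting: a fragment hits a region iff any
# genomic base lies in both (and strands match when required).
oracle_count <- function(regions, fragments, same_strand = TRUE) {
  out <- matrix(0L, nrow = nrow(regions),
                ncol = length(unique(fragments$sample_id)),
                dimnames = list(NULL, sort(unique(fragments$sample_id))))
  for (i in seq_len(nrow(regions))) {
    if (isTRUE(regions$flagged[i])) next
    if (regions$end[i] <= regions$start[i]) next
    rbases <- regions$start[i]:(regions$end[i] - 1L)
    for (j in seq_len(nrow(fragments))) {
      if (fragments$chrom[j] != regions$chrom[i]) next
      if (same_strand && fragments$strand[j] != regions$strand[i]) next
      fbases <- fragments$start[j]:(fragments$end[j] - 1L)
      if (any(fbases %in% rbases))
        out[i, fragments$sample_id[j]] <- out[i, fragments$sample_id[j]] + 1L
    }
  }
  out
}

# Exact Mann-Whitney oracle: U from pairwise comparisons (not rank sums),
# p by enumerating every assignment of pooled values to the x-group.
oracle_mwu <- function(x, y, alternative = "two.sided") {
  u_stat <- function(a, b) {
    sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  }
  U <- u_stat(x, y)
  pooled <- c(x, y)
  n <- length(x); N <- length(pooled)
  idx <- utils::combn(N, n)
  Us <- apply(idx, 2L, function(k) u_stat(pooled[k], pooled[-k]))
  mu <- n * (N - n) / 2
  eps <- 1e-9
  p <- switch(alternative,
              two.sided = mean(abs(Us - mu) >= abs(U - mu) - eps),
              greater = mean(Us >= U - eps),
              less = mean(Us <= U + eps))
  list(U = U, p = p)
}

# One-sided (enrichment) Fisher oracle by hypergeometric tail enumeration
oracle_fisher_greater <- function(a, b, c_, d) {
  # P(X >= a) where X ~ Hypergeom(drawn = a+b, white = a+c_, total = a+b+c_+d)
  k_max <- min(a + b, a + c_)
  ks <- a:k_max
  sum(choose(a + c_, ks) * choose(b + d, a + b - ks)) / choose(a + b + c_ + d, a + b)
}

# Small deterministic gene set spanning both strands
toy_genes <- function() {
  g <- data.frame(
    gene_id = c("gA", "gB", "gC"),
    chrom = "chr1",
    start = c(10000L, 40000L, 70000L),
    end = c(20000L, 52000L, 75000L),
    strand = c("+", "-", "+"),
    biotype = "protein_coding",
    stringsAsFactors = FALSE)
  g$exons <- list(
    cbind(start = c(10000L, 15000L), end = c(12000L, 20000L)),
    cbind(start = 40000L, end = 52000L),
    cbind(start = c(70000L, 72000L, 74000L), end = c(71000L, 73000L, 75000L)))
  g
}

# Fragment row constructor
frag <- function(chrom, start, end, strand, mapq = 60L, sample_id = "s1",
                 read_id = 1L) {
  data.table::data.table(chrom = chrom, start = as.integer(start),
                         end = as.integer(end), strand = strand,
                         mapq = as.integer(mapq), read_id = read_id,
                         sample_id = sample_id)
}

# A normalized count table built directly from a genes x samples matrix
table_from_matrix <- function(m, kind = "PROMPT", lib = NULL,
                              normalized = TRUE) {
  long <- data.table::data.table(
    kind = kind,
    gene_id = rep(rownames(m), ncol(m)),
    sample_id = rep(colnames(m), each = nrow(m)),
    count = as.vector(m))
  if (is.null(lib)) lib <- setNames(rep(1e6, ncol(m)), colnames(m))
  count_table(long, lib, normalized = normalized)
}

# Standard 4+4 sample sheet
sheet44 <- function() {
  data.frame(sample = c(paste0("noIR_rep", 1:4), paste0("IR_rep", 1:4)),
             condition = rep(c("noIR", "IR"), each = 4),
             antibody = "Y1P", replicate = rep(1:4, 2), batch = rep(1:4, 2),
             stringsAsFactors = FALSE)
}
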