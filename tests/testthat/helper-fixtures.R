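# Shared fixtures and independent brute-force oracles.

tiny_config <- function(seed = 11, ...) {
  args <- list(n_chroms = 1L, chrom_length = 30000L, n_genes_per_class = 8L,
               n_tags = 4000L, seed = seed)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(sim_config, args)
}

random_dna <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Brute-force per-bp coverage: stab every position against every interval.
brute_coverage <- function(starts0, ends0, chrom_length) {
  vapply(seq_len(chrom_length) - 1L, function(p) {
    sum(starts0 <= p & p < ends0)
  }, 0L)
}

# Brute-force windowed dA/dT frequency: enumerate every 7-mer per window.
brute_at_freq <- function(seq, window = 150L) {
  L <- nchar(seq)
  half <- window %/% 2L
  out <- rep(NA_real_, L)
  for (x in seq_len(L)) {
    lo <- x - half
    hi <- x + half - 1L
    if (lo < 1L || hi > L) next
    starts <- lo:(hi - 6L)
    kmers <- substring(seq, starts, starts + 6L)
    out[x] <- mean(is_at_tract(kmers))
  }
  out
}

# All 4^7 7-mers, for exhaustive parity checks.
all_7mers <- function() {
  g <- expand.grid(rep(list(c("A", "C", "G", "T")), 7),
                   stringsAsFactors = FALSE)
  apply(g, 1L, paste, collapse = "")
}

granges_sites <- function(chrom, start1, width, strand,
                          gene_id = sprintf("g%02d", seq_along(start1)),
                          class_label = "unlabeled") {
  gr <- GenomicRanges::GRanges(chrom,
                               IRanges::IRanges(start = start1, width = width),
                               strand = strand)
  S4Vectors::mcols(gr)$gene_id <- gene_id
  S4Vectors::mcols(gr)$class_label <- rep(class_label,
                                          length.out = length(start1))
  gr
}

granges_tags <- function(chrom, pos1, strand) {
  GenomicRanges::GRanges(chrom, IRanges::IRanges(start = pos1, width = 1L),
                         strand = strand)
}
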