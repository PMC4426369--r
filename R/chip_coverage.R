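#' Extend sequence tags to a fixed fragment length
#'
#' Single-end ChIP tags are extended 3'-ward from their 5' end to a fixed
#' total length (default 120 bp) to bridge the gap between forward and
#' reverse reads. Coordinates here are 0-based half-open, matching BED;
#' intervals are clipped at chromosome ends.
#'
#' @param five_prime Integer vector of 0-based 5' positions.
#' @param strand Character vector of "+" / "-".
#' @param chrom_length Chromosome length(s) in bp (recycled).
#' @param length Extension length in bp (default 120).
#' @return A `data.frame` with 0-based half-open `start`, `end`.
#' @export
extend_tag <- function(five_prime, strand, chrom_length, length = 120L) {
  stopifnot(length >= 1L, all(strand %in% c("+", "-")))
  if (any(five_prime < 0) || any(five_prime >= chrom_length)) {
    stop("tag 5' position outside chromosome")
  }
  start <- ifelse(strand == "+", five_prime, five_prime - length + 1)
  end <- ifelse(strand == "+", five_prime + length, five_prime + 1)
  data.frame(start = pmax(start, 0), end = pmin(end, chrom_length))
}

#' Per-base-pair coverage of extended tags
#'
#' Each tag is extended to `extend_length` bp from its 5' end
#' ([extend_tag()]) and the number of extended fragments overlapping every
#' base pair is summed, chromosome by chromosome. The result keeps the exact
#' integer mass identity: total coverage equals the summed (clipped) fragment
#' lengths.
#'
#' @param tags `GRanges` of width-1 tag 5' positions with strand, as from
#'   [read_bed()] `kind = "tag"` or [simulate_chip_tags()].
#' @param genome Named `DNAStringSet` (or named character vector); supplies
#'   chromosome names and lengths.
#' @param extend_length Fragment extension in bp (default 120).
#' @return A `CoverageTrack`: list with integer `counts` per chromosome,
#'   `chrom_lengths`, `total_tags`, `genome_size`, `extend_length`, and
#'   `mass` (the summed clipped fragment lengths).
#' @export
coverage_track <- function(tags, genome, extend_length = 120L) {
  lens <- chrom_lengths(genome)
  tag_chrom <- as.character(GenomicRanges::seqnames(tags))
  unknown <- setdiff(unique(tag_chrom), names(lens))
  if (length(unknown)) {
    stop("tags reference unknown chromosome(s): ",
         paste(unknown, collapse = ", "))
  }
  counts <- lapply(names(lens), function(chrom) {
    L <- lens[[chrom]]
    sel <- tag_chrom == chrom
    if (!any(sel)) return(integer(L))
    ext <- extend_tag(GenomicRanges::start(tags)[sel] - 1L,
                      as.character(GenomicRanges::strand(tags))[sel],
                      L, extend_length)
    ir <- IRanges::IRanges(start = ext$start + 1L, end = ext$end)
    as.integer(IRanges::coverage(ir, width = L))
  })
  names(counts) <- names(lens)
  structure(list(counts = counts,
                 chrom_lengths = lens,
                 total_tags = length(tags),
                 genome_size = sum(lens),
                 extend_length = extend_length,
                 mass = sum(vapply(counts, function(v) sum(as.numeric(v)), 0))),
            class = "CoverageTrack")
}

#' @export
print.CoverageTrack <- function(x, ...) {
  cat("CoverageTrack:", length(x$counts), "chromosome(s),",
      x$total_tags, "tags,", x$genome_size, "bp, mass", x$mass, "\n")
  invisible(x)
}

#' Expected per-base-pair coverage under uniform tag placement
#'
#' The genomic average used to ratio-normalize coverage:
#' `extend_length * total_tags / genome_size`.
#'
#' @param total_tags Number of tags; must be positive (the ratio
#'   normalization is undefined for an empty library).
#' @param genome_size Genome size in bp.
#' @param length Tag extension length in bp (default 120).
#' @return The expected coverage (a scalar).
#' @export
expected_per_bp <- function(total_tags, genome_size, length = 120L) {
  if (genome_size <= 0) stop("genome_size must be positive")
  if (total_tags <= 0) stop("normalization undefined: total_tags must be > 0")
  length * total_tags / genome_size
}

#' Genome-wide Z-score normalization of a coverage track
#'
#' Per base pair, coverage is divided by the genomic average
#' ([expected_per_bp()]) and log2-transformed; the log2 ratios are then
#' standardized to N(0,1) using their genome-wide mean and standard
#' deviation. Zero-coverage positions have no defined log2 ratio and are
#' masked (NA): they are excluded from the moments and propagate as missing
#' downstream.
#'
#' @param track A `CoverageTrack` from [coverage_track()].
#' @return A `ZScoreTrack`: list with per-chromosome numeric `z` (NA where
#'   masked), `mean_log2`, `sd_log2`, `chrom_lengths`.
#' @export
normalize_zscore <- function(track) {
  stopifnot(inherits(track, "CoverageTrack"))
  expect <- expected_per_bp(track$total_tags, track$genome_size,
                            track$extend_length)
  logs <- lapply(track$counts, function(v) {
    out <- rep(NA_real_, length(v))
    nz <- v > 0L
    out[nz] <- log2(v[nz] / expect)
    out
  })
  all_vals <- unlist(logs, use.names = FALSE)
  defined <- all_vals[!is.na(all_vals)]
  if (!length(defined)) stop("no covered positions: cannot standardize")
  mu <- mean(defined)
  sdev <- stats::sd(defined)
  if (is.na(sdev) || sdev == 0) {
    warning("constant log2 coverage ratio; Z-scores set to 0")
    z <- lapply(logs, function(v) ifelse(is.na(v), NA_real_, 0))
    sdev <- 0
  } else {
    z <- lapply(logs, function(v) (v - mu) / sdev)
  }
  structure(list(z = z, mean_log2 = mu, sd_log2 = sdev,
                 chrom_lengths = track$chrom_lengths),
            class = "ZScoreTrack")
}

#' @export
print.ZScoreTrack <- function(x, ...) {
  n_def <- sum(vapply(x$z, function(v) sum(!is.na(v)), 0))
  cat("ZScoreTrack:", length(x$z), "chromosome(s),", n_def,
      "defined bp; log2 mean", signif(x$mean_log2, 4),
      "sd", signif(x$sd_log2, 4), "\n")
  invisible(x)
}
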