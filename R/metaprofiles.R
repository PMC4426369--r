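## Meta-profiles: per-gene signal extracted around an anchor (motif center or
## TSS), oriented by gene strand, averaged unweighted across genes.

## Motif center: start + floor(width/2) in 0-based genomic coordinates.
## Deterministic for even motif lengths (14 bp).
site_centers0 <- function(sites) {
  (GenomicRanges::start(sites) - 1L) +
    floor(GenomicRanges::width(sites) / 2)
}

## Matrix of track values per site at gene-frame offsets -flank .. flank-1.
## For "-" strand sites the gene-frame offset d' maps to genomic offset -d'
## (mirror about the anchor base), so upstream signal lands at negative
## offsets for both strands. Out-of-chromosome positions are NA.
site_offset_matrix <- function(values, sites, flank, orient = TRUE) {
  offsets <- seq.int(-flank, flank - 1L)
  centers0 <- site_centers0(sites)
  chroms <- as.character(GenomicRanges::seqnames(sites))
  strands <- as.character(GenomicRanges::strand(sites))
  m <- matrix(NA_real_, nrow = length(sites), ncol = length(offsets))
  for (i in seq_along(sites)) {
    v <- values[[chroms[i]]]
    if (is.null(v)) stop("site on unknown chromosome: ", chroms[i])
    pos0 <- if (orient && strands[i] == "-") centers0[i] - offsets
            else centers0[i] + offsets
    idx <- pos0 + 1L
    ok <- idx >= 1L & idx <= length(v)
    m[i, ok] <- v[idx[ok]]
  }
  list(matrix = m, offsets = offsets)
}

new_metaprofile <- function(offset, mean, n_contributing, n_genes) {
  structure(data.frame(offset = offset, mean = mean,
                       n_contributing = n_contributing),
            n_genes = n_genes,
            class = c("MetaProfile", "data.frame"))
}

#' Motif-centered meta-profile of a signal track
#'
#' Extracts track values on `[center - flank, center + flank)` around each
#' motif center, orients by gene strand (negative offsets upstream), averages
#' within fixed bins (default 10 bp, offset 0 at a bin boundary) ignoring
#' masked values, then averages unweighted across sites. Sites near a
#' chromosome end contribute only their defined offsets.
#'
#' @param track A `ZScoreTrack`, `CoverageTrack`, or named list of per-bp
#'   numeric vectors.
#' @param sites `GRanges` of motif sites (strand used when `orient = TRUE`).
#' @param flank Half-width in bp (default 500).
#' @param bin Bin width in bp (default 10); offsets reported as bin left edges.
#' @param orient Mirror minus-strand sites into gene orientation
#'   (default TRUE).
#' @return A `MetaProfile` data.frame: `offset`, `mean`, `n_contributing`,
#'   with attribute `n_genes`.
#' @export
motif_centered_profile <- function(track, sites, flank = 500L, bin = 10L,
                                   orient = TRUE) {
  if (length(sites) == 0L) stop("empty site list")
  stopifnot(flank >= bin, bin >= 1L, flank %% bin == 0L)
  values <- track_values(track)
  som <- site_offset_matrix(values, sites, flank, orient)
  bin_idx <- floor(som$offsets / bin)  # bins [k*bin, (k+1)*bin)
  ks <- sort(unique(bin_idx))
  per_site <- vapply(ks, function(k) {
    cols <- som$matrix[, bin_idx == k, drop = FALSE]
    rowMeans(cols, na.rm = TRUE)
  }, numeric(nrow(som$matrix)))
  per_site <- matrix(per_site, nrow = nrow(som$matrix))
  per_site[is.nan(per_site)] <- NA_real_
  n_contrib <- colSums(!is.na(per_site))
  means <- ifelse(n_contrib > 0, colMeans(per_site, na.rm = TRUE), NA_real_)
  new_metaprofile(ks * bin, means, n_contrib, length(sites))
}

#' TSS-centered sliding-window meta-profile
#'
#' Per gene, the value at offset `x` is the mean of the track over a window
#' `[x - floor(w/2), x - floor(w/2) + w)` in gene orientation relative to the
#' TSS; offsets advance by `step`. Values are then averaged unweighted across
#' genes.
#'
#' @param track As in [motif_centered_profile()].
#' @param tss `GRanges` of width-1 TSS positions with strand.
#' @param window Smoothing window in bp (default 100).
#' @param step Offset increment in bp (default 10).
#' @param flank Half-range of offsets in bp (default 500).
#' @return A `MetaProfile` data.frame.
#' @export
tss_profile <- function(track, tss, window = 100L, step = 10L, flank = 500L) {
  if (length(tss) == 0L) stop("empty gene list")
  stopifnot(window >= 1L, step >= 1L, flank >= step)
  values <- track_values(track)
  offsets <- seq.int(-flank, flank, by = step)
  t0 <- GenomicRanges::start(tss) - 1L
  chroms <- as.character(GenomicRanges::seqnames(tss))
  strands <- as.character(GenomicRanges::strand(tss))
  half <- floor(window / 2)
  m <- matrix(NA_real_, nrow = length(tss), ncol = length(offsets))
  win_rel <- seq.int(0L, window - 1L) - half
  for (i in seq_along(tss)) {
    v <- values[[chroms[i]]]
    if (is.null(v)) stop("TSS on unknown chromosome: ", chroms[i])
    for (j in seq_along(offsets)) {
      g <- offsets[j] + win_rel  # gene-frame window positions
      pos0 <- if (strands[i] == "-") t0[i] - g else t0[i] + g
      idx <- pos0 + 1L
      idx <- idx[idx >= 1L & idx <= length(v)]
      if (length(idx)) {
        mv <- mean(v[idx], na.rm = TRUE)
        m[i, j] <- if (is.nan(mv)) NA_real_ else mv
      }
    }
  }
  n_contrib <- colSums(!is.na(m))
  means <- ifelse(n_contrib > 0, colMeans(m, na.rm = TRUE), NA_real_)
  new_metaprofile(offsets, means, n_contrib, length(tss))
}

#' Difference of two meta-profiles
#'
#' Elementwise `a - b` on identical offset grids; undefined wherever either
#' side is undefined.
#'
#' @param profile_a,profile_b `MetaProfile`s on the same offset grid.
#' @return A `MetaProfile`-shaped data.frame of differences.
#' @export
profile_delta <- function(profile_a, profile_b) {
  if (!identical(profile_a$offset, profile_b$offset)) {
    stop("offset grids differ; profiles are not comparable")
  }
  mean_d <- profile_a$mean - profile_b$mean
  n_contrib <- pmin(profile_a$n_contributing, profile_b$n_contributing)
  mean_d[profile_a$n_contributing == 0 | profile_b$n_contributing == 0] <- NA_real_
  new_metaprofile(profile_a$offset, mean_d, n_contrib,
                  min(attr(profile_a, "n_genes"), attr(profile_b, "n_genes")))
}

#' Value of a meta-profile at a given offset
#'
#' @param profile A `MetaProfile`.
#' @param offset Offset (bin left edge / grid point) to look up, default 0.
#' @return The mean signal at that offset.
#' @export
profile_at <- function(profile, offset = 0) {
  i <- match(offset, profile$offset)
  if (is.na(i)) stop("offset ", offset, " not on the profile grid")
  profile$mean[i]
}
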