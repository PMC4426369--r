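## Poly(dA:dT) nucleosome-disfavoring sequence statistic: 7-mers containing
## at least six A's or at least six T's, counted in sliding 150-bp windows,
## plus PWM log-odds scoring and the two-standard-deviation site-conservation
## criterion.

#' Is a 7-mer a nucleosome-disfavoring dA/dT tract?
#'
#' TRUE iff the 7-bp sequence contains at least six A's or at least six T's.
#' `N` counts as neither. Vectorized over k-mers.
#'
#' @param kmer Character vector of 7-bp strings over `{A,C,G,T,N}`.
#' @return Logical vector.
#' @export
is_at_tract <- function(kmer) {
  if (any(nchar(kmer) != 7L)) stop("is_at_tract expects 7-bp strings")
  up <- toupper(kmer)
  if (any(grepl("[^ACGTN]", up))) stop("alphabet must be {A,C,G,T,N}")
  n_a <- nchar(gsub("[^A]", "", up))
  n_t <- nchar(gsub("[^T]", "", up))
  n_a >= 6L | n_t >= 6L
}

## Logical indicator over 7-mer start positions (length L-6) for a single
## sequence, split by tract identity. Vectorized via cumulative sums.
tract_indicators <- function(seq) {
  chars <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  L <- length(chars)
  if (L < 7L) stop("sequence shorter than 7 bp")
  roll7 <- function(ind) {
    cs <- c(0, cumsum(ind))
    cs[8:(L + 1L)] - cs[1:(L - 6L)]
  }
  a7 <- roll7(chars == "A")
  t7 <- roll7(chars == "T")
  list(A = a7 >= 6L, T = t7 >= 6L)
}

## Rolling count of TRUE indicator values over the n_starts = window - 6
## 7-mer starts inside the centered window; NA where the window leaves the
## sequence. Returns numeric length nchar(seq).
window_tract_freq <- function(ind, L, window) {
  half <- window %/% 2L
  n_starts <- window - 6L
  cs <- c(0, cumsum(ind))
  out <- rep(NA_real_, L)
  # window at x (1-based) covers bases [x-half, x+half-1]; valid 7-mer starts
  # s in [x-half, x+half-7]; defined iff the window lies inside the sequence
  xs <- seq.int(half + 1L, L - half + 1L)
  xs <- xs[xs >= 1L & xs <= L]
  if (length(xs)) {
    lo <- xs - half          # first start
    hi <- xs + half - 7L     # last start
    out[xs] <- (cs[hi + 1L] - cs[lo]) / n_starts
  }
  out
}

#' Sliding-window dA/dT tract frequency along a sequence
#'
#' The value at position `x` is the fraction of 7-mer start positions inside
#' the `window`-bp window centered at `x` whose 7-mer satisfies
#' [is_at_tract()]; the denominator is `window - 6` valid starts. The window
#' slides 1 bp; positions whose window leaves the sequence are `NA`.
#'
#' @param seq A single DNA string (character or `DNAString`).
#' @param window Window width in bp (default 150).
#' @return Numeric vector, one value per base of `seq`, in `[0, 1]` or `NA`.
#' @export
at_tract_window_freq <- function(seq, window = 150L) {
  seq <- as.character(seq)
  L <- nchar(seq)
  if (L < window) stop("sequence (", L, " bp) shorter than window (",
                       window, " bp)")
  ind <- tract_indicators(seq)
  window_tract_freq(ind$A | ind$T, L, window)
}

#' A-tract / T-tract decomposition of the windowed frequency
#'
#' Splits [at_tract_window_freq()] into its two disjoint components: 7-mers
#' with >= 6 A's and 7-mers with >= 6 T's (no 7-mer satisfies both). The two
#' arrays sum pointwise to the combined statistic.
#'
#' @inheritParams at_tract_window_freq
#' @return A list with numeric arrays `A` and `T`.
#' @export
tract_decomposition <- function(seq, window = 150L) {
  seq <- as.character(seq)
  L <- nchar(seq)
  if (L < window) stop("sequence (", L, " bp) shorter than window (",
                       window, " bp)")
  ind <- tract_indicators(seq)
  list(A = window_tract_freq(ind$A, L, window),
       T = window_tract_freq(ind$T, L, window))
}

## Gene-strand promoter sequence spanning gene-frame offsets
## [-flank - half, flank + half] around the motif center; returns NA-padded
## character or NULL when wholly off-chromosome. Offsets whose window would
## overlap the padding come back NA from the caller's windowing.
site_flank_sequence <- function(genome, site, flank, half) {
  genome <- as_genome(genome)
  chrom <- as.character(GenomicRanges::seqnames(site))
  if (!chrom %in% names(genome)) stop("site on unknown chromosome: ", chrom)
  L <- length(genome[[chrom]])
  center1 <- site_centers0(site) + 1L
  ext <- flank + half
  lo <- center1 - ext
  hi <- center1 + ext
  lo_c <- max(lo, 1L)
  hi_c <- min(hi, L)
  if (lo_c > hi_c) return(NULL)
  s <- Biostrings::subseq(genome[[chrom]], lo_c, hi_c)
  pad_l <- lo_c - lo
  pad_r <- hi - hi_c
  seq <- paste0(strrep("N", pad_l), as.character(s), strrep("N", pad_r))
  if (as.character(GenomicRanges::strand(site)) == "-") {
    seq <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
    pad <- pad_l; pad_l <- pad_r; pad_r <- pad
  }
  list(seq = seq, pad_left = pad_l, pad_right = pad_r)
}

## Per-gene dA/dT frequency at gene-frame offsets -flank..flank (coding
## strand). Rows = sites, columns = offsets. Positions whose window touches
## off-chromosome padding are NA.
site_at_freq_matrix <- function(genome, sites, flank = 500L, window = 150L,
                                component = c("both", "A", "T")) {
  component <- match.arg(component)
  half <- window %/% 2L
  offsets <- seq.int(-flank, flank)
  m <- matrix(NA_real_, nrow = length(sites), ncol = length(offsets))
  for (i in seq_along(sites)) {
    fs <- site_flank_sequence(genome, sites[i], flank, half)
    if (is.null(fs)) next
    freq <- switch(component,
                   both = at_tract_window_freq(fs$seq, window),
                   A = tract_decomposition(fs$seq, window)$A,
                   T = tract_decomposition(fs$seq, window)$T)
    # mask positions whose window overlaps the N padding
    Lq <- nchar(fs$seq)
    if (fs$pad_left > 0L) freq[seq_len(min(fs$pad_left + half, Lq))] <- NA_real_
    if (fs$pad_right > 0L) {
      freq[seq.int(max(Lq - fs$pad_right - half + 1L, 1L), Lq)] <- NA_real_
    }
    # offset d maps to index flank + half + 1 + d
    m[i, ] <- freq[flank + half + 1L + offsets]
  }
  list(matrix = m, offsets = offsets)
}

#' Class-averaged dA/dT tract frequency profile around motif sites
#'
#' Per gene, the promoter sequence is taken on the coding strand (minus-strand
#' sites are reverse-complemented) so negative offsets are upstream of the
#' motif in gene orientation; the windowed dA/dT frequency is computed per
#' offset and averaged unweighted within each class.
#'
#' @param genome Named `DNAStringSet` or named character vector.
#' @param sites `GRanges` with `gene_id` and `class_label` metadata.
#' @param flank Half-range of offsets in bp (default 500).
#' @param window Sliding window width in bp (default 150).
#' @param component `"both"` (the dA/dT statistic), `"A"`, or `"T"` for the
#'   tract decomposition.
#' @return An `ATProfile` data.frame: `offset`, `class_label`, `mean`, `n`,
#'   long format; attribute `n_genes` is a named count per class.
#' @export
class_average_at_profile <- function(genome, sites, flank = 500L,
                                     window = 150L,
                                     component = c("both", "A", "T")) {
  component <- match.arg(component)
  if (length(sites) == 0L) stop("no sites supplied")
  cls <- S4Vectors::mcols(sites)$class_label
  if (is.null(cls)) stop("sites need a class_label metadata column")
  mats <- site_at_freq_matrix(genome, sites, flank, window, component)
  out <- do.call(rbind, lapply(sort(unique(cls)), function(cl) {
    rows <- mats$matrix[cls == cl, , drop = FALSE]
    if (nrow(rows) == 0L) {
      warning("class '", cl, "' has zero genes; omitted")
      return(NULL)
    }
    n_def <- colSums(!is.na(rows))
    data.frame(offset = mats$offsets,
               class_label = cl,
               mean = ifelse(n_def > 0, colMeans(rows, na.rm = TRUE), NA_real_),
               n = n_def)
  }))
  n_genes <- vapply(split(cls, cls), length, 0L)
  structure(out, n_genes = n_genes, class = c("ATProfile", "data.frame"))
}

#' Cross-species dA/dT profiles over orthologous promoters
#'
#' Computes one class-averaged profile per species, each species scored
#' independently on its own genome and site coordinates (orthology is
#' established upstream; sites share `gene_id`s). Genes missing in a species
#' are simply absent from that species' site set.
#'
#' @param species Named list; each element a list with `genome` and `sites`.
#' @param flank,window As in [class_average_at_profile()].
#' @return Named list of `ATProfile`s, one per species.
#' @export
cross_species_profiles <- function(species, flank = 500L, window = 150L) {
  stopifnot(is.list(species), length(species) >= 1L,
            !is.null(names(species)))
  lapply(stats::setNames(names(species), names(species)), function(sp) {
    x <- species[[sp]]
    if (is.null(x$sites) || length(x$sites) == 0L) {
      stop("species '", sp, "' has zero mapped genes")
    }
    class_average_at_profile(x$genome, x$sites, flank = flank, window = window)
  })
}

#' Build a position weight matrix
#'
#' @param mat Numeric matrix, one row per motif position, columns
#'   `A`, `C`, `G`, `T` (per-position base probabilities).
#' @param background Length-4 background base probabilities (default uniform).
#' @param pseudo Pseudo-probability added to every cell before renormalizing
#'   (default 1e-3), so log-odds are finite.
#' @return A `PWM` object.
#' @export
pwm <- function(mat, background = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25),
                pseudo = 1e-3) {
  mat <- as.matrix(mat)
  if (ncol(mat) != 4L) stop("PWM needs 4 columns (A, C, G, T)")
  colnames(mat) <- c("A", "C", "G", "T")
  if (any(mat < 0)) stop("PWM probabilities must be non-negative")
  mat <- mat + pseudo
  mat <- mat / rowSums(mat)
  background <- background / sum(background)
  names(background) <- c("A", "C", "G", "T")
  if (any(background <= 0)) stop("background probabilities must be positive")
  structure(list(mat = mat, background = background), class = "PWM")
}

#' @export
print.PWM <- function(x, ...) {
  cat("PWM:", nrow(x$mat), "positions; consensus",
      paste(colnames(x$mat)[max.col(x$mat)], collapse = ""), "\n")
  invisible(x)
}

#' PWM from a consensus sequence
#'
#' Every position gives probability `p` to the consensus base and
#' `(1 - p) / 3` to each alternative — the equal-alternative structure keeps
#' all single-substitution log-odds penalties identical, which is convenient
#' for simulated motif sets.
#'
#' @param consensus Consensus string over `{A,C,G,T}`.
#' @param p Probability of the consensus base per position (default 0.7).
#' @inheritParams pwm
#' @return A `PWM`.
#' @export
pwm_from_consensus <- function(consensus, p = 0.7,
                               background = c(A = 0.25, C = 0.25,
                                              G = 0.25, T = 0.25),
                               pseudo = 1e-3) {
  bases <- strsplit(toupper(consensus), "", fixed = TRUE)[[1]]
  if (any(!bases %in% c("A", "C", "G", "T"))) {
    stop("consensus must be over {A,C,G,T}")
  }
  m <- matrix((1 - p) / 3, nrow = length(bases), ncol = 4L,
              dimnames = list(NULL, c("A", "C", "G", "T")))
  m[cbind(seq_along(bases), match(bases, c("A", "C", "G", "T")))] <- p
  pwm(m, background = background, pseudo = pseudo)
}

#' Read / write a PWM as tab-separated probabilities
#'
#' File format: header `A C G T` (tab-separated), one row of probabilities
#' per motif position.
#'
#' @param path File path.
#' @inheritParams pwm
#' @return [read_pwm()] returns a `PWM`; [write_pwm()] returns `path`.
#' @export
read_pwm <- function(path, background = c(A = 0.25, C = 0.25,
                                          G = 0.25, T = 0.25),
                     pseudo = 1e-3) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t")
  if (!all(c("A", "C", "G", "T") %in% names(df))) {
    stop("PWM file needs columns A, C, G, T: ", path)
  }
  pwm(as.matrix(df[, c("A", "C", "G", "T")]), background = background,
      pseudo = pseudo)
}

#' @rdname read_pwm
#' @param x A `PWM`.
#' @export
write_pwm <- function(x, path) {
  stopifnot(inherits(x, "PWM"))
  write_table_strict(as.data.frame(x$mat), path)
}

#' Log-odds PWM score of motif-length sequences
#'
#' Score = sum over positions of `log2(p_i[base] / background[base])`.
#' Sequences must be given on the strand to be scored; use
#' [site_sequences()] to extract minus-strand sites already
#' reverse-complemented.
#'
#' @param site_seq Character vector of sequences, each of motif length.
#' @param pwm A `PWM`.
#' @return Numeric vector of log2 odds scores.
#' @export
pwm_score <- function(site_seq, pwm) {
  stopifnot(inherits(pwm, "PWM"))
  L <- nrow(pwm$mat)
  if (any(nchar(site_seq) != L)) {
    stop("site length mismatch: PWM has ", L, " positions")
  }
  logodds <- log2(sweep(pwm$mat, 2L, pwm$background, "/"))
  vapply(site_seq, function(s) {
    b <- match(strsplit(toupper(s), "", fixed = TRUE)[[1]],
               c("A", "C", "G", "T"))
    if (anyNA(b)) stop("sequence contains non-ACGT base: ", s)
    sum(logodds[cbind(seq_len(L), b)])
  }, 0, USE.NAMES = FALSE)
}

#' Extract site sequences on the gene strand
#'
#' @param genome Named `DNAStringSet` or named character vector.
#' @param sites `GRanges`; minus-strand sites are reverse-complemented.
#' @return Character vector of sequences, named by `gene_id` when present.
#' @export
site_sequences <- function(genome, sites) {
  genome <- as_genome(genome)
  out <- vapply(seq_along(sites), function(i) {
    chrom <- as.character(GenomicRanges::seqnames(sites)[i])
    if (!chrom %in% names(genome)) stop("unknown chromosome: ", chrom)
    s <- Biostrings::subseq(genome[[chrom]],
                            GenomicRanges::start(sites)[i],
                            GenomicRanges::end(sites)[i])
    if (as.character(GenomicRanges::strand(sites)[i]) == "-") {
      s <- Biostrings::reverseComplement(s)
    }
    as.character(s)
  }, "")
  gid <- S4Vectors::mcols(sites)$gene_id
  if (!is.null(gid)) names(out) <- gid
  out
}

#' Call cross-species conservation of motif sites
#'
#' The reference-species score distribution (mean `mu`, sd `sigma` over the
#' scored reference sites) defines the acceptance band: a site is conserved
#' iff in every non-reference species its orthologous site scores at least
#' `mu - n_sd * sigma` (default two standard deviations below the motif
#' average).
#'
#' @param ref_scores Numeric vector of reference-species site scores, named
#'   by `gene_id`.
#' @param species_scores data.frame with column `gene_id` plus one numeric
#'   score column per non-reference species.
#' @param n_sd Width of the band in reference SDs (default 2).
#' @return A `data.frame` with `gene_id`, the per-species scores, and a
#'   logical `conserved`; attributes `mu`, `sigma`, `threshold`.
#' @export
call_conserved <- function(ref_scores, species_scores, n_sd = 2) {
  stopifnot(is.numeric(ref_scores), length(ref_scores) >= 2L)
  mu <- mean(ref_scores)
  sigma <- stats::sd(ref_scores)
  if (is.na(sigma) || sigma == 0) {
    stop("reference score distribution has zero sd; criterion undefined")
  }
  if (!"gene_id" %in% names(species_scores)) {
    stop("species_scores needs a gene_id column")
  }
  sp_cols <- setdiff(names(species_scores), "gene_id")
  if (!length(sp_cols)) stop("no species score columns supplied")
  thr <- mu - n_sd * sigma
  score_mat <- as.matrix(species_scores[, sp_cols, drop = FALSE])
  conserved <- apply(score_mat >= thr, 1L, all)
  out <- cbind(species_scores, conserved = conserved)
  structure(out, mu = mu, sigma = sigma, threshold = thr)
}
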