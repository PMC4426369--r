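#' Classify a factor target from its expression change
#'
#' Targets whose transcripts drop at least `responsive_fold` (1.5-fold by
#' default, i.e. `log2fc <= -log2(1.5)`) are *transcriptionally responsive*;
#' targets with `|log2fc| < memory_cutoff` (0.2 by default) are *memory
#' effect*; everything between is *intermediate*. Negative `log2fc` means
#' reduced expression in the mutant. Boundary behavior is fixed:
#' `log2fc = -log2(1.5)` is responsive, `|log2fc| = memory_cutoff` is
#' intermediate.
#'
#' @param log2fc Numeric vector of log2 fold changes (mutant vs wild type);
#'   must be finite.
#' @param responsive_fold Fold-decrease threshold (default 1.5).
#' @param memory_cutoff Absolute log2 change below which a target is a
#'   memory-effect gene (default 0.2).
#' @return Character vector over `{"responsive", "memory", "intermediate"}`.
#' @export
classify_target <- function(log2fc, responsive_fold = 1.5,
                            memory_cutoff = 0.2) {
  if (any(!is.finite(log2fc))) stop("log2fc must be finite")
  stopifnot(responsive_fold > 1, memory_cutoff > 0,
            memory_cutoff < log2(responsive_fold))
  out <- rep("intermediate", length(log2fc))
  out[log2fc <= -log2(responsive_fold)] <- "responsive"
  out[abs(log2fc) < memory_cutoff] <- "memory"
  out
}

#' Classify an expression table
#'
#' @param expression data.frame with `gene_id` and `log2fc` columns; gene ids
#'   must be unique.
#' @inheritParams classify_target
#' @return data.frame with an added `class_label` column; summary counts are
#'   reported via `message()`.
#' @export
classify_table <- function(expression, responsive_fold = 1.5,
                           memory_cutoff = 0.2) {
  stopifnot(all(c("gene_id", "log2fc") %in% names(expression)))
  if (anyDuplicated(expression$gene_id)) {
    stop("duplicate gene_id(s): ",
         paste(unique(expression$gene_id[duplicated(expression$gene_id)]),
               collapse = ", "))
  }
  expression$class_label <- if (nrow(expression)) {
    classify_target(expression$log2fc, responsive_fold, memory_cutoff)
  } else character()
  counts <- table(factor(expression$class_label,
                         levels = c("memory", "responsive", "intermediate")))
  message("classified ", nrow(expression), " genes: ",
          paste(names(counts), counts, sep = "=", collapse = ", "))
  expression
}

#' Overlap between two peak sets
#'
#' A peak is *shared* if it overlaps at least `min_overlap` bp with any peak
#' of the other set; shared counting is per set, so one peak overlapping two
#' peaks of the other set counts once (Venn-style semantics). The counts
#' partition each set.
#'
#' @param peaks_a,peaks_b `GRanges` of peak intervals.
#' @param min_overlap Minimum overlap in bp (default 1).
#' @return List with `a_only`, `b_only`, `shared_a`, `shared_b` (shared
#'   counts from each set's side; they can differ when overlaps are not
#'   one-to-one).
#' @export
peak_overlap <- function(peaks_a, peaks_b, min_overlap = 1L) {
  stopifnot(min_overlap >= 1L)
  shared_a <- sum(GenomicRanges::countOverlaps(
    peaks_a, peaks_b, minoverlap = min_overlap, ignore.strand = TRUE) > 0L)
  shared_b <- sum(GenomicRanges::countOverlaps(
    peaks_b, peaks_a, minoverlap = min_overlap, ignore.strand = TRUE) > 0L)
  list(a_only = length(peaks_a) - shared_a,
       b_only = length(peaks_b) - shared_b,
       shared_a = shared_a,
       shared_b = shared_b)
}
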