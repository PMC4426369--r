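#' Read a genome FASTA file
#'
#' Sequences are uppercased and validated against the DNA alphabet
#' `{A, C, G, T, N}`. RNA (`U`) and duplicated headers are rejected: every
#' downstream coordinate is interpreted against these sequences, so silent
#' repairs are not allowed.
#'
#' @param path Path to a FASTA file.
#' @return A named [Biostrings::DNAStringSet], one element per chromosome.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  first <- readLines(path, n = 1L)
  if (length(first) == 0L || !startsWith(first, ">")) {
    stop("malformed FASTA header at line 1 of ", path,
         ": expected a line starting with '>'")
  }
  x <- Biostrings::readBStringSet(path)
  nm <- names(x)
  if (anyDuplicated(nm)) {
    stop("duplicate FASTA header(s): ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "))
  }
  seqs <- toupper(as.character(x))
  if (any(grepl("U", seqs, fixed = TRUE))) {
    stop("RNA alphabet (U) not supported; supply DNA sequences")
  }
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad)) {
    stop("sequence '", nm[which(bad)[1]],
         "' contains characters outside {A,C,G,T,N}")
  }
  if (any(nchar(seqs) < 1L)) stop("zero-length sequence in ", path)
  out <- Biostrings::DNAStringSet(seqs)
  names(out) <- nm
  out
}

#' Write a genome FASTA file
#'
#' @param genome Named [Biostrings::DNAStringSet] (or named character vector).
#' @param path Output path; 60-column wrapped, LF line endings.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(genome, path) {
  genome <- as_genome(genome)
  Biostrings::writeXStringSet(genome, filepath = path, width = 60L)
  invisible(path)
}

## Coerce named character vectors to DNAStringSet so both work everywhere.
as_genome <- function(genome) {
  if (methods::is(genome, "DNAStringSet")) return(genome)
  if (is.character(genome) && !is.null(names(genome))) {
    out <- Biostrings::DNAStringSet(toupper(genome))
    names(out) <- names(genome)
    return(out)
  }
  stop("genome must be a named DNAStringSet or named character vector")
}

chrom_lengths <- function(genome) {
  genome <- as_genome(genome)
  stats::setNames(Biostrings::width(genome), names(genome))
}

#' Read a BED file as sites, peaks, or sequence tags
#'
#' Intervals are 0-based half-open on disk (standard BED) and converted to the
#' 1-based closed convention of [GenomicRanges::GRanges] in memory. For
#' `kind = "tag"` each record is collapsed to the 5' end of the read: the
#' `start` coordinate for `+` tags, `end - 1` (0-based) for `-` tags.
#'
#' Motif sites carry `gene_id` and `class_label` metadata parsed from the BED
#' name field, written as `geneid|class`; a name without a class part is
#' labeled `unlabeled`.
#'
#' @param path Path to a BED3/BED6 file (tab-separated, no header).
#' @param kind One of `"site"`, `"peak"`, `"tag"`.
#' @return A `GRanges`. Sites have `gene_id` and `class_label` metadata
#'   columns; peaks have `score`; tags are width-1 ranges at the 5' base.
#' @export
read_bed <- function(path, kind = c("site", "peak", "tag")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("BED file not found: ", path)
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE, comment.char = "",
                          quote = "", colClasses = "character")
  if (ncol(df) < 3L) stop("BED needs at least 3 columns: ", path)
  start0 <- suppressWarnings(as.numeric(df[[2]]))
  end0 <- suppressWarnings(as.numeric(df[[3]]))
  if (anyNA(start0) || anyNA(end0)) stop("non-numeric BED coordinates in ", path)
  if (any(start0 < 0)) stop("negative BED start in ", path)
  if (any(start0 >= end0)) {
    i <- which(start0 >= end0)[1]
    stop("BED record ", i, " in ", path, " has start >= end (",
         start0[i], " >= ", end0[i], ")")
  }
  has6 <- ncol(df) >= 6L
  strand <- if (has6) df[[6]] else rep(".", nrow(df))
  if (kind %in% c("site", "tag")) {
    if (!has6 || !all(strand %in% c("+", "-"))) {
      stop("kind='", kind, "' requires BED6 with strand +/- in ", path)
    }
  }
  name <- if (ncol(df) >= 4L) df[[4]] else rep(".", nrow(df))
  score <- if (ncol(df) >= 5L) suppressWarnings(as.numeric(df[[5]])) else rep(0, nrow(df))
  if (kind == "tag") {
    pos0 <- ifelse(strand == "+", start0, end0 - 1)
    gr <- GenomicRanges::GRanges(df[[1]],
                                 IRanges::IRanges(start = pos0 + 1, width = 1L),
                                 strand = strand)
    return(gr)
  }
  gr <- GenomicRanges::GRanges(df[[1]],
                               IRanges::IRanges(start = start0 + 1, end = end0),
                               strand = ifelse(strand %in% c("+", "-"), strand, "*"))
  if (kind == "site") {
    parts <- strsplit(name, "|", fixed = TRUE)
    gene_id <- vapply(parts, `[`, "", 1L)
    class_label <- vapply(parts, function(p) if (length(p) >= 2L) p[2] else "unlabeled", "")
    S4Vectors::mcols(gr)$gene_id <- gene_id
    S4Vectors::mcols(gr)$class_label <- class_label
  } else {
    S4Vectors::mcols(gr)$score <- score
  }
  gr
}

#' Write sites, peaks, or tags as BED6
#'
#' Inverse of [read_bed()]: 0-based half-open coordinates, LF endings, no
#' trailing whitespace. Sites encode `gene_id|class_label` in the name field;
#' tags are written as width-1 intervals at the 5' base.
#'
#' @param gr A `GRanges` as produced by [read_bed()] or the simulator.
#' @param path Output path.
#' @param kind One of `"site"`, `"peak"`, `"tag"`.
#' @return `path`, invisibly.
#' @export
write_bed <- function(gr, path, kind = c("site", "peak", "tag")) {
  kind <- match.arg(kind)
  chrom <- as.character(GenomicRanges::seqnames(gr))
  start0 <- GenomicRanges::start(gr) - 1L
  end0 <- GenomicRanges::end(gr)
  strand <- as.character(GenomicRanges::strand(gr))
  strand[strand == "*"] <- "."
  mc <- S4Vectors::mcols(gr)
  name <- if (kind == "site" && !is.null(mc$gene_id)) {
    paste(mc$gene_id, mc$class_label, sep = "|")
  } else if (!is.null(mc$name)) mc$name else rep(".", length(gr))
  score <- if (!is.null(mc$score)) mc$score else rep(0, length(gr))
  lines <- paste(chrom, start0, end0, name, score, strand, sep = "\t")
  writeLines(lines, path, sep = "\n")
  invisible(path)
}

#' Read a headered TSV table with validation
#'
#' @param path Path to a tab-separated file with a header row.
#' @param required_columns Character vector of column names that must be
#'   present; all required columns other than `gene_id` must parse as numeric.
#' @return A `data.frame`. `gene_id` uniqueness is enforced.
#' @export
read_table_strict <- function(path, required_columns = c("gene_id")) {
  if (!file.exists(path)) stop("table not found: ", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE,
                          colClasses = "character")
  missing <- setdiff(required_columns, names(df))
  if (length(missing)) {
    stop("missing required column(s) in ", path, ": ",
         paste(missing, collapse = ", "))
  }
  for (col in setdiff(required_columns, "gene_id")) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    if (anyNA(v) && !all(is.na(df[[col]]) | df[[col]] %in% c("NA", ""))) {
      bad <- which(is.na(v) & !(df[[col]] %in% c("NA", "")))[1]
      stop("non-numeric value '", df[[col]][bad], "' in column '", col,
           "', row ", bad, " of ", path)
    }
    df[[col]] <- v
  }
  if ("gene_id" %in% names(df) && anyDuplicated(df$gene_id)) {
    stop("duplicate gene_id(s) in ", path, ": ",
         paste(unique(df$gene_id[duplicated(df$gene_id)]), collapse = ", "))
  }
  df
}

#' Write a TSV table
#'
#' @param df A data.frame.
#' @param path Output path; header, tab-separated, LF endings.
#' @return `path`, invisibly.
#' @export
write_table_strict <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, eol = "\n")
  invisible(path)
}

#' Write a per-base-pair track as TSV
#'
#' One row per base: `chrom`, `pos0` (0-based), `value`; masked/undefined
#' positions are written as `NA`.
#'
#' @param track A [CoverageTrack], [ZScoreTrack], or named list of numeric
#'   vectors.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_track <- function(track, path) {
  values <- track_values(track)
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines("chrom\tpos0\tvalue", con)
  for (chrom in names(values)) {
    v <- values[[chrom]]
    writeLines(paste(chrom, seq_along(v) - 1L, format(v, trim = TRUE,
                                                      scientific = FALSE),
                     sep = "\t"), con)
  }
  invisible(path)
}

#' Read a per-base-pair track TSV
#'
#' @param path Path written by [write_track()].
#' @return Named list of numeric vectors (NA where masked).
#' @export
read_track <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  stopifnot(all(c("chrom", "pos0", "value") %in% names(df)))
  out <- lapply(split(df, df$chrom), function(d) {
    v <- rep(NA_real_, max(d$pos0) + 1L)
    v[d$pos0 + 1L] <- as.numeric(d$value)
    v
  })
  out[unique(df$chrom)]
}

## Per-chromosome numeric values behind any track-like object.
track_values <- function(track) {
  if (inherits(track, "ZScoreTrack")) return(track$z)
  if (inherits(track, "CoverageTrack")) return(lapply(track$counts, as.numeric))
  if (is.list(track) && !is.null(names(track))) return(lapply(track, as.numeric))
  stop("not a track: expected CoverageTrack, ZScoreTrack, or named list")
}
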