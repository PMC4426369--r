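## Synthetic data with the statistical structure the analysis assumes: two
## promoter classes sharing one planted motif but differing in upstream
## T-tract density, ChIP tag enrichment at motifs that drops between two
## conditions, class-dependent expression fold changes, and class-dependent
## expression noise.

#' Default planted motif (14 bp)
#' @export
default_motif <- function() "TCACGATGAGTACG"

#' Simulation configuration
#'
#' Defaults are the study conditions the downstream acceptance checks run
#' under: 60 genes per class on a 2 x 250-kb genome, a 14-bp motif, upstream
#' T-tract insertion rates 0.08 (memory) vs 0.02 (responsive) per bp over
#' gene-frame offsets `[-200, -20)`, 50,000 tags per ChIP condition with
#' 5-fold (wild type) vs 2-fold (ts mutant) motif enrichment, expression
#' log2 fold changes centered at -1 (responsive) vs 0 (memory) with sd 0.1,
#' and noise values centered at -0.5 (memory) vs 0 (responsive) with sd 0.2.
#'
#' @param n_chroms,chrom_length Genome shape.
#' @param n_genes_per_class Genes per class (`memory`, `responsive`).
#' @param motif Planted consensus (14 bp default).
#' @param upstream_ttract_rate_memory,upstream_ttract_rate_responsive
#'   Per-bp probability of starting a T-tract (run of 5-8 T on the coding
#'   strand) inside `ttract_region`.
#' @param ttract_region Gene-frame offset interval, half-open, relative to
#'   the motif center (default `c(-200, -20)`).
#' @param chip_enrichment_wt,chip_enrichment_ts Fold enrichment of coverage
#'   at motif centers over the genomic mean, per condition; must be >= 1.
#' @param n_tags Tags per ChIP condition.
#' @param fragment_offset 5'-end displacement of motif-derived tags from the
#'   motif center in bp (default 60; half the 120-bp extension).
#' @param tag_jitter_sd SD of the Normal tag-position jitter in bp.
#' @param log2fc_mean_responsive,log2fc_mean_memory,log2fc_sd Expression
#'   change distribution per class (log2 units).
#' @param noise_mean_by_class Named numeric, mean noise value per class.
#' @param noise_sd SD of noise values.
#' @param seed Master seed; every simulated object draws from a stream
#'   derived from it by a fixed offset.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n_chroms = 2L,
                       chrom_length = 250000L,
                       n_genes_per_class = 60L,
                       motif = default_motif(),
                       upstream_ttract_rate_memory = 0.08,
                       upstream_ttract_rate_responsive = 0.02,
                       ttract_region = c(-200L, -20L),
                       chip_enrichment_wt = 5,
                       chip_enrichment_ts = 2,
                       n_tags = 50000L,
                       fragment_offset = 60L,
                       tag_jitter_sd = 20,
                       log2fc_mean_responsive = -1.0,
                       log2fc_mean_memory = 0.0,
                       log2fc_sd = 0.1,
                       noise_mean_by_class = c(memory = -0.5, responsive = 0.0),
                       noise_sd = 0.2,
                       seed = 1L) {
  cfg <- list(n_chroms = as.integer(n_chroms),
              chrom_length = as.integer(chrom_length),
              n_genes_per_class = as.integer(n_genes_per_class),
              motif = toupper(motif),
              upstream_ttract_rate_memory = upstream_ttract_rate_memory,
              upstream_ttract_rate_responsive = upstream_ttract_rate_responsive,
              ttract_region = as.integer(ttract_region),
              chip_enrichment_wt = chip_enrichment_wt,
              chip_enrichment_ts = chip_enrichment_ts,
              n_tags = as.integer(n_tags),
              fragment_offset = as.integer(fragment_offset),
              tag_jitter_sd = tag_jitter_sd,
              log2fc_mean_responsive = log2fc_mean_responsive,
              log2fc_mean_memory = log2fc_mean_memory,
              log2fc_sd = log2fc_sd,
              noise_mean_by_class = noise_mean_by_class,
              noise_sd = noise_sd,
              seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  stopifnot(cfg$n_chroms >= 1L, cfg$chrom_length >= 1L,
            cfg$n_genes_per_class >= 0L, cfg$n_tags >= 0L,
            nchar(cfg$motif) >= 1L)
  if (grepl("[^ACGT]", cfg$motif)) stop("motif must be over {A,C,G,T}")
  rates <- c(cfg$upstream_ttract_rate_memory,
             cfg$upstream_ttract_rate_responsive)
  if (any(rates < 0 | rates > 1)) stop("T-tract rates must lie in [0, 1]")
  if (cfg$chip_enrichment_wt < 1 || cfg$chip_enrichment_ts < 1) {
    stop("chip_enrichment must be >= 1")
  }
  if (cfg$ttract_region[1] >= cfg$ttract_region[2]) {
    stop("ttract_region must be a non-empty half-open interval")
  }
  if (cfg$ttract_region[1] < -sim_promoter_flank() ||
      cfg$ttract_region[2] > sim_promoter_flank()) {
    stop("ttract_region must lie within the simulated promoter span (+/-",
         sim_promoter_flank(), " bp)")
  }
  invisible(cfg)
}

## Promoter span the generator guarantees free of neighboring genes, each
## side of the motif center.
sim_promoter_flank <- function() 600L

## Fixed seed offsets: one RNG stream per simulated object, so adding one
## simulation never perturbs another.
sim_seed <- function(cfg, stream) {
  offs <- c(genome = 1L, tags_wt = 2L, tags_ts = 3L, expression = 4L,
            metrics = 5L)
  (cfg$seed + offs[[stream]]) %% .Machine$integer.max
}

rand_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

revcomp_chr <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

#' Generate a toy genome with planted motif sites and class-dependent
#' T-tracts
#'
#' Background bases are i.i.d. uniform over `{A,C,G,T}`. One motif is planted
#' per gene at a recorded stranded position, genes spaced so their promoter
#' flanks never overlap. Memory-class promoters then receive extra T-tract
#' insertions (runs of 5-8 T on the coding strand, replacing background bases
#' in place so coordinates stay fixed) in the configured upstream region at
#' the memory rate; responsive promoters at the responsive rate. Tracts never
#' overwrite the motif.
#'
#' @param config A [sim_config()].
#' @return A list: `genome` (named `DNAStringSet`) and `sites` (`GRanges`
#'   with `gene_id`, `class_label`).
#' @export
generate_genome <- function(config) {
  validate_sim_config(config)
  set.seed(sim_seed(config, "genome"))
  flank <- sim_promoter_flank()
  spacing <- 2L * flank + 100L
  margin <- flank + 50L
  n_genes <- 2L * config$n_genes_per_class
  per_chrom <- max(0L, (config$chrom_length - 2L * margin) %/% spacing + 1L)
  if (config$chrom_length < 2L * margin) per_chrom <- 0L
  if (n_genes > 0L && per_chrom * config$n_chroms < n_genes) {
    stop("cannot place ", n_genes, " genes with non-overlapping +/-", flank,
         " bp promoter flanks: ", config$n_chroms, " x ",
         config$chrom_length, " bp holds at most ",
         per_chrom * config$n_chroms, " genes (spacing ", spacing, " bp)")
  }
  chrom_names <- sprintf("chr%s", utils::as.roman(seq_len(config$n_chroms)))
  seqs <- vapply(chrom_names, function(x) rand_dna(config$chrom_length), "")

  if (n_genes == 0L) {
    genome <- Biostrings::DNAStringSet(seqs)
    names(genome) <- chrom_names
    return(list(genome = genome, sites = GenomicRanges::GRanges(
      seqnames = character(), ranges = IRanges::IRanges(), strand = character(),
      gene_id = character(), class_label = character())))
  }

  classes <- sample(rep(c("memory", "responsive"),
                        each = config$n_genes_per_class))
  strands <- sample(c("+", "-"), n_genes, replace = TRUE)
  # spread genes over chromosomes in order
  slot_chrom <- rep(seq_len(config$n_chroms),
                    each = per_chrom)[seq_len(n_genes)]
  slot_idx <- unlist(lapply(seq_len(config$n_chroms),
                            function(i) seq_len(sum(slot_chrom == i))))
  centers1 <- margin + (slot_idx - 1L) * spacing + 1L  # 1-based motif centers

  L <- nchar(config$motif)
  half_lo <- floor(L / 2)  # center sits at motif index half_lo + 1
  chars_by_chrom <- lapply(seqs, function(s) strsplit(s, "", fixed = TRUE)[[1]])
  names(chars_by_chrom) <- chrom_names
  reg <- config$ttract_region
  region_off <- seq.int(reg[1], reg[2] - 1L)

  for (g in seq_len(n_genes)) {
    ch <- chrom_names[slot_chrom[g]]
    c1 <- centers1[g]
    motif_g <- if (strands[g] == "+") config$motif else revcomp_chr(config$motif)
    m_start <- c1 - half_lo
    chars_by_chrom[[ch]][m_start:(m_start + L - 1L)] <-
      strsplit(motif_g, "", fixed = TRUE)[[1]]
    rate <- if (classes[g] == "memory") config$upstream_ttract_rate_memory
            else config$upstream_ttract_rate_responsive
    if (rate > 0) {
      hit <- region_off[stats::runif(length(region_off)) < rate]
      for (off in hit) {
        run_len <- sample(5:8, 1L)
        gene_off <- seq.int(off, off + run_len - 1L)
        gene_off <- gene_off[gene_off < reg[2]]  # stay inside the region
        if (strands[g] == "+") {
          pos <- c1 + gene_off
          chars_by_chrom[[ch]][pos] <- "T"
        } else {
          pos <- c1 - gene_off
          chars_by_chrom[[ch]][pos] <- "A"  # coding-strand T
        }
      }
    }
  }

  genome <- Biostrings::DNAStringSet(vapply(chars_by_chrom, paste, "",
                                            collapse = ""))
  names(genome) <- chrom_names
  # site start so that start0 + floor(L/2) = center0, i.e. start1 = c1 - half_lo
  sites <- GenomicRanges::GRanges(
    seqnames = chrom_names[slot_chrom],
    ranges = IRanges::IRanges(start = centers1 - half_lo, width = L),
    strand = strands)
  S4Vectors::mcols(sites)$gene_id <- sprintf("g%03d", seq_len(n_genes))
  S4Vectors::mcols(sites)$class_label <- classes
  list(genome = genome, sites = sites)
}

#' Simulate single-end ChIP tags with motif-centered enrichment
#'
#' Tag 5' positions are drawn from a mixture of a uniform genomic background
#' and a motif-centered component: `+` tags at `center - fragment_offset`,
#' `-` tags at `center + fragment_offset`, both with Normal jitter rounded to
#' integers and clipped at chromosome ends. The mixture weight is solved so
#' the expected coverage of 120-bp-extended tags at motif centers, divided by
#' the genomic mean, is approximately `enrichment`; `enrichment = 1` gives a
#' pure uniform background.
#'
#' @param genome Named `DNAStringSet` or named character vector.
#' @param sites `GRanges` of motif sites (may be empty).
#' @param enrichment Fold enrichment at motif centers; must be >= 1.
#' @param n_tags Number of tags (0 allowed).
#' @param fragment_offset 5' displacement from the motif center in bp.
#' @param seed RNG seed for this tag set.
#' @param jitter_sd SD of positional jitter in bp (default 20).
#' @param extend_length Extension used downstream, for the weight
#'   calculation (default 120).
#' @return `GRanges` of width-1 tag 5' positions with strand.
#' @export
simulate_chip_tags <- function(genome, sites, enrichment, n_tags,
                               fragment_offset = 60L, seed = 1L,
                               jitter_sd = 20, extend_length = 120L) {
  if (enrichment < 1) stop("enrichment must be >= 1")
  lens <- chrom_lengths(genome)
  G <- sum(lens)
  set.seed(seed)
  empty <- GenomicRanges::GRanges(seqnames = character(),
                                  ranges = IRanges::IRanges(),
                                  strand = character())
  if (n_tags == 0L) return(empty)
  n_sites <- length(sites)
  w <- 0
  if (enrichment > 1 && n_sites > 0L) {
    # coverage at a center: background (1-w)*m + motif w*n_tags/n_sites,
    # with m = extend_length*n_tags/G; solve for weight giving E*m total.
    w <- (enrichment - 1) * extend_length * n_sites /
      (G - extend_length * n_sites)
    if (w < 0 || w > 1) {
      stop("requested enrichment ", enrichment,
           " not achievable with ", n_sites, " sites on a ", G, " bp genome")
    }
  }
  is_motif <- stats::runif(n_tags) < w
  n_bg <- sum(!is_motif)
  n_mt <- sum(is_motif)
  chrom <- character(n_tags)
  pos0 <- integer(n_tags)
  strand <- sample(c("+", "-"), n_tags, replace = TRUE)
  if (n_bg > 0L) {
    bg_chrom <- sample(names(lens), n_bg, replace = TRUE, prob = lens / G)
    bg_pos0 <- floor(stats::runif(n_bg) * lens[bg_chrom])
    chrom[!is_motif] <- bg_chrom
    pos0[!is_motif] <- as.integer(bg_pos0)
  }
  if (n_mt > 0L) {
    si <- sample.int(n_sites, n_mt, replace = TRUE)
    centers0 <- site_centers0(sites)[si]
    mt_chrom <- as.character(GenomicRanges::seqnames(sites))[si]
    jitter <- round(stats::rnorm(n_mt, 0, jitter_sd))
    mt_pos0 <- ifelse(strand[is_motif] == "+",
                      centers0 - fragment_offset,
                      centers0 + fragment_offset) + jitter
    mt_pos0 <- pmin(pmax(mt_pos0, 0L), lens[mt_chrom] - 1L)
    chrom[is_motif] <- mt_chrom
    pos0[is_motif] <- as.integer(mt_pos0)
  }
  GenomicRanges::GRanges(seqnames = chrom,
                         ranges = IRanges::IRanges(start = pos0 + 1L,
                                                   width = 1L),
                         strand = strand)
}

#' Simulate per-gene expression changes and noise metrics
#'
#' Responsive genes draw log2 fold changes from
#' `Normal(log2fc_mean_responsive, log2fc_sd)`, memory genes from
#' `Normal(log2fc_mean_memory, log2fc_sd)`. Because the classes are defined
#' by the expression thresholds (>= 1.5-fold decrease for responsive,
#' `|log2fc| < 0.2` for memory), draws are truncated to the class-defining
#' region: a planted memory gene with `|log2fc| >= 0.2` would not be a
#' memory gene. Noise values come from
#' `Normal(noise_mean_by_class[class], noise_sd)`.
#'
#' @param sites `GRanges` with `gene_id`, `class_label`.
#' @param config A [sim_config()].
#' @return List of two data.frames: `expression` (`gene_id`, `log2fc`) and
#'   `metrics` (`gene_id`, `noise`).
#' @export
simulate_expression_and_metrics <- function(sites, config) {
  validate_sim_config(config)
  gid <- S4Vectors::mcols(sites)$gene_id
  cls <- S4Vectors::mcols(sites)$class_label
  set.seed(sim_seed(config, "expression"))
  mu_fc <- ifelse(cls == "responsive", config$log2fc_mean_responsive,
                  config$log2fc_mean_memory)
  fc <- stats::rnorm(length(gid), mu_fc, config$log2fc_sd)
  # classes are defined by the expression thresholds, so draws are truncated
  # to the class-defining region (rejection resampling)
  if (config$log2fc_sd > 0) {
    ok <- function(x) ifelse(cls == "responsive", x <= -log2(1.5),
                             abs(x) < 0.2)
    for (iter in 1:100) {
      bad <- which(!ok(fc))
      if (!length(bad)) break
      fc[bad] <- stats::rnorm(length(bad), mu_fc[bad], config$log2fc_sd)
    }
    if (any(!ok(fc))) stop("log2fc parameters incompatible with class definitions")
  }
  expression <- data.frame(gene_id = gid, log2fc = fc)
  set.seed(sim_seed(config, "metrics"))
  mu_noise <- config$noise_mean_by_class[cls]
  metrics <- data.frame(gene_id = gid,
                        noise = stats::rnorm(length(gid), mu_noise,
                                             config$noise_sd))
  list(expression = expression, metrics = metrics)
}

#' Sequence-derived nucleosome occupancy stand-in
#'
#' Per-base occupancy is `plogis(a - b * f)` where `f` is the local dA/dT
#' 7-mer frequency in a 150-bp window ([at_tract_window_freq()]; truncated
#' windows at chromosome ends use their own valid-start denominator), so
#' T-tract-rich promoters get low occupancy. Values lie strictly in (0, 1).
#' This is a deliberately simple synthetic stand-in for measured or
#' model-predicted occupancy tracks, not a nucleosome model.
#'
#' @param genome Named `DNAStringSet` or named character vector.
#' @param a,b Logistic intercept and slope (defaults 2 and 8).
#' @param window Window width in bp (default 150).
#' @return Named list of per-bp numeric occupancy vectors (a plain track,
#'   usable wherever a `CoverageTrack`-like object is accepted).
#' @export
simulate_occupancy <- function(genome, a = 2, b = 8, window = 150L) {
  genome <- as_genome(genome)
  half <- window %/% 2L
  out <- lapply(stats::setNames(names(genome), names(genome)), function(ch) {
    s <- as.character(genome[[ch]])
    L <- nchar(s)
    ind <- tract_indicators(s)
    comb <- ind$A | ind$T
    cs <- c(0, cumsum(comb))
    x <- seq_len(L)
    lo <- pmax(x - half, 1L)
    hi <- pmin(x + half - 7L, L - 6L)
    n_starts <- pmax(hi - lo + 1L, 0L)
    cnt <- ifelse(n_starts > 0L, cs[hi + 1L] - cs[lo], 0)
    f <- ifelse(n_starts > 0L, cnt / n_starts, 0)
    stats::plogis(a - b * f)
  })
  out
}

#' Simulate a complete synthetic study
#'
#' Runs [generate_genome()], [simulate_chip_tags()] for the wild-type and ts
#' conditions, [simulate_expression_and_metrics()], and
#' [simulate_occupancy()], each on its own RNG stream derived from the master
#' seed. Identical configs (including seed) give bitwise-identical output.
#'
#' @param config A [sim_config()].
#' @return A `sim_output` list: `genome`, `sites`, `tags` (list `wt`, `ts`),
#'   `expression`, `metrics`, `occupancy`, `config`.
#' @export
simulate_dataset <- function(config) {
  validate_sim_config(config)
  gen <- generate_genome(config)
  tags <- list(
    wt = simulate_chip_tags(gen$genome, gen$sites,
                            enrichment = config$chip_enrichment_wt,
                            n_tags = config$n_tags,
                            fragment_offset = config$fragment_offset,
                            seed = sim_seed(config, "tags_wt"),
                            jitter_sd = config$tag_jitter_sd),
    ts = simulate_chip_tags(gen$genome, gen$sites,
                            enrichment = config$chip_enrichment_ts,
                            n_tags = config$n_tags,
                            fragment_offset = config$fragment_offset,
                            seed = sim_seed(config, "tags_ts"),
                            jitter_sd = config$tag_jitter_sd))
  em <- simulate_expression_and_metrics(gen$sites, config)
  occ <- simulate_occupancy(gen$genome)
  structure(list(genome = gen$genome, sites = gen$sites, tags = tags,
                 expression = em$expression, metrics = em$metrics,
                 occupancy = occ, config = config),
            class = "sim_output")
}

#' Write a simulated study to disk
#'
#' Emits `genome.fa` (60-column FASTA), `sites.bed` (BED6, name =
#' `geneid|class`), `tags_wt.bed` / `tags_ts.bed` (BED6 of extended-ready 5'
#' positions, score 0), `expression.tsv`, `metrics.tsv`, and
#' `occupancy.tsv` (chrom, pos0, value).
#'
#' @param sim A `sim_output` from [simulate_dataset()].
#' @param dir Output directory (created if needed).
#' @param write_occupancy Write the (large) per-bp occupancy track
#'   (default FALSE).
#' @return Named character vector of written paths, invisibly.
#' @export
write_sim_output <- function(sim, dir, write_occupancy = FALSE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(genome = file.path(dir, "genome.fa"),
             sites = file.path(dir, "sites.bed"),
             tags_wt = file.path(dir, "tags_wt.bed"),
             tags_ts = file.path(dir, "tags_ts.bed"),
             expression = file.path(dir, "expression.tsv"),
             metrics = file.path(dir, "metrics.tsv"))
  write_fasta(sim$genome, paths["genome"])
  write_bed(sim$sites, paths["sites"], kind = "site")
  write_bed(sim$tags$wt, paths["tags_wt"], kind = "tag")
  write_bed(sim$tags$ts, paths["tags_ts"], kind = "tag")
  write_table_strict(sim$expression, paths["expression"])
  write_table_strict(sim$metrics, paths["metrics"])
  if (write_occupancy) {
    paths <- c(paths, occupancy = file.path(dir, "occupancy.tsv"))
    write_track(sim$occupancy, paths["occupancy"])
  }
  invisible(paths)
}

#' Simulate an orthologous motif-site set for conservation calling
#'
#' Reference sites are the consensus with `k` substitutions, `k` drawn from
#' `mismatch_probs` over `{0, 1, 2}`; substituted bases are uniform over the
#' three alternatives. Each non-reference species then mutates every base of
#' its ortholog independently with probability `rate` (to a uniformly random
#' different base). With the equal-alternative PWM of
#' [pwm_from_consensus()], all single-substitution penalties share one value
#' `d`, so reference scores form a lattice. The default two-level mix
#' (`k` in `{0, 1}`, probs 0.6/0.4) keeps every reference score within two
#' reference SDs of the motif average whenever at least 20% of sites carry a
#' mismatch — a binomial tail below 1e-4 at 80 sites — so at `rate = 0` the
#' conserved fraction is 1.
#'
#' @param n_sites Number of orthologous site groups.
#' @param consensus Motif consensus string.
#' @param n_species Number of non-reference species.
#' @param rate Per-bp mutation probability in each non-reference species.
#' @param mismatch_probs Probabilities of 0, 1, 2 reference mismatches
#'   (default `c(0.6, 0.4, 0)`).
#' @param seed RNG seed.
#' @return List with `ref` (character vector named by gene id) and `species`
#'   (named list of character vectors).
#' @export
simulate_ortholog_sites <- function(n_sites, consensus = default_motif(),
                                    n_species = 4L, rate = 0,
                                    mismatch_probs = c(0.6, 0.4, 0),
                                    seed = 1L) {
  stopifnot(n_sites >= 2L, rate >= 0, rate <= 1)
  set.seed(seed)
  bases <- c("A", "C", "G", "T")
  cons <- strsplit(toupper(consensus), "", fixed = TRUE)[[1]]
  L <- length(cons)
  ref <- vapply(seq_len(n_sites), function(i) {
    k <- sample(0:2, 1L, prob = mismatch_probs)
    s <- cons
    if (k > 0L) {
      pos <- sample.int(L, k)
      s[pos] <- vapply(s[pos], function(b) sample(setdiff(bases, b), 1L), "")
    }
    paste(s, collapse = "")
  }, "")
  names(ref) <- sprintf("g%03d", seq_len(n_sites))
  species <- lapply(stats::setNames(
    sprintf("species_%d", seq_len(n_species)),
    sprintf("species_%d", seq_len(n_species))), function(sp) {
      stats::setNames(mutate_sequences(ref, rate), names(ref))
    })
  list(ref = ref, species = species)
}

#' Mutate sequences with a per-base substitution rate
#'
#' Each base mutates independently with probability `rate` to a uniformly
#' random different base. Uses the current RNG stream.
#'
#' @param seqs Character vector of DNA strings.
#' @param rate Per-bp substitution probability.
#' @return Character vector of mutated sequences.
#' @export
mutate_sequences <- function(seqs, rate) {
  stopifnot(rate >= 0, rate <= 1)
  if (rate == 0) return(seqs)
  bases <- c("A", "C", "G", "T")
  vapply(seqs, function(s) {
    ch <- strsplit(toupper(s), "", fixed = TRUE)[[1]]
    hit <- which(stats::runif(length(ch)) < rate)
    if (length(hit)) {
      ch[hit] <- vapply(ch[hit], function(b) sample(setdiff(bases, b), 1L), "")
    }
    paste(ch, collapse = "")
  }, "", USE.NAMES = FALSE)
}
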