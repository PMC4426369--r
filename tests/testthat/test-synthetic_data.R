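test_that("config validation catches impossible or malformed settings", {
  expect_error(sim_config(chip_enrichment_wt = 0.5), ">= 1")
  expect_error(sim_config(upstream_ttract_rate_memory = 1.2), "rates")
  expect_error(sim_config(ttract_region = c(-20, -200)), "half-open")
  expect_error(sim_config(ttract_region = c(-2000, -20)), "promoter span")
  expect_error(sim_config(motif = "ACGTX"), "motif")
  # density too high for non-overlapping flanks names the constraint
  cfg <- sim_config(n_chroms = 1L, chrom_length = 5000L,
                    n_genes_per_class = 50L)
  expect_error(generate_genome(cfg), "non-overlapping")
})

test_that("genome generation is deterministic and plants exact motifs", {
  cfg <- tiny_config(seed = 3)
  g1 <- generate_genome(cfg)
  g2 <- generate_genome(cfg)
  expect_identical(as.character(g1$genome), as.character(g2$genome))
  expect_identical(g1$sites, g2$sites)
  # FASTA bytes identical too
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_fasta(g1$genome, f1); write_fasta(g2$genome, f2)
  expect_identical(readLines(f1), readLines(f2))
  # every site carries the planted consensus on the gene strand
  seqs <- site_sequences(g1$genome, g1$sites)
  expect_true(all(seqs == cfg$motif))
  expect_equal(length(g1$sites), 2L * cfg$n_genes_per_class)
  # empty case
  g0 <- generate_genome(tiny_config(n_genes_per_class = 0L))
  expect_equal(length(g0$sites), 0L)
})

test_that("memory promoters carry denser upstream dA/dT than responsive ones", {
  cfg <- sim_config(n_chroms = 1L, chrom_length = 80000L,
                    n_genes_per_class = 20L, seed = 13)
  gen <- generate_genome(cfg)
  cls <- S4Vectors::mcols(gen$sites)$class_label
  # recompute frequencies with the windowed statistic and compare class means
  m <- memorychrom:::site_at_freq_matrix(gen$genome, gen$sites, flank = 300L)
  up <- m$offsets >= -200 & m$offsets < -20
  per_gene <- rowMeans(m$matrix[, up], na.rm = TRUE)
  expect_gt(mean(per_gene[cls == "memory"]),
            mean(per_gene[cls == "responsive"]))
})

test_that("ChIP tags are uniform at enrichment 1 and enriched above it", {
  cfg <- tiny_config(seed = 19)
  gen <- generate_genome(cfg)
  # enrichment 1: KS against uniform should rarely reject at alpha = 0.01
  pvals <- vapply(1:10, function(s) {
    tags <- simulate_chip_tags(gen$genome, gen$sites, enrichment = 1,
                               n_tags = 2000L, seed = s)
    pos <- GenomicRanges::start(tags) - 1 + runif(length(tags))  # de-tie
    suppressWarnings(ks.test(pos / cfg$chrom_length, "punif")$p.value)
  }, 0)
  expect_lte(sum(pvals < 0.01), 2L)
  # empty site list falls back to pure background
  tags0 <- simulate_chip_tags(gen$genome, gen$sites[0], enrichment = 5,
                              n_tags = 100L, seed = 1)
  expect_equal(length(tags0), 100L)
  expect_equal(length(simulate_chip_tags(gen$genome, gen$sites, 5, 0L)), 0L)
  expect_error(simulate_chip_tags(gen$genome, gen$sites, 0.5, 100L), ">= 1")
})

test_that("simulated enrichment puts the meta-profile peak at the motif", {
  cfg <- sim_config(n_chroms = 1L, chrom_length = 100000L,
                    n_genes_per_class = 12L, seed = 23)
  gen <- generate_genome(cfg)
  tags <- simulate_chip_tags(gen$genome, gen$sites, enrichment = 5,
                             n_tags = 50000L, seed = 99)
  z <- normalize_zscore(coverage_track(tags, gen$genome))
  p <- motif_centered_profile(z, gen$sites)
  expect_lte(abs(p$offset[which.max(p$mean)]), 10)
})

test_that("expression and metrics are deterministic, class-shifted, and label-consistent", {
  cfg <- tiny_config(seed = 29)
  gen <- generate_genome(cfg)
  em1 <- simulate_expression_and_metrics(gen$sites, cfg)
  em2 <- simulate_expression_and_metrics(gen$sites, cfg)
  expect_identical(em1, em2)
  cls <- S4Vectors::mcols(gen$sites)$class_label
  expect_lt(mean(em1$expression$log2fc[cls == "responsive"]), -0.58)
  expect_lt(max(abs(em1$expression$log2fc[cls == "memory"])), 0.2)
  expect_lt(mean(em1$metrics$noise[cls == "memory"]),
            mean(em1$metrics$noise[cls == "responsive"]))
  # sd = 0 collapses each class to its mean exactly
  cfg0 <- tiny_config(seed = 29, log2fc_sd = 0)
  em0 <- simulate_expression_and_metrics(gen$sites, cfg0)
  expect_true(all(em0$expression$log2fc[cls == "responsive"] == -1))
  expect_true(all(em0$expression$log2fc[cls == "memory"] == 0))
})

test_that("occupancy is a logistic map of local dA/dT density", {
  occ_t <- simulate_occupancy(c(cT = strrep("T", 400)))
  occ_gc <- simulate_occupancy(c(cGC = strrep("GC", 200)))
  expect_true(all(occ_t$cT < 0.02))          # saturated tract: minimal
  expect_equal(unique(occ_gc$cGC), plogis(2)) # no tracts: maximal
  expect_true(all(occ_t$cT > 0 & occ_t$cT < 1))
  # memory-class upstream occupancy sits below responsive-class upstream
  cfg <- sim_config(n_chroms = 1L, chrom_length = 80000L,
                    n_genes_per_class = 15L, seed = 31)
  gen <- generate_genome(cfg)
  occ <- simulate_occupancy(gen$genome)
  cls <- S4Vectors::mcols(gen$sites)$class_label
  up <- function(p) mean(p$mean[p$offset >= -200 & p$offset < -20])
  p_mem <- motif_centered_profile(occ, gen$sites[cls == "memory"])
  p_res <- motif_centered_profile(occ, gen$sites[cls == "responsive"])
  expect_lt(up(p_mem), up(p_res))
})

test_that("whole simulated studies are bitwise reproducible from the seed", {
  cfg <- tiny_config(seed = 37)
  s1 <- simulate_dataset(cfg)
  s2 <- simulate_dataset(cfg)
  expect_identical(as.character(s1$genome), as.character(s2$genome))
  expect_identical(s1$tags, s2$tags)
  expect_identical(s1$expression, s2$expression)
  expect_identical(s1$metrics, s2$metrics)
  expect_identical(s1$occupancy, s2$occupancy)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  p1 <- write_sim_output(s1, d1); p2 <- write_sim_output(s2, d2)
  expect_identical(unname(tools::md5sum(p1)), unname(tools::md5sum(p2)))
})

test_that("stronger enrichment raises the profile peak monotonically", {
  cfg <- sim_config(n_chroms = 1L, chrom_length = 60000L,
                    n_genes_per_class = 10L, seed = 41)
  gen <- generate_genome(cfg)
  peak <- function(enr) {
    mean(vapply(1:3, function(s) {
      tags <- simulate_chip_tags(gen$genome, gen$sites, enrichment = enr,
                                 n_tags = 20000L, seed = 100 + s)
      z <- normalize_zscore(coverage_track(tags, gen$genome))
      profile_at(motif_centered_profile(z, gen$sites), 0)
    }, 0))
  }
  peaks <- vapply(c(1, 3, 9), peak, 0)
  expect_true(all(diff(peaks) > 0))
})
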