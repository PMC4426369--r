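test_that("dA/dT tract calls match a letter-count oracle on all 16384 7-mers", {
  kmers <- all_7mers()
  got <- is_at_tract(kmers)
  oracle <- vapply(strsplit(kmers, "", fixed = TRUE), function(ch) {
    sum(ch == "A") >= 6L || sum(ch == "T") >= 6L
  }, NA)
  expect_identical(got, oracle)
  expect_true(is_at_tract("AAAAAAA"))
  expect_true(is_at_tract("TTTTTTG"))
  expect_false(is_at_tract("AAATTTA"))  # 4 A + 3 T: neither base reaches 6
  expect_true(is_at_tract("NAAAAAA"))   # N is neither A nor T, but 6 A's suffice
  expect_false(is_at_tract("NNAAAAA"))  # 5 A's: N never counts toward a tract
  expect_error(is_at_tract("AAAA"), "7-bp")
})

test_that("windowed tract frequency matches brute-force 7-mer enumeration", {
  set.seed(17)
  for (i in 1:6) {
    s <- random_dna(1000)
    expect_equal(at_tract_window_freq(s), brute_at_freq(s), tolerance = 1e-12)
  }
  # saturating cases
  expect_equal(at_tract_window_freq(strrep("A", 150))[76], 1.0)
  expect_true(all(at_tract_window_freq(strrep("GC", 200)) %in% c(0, NA)))
  expect_error(at_tract_window_freq(random_dna(100)), "shorter")
})

test_that("frequency arrays are translation-equivariant and bounded", {
  set.seed(19)
  s <- random_dna(600)
  shift <- 37L
  padded <- paste0(random_dna(shift), s)
  f1 <- at_tract_window_freq(s)
  f2 <- at_tract_window_freq(padded)
  # interior values shift with the sequence
  idx <- 200:400
  expect_equal(f2[idx + shift], f1[idx], tolerance = 1e-12)
  expect_true(all(f1 >= 0 & f1 <= 1, na.rm = TRUE))
})

test_that("A/T tract decomposition is disjoint, additive, and strand-mirrored", {
  expect_equal(tract_decomposition(strrep("T", 200))$T[100], 1.0)
  expect_equal(tract_decomposition(strrep("T", 200))$A[100], 0.0)
  set.seed(23)
  s <- paste0(random_dna(200), strrep("T", 30), random_dna(200))
  dec <- tract_decomposition(s)
  comb <- at_tract_window_freq(s)
  expect_equal(dec$A + dec$T, comb, tolerance = 1e-12)
  # reverse complement swaps tract identity and mirrors positions; the even
  # window makes the mirrored grid land one base off (window [x-75, x+74])
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  dec_rc <- tract_decomposition(rc)
  L <- nchar(s)
  expect_equal(dec_rc$A[-1], rev(dec$T)[-L], tolerance = 1e-12)
  expect_equal(dec_rc$T[-1], rev(dec$A)[-L], tolerance = 1e-12)
})

test_that("class-averaged profiles separate planted upstream T-tract classes", {
  cfg <- sim_config(n_chroms = 1L, chrom_length = 60000L,
                    n_genes_per_class = 15L, seed = 41)
  gen <- generate_genome(cfg)
  prof <- class_average_at_profile(gen$genome, gen$sites, flank = 300L)
  up <- prof$offset >= -200 & prof$offset < -20
  dn <- prof$offset >= 20 & prof$offset < 200
  mem_up <- mean(prof$mean[up & prof$class_label == "memory"])
  res_up <- mean(prof$mean[up & prof$class_label == "responsive"])
  mem_dn <- mean(prof$mean[dn & prof$class_label == "memory"])
  res_dn <- mean(prof$mean[dn & prof$class_label == "responsive"])
  expect_gt(mem_up, res_up)
  expect_lt(abs(mem_dn - res_dn), 0.05)
})

test_that("single-gene classes return that gene's own frequency array", {
  cfg <- sim_config(n_chroms = 1L, chrom_length = 20000L,
                    n_genes_per_class = 1L, seed = 43)
  gen <- generate_genome(cfg)
  prof <- class_average_at_profile(gen$genome, gen$sites, flank = 200L)
  for (i in seq_along(gen$sites)) {
    cl <- S4Vectors::mcols(gen$sites)$class_label[i]
    fs <- memorychrom:::site_flank_sequence(gen$genome, gen$sites[i],
                                            flank = 200L, half = 75L)
    freq <- at_tract_window_freq(fs$seq)
    sub <- prof[prof$class_label == cl, ]
    expect_equal(sub$mean, freq[200 + 75 + 1 + sub$offset], tolerance = 1e-12)
  }
  # identical sequences in both classes give identical curves
  sites2 <- gen$sites
  S4Vectors::mcols(sites2)$class_label <- c("memory", "responsive")
  sites3 <- sites2
  GenomicRanges::ranges(sites3) <- rep(GenomicRanges::ranges(sites2)[1], 2)
  GenomicRanges::strand(sites3) <- rep(GenomicRanges::strand(sites2)[1], 2)
  prof2 <- class_average_at_profile(gen$genome, sites3, flank = 200L)
  wide <- split(prof2$mean, prof2$class_label)
  expect_equal(wide$memory, wide$responsive)
})

test_that("cross-species profiles are independent per species", {
  cfg <- sim_config(n_chroms = 1L, chrom_length = 40000L,
                    n_genes_per_class = 8L, seed = 47)
  gen <- generate_genome(cfg)
  sp <- list(ref = list(genome = gen$genome, sites = gen$sites),
             dup = list(genome = gen$genome, sites = gen$sites))
  profs <- cross_species_profiles(sp, flank = 200L)
  expect_named(profs, c("ref", "dup"))
  expect_equal(profs$ref$mean, profs$dup$mean)
  sp$dup$sites <- gen$sites[0]
  expect_error(cross_species_profiles(sp, flank = 200L), "dup")
})

test_that("PWM log-odds scoring: argmax construction wins an exhaustive search", {
  set.seed(29)
  m <- matrix(runif(6 * 4), ncol = 4)
  m <- m / rowSums(m)
  p <- pwm(m)
  bases <- c("A", "C", "G", "T")
  best_seq <- paste(bases[max.col(p$mat)], collapse = "")
  grid <- expand.grid(rep(list(bases), 6), stringsAsFactors = FALSE)
  all_seqs <- apply(grid, 1, paste, collapse = "")
  scores <- pwm_score(all_seqs, p)
  expect_equal(all_seqs[which.max(scores)], best_seq)
  # uniform PWM equal to background scores 0 for any sequence
  u <- pwm(matrix(0.25, nrow = 6, ncol = 4), pseudo = 0)
  expect_equal(pwm_score(c("ACGTAC", "TTTTTT"), u), c(0, 0))
  expect_error(pwm_score("ACGT", p), "length mismatch")
})

test_that("PWM files round-trip and site extraction respects strand", {
  f <- withr::local_tempfile(fileext = ".tsv")
  p <- pwm_from_consensus("ACGTT", p = 0.8)
  write_pwm(p, f)
  p2 <- read_pwm(f, pseudo = 0)
  expect_equal(p2$mat, p$mat, tolerance = 1e-9)
  expect_true(all(abs(rowSums(p2$mat) - 1) < 1e-9))

  genome <- c(c1 = "AAAACGTTAAAAAA")
  site_p <- granges_sites("c1", 4L, 5L, "+")
  site_m <- granges_sites("c1", 4L, 5L, "-")
  expect_equal(unname(site_sequences(genome, site_p)), "ACGTT")
  expect_equal(unname(site_sequences(genome, site_m)), "AACGT")
  expect_equal(pwm_score(site_sequences(genome, site_p), p),
               max(pwm_score(site_sequences(genome, site_p), p)))
})

test_that("conservation calls apply the two-SD band on reference scores", {
  p <- pwm_from_consensus(default_motif())
  os <- simulate_ortholog_sites(40, rate = 0, seed = 5)
  ref <- pwm_score(os$ref, p)
  sp <- data.frame(gene_id = names(os$ref),
                   lapply(os$species, function(s) pwm_score(s, p)))
  cc <- call_conserved(ref, sp)
  expect_true(all(cc$conserved))  # identical orthologs are all conserved
  # a site dropped 3 SDs below the mean is not conserved
  sp2 <- sp
  sp2$species_1[1] <- mean(ref) - 3 * sd(ref)
  cc2 <- call_conserved(ref, sp2)
  expect_false(cc2$conserved[1])
  expect_true(all(cc2$conserved[-1]))
  expect_error(call_conserved(rep(1.5, 10), sp), "zero sd")
})

test_that("conserved fraction decreases with the ortholog mutation rate", {
  p <- pwm_from_consensus(default_motif())
  fracs <- vapply(c(0, 0.1, 0.5), function(rate) {
    mean(vapply(1:3, function(s) {
      os <- simulate_ortholog_sites(40, rate = rate, seed = s)
      sp <- data.frame(gene_id = names(os$ref),
                       lapply(os$species, function(x) pwm_score(x, p)))
      mean(call_conserved(pwm_score(os$ref, p), sp)$conserved)
    }, 0))
  }, 0)
  expect_equal(fracs[1], 1.0)
  expect_true(all(diff(fracs) <= 0))
  expect_lt(fracs[3], 0.1)
})
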