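test_that("a unit impulse at the motif center peaks in the offset-0 bin", {
  track <- list(c1 = rep(0, 2000))
  site <- granges_sites("c1", 994L, 14L, "+")  # center0 = 993+7 = 1000
  track$c1[1001] <- 1  # 0-based position 1000
  p <- motif_centered_profile(track, site, flank = 100L, bin = 10L)
  expect_equal(p$offset[which.max(p$mean)], 0)
  expect_true(all(p$mean[p$offset != 0] == 0))
})

test_that("minus-strand sites mirror into gene orientation", {
  # signal 20 bp 5' of the motif in gene orientation:
  # "+" gene: genomic center - 20; "-" gene: genomic center + 20
  track_p <- list(c1 = rep(0, 2000)); track_p$c1[1001 - 20] <- 1
  track_m <- list(c1 = rep(0, 2000)); track_m$c1[1001 + 20] <- 1
  site_p <- granges_sites("c1", 994L, 14L, "+")
  site_m <- granges_sites("c1", 994L, 14L, "-")
  pp <- motif_centered_profile(track_p, site_p, flank = 100L)
  pm <- motif_centered_profile(track_m, site_m, flank = 100L)
  expect_equal(pp$offset[which.max(pp$mean)], -20)
  expect_equal(pm$mean, pp$mean)
})

test_that("profiles are linear: two sites average the single-site profiles", {
  set.seed(5)
  track <- list(c1 = rnorm(4000))
  s1 <- granges_sites("c1", 1001L, 14L, "+")
  s2 <- granges_sites("c1", 2801L, 14L, "-")
  both <- c(s1, s2)
  p1 <- motif_centered_profile(track, s1, flank = 200L)
  p2 <- motif_centered_profile(track, s2, flank = 200L)
  p12 <- motif_centered_profile(track, both, flank = 200L)
  expect_equal(p12$mean, (p1$mean + p2$mean) / 2, tolerance = 1e-12)
  expect_error(motif_centered_profile(track, both[0], flank = 200L), "empty")
})

test_that("edge-proximal sites contribute only defined offsets", {
  track <- list(c1 = rep(1, 300))
  near_edge <- granges_sites("c1", 21L, 14L, "+")  # center0 = 27
  p <- motif_centered_profile(track, near_edge, flank = 100L)
  expect_true(any(p$n_contributing == 0))
  expect_true(all(is.na(p$mean[p$n_contributing == 0])))
  expect_true(all(p$mean[p$n_contributing > 0] == 1))
})

test_that("masked values do not bias bins (brute-force mean check)", {
  set.seed(9)
  v <- rnorm(3000)
  v[sample.int(3000, 600)] <- NA
  track <- list(c1 = v)
  sites <- granges_sites("c1", c(801L, 1601L, 2201L), 14L, c("+", "+", "+"))
  p <- motif_centered_profile(track, sites, flank = 100L, bin = 10L)
  centers0 <- GenomicRanges::start(sites) - 1L + 7L
  for (k in unique(floor(seq(-100, 99) / 10))) {
    per_site <- vapply(centers0, function(c0) {
      offs <- seq(k * 10, k * 10 + 9)
      mean(v[c0 + offs + 1L], na.rm = TRUE)
    }, 0)
    expected <- mean(per_site[!is.nan(per_site)])
    expect_equal(p$mean[p$offset == k * 10], expected, tolerance = 1e-12)
  }
})

test_that("TSS profile is flat on constant tracks and plateaus on impulses", {
  track <- list(c1 = rep(3.5, 4000))
  tss <- granges_tags("c1", 2000L, "+")
  p <- tss_profile(track, tss, window = 100L, step = 10L, flank = 300L)
  expect_true(all(p$mean == 3.5))

  # impulse at the TSS spreads over ~window around offset 0 (boxcar mean)
  track$c1 <- rep(0, 4000); track$c1[2000] <- 1  # pos0 = 1999 = TSS
  p <- tss_profile(track, tss, window = 100L, step = 10L, flank = 300L)
  # convolution oracle: value at offset x = mean over [x-50, x+49]
  oracle <- vapply(p$offset, function(x) {
    win <- 1999 + seq(x - 50, x + 49)
    mean(track$c1[win + 1L])
  }, 0)
  expect_equal(p$mean, oracle, tolerance = 1e-12)
  expect_true(p$mean[p$offset == 0] > 0)
  expect_true(all(p$mean[abs(p$offset) > 60] == 0))
})

test_that("window=1, step=1 TSS profile matches the unsmoothed bin=1 motif profile", {
  set.seed(13)
  track <- list(c1 = rnorm(3000))
  # width-1 site: motif center = start; same anchor as the TSS
  site <- granges_sites("c1", 1500L, 1L, "+")
  tssp <- tss_profile(track, granges_tags("c1", 1500L, "+"),
                      window = 1L, step = 1L, flank = 100L)
  motp <- motif_centered_profile(track, site, flank = 100L, bin = 1L)
  shared <- intersect(tssp$offset, motp$offset)
  expect_equal(tssp$mean[match(shared, tssp$offset)],
               motp$mean[match(shared, motp$offset)], tolerance = 1e-12)
})

test_that("profile differences subtract elementwise and are antisymmetric", {
  set.seed(21)
  track1 <- list(c1 = rnorm(3000))
  track2 <- list(c1 = rnorm(3000))
  sites <- granges_sites("c1", c(1001L, 2001L), 14L, c("+", "-"))
  a <- motif_centered_profile(track1, sites, flank = 200L)
  b <- motif_centered_profile(track2, sites, flank = 200L)
  d <- profile_delta(a, b)
  expect_equal(d$mean, a$mean - b$mean)
  expect_equal(profile_delta(a, a)$mean, rep(0, nrow(a)))
  zero <- a; zero$mean <- rep(0, nrow(a))
  expect_equal(profile_delta(a, zero)$mean, a$mean)
  d_rev <- profile_delta(b, a)
  expect_equal(d_rev$mean, -d$mean)
  short <- motif_centered_profile(track2, sites, flank = 100L)
  expect_error(profile_delta(a, short), "grid")
})

test_that("reversing strands and mirroring the track mirrors the profile", {
  set.seed(33)
  L <- 3001L
  v <- rnorm(L)
  sites <- granges_sites("c1", c(901L, 1801L), 15L, c("+", "-"))
  p <- motif_centered_profile(list(c1 = v), sites, flank = 150L, bin = 10L)
  # mirror the genome around each center: equivalent construction with
  # flipped strands on the reversed track
  centers0 <- GenomicRanges::start(sites) - 1L + 7L
  mirrored_centers0 <- (L - 1L) - centers0
  flipped <- granges_sites("c1", mirrored_centers0 - 7L + 1L, 15L,
                           c("-", "+"))
  p_flip <- motif_centered_profile(list(c1 = rev(v)), flipped,
                                   flank = 150L, bin = 10L)
  expect_equal(p_flip$mean, p$mean, tolerance = 1e-12)
})
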