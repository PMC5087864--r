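# cna_calling: baseline, deviation rules, segment filter, segmentation.

test_that("baseline excludes configured regions and the X chromosome", {
  probes <- make_probes(c(chr1 = 40L, chr7 = 40L, chrX = 20L))
  pattern <- c(rep(0, 40), rep(5, 40), rep(-3, 20))
  pattern <- pattern + rep(c(0.1, -0.1), 50) # non-degenerate sd
  bl <- compute_baseline(pattern, probes, exclude = "chr7")
  expect_equal(bl$genomic_mean, mean(pattern[1:40]))
  # X never enters the genomic stats even with no exclusions
  bl2 <- compute_baseline(pattern, probes, exclude = character(0))
  expect_equal(bl2$genomic_mean, mean(pattern[1:80]))
  # per-chromosome stats cover all chromosomes, including excluded ones
  expect_setequal(bl$per_chromosome$chrom, c("chr1", "chr7", "chrX"))

  expect_error(compute_baseline(rep(1, 100), probes, exclude = "chr7"),
               "zero")
  expect_error(compute_baseline(pattern[1:10], probes), "length")
})

test_that("toy two-chromosome baseline matches direct arithmetic", {
  probes <- make_probes(c(chr1 = 4L, chr2 = 4L))
  pattern <- c(1, 2, 3, 4, 10, 12, 14, 16)
  bl <- compute_baseline(pattern, probes, exclude = character(0))
  expect_equal(bl$genomic_mean, mean(pattern))
  expect_equal(bl$genomic_std, sd(pattern))
  i2 <- bl$per_chromosome$chrom == "chr2"
  expect_equal(bl$per_chromosome$mean[i2], 13)
  expect_equal(bl$per_chromosome$sd[i2], sd(c(10, 12, 14, 16)))
})

test_that("chromosome/arm calls fire on the strict 2-sigma genomic rule", {
  probes <- make_probes(c(chr1 = 100L, chr2 = 100L))
  set.seed(5)
  noise <- rnorm(200, sd = 1)
  bl <- compute_baseline(noise, probes, exclude = "chr2")
  gm <- bl$genomic_mean; gs <- bl$genomic_std

  shifted <- noise
  shifted[101:200] <- noise[101:200] - mean(noise[101:200]) + gm + 3 * gs
  expect_equal(call_chromosome_or_arm(shifted, probes, bl, "chr2")$direction,
               "gain")
  shifted[101:200] <- noise[101:200] - mean(noise[101:200]) + gm - 1 * gs
  expect_equal(call_chromosome_or_arm(shifted, probes, bl, "chr2")$direction,
               "none")
  # exact boundary -> none (strict inequality)
  shifted[101:200] <- gm - 2 * gs
  expect_equal(call_chromosome_or_arm(shifted, probes, bl, "chr2")$direction,
               "none")
  expect_error(call_chromosome_or_arm(noise, probes, bl, "chr9"),
               "no probes")
})

test_that("segment calls apply the genomic and consistent chromosomal rules", {
  probes <- make_probes(c(chr1 = 200L, chr2 = 200L))
  pattern <- rep(0, 400)
  pattern[1:200] <- rep(c(0.5, -0.5), 100)     # chr1: mean 0, sd ~0.5
  pattern[201:400] <- rep(c(0.25, -0.25), 100) # chr2 baseline chromosome
  bl <- compute_baseline(pattern, probes, exclude = character(0))
  gm <- bl$genomic_mean; gs <- bl$genomic_std
  cs1 <- bl$per_chromosome[bl$per_chromosome$chrom == "chr1", ]

  seg <- function(a, b) list(chrom = "chr1", start = a * 1000L,
                             end = b * 1000L)
  # genomic rule: segment mean at gm + 2.5 gs
  p2 <- pattern
  p2[1:20] <- gm + 2.5 * gs
  out <- call_segment(p2, probes, bl, seg(0, 20))
  expect_equal(out$direction, "gain")
  expect_equal(out$rule, "genomic")

  # chromosomal rule: within 2 gs of genomic mean but > 1 chrom sd above the
  # chromosome mean, with consistent signs
  p3 <- pattern
  p3[1:20] <- cs1$mean + 1.5 * cs1$sd
  stopifnot(abs(p3[1] - gm) < 2 * gs)
  out3 <- call_segment(p3, probes, bl, seg(0, 20))
  expect_equal(out3$rule, "chromosomal")
  expect_equal(out3$direction, "gain")

  # inconsistent signs -> none: above the chromosome mean, below the genomic
  probes_b <- make_probes(c(chr1 = 100L, chr2 = 100L))
  pb <- c(rep(-2, 100), rep(c(1, -1), 50))
  pb[1:10] <- -1.2 # above chr1 mean (-2ish) but below genomic mean
  blb <- compute_baseline(pb, probes_b, exclude = character(0))
  outb <- call_segment(pb, probes_b, blb, list(chrom = "chr1", start = 0L,
                                               end = 10000L))
  if (abs((mean(pb[1:10]) - blb$genomic_mean) / blb$genomic_std) < 2) {
    expect_equal(outb$direction, "none")
  }
  expect_error(call_segment(pattern, probes, bl,
                            list(chrom = "chr1", start = 9e6, end = 9.1e6)),
               "overlaps no probes")
})

test_that("per-probe calls equal the independent rule evaluator", {
  probes <- make_probes(c(chr1 = 60L, chr2 = 60L))
  set.seed(9)
  pattern <- rnorm(120)
  pattern[10:20] <- pattern[10:20] + 3
  bl <- compute_baseline(pattern, probes, exclude = character(0))
  calls <- call_probes(pattern, probes, bl)
  cmeans <- setNames(as.list(bl$per_chromosome$mean), bl$per_chromosome$chrom)
  csds <- setNames(as.list(bl$per_chromosome$sd), bl$per_chromosome$chrom)
  expect_equal(calls$direction,
               oracle_probe_calls(pattern, probes, bl$genomic_mean,
                                  bl$genomic_std, cmeans, csds))
  expect_equal(calls$direction[1], "none") # unshifted probe at the mean
})

test_that("calls are invariant to additive offset and positive scaling", {
  probes <- make_probes(c(chr1 = 80L, chr2 = 80L, chr3 = 80L))
  set.seed(13)
  pattern <- rnorm(240, sd = 0.2)
  pattern[81:160] <- pattern[81:160] + 1 # planted chr2 gain
  run <- function(p) {
    bl <- compute_baseline(p, probes, exclude = "chr2")
    list(chrom = vapply(c("chr1", "chr2", "chr3"), function(ch) {
      call_chromosome_or_arm(p, probes, bl, ch)$direction
    }, ""), probe = call_probes(p, probes, bl)$direction)
  }
  base <- run(pattern)
  expect_equal(base$chrom[["chr2"]], "gain")
  for (tf in list(function(p) p + 5, function(p) 3.7 * p,
                  function(p) 0.01 * p - 2)) {
    out <- run(tf(pattern))
    expect_identical(out$chrom, base$chrom)
    expect_identical(out$probe, base$probe)
  }
})

test_that("planted region shifts are recovered exactly at all levels", {
  # regions with >= 50 probes shifted by > 2.5 noise sd; shifted chromosomes
  # excluded from the baseline as the calling convention prescribes
  probes <- make_probes(c(chr1 = 120L, chr2 = 120L, chr3 = 120L,
                          chr4 = 120L))
  set.seed(31)
  noise_sd <- 0.2
  pattern <- rnorm(480, sd = noise_sd)
  truth <- c(chr1 = "none", chr2 = "gain", chr3 = "loss", chr4 = "none")
  pattern[121:240] <- pattern[121:240] + 3 * noise_sd
  pattern[241:360] <- pattern[241:360] - 3 * noise_sd
  bl <- compute_baseline(pattern, probes, exclude = c("chr2", "chr3"))
  got <- vapply(names(truth), function(ch) {
    call_chromosome_or_arm(pattern, probes, bl, ch)$direction
  }, "")
  expect_identical(got, truth)
  # arm level: both arms of the shifted chromosomes carry the shift
  arms <- c(chr2p = "gain", chr2q = "gain", chr3p = "loss", chr3q = "loss",
            chr1p = "none", chr4q = "none")
  got_arm <- vapply(names(arms), function(a) {
    call_chromosome_or_arm(pattern, probes, bl, a)$direction
  }, "")
  expect_identical(got_arm, arms)
  # segment level: 60-probe segments inside each region
  segs <- data.frame(chrom = c("chr2", "chr3", "chr1"),
                     start = c(30000L, 30000L, 30000L),
                     end = c(90000L, 90000L, 90000L),
                     probe_count = c(60L, 60L, 60L))
  got_seg <- call_segments(pattern, probes, bl, segs)$direction
  expect_identical(got_seg, c("gain", "loss", "none"))
})

test_that("filter_segments applies the probe-count threshold", {
  segs <- data.frame(chrom = "chr1", start = c(0, 10, 20),
                     end = c(5, 15, 25), probe_count = c(3L, 5L, 12L))
  expect_equal(nrow(filter_segments(segs, 5)), 2)
  expect_equal(filter_segments(segs, 1), segs)
  expect_equal(nrow(filter_segments(segs[0, ], 5)), 0)
  expect_error(filter_segments(segs[, 1:3], 5), "probe_count")
})

test_that("segmentation finds planted steps and respects chromosome bounds", {
  probes <- make_probes(c(chr1 = 200L))
  # constant pattern: no change points
  expect_equal(nrow(segment_arraylet(rep(1, 200), probes, seed = 1)), 0)

  # planted step at probe 100
  set.seed(17)
  x <- c(rnorm(100, 0, 0.1), rnorm(100, 1, 0.1))
  cp <- segment_arraylet(x, probes, seed = 2)
  expect_gte(nrow(cp), 1)
  expect_true(any(abs(cp$index_in_chrom - 100) <= 2))

  # two chromosomes, one step inside each, none at the boundary
  probes2 <- make_probes(c(chr1 = 100L, chr2 = 100L))
  y <- c(rnorm(50, 0, 0.1), rnorm(50, 1, 0.1),
         rnorm(60, 0, 0.1), rnorm(40, -1, 0.1))
  cp2 <- segment_arraylet(y, probes2, seed = 3)
  expect_true(any(cp2$chrom == "chr1") && any(cp2$chrom == "chr2"))
  expect_false(any(cp2$index_global == 100)) # chromosome boundary
})
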