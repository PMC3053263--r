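test_that("read shifting moves strands in opposite directions and clips", {
  lens <- c(chrX = 5000L)
  rs <- read_set(list(chrX = list(pos = c(100L, 1000L, 4990L),
                                  strand = c("+", "-", "+"))),
                 36L, lens, frag_len = 150)
  expect_identical(shift_reads(rs, 0)$reads, rs$reads)
  sh <- shift_reads(rs, 75)
  expect_equal(sh$reads$chrX$pos, c(175L, 925L, 4999L))
  expect_error(shift_reads(rs, 6000), "smaller")
})

test_that("binning counts 5' positions half-open and conserves totals", {
  g <- toy_genome_for(toy_track(numeric(4), bin = 50))
  rs <- read_set(list(chrX = list(pos = c(10L, 49L, 50L),
                                  strand = c("+", "+", "-"))), 36L,
                 g$chrom_lengths)
  ct <- bin_counts(rs, g, 50)
  expect_equal(ct$values$chrX, c(2, 1, 0, 0))

  empty <- read_set(list(chrX = list(pos = integer(), strand = character())),
                    36L, g$chrom_lengths)
  expect_true(all(bin_counts(empty, g)$values$chrX == 0))

  gen <- small_genome(seed = 71, lengths = 1e5)
  sim <- simulate_reads(constant_track(gen), gen, 2e4, seed = 72)
  ct2 <- bin_counts(sim, gen)
  perchrom <- sapply(names(sim$reads), function(ch) length(sim$reads[[ch]]$pos))
  expect_equal(sapply(ct2$values, sum)[names(perchrom)], perchrom)

  stray <- read_set(list(nope = list(pos = 1L, strand = "+")), 36L,
                    c(nope = 100L))
  expect_error(bin_counts(stray, gen), "nope")
})

test_that("probe binning averages midpoint-assigned intensities and masks gaps", {
  g <- toy_genome_for(toy_track(numeric(4), bin = 50))
  probes <- data.frame(chrom = "chrX", start = c(0L, 10L, 100L),
                       end = c(40L, 60L, 150L),
                       probe_id = c("a", "b", "c"),
                       ip_intensity = c(2, 4, 6),
                       input_intensity = c(1, 1, 3))
  b <- bin_probes(probes, g, 50)
  expect_equal(b$ip$values$chrX, c(3, 0, 6, 0))     # mean(2,4) in bin 1
  expect_equal(b$input$values$chrX, c(1, 0, 3, 0))
  expect_equal(b$probe_mask$chrX, c(TRUE, FALSE, TRUE, FALSE))
})

test_that("Gaussian smoother preserves constants, is linear, matches the kernel", {
  const <- toy_track(rep(3.5, 100))
  expect_equal(gaussian_smooth(const)$values$chrX, rep(3.5, 100))

  imp <- numeric(101); imp[51] <- 1
  sm <- gaussian_smooth(toy_track(imp), bandwidth = 50)$values$chrX
  # hand evaluation: weights exp(-(50 d)^2 / (2*50^2)) over the 400-neighbor
  # window, normalized
  w <- exp(-(50 * (-200:200))^2 / (2 * 50^2))
  norm <- sum(w)
  for (d in 0:2)
    expect_equal(sm[51 + d], exp(-(50 * d)^2 / 5000) / norm,
                 tolerance = 1e-12)

  set.seed(8)
  y <- rnorm(100); z <- rnorm(100)
  lin <- gaussian_smooth(toy_track(2 * y + 3 * z))$values$chrX
  parts <- 2 * gaussian_smooth(toy_track(y))$values$chrX +
    3 * gaussian_smooth(toy_track(z))$values$chrX
  expect_equal(lin, parts, tolerance = 1e-12)

  raw <- gaussian_smooth(toy_track(imp), normalize = FALSE)$values$chrX
  expect_equal(raw[51], 1)            # unnormalized weighted sum
  expect_equal(raw[52], exp(-0.5))
  expect_error(gaussian_smooth(toy_track(1:10), max_neighbors = 5), "even")
})

test_that("enrichment is a centered log ratio and antisymmetric", {
  a <- toy_track(c(1, 2, 3, 4))
  expect_true(all(enrichment(a, a)$track$values$chrX == 0))

  b4 <- toy_track(4 * c(1, 2, 3, 4))
  e <- enrichment(b4, a)
  expect_equal(e$track$values$chrX, rep(2, 4))

  set.seed(9)
  x <- toy_track(runif(50, 1, 5)); y <- toy_track(runif(50, 1, 5))
  expect_equal(enrichment(x, y)$track$values$chrX,
               -enrichment(y, x)$track$values$chrX)
  expect_error(enrichment(x, toy_track(runif(10, 1, 2))), "aligned")

  # count tracks: library-size scaling makes a 2x deeper library equivalent
  ca <- toy_track(c(10, 20, 30, 40), kind = "count")
  cb <- toy_track(2 * c(10, 20, 30, 40), kind = "count")
  expect_equal(enrichment(cb, ca, pseudocount = 1e-8)$track$values$chrX,
               rep(0, 4), tolerance = 1e-6)
})

test_that("input profiles obey the log law", {
  a <- toy_track(c(1, 2, 4, 8))
  p <- input_profile(a)
  p2 <- input_profile(toy_track(2 * c(1, 2, 4, 8)))
  expect_equal(p2$track$values$chrX - p$track$values$chrX, rep(1, 4))
  expect_equal(input_profile(toy_track(rep(4, 6)))$track$values$chrX,
               rep(2, 6))
})

test_that("bin aggregation averages masked-in children and composes", {
  v <- as.numeric(1:40)
  p <- as_profile(toy_track(v, kind = "log-ratio"))
  agg <- aggregate_bins(p, 20)
  expect_equal(agg$track$values$chrX, c(10.5, 30.5))
  expect_identical(aggregate_bins(p, 1), p)

  two_then_ten <- aggregate_bins(aggregate_bins(p, 2), 10)
  expect_equal(two_then_ten$track$values$chrX,
               aggregate_bins(p, 20)$track$values$chrX)

  # masked-out children are excluded; fully masked-out groups drop out
  m <- list(chrX = rep(TRUE, 40)); m$chrX[1:10] <- FALSE; m$chrX[21:40] <- FALSE
  pm <- as_profile(toy_track(v, kind = "log-ratio"), mask = m)
  am <- aggregate_bins(pm, 20)
  expect_equal(am$track$values$chrX[1], mean(11:20))
  expect_false(am$mask$chrX[2])
})

test_that("variability mask flags only high-variance bins", {
  v <- rep(0, 2000)
  mk <- function(x) as_profile(toy_track(x, kind = "log-ratio"))
  same <- list(mk(v), mk(v), mk(v))
  expect_true(all(variability_mask(same, 0.95)$chrX))

  set.seed(10)
  base <- rnorm(2000, sd = 0.1)
  spiked <- base; spiked[500] <- 50
  noisy <- list(mk(base + rnorm(2000, sd = 0.05)),
                mk(spiked + rnorm(2000, sd = 0.05)),
                mk(base + rnorm(2000, sd = 0.05)))
  vm <- variability_mask(noisy, 0.99)
  expect_false(vm$chrX[500])
  expect_gt(mean(vm$chrX), 0.98)
  expect_error(variability_mask(same[1]), "at least two")
})

test_that("noise-free array pipeline recovers log2 effect exactly at 1 kb", {
  g <- small_genome(lengths = 1e5, n_chrom = 1, seed = 81)
  truth <- data.frame(chrom = "chr1", start = 40000, end = 44000, effect = 6)
  lam <- regions_to_lambda(g, truth)
  pr <- simulate_array(lam, constant_track(g), g, noise_sd = 0,
                       coverage_target = 1, seed = 82)
  prof <- array_enrichment(pr, g, smooth = FALSE, aggregate = 20)
  v <- prof$track$values$chr1
  inner <- 42  # 1 kb bin fully inside [40000, 44000), away from edges
  expect_equal(v[inner], log2(6), tolerance = 1e-12)
  expect_equal(v[10], 0, tolerance = 1e-12)
})
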