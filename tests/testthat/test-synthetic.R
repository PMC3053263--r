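test_that("GC track has the requested mean, bounded amplitude, and is smooth", {
  g <- make_genome(n_chrom = 1, lengths = 1e6, gc_mean = 0.42,
                   gc_amplitude = 0.1, seed = 7)
  gc <- g$gc_track$values$chr1
  expect_equal(mean(gc), 0.42, tolerance = 0.01)
  expect_gte(min(gc), 0.2)
  expect_lte(max(gc), 0.65)
  # smoothness: adjacent-bin differences are tiny relative to the amplitude
  expect_lt(max(abs(diff(gc))), 0.01)
})

test_that("zero amplitude gives a constant GC track and seeds reproduce bitwise", {
  g0 <- make_genome(n_chrom = 2, lengths = 1e4, gc_amplitude = 0, seed = 1)
  expect_true(all(unlist(g0$gc_track$values) == 0.42))
  a <- make_genome(n_chrom = 2, lengths = 5e4, seed = 42)
  b <- make_genome(n_chrom = 2, lengths = 5e4, seed = 42)
  expect_identical(a, b)
  expect_error(make_genome(gc_mean = 0.95, gc_amplitude = 0.1),
               "within \\(0, 1\\)")
})

test_that("planted regions never overlap and build the expected rate track", {
  g <- small_genome(lengths = 1e6, n_chrom = 1)
  pl <- plant_regions(g, 50, seed = 3)
  expect_equal(nrow(pl$truth), 50)
  # brute-force pairwise interval intersection
  tr <- pl$truth
  clashes <- 0
  for (i in seq_len(nrow(tr) - 1)) for (j in (i + 1):nrow(tr))
    if (tr$chrom[i] == tr$chrom[j] &&
        tr$start[i] < tr$end[j] && tr$start[j] < tr$end[i])
      clashes <- clashes + 1
  expect_equal(clashes, 0)
  expect_true(all(tr$effect > 1 & tr$start < tr$end))

  # explicit region: rate is effect inside, 1 outside
  truth <- data.frame(chrom = "chr1", start = 1000, end = 2000, effect = 5)
  lam <- regions_to_lambda(g, truth)
  v <- lam$values$chr1
  inside <- bin_centers(lam, "chr1") >= 1000 & bin_centers(lam, "chr1") < 2000
  expect_true(all(v[inside] == 5))
  expect_true(all(v[!inside] == 1))

  # empty truth
  pl0 <- plant_regions(g, 0)
  expect_equal(nrow(pl0$truth), 0)
  expect_true(all(unlist(pl0$lambda$values) == 1))

  # impossible placement errors out
  tiny <- make_genome(1, 3000, seed = 1)
  expect_error(plant_regions(tiny, 50, seed = 1, max_tries = 500),
               "could not place")
})

test_that("read simulation respects depth, bounds, and GC bias direction", {
  g <- make_genome(1, 1e6, seed = 21)
  flat <- constant_track(g)
  r <- simulate_reads(flat, g, 1e5, seed = 22)
  expect_equal(r$total_reads, length(r$reads$chr1$pos))
  expect_true(all(r$reads$chr1$pos >= 0 &
                    r$reads$chr1$pos <= g$chrom_lengths[["chr1"]] - 1))
  # Poisson bound on the realized total
  expect_lt(abs(r$total_reads - 1e5), 4 * sqrt(1e5))

  counts0 <- bin_counts(r, g, 1000)
  gc1k <- aggregate_track(g$gc_track, 20)
  rho0 <- cor(counts0$values$chr1, gc1k$values$chr1, method = "spearman")
  expect_lt(abs(rho0), 0.05)

  rho <- sapply(c(0.5, 2, 5), function(beta) {
    rb <- simulate_reads(flat, g, 1e5, gc_beta = beta, seed = 23)
    cor(bin_counts(rb, g, 1000)$values$chr1, gc1k$values$chr1,
        method = "spearman")
  })
  expect_true(all(diff(rho) > 0))
  expect_gt(rho[1], 0.1)

  expect_error(simulate_reads(constant_track(g, value = 0), g, 100),
               "zero everywhere")
  expect_error(simulate_reads(flat, g, 100, frag_len = 10, read_len = 36),
               "frag_len")
})

test_that("unbiased input counts are exchangeable across GC deciles", {
  g <- make_genome(1, 1e6, seed = 31)
  r <- simulate_reads(constant_track(g), g, 2e5, gc_beta = 0, seed = 32)
  counts <- bin_counts(r, g, 1000)$values$chr1
  gc <- aggregate_track(g$gc_track, 20)$values$chr1
  qs <- stats::quantile(gc, c(0.1, 0.9))
  top <- counts[gc >= qs[2]]
  bottom <- counts[gc <= qs[1]]
  se <- sqrt(stats::var(top) / length(top) +
               stats::var(bottom) / length(bottom))
  expect_lt(abs(mean(top) - mean(bottom)), 3 * se)
})

test_that("array simulation hits coverage and reproduces effects exactly without noise", {
  g <- small_genome(lengths = 5e5, n_chrom = 1, seed = 41)
  flat <- constant_track(g)
  pr <- simulate_array(flat, flat, g, noise_sd = 0, seed = 42)
  expect_equal(attr(pr, "coverage"), 0.7, tolerance = 0.02)
  expect_true(all(log2(pr$ip_intensity / pr$input_intensity) == 0))
  expect_true(all(pr$ip_intensity > 0 & pr$input_intensity > 0))
  expect_true(!is.unsorted(pr$start[pr$chrom == "chr1"]))

  truth <- data.frame(chrom = "chr1", start = 10000, end = 14000, effect = 4)
  lam <- regions_to_lambda(g, truth)
  pr4 <- simulate_array(lam, flat, g, noise_sd = 0, seed = 43)
  mid <- (pr4$start + pr4$end) / 2
  inside <- mid >= 10000 & mid < 14000
  lr <- log2(pr4$ip_intensity / pr4$input_intensity)
  expect_true(all(lr[inside] == 2))
  expect_true(all(lr[!inside] == 0))
})

test_that("replicate arrays share their design but not their noise", {
  g <- small_genome(lengths = 2e5, n_chrom = 1, seed = 51)
  flat <- constant_track(g)
  a <- simulate_array(flat, flat, g, noise_sd = 0.3, dye_bias_sd = 0.5,
                      design_seed = 9, seed = 1)
  b <- simulate_array(flat, flat, g, noise_sd = 0.3, dye_bias_sd = 0.5,
                      design_seed = 9, seed = 2)
  expect_identical(a$probe_id, b$probe_id)  # same dropout pattern
  lra <- log2(a$ip_intensity / a$input_intensity)
  lrb <- log2(b$ip_intensity / b$input_intensity)
  # shared dye bias induces positive correlation between replicate ratios
  expect_gt(cor(lra, lrb), 0.3)
  expect_false(any(lra == lrb))
})

test_that("subsampling is binomial thinning and composes", {
  g <- make_genome(1, 5e5, seed = 61)
  r <- simulate_reads(constant_track(g), g, 1e5, seed = 62)
  expect_identical(subsample_reads(r, 1), r)
  half <- subsample_reads(r, 0.5, seed = 63)
  expect_lt(abs(half$total_reads - 0.5 * r$total_reads),
            4 * sqrt(r$total_reads * 0.25))
  again <- subsample_reads(half, 0.4, seed = 64)
  expect_lt(abs(again$total_reads - 0.2 * r$total_reads),
            4 * sqrt(r$total_reads * 0.2 * 0.8) + 4 * sqrt(half$total_reads * 0.24))
  expect_identical(subsample_reads(r, 0.3, seed = 65),
                   subsample_reads(r, 0.3, seed = 65))
  expect_error(subsample_reads(r, 0), "proportion")
  expect_error(subsample_reads(r, 1.2), "proportion")
})
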