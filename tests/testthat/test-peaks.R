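test_that("the hand-worked 10-bin example gives the documented region and p", {
  v <- c(0, 0, 0, 5, 5, 5, 0, 0, 0, 0)
  ps <- call_peaks(as_profile(toy_track(v, kind = "log-ratio")))
  expect_equal(nrow(ps$peaks), 1)
  expect_equal(ps$peaks$m, 3)
  expect_equal(ps$peaks$l, 15)
  expect_equal(ps$peaks$start, 150)
  expect_equal(ps$peaks$end, 300)
  xbar <- mean(v); s <- sd(v)
  expect_equal(xbar, 1.5)
  p_direct <- 1 - pnorm((15 - 3 * xbar) / (s * sqrt(3)))
  expect_equal(ps$peaks$p, p_direct, tolerance = 1e-14)
  expect_equal(ps$peaks$q, p_direct, tolerance = 1e-14)  # single test
})

test_that("the caller matches a brute-force scanner on random masked profiles", {
  set.seed(23)
  for (rep in 1:25) {
    n <- sample(20:200, 1)
    v <- rnorm(n) + (runif(n) < 0.1) * rexp(n, 1 / 3)
    m <- runif(n) > 0.1
    if (sum(m) < 5 || sd(v[m]) == 0) next
    k <- sample(c(-1, 0, 1), 1)
    got <- call_peaks(as_profile(toy_track(v, kind = "log-ratio"),
                                 mask = list(chrX = m)), k = k)$peaks
    want <- brute_force_peaks(v, m, k = k)
    expect_equal(nrow(got), nrow(want))
    expect_equal(got$start, want$start)
    expect_equal(got$end, want$end)
    expect_equal(got$m, want$m)
    expect_equal(got$l, want$l, tolerance = 1e-12)
    expect_equal(got$p, want$p, tolerance = 1e-12)
  }
})

test_that("raising k shrinks the selected bin set and nests surviving regions", {
  set.seed(24)
  v <- rnorm(500) + (runif(500) < 0.05) * 5
  prof <- as_profile(toy_track(v, kind = "log-ratio"))
  prev <- call_peaks(prof, k = -0.5)$peaks
  for (k in c(0, 0.5, 1, 2)) {
    cur <- call_peaks(prof, k = k)$peaks
    # the above-threshold bin set only loses bins as k rises
    expect_lte(sum(cur$m), sum(prev$m))
    # every region at larger k nests inside a region at smaller k, so no
    # surviving region ever widens
    for (i in seq_len(nrow(cur))) {
      host <- prev$start <= cur$start[i] & prev$end >= cur$end[i]
      expect_true(any(host))
    }
    prev <- cur
  }
  expect_error(call_peaks(as_profile(toy_track(rep(1, 50),
                                               kind = "log-ratio"))),
               "zero variance")
})

test_that("BH adjustment matches the step-up oracle and preserves order", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(rep(0.2, 5)), rep(0.2, 5))
  p <- c(0.01, 0.02, 0.03, 0.5)
  expect_equal(bh_adjust(p), brute_force_bh(p), tolerance = 1e-15)

  set.seed(25)
  r <- runif(200)^2
  expect_equal(bh_adjust(r), brute_force_bh(r), tolerance = 1e-15)
  perm <- sample(200)
  expect_equal(bh_adjust(r[perm]), bh_adjust(r)[perm])
  expect_true(all(bh_adjust(r) >= r))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("peak statistics and top-N ranking are deterministic", {
  mk_ps <- function(df) structure(list(peaks = df, k = 0, fdr = 0.05,
                                       bin_size = 50), class = "PeakSet")
  empty <- mk_ps(data.frame(chrom = character(), start = integer(),
                            end = integer(), m = integer(), l = numeric(),
                            p = numeric(), q = numeric(),
                            significant = logical()))
  expect_equal(peak_stats(empty), list(count = 0, median_width = 0,
                                       mean_width = 0))
  df <- data.frame(chrom = "chr1", start = c(0, 500, 2000),
                   end = c(100, 800, 3100), m = c(2, 6, 22),
                   l = c(5, 8, 30), p = c(0.01, 0.001, 0.01),
                   q = c(0.01, 0.003, 0.01),
                   significant = c(TRUE, TRUE, TRUE))
  st <- peak_stats(mk_ps(df))
  expect_equal(st$count, 3)
  expect_equal(st$median_width, 300)
  expect_equal(st$mean_width, 500)

  expect_equal(nrow(top_peaks(mk_ps(df), 10)$peaks), 3)
  expect_equal(top_peaks(mk_ps(df), 1)$peaks$start, 500)
  # p ties break by larger l: rows 1 and 3 tie at p = 0.01
  two <- top_peaks(mk_ps(df), 2)$peaks
  expect_true(all(c(500, 2000) %in% two$start))

  set.seed(26)
  big <- data.frame(chrom = "chr1", start = seq(0, by = 200, length = 100),
                    end = seq(100, by = 200, length = 100),
                    m = rep(2, 100), l = runif(100), p = runif(100),
                    q = runif(100), significant = TRUE)
  ranked <- top_peaks(mk_ps(big), 10)$peaks
  oracle <- big[order(big$p, -big$l, big$chrom, big$start), ][1:10, ]
  expect_setequal(ranked$start, oracle$start)
})

test_that("overlap proportion follows the interval-intersection definition", {
  mk_ps <- function(start, end) structure(
    list(peaks = data.frame(chrom = rep("chr1", length(start)),
                            start = start, end = end,
                            m = rep(1, length(start)),
                            l = rep(1, length(start)),
                            p = rep(0.01, length(start)),
                            q = rep(0.01, length(start)),
                            significant = rep(TRUE, length(start))),
         k = 0, fdr = 0.05, bin_size = 50), class = "PeakSet")
  a <- mk_ps(c(0, 200), c(100, 300))
  b <- mk_ps(90, 110)
  expect_equal(overlap_proportion(a, a, "average"), 1)
  expect_equal(overlap_proportion(a, a, "smaller"), 1)
  expect_equal(overlap_proportion(a, b, "average"), (1 / 2 + 1) / 2)
  expect_equal(overlap_proportion(a, b, "smaller"), 1)
  far <- mk_ps(5000, 5100)
  expect_equal(overlap_proportion(a, far, "average"), 0)
  empty <- mk_ps(numeric(), numeric())
  expect_error(overlap_proportion(a, empty), "empty")
})

test_that("identical inputs give identical peak sets in the swap experiment", {
  g <- small_genome(lengths = 2e5, n_chrom = 1, seed = 27)
  pl <- plant_regions(g, 8, seed = 28)
  chip <- simulate_reads(pl$lambda, g, 4e5, seed = 29)
  input <- simulate_reads(constant_track(g), g, 4e5, seed = 30)
  swap <- input_swap_peaks(chip, list(a = input, b = input), g,
                           aggregate = 20)
  expect_equal(swap$table$n_peaks[1], swap$table$n_peaks[2])
  expect_equal(swap$overlap["a", "b"], 1)
  expect_identical(swap$peaksets$a$peaks, swap$peaksets$b$peaks)
})
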