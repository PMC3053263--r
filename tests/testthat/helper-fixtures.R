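# Shared small fixtures, built in code. Sizes are kept modest so the whole
# suite runs in minutes on one CPU.

small_genome <- function(seed = 101, n_chrom = 2, lengths = 2e5, ...) {
  make_genome(n_chrom = n_chrom, lengths = lengths, seed = seed, ...)
}

# A hand-built single-chromosome track: values v on a chromosome whose
# length is exactly length(v) * bin bp.
toy_track <- function(v, bin = 50, kind = "intensity", chrom = "chrX") {
  lens <- stats::setNames(length(v) * bin, chrom)
  binned_track(stats::setNames(list(v), chrom), bin, lens, kind)
}

toy_genome_for <- function(track) {
  gc <- lapply(track$values, function(v) rep(0.5, length(v)))
  structure(list(chrom_lengths = track$chrom_lengths,
                 gc_track = binned_track(gc, track$bin_size,
                                         track$chrom_lengths, "fraction")),
            class = "GenomeModel")
}

# Brute-force re-implementation of the two-step caller used as the oracle:
# explicit loops re-deriving the threshold, runs, l, m and the normal p.
brute_force_peaks <- function(values, mask, k = 0, bin = 50) {
  vals <- values[mask]
  xbar <- mean(vals)
  s <- stats::sd(vals)
  out <- list()
  run_start <- NA
  for (i in seq_len(length(values) + 1)) {
    hot <- i <= length(values) && mask[i] && values[i] > xbar + k * s
    if (hot && is.na(run_start)) run_start <- i
    if (!hot && !is.na(run_start)) {
      idx <- run_start:(i - 1)
      l <- sum(values[idx])
      m <- length(idx)
      z <- (l - m * xbar) / (s * sqrt(m))
      out[[length(out) + 1]] <- data.frame(
        start = (run_start - 1) * bin, end = (i - 1) * bin,
        m = m, l = l, p = 1 - stats::pnorm(z))
      run_start <- NA
    }
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(start = integer(), end = integer(), m = integer(),
               l = numeric(), p = numeric())
}

# Step-up BH oracle, written out longhand.
brute_force_bh <- function(p) {
  n <- length(p)
  if (n <= 1) return(p)
  o <- order(p)
  ranked <- p[o] * n / seq_len(n)
  for (i in (n - 1):1) ranked[i] <- min(ranked[i], ranked[i + 1])
  q <- numeric(n)
  q[o] <- pmin(ranked, 1)
  q
}
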