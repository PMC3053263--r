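## Synthetic genomes, planted enrichment regions, and paired platform
## observations (sequencing reads and two-channel probe intensities)
## generated from one shared underlying signal, with ground truth retained
## for recovery tests.

## Normalized Gaussian (Nadaraya-Watson) convolution of an equally spaced
## series. w are kernel weights at offsets 0..H; masked-out entries (if a
## mask is supplied) contribute neither value nor weight. Chromosome ends
## use whatever one-sided neighborhood exists.
nw_convolve <- function(y, w, mask = NULL, normalize = TRUE) {
  n <- length(y)
  H <- length(w) - 1L
  m <- if (is.null(mask)) rep(1, n) else as.numeric(mask)
  ym <- y * m
  num <- w[1L] * ym
  den <- w[1L] * m
  H <- min(H, n - 1L)
  if (H >= 1L) for (d in seq_len(H)) {
    wd <- w[d + 1L]
    if (wd == 0) next
    left <- seq_len(n - d)          # receive from the right neighbor
    right <- left + d
    num[left] <- num[left] + wd * ym[right]
    den[left] <- den[left] + wd * m[right]
    num[right] <- num[right] + wd * ym[left]
    den[right] <- den[right] + wd * m[left]
  }
  if (!normalize) return(num)
  out <- num / den
  out[den == 0] <- NA_real_
  out
}

gauss_weights <- function(bin_size, bandwidth, half_neighbors) {
  d <- 0:half_neighbors
  exp(-(d * bin_size)^2 / (2 * bandwidth^2))
}

#' Generate a toy multi-chromosome genome with a smooth GC track
#'
#' The GC fraction track is Gaussian-smoothed white noise, centered on
#' `gc_mean` and rescaled per chromosome so its largest deviation equals
#' `gc_amplitude`, then clipped to \[0.05, 0.95\]. `gc_scale` sets the
#' correlation length of the variation.
#'
#' @param n_chrom Number of chromosomes.
#' @param lengths Chromosome lengths in bp (recycled to `n_chrom`).
#' @param gc_mean Mean GC fraction.
#' @param gc_amplitude Maximum deviation of the GC track from its mean.
#' @param gc_scale Correlation length of GC variation in bp.
#' @param bin_size GC track bin width in bp.
#' @param seed Integer seed; fixed seed gives bitwise-identical output.
#' @return A `GenomeModel`: `chrom_lengths` (named) and `gc_track`
#'   (`BinnedTrack` of kind `"fraction"`).
#' @export
make_genome <- function(n_chrom = 2, lengths = 5e5, gc_mean = 0.42,
                        gc_amplitude = 0.1, gc_scale = 10000,
                        bin_size = 50, seed = NULL) {
  if (gc_amplitude < 0 || gc_mean - gc_amplitude <= 0 ||
      gc_mean + gc_amplitude >= 1)
    stop("gc_mean +/- gc_amplitude must lie within (0, 1)")
  if (gc_scale <= 0) stop("gc_scale must be positive")
  lengths <- as.integer(rep_len(lengths, n_chrom))
  if (any(lengths <= 0)) stop("chromosome lengths must be positive")
  chroms <- paste0("chr", seq_len(n_chrom))
  names(lengths) <- chroms
  gc <- with_seed(seed, {
    lapply(lengths, function(L) {
      n <- n_bins_for(L, bin_size)
      if (gc_amplitude == 0) return(rep(gc_mean, n))
      z <- stats::rnorm(n)
      sd_bins <- gc_scale / bin_size
      w <- exp(-(0:ceiling(4 * sd_bins))^2 / (2 * sd_bins^2))
      z <- nw_convolve(z, w)
      z <- z - mean(z)
      z <- z * gc_amplitude / max(abs(z))
      pmin(pmax(gc_mean + z, 0.05), 0.95)
    })
  })
  structure(list(chrom_lengths = lengths,
                 gc_track = binned_track(gc, bin_size, lengths, "fraction")),
            class = "GenomeModel")
}

#' @export
print.GenomeModel <- function(x, ...) {
  cat(sprintf("GenomeModel: %d chromosome(s), %s bp total, GC bins of %d bp\n",
              length(x$chrom_lengths),
              format(sum(as.double(x$chrom_lengths)), big.mark = ","),
              x$gc_track$bin_size))
  invisible(x)
}

#' Convert a truth table of regions into a rate multiplier track
#'
#' The rate track is 1 everywhere and `effect` inside each region; a bin
#' belongs to a region when its center falls inside \[start, end).
#' Effects below 1 model depleted marks.
#'
#' @param genome A `GenomeModel`.
#' @param truth Data frame with columns chrom, start, end, effect.
#' @param bin_size Bin width (default: the genome's GC bin size).
#' @return A `BinnedTrack` of kind `"rate"`.
#' @export
regions_to_lambda <- function(genome, truth, bin_size = NULL) {
  if (is.null(bin_size)) bin_size <- genome$gc_track$bin_size
  lam <- constant_track(genome, bin_size, 1, "rate")
  for (i in seq_len(nrow(truth))) {
    chrom <- truth$chrom[i]
    if (!chrom %in% names(lam$values))
      stop(sprintf("region on unknown chromosome '%s'", chrom))
    ctr <- bin_centers(lam, chrom)
    sel <- ctr >= truth$start[i] & ctr < truth$end[i]
    lam$values[[chrom]][sel] <- lam$values[[chrom]][sel] * truth$effect[i]
  }
  lam
}

#' Plant non-overlapping enrichment regions on a genome
#'
#' Draws `n_regions` regions with widths from a narrow or a broad class and
#' uniform effect multipliers, rejecting overlaps; returns the truth table
#' and the per-bin rate multiplier track.
#'
#' @param genome A `GenomeModel`.
#' @param n_regions Number of regions to place.
#' @param narrow_range,broad_range Width ranges (bp) of the two classes.
#' @param broad_fraction Probability that a region is broad.
#' @param effect_range Range of the enrichment multiplier (min must be > 1).
#' @param bin_size Bin size of the returned rate track.
#' @param seed Integer seed.
#' @param max_tries Placement attempts before giving up.
#' @return List with `truth` (data frame: chrom, start, end, effect,
#'   width_class) and `lambda` (`BinnedTrack`).
#' @export
plant_regions <- function(genome, n_regions, narrow_range = c(500, 1500),
                          broad_range = c(2000, 8000), broad_fraction = 0.5,
                          effect_range = c(4, 8), bin_size = NULL,
                          seed = NULL, max_tries = 1000 * max(n_regions, 1)) {
  if (n_regions > 0 && effect_range[1] <= 1)
    stop("effect_range minimum must exceed 1 for enriched regions")
  if (any(c(narrow_range, broad_range) <= 0))
    stop("width ranges must be positive")
  truth <- data.frame(chrom = character(), start = integer(), end = integer(),
                      effect = numeric(), width_class = character(),
                      stringsAsFactors = FALSE)
  if (n_regions > 0) {
    lens <- genome$chrom_lengths
    truth <- with_seed(seed, {
      placed <- vector("list", n_regions)
      k <- 0L; tries <- 0L
      while (k < n_regions) {
        tries <- tries + 1L
        if (tries > max_tries)
          stop("could not place all regions without overlap; genome too small")
        broad <- stats::runif(1) < broad_fraction
        rng <- if (broad) broad_range else narrow_range
        width <- round(stats::runif(1, rng[1], rng[2]))
        chrom <- sample(names(lens), 1, prob = as.double(lens))
        if (lens[[chrom]] <= width) next
        start <- floor(stats::runif(1, 0, lens[[chrom]] - width))
        end <- start + width
        clash <- FALSE
        for (r in placed[seq_len(k)])
          if (r$chrom == chrom && start < r$end && r$start < end) {
            clash <- TRUE; break
          }
        if (clash) next
        k <- k + 1L
        placed[[k]] <- list(chrom = chrom, start = start, end = end,
                            effect = stats::runif(1, effect_range[1],
                                                  effect_range[2]),
                            width_class = if (broad) "broad" else "narrow")
      }
      do.call(rbind, lapply(placed, as.data.frame,
                            stringsAsFactors = FALSE))
    })
    truth <- truth[order(truth$chrom, truth$start), , drop = FALSE]
    rownames(truth) <- NULL
  }
  list(truth = truth,
       lambda = regions_to_lambda(genome, truth, bin_size))
}

#' Simulate a sequencing read library from a rate track
#'
#' Per-bin sampling rates are `lambda * exp(gc_beta * (gc - mean(gc)))`;
#' the total read count is Poisson around `depth`; fragment midpoints are
#' drawn from the rate, a strand is assigned uniformly, and the stored
#' position is the fragment midpoint offset by `frag_len/2` toward the
#' read's 5' end (minus for + strand, plus for - strand), clipped to the
#' chromosome.
#'
#' @param lambda `BinnedTrack` of enrichment rate multipliers (same bins as
#'   the genome GC track).
#' @param genome A `GenomeModel`.
#' @param depth Expected total read count.
#' @param gc_beta Strength of the exponential GC tilt (0 = unbiased).
#' @param frag_len Fragment length in bp (no length variability is modeled).
#' @param read_len Read length in bp.
#' @param seed Integer seed.
#' @return A `ReadSet`: per chromosome 0-based positions and strands, plus
#'   `read_length`, `frag_len`, `total_reads`, `chrom_lengths`.
#' @export
simulate_reads <- function(lambda, genome, depth, gc_beta = 0,
                           frag_len = 200, read_len = 36, seed = NULL) {
  if (depth <= 0) stop("depth must be positive")
  if (frag_len < read_len) stop("frag_len must be >= read_len")
  gc <- genome$gc_track
  stopifnot_aligned(lambda, gc)
  gcv <- unlist(gc$values, use.names = FALSE)
  lamv <- unlist(lambda$values, use.names = FALSE)
  if (all(lamv == 0)) stop("lambda is zero everywhere; nothing to sample")
  rate <- lamv * exp(gc_beta * (gcv - mean(gcv)))
  ## weight bins by their width so partial end bins are not over-sampled
  bin <- lambda$bin_size
  widths <- unlist(lapply(names(lambda$values), function(chrom) {
    n <- length(lambda$values[[chrom]])
    w <- rep(bin, n)
    w[n] <- genome$chrom_lengths[[chrom]] - (n - 1L) * bin
    w
  }), use.names = FALSE)
  chrom_of <- rep(names(lambda$values), lengths(lambda$values))
  start_of <- unlist(lapply(lambda$values, function(v)
    (seq_along(v) - 1) * bin), use.names = FALSE)
  half <- frag_len %/% 2L
  with_seed(seed, {
    n_total <- stats::rpois(1, depth)
    counts <- as.vector(stats::rmultinom(1, n_total, rate * widths))
    reads <- lapply(names(genome$chrom_lengths), function(chrom) {
      sel <- chrom_of == chrom & counts > 0
      k <- counts[sel]
      if (sum(k) == 0)
        return(list(pos = integer(), strand = character()))
      mid <- rep(start_of[sel], k) +
        floor(stats::runif(sum(k)) * rep(widths[sel], k))
      strand <- ifelse(stats::runif(sum(k)) < 0.5, "+", "-")
      pos <- ifelse(strand == "+", mid - half, mid + half)
      pos <- pmin(pmax(pos, 0), genome$chrom_lengths[[chrom]] - 1L)
      o <- order(pos)
      list(pos = as.integer(pos[o]), strand = strand[o])
    })
    names(reads) <- names(genome$chrom_lengths)
    read_set(reads, read_len, genome$chrom_lengths, frag_len = frag_len)
  })
}

read_set <- function(reads, read_length, chrom_lengths, frag_len = NA) {
  total <- sum(vapply(reads, function(r) length(r$pos), integer(1)))
  structure(list(reads = reads, read_length = as.integer(read_length),
                 frag_len = frag_len, total_reads = total,
                 chrom_lengths = chrom_lengths),
            class = "ReadSet")
}

#' @export
print.ReadSet <- function(x, ...) {
  cat(sprintf("ReadSet: %s reads of %d bp on %d chromosome(s)\n",
              format(x$total_reads, big.mark = ","), x$read_length,
              length(x$reads)))
  invisible(x)
}

#' Simulate a two-channel tiling-array hybridization
#'
#' Probes tile each chromosome contiguously at `probe_spacing` and random
#' contiguous blocks (mean ~5 kb) are dropped until the covered fraction of
#' the genome matches `coverage_target`. Intensities are
#' `ip = lambda^gamma * 2^(e1 + d/2)` and
#' `input = input_rate^gamma * 2^(e2 - d/2)` with `e ~ N(0, noise_sd^2)`
#' independent per channel and `d` an optional probe-specific dye bias
#' (`N(0, dye_bias_sd^2)`) that is fixed by `design_seed`, i.e. shared by
#' replicate hybridizations of the same array design.
#'
#' @param lambda `BinnedTrack` of IP rate multipliers.
#' @param input_rate `BinnedTrack` of input-channel rate multipliers
#'   (use [constant_track()] for an unbiased input, or [gc_rate_track()]).
#' @param genome A `GenomeModel`.
#' @param probe_spacing Probe length and spacing in bp (contiguous tiling).
#' @param coverage_target Fraction of the genome retained after dropout.
#' @param noise_sd Log2 standard deviation of per-channel multiplicative noise.
#' @param gamma Response exponent (dynamic-range compression; 1 = linear).
#' @param dye_bias_sd Log2 SD of the probe-specific dye bias (0 = none).
#' @param design_seed Seed fixing probe dropout and dye bias (the array
#'   design); replicate arrays share it. Defaults to `seed`.
#' @param seed Integer seed for hybridization noise.
#' @return A `ProbeSet` data frame: chrom, start, end, probe_id,
#'   ip_intensity, input_intensity (sorted), with the realized coverage in
#'   `attr(, "coverage")`.
#' @export
simulate_array <- function(lambda, input_rate, genome, probe_spacing = 50,
                           coverage_target = 0.7, noise_sd = 0.3,
                           gamma = 1, dye_bias_sd = 0,
                           design_seed = NULL, seed = NULL) {
  if (coverage_target <= 0 || coverage_target > 1)
    stop("coverage_target must be in (0, 1]")
  if (noise_sd < 0 || dye_bias_sd < 0) stop("noise SDs must be >= 0")
  stopifnot_aligned(lambda, genome$gc_track)
  if (is.null(design_seed)) design_seed <- seed
  probe_len <- as.integer(probe_spacing)
  starts <- lapply(genome$chrom_lengths, function(L)
    seq.int(0L, L - probe_len, by = probe_len))
  chrom <- rep(names(starts), lengths(starts))
  start <- unlist(starts, use.names = FALSE)
  P <- length(start)
  design <- with_seed(design_seed, {
    need <- round((1 - coverage_target) * P)
    dropped <- logical(P)
    n_drop <- 0L
    mean_block <- max(1, round(5000 / probe_len))
    while (n_drop < need) {
      at <- sample.int(P, 1)
      len <- 1L + stats::rgeom(1, 1 / mean_block)
      idx <- at:min(P, at + len - 1L)
      idx <- idx[!dropped[idx]]
      if (length(idx) > need - n_drop) idx <- idx[seq_len(need - n_drop)]
      dropped[idx] <- TRUE
      n_drop <- n_drop + length(idx)
    }
    dye <- if (dye_bias_sd > 0) stats::rnorm(P, 0, dye_bias_sd) else numeric(P)
    list(dropped = dropped, dye = dye)
  })
  keep <- !design$dropped
  track_at <- function(track) {
    mid <- start + probe_len %/% 2L
    idx <- mid %/% track$bin_size + 1L
    unlist(lapply(unique(chrom), function(ch)
      track$values[[ch]][idx[chrom == ch]]), use.names = FALSE)
  }
  lam_p <- track_at(lambda)
  in_p <- track_at(input_rate)
  probes <- with_seed(seed, {
    n <- sum(keep)
    e1 <- stats::rnorm(n, 0, noise_sd)
    e2 <- stats::rnorm(n, 0, noise_sd)
    d <- design$dye[keep]
    data.frame(
      chrom = chrom[keep], start = start[keep],
      end = start[keep] + probe_len,
      probe_id = sprintf("p%07d", which(keep)),
      ip_intensity = lam_p[keep]^gamma * 2^(e1 + d / 2),
      input_intensity = in_p[keep]^gamma * 2^(e2 - d / 2),
      stringsAsFactors = FALSE)
  })
  probes <- probes[order(probes$chrom, probes$start), , drop = FALSE]
  rownames(probes) <- NULL
  class(probes) <- c("ProbeSet", "data.frame")
  attr(probes, "coverage") <-
    sum(keep) * probe_len / sum(as.double(genome$chrom_lengths))
  attr(probes, "probe_len") <- probe_len
  probes
}

#' GC-tilted rate track
#'
#' `exp(beta * (gc - mean(gc)))` over the genome; the noise-free model of a
#' GC-biased library's local sampling rate.
#'
#' @param genome A `GenomeModel`.
#' @param beta Tilt strength.
#' @return A `BinnedTrack` of kind `"rate"`.
#' @export
gc_rate_track <- function(genome, beta) {
  gc <- genome$gc_track
  m <- mean(unlist(gc$values, use.names = FALSE))
  vals <- lapply(gc$values, function(g) exp(beta * (g - m)))
  binned_track(vals, gc$bin_size, genome$chrom_lengths, "rate")
}

#' Add localized GC elevation around given sites
#'
#' Adds a Gaussian bump of the given amplitude and width to the GC track at
#' each site, emulating systematic GC structure around genomic features
#' (e.g. GC-rich promoters). Values are clipped to \[0.02, 0.98\].
#'
#' @param genome A `GenomeModel`.
#' @param sites Data frame with columns chrom, position.
#' @param amplitude GC increase at the bump center.
#' @param width Gaussian SD of the bump in bp.
#' @return A modified `GenomeModel`.
#' @export
plant_gc_bumps <- function(genome, sites, amplitude = 0.08, width = 500) {
  gc <- genome$gc_track
  for (i in seq_len(nrow(sites))) {
    chrom <- sites$chrom[i]
    ctr <- bin_centers(gc, chrom)
    bump <- amplitude * exp(-(ctr - sites$position[i])^2 / (2 * width^2))
    gc$values[[chrom]] <- gc$values[[chrom]] + bump
  }
  gc$values <- lapply(gc$values, function(v) pmin(pmax(v, 0.02), 0.98))
  genome$gc_track <- gc
  genome
}

#' Thin a read library by independent subsampling
#'
#' Each read is retained independently with probability `proportion`
#' (binomial thinning), as used for the depth-vs-coverage ladder.
#'
#' @param reads A `ReadSet`.
#' @param proportion Retention probability in (0, 1].
#' @param seed Integer seed.
#' @return A `ReadSet`.
#' @export
subsample_reads <- function(reads, proportion, seed = NULL) {
  if (proportion <= 0 || proportion > 1)
    stop("proportion must be in (0, 1]")
  if (proportion == 1) return(reads)
  kept <- with_seed(seed, {
    lapply(reads$reads, function(r) {
      keep <- stats::runif(length(r$pos)) < proportion
      list(pos = r$pos[keep], strand = r$strand[keep])
    })
  })
  read_set(kept, reads$read_length, reads$chrom_lengths,
           frag_len = reads$frag_len)
}

#' The read-subsampling ladder used throughout the package
#' @return Proportions 0.9, 0.8, ..., 0.1, 0.05, 0.01.
#' @export
depth_ladder <- function() c(seq(0.9, 0.1, by = -0.1), 0.05, 0.01)

#' Generate a random non-overlapping gene annotation
#'
#' @param genome A `GenomeModel`.
#' @param n_genes Number of genes to place.
#' @param length_range Gene length range in bp.
#' @param seed Integer seed.
#' @return A `GeneAnnotation` data frame: chrom, start, end, strand, id.
#' @export
make_genes <- function(genome, n_genes, length_range = c(1000, 8000),
                       seed = NULL) {
  placed <- plant_regions(genome, n_genes,
                          narrow_range = length_range,
                          broad_range = length_range,
                          broad_fraction = 0, effect_range = c(2, 3),
                          seed = seed)$truth
  genes <- with_seed(if (is.null(seed)) NULL else child_seed(seed, 1), {
    data.frame(chrom = placed$chrom, start = placed$start,
               end = placed$end,
               strand = sample(c("+", "-"), nrow(placed), replace = TRUE),
               id = sprintf("gene%04d", seq_len(nrow(placed))),
               stringsAsFactors = FALSE)
  })
  class(genes) <- c("GeneAnnotation", "data.frame")
  genes
}
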