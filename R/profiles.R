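## Profile construction: read shifting, 50 bp binning, Gaussian smoothing,
## log-ratio enrichment, input log2 profiles, 20-fold aggregation to 1 kb,
## and the probe / input-variability masks.

#' Shift read positions by a constant offset
#'
#' Positions on the + strand move by `+shift`, on the - strand by `-shift`,
#' clipped to chromosome bounds. The default pipeline shift is half the
#' fragment length, which moves each read's 5' position onto the fragment
#' midpoint; the sign is fully caller-controlled.
#'
#' @param reads A `ReadSet`.
#' @param shift Signed offset in bp.
#' @return A `ReadSet`.
#' @export
shift_reads <- function(reads, shift) {
  if (abs(shift) >= min(reads$chrom_lengths))
    stop("|shift| must be smaller than the shortest chromosome")
  shifted <- lapply(names(reads$reads), function(chrom) {
    r <- reads$reads[[chrom]]
    pos <- r$pos + ifelse(r$strand == "+", shift, -shift)
    pos <- pmin(pmax(pos, 0L), reads$chrom_lengths[[chrom]] - 1L)
    list(pos = as.integer(pos), strand = r$strand)
  })
  names(shifted) <- names(reads$reads)
  read_set(shifted, reads$read_length, reads$chrom_lengths,
           frag_len = reads$frag_len)
}

default_shift <- function(reads) {
  if (is.null(reads$frag_len) || is.na(reads$frag_len)) 0L
  else as.integer(reads$frag_len) %/% 2L
}

#' Count read 5' positions in fixed-width bins
#'
#' @param reads A `ReadSet` (already shifted if desired).
#' @param genome A `GenomeModel`.
#' @param bin_size Bin width in bp.
#' @return A `BinnedTrack` of kind `"count"`; per-chromosome sums equal the
#'   per-chromosome read counts.
#' @export
bin_counts <- function(reads, genome, bin_size = 50) {
  if (bin_size <= 0) stop("bin_size must be positive")
  extra <- setdiff(names(reads$reads)[vapply(reads$reads, function(r)
    length(r$pos) > 0, logical(1))], names(genome$chrom_lengths))
  if (length(extra))
    stop(sprintf("reads on chromosome(s) absent from genome: %s",
                 paste(extra, collapse = ", ")))
  vals <- lapply(names(genome$chrom_lengths), function(chrom) {
    n <- n_bins_for(genome$chrom_lengths[[chrom]], bin_size)
    r <- reads$reads[[chrom]]
    if (is.null(r) || length(r$pos) == 0) return(numeric(n))
    as.numeric(tabulate(r$pos %/% bin_size + 1L, nbins = n))
  })
  names(vals) <- names(genome$chrom_lengths)
  binned_track(vals, bin_size, genome$chrom_lengths, "count")
}

#' Bin probe intensities by probe midpoint
#'
#' Bin values are the mean intensity of probes whose midpoints fall in the
#' bin; bins containing no probe get value 0 and mask FALSE.
#'
#' @param probes A `ProbeSet`.
#' @param genome A `GenomeModel`.
#' @param bin_size Bin width in bp.
#' @return List with `ip` and `input` (`BinnedTrack`s of kind
#'   `"intensity"`) and `probe_mask` (per-chromosome logical).
#' @export
bin_probes <- function(probes, genome, bin_size = 50) {
  template <- lapply(genome$chrom_lengths, function(L)
    numeric(n_bins_for(L, bin_size)))
  ip <- input <- template
  mask <- lapply(template, function(v) rep(FALSE, length(v)))
  mid <- (probes$start + probes$end) %/% 2L
  idx <- mid %/% bin_size + 1L
  for (chrom in unique(probes$chrom)) {
    if (!chrom %in% names(template))
      stop(sprintf("probes on unknown chromosome '%s'", chrom))
    sel <- probes$chrom == chrom
    i <- idx[sel]
    ipm <- tapply(probes$ip_intensity[sel], i, mean)
    inm <- tapply(probes$input_intensity[sel], i, mean)
    at <- as.integer(names(ipm))
    ip[[chrom]][at] <- as.numeric(ipm)
    input[[chrom]][at] <- as.numeric(inm)
    mask[[chrom]][at] <- TRUE
  }
  list(ip = binned_track(ip, bin_size, genome$chrom_lengths, "intensity"),
       input = binned_track(input, bin_size, genome$chrom_lengths,
                            "intensity"),
       probe_mask = mask)
}

#' Gaussian-kernel smoothing of a binned track
#'
#' Nadaraya-Watson smoothing with weights
#' `w(d) = exp(-(d * bin_size)^2 / (2 * bandwidth^2))` over at most
#' `max_neighbors` nearest bins (`max_neighbors/2` on each side);
#' chromosome ends use one-sided neighborhoods. The normalized kernel
#' preserves constants; `normalize = FALSE` gives the raw weighted sum.
#' When a mask is supplied, masked-out bins contribute neither value nor
#' weight (smoothing over probe-bearing bins only).
#'
#' @param track A `BinnedTrack`.
#' @param bandwidth Kernel bandwidth in bp.
#' @param max_neighbors Total neighbor budget (even).
#' @param mask Optional per-chromosome logical mask.
#' @param normalize Divide by the summed kernel weights (default TRUE).
#' @return A `BinnedTrack` of the same kind.
#' @export
gaussian_smooth <- function(track, bandwidth = 50, max_neighbors = 400,
                            mask = NULL, normalize = TRUE) {
  if (bandwidth <= 0) stop("bandwidth must be positive")
  if (max_neighbors %% 2 != 0) stop("max_neighbors must be even")
  if (sum(lengths(track$values)) == 0) stop("empty track")
  w <- gauss_weights(track$bin_size, bandwidth, max_neighbors %/% 2L)
  vals <- lapply(names(track$values), function(chrom) {
    nw_convolve(track$values[[chrom]], w,
                mask = if (is.null(mask)) NULL else mask[[chrom]],
                normalize = normalize)
  })
  names(vals) <- names(track$values)
  binned_track(vals, track$bin_size, track$chrom_lengths, track$value_kind)
}

#' Log2-ratio enrichment of IP over input
#'
#' For count tracks, `log2((ip + c) / S_ip) - log2((input + c) / S_input)`
#' with `c` the pseudocount and `S` the genome-wide totals (library-size
#' scaling), which centers the genome-wide mean enrichment near zero. For
#' intensity tracks the pseudocount defaults to 0 and no scaling is applied
#' (intensities are strictly positive).
#'
#' @param ip,input Aligned `BinnedTrack`s of the same kind.
#' @param pseudocount Added to both channels; default 0.5 for counts,
#'   0 for intensities.
#' @param mask Optional per-chromosome logical mask to carry along.
#' @return An `EnrichmentProfile` (platform `"seq"` for counts, `"chip"`
#'   for intensities).
#' @export
enrichment <- function(ip, input, pseudocount = NULL, mask = NULL) {
  stopifnot_aligned(ip, input)
  is_count <- ip$value_kind == "count"
  if (is.null(pseudocount)) pseudocount <- if (is_count) 0.5 else 0
  if (is_count && pseudocount <= 0)
    stop("pseudocount must be positive for count tracks")
  tot <- function(track) {
    s <- sum(unlist(track$values, use.names = FALSE)) +
      pseudocount * sum(lengths(track$values))
    if (is_count) s else 1
  }
  s_ip <- tot(ip); s_in <- tot(input)
  vals <- lapply(names(ip$values), function(chrom) {
    log2((ip$values[[chrom]] + pseudocount) / s_ip) -
      log2((input$values[[chrom]] + pseudocount) / s_in)
  })
  names(vals) <- names(ip$values)
  track <- binned_track(vals, ip$bin_size, ip$chrom_lengths, "log-ratio")
  new_profile(track, if (is_count) "seq" else "chip", mask,
              pseudocount = pseudocount)
}

#' Log2 profile of an input library
#'
#' `log2(value + c)`; used as the enrichment measure of input (background)
#' libraries, which have no IP channel to take a ratio against.
#'
#' @param input A `BinnedTrack` (counts or intensities).
#' @param pseudocount Default 0.5 for counts, 0 for intensities.
#' @param mask Optional per-chromosome logical mask.
#' @param platform Platform tag (default by track kind).
#' @return An `EnrichmentProfile`.
#' @export
input_profile <- function(input, pseudocount = NULL, mask = NULL,
                          platform = NULL) {
  is_count <- input$value_kind == "count"
  if (is.null(pseudocount)) pseudocount <- if (is_count) 0.5 else 0
  if (is.null(platform)) platform <- if (is_count) "seq" else "chip"
  vals <- lapply(input$values, function(y) log2(y + pseudocount))
  track <- binned_track(vals, input$bin_size, input$chrom_lengths,
                        "log-ratio")
  new_profile(track, platform, mask, pseudocount = pseudocount)
}

#' Aggregate an enrichment profile to coarser bins
#'
#' Each output bin is the mean of the masked-in values among its `factor`
#' children (the paper-default factor 20 turns 50 bp bins into 1 kb bins);
#' the output bin is masked out only when all children are masked out.
#'
#' @param profile An `EnrichmentProfile`.
#' @param factor Integer aggregation factor.
#' @return An `EnrichmentProfile` at `bin_size * factor`.
#' @export
aggregate_bins <- function(profile, factor = 20) {
  factor <- as.integer(factor)
  if (factor < 1) stop("factor must be >= 1")
  if (factor == 1) return(profile)
  vals <- list(); mask <- list()
  for (chrom in names(profile$track$values)) {
    y <- profile$track$values[[chrom]]
    m <- profile$mask[[chrom]]
    g <- (seq_along(y) - 1L) %/% factor
    cnt <- as.numeric(tapply(m, g, sum))
    s <- as.numeric(tapply(ifelse(m, y, 0), g, sum))
    v <- ifelse(cnt > 0, s / cnt, 0)
    vals[[chrom]] <- v
    mask[[chrom]] <- cnt > 0
  }
  track <- binned_track(vals, profile$track$bin_size * factor,
                        profile$track$chrom_lengths, "log-ratio")
  new_profile(track, profile$platform, mask, bandwidth = profile$bandwidth,
              pseudocount = profile$pseudocount)
}

#' Mask bins with unusually variable input signal
#'
#' Computes the across-library standard deviation of input profiles per bin
#' and masks out bins whose SD exceeds the given genome-wide quantile.
#' Combine with a probe mask by logical AND for cross-platform comparisons.
#'
#' @param inputs List of at least two aligned `EnrichmentProfile`s.
#' @param quantile SD quantile above which bins are masked out.
#' @return Per-chromosome logical mask (TRUE = usable).
#' @export
variability_mask <- function(inputs, quantile = 0.95) {
  if (length(inputs) < 2) stop("need at least two input profiles")
  for (p in inputs[-1]) stopifnot_aligned(inputs[[1]]$track, p$track)
  chroms <- names(inputs[[1]]$track$values)
  sds <- lapply(chroms, function(chrom) {
    x <- sapply(inputs, function(p) p$track$values[[chrom]])
    allin <- Reduce(`&`, lapply(inputs, function(p) p$mask[[chrom]]))
    mu <- rowMeans(x)
    s <- sqrt(rowSums((x - mu)^2) / (ncol(x) - 1))
    s[!allin] <- NA_real_
    s
  })
  thr <- stats::quantile(unlist(sds), quantile, na.rm = TRUE, names = FALSE)
  mask <- lapply(sds, function(s) is.na(s) | s <= thr)
  names(mask) <- chroms
  mask
}

#' Combine per-bin masks by logical AND
#' @param ... Per-chromosome logical masks of identical shape.
#' @return A per-chromosome logical mask.
#' @export
combine_masks <- function(...) {
  masks <- list(...)
  out <- masks[[1]]
  for (m in masks[-1])
    for (chrom in names(out)) out[[chrom]] <- out[[chrom]] & m[[chrom]]
  out
}

#' ChIP-seq enrichment pipeline: reads to profile
#'
#' Shifts reads toward the fragment midpoint, counts 5' positions into
#' bins, Gaussian-smooths both libraries, takes the library-size-scaled
#' log2 ratio and optionally aggregates to coarser bins.
#'
#' @param ip_reads,input_reads `ReadSet`s.
#' @param genome A `GenomeModel`.
#' @param bin_size Working bin size (bp).
#' @param bandwidth Smoother bandwidth (bp); `smooth = FALSE` disables.
#' @param max_neighbors Smoother neighbor budget.
#' @param shift Read shift; default half the fragment length when known.
#' @param pseudocount Count pseudocount.
#' @param aggregate Aggregation factor applied at the end (1 = none).
#' @param smooth Apply the Gaussian smoother (default TRUE).
#' @return An `EnrichmentProfile`.
#' @export
seq_enrichment <- function(ip_reads, input_reads, genome, bin_size = 50,
                           bandwidth = 50, max_neighbors = 400,
                           shift = NULL, pseudocount = 0.5, aggregate = 1,
                           smooth = TRUE) {
  prep <- function(reads) {
    s <- if (is.null(shift)) default_shift(reads) else shift
    track <- bin_counts(if (s != 0) shift_reads(reads, s) else reads,
                        genome, bin_size)
    if (smooth) gaussian_smooth(track, bandwidth, max_neighbors) else track
  }
  prof <- enrichment(prep(ip_reads), prep(input_reads),
                     pseudocount = pseudocount)
  prof$bandwidth <- if (smooth) bandwidth else NA_real_
  if (aggregate > 1) prof <- aggregate_bins(prof, aggregate)
  prof
}

#' ChIP-chip enrichment pipeline: probes to profile
#'
#' Bins probe intensities, optionally smooths over probe-bearing bins, and
#' takes the log2 IP/input ratio with the probe mask attached.
#'
#' @inheritParams seq_enrichment
#' @param probes A `ProbeSet`.
#' @return An `EnrichmentProfile` with the probe mask.
#' @export
array_enrichment <- function(probes, genome, bin_size = 50, bandwidth = 50,
                             max_neighbors = 400, aggregate = 1,
                             smooth = TRUE) {
  b <- bin_probes(probes, genome, bin_size)
  ip <- b$ip; input <- b$input
  if (smooth) {
    ip <- gaussian_smooth(ip, bandwidth, max_neighbors, mask = b$probe_mask)
    input <- gaussian_smooth(input, bandwidth, max_neighbors,
                             mask = b$probe_mask)
    ## smoothing only defines values where some probe fell in range; keep
    ## the original probe mask and zero-fill unsmoothable bins
    for (chrom in names(ip$values)) {
      ip$values[[chrom]][!is.finite(ip$values[[chrom]])] <- 0
      input$values[[chrom]][!is.finite(input$values[[chrom]])] <- 0
    }
  }
  prof <- enrichment(ip, input, mask = b$probe_mask)
  prof$bandwidth <- if (smooth) bandwidth else NA_real_
  if (aggregate > 1) prof <- aggregate_bins(prof, aggregate)
  prof
}

#' Input library log2 profile pipeline
#'
#' @inheritParams seq_enrichment
#' @param reads A `ReadSet` of an input (background) library.
#' @return An `EnrichmentProfile` of log2 input signal.
#' @export
input_seq_profile <- function(reads, genome, bin_size = 50, bandwidth = 50,
                              max_neighbors = 400, shift = NULL,
                              pseudocount = 0.5, aggregate = 1,
                              smooth = TRUE) {
  s <- if (is.null(shift)) default_shift(reads) else shift
  track <- bin_counts(if (s != 0) shift_reads(reads, s) else reads,
                      genome, bin_size)
  if (smooth) track <- gaussian_smooth(track, bandwidth, max_neighbors)
  prof <- input_profile(track, pseudocount = pseudocount)
  prof$bandwidth <- if (smooth) bandwidth else NA_real_
  if (aggregate > 1) prof <- aggregate_bins(prof, aggregate)
  prof
}
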