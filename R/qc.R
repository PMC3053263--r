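## Signal-to-noise (truncated skewness), reproducibility, GC-bias,
## clustering and coverage statistics for enrichment and input profiles.

#' Truncated skewness of an enrichment distribution
#'
#' The third standardized sample moment `m3 / m2^(3/2)` (1/n moments),
#' computed after discarding the lowest and highest `trim` fraction of
#' values by rank. Positive skewness indicates a longer right tail, i.e. a
#' better signal-to-noise ratio of the profile.
#'
#' @param x Numeric vector or an `EnrichmentProfile` (masked-in values).
#' @param trim Fraction removed from each tail (default 0.05).
#' @return The truncated skewness.
#' @export
truncated_skewness <- function(x, trim = 0.05) {
  if (inherits(x, "EnrichmentProfile")) x <- profile_values(x)
  if (trim < 0 || trim >= 0.5) stop("trim must be in [0, 0.5)")
  x <- sort(x[is.finite(x)])
  k <- floor(length(x) * trim)
  if (k > 0) x <- x[(k + 1):(length(x) - k)]
  n <- length(x)
  if (n < 10) stop("fewer than 10 values remain after trimming")
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 == 0) stop("zero variance after trimming; skewness undefined")
  mean((x - m)^3) / m2^1.5
}

#' Correlation between two enrichment profiles
#'
#' Computed only on bins masked-in for both profiles.
#'
#' @param a,b Aligned `EnrichmentProfile`s.
#' @param method `"pearson"` or `"spearman"`.
#' @return The correlation coefficient.
#' @export
profile_correlation <- function(a, b, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  stopifnot_aligned(a$track, b$track)
  joint <- combine_masks(a$mask, b$mask)
  x <- unlist(mapply(function(v, m) v[m], a$track$values, joint,
                     SIMPLIFY = FALSE), use.names = FALSE)
  y <- unlist(mapply(function(v, m) v[m], b$track$values, joint,
                     SIMPLIFY = FALSE), use.names = FALSE)
  if (length(x) < 3) stop("fewer than 3 jointly masked-in bins")
  stats::cor(x, y, method = method)
}

#' Spearman correlation of an input profile with GC content
#'
#' The GC track is aggregated (by averaging) to the profile's bin size
#' first; the coefficient is computed on masked-in bins.
#'
#' @param input An `EnrichmentProfile` (typically a log2 input profile).
#' @param gc The genome GC `BinnedTrack`.
#' @return Spearman's rho.
#' @export
gc_correlation <- function(input, gc) {
  bs <- input$track$bin_size
  if (gc$bin_size != bs) {
    if (bs %% gc$bin_size != 0)
      stop("profile bin size is not a multiple of the GC bin size")
    gc <- aggregate_track(gc, bs %/% gc$bin_size)
  }
  profile_correlation(input, as_profile(gc, mask = input$mask),
                      method = "spearman")
}

#' Pairwise correlation matrix with hierarchical clustering
#'
#' Computes all pairwise correlations between profiles (plus optional extra
#' tracks such as GC content), each pair on its jointly masked-in bins, and
#' orders the leaves by average-linkage hierarchical clustering on the
#' distance `1 - rho`.
#'
#' @param profiles Named list of `EnrichmentProfile`s.
#' @param extra Named list of extra `BinnedTrack`s to include (e.g. GC).
#' @param method Correlation method (default `"spearman"`).
#' @return List with `matrix` (symmetric, unit diagonal), `order` (leaf
#'   labels after clustering) and `hclust`.
#' @export
correlation_heatmap <- function(profiles, extra = list(),
                                method = c("spearman", "pearson")) {
  method <- match.arg(method)
  if (length(profiles) < 2) stop("need at least two profiles")
  all_profiles <- c(profiles, lapply(extra, as_profile))
  labels <- names(all_profiles)
  if (is.null(labels) || any(labels == ""))
    labels <- names(all_profiles) <- paste0("profile", seq_along(all_profiles))
  n <- length(all_profiles)
  m <- diag(1, n)
  dimnames(m) <- list(labels, labels)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    r <- profile_correlation(all_profiles[[i]], all_profiles[[j]],
                             method = method)
    m[i, j] <- m[j, i] <- r
  }
  hc <- stats::hclust(stats::as.dist(1 - m), method = "average")
  list(matrix = m, order = labels[hc$order], hclust = hc)
}

#' Fraction of the genome covered by at least one read
#'
#' Reads are extended to `read_length` from their stored position; the
#' covered fraction is the base-level union over all reads.
#'
#' @param reads A `ReadSet`.
#' @param genome A `GenomeModel`.
#' @return Fraction of genomic bases covered.
#' @export
genomic_coverage <- function(reads, genome) {
  total <- sum(as.double(genome$chrom_lengths))
  covered <- 0
  for (chrom in names(reads$reads)) {
    r <- reads$reads[[chrom]]
    if (length(r$pos) == 0) next
    L <- genome$chrom_lengths[[chrom]]
    ir <- IRanges::IRanges(start = r$pos + 1L,
                           width = reads$read_length)
    ir <- IRanges::restrict(ir, start = 1L, end = L)
    covered <- covered + sum(as.double(IRanges::width(IRanges::reduce(ir))))
  }
  covered / total
}

#' Coverage as a function of subsampled depth
#'
#' Thins the library at each ladder proportion and records the retained
#' depth and genomic coverage; points are returned sorted by depth.
#'
#' @param reads A `ReadSet`.
#' @param genome A `GenomeModel`.
#' @param ladder Subsampling proportions in (0, 1]; default the
#'   0.9 ... 0.1, 0.05, 0.01 ladder ([depth_ladder()]).
#' @param seed Integer seed.
#' @return A `CoverageCurve` data frame: proportion, depth, coverage.
#' @export
coverage_curve <- function(reads, genome, ladder = depth_ladder(),
                           seed = NULL) {
  if (any(ladder <= 0 | ladder > 1)) stop("ladder values must be in (0, 1]")
  pts <- lapply(seq_along(ladder), function(i) {
    sub <- subsample_reads(reads, ladder[i],
                           seed = if (is.null(seed)) NULL
                                  else child_seed(seed, i))
    data.frame(proportion = ladder[i], depth = sub$total_reads,
               coverage = genomic_coverage(sub, genome))
  })
  curve <- do.call(rbind, pts)
  curve <- curve[order(curve$depth), , drop = FALSE]
  rownames(curve) <- NULL
  class(curve) <- c("CoverageCurve", "data.frame")
  curve
}
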