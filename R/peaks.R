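## Platform-agnostic heuristic peak caller: per-chromosome threshold
## x_bar + k*s, merging of adjacent above-threshold bins, a normal-sum
## p-value for each candidate region, and Benjamini-Hochberg FDR control.

#' Benjamini-Hochberg adjusted p-values
#'
#' Standard step-up adjustment with monotonicity enforcement, in the input
#' order (delegates to [stats::p.adjust()] after validation).
#'
#' @param pvalues Numeric vector of p-values in \[0, 1\].
#' @return Adjusted q-values, same order as the input.
#' @export
bh_adjust <- function(pvalues) {
  if (length(pvalues) == 0) return(numeric(0))
  if (any(!is.finite(pvalues)) || any(pvalues < 0 | pvalues > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}

#' Call enrichment regions with the heuristic two-step method
#'
#' Step 1: per chromosome, bins with enrichment above `x_bar + k*s` (mean
#' and SD of the masked-in values of that chromosome) are selected and
#' maximal runs of adjacent selected bins are merged into candidate regions
#' (a masked-out bin breaks a run). Step 2: a region of `m` bins with value
#' sum `l` gets the upper-tail p-value of `L ~ N(m*x_bar, m*s^2)`, i.e.
#' `p = 1 - pnorm((l - m*x_bar) / (s*sqrt(m)))`; q-values are BH-adjusted
#' genome-wide and regions with `q < fdr` are flagged significant.
#'
#' Region coordinates satisfy `end - start = m * bin_size` even when the
#' final bin of a chromosome is partial.
#'
#' @param profile An `EnrichmentProfile`.
#' @param k Threshold offset in SD units (default 0).
#' @param fdr FDR significance cutoff (default 0.05).
#' @return A `PeakSet`: `peaks` data frame (chrom, start, end, m, l, p, q,
#'   significant), the parameters used, and per-chromosome `stats`
#'   (x_bar, s).
#' @export
call_peaks <- function(profile, k = 0, fdr = 0.05) {
  bin <- profile$track$bin_size
  regions <- list()
  stats_rows <- list()
  for (chrom in names(profile$track$values)) {
    v <- profile$track$values[[chrom]]
    m <- profile$mask[[chrom]]
    vals <- v[m]
    if (length(vals) == 0) next
    xbar <- mean(vals)
    s <- stats::sd(vals)
    if (!is.finite(s) || s == 0)
      stop(sprintf("zero variance on chromosome '%s'; threshold undefined",
                   chrom))
    stats_rows[[chrom]] <- data.frame(chrom = chrom, x_bar = xbar, s = s,
                                      stringsAsFactors = FALSE)
    above <- m & v > xbar + k * s
    r <- rle(above)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    hit <- which(r$values)
    if (length(hit) == 0) next
    regions[[chrom]] <- data.frame(
      chrom = chrom,
      start = (starts[hit] - 1L) * bin,
      end = ends[hit] * bin,
      m = r$lengths[hit],
      l = vapply(hit, function(h)
        sum(v[starts[h]:ends[h]]), numeric(1)),
      stringsAsFactors = FALSE)
    regions[[chrom]]$p <- stats::pnorm(
      (regions[[chrom]]$l - regions[[chrom]]$m * xbar) /
        (s * sqrt(regions[[chrom]]$m)),
      lower.tail = FALSE)
  }
  peaks <- if (length(regions)) do.call(rbind, regions) else
    data.frame(chrom = character(), start = integer(), end = integer(),
               m = integer(), l = numeric(), p = numeric(),
               stringsAsFactors = FALSE)
  rownames(peaks) <- NULL
  peaks$q <- bh_adjust(peaks$p)
  peaks$significant <- peaks$q < fdr
  chrom_stats <- if (length(stats_rows))
    do.call(rbind, c(stats_rows, list(make.row.names = FALSE))) else NULL
  structure(list(peaks = peaks, k = k, fdr = fdr, bin_size = bin,
                 stats = chrom_stats),
            class = "PeakSet")
}

#' @export
print.PeakSet <- function(x, ...) {
  cat(sprintf("PeakSet: %d regions (%d significant at FDR < %g), k = %g\n",
              nrow(x$peaks), sum(x$peaks$significant), x$fdr, x$k))
  invisible(x)
}

#' Restrict a peak set to its significant regions
#' @param peaks A `PeakSet`.
#' @return A `PeakSet` containing only regions with `q < fdr`.
#' @export
significant_peaks <- function(peaks) {
  peaks$peaks <- peaks$peaks[peaks$peaks$significant, , drop = FALSE]
  rownames(peaks$peaks) <- NULL
  peaks
}

#' Summary statistics of a peak set
#'
#' @param peaks A `PeakSet`.
#' @param significant_only Count only regions with `q < fdr` (default).
#' @return List with `count`, `median_width`, `mean_width` (widths 0 when
#'   the set is empty).
#' @export
peak_stats <- function(peaks, significant_only = TRUE) {
  df <- peaks$peaks
  if (significant_only) df <- df[df$significant, , drop = FALSE]
  w <- df$end - df$start
  list(count = nrow(df),
       median_width = if (length(w)) stats::median(w) else 0,
       mean_width = if (length(w)) mean(w) else 0)
}

#' Top-ranked regions of a peak set
#'
#' The `n` regions with the smallest p-values; ties broken by larger `l`,
#' then genomic order, so ranking is deterministic.
#'
#' @param peaks A `PeakSet`.
#' @param n Number of regions to keep (default 1000).
#' @return A `PeakSet` with at most `n` regions.
#' @export
top_peaks <- function(peaks, n = 1000) {
  if (n < 1) stop("n must be >= 1")
  df <- peaks$peaks
  o <- order(df$p, -df$l, df$chrom, df$start)
  peaks$peaks <- df[o[seq_len(min(n, nrow(df)))], , drop = FALSE]
  peaks$peaks <- peaks$peaks[order(peaks$peaks$chrom, peaks$peaks$start), ,
                             drop = FALSE]
  rownames(peaks$peaks) <- NULL
  peaks
}

peaks_iranges <- function(df, chrom) {
  sel <- df$chrom == chrom
  IRanges::IRanges(start = df$start[sel] + 1L, end = df$end[sel])
}

#' Proportion of overlapping peaks between two peak sets
#'
#' A region overlaps the other set when it intersects any of its regions by
#' at least 1 bp. `mode = "average"` returns the mean of the two
#' directional proportions; `mode = "smaller"` returns the overlap
#' proportion of the set with fewer regions.
#'
#' @param a,b `PeakSet`s (filter with [significant_peaks()] or
#'   [top_peaks()] first as appropriate).
#' @param mode `"average"` or `"smaller"`.
#' @return A fraction in \[0, 1\].
#' @export
overlap_proportion <- function(a, b, mode = c("average", "smaller")) {
  mode <- match.arg(mode)
  da <- a$peaks; db <- b$peaks
  if (nrow(da) == 0 || nrow(db) == 0)
    stop("overlap proportion undefined for an empty peak set")
  hits <- function(x, y) {
    n <- 0L
    for (chrom in unique(x$chrom)) {
      irx <- peaks_iranges(x, chrom)
      iry <- peaks_iranges(y, chrom)
      n <- n + sum(IRanges::countOverlaps(irx, iry) > 0)
    }
    n
  }
  fa <- hits(da, db) / nrow(da)
  fb <- hits(db, da) / nrow(db)
  switch(mode,
         average = (fa + fb) / 2,
         smaller = if (nrow(da) <= nrow(db)) fa else fb)
}

#' Peak calling of one ChIP library against several input libraries
#'
#' Re-runs the enrichment pipeline and the peak caller once per input
#' library and tabulates peak counts, widths, and all pairwise overlap
#' proportions of the significant peak sets, reproducing the input-swap
#' experiment design.
#'
#' @param chip A `ReadSet` (the IP library).
#' @param inputs Named list of `ReadSet`s (the candidate backgrounds).
#' @param genome A `GenomeModel`.
#' @param k,fdr Peak caller parameters.
#' @param mode Overlap mode for the pairwise table.
#' @param ... Further arguments to [seq_enrichment()].
#' @return List with `table` (input, n_peaks, median_width, mean_width),
#'   `overlap` (matrix, NA where a set is empty) and `peaksets`.
#' @export
input_swap_peaks <- function(chip, inputs, genome, k = 0, fdr = 0.05,
                             mode = "average", ...) {
  if (length(inputs) < 2) stop("need at least two input libraries")
  if (is.null(names(inputs)))
    names(inputs) <- paste0("input", seq_along(inputs))
  peaksets <- lapply(inputs, function(input) {
    call_peaks(seq_enrichment(chip, input, genome, ...), k = k, fdr = fdr)
  })
  tab <- do.call(rbind, lapply(names(peaksets), function(id) {
    st <- peak_stats(peaksets[[id]])
    data.frame(input = id, n_peaks = st$count,
               median_width = st$median_width, mean_width = st$mean_width,
               stringsAsFactors = FALSE)
  }))
  sig <- lapply(peaksets, significant_peaks)
  n <- length(sig)
  ov <- matrix(NA_real_, n, n, dimnames = list(names(sig), names(sig)))
  diag(ov) <- 1
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (nrow(sig[[i]]$peaks) && nrow(sig[[j]]$peaks))
      ov[i, j] <- ov[j, i] <- overlap_proportion(sig[[i]], sig[[j]],
                                                 mode = mode)
  }
  list(table = tab, overlap = ov, peaksets = peaksets)
}
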