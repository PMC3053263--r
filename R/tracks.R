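#' @keywords internal
"_PACKAGE"

## Fixed-width binned genomic tracks are the working container of the whole
## package: read counts, probe intensities, GC fractions and log-ratio
## enrichment all live in the same structure. Coordinates are 0-based
## half-open throughout; bin i (1-based index) covers
## [(i-1)*bin_size, i*bin_size) and its center is (i-0.5)*bin_size.

.track_kinds <- c("count", "intensity", "log-ratio", "fraction", "rate")

n_bins_for <- function(len, bin_size) as.integer(ceiling(len / bin_size))

#' Construct a binned genomic track
#'
#' A `BinnedTrack` stores one numeric value per fixed-width genomic bin for
#' each chromosome. The last bin of a chromosome may be partial; it is always
#' included, so a chromosome of length `L` has `ceiling(L / bin_size)` bins.
#'
#' @param values Named list of numeric vectors, one per chromosome.
#' @param bin_size Bin width in base pairs.
#' @param chrom_lengths Named vector of chromosome lengths in base pairs.
#' @param value_kind One of `"count"`, `"intensity"`, `"log-ratio"`,
#'   `"fraction"`, `"rate"`.
#' @return An object of class `BinnedTrack`.
#' @export
binned_track <- function(values, bin_size, chrom_lengths, value_kind) {
  value_kind <- match.arg(value_kind, .track_kinds)
  if (bin_size <= 0) stop("bin_size must be positive")
  if (is.null(names(values)) || is.null(names(chrom_lengths)))
    stop("values and chrom_lengths must be named by chromosome")
  if (!setequal(names(values), names(chrom_lengths)))
    stop("values and chrom_lengths name different chromosomes")
  chrom_lengths <- chrom_lengths[names(values)]
  for (chrom in names(values)) {
    expect <- n_bins_for(chrom_lengths[[chrom]], bin_size)
    if (length(values[[chrom]]) != expect)
      stop(sprintf("chromosome '%s': expected %d bins, got %d",
                   chrom, expect, length(values[[chrom]])))
  }
  structure(
    list(values = values, bin_size = as.integer(bin_size),
         chrom_lengths = chrom_lengths, value_kind = value_kind),
    class = "BinnedTrack")
}

#' @export
print.BinnedTrack <- function(x, ...) {
  cat(sprintf("BinnedTrack [%s]: %d chromosome(s), bin size %d bp, %d bins\n",
              x$value_kind, length(x$values), x$bin_size,
              sum(lengths(x$values))))
  invisible(x)
}

#' Bin centers of a track chromosome
#' @param track A `BinnedTrack`.
#' @param chrom Chromosome name.
#' @return Numeric vector of bin center coordinates (bp).
#' @export
bin_centers <- function(track, chrom) {
  (seq_along(track$values[[chrom]]) - 0.5) * track$bin_size
}

#' Constant-valued track over a genome
#' @param genome A `GenomeModel` (or named chromosome-length vector).
#' @param bin_size Bin width (bp); defaults to the genome's GC bin size.
#' @param value Fill value.
#' @param value_kind Track kind.
#' @return A `BinnedTrack`.
#' @export
constant_track <- function(genome, bin_size = NULL, value = 1,
                           value_kind = "rate") {
  lens <- if (inherits(genome, "GenomeModel")) genome$chrom_lengths else genome
  if (is.null(bin_size)) {
    if (!inherits(genome, "GenomeModel"))
      stop("bin_size required when genome is a length vector")
    bin_size <- genome$gc_track$bin_size
  }
  vals <- lapply(lens, function(L) rep(value, n_bins_for(L, bin_size)))
  binned_track(vals, bin_size, lens, value_kind)
}

stopifnot_aligned <- function(a, b) {
  if (a$bin_size != b$bin_size ||
      !identical(names(a$values), names(b$values)) ||
      !identical(lengths(a$values), lengths(b$values)))
    stop("tracks are not aligned (bin size or chromosome layout differs)")
}

#' Aggregate a track to coarser bins by averaging
#'
#' Groups every `factor` adjacent bins and averages them; the trailing
#' partial group of a chromosome is averaged over the bins it has.
#'
#' @param track A `BinnedTrack`.
#' @param factor Integer aggregation factor (>= 1).
#' @return A `BinnedTrack` with `bin_size * factor`.
#' @export
aggregate_track <- function(track, factor) {
  factor <- as.integer(factor)
  if (factor < 1) stop("factor must be >= 1")
  if (factor == 1) return(track)
  vals <- lapply(track$values, function(y) {
    g <- (seq_along(y) - 1L) %/% factor
    as.numeric(tapply(y, g, mean))
  })
  binned_track(vals, track$bin_size * factor, track$chrom_lengths,
               track$value_kind)
}

full_mask <- function(track) lapply(track$values, function(y) rep(TRUE, length(y)))

new_profile <- function(track, platform, mask = NULL, bandwidth = NA_real_,
                        pseudocount = NA_real_) {
  if (is.null(mask)) mask <- full_mask(track)
  if (!identical(lengths(mask), lengths(track$values)))
    stop("mask shape does not match track")
  bad <- mapply(function(v, m) any(!is.finite(v[m])), track$values, mask)
  if (any(bad))
    stop("non-finite enrichment values on masked-in bins")
  structure(list(track = track, platform = platform, mask = mask,
                 bandwidth = bandwidth, pseudocount = pseudocount),
            class = "EnrichmentProfile")
}

#' Wrap a track as an enrichment profile
#'
#' Convenience coercion so that plain tracks (e.g. the GC track) can be fed
#' to correlation, heatmap and meta-profile machinery.
#'
#' @param track A `BinnedTrack`.
#' @param mask Optional per-chromosome logical mask (default all in).
#' @param platform Platform tag.
#' @return An `EnrichmentProfile`.
#' @export
as_profile <- function(track, mask = NULL, platform = "track") {
  new_profile(track, platform, mask)
}

#' @export
print.EnrichmentProfile <- function(x, ...) {
  nin <- sum(unlist(x$mask))
  cat(sprintf(
    "EnrichmentProfile [%s]: bin size %d bp, %d/%d bins masked in\n",
    x$platform, x$track$bin_size, nin, sum(lengths(x$track$values))))
  invisible(x)
}

#' Masked-in values of a profile as one vector
#' @param profile An `EnrichmentProfile`.
#' @return Numeric vector of values at masked-in bins, chromosome order.
#' @export
profile_values <- function(profile) {
  unlist(mapply(function(v, m) v[m], profile$track$values, profile$mask,
                SIMPLIFY = FALSE), use.names = FALSE)
}

## Evaluate an expression with a temporarily seeded RNG, restoring the
## caller's RNG state afterwards so seeded stages compose deterministically.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else suppressWarnings(rm(".Random.seed", envir = env))
  })
  set.seed(seed)
  expr
}

#' Derive a child seed from a master seed
#'
#' A single experiment seed fans out to per-stage child seeds so stages can
#' be re-run independently yet reproducibly. Kept below 2^31.
#'
#' @param seed Master integer seed.
#' @param index Stage index (any non-negative integer).
#' @return Integer child seed.
#' @export
child_seed <- function(seed, index) {
  as.integer((as.double(seed) * 7919 + as.double(index) * 104729 + 1) %%
               2147483629)
}
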