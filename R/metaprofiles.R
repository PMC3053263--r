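## Strand-aware average signal profiles around transcription start and end
## sites, and the input-swap meta-profile experiment.

#' Filter genes by minimum length
#'
#' Genes of exactly `min_length` are retained (inclusive bound); the
#' default 2 kb excludes short genes whose TSS and TES windows overlap.
#'
#' @param genes A `GeneAnnotation` data frame (chrom, start, end, strand, id).
#' @param min_length Minimum gene length in bp.
#' @return The filtered `GeneAnnotation`.
#' @export
select_genes <- function(genes, min_length = 2000) {
  out <- genes[genes$end - genes$start >= min_length, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Anchor positions (TSS or TES) of a gene annotation
#'
#' The TSS of a + strand gene is its start and of a - strand gene its end;
#' the TES is the opposite.
#'
#' @param genes A `GeneAnnotation`.
#' @param anchor `"tss"` or `"tes"`.
#' @return Data frame with chrom, position, strand.
#' @export
anchor_sites <- function(genes, anchor = c("tss", "tes")) {
  anchor <- match.arg(anchor)
  plus <- genes$strand == "+"
  position <- if (anchor == "tss") ifelse(plus, genes$start, genes$end)
              else ifelse(plus, genes$end, genes$start)
  data.frame(chrom = genes$chrom, position = position,
             strand = genes$strand, stringsAsFactors = FALSE)
}

#' Average signal profile around anchor sites
#'
#' For each site the `2*flank/bin_size` flanking bin values are extracted
#' (80 bins of 50 bp for the defaults), reversed for - strand sites so that
#' position 1 is always upstream in the gene's own orientation, and
#' averaged per position over all sites with a usable (masked-in,
#' in-bounds) value there.
#'
#' @param profile An `EnrichmentProfile` (typically at 50 bp).
#' @param sites Data frame with chrom, position, strand (see
#'   [anchor_sites()]).
#' @param flank Flank size in bp on each side (default 2000).
#' @param anchor Label stored on the result.
#' @return A `MetaProfile`: `values` (one per window bin), `positions`
#'   (offsets of window-bin centers from the anchor), `n_sites`, `scaled`.
#' @export
average_profile <- function(profile, sites, flank = 2000, anchor = "tss") {
  bin <- profile$track$bin_size
  if ((2 * flank) %% bin != 0)
    stop("2*flank must be a multiple of the profile bin size")
  w <- as.integer(2 * flank / bin)
  sums <- numeric(w)
  counts <- numeric(w)
  n_sites <- 0L
  for (i in seq_len(nrow(sites))) {
    chrom <- sites$chrom[i]
    v <- profile$track$values[[chrom]]
    if (is.null(v)) next
    m <- profile$mask[[chrom]]
    base <- (sites$position[i] - flank) %/% bin
    idx <- base + seq_len(w)            # 1-based bin indices
    ok <- idx >= 1L & idx <= length(v)
    use <- ok
    use[ok] <- m[idx[ok]]
    val <- rep(NA_real_, w)
    val[use] <- v[idx[use]]
    if (identical(sites$strand[i], "-")) {
      val <- rev(val)
      use <- rev(use)
    }
    if (!any(use)) next
    n_sites <- n_sites + 1L
    sums[use] <- sums[use] + val[use]
    counts[use] <- counts[use] + 1
  }
  if (n_sites == 0) stop("no usable anchor sites")
  values <- ifelse(counts > 0, sums / counts, NA_real_)
  structure(list(anchor = anchor,
                 values = values,
                 positions = seq(-flank + bin / 2, flank - bin / 2, by = bin),
                 n_sites = n_sites, scaled = FALSE,
                 bin_size = bin, flank = flank),
            class = "MetaProfile")
}

#' @export
print.MetaProfile <- function(x, ...) {
  cat(sprintf("MetaProfile [%s]: %d bins of %d bp, %d sites%s\n",
              x$anchor, length(x$values), x$bin_size, x$n_sites,
              if (x$scaled) ", z-scaled" else ""))
  invisible(x)
}

#' Z-scale a meta-profile to mean 0 and unit variance
#'
#' @param p A `MetaProfile` with non-zero variance.
#' @return The scaled `MetaProfile` (`scaled = TRUE`).
#' @export
scale_profile <- function(p) {
  v <- p$values
  ok <- is.finite(v)
  s <- stats::sd(v[ok])
  if (!is.finite(s) || s == 0) stop("zero variance; cannot scale profile")
  p$values[ok] <- (v[ok] - mean(v[ok])) / s
  p$scaled <- TRUE
  p
}

#' Pearson correlation between two meta-profiles
#' @param a,b `MetaProfile`s over the same window layout.
#' @return Pearson's r over positions finite in both.
#' @export
metaprofile_correlation <- function(a, b) {
  ok <- is.finite(a$values) & is.finite(b$values)
  stats::cor(a$values[ok], b$values[ok])
}

#' Meta-profiles of one ChIP library under several input backgrounds
#'
#' Recomputes the 50 bp enrichment profile of the ChIP library once per
#' input library, builds the z-scaled meta-profile at the requested anchor
#' for each, and tabulates the pairwise Pearson correlations between the
#' meta-profiles and each one's correlation with the GC-content
#' meta-profile — the diagnostic for an input that fails to capture the
#' platform's GC bias.
#'
#' @param chip A `ReadSet`.
#' @param inputs Named list of `ReadSet`s.
#' @param genome A `GenomeModel`.
#' @param genes A `GeneAnnotation` (filtered with [select_genes()] first).
#' @param anchor `"tss"` or `"tes"`.
#' @param flank Flank in bp.
#' @param ... Further arguments to [seq_enrichment()].
#' @return List with `profiles` (named `MetaProfile`s), `gc_profile`,
#'   `cor` (pairwise matrix) and `gc_cor` (named correlations with the GC
#'   meta-profile).
#' @export
input_swap_metaprofile <- function(chip, inputs, genome, genes,
                                   anchor = "tss", flank = 2000, ...) {
  if (length(inputs) < 2) stop("need at least two input libraries")
  if (is.null(names(inputs)))
    names(inputs) <- paste0("input", seq_along(inputs))
  sites <- anchor_sites(genes, anchor)
  mps <- lapply(inputs, function(input) {
    prof <- seq_enrichment(chip, input, genome, ...)
    scale_profile(average_profile(prof, sites, flank = flank,
                                  anchor = anchor))
  })
  gc_mp <- scale_profile(average_profile(as_profile(genome$gc_track),
                                         sites, flank = flank,
                                         anchor = anchor))
  n <- length(mps)
  cm <- diag(1, n)
  dimnames(cm) <- list(names(mps), names(mps))
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    cm[i, j] <- cm[j, i] <- metaprofile_correlation(mps[[i]], mps[[j]])
  gc_cor <- vapply(mps, metaprofile_correlation, numeric(1), b = gc_mp)
  list(profiles = mps, gc_profile = gc_mp, cor = cm, gc_cor = gc_cor)
}
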