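## Plain-text readers and writers for the interchange formats the package
## consumes and emits: BED (reads, peaks, truth regions), bedGraph
## (tracks), TSV (probes), and BED6/GFF3 gene annotations. Validation
## errors name the offending line; numeric values are written with enough
## digits for lossless round-trips.

fmt_num <- function(x) sprintf("%.17g", x)

read_tsv_lines <- function(path, n_fields, what) {
  lines <- readLines(path)
  lines <- lines[!grepl("^(#|track|browser)", lines) & nzchar(lines)]
  if (length(lines) == 0)
    return(NULL)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < n_fields)
  if (length(bad))
    stop(sprintf("%s line %d: expected %d tab-separated fields, got %d",
                 what, bad[1], n_fields, lengths(parts)[bad[1]]))
  parts
}

#' Write a read set as 6-column BED
#'
#' Columns: chrom, start (stored position), end = start + read_length,
#' name ".", score 0, strand; 0-based half-open.
#'
#' @param reads A `ReadSet`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_reads_bed <- function(reads, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (chrom in names(reads$reads)) {
    r <- reads$reads[[chrom]]
    if (length(r$pos) == 0) next
    writeLines(paste(chrom, r$pos, r$pos + reads$read_length, ".", 0L,
                     r$strand, sep = "\t"), con)
  }
  invisible(path)
}

#' Read a read set from 6-column BED
#'
#' Intervals must be 0-based half-open with constant width (the read
#' length); malformed lines are rejected with their line number.
#'
#' @param path BED file.
#' @param chrom_lengths Named chromosome lengths; inferred from the largest
#'   end coordinate per chromosome when omitted.
#' @return A `ReadSet`.
#' @export
read_reads_bed <- function(path, chrom_lengths = NULL) {
  parts <- read_tsv_lines(path, 6, "BED")
  if (is.null(parts)) {
    if (is.null(chrom_lengths))
      return(read_set(list(), 0L, integer()))
    empty <- lapply(chrom_lengths, function(L)
      list(pos = integer(), strand = character()))
    return(read_set(empty, 0L, chrom_lengths))
  }
  chrom <- vapply(parts, `[`, character(1), 1)
  start <- suppressWarnings(as.integer(vapply(parts, `[`, character(1), 2)))
  end <- suppressWarnings(as.integer(vapply(parts, `[`, character(1), 3)))
  strand <- vapply(parts, `[`, character(1), 6)
  bad <- which(is.na(start) | is.na(end) | start < 0 | end <= start |
                 !strand %in% c("+", "-", "."))
  if (length(bad))
    stop(sprintf(
      "BED line %d: invalid interval or strand (need 0-based start < end)",
      bad[1]))
  widths <- unique(end - start)
  if (length(widths) != 1)
    stop("BED read intervals have differing widths; not a read set")
  if (is.null(chrom_lengths)) {
    chrom_lengths <- tapply(end, chrom, max)
    chrom_lengths <- stats::setNames(as.integer(chrom_lengths),
                                     names(chrom_lengths))
  }
  reads <- lapply(names(chrom_lengths), function(ch) {
    sel <- chrom == ch
    o <- order(start[sel])
    list(pos = start[sel][o], strand = strand[sel][o])
  })
  names(reads) <- names(chrom_lengths)
  read_set(reads, widths, chrom_lengths)
}

#' Write a binned track as bedGraph
#'
#' Fixed-step intervals of the track's bin size (the final interval of a
#' chromosome may be shorter); values are written with 17 significant
#' digits so round-trips are lossless.
#'
#' @param track A `BinnedTrack`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path) {
  con <- file(path, "w")
  on.exit(close(con))
  bin <- track$bin_size
  for (chrom in names(track$values)) {
    v <- track$values[[chrom]]
    start <- (seq_along(v) - 1L) * bin
    end <- pmin(start + bin, track$chrom_lengths[[chrom]])
    writeLines(paste(chrom, start, end, fmt_num(v), sep = "\t"), con)
  }
  invisible(path)
}

#' Read a fixed-step bedGraph into a binned track
#'
#' The step must equal the bin size on every chromosome (the final
#' interval may be partial); deviations and unknown chromosomes are
#' rejected by name.
#'
#' @param path bedGraph file.
#' @param genome Optional `GenomeModel`; chromosomes in the file must then
#'   exist in the genome and lengths are taken from it.
#' @param value_kind Track kind of the result.
#' @return A `BinnedTrack`.
#' @export
read_bedgraph <- function(path, genome = NULL, value_kind = "intensity") {
  parts <- read_tsv_lines(path, 4, "bedGraph")
  if (is.null(parts)) stop("empty bedGraph file")
  chrom <- vapply(parts, `[`, character(1), 1)
  start <- as.integer(vapply(parts, `[`, character(1), 2))
  end <- as.integer(vapply(parts, `[`, character(1), 3))
  value <- as.numeric(vapply(parts, `[`, character(1), 4))
  if (anyNA(start) || anyNA(end) || anyNA(value))
    stop("bedGraph contains non-numeric coordinates or values")
  if (!is.null(genome)) {
    unknown <- setdiff(unique(chrom), names(genome$chrom_lengths))
    if (length(unknown))
      stop(sprintf("bedGraph chromosome(s) not in genome: %s",
                   paste(unknown, collapse = ", ")))
  }
  chroms <- unique(chrom)
  steps <- unlist(lapply(chroms, function(ch) {
    w <- (end - start)[chrom == ch]
    if (length(w) > 1) w[-length(w)] else w
  }))
  bin <- unique(steps)
  if (length(bin) != 1)
    stop("bedGraph step size is not constant; cannot form a binned track")
  vals <- lapply(chroms, function(ch) value[chrom == ch])
  names(vals) <- chroms
  lens <- if (!is.null(genome)) genome$chrom_lengths[chroms]
          else stats::setNames(vapply(chroms, function(ch)
            max(end[chrom == ch]), integer(1)), chroms)
  binned_track(vals, bin, lens, value_kind)
}

#' Write a probe set as TSV
#' @param probes A `ProbeSet`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_probes_tsv <- function(probes, path) {
  df <- as.data.frame(probes)
  df$ip_intensity <- fmt_num(df$ip_intensity)
  df$input_intensity <- fmt_num(df$input_intensity)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a probe set from TSV
#' @param path TSV with columns chrom, start, end, probe_id, ip_intensity,
#'   input_intensity.
#' @return A `ProbeSet`.
#' @export
read_probes_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  need <- c("chrom", "start", "end", "probe_id", "ip_intensity",
            "input_intensity")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop(sprintf("probe TSV lacks column(s): %s",
                 paste(missing, collapse = ", ")))
  if (any(df$ip_intensity <= 0) || any(df$input_intensity <= 0))
    stop("probe intensities must be strictly positive")
  df <- df[order(df$chrom, df$start), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("ProbeSet", "data.frame")
  df
}

#' Write a peak set as BED6+4
#'
#' Columns: chrom, start, end, id, score (-log10 p, capped at 1000),
#' strand ".", then m, l, p, q.
#'
#' @param peaks A `PeakSet`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_peaks_bed <- function(peaks, path) {
  df <- peaks$peaks
  con <- file(path, "w")
  on.exit(close(con))
  if (nrow(df)) {
    score <- pmin(round(-log10(pmax(df$p, 1e-300)), 3), 1000)
    writeLines(paste(df$chrom, df$start, df$end,
                     sprintf("peak%05d", seq_len(nrow(df))), score, ".",
                     df$m, fmt_num(df$l), fmt_num(df$p), fmt_num(df$q),
                     sep = "\t"), con)
  }
  invisible(path)
}

#' Write a truth table of planted regions as BED
#'
#' The enrichment effect multiplier is stored in the score column.
#'
#' @param truth Data frame with chrom, start, end, effect, width_class.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_truth_bed <- function(truth, path) {
  con <- file(path, "w")
  on.exit(close(con))
  if (nrow(truth))
    writeLines(paste(truth$chrom, truth$start, truth$end,
                     truth$width_class, fmt_num(truth$effect), ".",
                     sep = "\t"), con)
  invisible(path)
}

#' Read a gene annotation from BED6 or GFF3
#'
#' BED6 files are parsed directly (chrom, start, end, id, score, strand);
#' `.gff`/`.gff3` files are imported with rtracklayer and gene-type records
#' are converted to 0-based half-open coordinates.
#'
#' @param path Annotation file.
#' @return A `GeneAnnotation` data frame.
#' @export
read_genes <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("gff", "gff3")) {
    if (!requireNamespace("rtracklayer", quietly = TRUE))
      stop("reading GFF3 requires the rtracklayer package")
    gr <- rtracklayer::import(path)
    if ("type" %in% names(S4Vectors::mcols(gr)) &&
        any(gr$type == "gene"))
      gr <- gr[gr$type == "gene"]
    df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                     start = GenomicRanges::start(gr) - 1L,
                     end = GenomicRanges::end(gr),
                     strand = as.character(GenomicRanges::strand(gr)),
                     id = if (!is.null(gr$ID)) as.character(gr$ID)
                          else sprintf("gene%04d", seq_along(gr)),
                     stringsAsFactors = FALSE)
  } else {
    parts <- read_tsv_lines(path, 6, "BED")
    if (is.null(parts))
      df <- data.frame(chrom = character(), start = integer(),
                       end = integer(), strand = character(),
                       id = character(), stringsAsFactors = FALSE)
    else
      df <- data.frame(
        chrom = vapply(parts, `[`, character(1), 1),
        start = as.integer(vapply(parts, `[`, character(1), 2)),
        end = as.integer(vapply(parts, `[`, character(1), 3)),
        strand = vapply(parts, `[`, character(1), 6),
        id = vapply(parts, `[`, character(1), 4),
        stringsAsFactors = FALSE)
  }
  bad <- which(df$start >= df$end | !df$strand %in% c("+", "-"))
  if (length(bad))
    stop(sprintf("gene annotation record %d: start >= end or bad strand",
                 bad[1]))
  class(df) <- c("GeneAnnotation", "data.frame")
  df
}

#' Write a gene annotation as BED6
#' @param genes A `GeneAnnotation`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_genes_bed <- function(genes, path) {
  con <- file(path, "w")
  on.exit(close(con))
  if (nrow(genes))
    writeLines(paste(genes$chrom, genes$start, genes$end, genes$id, 0L,
                     genes$strand, sep = "\t"), con)
  invisible(path)
}

#' Write a meta-profile as TSV (offset, value)
#' @param mp A `MetaProfile`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_metaprofile_tsv <- function(mp, path) {
  utils::write.table(
    data.frame(offset = mp$positions, value = fmt_num(mp$values)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
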