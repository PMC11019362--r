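## genome_tracks: 1-Mbp bin tracks of accessibility, expression and
## mutational load.

#' Tile a genome into fixed-size bins
#'
#' @param seqlengths Named integer vector of contig lengths (or a reference
#'   accepted by [read_somatic_vcf()]'s `reference` argument).
#' @param bin_size Bin width in bp (default 1 Mbp). The last bin of each
#'   contig may be short.
#' @return A `bin_track` `data.frame` with columns `chrom`, `bin_index`
#'   (1-based, per chromosome), `start`, `end` (1-based, inclusive) and
#'   `value` initialised to 0.
#' @export
make_bins <- function(seqlengths, bin_size = 1e6) {
  if (!is.numeric(seqlengths)) seqlengths <- ref_seqlengths(seqlengths)
  if (is.null(names(seqlengths)) || any(!nzchar(names(seqlengths))))
    stopf("`seqlengths` must be named by contig")
  bin_size <- as.integer(bin_size)
  pieces <- lapply(names(seqlengths), function(ch) {
    len <- as.integer(seqlengths[[ch]])
    n <- max(1L, as.integer(ceiling(len / bin_size)))
    start <- (seq_len(n) - 1L) * bin_size + 1L
    data.frame(chrom = ch, bin_index = seq_len(n), start = start,
               end = pmin(start + bin_size - 1L, len), value = 0,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  attr(out, "bin_size") <- bin_size
  class(out) <- c("bin_track", "data.frame")
  out
}

#' Centered moving average with truncated windows
#'
#' A moving mean of odd window `k`; at sequence ends the window is
#' truncated rather than padded, so every position keeps a defined value.
#'
#' @param x Numeric vector.
#' @param k Odd window size (`k = 1` is the identity).
#' @return Numeric vector of `length(x)`.
#' @export
moving_average <- function(x, k = 3) {
  if (k %% 2 == 0 || k < 1) stopf("`k` must be an odd integer >= 1")
  n <- length(x)
  if (n == 0L || k == 1) return(x)
  h <- (k - 1) %/% 2
  cs <- cumsum(c(0, x))
  i <- seq_len(n)
  lo <- pmax(1L, i - h)
  hi <- pmin(n, i + h)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Bin a signal at fixed width and smooth it
#'
#' Aggregates a signal into genome bins and applies a centered moving
#' average per chromosome. For a `peak_set` (see [read_narrowpeak()]) the
#' `signalValue` mass of each peak is apportioned to the bins it overlaps
#' in proportion to the overlap length. Alternatively a per-bin count table
#' (`chrom`, `start`, `end`, `value`, matching the bin geometry) may be
#' supplied, e.g. read-count summaries for expression tracks.
#'
#' @param signal A `peak_set` or a per-bin value `data.frame`.
#' @param bins A `bin_track` giving the bin geometry (see [make_bins()]).
#' @param k Odd moving-average window in bins (default 3).
#' @return A `bin_track` with smoothed values.
#' @export
bin_and_smooth <- function(signal, bins, k = 3) {
  if (k %% 2 == 0 || k < 1) stopf("`k` must be an odd integer >= 1")
  out <- bins
  out$value <- 0
  if (inherits(signal, "peak_set")) {
    if (nrow(signal)) {
      ## narrowPeak is 0-based half-open; bins are 1-based inclusive
      pk <- GenomicRanges::GRanges(signal$chrom,
                                   IRanges::IRanges(signal$start + 1L, signal$end))
      bn <- GenomicRanges::GRanges(bins$chrom,
                                   IRanges::IRanges(bins$start, bins$end))
      ov <- GenomicRanges::findOverlaps(pk, bn)
      if (length(ov)) {
        qi <- S4Vectors::queryHits(ov)
        si <- S4Vectors::subjectHits(ov)
        wov <- GenomicRanges::width(GenomicRanges::pintersect(pk[qi], bn[si]))
        mass <- signal$signalValue[qi] * wov / GenomicRanges::width(pk)[qi]
        agg <- rowsum(mass, si)
        out$value[as.integer(rownames(agg))] <- agg[, 1]
      }
    }
  } else if (is.data.frame(signal)) {
    if (!all(c("chrom", "start", "value") %in% names(signal)))
      stopf("per-bin signal must have columns chrom, start, end, value")
    key_bins <- paste(out$chrom, out$start)
    key_sig <- paste(signal$chrom, signal$start)
    m <- match(key_sig, key_bins)
    if (anyNA(m)) stopf("per-bin signal rows do not match the bin geometry")
    out$value[m] <- signal$value
  } else {
    stopf("`signal` must be a peak_set or a per-bin data.frame")
  }
  out$value <- unlist(lapply(split(out$value, factor(out$chrom, unique(out$chrom))),
                             moving_average, k = k), use.names = FALSE)
  out
}

#' Z-score a bin track per chromosome
#'
#' Centers and scales `value` within each chromosome using the mean and
#' the population standard deviation. Chromosomes with zero variance are
#' set to 0.
#'
#' @param track A `bin_track`.
#' @return The track with normalized values.
#' @export
normalize_chromosome <- function(track) {
  stopifnot(is.data.frame(track), all(c("chrom", "value") %in% names(track)))
  f <- factor(track$chrom, unique(track$chrom))
  if (any(tabulate(f) < 2L)) stopf("each chromosome needs >= 2 bins")
  zs <- lapply(split(track$value, f), function(v) {
    mu <- mean(v)
    sdev <- sqrt(mean((v - mu)^2))
    if (sdev == 0) rep(0, length(v)) else (v - mu) / sdev
  })
  track$value <- unlist(zs, use.names = FALSE)
  track
}

#' Combine four histone-mark tracks into a DNA accessibility track
#'
#' The sum of the four per-chromosome z-scored ChIP-seq signals
#' (H3K4me1, H3K4me3, H3K36me3, H3K27ac) approximates DNA accessibility.
#' Bins above the genome-wide median are labelled open chromatin
#' (`high`); ties at the median are labelled `low`. Bins are also assigned
#' to genome-wide deciles (ties resolved to the lower decile).
#'
#' @param marks A list of 4 normalized `bin_track`s with identical binning.
#' @return An `accessibility_track` `data.frame` with columns `chrom`,
#'   `bin_index`, `start`, `end`, `value`, `label`, `decile`.
#' @export
build_accessibility <- function(marks) {
  if (!is.list(marks) || length(marks) < 2L)
    stopf("`marks` must be a list of normalized bin tracks")
  geom <- function(t) paste(t$chrom, t$start, t$end)
  g0 <- geom(marks[[1]])
  for (m in marks[-1]) {
    if (nrow(m) != nrow(marks[[1]]) || !identical(geom(m), g0))
      stopf("all marks must share an identical bin geometry")
  }
  out <- marks[[1]][, c("chrom", "bin_index", "start", "end")]
  out$value <- Reduce(`+`, lapply(marks, `[[`, "value"))
  out$label <- ifelse(out$value > stats::median(out$value), "high", "low")
  out$decile <- assign_deciles(out$value)
  attr(out, "bin_size") <- attr(marks[[1]], "bin_size")
  class(out) <- c("accessibility_track", "bin_track", "data.frame")
  out
}

#' Assign genome-wide deciles
#'
#' Decile `d` contains values in the d-th genome-wide 10-percentile
#' interval; values tied with a boundary fall in the lower decile.
#'
#' @param value Numeric vector.
#' @return Integer vector in 1..10.
#' @export
assign_deciles <- function(value) {
  b <- stats::quantile(value, probs = seq(0.1, 0.9, by = 0.1), names = FALSE)
  findInterval(value, b, left.open = TRUE) + 1L
}

#' Mean SNVs per Mbp across a cohort
#'
#' Counts SNVs per bin and sample, averages over the cohort, and smooths
#' the per-chromosome profile with a centered moving average. Mutations can
#' be stratified into the APOBEC-like TpC context and its complement using
#' the `is_tpc` annotation (see [extract_context()]).
#'
#' @param mutations Mutation `data.frame`; for context stratification it
#'   must carry a logical `is_tpc` column.
#' @param bins Bin geometry from [make_bins()].
#' @param stratify `"all"`, `"TpC"` or `"nonTpC"`.
#' @param k Odd smoothing window in bins (default 3).
#' @return A `bin_track` of mean SNVs per bin.
#' @export
mutational_load <- function(mutations, bins, stratify = c("all", "TpC", "nonTpC"),
                            k = 3) {
  stratify <- match.arg(stratify)
  if (nrow(mutations) == 0L) stopf("empty cohort")
  n_samples <- length(unique(mutations$sample_id))
  if (stratify != "all") {
    if (!"is_tpc" %in% names(mutations))
      stopf("context stratification needs an `is_tpc` column")
    keep <- if (stratify == "TpC") mutations$is_tpc else !mutations$is_tpc
    mutations <- mutations[keep, , drop = FALSE]
  }
  out <- bins
  out$value <- 0
  if (nrow(mutations)) {
    mu <- GenomicRanges::GRanges(mutations$chrom,
                                 IRanges::IRanges(mutations$pos, mutations$pos))
    bn <- GenomicRanges::GRanges(bins$chrom, IRanges::IRanges(bins$start, bins$end))
    hit <- GenomicRanges::findOverlaps(mu, bn, select = "first")
    cnt <- tabulate(hit[!is.na(hit)], nbins = nrow(bins))
    out$value <- cnt / n_samples
  }
  out$value <- unlist(lapply(split(out$value, factor(out$chrom, unique(out$chrom))),
                             moving_average, k = k), use.names = FALSE)
  out
}

#' Build an expression track from per-bin read counts
#'
#' Ingests a per-1-Mbp read-count table (as produced by standard BAM
#' summarisation tools), smooths it, z-scores it per chromosome and labels
#' bins above the genome-wide median as highly expressed.
#'
#' @param counts Per-bin count `data.frame` (`chrom`, `start`, `end`,
#'   `value` = mean raw read count).
#' @param bins Bin geometry from [make_bins()].
#' @param k Odd smoothing window (default 3).
#' @return A `bin_track` with a `label` column (`high`/`low`).
#' @export
build_expression <- function(counts, bins, k = 3) {
  tr <- bin_and_smooth(counts, bins, k = k)
  tr <- normalize_chromosome(tr)
  tr$label <- ifelse(tr$value > stats::median(tr$value), "high", "low")
  tr
}

#' Read a per-bin read-count TSV
#'
#' Ingests the per-1-Mbp read-count tables produced by standard BAM
#' summarisation tools: a tab-separated file with header columns `chrom`,
#' `start` (0-based), `end` and `value` (mean raw read count).
#'
#' @param path Input TSV path.
#' @return A `data.frame` with 1-based `start` coordinates, suitable for
#'   [bin_and_smooth()] / [build_expression()].
#' @export
read_bin_counts <- function(path) {
  if (!file.exists(path)) stopf("count table not found: %s", path)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("chrom", "start", "end", "value")
  if (!all(need %in% names(df)))
    stopf("count table needs columns: %s", paste(need, collapse = ", "))
  df$start <- as.integer(df$start) + 1L
  df
}

#' Export a bin track as a BED-like TSV
#'
#' Writes `chrom`, 0-based `start`, `end` and the value columns (plus
#' `label`/`decile` when present).
#'
#' @param track A `bin_track`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bin_track <- function(track, path) {
  df <- data.frame(chrom = track$chrom, start = track$start - 1L,
                   end = track$end, value = track$value,
                   stringsAsFactors = FALSE)
  for (col in c("label", "decile")) if (col %in% names(track)) df[[col]] <- track[[col]]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
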