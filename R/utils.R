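## Internal helpers shared across modules.

`%||%` <- function(x, y) if (is.null(x)) y else x

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

#' Evaluate an expression with a fixed RNG seed
#'
#' Runs `code` after `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so that deterministic generators do not perturb the global
#' random stream.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stopf("`seed` must be a single non-missing number")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

## Derive a child seed from a base seed; kept below 2^31 - 1.
child_seed <- function(seed, k) {
  as.integer((as.double(seed) * 1000003 + k * 7919) %% 2147483562L) + 1L
}

BASES <- c("A", "C", "G", "T")
COMP <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

## Reverse complement of a plain character string (ACGTN).
revcomp_chr <- function(x) {
  vapply(x, function(s) {
    if (is.na(s)) return(NA_character_)
    paste(rev(unname(COMP[strsplit(s, "")[[1]]])), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

is_wc_pair <- function(a, b) {
  (a == "A" & b == "T") | (a == "T" & b == "A") |
    (a == "C" & b == "G") | (a == "G" & b == "C")
}

## Normalize chromosome names to one dialect.
norm_chrom <- function(x, style = c("keep", "strip", "add")) {
  style <- match.arg(style)
  x <- as.character(x)
  if (style == "strip") sub("^chr", "", x)
  else if (style == "add") ifelse(grepl("^chr", x), x, paste0("chr", x))
  else x
}

## Resolve a reference argument into an object getSeq()/seqlengths can use.
## Accepts a path to an indexed FASTA, an Rsamtools::FaFile, or a
## Biostrings::DNAStringSet.
resolve_reference <- function(reference) {
  if (is.character(reference) && length(reference) == 1L) {
    if (!file.exists(reference)) stopf("reference FASTA not found: %s", reference)
    if (!file.exists(paste0(reference, ".fai"))) Rsamtools::indexFa(reference)
    return(Rsamtools::FaFile(reference))
  }
  if (inherits(reference, "FaFile") || inherits(reference, "DNAStringSet"))
    return(reference)
  stopf("`reference` must be a FASTA path, FaFile or DNAStringSet")
}

ref_seqlengths <- function(reference) {
  reference <- resolve_reference(reference)
  if (inherits(reference, "DNAStringSet")) {
    stats::setNames(Biostrings::width(reference), names(reference))
  } else {
    info <- Rsamtools::seqinfo(reference)
    stats::setNames(GenomeInfoDb::seqlengths(info), GenomeInfoDb::seqnames(info))
  }
}

## Fetch [start, end] (1-based, clipped to the contig) as a character string.
ref_window <- function(reference, chrom, start, end) {
  reference <- resolve_reference(reference)
  sl <- ref_seqlengths(reference)
  if (!chrom %in% names(sl)) stopf("contig '%s' not present in reference", chrom)
  start <- max(1L, as.integer(start))
  end <- min(as.integer(sl[[chrom]]), as.integer(end))
  if (start > end) return("")
  if (inherits(reference, "DNAStringSet")) {
    as.character(Biostrings::subseq(reference[[chrom]], start, end))
  } else {
    gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start, end))
    as.character(Biostrings::getSeq(reference, gr)[[1]])
  }
}
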