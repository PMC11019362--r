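## variant_io: somatic SNV ingest, mutation contexts, narrowPeak ingest.

MUTATION_COLS <- c("sample_id", "chrom", "pos", "ref", "alt",
                   "alt_reads", "depth", "tumor_cn", "normal_cn")

#' Assemble and validate a mutation table
#'
#' The internal representation of somatic SNVs is a plain `data.frame` with
#' columns `sample_id`, `chrom`, `pos` (1-based), `ref`, `alt` (single
#' bases), `alt_reads`, `depth`, `tumor_cn` (local tumor copy number) and
#' `normal_cn` (2 for autosomes, 1 for allosomes).
#'
#' @param sample_id,chrom,pos,ref,alt,alt_reads,depth,tumor_cn,normal_cn
#'   Column vectors, recycled to a common length.
#' @return A validated mutation `data.frame`.
#' @export
mutation_table <- function(sample_id, chrom, pos, ref, alt,
                           alt_reads = NA_integer_, depth = NA_integer_,
                           tumor_cn = NA_real_, normal_cn = 2) {
  df <- data.frame(sample_id = as.character(sample_id),
                   chrom = as.character(chrom),
                   pos = as.integer(pos),
                   ref = toupper(as.character(ref)),
                   alt = toupper(as.character(alt)),
                   alt_reads = as.integer(alt_reads),
                   depth = as.integer(depth),
                   tumor_cn = as.numeric(tumor_cn),
                   normal_cn = as.numeric(normal_cn),
                   stringsAsFactors = FALSE)
  validate_mutations(df)
}

#' Validate a mutation table against its invariants
#'
#' Checks single-base ref/alt, `ref != alt`, `pos >= 1`, and
#' `alt_reads <= depth` where read counts are present.
#'
#' @param mutations A mutation `data.frame` (see [mutation_table()]).
#' @return The input, invisibly validated (returned unchanged).
#' @export
validate_mutations <- function(mutations) {
  missing_cols <- setdiff(MUTATION_COLS, names(mutations))
  if (length(missing_cols))
    stopf("mutation table lacks columns: %s", paste(missing_cols, collapse = ", "))
  if (nrow(mutations) == 0L) return(mutations)
  if (!all(mutations$ref %in% BASES) || !all(mutations$alt %in% BASES))
    stopf("ref/alt must be single bases A/C/G/T")
  if (any(mutations$ref == mutations$alt))
    stopf("ref and alt must differ")
  if (any(mutations$pos < 1L))
    stopf("positions must be >= 1")
  has_reads <- !is.na(mutations$alt_reads) & !is.na(mutations$depth)
  if (any(has_reads & (mutations$depth < 1L |
                       mutations$alt_reads > mutations$depth |
                       mutations$alt_reads < 0L)))
    stopf("read counts must satisfy 0 <= alt_reads <= depth, depth >= 1")
  mutations
}

#' Read somatic SNVs from a VCF file
#'
#' Reads a VCF 4.x file and returns biallelic SNVs as a mutation table.
#' Multi-allelic records, indels and MNVs are skipped (with a message
#' giving the count). Variant read support is taken from per-sample
#' `AD`/`DP` FORMAT fields by default; both field names are configurable
#' because callers differ in their FORMAT conventions.
#'
#' @param path Path to a VCF (optionally bgzipped).
#' @param sample_id Sample column to read; defaults to the first genotype
#'   column. Also used as the `sample_id` of the returned records.
#' @param cn_table Optional copy-number segment table with columns
#'   `chrom`, `start`, `end` (1-based, inclusive) and `cn`; each mutation's
#'   `tumor_cn` is looked up by interval overlap. Mutations outside every
#'   segment get `sample_ploidy` when given, otherwise `NA`.
#' @param sample_ploidy Fallback tumor copy number for unsegmented sites.
#' @param ad_field,dp_field FORMAT field names for allelic depths and total
#'   depth.
#' @param chrom_style One of `"keep"`, `"strip"`, `"add"`: normalisation of
#'   the `chr` prefix on contig names.
#' @param reference Optional reference (FASTA path, `FaFile` or
#'   `DNAStringSet`); records on contigs absent from it are dropped with a
#'   message giving the count.
#' @return A mutation `data.frame` (see [mutation_table()]).
#' @export
read_somatic_vcf <- function(path, sample_id = NULL, cn_table = NULL,
                             sample_ploidy = NULL,
                             ad_field = "AD", dp_field = "DP",
                             chrom_style = "keep", reference = NULL) {
  if (!file.exists(path)) stopf("VCF file not found: %s", path)
  vcf <- suppressWarnings(vcfR::read.vcfR(path, verbose = FALSE))
  fix <- as.data.frame(vcfR::getFIX(vcf), stringsAsFactors = FALSE)
  if (nrow(fix) == 0L) {
    return(data.frame(sample_id = character(), chrom = character(),
                      pos = integer(), ref = character(), alt = character(),
                      alt_reads = integer(), depth = integer(),
                      tumor_cn = numeric(), normal_cn = numeric(),
                      stringsAsFactors = FALSE))
  }
  ref <- toupper(fix$REF)
  alt <- toupper(fix$ALT)
  is_snv <- !is.na(alt) & nchar(ref) == 1L & nchar(alt) == 1L &
    ref %in% BASES & alt %in% BASES
  n_skip <- sum(!is_snv)
  if (n_skip > 0L)
    message(sprintf("read_somatic_vcf: skipped %d non-SNV/multi-allelic record(s)", n_skip))

  gt_samples <- colnames(vcf@gt)[-1]
  if (is.null(sample_id)) {
    if (length(gt_samples) == 0L) stopf("VCF has no genotype columns")
    sample_id <- gt_samples[1]
  }
  alt_reads <- rep(NA_integer_, nrow(fix))
  depth <- rep(NA_integer_, nrow(fix))
  if (sample_id %in% gt_samples) {
    ad <- tryCatch(vcfR::extract.gt(vcf, element = ad_field)[, sample_id],
                   error = function(e) rep(NA_character_, nrow(fix)))
    dp <- tryCatch(vcfR::extract.gt(vcf, element = dp_field)[, sample_id],
                   error = function(e) rep(NA_character_, nrow(fix)))
    ad_split <- strsplit(ad, ",", fixed = TRUE)
    alt_reads <- vapply(ad_split, function(x) {
      if (length(x) >= 2L) suppressWarnings(as.integer(x[2])) else NA_integer_
    }, integer(1))
    depth <- suppressWarnings(as.integer(dp))
    ## fall back to the AD sum when DP is absent
    depth_ad <- vapply(ad_split, function(x) {
      v <- suppressWarnings(as.integer(x))
      if (all(is.na(v))) NA_integer_ else as.integer(sum(v, na.rm = TRUE))
    }, integer(1))
    depth <- ifelse(is.na(depth), depth_ad, depth)
  }

  chrom <- norm_chrom(fix$CHROM, chrom_style)
  keep <- is_snv
  if (!is.null(reference)) {
    sl <- ref_seqlengths(reference)
    on_ref <- chrom %in% names(sl)
    n_off <- sum(keep & !on_ref)
    if (n_off > 0L)
      message(sprintf("read_somatic_vcf: dropped %d record(s) on contigs absent from the reference", n_off))
    keep <- keep & on_ref
  }

  out <- data.frame(sample_id = sample_id,
                    chrom = chrom[keep],
                    pos = as.integer(fix$POS[keep]),
                    ref = ref[keep],
                    alt = alt[keep],
                    alt_reads = alt_reads[keep],
                    depth = depth[keep],
                    tumor_cn = NA_real_,
                    normal_cn = 2,
                    stringsAsFactors = FALSE)
  out$normal_cn <- ifelse(sub("^chr", "", out$chrom) %in% c("X", "Y"), 1, 2)
  if (!is.null(cn_table)) {
    out$tumor_cn <- lookup_segment_cn(out$chrom, out$pos, cn_table,
                                      default = sample_ploidy %||% NA_real_)
  } else if (!is.null(sample_ploidy)) {
    out$tumor_cn <- as.numeric(sample_ploidy)
  }
  validate_mutations(out)
}

## Interval lookup of per-segment copy number.
lookup_segment_cn <- function(chrom, pos, cn_table, default = NA_real_) {
  stopifnot(all(c("chrom", "start", "end", "cn") %in% names(cn_table)))
  q <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos, pos))
  s <- GenomicRanges::GRanges(cn_table$chrom,
                              IRanges::IRanges(cn_table$start, cn_table$end))
  hit <- GenomicRanges::findOverlaps(q, s, select = "first")
  out <- rep(as.numeric(default), length(pos))
  ok <- !is.na(hit)
  out[ok] <- cn_table$cn[hit[ok]]
  out
}

#' Write / read the internal mutation TSV dialect
#'
#' A tab-separated file with header columns `sample_id chrom pos ref alt
#' alt_reads depth tumor_cn normal_cn`. Round-trips losslessly through
#' [read_mutation_tsv()].
#'
#' @param mutations A mutation `data.frame`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_mutation_tsv <- function(mutations, path) {
  validate_mutations(mutations)
  utils::write.table(mutations[, MUTATION_COLS], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_mutation_tsv
#' @export
read_mutation_tsv <- function(path) {
  if (!file.exists(path)) stopf("mutation TSV not found: %s", path)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          colClasses = c(sample_id = "character",
                                         chrom = "character", pos = "integer",
                                         ref = "character", alt = "character",
                                         alt_reads = "integer", depth = "integer",
                                         tumor_cn = "numeric", normal_cn = "numeric"),
                          stringsAsFactors = FALSE)
  validate_mutations(df)
}

#' Extract the pyrimidine-normalized mutation context
#'
#' Returns, for each mutated site, the trinucleotide context on the strand
#' where the mutated base is a pyrimidine (the convention of mutational
#' signature analysis), the tetranucleotide frame used for APOBEC3A/3B
#' attribution (the 4-mer ending one base 3' of the mutated C, so that
#' YTCA/RTCA have the mutated C in third position), whether the site is in
#' a TpC context, and whether the strand was flipped.
#'
#' @param reference Reference genome (FASTA path, `FaFile` or
#'   `DNAStringSet`).
#' @param chrom,pos,ref Vectors describing the mutated sites; `ref` must
#'   match the reference base at `pos`.
#' @param alt Alternate bases (accepted for a complete site description;
#'   the context depends only on the reference strand).
#' @return A `data.frame` with columns `trinucleotide`, `tetranucleotide`,
#'   `is_tpc`, `strand_flipped`.
#' @export
extract_context <- function(reference, chrom, pos, ref, alt = NA) {
  reference <- resolve_reference(reference)
  sl <- ref_seqlengths(reference)
  n <- length(pos)
  chrom <- rep_len(as.character(chrom), n)
  ref <- rep_len(toupper(ref), n)
  out <- data.frame(trinucleotide = character(n), tetranucleotide = NA_character_,
                    is_tpc = logical(n), strand_flipped = logical(n),
                    stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    if (!chrom[i] %in% names(sl))
      stopf("contig '%s' not present in reference", chrom[i])
    clen <- sl[[chrom[i]]]
    if (pos[i] <= 1L || pos[i] >= clen)
      stopf("context unavailable: %s:%d is within 1 base of the contig end",
            chrom[i], pos[i])
    win <- ref_window(reference, chrom[i], pos[i] - 2L, pos[i] + 2L)
    ## index of the mutated base inside the (possibly clipped) window
    off <- pos[i] - max(1L, pos[i] - 2L) + 1L
    wchars <- strsplit(win, "")[[1]]
    if (wchars[off] != ref[i])
      stopf("reference mismatch at %s:%d: expected %s, found %s",
            chrom[i], pos[i], wchars[off], ref[i])
    flip <- ref[i] %in% c("G", "A")
    if (!flip) {
      tri <- paste(wchars[(off - 1L):(off + 1L)], collapse = "")
      tetra <- if (off - 2L >= 1L)
        paste(wchars[(off - 2L):(off + 1L)], collapse = "") else NA_character_
    } else {
      tri <- revcomp_chr(paste(wchars[(off - 1L):(off + 1L)], collapse = ""))
      tetra <- if (off + 2L <= length(wchars))
        revcomp_chr(paste(wchars[(off - 1L):(off + 2L)], collapse = "")) else NA_character_
    }
    out$trinucleotide[i] <- tri
    out$tetranucleotide[i] <- tetra
    out$is_tpc[i] <- substr(tri, 1L, 1L) == "T" & substr(tri, 2L, 2L) == "C"
    out$strand_flipped[i] <- flip
  }
  out
}

#' Read an ENCODE narrowPeak file
#'
#' Reads a BED6+4 narrowPeak file and keeps peaks passing the q-value
#' filter: column 9 holds -log10(q) and a peak is retained when
#' `q < q_threshold`. Records with the q column set to `-1` (q-value not
#' available) are dropped and counted in the `n_dropped_na_q` attribute.
#'
#' @param path Path to a narrowPeak file (plain text).
#' @param q_threshold Maximum q-value to retain a peak (default 0.05).
#' @param chrom_style Contig-name normalisation, see [read_somatic_vcf()].
#' @return A `data.frame` of class `peak_set` with 0-based half-open
#'   `start`/`end` coordinates and columns `signalValue`, `pValue`,
#'   `qValue` (-log10 scale) and `peak`.
#' @export
read_narrowpeak <- function(path, q_threshold = 0.05, chrom_style = "keep") {
  if (!file.exists(path)) stopf("narrowPeak file not found: %s", path)
  nf <- utils::count.fields(path, sep = "\t", quote = "")
  if (length(nf) && any(nf != 10L)) {
    bad <- which(nf != 10L)[1]
    stopf("narrowPeak format error at line %d: expected 10 tab-separated columns, found %d",
          bad, nf[bad])
  }
  cols <- c("chrom", "start", "end", "name", "score", "strand",
            "signalValue", "pValue", "qValue", "peak")
  df <- utils::read.table(path, sep = "\t", quote = "", comment.char = "",
                          col.names = cols, stringsAsFactors = FALSE)
  df$chrom <- norm_chrom(df$chrom, chrom_style)
  if (any(df$start >= df$end))
    stopf("narrowPeak format error: start must be < end")
  na_q <- df$qValue < 0
  df <- df[!na_q & df$qValue > -log10(q_threshold), , drop = FALSE]
  rownames(df) <- NULL
  attr(df, "n_dropped_na_q") <- sum(na_q)
  attr(df, "q_threshold") <- q_threshold
  class(df) <- c("peak_set", "data.frame")
  df
}

#' Write a minimal somatic VCF (fixture helper)
#'
#' Serialises a mutation table as a small VCF 4.2 file with per-sample
#' `AD`/`DP` FORMAT fields. Intended for generating test fixtures and round
#' trips with [read_somatic_vcf()]; one file per sample.
#'
#' @param mutations Mutation `data.frame` for a single sample.
#' @param path Output path (plain text).
#' @return `path`, invisibly.
#' @export
write_somatic_vcf <- function(mutations, path) {
  validate_mutations(mutations)
  if (length(unique(mutations$sample_id)) > 1L)
    stopf("write_somatic_vcf writes one sample per file")
  sid <- if (nrow(mutations)) mutations$sample_id[1] else "SAMPLE"
  hdr <- c("##fileformat=VCFv4.2",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
           "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
           paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
                 "FORMAT", sid, sep = "\t"))
  body <- character(0)
  if (nrow(mutations)) {
    ref_reads <- ifelse(is.na(mutations$depth) | is.na(mutations$alt_reads),
                        ".", mutations$depth - mutations$alt_reads)
    ad <- ifelse(ref_reads == ".", ".",
                 paste0(ref_reads, ",", mutations$alt_reads))
    dp <- ifelse(is.na(mutations$depth), ".", mutations$depth)
    body <- paste(mutations$chrom, mutations$pos, ".", mutations$ref,
                  mutations$alt, ".", "PASS", ".", "GT:AD:DP",
                  paste0("0/1:", ad, ":", dp), sep = "\t")
  }
  writeLines(c(hdr, body), path)
  invisible(path)
}
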