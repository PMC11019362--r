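## Shared fixtures, built in code at test time.

## Small random reference genome, deterministic.
fixture_reference <- local({
  ref <- NULL
  function() {
    if (is.null(ref)) ref <<- simulate_reference(c(chr1 = 20000, chr2 = 12000),
                                                 seed = 421)
    ref
  }
})

## A deterministic APOBEC-like cohort on the fixture reference.
fixture_cohort <- local({
  m <- NULL
  function() {
    if (is.null(m)) m <<- simulate_apobec_cohort(fixture_reference(),
                                                 n_samples = 4,
                                                 muts_per_sample = 120,
                                                 tcw_fraction = 0.75,
                                                 seed = 99)
    m
  }
})

## Reference with an embedded perfect hairpin whose loop TCAAC carries a
## didymi pair (TpC at loop index 1, ApC at index 4).
didymi_reference <- function() {
  left <- "ATTATAGGAAATTAAGCCGG"
  loop <- "TCAAC"
  right <- "CCGGCTTAATAAATTAGGAT"
  seqc <- paste0(strrep("ACGTAGGTCA", 6), left, loop, right,
                 strrep("TGCATCAGGT", 6))
  list(ref = Biostrings::DNAStringSet(c(chr1 = seqc)),
       pos_tpc = 60L + nchar(left) + 2L,   # C at loop index 1
       pos_apc = 60L + nchar(left) + 5L)   # C at loop index 4
}

## Cohort mutated at the didymi positions (3 + 2 tumors, C>T).
didymi_cohort <- function(fix = didymi_reference()) {
  mutation_table(sample_id = c("a", "b", "c", "a", "b"),
                 chrom = "chr1",
                 pos = c(rep(fix$pos_tpc, 3), rep(fix$pos_apc, 2)),
                 ref = "C", alt = "T", alt_reads = 5, depth = 10)
}

## Minimal narrowPeak writer.
write_peaks <- function(path, chrom, start, end, signal, qlog) {
  writeLines(paste(chrom, start, end, "peak", 0, ".", signal, qlog + 1,
                   qlog, as.integer((end - start) / 2), sep = "\t"), path)
  path
}

## Uniform random 41-nt windows for hairpin property tests.
random_windows <- function(n, width = 41L, seed = 1L) {
  apohm:::with_seed(seed, {
    vapply(seq_len(n), function(i)
      paste(sample(c("A", "C", "G", "T"), width, replace = TRUE),
            collapse = ""), character(1))
  })
}

## Synthetic driver-model catalog with counts drawn from a stated Poisson
## GLM (lambda = exp(b0 + b_decile * decile [+ b_dg * dG + b_lp * flag])).
glm_catalog <- function(n, group = c("outside_loop", "in_loop"),
                        b0 = 1.6, b_decile = 0.12, b_dg = 0, b_lp = 0,
                        seed = 1L, min_count = 2L) {
  group <- match.arg(group)
  apohm:::with_seed(seed, {
    dec <- sample(1:10, n, replace = TRUE)
    tri <- sample(c("TCA", "TCT", "TCC", "TCG"), n, replace = TRUE)
    dg <- if (group == "in_loop") stats::rnorm(n, -1.5, 1.2) else NA_real_
    lp <- if (group == "in_loop") stats::runif(n) < 0.2 else FALSE
    lam <- exp(b0 + b_decile * dec +
                 (if (group == "in_loop") b_dg * dg + b_lp * as.numeric(lp) else 0))
    y <- stats::rpois(n, lam)
    df <- data.frame(chrom = "sim", pos = seq_len(n), n_mut = y,
                     trinucleotide = tri, context_group = "TpC",
                     is_tpc = TRUE, in_loop = group == "in_loop",
                     accessibility_decile = dec, delta_g = dg,
                     loop_pattern = lp, lambda_true = lam,
                     stringsAsFactors = FALSE)
    df[df$n_mut >= min_count, , drop = FALSE]
  })
}
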