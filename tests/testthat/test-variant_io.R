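test_that("VCF ingest keeps biallelic SNVs and maps AD/DP fields", {
  vcf <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"GT\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"AD\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"DP\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tT1",
    "chr1\t100\t.\tC\tT\t.\tPASS\t.\tGT:AD:DP\t0/1:5,5:10",
    "chr1\t200\t.\tG\tA\t.\tPASS\t.\tGT:AD:DP\t0/1:20,8:28",
    "chr1\t300\t.\tA\tAT\t.\tPASS\t.\tGT:AD:DP\t0/1:9,3:12",
    "chr2\t50\t.\tT\tG\t.\tPASS\t.\tGT:AD:DP\t0/1:12,4:16"), vcf)
  expect_message(m <- read_somatic_vcf(vcf, sample_id = "T1"),
                 "skipped 1 non-SNV")
  expect_equal(nrow(m), 3L)
  expect_equal(m$alt_reads[m$pos == 100], 5L)
  expect_equal(m$depth[m$pos == 100], 10L)
  expect_equal(m$ref[m$pos == 200], "G")
  ## copy-number join by segment overlap
  cn <- data.frame(chrom = "chr1", start = 1, end = 250, cn = 3.2)
  m2 <- read_somatic_vcf(vcf, "T1", cn_table = cn, sample_ploidy = 2.1)
  expect_equal(m2$tumor_cn[m2$pos == 100], 3.2)
  expect_equal(m2$tumor_cn[m2$chrom == "chr2"], 2.1)
})

test_that("empty VCF bodies and missing files behave per contract", {
  vcf <- tempfile(fileext = ".vcf")
  writeLines(c("##fileformat=VCFv4.2",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"), vcf)
  m <- read_somatic_vcf(vcf, sample_id = "X")
  expect_equal(nrow(m), 0L)
  expect_error(read_somatic_vcf(tempfile()), "not found")
})

test_that("mutation TSV dialect round-trips exactly", {
  m <- fixture_cohort()
  path <- tempfile(fileext = ".tsv")
  write_mutation_tsv(m, path)
  m2 <- read_mutation_tsv(path)
  expect_identical(m2, m[, colnames(m2)])
})

test_that("mutation tables enforce their invariants", {
  expect_error(mutation_table("s", "chr1", 10, "C", "C"), "must differ")
  expect_error(mutation_table("s", "chr1", 0, "C", "T"), ">= 1")
  expect_error(mutation_table("s", "chr1", 5, "C", "T", alt_reads = 11,
                              depth = 10), "alt_reads")
  expect_silent(validate_mutations(fixture_cohort()))
})

test_that("pyrimidine-normalized contexts read off both strands", {
  ref <- Biostrings::DNAStringSet(c(chr1 = "GGATCAGGCTGATAACAGTT"))
  ## direct read-off at a C in ATCAG
  ctx <- extract_context(ref, "chr1", 5, "C")
  expect_equal(ctx$trinucleotide, "TCA")
  expect_true(ctx$is_tpc)
  expect_false(ctx$strand_flipped)
  expect_equal(ctx$tetranucleotide, "ATCA")
  ## G mutation: reverse complement of CTGAT reads TCA
  ctx2 <- extract_context(ref, "chr1", 11, "G")
  expect_equal(ctx2$trinucleotide, "TCA")
  expect_true(ctx2$strand_flipped)
  ## non-TpC context
  ctx3 <- extract_context(ref, "chr1", 16, "C")
  expect_equal(ctx3$trinucleotide, "ACA")
  expect_false(ctx3$is_tpc)
  ## contract errors
  expect_error(extract_context(ref, "chr1", 1, "G"), "within 1 base")
  expect_error(extract_context(ref, "chr1", 5, "G"), "mismatch")
})

test_that("context extraction is an involution under strand flip", {
  ref <- fixture_reference()
  rc <- Biostrings::DNAStringSet(lapply(ref, Biostrings::reverseComplement))
  names(rc) <- names(ref)
  lens <- setNames(Biostrings::width(ref), names(ref))
  set.seed(11)
  pos <- sample(seq(25, lens[["chr1"]] - 25), 50)
  base <- vapply(pos, function(p) substr(as.character(ref$chr1), p, p), "")
  ctx_f <- extract_context(ref, "chr1", pos, base)
  pos_rc <- lens[["chr1"]] - pos + 1L
  base_rc <- unname(c(A = "T", C = "G", G = "C", T = "A")[base])
  ctx_r <- extract_context(rc, "chr1", pos_rc, base_rc)
  expect_equal(ctx_f$trinucleotide, ctx_r$trinucleotide)
  expect_equal(ctx_f$tetranucleotide, ctx_r$tetranucleotide)
  expect_equal(ctx_f$is_tpc, ctx_r$is_tpc)
  expect_equal(ctx_f$strand_flipped, !ctx_r$strand_flipped)
})

test_that("narrowPeak ingest applies the q-value filter", {
  np <- tempfile(fileext = ".narrowPeak")
  q <- -log10(c(0.01, 0.04, 0.2))
  writeLines(c(paste("chr1", 100, 600, "p1", 0, ".", 5, 3, q[1], 250, sep = "\t"),
               paste("chr1", 1000, 1500, "p2", 0, ".", 2, 2, q[2], 250, sep = "\t"),
               paste("chr1", 2000, 2400, "p3", 0, ".", 3, 2, q[3], 200, sep = "\t"),
               paste("chr1", 3000, 3400, "p4", 0, ".", 3, 2, -1, 200, sep = "\t")),
             np)
  pk <- read_narrowpeak(np)
  expect_equal(nrow(pk), 2L)
  expect_equal(attr(pk, "n_dropped_na_q"), 1L)
  ## malformed column counts are reported with the line number
  bad <- tempfile()
  writeLines(c(paste("chr1", 1, 2, "p", 0, ".", 1, 1, 2, 1, sep = "\t"),
               "chr1\t5\t10\tonly4cols"), bad)
  expect_error(read_narrowpeak(bad), "line 2")
})

test_that("fuzzed VCF round trips yield valid mutation records", {
  ref <- fixture_reference()
  coh <- fixture_cohort()
  for (s in unique(coh$sample_id)) {
    m <- coh[coh$sample_id == s, ]
    vcf <- tempfile(fileext = ".vcf")
    write_somatic_vcf(m, vcf)
    m2 <- read_somatic_vcf(vcf, sample_id = s, reference = ref)
    expect_silent(validate_mutations(m2))
    expect_equal(nrow(m2), nrow(m))
    expect_equal(m2$pos[order(m2$chrom, m2$pos)], m$pos[order(m$chrom, m$pos)])
  }
})
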