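test_that("hotspots require two tumors and pool substitution alleles", {
  fix <- didymi_reference()
  ## 3 tumors at one position, 1 at another: only the first is a hotspot
  m <- mutation_table(sample_id = c("a", "b", "c", "a"),
                      chrom = "chr1",
                      pos = c(rep(fix$pos_tpc, 3), fix$pos_apc),
                      ref = "C", alt = "T", alt_reads = 5, depth = 10)
  cat1 <- build_catalog(m, fix$ref)
  expect_equal(nrow(cat1), 1L)
  expect_equal(cat1$n_mut, 3L)
  ## a serial biopsy (same sample twice) counts once, with a warning
  m2 <- rbind(m, m[1, ])
  expect_warning(cat2 <- build_catalog(m2, fix$ref), "duplicate")
  expect_equal(cat2$n_mut, 3L)
  ## mixed alleles pool into one site; C>T dominates ties
  m3 <- mutation_table(sample_id = c("a", "b", "c"), chrom = "chr1",
                       pos = fix$pos_tpc, ref = "C", alt = c("T", "T", "G"),
                       alt_reads = 5, depth = 10)
  cat3 <- build_catalog(m3, fix$ref)
  expect_equal(nrow(cat3), 1L)
  expect_equal(cat3$n_mut, 3L)
  expect_equal(cat3$dominant_sub, "C>T")
})

test_that("catalog sites carry contexts, hairpins and accessibility deciles", {
  fix <- didymi_reference()
  cat1 <- build_catalog(didymi_cohort(fix), fix$ref)
  expect_equal(nrow(cat1), 2L)
  expect_equal(cat1$context_group, c("TpC", "ApC"))
  expect_true(all(cat1$in_loop))
  expect_equal(cat1$loop_seq, rep("TCAAC", 2))
  expect_true(all(cat1$loop_pattern))
  ## accessibility decile attaches by bin lookup
  bins <- make_bins(c(chr1 = Biostrings::width(fix$ref)[1]), 50)
  set.seed(2); marks <- lapply(1:4, function(i) { b <- bins; b$value <- rnorm(nrow(b)); b })
  acc <- build_accessibility(marks)
  cat2 <- build_catalog(didymi_cohort(fix), fix$ref, accessibility = acc)
  expect_true(all(cat2$accessibility_decile %in% 1:10))
})

test_that("catalog size grows monotonically with cohort extensions", {
  ref <- fixture_reference()
  coh <- fixture_cohort()
  samples <- unique(coh$sample_id)
  sizes <- vapply(2:4, function(k) {
    nrow(build_catalog(coh[coh$sample_id %in% samples[1:k], ], ref))
  }, numeric(1))
  expect_true(all(diff(sizes) >= 0))
  ## removing every sample carrying a site's mutations removes the site
  full <- build_catalog(coh, ref)
  if (nrow(full) > 0) {
    site <- full[1, ]
    carriers <- unique(coh$sample_id[coh$chrom == site$chrom & coh$pos == site$pos])
    rest <- coh[!coh$sample_id %in% carriers, ]
    if (length(unique(rest$sample_id)) >= 2) {
      reduced <- build_catalog(rest, ref)
      expect_false(any(reduced$chrom == site$chrom & reduced$pos == site$pos))
    }
  }
})

test_that("twin mutations share a loop and didymi follow their definition", {
  fix <- didymi_reference()
  cat1 <- build_catalog(didymi_cohort(fix), fix$ref)
  tw <- find_twins(cat1, fix$ref)
  expect_equal(nrow(tw), 1L)
  expect_equal(tw$separation, 2L)
  expect_equal(tw$separator_seq, "AA")
  expect_true(tw$is_didymi)
  ## separator sequence reconstruction without a reference agrees
  tw2 <- find_twins(cat1)
  expect_equal(tw2$separator_seq, tw$separator_seq)
  ## didymi imply the loop-pattern motif at both sites (cross-module)
  expect_true(all(cat1$loop_pattern[c(tw$site1, tw$site2)]))
  ## a lone hotspot in a loop yields no pair
  tw3 <- find_twins(cat1[1, , drop = FALSE])
  expect_equal(nrow(tw3), 0L)
})

test_that("three hotspots in one loop give all unordered pairs", {
  ## synthetic catalog rows sharing one loop span
  cat3 <- data.frame(chrom = "c", pos = c(100, 102, 104),
                     n_mut = 2L, dominant_sub = "C>T",
                     trinucleotide = "TCA", is_tpc = TRUE,
                     context_group = "TpC", in_loop = TRUE,
                     stem_len = 4L, loop_seq = "CACAC", loop_len = 5L,
                     mut_loop_index = 0L, delta_g = -2,
                     loop_pattern = TRUE, loop_gstart = 100L,
                     loop_gend = 104L, strand_flipped = FALSE)
  tw <- find_twins(cat3)
  expect_equal(nrow(tw), 3L)
  expect_setequal(paste(tw$pos1, tw$pos2),
                  c("100 102", "100 104", "102 104"))
})

test_that("didymi classification rejects G separators and non-C>T pairs", {
  base <- data.frame(dominant_sub1 = "C>T", dominant_sub2 = "C>T",
                     separation = 2L, separator_seq = "AA",
                     context_group1 = "TpC", context_group2 = "ApC",
                     stringsAsFactors = FALSE)
  expect_true(classify_didymi(base))
  g <- base; g$separator_seq <- "AG"
  expect_false(classify_didymi(g))
  far <- base; far$separation <- 3L; far$separator_seq <- "ATA"
  expect_false(classify_didymi(far))
  cg <- base; cg$dominant_sub1 <- "C>G"; cg$dominant_sub2 <- "C>G"
  expect_false(classify_didymi(cg))
  no_tpc <- base; no_tpc$context_group1 <- "ApC"
  expect_false(classify_didymi(no_tpc))
  one_base <- base; one_base$separation <- 1L; one_base$separator_seq <- "T"
  expect_true(classify_didymi(one_base))
})
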