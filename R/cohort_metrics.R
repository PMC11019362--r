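## cohort_metrics: APOBEC enrichment scoring, A3A/A3B tetranucleotide
## attribution, variant copy number and cancer cell fraction.

## Is the mutation a C>T or C>G change on the pyrimidine-normalized strand?
is_c_mutation <- function(ref, alt) {
  (ref == "C" & alt %in% c("T", "G")) | (ref == "G" & alt %in% c("A", "C"))
}

## Count motif occurrences on both strands of a window sequence.
count_motif_2strand <- function(seq_chr, motif) {
  s <- Biostrings::DNAString(seq_chr)
  Biostrings::countPattern(motif, s, fixed = FALSE) +
    Biostrings::countPattern(motif, Biostrings::reverseComplement(s), fixed = FALSE)
}

#' TCW fold enrichment of APOBEC-associated mutations
#'
#' For one sample, computes the fold enrichment `E` of C>T and C>G
#' mutations in the TCW context (W = A or T; pyrimidine-normalized):
#' `E = (n_mut_tcw * ctx_c) / (n_mut_c * ctx_tcw)`, where `n_mut_tcw` is
#' the number of C>T/C>G mutations in TCW, `n_mut_c` all C>T/C>G
#' mutations, and `ctx_tcw` / `ctx_c` count TCW motifs / cytosines on both
#' strands within `flank` nt of each such mutation. Significance is a
#' one-sided Fisher's exact test of motif excess among mutations relative
#' to local context.
#'
#' @param mutations Mutation `data.frame` for one sample.
#' @param reference Reference genome (FASTA path, `FaFile`,
#'   `DNAStringSet`).
#' @param flank Context half-window in nt around each mutation
#'   (default 20).
#' @return A one-row `data.frame`: `E`, `p`, `n_mut_tcw`, `n_mut_c`,
#'   `ctx_tcw`, `ctx_c`.
#' @export
tcw_fold_enrichment <- function(mutations, reference, flank = 20) {
  enr <- motif_enrichment(mutations, reference, motif = "TCW", flank = flank)
  if (enr$ctx_motif == 0 || enr$n_mut_c == 0)
    stopf("enrichment undefined: no C>T/C>G mutations or no TCW context")
  tab <- matrix(c(enr$n_mut_motif, enr$n_mut_c - enr$n_mut_motif,
                  enr$ctx_motif, enr$ctx_c - enr$ctx_motif), nrow = 2)
  p <- stats::fisher.test(tab, alternative = "greater")$p.value
  data.frame(E = enr$E, p = p, n_mut_tcw = enr$n_mut_motif,
             n_mut_c = enr$n_mut_c, ctx_tcw = enr$ctx_motif, ctx_c = enr$ctx_c)
}

## Shared enrichment core for TCW / YTCA / RTCA.
## `motif` uses IUPAC ambiguity codes; the mutated C sits at the position
## of the "C" in the motif (TCW: second of three; YTCA/RTCA: third of
## four). Context counts use both strands of the +/- flank window.
motif_enrichment <- function(mutations, reference, motif, flank = 20) {
  reference <- resolve_reference(reference)
  cmut <- mutations[is_c_mutation(mutations$ref, mutations$alt), , drop = FALSE]
  n_mut_c <- nrow(cmut)
  if (n_mut_c == 0L)
    return(list(E = NA_real_, n_mut_motif = 0L, n_mut_c = 0L,
                ctx_motif = 0L, ctx_c = 0L))
  ctx <- extract_context(reference, cmut$chrom, cmut$pos, cmut$ref, cmut$alt)
  n_mut_motif <- sum(mutation_matches_motif(ctx, motif))
  ctx_motif <- 0L
  ctx_c <- 0L
  for (i in seq_len(n_mut_c)) {
    win <- ref_window(reference, cmut$chrom[i], cmut$pos[i] - flank,
                      cmut$pos[i] + flank)
    ctx_motif <- ctx_motif + count_motif_2strand(win, motif)
    ctx_c <- ctx_c + count_motif_2strand(win, "C")
  }
  E <- if (ctx_motif == 0) NA_real_ else
    (n_mut_motif * ctx_c) / (n_mut_c * ctx_motif)
  list(E = E, n_mut_motif = n_mut_motif, n_mut_c = n_mut_c,
       ctx_motif = ctx_motif, ctx_c = ctx_c)
}

## Does a pyrimidine-normalized context match an APOBEC motif?
mutation_matches_motif <- function(ctx, motif) {
  if (motif == "TCW") {
    grepl("^TC[AT]$", ctx$trinucleotide)
  } else if (motif == "YTCA") {
    !is.na(ctx$tetranucleotide) & grepl("^[CT]TCA$", ctx$tetranucleotide)
  } else if (motif == "RTCA") {
    !is.na(ctx$tetranucleotide) & grepl("^[AG]TCA$", ctx$tetranucleotide)
  } else stopf("unknown motif '%s'", motif)
}

#' APOBEC3A/3B tetranucleotide fold enrichment
#'
#' Fold enrichment of C>T/C>G mutations in the YTCA (Y = C/T; linked to
#' APOBEC3A) and RTCA (R = A/G; linked to APOBEC3B) tetranucleotide
#' contexts, with the mutated C in third position. Uses the same ratio
#' construction as [tcw_fold_enrichment()].
#'
#' @inheritParams tcw_fold_enrichment
#' @return A one-row `data.frame` with `E_ytca` and `E_rtca`.
#' @export
tetra_enrichment <- function(mutations, reference, flank = 20) {
  y <- motif_enrichment(mutations, reference, "YTCA", flank)
  r <- motif_enrichment(mutations, reference, "RTCA", flank)
  if (y$n_mut_c == 0L || (y$ctx_motif == 0 && r$ctx_motif == 0))
    stopf("enrichment undefined: no C>T/C>G mutations or no YTCA/RTCA context")
  e_of <- function(m) {
    if (m$ctx_motif == 0) 0 else (m$n_mut_motif * m$ctx_c) / (m$n_mut_c * m$ctx_motif)
  }
  data.frame(E_ytca = e_of(y), E_rtca = e_of(r))
}

#' Classify a tumor by APOBEC enrichment
#'
#' Tumors are APOBEC-positive only when the BH-adjusted enrichment p-value
#' is < 0.01; positives are `high` when `E >= 3`, `medium` when
#' `2 <= E < 3` and `low` when `1 < E < 2`. Everything else (including
#' `E <= 1`) is `none`.
#'
#' @param E Fold enrichment (vector).
#' @param adj_p BH-adjusted p-value (vector).
#' @return Character vector in `c("high", "medium", "low", "none")`.
#' @export
classify_apobec <- function(E, adj_p) {
  stopifnot(length(E) == length(adj_p))
  if (any(E < 0, na.rm = TRUE) || any(adj_p < 0 | adj_p > 1, na.rm = TRUE))
    stopf("E must be >= 0 and adj_p in [0, 1]")
  out <- rep("none", length(E))
  sig <- !is.na(adj_p) & adj_p < 0.01 & !is.na(E)
  out[sig & E >= 3] <- "high"
  out[sig & E >= 2 & E < 3] <- "medium"
  out[sig & E > 1 & E < 2] <- "low"
  out
}

#' Per-sample APOBEC enrichment over a cohort
#'
#' Runs [tcw_fold_enrichment()] and [tetra_enrichment()] for every sample,
#' adjusts the Fisher p-values across samples with Benjamini-Hochberg, and
#' classifies each tumor with [classify_apobec()].
#'
#' @param mutations Mutation `data.frame` for the whole cohort.
#' @inheritParams tcw_fold_enrichment
#' @return A `data.frame` with one row per sample: `sample_id`, `E`, `p`,
#'   `adj_p`, `apobec_class`, `E_ytca`, `E_rtca` and the four counts.
#' @export
apobec_enrichment <- function(mutations, reference, flank = 20) {
  reference <- resolve_reference(reference)
  samples <- unique(mutations$sample_id)
  rows <- lapply(samples, function(s) {
    m <- mutations[mutations$sample_id == s, , drop = FALSE]
    e <- tcw_fold_enrichment(m, reference, flank)
    t4 <- tetra_enrichment(m, reference, flank)
    cbind(data.frame(sample_id = s, stringsAsFactors = FALSE), e, t4)
  })
  out <- do.call(rbind, rows)
  out$adj_p <- stats::p.adjust(out$p, method = "BH")
  out$apobec_class <- classify_apobec(out$E, out$adj_p)
  out[, c("sample_id", "E", "p", "adj_p", "apobec_class", "E_ytca", "E_rtca",
          "n_mut_tcw", "n_mut_c", "ctx_tcw", "ctx_c")]
}

#' Variant copy number of an SNV
#'
#' The number of genomic copies carrying a variant, corrected for tumor
#' purity and local copy number:
#' `n_snv = (f_m / p) * (p * C_t + (1 - p) * C_h)`, with `f_m` the variant
#' allele frequency, `p` the tumor purity, `C_t` the tumor copy number at
#' the site and `C_h` the healthy copy number (2 on autosomes, 1 on
#' allosomes). Mutations with `n_snv > 0.75` are considered clonal.
#'
#' @param f_m Variant allele frequency in `[0, 1]`.
#' @param purity Tumor purity in `(0, 1]`.
#' @param C_t Tumor copy number (> 0).
#' @param C_h Healthy copy number (> 0, default 2).
#' @return Numeric vector of variant copy numbers.
#' @export
variant_copy_number <- function(f_m, purity, C_t, C_h = 2) {
  if (any(purity <= 0)) stopf("purity must be > 0")
  if (any(f_m < 0 | f_m > 1)) stopf("f_m must be in [0, 1]")
  if (any(C_t <= 0) || any(C_h <= 0)) stopf("copy numbers must be > 0")
  (f_m / purity) * (purity * C_t + (1 - purity) * C_h)
}

#' Cancer cell fraction by binomial maximum likelihood
#'
#' Estimates the number of allelic copies `n_chr` carrying a mutation by
#' maximising the binomial likelihood of the observed variant reads over
#' candidate multiplicities `1..round(C_t)`, where candidate `n_chr` has
#' expected VAF `n_chr * p / (p * C_t + (1 - p) * C_h)`. Ties prefer the
#' smaller multiplicity; candidates with expected VAF > 1 are infeasible.
#' The cancer cell fraction is `min(1, n_snv / n_chr)` with `n_snv` from
#' [variant_copy_number()].
#'
#' @param alt_reads,depth Variant and total read counts (vectors).
#' @inheritParams variant_copy_number
#' @return A `data.frame` with columns `n_snv`, `n_chr`, `ccf`, `clonal`.
#' @export
cancer_cell_fraction <- function(alt_reads, depth, purity, C_t, C_h = 2) {
  n <- length(alt_reads)
  depth <- rep_len(depth, n); purity <- rep_len(purity, n)
  C_t <- rep_len(C_t, n); C_h <- rep_len(C_h, n)
  if (any(depth <= 0)) stopf("depth must be > 0")
  if (any(alt_reads < 0 | alt_reads > depth))
    stopf("alt_reads must be in [0, depth]")
  n_snv <- variant_copy_number(alt_reads / depth, purity, C_t, C_h)
  kmax <- max(1L, max(round(C_t)))
  denom <- purity * C_t + (1 - purity) * C_h
  ## expected VAF grows with the multiplicity, so feasibility (VAF <= 1)
  ## is decided by the single-copy candidate
  if (any(purity / denom > 1))
    stopf("degenerate input: all candidate multiplicities have expected VAF > 1")
  ## log-likelihood matrix over candidate multiplicities 1..kmax;
  ## -Inf marks infeasible candidates (and zero-likelihood feasible ones,
  ## which max.col's first-tie rule resolves to the smallest multiplicity)
  ll <- matrix(-Inf, n, kmax)
  for (k in seq_len(kmax)) {
    active <- k <= pmax(1L, round(C_t))
    vaf <- k * purity / denom
    ok <- active & vaf <= 1
    ll[ok, k] <- stats::dbinom(alt_reads[ok], depth[ok], vaf[ok], log = TRUE)
  }
  n_chr <- max.col(ll, ties.method = "first")  # smallest multiplicity on ties
  data.frame(n_snv = n_snv, n_chr = n_chr,
             ccf = pmin(1, n_snv / n_chr), clonal = n_snv > 0.75)
}

#' Association of a hotspot mutation with APOBEC enrichment
#'
#' Logistic regression (fitted by iteratively reweighted least squares) of
#' per-sample hotspot presence on the continuous APOBEC fold enrichment
#' `E`, with a two-sided Wald test on the slope. Benjamini-Hochberg
#' correction across hotspots is left to the caller.
#'
#' @param hotspot_present Logical vector: does each sample carry the
#'   hotspot mutation?
#' @param E Per-sample fold enrichment.
#' @return A list with `coefficient` (log-odds slope per unit `E`),
#'   `wald_p`, and `converged` (FALSE flags separation; then `wald_p` is
#'   `NA`).
#' @export
hotspot_apobec_association <- function(hotspot_present, E) {
  stopifnot(length(hotspot_present) == length(E))
  y <- as.logical(hotspot_present)
  if (sum(y) < 2L || sum(!y) < 2L)
    stopf("need >= 2 samples in each outcome class")
  fit <- suppressWarnings(stats::glm(y ~ E, family = stats::binomial()))
  mu <- stats::fitted(fit)
  separated <- !fit$converged || any(mu > 1 - 1e-8) || any(mu < 1e-8)
  if (separated)
    return(list(coefficient = unname(stats::coef(fit)[2]), wald_p = NA_real_,
                converged = FALSE))
  sm <- summary(fit)$coefficients
  list(coefficient = unname(sm["E", "Estimate"]),
       wald_p = unname(sm["E", "Pr(>|z|)"]), converged = TRUE)
}
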