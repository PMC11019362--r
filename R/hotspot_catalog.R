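## hotspot_catalog: recurrent positions, twin mutations in shared loops,
## didymi classification.

## Substitution class on the pyrimidine-normalized strand ("C>T" etc.).
normalized_substitution <- function(ref, alt) {
  flip <- ref %in% c("G", "A")
  r <- ifelse(flip, unname(COMP[ref]), ref)
  a <- ifelse(flip, unname(COMP[alt]), alt)
  paste0(r, ">", a)
}

## Most frequent substitution class at a site; ties prefer C>T.
dominant_substitution <- function(subs) {
  tab <- sort(table(subs), decreasing = TRUE)
  top <- names(tab)[tab == tab[1]]
  if ("C>T" %in% top) "C>T" else top[1]
}

#' Build the cohort hotspot catalog
#'
#' A hotspot is a genomic position mutated in two or more tumors of the
#' cohort, pooling all substitution alleles at the position. Each site is
#' annotated with its pyrimidine-normalized trinucleotide context, the
#' context group (TpC/ApC/CpC/GpC from the 5' neighbor; `other` when the
#' mutated base is not a cytosine after normalization), its dominant
#' substitution, DNA accessibility decile, and its best hairpin loop.
#'
#' @param mutations Cohort mutation `data.frame`. Duplicate
#'   (sample, position) records - e.g. serial biopsies - are collapsed
#'   with a warning so each tumor contributes at most one mutation per
#'   position.
#' @param reference Reference genome, used for contexts and hairpins.
#' @param accessibility Optional `accessibility_track` (see
#'   [build_accessibility()]); sites get the decile of their bin.
#' @param hairpins Optional precomputed [annotate_hairpins()] table; when
#'   `NULL`, hairpins are computed for the catalog sites.
#' @param min_recurrence Minimum number of mutated tumors (default 2).
#' @return A `hotspot_catalog` `data.frame`, one row per hotspot site.
#' @export
build_catalog <- function(mutations, reference, accessibility = NULL,
                          hairpins = NULL, min_recurrence = 2L) {
  validate_mutations(mutations)
  key <- paste(mutations$sample_id, mutations$chrom, mutations$pos)
  if (anyDuplicated(key)) {
    warnf("build_catalog: %d duplicate (sample, position) record(s) collapsed",
          sum(duplicated(key)))
    mutations <- mutations[!duplicated(key), , drop = FALSE]
  }
  site <- paste(mutations$chrom, mutations$pos)
  n_mut <- tapply(mutations$sample_id, site, function(s) length(unique(s)))
  keep_sites <- names(n_mut)[n_mut >= min_recurrence]
  if (!length(keep_sites)) {
    empty <- data.frame(chrom = character(), pos = integer(), n_mut = integer())
    class(empty) <- c("hotspot_catalog", "data.frame")
    return(empty)
  }
  m <- mutations[site %in% keep_sites, , drop = FALSE]
  m$site <- paste(m$chrom, m$pos)
  subs <- normalized_substitution(m$ref, m$alt)
  dom <- tapply(subs, m$site, dominant_substitution)
  first <- m[!duplicated(m$site), , drop = FALSE]
  out <- data.frame(chrom = first$chrom, pos = first$pos,
                    n_mut = as.integer(n_mut[first$site]),
                    ref = first$ref,
                    dominant_sub = as.character(dom[first$site]),
                    stringsAsFactors = FALSE)
  out <- out[order(out$chrom, out$pos), , drop = FALSE]
  rownames(out) <- NULL

  ctx <- extract_context(reference, out$chrom, out$pos, out$ref)
  out$trinucleotide <- ctx$trinucleotide
  out$is_tpc <- ctx$is_tpc
  center <- substr(ctx$trinucleotide, 2, 2)
  five <- substr(ctx$trinucleotide, 1, 1)
  out$context_group <- ifelse(center != "C", "other",
                              paste0(ifelse(five %in% BASES, five, "N"), "pC"))
  out$context_group[out$context_group == "NpC"] <- "other"

  hp <- hairpins %||% annotate_hairpins(reference, out)
  hkey <- paste(hp$chrom, hp$pos)
  idx <- match(paste(out$chrom, out$pos), hkey)
  if (anyNA(idx)) stopf("hairpin annotations missing for %d site(s)", sum(is.na(idx)))
  for (col in c("in_loop", "stem_len", "loop_seq", "loop_len", "mut_loop_index",
                "delta_g", "loop_pattern", "loop_gstart", "loop_gend",
                "strand_flipped")) {
    out[[col]] <- hp[[col]][idx]
  }

  out$accessibility_decile <- NA_integer_
  if (!is.null(accessibility)) {
    bn <- GenomicRanges::GRanges(accessibility$chrom,
                                 IRanges::IRanges(accessibility$start,
                                                  accessibility$end))
    q <- GenomicRanges::GRanges(out$chrom, IRanges::IRanges(out$pos, out$pos))
    hit <- GenomicRanges::findOverlaps(q, bn, select = "first")
    out$accessibility_decile <- accessibility$decile[hit]
  }
  class(out) <- c("hotspot_catalog", "data.frame")
  out
}

#' Find twin mutations sharing a hairpin loop
#'
#' Twin mutations are two hotspot sites whose positions both fall inside
#' the loop of a common hairpin. A pair is accepted when either site's
#' best hairpin contains both positions in its loop (the two site-centered
#' windows may disagree; either is evidence of a shared loop).
#'
#' @param catalog A `hotspot_catalog` with hairpin annotations.
#' @param reference Optional reference genome used to report the separator
#'   sequence on the forward strand; when `NULL` it is reconstructed from
#'   the loop sequence.
#' @return A `data.frame` of class `twin_pairs`: positions of both sites,
#'   `separation` (bases between them), `separator_seq`, context/dominant
#'   substitution of each site, and `is_didymi` from [classify_didymi()].
#' @export
find_twins <- function(catalog, reference = NULL) {
  looped <- which(catalog$in_loop)
  pairs <- list()
  for (i in looped) {
    same <- which(catalog$chrom == catalog$chrom[i] &
                    catalog$pos >= catalog$loop_gstart[i] &
                    catalog$pos <= catalog$loop_gend[i])
    same <- setdiff(same, i)
    for (j in same) {
      a <- min(i, j); b <- max(i, j)
      pairs[[paste(a, b)]] <- c(a, b)
    }
  }
  if (!length(pairs)) {
    out <- data.frame(chrom = character(), pos1 = integer(), pos2 = integer(),
                      separation = integer(), separator_seq = character(),
                      is_didymi = logical())
    class(out) <- c("twin_pairs", "data.frame")
    return(out)
  }
  mat <- do.call(rbind, unname(pairs))
  a <- mat[, 1]; b <- mat[, 2]
  lo <- ifelse(catalog$pos[a] <= catalog$pos[b], a, b)
  hi <- ifelse(catalog$pos[a] <= catalog$pos[b], b, a)
  sep <- catalog$pos[hi] - catalog$pos[lo] - 1L
  sep_seq <- character(length(lo))
  for (k in seq_along(lo)) {
    if (sep[k] == 0L) { sep_seq[k] <- ""; next }
    s1 <- catalog$pos[lo[k]] + 1L; s2 <- catalog$pos[hi[k]] - 1L
    if (!is.null(reference)) {
      sep_seq[k] <- ref_window(reference, catalog$chrom[lo[k]], s1, s2)
    } else {
      ## reconstruct from the loop sequence of a containing hairpin
      host <- if (!is.na(catalog$loop_gstart[lo[k]]) &&
                  catalog$pos[hi[k]] <= catalog$loop_gend[lo[k]] &&
                  catalog$pos[hi[k]] >= catalog$loop_gstart[lo[k]]) lo[k] else hi[k]
      seqc <- strsplit(catalog$loop_seq[host], "")[[1]]
      if (isTRUE(catalog$strand_flipped[host])) seqc <- rev(unname(COMP[seqc]))
      offs <- (s1:s2) - catalog$loop_gstart[host] + 1L
      sep_seq[k] <- paste(seqc[offs], collapse = "")
    }
  }
  out <- data.frame(chrom = catalog$chrom[lo],
                    pos1 = catalog$pos[lo], pos2 = catalog$pos[hi],
                    site1 = lo, site2 = hi,
                    separation = sep, separator_seq = sep_seq,
                    dominant_sub1 = catalog$dominant_sub[lo],
                    dominant_sub2 = catalog$dominant_sub[hi],
                    context_group1 = catalog$context_group[lo],
                    context_group2 = catalog$context_group[hi],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out$is_didymi <- classify_didymi(out)
  class(out) <- c("twin_pairs", "data.frame")
  out
}

#' Classify twin pairs as didymi
#'
#' Didymi are two C>T hotspot mutations in a hairpin loop separated by one
#' or two A/T bases, with at least one of the two in a TpC context (the
#' other in NpC). Equivalently, the loop carries a `101` or `1001` motif
#' (A/T = 0, G/C = 1) with the mutated cytosines at the terminal `1`s.
#'
#' @param twins A `twin_pairs` `data.frame` (see [find_twins()]), or any
#'   `data.frame` with columns `dominant_sub1`, `dominant_sub2`,
#'   `separation`, `separator_seq`, `context_group1`, `context_group2`.
#' @return Logical vector, one element per pair.
#' @export
classify_didymi <- function(twins) {
  if (!nrow(twins)) return(logical(0))
  both_ct <- twins$dominant_sub1 == "C>T" & twins$dominant_sub2 == "C>T"
  sep_ok <- twins$separation %in% c(1L, 2L) &
    vapply(strsplit(toupper(twins$separator_seq), ""), function(ch)
      length(ch) > 0L && all(ch %in% c("A", "T")), logical(1))
  tpc_ok <- twins$context_group1 == "TpC" | twins$context_group2 == "TpC"
  npc_ok <- twins$context_group1 %in% c("TpC", "ApC", "CpC", "GpC") &
    twins$context_group2 %in% c("TpC", "ApC", "CpC", "GpC")
  both_ct & sep_ok & tpc_ok & npc_ok
}

#' Export the hotspot catalog as TSV
#'
#' @param catalog A `hotspot_catalog`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_catalog_tsv <- function(catalog, path) {
  utils::write.table(catalog, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
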