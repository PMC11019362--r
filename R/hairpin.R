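## hairpin: stem-loop detection at mutated sites and nearest-neighbor
## free-energy scoring.

#' Load the DNA hairpin thermodynamic parameter table
#'
#' Reads the shipped nearest-neighbor parameter TSV (37 degrees C free
#' energies in kcal/mol): Watson-Crick stack terms, hairpin-loop
#' initiation penalties by loop size, sequence-specific tri/tetraloop
#' increments, and single-mismatch / single-bulge increments. The TSV is
#' the source of truth; pass a different file to swap parameter sets.
#'
#' @param path Parameter TSV (defaults to the copy shipped with the
#'   package).
#' @return A list with components `stack`, `loop`, `special`, `mismatch`
#'   and `bulge1`.
#' @export
load_thermo_params <- function(path = NULL) {
  path <- path %||% system.file("extdata", "nn_thermo_dna37.tsv",
                                package = "apohm", mustWork = TRUE)
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          comment.char = "#", stringsAsFactors = FALSE,
                          colClasses = c("character", "character", "numeric"))
  pick <- function(what) {
    x <- df[df$term == what, ]
    stats::setNames(x$dg, x$key)
  }
  list(stack = pick("stack"), loop = pick("hairpin_loop"),
       special = pick("special_loop"), mismatch = pick("mismatch"),
       bulge1 = unname(pick("bulge")["1"]))
}

## Cached default parameter set.
.thermo_cache <- new.env(parent = emptyenv())
default_thermo <- function() {
  if (is.null(.thermo_cache$params)) .thermo_cache$params <- load_thermo_params()
  .thermo_cache$params
}

## ---------------------------------------------------------------------
## Structure representation: a list of class "hairpin_structure" with
##   window       character vector of window bases (loop strand)
##   center       index of the mutated base in the window
##   loop_start/loop_end  window indices of the loop (closing pair excluded)
##   stem_len     number of base pairs including the closing pair
##   defect       list(type = "none"|"mismatch"|"bulge", index = pair index
##                (0 = closing) for a mismatch, or gap index j for a bulge
##                between pairs j and j+1; side = "left"|"right" for bulges)
##   pairs        m x 2 matrix of window indices (left, right), closing first
##   delta_g      free energy, kcal/mol
##   mut_loop_index  0-based position of the mutated base within the loop
##   strand_flipped  TRUE when the window was reverse-complemented
## ---------------------------------------------------------------------

## Window positions of the stem pairs for a configuration.
stem_pair_positions <- function(loop_start, loop_len, stem_len, defect) {
  i <- seq_len(stem_len) - 1L
  left <- loop_start - 1L - i
  right <- loop_start + loop_len + i
  if (defect$type == "bulge") {
    if (defect$side == "left") left[i > defect$index] <- left[i > defect$index] - 1L
    else right[i > defect$index] <- right[i > defect$index] + 1L
  }
  cbind(left, right)
}

## Enumerate all admissible stem-loop configurations whose loop contains
## `center`. Loop length 3..10 (closing pair excluded), contiguous stem of
## >= 2 pairs growing outward from a Watson-Crick closing pair, and at most
## one defect: an internal mismatched pair, or a single-nucleotide bulge
## strictly between two stem pairs and not adjacent to the closing pair.
## Only maximal stems are emitted: with strictly negative stack terms any
## truncation of a stem is dominated.
hairpin_candidates <- function(wchars, center, loop_min = 3L, loop_max = 10L,
                               min_stem = 2L) {
  n <- length(wchars)
  out <- list()
  add <- function(s, L, m, defect) {
    pairs <- stem_pair_positions(s, L, m, defect)
    out[[length(out) + 1L]] <<- list(loop_start = s, loop_len = L,
                                     stem_len = m, defect = defect,
                                     pairs = pairs)
  }
  run_from <- function(left0, right0, step_left) {
    ## length of the WC-matched run going outward from (left0, right0)
    k <- 0L
    while (left0 - k >= 1L && right0 + k <= n &&
           is_wc_pair(wchars[left0 - k], wchars[right0 + k])) k <- k + 1L
    k
  }
  for (L in seq(loop_min, loop_max)) {
    for (s in seq(center - L + 1L, center)) {
      if (s - min_stem < 1L || s + L + min_stem - 1L > n) next
      cl <- s - 1L; cr <- s + L  # closing pair
      if (!is_wc_pair(wchars[cl], wchars[cr])) next
      r0 <- run_from(cl, cr)    # leading matched run, >= 1 (closing matched)
      if (r0 >= min_stem) add(s, L, r0, list(type = "none"))
      ## one internal mismatched pair at index r0
      ml <- cl - r0; mr <- cr + r0
      if (ml >= 1L && mr <= n) {
        r1 <- run_from(ml - 1L, mr + 1L)
        if (r1 >= 1L)
          add(s, L, r0 + 1L + r1,
              list(type = "mismatch", index = r0))
      }
      ## single-nucleotide bulge between pairs j and j+1 (j >= 1)
      if (r0 >= 2L) {
        for (j in seq(1L, r0 - 1L)) {
          bl <- cl - j - 1L          # skipped base on the left arm
          if (bl - 1L >= 1L) {
            r2 <- run_from(bl - 1L, cr + j + 1L)
            if (r2 >= 1L)
              add(s, L, j + 1L + r2,
                  list(type = "bulge", index = j, side = "left"))
          }
          br <- cr + j + 1L          # skipped base on the right arm
          if (br + 1L <= n) {
            r2 <- run_from(cl - j - 1L, br + 1L)
            if (r2 >= 1L)
              add(s, L, j + 1L + r2,
                  list(type = "bulge", index = j, side = "right"))
          }
        }
      }
    }
  }
  out
}

#' Nearest-neighbor free energy of a hairpin structure
#'
#' Sums stacking free energies over adjacent stem base pairs (a mismatch
#' interrupts stacking and contributes its own increment; the flanking
#' stack is retained across a single-nucleotide bulge), adds the
#' loop-initiation penalty for the loop size, a sequence-specific
#' increment for tri/tetraloops listed in the parameter table, and the
#' defect increment. Lower (more negative) values mean a more stable
#' hairpin.
#'
#' @param structure A `hairpin_structure` (see [find_best_hairpin()]).
#' @param params Thermodynamic parameters from [load_thermo_params()].
#' @return Free energy in kcal/mol.
#' @export
hairpin_delta_g <- function(structure, params = NULL) {
  params <- params %||% default_thermo()
  w <- structure$window
  if (is.character(w) && length(w) == 1L) w <- strsplit(w, "")[[1]]
  if (!all(w[!is.na(w)] %in% BASES))
    stopf("window contains bases outside A/C/G/T")
  pairs <- structure$pairs
  m <- structure$stem_len
  defect <- structure$defect
  mm_index <- if (defect$type == "mismatch") defect$index else -1L
  dg <- 0
  for (i in seq_len(m - 1L)) {        # step between pair i-1 and pair i
    if ((i - 1L) == mm_index || i == mm_index) next
    key <- paste0(w[pairs[i + 1L, 1L]], w[pairs[i, 1L]])
    val <- params$stack[key]
    if (is.na(val)) stopf("no stack parameter for step %s", key)
    dg <- dg + unname(val)
  }
  if (defect$type == "mismatch") {
    b <- sort(c(w[pairs[mm_index + 1L, 1L]], w[pairs[mm_index + 1L, 2L]]))
    key <- paste0(b[1L], b[2L])
    val <- params$mismatch[key]
    if (is.na(val)) stopf("no mismatch parameter for pair %s", key)
    dg <- dg + unname(val)
  } else if (defect$type == "bulge") {
    dg <- dg + params$bulge1
  }
  L <- structure$loop_len %||% (structure$loop_end - structure$loop_start + 1L)
  loop_sizes <- as.integer(names(params$loop))
  if (L %in% loop_sizes) {
    dg <- dg + unname(params$loop[as.character(L)])
  } else {
    ## logarithmic extrapolation beyond the tabulated sizes
    lmax <- max(loop_sizes)
    dg <- dg + unname(params$loop[as.character(lmax)]) +
      1.75 * 0.0019872 * 310.15 * log(L / lmax)
  }
  if (L <= 4L) {
    ls <- structure$loop_start %||% (pairs[1L, 1L] + 1L)
    key <- paste(w[(ls - 1L):(ls + L)], collapse = "")
    bonus <- params$special[key]
    if (!is.na(bonus)) dg <- dg + unname(bonus)
  }
  dg
}

## Order candidates: minimum delta G, then longer stem, then smaller loop,
## then smallest loop_start. Returns the index of the winner.
pick_best_structure <- function(cands, dgs) {
  stem <- vapply(cands, `[[`, integer(1), "stem_len")
  loopl <- vapply(cands, `[[`, integer(1), "loop_len")
  ls <- vapply(cands, `[[`, integer(1), "loop_start")
  ord <- order(round(dgs, 9), -stem, loopl, ls)
  ord[1L]
}

#' Best hairpin loop in a sequence window
#'
#' Enumerates every admissible stem-loop configuration whose loop contains
#' the `center` position (loop size 3-10 excluding the closing pair, stem
#' of at least 2 contiguous pairs, at most one internal mismatch or
#' single-nucleotide bulge) and returns the one with minimum free energy.
#' Free-energy ties are broken towards the longer stem, then the smaller
#' loop, then the left-most loop.
#'
#' @param window Character string of window sequence (odd length for a
#'   centered site).
#' @param center 1-based index of the mutated base within `window`.
#' @param params Thermodynamic parameters ([load_thermo_params()]).
#' @param loop_min,loop_max,min_stem Structural bounds.
#' @return A `hairpin_structure` list, or `NULL` when no admissible
#'   configuration exists.
#' @export
best_hairpin_in_window <- function(window, center = (nchar(window) + 1L) %/% 2L,
                                   params = NULL, loop_min = 3L, loop_max = 10L,
                                   min_stem = 2L) {
  params <- params %||% default_thermo()
  wchars <- strsplit(toupper(window), "")[[1]]
  if (any(!wchars %in% c(BASES, "N"))) stopf("window contains non-ACGTN bases")
  if (any(wchars == "N")) return(NULL)  # ambiguous windows carry no call
  cands <- hairpin_candidates(wchars, center, loop_min, loop_max, min_stem)
  if (!length(cands)) return(NULL)
  dgs <- vapply(cands, function(cc) {
    cc$window <- wchars
    hairpin_delta_g(cc, params)
  }, numeric(1))
  best <- cands[[pick_best_structure(cands, dgs)]]
  structure(list(window = wchars, center = center,
                 loop_start = best$loop_start,
                 loop_end = best$loop_start + best$loop_len - 1L,
                 loop_len = best$loop_len,
                 loop_seq = paste(wchars[best$loop_start:(best$loop_start + best$loop_len - 1L)],
                                  collapse = ""),
                 stem_len = best$stem_len, defect = best$defect,
                 pairs = best$pairs,
                 mut_loop_index = center - best$loop_start,
                 delta_g = dgs[pick_best_structure(cands, dgs)],
                 strand_flipped = FALSE),
            class = "hairpin_structure")
}

#' Most stable DNA hairpin loop at a mutated genomic site
#'
#' Considers 50 bases on each side of the mutated position. When the
#' reference base is a purine the window is reverse-complemented first, so
#' the mutated base is read as a pyrimidine (the strand APOBEC deaminates).
#' Returns the minimum-free-energy stem-loop whose loop contains the site,
#' or `NULL` (with a warning for windows truncated by a contig end).
#'
#' @param reference Reference genome (FASTA path, `FaFile`,
#'   `DNAStringSet`).
#' @param chrom,pos Site coordinates (1-based).
#' @param ref_base Optional expected reference base for validation.
#' @param flank Window half-width in nt (default 50).
#' @param params Thermodynamic parameters ([load_thermo_params()]).
#' @return A `hairpin_structure` or `NULL`.
#' @export
find_best_hairpin <- function(reference, chrom, pos, ref_base = NULL,
                              flank = 50L, params = NULL) {
  reference <- resolve_reference(reference)
  sl <- ref_seqlengths(reference)
  if (!chrom %in% names(sl)) stopf("contig '%s' not present in reference", chrom)
  if (pos - flank < 1L || pos + flank > sl[[chrom]]) {
    warnf("window at %s:%d truncated by the contig end; no hairpin call", chrom, pos)
    return(NULL)
  }
  win <- ref_window(reference, chrom, pos - flank, pos + flank)
  wchars <- strsplit(win, "")[[1]]
  center <- flank + 1L
  base <- wchars[center]
  if (!is.null(ref_base) && toupper(ref_base) != base)
    stopf("reference mismatch at %s:%d: expected %s, found %s",
          chrom, pos, base, ref_base)
  flipped <- base %in% c("G", "A")
  if (flipped) win <- revcomp_chr(win)
  hp <- best_hairpin_in_window(win, center = center, params = params)
  if (is.null(hp)) return(NULL)
  hp$strand_flipped <- flipped
  hp
}

#' Loop sequence pattern flag for twin-mutation motifs
#'
#' Maps the loop to a binary code (A/T = 0, G/C = 1) and reports whether it
#' contains a `101` or `1001` motif with a mutated base at one of the
#' motif's terminal `1` positions - the sequence signature of didymi.
#'
#' @param loop_seq Loop sequence.
#' @param mutated_positions 0-based indices of mutated bases within the
#'   loop.
#' @return `TRUE`/`FALSE`.
#' @export
loop_pattern_flag <- function(loop_seq, mutated_positions) {
  chars <- strsplit(toupper(loop_seq), "")[[1]]
  if (length(mutated_positions) &&
      any(mutated_positions < 0 | mutated_positions >= length(chars)))
    stopf("mutated positions must lie within the loop")
  bin <- ifelse(chars %in% c("G", "C"), 1L, 0L)
  n <- length(bin)
  for (w in c(3L, 4L)) {
    if (n < w) next
    motif <- if (w == 3L) c(1L, 0L, 1L) else c(1L, 0L, 0L, 1L)
    for (q in seq_len(n - w + 1L)) {
      if (all(bin[q:(q + w - 1L)] == motif)) {
        ends <- c(q - 1L, q + w - 2L)  # 0-based terminal "1" positions
        if (any(ends %in% mutated_positions)) return(TRUE)
      }
    }
  }
  FALSE
}

## Genomic coordinates of a window index for a (possibly strand-flipped)
## hairpin computed at genomic position `pos`.
hairpin_genomic_coord <- function(hp, pos, idx) {
  if (isTRUE(hp$strand_flipped)) pos + hp$center - idx else pos - hp$center + idx
}

#' Annotate sites with their best hairpin loop
#'
#' Runs [find_best_hairpin()] for each (chrom, pos) site and collects the
#' structural annotations used by the hotspot catalog: loop membership,
#' stem length, loop sequence and size, the mutated base's loop index, the
#' free energy, the didymi loop-pattern flag and the genomic span of the
#' loop.
#'
#' @param reference Reference genome.
#' @param sites `data.frame` with columns `chrom` and `pos`.
#' @param params Thermodynamic parameters ([load_thermo_params()]).
#' @param flank Window half-width (default 50).
#' @return A `data.frame` with one row per site.
#' @export
annotate_hairpins <- function(reference, sites, params = NULL, flank = 50L) {
  reference <- resolve_reference(reference)
  params <- params %||% default_thermo()
  n <- nrow(sites)
  out <- data.frame(chrom = sites$chrom, pos = sites$pos,
                    in_loop = FALSE, stem_len = NA_integer_,
                    loop_seq = NA_character_, loop_len = NA_integer_,
                    mut_loop_index = NA_integer_, delta_g = NA_real_,
                    defect = NA_character_, loop_pattern = FALSE,
                    loop_gstart = NA_integer_, loop_gend = NA_integer_,
                    strand_flipped = NA, stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    hp <- withCallingHandlers(
      find_best_hairpin(reference, sites$chrom[i], sites$pos[i],
                        flank = flank, params = params),
      warning = function(w) invokeRestart("muffleWarning"))
    if (is.null(hp)) next
    g1 <- hairpin_genomic_coord(hp, sites$pos[i], hp$loop_start)
    g2 <- hairpin_genomic_coord(hp, sites$pos[i], hp$loop_end)
    out$in_loop[i] <- TRUE
    out$stem_len[i] <- hp$stem_len
    out$loop_seq[i] <- hp$loop_seq
    out$loop_len[i] <- hp$loop_len
    out$mut_loop_index[i] <- hp$mut_loop_index
    out$delta_g[i] <- hp$delta_g
    out$defect[i] <- hp$defect$type
    out$loop_pattern[i] <- loop_pattern_flag(hp$loop_seq, hp$mut_loop_index)
    out$loop_gstart[i] <- min(g1, g2)
    out$loop_gend[i] <- max(g1, g2)
    out$strand_flipped[i] <- hp$strand_flipped
  }
  out
}

#' @export
print.hairpin_structure <- function(x, ...) {
  cat(sprintf("hairpin: stem %d bp, loop %s (%d nt), defect %s, dG %.2f kcal/mol\n",
              x$stem_len, x$loop_seq, x$loop_len, x$defect$type, x$delta_g))
  invisible(x)
}
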