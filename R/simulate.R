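## simulate: synthetic hotspot genomes, cohort resampling, power analysis,
## and sequence/cohort fixture generators.

#' Configuration for the synthetic hotspot genome
#'
#' Describes the statistical structure of a simulated hotspot catalog: the
#' number of background hotspot positions, the Poisson recurrence rate at
#' the reference cohort size (truncated so every simulated position is a
#' hotspot, i.e. mutated in at least `truncate_min` tumors), the covariate
#' generators, and the spiked-in drivers with their prevalence range.
#'
#' Defaults describe a metastatic urothelial carcinoma-like cohort of 115
#' tumors: a background recurrence rate of 0.3 mutations per candidate
#' position (so that about 99% of hotspot positions carry at most 3
#' mutations), a TpC-dominant context spectrum, one in five hotspots
#' inside a hairpin loop, and 27 spiked drivers at 3-15% prevalence.
#'
#' @param n_hotspot_positions Background hotspot positions (default 1e6).
#' @param background_lambda Poisson recurrence rate per position at the
#'   reference cohort size, before truncation (default 0.3).
#' @param n_ref Reference cohort size in tumors (default 115).
#' @param n_drivers Spiked driver positions (default 27).
#' @param driver_prevalence_range Driver prevalence bounds as a fraction
#'   of the cohort (default `c(0.03, 0.15)`).
#' @param loop_fraction Fraction of background hotspots inside hairpin
#'   loops (default 0.2).
#' @param driver_loop_fraction Fraction of drivers inside loops
#'   (default 0.5).
#' @param context_probs Named probabilities over site contexts: TpC
#'   trinucleotides (TCA/TCT/TCC/TCG) and non-TpC groups (ApC/CpC/GpC).
#' @param decile_probs Distribution of accessibility deciles 1-10.
#' @param delta_g_mean,delta_g_sd Normal law for in-loop hairpin free
#'   energies (kcal/mol).
#' @param loop_pattern_prob Probability that an in-loop site carries the
#'   didymi 101/1001 loop motif.
#' @param truncate_min Minimum recurrence defining a hotspot (default 2;
#'   0 disables truncation, e.g. for GLM parameter-recovery studies).
#' @param decile_effect,delta_g_effect,pattern_effect Optional log-linear
#'   covariate effects on the background rate (default 0: recurrence is
#'   covariate-independent, as in a passenger-only genome).
#' @return A `synthetic_genome_config` list.
#' @export
synthetic_genome_config <- function(n_hotspot_positions = 1e6,
                                    background_lambda = 0.3,
                                    n_ref = 115L,
                                    n_drivers = 27L,
                                    driver_prevalence_range = c(0.03, 0.15),
                                    loop_fraction = 0.2,
                                    driver_loop_fraction = 0.5,
                                    context_probs = c(TCA = 0.25, TCT = 0.20,
                                                      TCC = 0.15, TCG = 0.05,
                                                      ApC = 0.15, CpC = 0.10,
                                                      GpC = 0.10),
                                    decile_probs = rep(0.1, 10),
                                    delta_g_mean = -1.5, delta_g_sd = 1.2,
                                    loop_pattern_prob = 0.1,
                                    truncate_min = 2L,
                                    decile_effect = 0, delta_g_effect = 0,
                                    pattern_effect = 0) {
  cfg <- list(n_hotspot_positions = as.integer(n_hotspot_positions),
              background_lambda = background_lambda, n_ref = as.integer(n_ref),
              n_drivers = as.integer(n_drivers),
              driver_prevalence_range = driver_prevalence_range,
              loop_fraction = loop_fraction,
              driver_loop_fraction = driver_loop_fraction,
              context_probs = context_probs / sum(context_probs),
              decile_probs = decile_probs / sum(decile_probs),
              delta_g_mean = delta_g_mean, delta_g_sd = delta_g_sd,
              loop_pattern_prob = loop_pattern_prob,
              truncate_min = as.integer(truncate_min),
              decile_effect = decile_effect, delta_g_effect = delta_g_effect,
              pattern_effect = pattern_effect)
  stopifnot(cfg$n_hotspot_positions > 0, cfg$background_lambda > 0,
            cfg$n_ref >= 2, cfg$n_drivers >= 0,
            length(cfg$driver_prevalence_range) == 2,
            all(cfg$driver_prevalence_range > 0),
            all(cfg$driver_prevalence_range <= 1),
            cfg$n_drivers < cfg$n_hotspot_positions,
            cfg$loop_fraction >= 0, cfg$loop_fraction <= 1,
            length(cfg$decile_probs) == 10)
  class(cfg) <- "synthetic_genome_config"
  cfg
}

#' Power-analysis preset of the synthetic genome
#'
#' A catalog-scale preset for power studies: 6,750 background hotspot
#' positions, matching the empirical hotspot catalog of a 115-tumor
#' reference cohort in which 27 drivers made up 0.40% of hotspot sites.
#' Statistical power under per-group BH correction depends directly on the
#' number of tested sites, so the simulated catalog mirrors what a real
#' cohort analysis tests rather than the full synthetic-genome pool.
#'
#' @param n_hotspot_positions Background catalog size (default 6,750).
#' @param ... Further overrides passed to [synthetic_genome_config()].
#' @return A `synthetic_genome_config`.
#' @export
power_preset <- function(n_hotspot_positions = 6750L, ...) {
  synthetic_genome_config(n_hotspot_positions = n_hotspot_positions, ...)
}

## Truncated-Poisson sampler (X >= lo) by inverse CDF; exact and O(n).
rpois_truncated <- function(n, lambda, lo) {
  if (lo <= 0) return(stats::rpois(n, lambda))
  p_lo <- stats::ppois(lo - 1, lambda)
  if (any(1 - p_lo < 1e-12))
    stopf("truncation infeasible: P(X >= %d) ~ 0 at lambda = %g", lo, min(lambda))
  u <- stats::runif(n, p_lo, 1)
  stats::qpois(u, lambda)
}

## Sample per-site contexts/covariates shared by background and drivers.
sample_site_covariates <- function(n, cfg, in_loop) {
  ctxs <- names(cfg$context_probs)
  ctx <- sample(ctxs, n, replace = TRUE, prob = cfg$context_probs)
  is_tpc <- ctx %in% c("TCA", "TCT", "TCC", "TCG")
  data.frame(trinucleotide = ifelse(is_tpc, ctx, NA_character_),
             context_group = ifelse(is_tpc, "TpC", ctx),
             is_tpc = is_tpc,
             in_loop = in_loop,
             accessibility_decile = sample(1:10, n, replace = TRUE,
                                           prob = cfg$decile_probs),
             delta_g = ifelse(in_loop,
                              stats::rnorm(n, cfg$delta_g_mean, cfg$delta_g_sd),
                              NA_real_),
             loop_pattern = in_loop &
               (stats::runif(n) < cfg$loop_pattern_prob),
             stringsAsFactors = FALSE)
}

#' Generate a synthetic hotspot genome
#'
#' Simulates a catalog of background hotspot positions whose recurrence at
#' the reference cohort size follows a truncated Poisson law (every
#' position is mutated in at least `truncate_min` tumors), with covariates
#' drawn from the configured generators, plus `n_drivers` spiked driver
#' positions whose recurrence is binomial at a prevalence drawn uniformly
#' from the configured range. Fully reproducible from `seed`.
#'
#' @param config A [synthetic_genome_config()].
#' @param seed Integer seed.
#' @return A `data.frame` of class `synthetic_genome` with one row per
#'   position: `chrom`, `pos`, `n_mut` (recurrence at the reference
#'   cohort size), covariate columns, `is_driver` and `prevalence`.
#' @export
generate_synthetic_genome <- function(config = synthetic_genome_config(),
                                      seed = 1L) {
  cfg <- config
  with_seed(seed, {
    n <- cfg$n_hotspot_positions
    in_loop <- stats::runif(n) < cfg$loop_fraction
    cov <- sample_site_covariates(n, cfg, in_loop)
    loglam <- log(cfg$background_lambda) +
      cfg$decile_effect * cov$accessibility_decile +
      ifelse(cov$in_loop, cfg$delta_g_effect * cov$delta_g, 0) +
      cfg$pattern_effect * as.numeric(cov$loop_pattern)
    n_mut <- rpois_truncated(n, exp(loglam), cfg$truncate_min)
    out <- cbind(data.frame(chrom = "sim1", pos = seq_len(n)), cov)
    out$n_mut <- n_mut
    out$is_driver <- FALSE
    out$prevalence <- NA_real_
    if (cfg$n_drivers > 0L) {
      nd <- cfg$n_drivers
      din_loop <- stats::runif(nd) < cfg$driver_loop_fraction
      dcov <- sample_site_covariates(nd, cfg, din_loop)
      ## drivers are APOBEC hotspot mutations: force a TpC context
      tpc <- c("TCA", "TCT", "TCC", "TCG")
      tpc_p <- cfg$context_probs[tpc] / sum(cfg$context_probs[tpc])
      dcov$trinucleotide <- sample(tpc, nd, replace = TRUE, prob = tpc_p)
      dcov$context_group <- "TpC"
      dcov$is_tpc <- TRUE
      prev <- stats::runif(nd, cfg$driver_prevalence_range[1],
                           cfg$driver_prevalence_range[2])
      drv <- cbind(data.frame(chrom = "sim1", pos = n + seq_len(nd)), dcov)
      drv$n_mut <- stats::rbinom(nd, cfg$n_ref, prev)
      drv$is_driver <- TRUE
      drv$prevalence <- prev
      out <- rbind(out, drv)
    }
    attr(out, "config") <- cfg
    class(out) <- c("synthetic_genome", "data.frame")
    out
  })
}

#' Resample a synthetic genome into a cohort of given size
#'
#' Background recurrence is binomially thinned from the reference cohort
#' size to `n_samples` (each of the reference mutations is retained with
#' probability `n_samples / n_ref`; for cohorts larger than the reference,
#' counts are redrawn as `Binomial(n_samples, n_mut / n_ref)`). Driver
#' counts are drawn as `Binomial(n_samples, prevalence)`. Positions whose
#' observed count falls below 2 are no longer hotspots and drop out of the
#' observed catalog.
#'
#' @param genome A `synthetic_genome`.
#' @param n_samples Cohort size (>= 2 tumors).
#' @param seed Integer seed.
#' @param redraw_prevalence Redraw each driver's prevalence from the
#'   configured range for this cohort (per-cohort prevalence draws).
#' @return The observed catalog: same columns as the genome, with `n_mut`
#'   holding the cohort's observed counts and a `prevalence` column giving
#'   the draws used.
#' @export
simulate_cohort <- function(genome, n_samples, seed = 1L,
                            redraw_prevalence = FALSE) {
  if (n_samples < 2) stopf("`n_samples` must be >= 2")
  cfg <- attr(genome, "config")
  n_ref <- cfg$n_ref
  with_seed(seed, {
    out <- genome
    bg <- !out$is_driver
    if (n_samples <= n_ref) {
      out$n_mut[bg] <- stats::rbinom(sum(bg), out$n_mut[bg], n_samples / n_ref)
    } else {
      out$n_mut[bg] <- stats::rbinom(sum(bg), n_samples,
                                     pmin(1, out$n_mut[bg] / n_ref))
    }
    if (any(out$is_driver)) {
      drv <- which(out$is_driver)
      if (redraw_prevalence) {
        out$prevalence[drv] <- stats::runif(length(drv),
                                            cfg$driver_prevalence_range[1],
                                            cfg$driver_prevalence_range[2])
      }
      out$n_mut[drv] <- stats::rbinom(length(drv), n_samples,
                                      out$prevalence[drv])
    }
    observed <- out[out$n_mut >= 2L, , drop = FALSE]
    rownames(observed) <- NULL
    attr(observed, "config") <- cfg
    attr(observed, "n_samples") <- n_samples
    attr(observed, "genome_drivers") <- sum(genome$is_driver)
    attr(observed, "driver_prevalence") <-
      stats::setNames(out$prevalence[out$is_driver], out$pos[out$is_driver])
    class(observed) <- c("synthetic_genome", "data.frame")
    observed
  })
}

#' Statistical power of driver detection over simulated cohorts
#'
#' For each cohort size, simulates `n_replicates` cohorts from a synthetic
#' genome, runs the full driver-calling pipeline ([call_drivers()]) on
#' each observed catalog, and reports the fraction of true drivers
#' detected at BH-adjusted p < `alpha`, split by driver prevalence
#' (at most vs. above `prevalence_split`). Drivers that drop below the
#' hotspot threshold in a given cohort count as undetected. The
#' false-positive rate is the fraction of tested background sites called
#' drivers.
#'
#' @param config A [synthetic_genome_config()]; defaults to
#'   [power_preset()].
#' @param cohort_sizes Integer vector of cohort sizes to evaluate.
#' @param n_replicates Simulated cohorts per size (default 100).
#' @param alpha Driver threshold on the BH-adjusted p (default 0.05).
#' @param seed Integer seed driving the whole grid.
#' @param prevalence_split Boundary between rare and frequent drivers
#'   (default 0.10).
#' @param ... Passed to [call_drivers()] (e.g. `loo`).
#' @return A `data.frame` of class `power_result`: one row per cohort size
#'   and prevalence bin with `power`, `se` (Monte-Carlo standard error),
#'   `false_positive_rate` and `n_replicates`.
#' @export
power_analysis <- function(config = power_preset(), cohort_sizes,
                           n_replicates = 100L, alpha = 0.05, seed = 1L,
                           prevalence_split = 0.10, ...) {
  if (n_replicates < 2) stopf("need at least 2 replicates")
  genome <- generate_synthetic_genome(config, seed = child_seed(seed, 0L))
  rows <- list()
  for (ns in cohort_sizes) {
    det <- matrix(0, n_replicates, 2,
                  dimnames = list(NULL, c("low", "high")))
    tot <- matrix(0, n_replicates, 2,
                  dimnames = list(NULL, c("low", "high")))
    fpr <- numeric(n_replicates)
    for (r in seq_len(n_replicates)) {
      obs <- simulate_cohort(genome, ns,
                             seed = child_seed(seed, ns * 1000L + r),
                             redraw_prevalence = TRUE)
      calls <- suppressWarnings(call_drivers(obs, alpha = alpha, ...))
      prev <- attr(obs, "driver_prevalence")
      bin <- ifelse(prev > prevalence_split, "high", "low")
      tot[r, ] <- c(sum(bin == "low"), sum(bin == "high"))
      hit_sites <- calls$site[calls$is_driver]
      hit <- obs$is_driver[hit_sites]
      hit_prev <- obs$prevalence[hit_sites[hit]]
      hbin <- ifelse(hit_prev > prevalence_split, "high", "low")
      det[r, ] <- c(sum(hbin == "low"), sum(hbin == "high"))
      tested_bg <- !obs$is_driver[calls$site]
      fpr[r] <- if (any(tested_bg))
        sum(!hit) / sum(tested_bg) else 0
    }
    for (b in c("low", "high")) {
      p_rep <- det[, b] / pmax(tot[, b], 1)
      rows[[paste(ns, b)]] <- data.frame(
        cohort_size = ns,
        prevalence_bin = if (b == "high")
          sprintf(">%.0f%%", 100 * prevalence_split)
        else sprintf("<=%.0f%%", 100 * prevalence_split),
        n_replicates = n_replicates,
        power = sum(det[, b]) / max(1, sum(tot[, b])),
        se = stats::sd(p_rep) / sqrt(n_replicates),
        false_positive_rate = mean(fpr),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("power_result", "data.frame")
  out
}

#' Simulate a random reference sequence (fixture generator)
#'
#' @param seqlengths Named vector of contig lengths.
#' @param seed Integer seed.
#' @param gc GC content (default 0.41, human-like).
#' @return A [Biostrings::DNAStringSet].
#' @export
simulate_reference <- function(seqlengths, seed = 1L, gc = 0.41) {
  with_seed(seed, {
    p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
    seqs <- vapply(seqlengths, function(len) {
      paste(sample(names(p), len, replace = TRUE, prob = p), collapse = "")
    }, character(1))
    Biostrings::DNAStringSet(seqs)
  })
}

#' Simulate an APOBEC-like somatic mutation cohort (fixture generator)
#'
#' Draws per-sample SNVs from a reference sequence, placing a configurable
#' fraction of C>T/C>G mutations into TpC sites (APOBEC-like targeting)
#' and the remainder uniformly over all positions, with binomial read
#' counts at the given depth.
#'
#' @param reference A `DNAStringSet` (or FASTA path).
#' @param n_samples Number of tumors.
#' @param muts_per_sample SNVs per tumor.
#' @param tcw_fraction Fraction of each tumor's mutations targeted at
#'   TpC cytosines as C>T/C>G (the rest are random substitutions).
#' @param depth Mean sequencing depth for simulated read counts.
#' @param seed Integer seed.
#' @return A mutation `data.frame` (see [mutation_table()]).
#' @export
simulate_apobec_cohort <- function(reference, n_samples = 5, muts_per_sample = 200,
                                   tcw_fraction = 0.7, depth = 60, seed = 1L) {
  reference <- resolve_reference(reference)
  if (!inherits(reference, "DNAStringSet"))
    stopf("simulate_apobec_cohort needs an in-memory DNAStringSet reference")
  with_seed(seed, {
    ## candidate TpC sites (both strands) per contig
    tpc_sites <- lapply(seq_along(reference), function(ci) {
      s <- reference[[ci]]
      len <- length(s)
      fw <- Biostrings::start(Biostrings::matchPattern("TC", s)) + 1L
      rv <- Biostrings::start(Biostrings::matchPattern("GA", s))
      list(fwd = fw[fw >= 2L & fw <= len - 1L],
           rev = rv[rv >= 2L & rv <= len - 1L])
    })
    contigs <- names(reference)
    lens <- Biostrings::width(reference)
    rows <- list()
    for (si in seq_len(n_samples)) {
      n_tcw <- stats::rbinom(1, muts_per_sample, tcw_fraction)
      n_other <- muts_per_sample - n_tcw
      ci <- sample(seq_along(contigs), n_tcw + n_other, replace = TRUE,
                   prob = lens / sum(lens))
      pos <- integer(0); ref <- character(0); alt <- character(0)
      chrom <- character(0)
      for (k in seq_len(n_tcw)) {
        sites <- tpc_sites[[ci[k]]]
        use_fwd <- stats::runif(1) < 0.5 && length(sites$fwd) > 0
        if (!use_fwd && length(sites$rev) == 0) {
          if (length(sites$fwd) == 0) next
          use_fwd <- TRUE
        }
        p <- if (use_fwd) sites$fwd[sample.int(length(sites$fwd), 1)]
             else sites$rev[sample.int(length(sites$rev), 1)]
        r <- if (use_fwd) "C" else "G"
        a <- if (use_fwd) sample(c("T", "G"), 1, prob = c(0.7, 0.3))
             else sample(c("A", "C"), 1, prob = c(0.7, 0.3))
        chrom <- c(chrom, contigs[ci[k]]); pos <- c(pos, p)
        ref <- c(ref, r); alt <- c(alt, a)
      }
      for (k in seq_len(n_other)) {
        cc <- ci[n_tcw + k]
        p <- sample(seq(2L, lens[cc] - 1L), 1)
        r <- as.character(Biostrings::subseq(reference[[cc]], p, p))
        a <- sample(setdiff(BASES, r), 1)
        chrom <- c(chrom, contigs[cc]); pos <- c(pos, p)
        ref <- c(ref, r); alt <- c(alt, a)
      }
      dp <- pmax(10L, stats::rpois(length(pos), depth))
      ar <- stats::rbinom(length(pos), dp, 0.4)
      rows[[si]] <- data.frame(sample_id = sprintf("S%02d", si), chrom = chrom,
                               pos = pos, ref = ref, alt = alt,
                               alt_reads = pmax(1L, ar), depth = dp,
                               tumor_cn = 2, normal_cn = 2,
                               stringsAsFactors = FALSE)
    }
    out <- do.call(rbind, rows)
    ## one record per (sample, site)
    out <- out[!duplicated(paste(out$sample_id, out$chrom, out$pos)), ]
    rownames(out) <- NULL
    validate_mutations(out)
  })
}

#' Export a power curve as TSV
#'
#' @param power A `power_result` from [power_analysis()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_power_tsv <- function(power, path) {
  utils::write.table(power, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
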