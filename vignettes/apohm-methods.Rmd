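---
title: "Methods: detecting driver APOBEC hotspot mutations"
author: "apohm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: detecting driver APOBEC hotspot mutations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

## The problem

APOBEC cytidine deaminases attack cytosines in single-stranded DNA, most
often in a TpC dinucleotide context, and with a marked preference for the
exposed loops of DNA stem-loop (hairpin) structures. Because the enzyme's
substrate preference is a property of the *sequence*, the same genomic
positions are mutated independently in many tumors. The result is a class
of recurrent "hotspot" mutations that mimics the recurrence signal used to
nominate driver mutations. Deciding whether a given APOBEC hotspot is a
passenger (a favourable substrate) or a driver (positively selected)
therefore requires a background model that knows how strongly the local
sequence and chromatin attract APOBEC.

`apohm` implements that framework end to end: per-sample APOBEC activity
scoring, genomic covariate tracks, hairpin detection with thermodynamic
scoring, a hotspot/twin-mutation catalog, a covariate-adjusted Poisson
driver test, and a simulation module for statistical power analysis.

## Per-sample APOBEC enrichment

For one tumor, the fold enrichment of C>T/C>G mutations in the TCW context
(W = A or T; all contexts read on the strand where the mutated base is a
pyrimidine) is

$$E = \frac{n_{TCW} \cdot c_C}{n_C \cdot c_{TCW}},$$

where $n_{TCW}$ and $n_C$ count TCW-context and all C>T/C>G mutations, and
$c_{TCW}$, $c_C$ count TCW motifs and cytosines on both strands within a
flanking window around each mutation. The flank is ±20 nt by default — the
window in which local sequence composition is a fair proxy for what the
mutational process could have hit; it is exposed as a parameter because no
single value is canonical. Significance comes from a one-sided Fisher's
exact test of the 2×2 motif-by-source table, corrected across the cohort
with Benjamini–Hochberg; tumors are APOBEC-positive at adjusted p < 0.01
and graded **high** ($E \ge 3$), **medium** ($2 \le E < 3$) or **low**
($1 < E < 2$). The same ratio with the tetranucleotide motifs YTCA and
RTCA (mutated C in third position) attributes activity to APOBEC3A versus
APOBEC3B.

## Clonality

The variant copy number of an SNV is
$n_{SNV} = \frac{f_m}{p}\left[p\,C_t + (1-p)\,C_h\right]$
with $f_m$ the variant allele frequency, $p$ tumor purity, $C_t$ the local
tumor copy number and $C_h$ the healthy copy number (2 on autosomes, 1 on
allosomes). Mutations with $n_{SNV} > 0.75$ are treated as clonal. The
allelic multiplicity $n_{chr}$ is the value in $1..\mathrm{round}(C_t)$
maximising the binomial likelihood of the observed read counts at expected
VAF $n_{chr}\,p / (p\,C_t + (1-p)\,C_h)$; ties resolve to the smallest
multiplicity and candidates with expected VAF above 1 are infeasible. The
cancer cell fraction is $\min(1, n_{SNV}/n_{chr})$ — capped because it is
a fraction of cells.

## Genomic tracks

All tracks live on 1-Mbp bins. ChIP-seq peaks (ENCODE narrowPeak, q < 0.05)
contribute their `signalValue` mass to bins in proportion to overlap
length; per-bin signals are smoothed with a centered moving average
(k = 3 bins, truncated — not NA-padded — at chromosome ends so every bin
keeps a value for downstream decile assignment) and z-scored per
chromosome with the population standard deviation (the scores are used
ordinally, so the n vs n−1 distinction is immaterial; zero-variance
chromosomes map to 0). The sum of the four histone marks H3K4me1, H3K4me3,
H3K36me3 and H3K27ac approximates DNA accessibility: bins strictly above
the genome-wide median are open chromatin (ties fall to "low"), and bins
are ranked into genome-wide deciles (ties to the lower decile). Mutational
load tracks average SNV counts per bin over the cohort, optionally split
into TpC and non-TpC strata. Expression tracks ingest precomputed per-bin
read-count tables; BAM summarisation itself is out of scope.

## Hairpin loops and their stability

For every mutated site the package searches the 101-nt window centered on
the mutation (reverse-complemented first when the reference base is a
purine, so the mutated base reads as the pyrimidine APOBEC attacks) for
stem-loop structures whose loop contains the site. Admissible structures
have loop size 3–10 (the closing pair not counted), a contiguous stem of
at least 2 pairs growing outward from a Watson–Crick closing pair, and at
most one defect: a single internal non-complementary pair or a
single-nucleotide bulge. A defect may not sit at the closing pair nor at
the outermost pair — such configurations re-parse as a different loop or a
shorter stem.

Stability is scored with a nearest-neighbor free-energy sum at 37 °C:
stacking terms over adjacent stem pairs, a loop-initiation penalty by loop
size, a sequence-specific increment for tabulated tri/tetraloops (loops
larger than 4 use the size-only penalty), a mismatch increment by base
pair, and a +4 kcal/mol single-bulge increment with the flanking stack
retained. All parameters ship in
`inst/extdata/nn_thermo_dna37.tsv` — a versioned file that is the single
source of truth, so a different parameterisation can be swapped in without
touching code. "Most stable" means minimum ΔG; exact ties (compared at
9 decimals) break towards the longer stem, then the smaller loop, then the
left-most loop, making the search a total, deterministic function. Windows
truncated by a contig end yield no call, with a warning.

## Hotspots, twins and didymi

A hotspot is a position mutated in ≥ 2 tumors, pooling all substitution
alleles; serial biopsies of one patient count once. Each site carries its
pyrimidine-normalized trinucleotide, a context group (TpC/ApC/CpC/GpC from
the 5′ neighbor), its dominant substitution (ties involving C>T resolve to
C>T), accessibility decile and hairpin annotations. Two hotspots whose
positions fall in the loop of a common hairpin are twin mutations; a pair
is accepted when *either* site's centered hairpin contains both positions,
because the two centered windows may legitimately disagree about the best
fold. **Didymi** are twin pairs where both sites are dominantly C>T,
separated by one or two A/T bases, with at least one site in TpC context —
equivalently the loop shows a `101`/`1001` motif (A/T = 0, G/C = 1) with
the mutated cytosines at the terminal 1s.

## The driver model

Hotspots are tested in two groups. Outside hairpin loops only TpC-context
sites are eligible (APOBEC-initiated); inside loops all NpC contexts are
eligible, because didymi recruit ApC/CpC/GpC partners. The recurrence of
the *remaining* hotspot sites — the focal site is always excluded from its
own background — is modelled as a Poisson regression with log link:
accessibility decile outside loops; accessibility decile, hairpin ΔG
(kcal/mol, continuous) and the binary loop motif flag inside loops. TpC
sites are additionally stratified by trinucleotide (TCA/TCC/TCG/TCT),
non-TpC loop sites by context group; a stratum with fewer than 2
background sites falls back to a pooled fit without context
stratification. The accessibility decile enters as one ordinal covariate
by default (a 10-level factor sits behind `decile_as_factor`) — a
monotone chromatin effect costs one parameter instead of nine, which
matters in thin strata.

Each focal site's expected recurrence λ is predicted from its covariates
under the leave-one-out fit; the observed count is tested with the
upper-tail exact Poisson test $P(X \ge n_{obs})$, p-values are
BH-adjusted per group, and sites below adjusted p 0.05 (configurable) are
drivers. Counts are modelled untruncated even though every catalog site
has $n \ge 2$; with the intercept free this mainly shifts the baseline
and keeps the model in plain `glm` territory.

Leave-one-out refits are exact by definition but quadratic in catalog
size. The default (`loo = "onestep"`) therefore removes the focal site
with a one-step Newton downdate (Sherman–Morrison on the weighted
information matrix) of the converged fit — the case-deletion error is
$O(1/n^2)$ — and switches to the exact refit whenever the fitting set has
fewer than 500 rows, where refits are cheap and the approximation is
least accurate. `loo = "exact"` forces full refits everywhere. Fits that
fail to converge within 100 IRLS iterations fall back to an
intercept-only background with a warning.

McFadden's $R^2 = 1 - \ell_{model}/\ell_{null}$ is provided for model
comparison across covariate sets.

## The simulator and statistical power

`generate_synthetic_genome()` reproduces the statistical structure the
driver model assumes rather than nucleotide-level sequence: positions with
recurrence drawn from a Poisson law truncated to ≥ 2 (every simulated
position is a hotspot by construction), covariates from configurable
generators, and spiked drivers whose per-cohort mutation counts are
binomial at a prevalence drawn uniformly from 3–15%. Defaults describe a
115-tumor urothelial-like reference cohort:

* `background_lambda = 0.3` — with truncation at 2 this leaves ~99% of
  hotspot positions with ≤ 3 mutations, the heavy-tailed-free background
  a passenger-only genome should show;
* context spectrum TCA .25 / TCT .20 / TCC .15 / TCG .05 / ApC .15 /
  CpC .10 / GpC .10 — TpC-dominant, as in APOBEC cohorts;
* 20% of hotspots inside hairpin loops; loop-motif probability 0.1;
  in-loop ΔG ~ Normal(−1.5, 1.2) kcal/mol, the range spanned by
  stem 2–5 / loop 3–10 folds under the shipped table;
* 27 drivers, half inside loops, all TpC (they model APOBEC-derived
  drivers).

Truncated recurrence is sampled by inversion (`qpois` on a uniform
restricted to the upper tail) — exact, O(n) and single-pass, where naive
rejection needs unbounded resampling rounds at small λ. Cohorts of
`n_samples` tumors are derived by binomial thinning of each position's
reference-cohort recurrence (ratio `n_samples / n_ref`; upscaling beyond
the reference redraws counts binomially), and positions falling below 2
observed mutations drop out of the catalog. `power_analysis()` runs the
full driver pipeline on each simulated cohort and reports the detected
fraction of true drivers split at 10% prevalence, with Monte-Carlo
standard errors and the background false-positive rate.

The default `power_preset()` uses 6,750 background positions — the
catalog scale at which ~27 drivers make up 0.4% of hotspot sites in a
115-tumor cohort — because BH-corrected power depends directly on the
number of tested sites; the 10⁶-position default of the full generator is
a background *pool*, not what a cohort analysis tests. Full-scale runs
remain available by passing `synthetic_genome_config()` unchanged.

### What power to expect, and why

Two structural facts cap the achievable power in this design. First,
because every catalog site has at least 2 mutations, the fitted background
mean is ≈ 2.1 no matter how small the generating λ is. Second, BH across
a few thousand tested sites only rejects raw p below roughly
$r \cdot 0.05/m$, which at $m \approx 2{,}000$–$3{,}000$ means observed
counts of 9–10 under λ ≈ 2.1. A driver at 10–15% prevalence in a cohort
of 75 tumors carries a Binomial(75, p) count with mean 7.9–11.25, so
roughly half of such drivers clear the bar — the power the package's own
simulations report for frequent drivers at that cohort size, rising
towards 1 as cohorts grow. Rare drivers (≤ 10%) are mostly undetectable
at this scale. Any claim of substantially higher power at 75 samples
implies either a smaller tested catalog or a background mean below 2,
neither of which is compatible with a catalog restricted to recurrent
positions.

### What the simulator does not emulate

Covariates are drawn independently of recurrence under the null (the
generator's covariate effects default to zero), so passing null
calibration here does not certify calibration under real covariate
confounding; real genomes also correlate accessibility with replication
timing, expression and GC content, which the simulator leaves out.
Sequence is not simulated at nucleotide level, so enrichment scoring and
hairpin detection are exercised on separately generated random references
(`simulate_reference()`, `simulate_apobec_cohort()`) rather than on the
synthetic hotspot catalog.

## Numerical and design choices

* Coordinates are 1-based internally (VCF convention); narrowPeak input
  is converted from 0-based half-open on ingest, BED-like exports convert
  back.
* Copy-number join: per-mutation $C_t$ by segment-interval lookup;
  mutations outside every segment take the sample ploidy when provided,
  otherwise stay `NA` and are excluded from clonality calculations.
* Read-depth fields default to `AD`/`DP` but are configurable; callers
  differ in FORMAT conventions.
* Decile ties go to the lower decile; median ties are "low" — both keep
  the strict reading of "above the median".
* The enrichment test is Fisher's exact (one-sided) — a binomial test is
  the main alternative; both are monotone in the same statistic, and the
  choice is isolated behind `tcw_fold_enrichment()`.
* Hairpin ΔG ties and defect placement rules are stated above and fixed;
  they are conventions, not physics, and live next to the parameter table
  so they can be revisited coherently.
* The power preset's catalog scale (6,750) is a deliberate modelling
  choice documented above; problem sizes in the test suite (e.g.
  10,000-site null catalogs, 5,000-site recovery catalogs, 41-nt
  enumeration windows) were chosen so each check is statistically
  informative at interactive runtimes.

## Limitations

The thermodynamic table is a compact parameterisation (unified
Watson–Crick stacks, size-dependent loop penalties, a small special-loop
set, single-defect increments); it ranks structures sensibly but is not a
full secondary-structure model — multiloops, pseudoknots, temperature and
salt corrections are out of scope. Driver calling assumes mutations are
independent across tumors given the covariates; kataegis-style clustered
events violate this and should be filtered upstream. The didymi
definition keys on dominant substitutions and A/T separators only; it
does not model the two mutations' joint VAFs.
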