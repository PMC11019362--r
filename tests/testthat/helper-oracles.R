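## Independent oracles: deliberately plain re-derivations used to check
## the package implementations.

## Textbook BH step-up.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

## Upper-tail Poisson probability by direct pmf summation.
oracle_poisson_tail <- function(n_obs, lambda) {
  if (n_obs == 0) return(1)
  k <- 0:(n_obs - 1)
  1 - sum(exp(-lambda) * lambda^k / factorial(k))
}

## Binomial-ML multiplicity by explicit grid evaluation.
oracle_ccf_nchr <- function(alt, depth, purity, C_t, C_h = 2) {
  cand <- 1:max(1, round(C_t))
  lik <- sapply(cand, function(k) {
    vaf <- k * purity / (purity * C_t + (1 - purity) * C_h)
    if (vaf > 1) -Inf else stats::dbinom(alt, depth, vaf, log = TRUE)
  })
  cand[which.max(lik)]
}

## ---------------------------------------------------------------------
## Brute-force hairpin enumeration: every (loop, stem length, defect)
## configuration is generated and validated explicitly, then scored with
## an independently written free-energy sum over the same parameter table.
## ---------------------------------------------------------------------
oracle_wc <- function(a, b) {
  paste0(a, b) %in% c("AT", "TA", "CG", "GC")
}

oracle_delta_g <- function(w, left, right, mm_at, bulge_gap, loop_start,
                           loop_len, params) {
  m <- length(left)
  dg <- 0
  for (i in seq_len(m - 1)) {     # step between pair i and i+1
    if (!is.na(mm_at) && (mm_at == i || mm_at == i + 1)) next
    dg <- dg + unname(params$stack[paste0(w[left[i + 1]], w[left[i]])])
  }
  if (!is.na(mm_at)) {
    b <- sort(c(w[left[mm_at]], w[right[mm_at]]))
    dg <- dg + unname(params$mismatch[paste0(b[1], b[2])])
  }
  if (!is.na(bulge_gap)) dg <- dg + params$bulge1
  dg <- dg + unname(params$loop[as.character(loop_len)])
  if (loop_len <= 4) {
    key <- paste(w[(loop_start - 1):(loop_start + loop_len)], collapse = "")
    if (key %in% names(params$special)) dg <- dg + unname(params$special[key])
  }
  dg
}

## All admissible structures for a window; returns a data.frame of
## (loop_start, loop_len, stem_len, defect, dg).
oracle_enumerate <- function(window, center, params) {
  w <- strsplit(window, "")[[1]]
  n <- length(w)
  r_ls <- integer(0); r_ll <- integer(0); r_sl <- integer(0)
  r_df <- character(0); r_dg <- numeric(0)
  keep <- function(s, L, m, type, dg) {
    r_ls[length(r_ls) + 1L] <<- s
    r_ll[length(r_ll) + 1L] <<- L
    r_sl[length(r_sl) + 1L] <<- m
    r_df[length(r_df) + 1L] <<- type
    r_dg[length(r_dg) + 1L] <<- dg
  }
  for (L in 3:10) {
    for (s in (center - L + 1):center) {
      if (s < 3 || s + L + 1 > n) next
      cl <- s - 1; cr <- s + L
      for (m in 2:min(cl, n - cr + 1)) {
        ## pair index 1..m from the closing pair outward
        base_l <- cl - (seq_len(m) - 1)
        base_r <- cr + (seq_len(m) - 1)
        pair0 <- oracle_wc(w[base_l], w[base_r])
        ## no defect
        if (all(pair0))
          keep(s, L, m, "none",
               oracle_delta_g(w, base_l, base_r, NA, NA, s, L, params))
        ## internal mismatch at pair k in 2..m-1 (pairs numbered 1..m
        ## outward from the closing pair)
        if (m >= 3) for (k in 2:(m - 1)) {
          if (!pair0[k] && all(pair0[-k]))
            keep(s, L, m, "mm",
                 oracle_delta_g(w, base_l, base_r, k, NA, s, L, params))
        }
        ## single-base bulge in the gap before pair g in 3..m (not next
        ## to the closing pair; flanked by stem pairs on both sides)
        if (m >= 3) for (g in 3:m) {
          for (side in c("L", "R")) {
            left <- base_l; right <- base_r
            if (side == "L") left[g:m] <- left[g:m] - 1L
            else right[g:m] <- right[g:m] + 1L
            if (min(left) < 1L || max(right) > n) next
            if (all(oracle_wc(w[left], w[right])))
              keep(s, L, m, "bulge",
                   oracle_delta_g(w, left, right, NA, g, s, L, params))
          }
        }
      }
    }
  }
  if (!length(r_ls)) return(NULL)
  data.frame(loop_start = r_ls, loop_len = r_ll, stem_len = r_sl,
             defect = r_df, dg = r_dg)
}

## Minimum-free-energy structure under the package tie-break rules.
oracle_best <- function(window, center, params) {
  all <- oracle_enumerate(window, center, params)
  if (is.null(all)) return(NULL)
  o <- order(round(all$dg, 9), -all$stem_len, all$loop_len, all$loop_start)
  all[o[1], , drop = FALSE]
}
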