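## driver_model: Poisson background models of hotspot recurrence, exact
## Poisson tests and per-group BH correction.

#' Upper-tail exact Poisson test
#'
#' Probability of observing `n_obs` or more events under a Poisson law
#' with mean `lambda`, computed with the stable survival function.
#'
#' @param n_obs Observed counts (non-negative integers).
#' @param lambda Expected counts (> 0).
#' @return P(X >= n_obs), vectorized.
#' @export
exact_poisson_test <- function(n_obs, lambda) {
  if (any(lambda <= 0)) stopf("lambda must be > 0")
  if (any(n_obs < 0)) stopf("n_obs must be >= 0")
  stats::ppois(n_obs - 1, lambda, lower.tail = FALSE)
}

#' Benjamini-Hochberg adjustment, optionally per group
#'
#' Step-up false-discovery-rate control applied separately within each
#' level of `groups` (e.g. hotspot sites outside vs. within hairpin
#' loops).
#'
#' @param pvals Raw p-values in `[0, 1]`.
#' @param groups Optional grouping vector of the same length.
#' @return Adjusted p-values in the input order.
#' @export
bh_adjust <- function(pvals, groups = NULL) {
  if (any(pvals < 0 | pvals > 1, na.rm = TRUE)) stopf("p-values must be in [0, 1]")
  if (is.null(groups)) return(stats::p.adjust(pvals, method = "BH"))
  stopifnot(length(groups) == length(pvals))
  out <- pvals
  for (g in unique(groups)) {
    i <- which(groups == g)
    out[i] <- stats::p.adjust(pvals[i], method = "BH")
  }
  out
}

## ---------------------------------------------------------------------
## Group membership and stratification of catalog sites.
## Outside loops only TpC-context hotspots are eligible (APOBEC-initiated);
## within loops TpC plus ApC/CpC/GpC are eligible (didymi partners).
## TpC sites are stratified by trinucleotide (TCA/TCC/TCG/TCT), non-TpC
## loop sites by context group.
## ---------------------------------------------------------------------
driver_group_mask <- function(catalog, group) {
  if (group == "outside_loop") !catalog$in_loop & catalog$context_group == "TpC"
  else catalog$in_loop & catalog$context_group %in% c("TpC", "ApC", "CpC", "GpC")
}

driver_stratum <- function(catalog) {
  ifelse(catalog$context_group == "TpC", catalog$trinucleotide,
         catalog$context_group)
}

driver_model_matrix <- function(catalog, idx, group, decile_as_factor = FALSE) {
  dec <- catalog$accessibility_decile[idx]
  if (anyNA(dec)) stopf("accessibility deciles missing for tested sites")
  X <- if (decile_as_factor) {
    stats::model.matrix(~ factor(dec, levels = 1:10))
  } else {
    cbind("(Intercept)" = 1, accessibility_decile = as.numeric(dec))
  }
  if (group == "in_loop") {
    dg <- catalog$delta_g[idx]
    lp <- catalog$loop_pattern[idx]
    if (anyNA(dg) || anyNA(lp)) stopf("hairpin covariates missing for in-loop sites")
    X <- cbind(X, delta_g = as.numeric(dg), loop_pattern = as.numeric(lp))
  }
  X
}

## Leave-one-out expected counts under a Poisson GLM fitted on (X, y).
## method "onestep" removes each focal row with a one-step Newton downdate
## of the converged IRLS fit (Sherman-Morrison on X'WX); "exact" refits
## the GLM without the row. The downdate error is O(1/n^2), so "onestep"
## switches to the exact refit for fitting sets below `exact_cutoff` rows,
## where refits are cheap and the approximation is least accurate. Rows
## whose leverage makes the downdate ill-conditioned also fall back to the
## exact refit.
loo_poisson_lambda <- function(X, y, focal = seq_len(nrow(X)),
                               method = c("onestep", "exact"), maxit = 100L,
                               exact_cutoff = 500L) {
  method <- match.arg(method)
  if (method == "onestep" && nrow(X) <= exact_cutoff) method <- "exact"
  ctl <- stats::glm.control(maxit = maxit)
  fit <- suppressWarnings(stats::glm.fit(X, y, family = stats::poisson(),
                                         control = ctl))
  intercept_only <- FALSE
  if (!fit$converged) {
    warnf("Poisson background fit did not converge in %d iterations; using an intercept-only background", maxit)
    X <- X[, 1L, drop = FALSE]
    fit <- suppressWarnings(stats::glm.fit(X, y, family = stats::poisson(),
                                           control = ctl))
    intercept_only <- TRUE
  }
  beta <- fit$coefficients
  ok <- !is.na(beta)
  Xo <- X[, ok, drop = FALSE]
  beta <- beta[ok]
  eta <- drop(Xo %*% beta)
  mu <- exp(eta)
  exact_one <- function(i) {
    f2 <- suppressWarnings(stats::glm.fit(Xo[-i, , drop = FALSE], y[-i],
                                          family = stats::poisson(), control = ctl))
    b2 <- f2$coefficients
    b2[is.na(b2)] <- 0
    exp(drop(Xo[i, , drop = FALSE] %*% b2))
  }
  if (method == "exact") {
    lam <- vapply(focal, exact_one, numeric(1))
  } else {
    A <- crossprod(Xo * mu, Xo)
    Ainv <- tryCatch(solve(A), error = function(e) NULL)
    if (is.null(Ainv)) {
      lam <- vapply(focal, exact_one, numeric(1))
    } else {
      U <- Xo %*% Ainv
      h <- mu * rowSums(U * Xo)
      eta_loo <- eta - h * (y - mu) / (mu * (1 - h))
      lam_all <- exp(eta_loo)
      bad <- !is.finite(lam_all) | h > 1 - 1e-8
      lam <- lam_all[focal]
      if (any(bad[focal])) {
        fb <- focal[bad[focal]]
        lam[bad[focal]] <- vapply(fb, exact_one, numeric(1))
      }
    }
  }
  list(lambda = lam, intercept_only = intercept_only,
       log_lik = sum(stats::dpois(y, mu, log = TRUE)),
       coefficients = fit$coefficients)
}

#' Fit the Poisson background model for one focal hotspot
#'
#' Models the recurrence counts of the remaining hotspot sites (the focal
#' site is excluded from its own background) as a Poisson regression on
#' covariates: DNA accessibility decile outside loops, plus hairpin free
#' energy and the loop-sequence flag for in-loop sites. TpC sites are
#' stratified by trinucleotide; when fewer than `min_background` background
#' sites share the stratum, a pooled model without context stratification
#' is used instead.
#'
#' @param catalog A `hotspot_catalog` (or compatible `data.frame` with
#'   columns `n_mut`, `in_loop`, `context_group`, `trinucleotide`,
#'   `accessibility_decile`, and for loops `delta_g`, `loop_pattern`).
#' @param focal_site Row index of the focal site in `catalog`.
#' @param group `"outside_loop"` or `"in_loop"`.
#' @param decile_as_factor Model the accessibility decile as a 10-level
#'   factor instead of a single ordinal covariate.
#' @param min_background Minimum background sites for a stratified fit
#'   (default 2).
#' @return An object of class `poisson_background`: the fitted [stats::glm()]
#'   (`$fit`), `$stratum`, `$n_background`, `$fallback`, `$log_likelihood`.
#' @export
fit_background <- function(catalog, focal_site, group = c("outside_loop", "in_loop"),
                           decile_as_factor = FALSE, min_background = 2L) {
  group <- match.arg(group)
  sel <- driver_group_mask(catalog, group)
  if (!isTRUE(sel[focal_site]))
    stopf("focal site %d is not eligible for group %s", focal_site, group)
  strat <- driver_stratum(catalog)
  bg <- setdiff(which(sel & strat == strat[focal_site]), focal_site)
  fallback <- length(bg) < min_background
  if (fallback) bg <- setdiff(which(sel), focal_site)
  df <- data.frame(n_mut = catalog$n_mut[bg],
                   accessibility_decile = catalog$accessibility_decile[bg])
  form <- n_mut ~ accessibility_decile
  if (decile_as_factor) {
    df$accessibility_decile <- factor(df$accessibility_decile, levels = 1:10)
  }
  if (group == "in_loop") {
    df$delta_g <- catalog$delta_g[bg]
    df$loop_pattern <- as.numeric(catalog$loop_pattern[bg])
    form <- n_mut ~ accessibility_decile + delta_g + loop_pattern
  }
  fit <- suppressWarnings(stats::glm(form, family = stats::poisson(), data = df,
                                     control = stats::glm.control(maxit = 100)))
  if (!fit$converged) {
    warnf("background fit for focal site %d did not converge; intercept-only fallback", focal_site)
    fit <- stats::glm(n_mut ~ 1, family = stats::poisson(), data = df)
  }
  structure(list(fit = fit, group = group,
                 stratum = if (fallback) "pooled" else strat[focal_site],
                 n_background = length(bg), fallback = fallback,
                 log_likelihood = as.numeric(stats::logLik(fit)),
                 coefficients = stats::coef(fit)),
            class = "poisson_background")
}

#' Expected recurrence of a site under a background model
#'
#' @param model A `poisson_background` from [fit_background()].
#' @param catalog,site Catalog and focal row index.
#' @return Expected Poisson mean for the site's covariates.
#' @export
predict_lambda <- function(model, catalog, site) {
  nd <- data.frame(accessibility_decile = catalog$accessibility_decile[site],
                   delta_g = catalog$delta_g[site],
                   loop_pattern = as.numeric(catalog$loop_pattern[site]))
  if (is.factor(model$fit$model$accessibility_decile))
    nd$accessibility_decile <- factor(nd$accessibility_decile, levels = 1:10)
  as.numeric(stats::predict(model$fit, newdata = nd, type = "response"))
}

#' Call driver hotspot mutations
#'
#' Tests every eligible hotspot site against a leave-one-out Poisson
#' background: sites outside hairpin loops are tested only in the TpC
#' context (accessibility decile as covariate, stratified by
#' trinucleotide); sites within loops are tested in all NpC contexts
#' (accessibility decile, hairpin free energy and the didymi loop-pattern
#' flag as covariates; TpC stratified by trinucleotide, other sites by
#' context group). Strata with fewer than `min_background` background
#' sites fall back to a pooled model without context stratification.
#' Each site's observed recurrence is compared to its expected value with
#' the upper-tail exact Poisson test, p-values are BH-adjusted per group,
#' and sites with adjusted p below `alpha` are flagged as drivers.
#'
#' @inheritParams fit_background
#' @param alpha Adjusted-p driver threshold (default 0.05).
#' @param loo `"onestep"` (default: a one-step Newton downdate of the
#'   converged background fit for large fitting sets, switching to the
#'   exact refit below 500 background sites) or `"exact"` (full refit per
#'   focal site).
#' @return A `data.frame` with one row per tested site: `site` (catalog
#'   row), `chrom`/`pos` when present, `group`, `stratum`, `fallback`,
#'   `n_background`, `n_obs`, `lambda`, `p`, `adj_p`, `is_driver`.
#' @export
call_drivers <- function(catalog, alpha = 0.05, loo = c("onestep", "exact"),
                         decile_as_factor = FALSE, min_background = 2L) {
  loo <- match.arg(loo)
  needed <- c("n_mut", "in_loop", "context_group", "trinucleotide",
              "accessibility_decile")
  missing_cols <- setdiff(needed, names(catalog))
  if (length(missing_cols))
    stopf("catalog lacks columns: %s", paste(missing_cols, collapse = ", "))
  strat_all <- driver_stratum(catalog)
  res <- list()
  for (g in c("outside_loop", "in_loop")) {
    sel <- driver_group_mask(catalog, g)
    idx <- which(sel)
    if (!length(idx)) {
      warnf("no eligible sites in group %s", g)
      next
    }
    y <- catalog$n_mut[idx]
    X <- driver_model_matrix(catalog, idx, g, decile_as_factor)
    strat <- strat_all[idx]
    m <- length(idx)
    lambda <- rep(NA_real_, m)
    fallback <- logical(m)
    n_bg <- integer(m)
    for (s in unique(strat)) {
      sidx <- which(strat == s)
      if (length(sidx) - 1L >= min_background) {
        fit <- loo_poisson_lambda(X[sidx, , drop = FALSE], y[sidx], method = loo)
        lambda[sidx] <- fit$lambda
        n_bg[sidx] <- length(sidx) - 1L
      } else {
        fallback[sidx] <- TRUE
      }
    }
    if (any(fallback)) {
      fb <- which(fallback)
      fit <- loo_poisson_lambda(X, y, focal = fb, method = loo)
      lambda[fb] <- fit$lambda
      n_bg[fb] <- m - 1L
    }
    p <- exact_poisson_test(y, lambda)
    adj <- stats::p.adjust(p, method = "BH")
    row <- data.frame(site = idx, group = g,
                      stratum = ifelse(fallback, "pooled", strat),
                      fallback = fallback, n_background = n_bg,
                      n_obs = y, lambda = lambda, p = p, adj_p = adj,
                      is_driver = adj < alpha, stringsAsFactors = FALSE)
    res[[g]] <- row
  }
  if (!length(res)) {
    return(data.frame(site = integer(), group = character(),
                      stratum = character(), fallback = logical(),
                      n_background = integer(), n_obs = integer(),
                      lambda = numeric(), p = numeric(), adj_p = numeric(),
                      is_driver = logical()))
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  for (col in c("chrom", "pos")) {
    if (col %in% names(catalog)) out[[col]] <- catalog[[col]][out$site]
  }
  out[order(out$site), , drop = FALSE]
}

#' McFadden's pseudo R-squared
#'
#' `1 - logLik(model) / logLik(null_model)`, a likelihood-based
#' goodness-of-fit measure for nested GLMs; the null model is the
#' intercept-only fit on the same data.
#'
#' @param model A fitted [stats::glm()] or `poisson_background`.
#' @param null_model The intercept-only counterpart; refitted from
#'   `model` when omitted.
#' @return McFadden's R-squared.
#' @export
mcfadden_r2 <- function(model, null_model = NULL) {
  getfit <- function(m) if (inherits(m, "poisson_background")) m$fit else m
  fit <- getfit(model)
  nul <- if (is.null(null_model)) {
    yv <- fit$y
    stats::glm(yv ~ 1, family = fit$family)
  } else getfit(null_model)
  ll1 <- as.numeric(stats::logLik(fit))
  ll0 <- as.numeric(stats::logLik(nul))
  if (ll0 == 0) stopf("null model log-likelihood is zero; R-squared undefined")
  1 - ll1 / ll0
}

#' Export driver calls as TSV
#'
#' @param calls Output of [call_drivers()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_driver_tsv <- function(calls, path) {
  utils::write.table(calls, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
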