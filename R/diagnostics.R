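#' Instrument-strength F-statistic
#'
#' The squared z-statistic of the instrument-exposure association,
#' `(beta_x / se_x)^2`.  Values above 10 conventionally indicate an
#' instrument strong enough for two-sample MR.
#'
#' @param beta_x,se_x exposure effect(s) and SE(s); vectorized.
#' @return numeric vector of F values.
#' @export
f_statistic <- function(beta_x, se_x) {
  stopifnot(all(se_x > 0))
  (beta_x / se_x)^2
}

#' Per-instrument exposure variance explained
#'
#' Primary formula (needs allele frequencies):
#' `R2_j = 2 eaf (1 - eaf) beta_x^2 / var_exposure`, with the exposure
#' variance taken as `sd_scale^2` when the effects are in the exposure's
#' measurement units.  When `eaf` is missing the F-based approximation
#' `R2_j = F_j / (n - 2 + F_j)` is used instead; the two agree as the
#' exposure sample size grows.
#'
#' @param beta_x,se_x exposure effects and SEs.
#' @param eaf effect-allele frequencies (NA allowed).
#' @param n exposure-study sample size (used by the fallback).
#' @param var_exposure exposure variance (default `sd_scale^2`).
#' @param sd_scale exposure SD in effect units.
#' @return numeric vector of per-instrument R-squared values.
#' @export
variance_explained <- function(beta_x, se_x, eaf = NULL, n = NULL,
                               var_exposure = sd_scale^2, sd_scale = 0.65) {
  L <- length(beta_x)
  r2 <- rep(NA_real_, L)
  has_eaf <- !is.null(eaf) & length(eaf) == L
  use_freq <- if (has_eaf) !is.na(eaf) else rep(FALSE, L)
  r2[use_freq] <- 2 * eaf[use_freq] * (1 - eaf[use_freq]) *
    beta_x[use_freq]^2 / var_exposure
  if (any(!use_freq)) {
    if (is.null(n)) {
      warning("eaf and n both missing for some instruments; ",
              "R-squared skipped there")
    } else {
      f <- f_statistic(beta_x[!use_freq], se_x[!use_freq])
      r2[!use_freq] <- f / (n - 2 + f)
    }
  }
  r2
}

#' Cochran's Q for heterogeneity of the Wald ratios
#'
#' `Q = sum_j w_j (theta_j - theta)^2` with `w_j = (beta_x_j/se_y_j)^2`,
#' the inverse variances of the per-variant ratio estimates; referred to
#' a chi-squared distribution with L - 1 degrees of freedom.  Supplies
#' the multiplicative variance-inflation factor of the random-effects
#' IVW model.
#'
#' @param x an [instrument_set()] with L >= 2.
#' @param theta pooled estimate on the pre-rescaling (per effect unit)
#'   scale; defaults to the fixed-effect IVW value.
#' @return list with elements `q`, `df`, `p`.
#' @export
cochran_q <- function(x, theta = NULL) {
  L <- nrow(x)
  if (L < 2L) stop("Cochran's Q needs at least 2 instruments",
                   call. = FALSE)
  .check_beta_x(x)
  w <- .ratio_weights(x)
  if (is.null(theta)) {
    theta <- sum(w * .ratios(x)) / sum(w)
  }
  q <- sum(w * (.ratios(x) - theta)^2)
  list(q = q, df = L - 1L, p = pchisq(q, df = L - 1L, lower.tail = FALSE))
}

#' I-squared for the no-measurement-error (NOME) assumption
#'
#' Measures the dispersion of the instrument-exposure effects relative
#' to their standard errors:
#' `I2_GX = max(0, (Q_GX - (L - 1)) / Q_GX)` with
#' `Q_GX = sum_j se_x_j^-2 (beta_x_j - m)^2` about the precision-weighted
#' mean m, instruments oriented so all exposure effects are positive
#' (consistent with MR-Egger).  Values near 1 indicate that
#' regression-dilution bias in the MR-Egger slope is minimal.
#'
#' @param x an [instrument_set()] with L >= 2.
#' @return I-squared in [0, 1].
#' @export
i2_gx <- function(x) {
  L <- nrow(x)
  if (L < 2L) stop("I2_GX needs at least 2 instruments", call. = FALSE)
  stopifnot(all(x$se_x > 0))
  o <- .orient(x)
  w <- 1 / o$se_x^2
  m <- sum(w * o$beta_x) / sum(w)
  q_gx <- sum(w * (o$beta_x - m)^2)
  if (q_gx == 0) {
    warning("no dispersion in exposure effects; I2_GX = 0")
    return(0)
  }
  max(0, (q_gx - (L - 1)) / q_gx)
}

#' Funnel plot coordinates
#'
#' One point per instrument: the per-variant causal estimate (per SD of
#' exposure) against its precision.  With `y_axis = "precision"`
#' (default) the vertical coordinate is `1/se` of the Wald ratio; with
#' `y_axis = "exposure_effect"` it is `|beta_x|`, the alternative
#' strength-based reading of a genetic funnel plot.  Asymmetry of the
#' funnel suggests directional pleiotropy.
#'
#' @param x an [instrument_set()].
#' @param y_axis `"precision"` or `"exposure_effect"`.
#' @return data frame `rsid`, `estimate`, `precision`.
#' @export
funnel_data <- function(x, y_axis = c("precision", "exposure_effect")) {
  y_axis <- match.arg(y_axis)
  .check_beta_x(x)
  s <- sd_scale(x)
  est <- .ratios(x) * s
  prec <- switch(y_axis,
                 precision = abs(x$beta_x) / (x$se_y * s),
                 exposure_effect = abs(x$beta_x))
  data.frame(rsid = x$rsid, estimate = est, precision = prec,
             stringsAsFactors = FALSE)
}

#' Forest plot rows
#'
#' Per-variant odds ratios (per SD of exposure) with 95% CIs, in input
#' order, followed by the pooled row.
#'
#' @param x an [instrument_set()].
#' @param pooled pooled `mr_estimate`; defaults to random-effects IVW.
#' @return data frame `rsid`, `or`, `ci_low`, `ci_high` with L + 1 rows.
#' @export
forest_data <- function(x, pooled = NULL) {
  .check_beta_x(x)
  if (is.null(pooled)) {
    pooled <- mr_ivw(x, if (nrow(x) >= 2L) "random" else "fixed")
  }
  s <- sd_scale(x)
  beta <- .ratios(x) * s
  se <- (x$se_y / abs(x$beta_x)) * s
  rows <- data.frame(rsid = x$rsid,
                     or = exp(beta),
                     ci_low = exp(beta - 1.96 * se),
                     ci_high = exp(beta + 1.96 * se),
                     stringsAsFactors = FALSE)
  pooled_or <- if (pooled$scale == "log-odds") to_odds_ratio(pooled) else
    pooled
  rbind(rows, data.frame(rsid = paste0("pooled-", pooled$method),
                         or = pooled_or$beta, ci_low = pooled_or$ci_low,
                         ci_high = pooled_or$ci_high))
}

#' Full instrument diagnostics bundle
#'
#' Per-instrument F-statistics and variance explained with their
#' summaries, Cochran's Q, I2 for the NOME assumption, funnel and forest
#' coordinates, and a per-variant outcome-association screen reporting
#' raw p-values alongside Bonferroni-adjusted significance at 0.05/L.
#'
#' @param x an [instrument_set()].
#' @param n_exposure exposure-study sample size for the R-squared
#'   fallback; optional.
#' @return an object of class `instrument_diagnostics` (a list).
#' @export
instrument_diagnostics <- function(x, n_exposure = NULL) {
  L <- nrow(x)
  f <- f_statistic(x$beta_x, x$se_x)
  r2 <- suppressWarnings(
    variance_explained(x$beta_x, x$se_x, eaf = x$eaf, n = n_exposure,
                       sd_scale = sd_scale(x)))
  q <- if (L >= 2L) cochran_q(x) else list(q = NA_real_, df = NA, p = NA_real_)
  p_out <- 2 * pnorm(-abs(x$beta_y / x$se_y))
  out <- list(
    rsid = x$rsid,
    per_snp_f = f, mean_f = mean(f), min_f = min(f), max_f = max(f),
    per_snp_r2 = r2, total_r2 = if (all(is.na(r2))) NA_real_ else
      sum(r2, na.rm = TRUE),
    q = q$q, q_df = q$df, q_p = q$p,
    i2_gx = if (L >= 2L) suppressWarnings(i2_gx(x)) else NA_real_,
    outcome_p = p_out,
    outcome_sig_raw = p_out < 0.05,
    outcome_sig_bonferroni = p_out < 0.05 / L,
    funnel = funnel_data(x),
    forest = forest_data(x))
  class(out) <- "instrument_diagnostics"
  out
}

#' @export
print.instrument_diagnostics <- function(x, ...) {
  cat(sprintf("Instrument diagnostics (%d SNPs)\n", length(x$rsid)))
  cat(sprintf("  F: mean %.1f, range %.1f-%.1f\n",
              x$mean_f, x$min_f, x$max_f))
  if (!is.na(x$total_r2)) {
    cat(sprintf("  variance explained: %.2f%%\n", 100 * x$total_r2))
  }
  if (!is.na(x$q)) {
    cat(sprintf("  Cochran's Q = %.2f (df %d), p = %s\n", x$q, x$q_df,
                format.pval(x$q_p, digits = 3)))
  }
  if (!is.na(x$i2_gx)) {
    cat(sprintf("  I2 (NOME) = %.1f%%\n", 100 * x$i2_gx))
  }
  invisible(x)
}
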