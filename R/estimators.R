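.new_estimate <- function(method, beta, se, n_snps, df = NULL,
                          ci_level = 0.95, ...) {
  crit <- if (is.null(df)) qnorm(1 - (1 - ci_level) / 2) else {
    stats::qt(1 - (1 - ci_level) / 2, df)
  }
  z <- beta / se
  p <- if (is.null(df)) 2 * pnorm(-abs(z)) else 2 * pt(-abs(z), df)
  out <- c(list(method = method, beta = beta, se = se,
                ci_low = beta - crit * se, ci_high = beta + crit * se,
                p = p, n_snps = n_snps, ci_level = ci_level,
                scale = "log-odds"),
           list(...))
  class(out) <- "mr_estimate"
  out
}

#' @export
print.mr_estimate <- function(x, digits = 3, ...) {
  or <- if (x$scale == "log-odds") exp(c(x$beta, x$ci_low, x$ci_high)) else
    c(x$beta, x$ci_low, x$ci_high)
  cat(sprintf("%s estimate (%d SNPs): OR %.2f (%.2f to %.2f), p = %s\n",
              x$method, x$n_snps, or[1], or[2], or[3],
              format.pval(x$p, digits = digits)))
  if (!is.null(x$intercept)) {
    cat(sprintf("  intercept %.4g (SE %.3g), p = %s\n", x$intercept,
                x$intercept_se, format.pval(x$intercept_p, digits = digits)))
  }
  invisible(x)
}

.check_beta_x <- function(x) {
  zero <- x$beta_x == 0
  if (any(zero)) {
    stop("undefined Wald ratio (beta_x = 0) at rsid(s): ",
         paste(x$rsid[zero], collapse = ", "), call. = FALSE)
  }
}

#' Per-variant Wald ratio causal estimate
#'
#' The ratio of the outcome effect to the exposure effect for a single
#' instrument, with the first-order standard error `se_y / |beta_x|`.
#'
#' @param beta_x,se_x per-allele exposure effect and its SE.
#' @param beta_y,se_y per-allele outcome effect (log odds) and its SE.
#' @param sd_scale exposure SD for per-SD rescaling (1 = no rescaling).
#' @param rsid optional variant label carried into the result.
#' @return an `mr_estimate` with `method = "wald"`, on the log-odds per
#'   SD of exposure scale.
#' @export
wald_ratio <- function(beta_x, se_x, beta_y, se_y, sd_scale = 1,
                       rsid = NULL) {
  if (beta_x == 0) {
    stop("undefined Wald ratio (beta_x = 0)",
         if (!is.null(rsid)) paste0(" at rsid ", rsid), call. = FALSE)
  }
  est <- .new_estimate("wald", beta = beta_y / beta_x,
                       se = se_y / abs(beta_x), n_snps = 1L, rsid = rsid)
  rescale_per_sd(est, sd_scale)
}

.ratios <- function(x) x$beta_y / x$beta_x
.ratio_weights <- function(x) (x$beta_x / x$se_y)^2

#' Inverse-variance weighted causal estimate
#'
#' Precision-weighted pooling of the per-variant Wald ratios;
#' equivalently, weighted least-squares regression of the outcome effects
#' on the exposure effects through the origin with weights `1/se_y^2`.
#' The multiplicative random-effects model inflates the fixed-effect SE
#' by `max(1, sqrt(Q/(L-1)))`, Cochran's Q measuring the heterogeneity of
#' the ratio estimates; it never yields a narrower interval than the
#' fixed-effect model.
#'
#' @param x an [instrument_set()].
#' @param model `"random"` (multiplicative random effects; default) or
#'   `"fixed"`.
#' @param ci_level confidence level (default 0.95).
#' @return an `mr_estimate` on the log-odds per SD of exposure scale,
#'   with auxiliary fields `q` and `q_p`.
#' @export
mr_ivw <- function(x, model = c("random", "fixed"), ci_level = 0.95) {
  model <- match.arg(model)
  L <- nrow(x)
  if (L < 1L) stop("empty instrument set", call. = FALSE)
  if (model == "random" && L < 2L) {
    stop("random-effects IVW needs at least 2 instruments", call. = FALSE)
  }
  .check_beta_x(x)
  w <- 1 / x$se_y^2
  s_xx <- sum(w * x$beta_x^2)
  theta <- sum(w * x$beta_x * x$beta_y) / s_xx
  se_fixed <- 1 / sqrt(s_xx)
  q <- if (L >= 2L) cochran_q(x, theta) else
    list(q = NA_real_, p = NA_real_)
  se <- if (model == "random" && L >= 2L) {
    se_fixed * max(1, sqrt(q$q / (L - 1)))
  } else se_fixed
  est <- .new_estimate(paste0("ivw-", model), beta = theta, se = se,
                       n_snps = L, ci_level = ci_level,
                       q = q$q, q_p = q$p)
  rescale_per_sd(est, sd_scale(x))
}

.orient <- function(x) {
  neg <- x$beta_x < 0
  x$beta_x[neg] <- -x$beta_x[neg]
  x$beta_y[neg] <- -x$beta_y[neg]
  x
}

#' MR-Egger regression
#'
#' Weighted linear regression of the outcome effects on the exposure
#' effects with an unconstrained intercept (weights `1/se_y^2`),
#' instruments oriented so all exposure effects are positive.  The slope
#' is a pleiotropy-adjusted causal estimate (valid under the InSIDE
#' assumption); the intercept estimates the average directional
#' pleiotropic effect per instrument and its deviation from zero is a
#' formal test for directional pleiotropy.  Standard errors carry a
#' multiplicative random-effects scaling `max(1, residual SD)` and
#' inference uses the t distribution with L - 2 degrees of freedom.
#' The slope is rescaled per SD of exposure; the intercept, being an
#' outcome-scale quantity, is not.
#'
#' @param x an [instrument_set()] with at least 3 instruments.
#' @param ci_level confidence level.
#' @return an `mr_estimate` with `method = "egger"` and fields
#'   `intercept`, `intercept_se`, `intercept_p`.
#' @export
mr_egger <- function(x, ci_level = 0.95) {
  L <- nrow(x)
  if (L < 3L) stop("MR-Egger needs at least 3 instruments", call. = FALSE)
  .check_beta_x(x)
  o <- .orient(x)
  w <- 1 / o$se_y^2
  bx <- o$beta_x; by <- o$beta_y
  s_w <- sum(w); s_x <- sum(w * bx); s_y <- sum(w * by)
  s_xx <- sum(w * bx^2); s_xy <- sum(w * bx * by)
  denom <- s_w * s_xx - s_x^2
  if (denom <= 1e-10 * s_w * s_xx) {
    stop("exposure effects are collinear (all identical after orientation)",
         call. = FALSE)
  }
  slope <- (s_w * s_xy - s_x * s_y) / denom
  intercept <- (s_y - slope * s_x) / s_w
  resid <- by - intercept - slope * bx
  sigma2 <- sum(w * resid^2) / (L - 2)
  infl <- max(1, sigma2)
  se_slope <- sqrt(infl * s_w / denom)
  se_int <- sqrt(infl * s_xx / denom)
  df <- L - 2
  est <- .new_estimate("egger", beta = slope, se = se_slope, n_snps = L,
                       df = df, ci_level = ci_level,
                       intercept = intercept, intercept_se = se_int,
                       intercept_p = 2 * pt(-abs(intercept / se_int), df),
                       residual_scale = sqrt(sigma2))
  rescale_per_sd(est, sd_scale(x))
}

.weighted_median_point <- function(ratios, weights) {
  ord <- order(ratios)
  r <- ratios[ord]
  w <- weights[ord] / sum(weights)
  s <- cumsum(w) - w / 2
  if (0.5 <= s[1]) return(r[1])
  if (0.5 >= s[length(s)]) return(r[length(r)])
  approx(s, r, xout = 0.5, ties = "ordered")$y
}

#' Weighted median causal estimate
#'
#' The median of the inverse-variance-weight-ordered Wald ratios,
#' obtained by linear interpolation of the sorted ratio estimates
#' against the cumulative weight midpoints at 50% of the total weight.
#' Consistent when valid instruments contribute more than half of the
#' weight, so it tolerates up to 50% invalid weight.  The standard error
#' comes from a parametric bootstrap: exposure and outcome effects are
#' resampled from normal distributions centred at their observed values
#' with their reported SEs, the weighted median recomputed each time,
#' and the SE taken as the SD across replicates.
#'
#' @param x an [instrument_set()] with at least 3 instruments.
#' @param n_boot bootstrap replicates (default 1000).
#' @param seed integer seed; required, so results are reproducible by
#'   construction.
#' @param ci_level confidence level.
#' @return an `mr_estimate` with fields `n_boot` and `seed`.
#' @export
mr_weighted_median <- function(x, n_boot = 1000, seed, ci_level = 0.95) {
  L <- nrow(x)
  if (L < 3L) stop("weighted median needs at least 3 instruments",
                   call. = FALSE)
  if (missing(seed) || is.null(seed)) {
    stop("an explicit seed is required for the bootstrap", call. = FALSE)
  }
  stopifnot(n_boot >= 1)
  .check_beta_x(x)
  point <- .weighted_median_point(.ratios(x), .ratio_weights(x))
  boot <- .with_seed(seed, {
    vapply(seq_len(n_boot), function(i) {
      bx <- rnorm(L, x$beta_x, x$se_x)
      by <- rnorm(L, x$beta_y, x$se_y)
      ok <- bx != 0
      .weighted_median_point(by[ok] / bx[ok], (bx[ok] / x$se_y[ok])^2)
    }, numeric(1))
  })
  se <- sd(boot)
  est <- .new_estimate("weighted-median", beta = point, se = se,
                       n_snps = L, ci_level = ci_level,
                       n_boot = as.integer(n_boot), seed = as.integer(seed))
  rescale_per_sd(est, sd_scale(x))
}

# evaluate expr under a local RNG state, restoring the caller's stream
.with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Express a causal estimate as an odds ratio
#'
#' Exponentiates the point estimate and confidence bounds of a log-odds
#' estimate; the SE is retained on the log scale.
#'
#' @param est an `mr_estimate` on the log-odds scale.
#' @return the estimate with `scale = "odds-ratio"`.
#' @export
to_odds_ratio <- function(est) {
  if (!identical(est$scale, "log-odds")) {
    stop("estimate is not on the log-odds scale", call. = FALSE)
  }
  est$beta <- exp(est$beta)
  est$ci_low <- exp(est$ci_low)
  est$ci_high <- exp(est$ci_high)
  est$scale <- "odds-ratio"
  est
}

#' Run several MR estimators on one instrument set
#'
#' @param x an [instrument_set()].
#' @param methods subset of `c("ivw", "egger", "weighted-median")`.
#' @param n_boot,seed bootstrap controls for the weighted median.
#' @param ci_level confidence level.
#' @return named list of `mr_estimate` objects (IVW reported under both
#'   fixed- and random-effects models).
#' @export
mr_estimate_all <- function(x, methods = c("ivw", "egger",
                                           "weighted-median"),
                            n_boot = 1000, seed = NULL, ci_level = 0.95) {
  methods <- match.arg(methods, several.ok = TRUE)
  out <- list()
  if ("ivw" %in% methods) {
    out$`ivw-fixed` <- mr_ivw(x, "fixed", ci_level)
    if (nrow(x) >= 2L) out$`ivw-random` <- mr_ivw(x, "random", ci_level)
  }
  if ("egger" %in% methods) out$egger <- mr_egger(x, ci_level)
  if ("weighted-median" %in% methods) {
    out$`weighted-median` <- mr_weighted_median(x, n_boot, seed, ci_level)
  }
  out
}
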