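#' Convert a percentage change to a change in log units
#'
#' GWAS of positively skewed biomarkers (serum enzyme concentrations,
#' triglycerides, ...) often report per-allele effects as percentage
#' changes.  Downstream instrumental-variable arithmetic needs additive
#' effects, i.e. changes in the log-transformed trait.
#'
#' @param pct numeric vector of percentage changes; must be > -100.
#' @return `log(1 + pct/100)`, the equivalent change in log units.
#' @seealso [log_to_percent()] for the exact inverse.
#' @examples
#' percent_to_log(100)  # doubling = log 2
#' percent_to_log(92)   # ~0.65 log units
#' @export
percent_to_log <- function(pct) {
  stopifnot(is.numeric(pct))
  if (any(is.finite(pct) & pct <= -100)) {
    stop("percentage change must be > -100", call. = FALSE)
  }
  log1p(pct / 100)
}

#' Convert a change in log units to a percentage change
#'
#' @param delta numeric vector of changes on the log scale.
#' @return `(exp(delta) - 1) * 100`; exact inverse of [percent_to_log()].
#' @examples
#' log_to_percent(0.65)  # ~92 percent increase
#' @export
log_to_percent <- function(delta) {
  stopifnot(is.numeric(delta))
  expm1(delta) * 100
}

#' Rescale a causal estimate to a per-SD exposure scale
#'
#' Multiplies the point estimate, standard error and confidence bounds by
#' `sd_scale`, the exposure standard deviation expressed in the units the
#' per-allele effects were measured in (e.g. 0.65 log units per SD for
#' serum GGT).  The z-statistic and p-value are unchanged.
#'
#' @param est an `mr_estimate` (see [mr_ivw()]) or a list with elements
#'   `beta`, `se`, `ci_low`, `ci_high`.
#' @param sd_scale positive scalar, exposure SD in effect units.
#' @return the estimate with `beta`, `se`, `ci_low`, `ci_high` multiplied
#'   by `sd_scale`.
#' @export
rescale_per_sd <- function(est, sd_scale) {
  stopifnot(is.numeric(sd_scale), length(sd_scale) == 1L)
  if (!is.finite(sd_scale) || sd_scale <= 0) {
    stop("sd_scale must be a positive finite number", call. = FALSE)
  }
  for (fld in c("beta", "se", "ci_low", "ci_high")) {
    if (!is.null(est[[fld]])) est[[fld]] <- est[[fld]] * sd_scale
  }
  est
}
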