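#' Analytic power for two-sample MR with a binary outcome
#'
#' Non-centrality approximation for the Wald test of the IVW estimate in
#' a case-control outcome study.  The odds ratio per SD of exposure is
#' first attenuated to the risk-difference scale,
#' `b = K (OR / (1 + K (OR - 1)) - 1)`, the binary outcome variance net
#' of the effect is `v = K (1 - K) - b^2`, the non-centrality parameter
#' is `NCP = N R2 b^2 / v`, and power at two-sided level alpha is
#' `pnorm(sqrt(NCP) - qnorm(1 - alpha/2))`.  All intermediates are
#' returned for audit.
#'
#' @param n_total outcome-study sample size N (cases + controls).
#' @param case_fraction proportion of cases K, in (0, 1).
#' @param r2 proportion of exposure variance explained by the
#'   instruments, in (0, 1).
#' @param or_alt true odds ratio per SD of exposure under the
#'   alternative.
#' @param alpha two-sided significance level (default 0.05).
#' @param adjust_r2 if `TRUE`, inflate the NCP by `1/(1 - r2)` (a
#'   variant used by some calculators); default `FALSE`.
#' @return list with `power`, `b`, `v`, `ncp` and the echoed inputs.
#' @examples
#' mr_power_binary(54162, 17008 / 54162, 0.019, 1.20)
#' @export
mr_power_binary <- function(n_total, case_fraction, r2, or_alt,
                            alpha = 0.05, adjust_r2 = FALSE) {
  stopifnot(n_total > 0, case_fraction > 0, case_fraction < 1,
            r2 > 0, r2 < 1, or_alt > 0, alpha > 0, alpha < 1)
  k <- case_fraction
  b <- k * (or_alt / (1 + k * (or_alt - 1)) - 1)
  v <- k * (1 - k) - b^2
  if (v <= 0) {
    stop("variance term non-positive: OR/case-fraction combination too ",
         "extreme for the attenuation approximation", call. = FALSE)
  }
  ncp <- n_total * r2 * b^2 / v
  if (adjust_r2) ncp <- ncp / (1 - r2)
  list(power = pnorm(sqrt(ncp) - qnorm(1 - alpha / 2)),
       b = b, v = v, ncp = ncp,
       n_total = n_total, case_fraction = k, r2 = r2, or_alt = or_alt,
       alpha = alpha, adjust_r2 = adjust_r2)
}

#' Minimum detectable odds ratio at a target power
#'
#' Inverts [mr_power_binary()] by monotone bisection over OR in (1, 10],
#' to a tolerance of 1e-6 in power.
#'
#' @inheritParams mr_power_binary
#' @param target_power desired power, in (alpha, 1).
#' @return the smallest OR > 1 achieving `target_power`, or an error if
#'   it is unattainable at OR = 10.
#' @export
minimum_detectable_or <- function(n_total, case_fraction, r2, target_power,
                                  alpha = 0.05, adjust_r2 = FALSE) {
  stopifnot(target_power > alpha, target_power < 1)
  pw <- function(or) mr_power_binary(n_total, case_fraction, r2, or,
                                     alpha, adjust_r2)$power
  # the attenuation approximation degenerates as v -> 0 (the NCP blows
  # up); restrict the search to ORs where the attenuated effect leaves
  # b^2 <= 0.9 K (1 - K), i.e. v >= 0.1 K (1 - K)
  k <- case_fraction
  b_of <- function(or) k * (or / (1 + k * (or - 1)) - 1)
  b_cap <- sqrt(0.9 * k * (1 - k))
  hi <- 10
  if (b_of(hi) > b_cap) {
    blo <- 1; bhi <- 10
    for (i in 1:60) {
      mid <- (blo + bhi) / 2
      if (b_of(mid) > b_cap) bhi <- mid else blo <- mid
    }
    hi <- blo
  }
  if (pw(hi) < target_power) {
    stop("target power unattainable within the feasible OR range (1, 10]",
         call. = FALSE)
  }
  lo <- 1 + 1e-12
  repeat {
    mid <- (lo + hi) / 2
    p <- pw(mid)
    if (abs(p - target_power) < 1e-6 || (hi - lo) < 1e-12) return(mid)
    if (p < target_power) lo <- mid else hi <- mid
  }
}
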