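#' Run the full two-sample MR pipeline and write a report bundle
#'
#' Reads (or accepts) exposure and outcome association tables, converts
#' the exposure to log units if it arrives as percentage changes,
#' harmonizes, runs the requested estimators, computes diagnostics, and
#' optionally writes the results to an output directory: `report.json`
#' (estimates, diagnostics summary and the full configuration used),
#' `harmonized.tsv`, `funnel.tsv` and `forest.tsv`.
#'
#' @param exposure path to an exposure summary-statistics file, or a
#'   `variant_associations` data frame.
#' @param outcome path to an outcome file, or a data frame; effects must
#'   be (or be read as) log odds ratios.
#' @param exposure_scale scale of the exposure file when `exposure` is a
#'   path (`"percent-change"` or `"log-units"`).
#' @param sd_scale exposure SD in log units per SD (default 0.65).
#' @param methods estimators to run.
#' @param palindromic_policy passed to [harmonize()].
#' @param n_boot,seed weighted-median bootstrap controls; `seed` is
#'   required when the weighted median is requested.
#' @param n_exposure exposure-GWAS sample size for diagnostics
#'   (optional).
#' @param column_map_exposure,column_map_outcome column maps for
#'   [read_associations()].
#' @param out_dir directory for the report bundle; `NULL` (default)
#'   writes nothing.
#' @param ci_level confidence level.
#' @return list with `instruments`, `estimates`, `diagnostics`,
#'   `config`, invisibly when `out_dir` is given.
#' @export
run_mr <- function(exposure, outcome,
                   exposure_scale = c("log-units", "percent-change"),
                   sd_scale = 0.65,
                   methods = c("ivw", "egger", "weighted-median"),
                   palindromic_policy = "flag",
                   n_boot = 1000, seed = NULL, n_exposure = NULL,
                   column_map_exposure = NULL, column_map_outcome = NULL,
                   out_dir = NULL, ci_level = 0.95) {
  exposure_scale <- match.arg(exposure_scale)
  methods <- match.arg(methods, c("ivw", "egger", "weighted-median"),
                       several.ok = TRUE)
  if ("weighted-median" %in% methods && is.null(seed)) {
    stop("seed is required when the weighted median is requested",
         call. = FALSE)
  }
  if (is.character(exposure)) {
    exposure <- read_associations(exposure, scale = exposure_scale,
                                  column_map = column_map_exposure,
                                  trait = "exposure")
  }
  if (is.character(outcome)) {
    outcome <- read_associations(outcome, scale = "log-odds",
                                 column_map = column_map_outcome,
                                 trait = "outcome")
  }
  if (unique(exposure$scale) == "percent-change") {
    exposure <- convert_scale(exposure, "log-units")
  }
  inst <- harmonize(exposure, outcome,
                    palindromic_policy = palindromic_policy,
                    sd_scale = sd_scale)
  ests <- mr_estimate_all(inst, methods = methods, n_boot = n_boot,
                          seed = seed, ci_level = ci_level)
  diag <- instrument_diagnostics(inst, n_exposure = n_exposure)
  config <- list(sd_scale = sd_scale, methods = methods,
                 palindromic_policy = palindromic_policy,
                 n_boot = n_boot, seed = seed, ci_level = ci_level,
                 n_snps = nrow(inst),
                 package_version = as.character(
                   utils::packageVersion("mrsummary")))
  result <- list(instruments = inst, estimates = ests,
                 diagnostics = diag, config = config)
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    write_instruments(inst, file.path(out_dir, "harmonized.tsv"))
    write.table(diag$funnel, file.path(out_dir, "funnel.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(diag$forest, file.path(out_dir, "forest.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(mr_report_json(result),
                         file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    return(invisible(result))
  }
  result
}

#' Serializable summary of a pipeline run
#'
#' Flattens a [run_mr()] result into plain lists suitable for JSON:
#' one record per method (log-odds and odds-ratio scales, CIs, p-values,
#' Egger intercept and bootstrap metadata where applicable), the
#' diagnostics summary, and the full configuration.
#'
#' @param result a [run_mr()] return value.
#' @return a nested list.
#' @export
mr_report_json <- function(result) {
  fmt <- function(e) {
    or <- to_odds_ratio(e)
    rec <- list(method = e$method, n_snps = e$n_snps,
                beta = e$beta, se = e$se, p = e$p,
                or = or$beta, ci_low_or = or$ci_low,
                ci_high_or = or$ci_high)
    for (fld in c("intercept", "intercept_se", "intercept_p",
                  "n_boot", "seed", "q", "q_p")) {
      if (!is.null(e[[fld]])) rec[[fld]] <- e[[fld]]
    }
    rec
  }
  d <- result$diagnostics
  list(estimates = lapply(result$estimates, fmt),
       diagnostics = list(mean_f = d$mean_f, min_f = d$min_f,
                          max_f = d$max_f, total_r2 = d$total_r2,
                          q = d$q, q_p = d$q_p, i2_gx = d$i2_gx),
       config = result$config)
}
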