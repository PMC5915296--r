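#' @importFrom stats pnorm pchisq pt qnorm approx rnorm runif sd setNames format.pval
#' @importFrom utils read.delim write.table
NULL

.SCALES <- c("percent-change", "log-units", "log-odds")

.complement <- function(allele) {
  chartr("ACGTacgt", "TGCAtgca", allele)
}

.is_palindromic <- function(a1, a2) {
  nchar(a1) == 1L & nchar(a2) == 1L &
    toupper(a1) == toupper(.complement(a2))
}

.check_alleles <- function(x, what) {
  bad <- !grepl("^[ACGTacgt]+$", x)
  if (any(bad)) {
    stop(sprintf("%s contains non-nucleotide alleles: %s",
                 what, paste(unique(x[bad]), collapse = ", ")),
         call. = FALSE)
  }
  invisible(x)
}

#' Validate a table of per-variant summary associations
#'
#' Checks the invariants every association row must satisfy: finite beta,
#' strictly positive se, nucleotide alleles, frequencies inside (0,1),
#' a recognised scale tag and unique variant identifiers.
#'
#' @param assoc data frame with columns `rsid`, `effect_allele`,
#'   `other_allele`, `beta`, `se`, `scale`, and optionally `eaf`, `n`,
#'   `p`, `trait`.
#' @return the validated data frame, invisibly classed
#'   `variant_associations`.
#' @export
validate_associations <- function(assoc) {
  need <- c("rsid", "effect_allele", "other_allele", "beta", "se", "scale")
  miss <- setdiff(need, names(assoc))
  if (length(miss)) {
    stop("missing required column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(assoc$rsid)) {
    stop("duplicate rsid(s): ",
         paste(unique(assoc$rsid[duplicated(assoc$rsid)]), collapse = ", "),
         call. = FALSE)
  }
  if (!all(assoc$scale %in% .SCALES)) {
    stop("scale must be one of: ", paste(.SCALES, collapse = ", "),
         call. = FALSE)
  }
  if (!all(is.finite(assoc$beta))) stop("beta must be finite", call. = FALSE)
  if (!all(is.finite(assoc$se) & assoc$se > 0)) {
    stop("se must be finite and > 0", call. = FALSE)
  }
  .check_alleles(assoc$effect_allele, "effect_allele")
  .check_alleles(assoc$other_allele, "other_allele")
  if (!is.null(assoc$eaf)) {
    ok <- is.na(assoc$eaf) | (assoc$eaf > 0 & assoc$eaf < 1)
    if (!all(ok)) stop("eaf must lie in (0, 1)", call. = FALSE)
  }
  class(assoc) <- unique(c("variant_associations", class(assoc)))
  invisible(assoc)
}

#' Read per-variant summary associations from a delimited text file
#'
#' Reads a tab- or comma-delimited summary-statistics table with a header
#' row, maps its columns onto the standard names, attaches a scale tag to
#' every record, and rejects rows with missing or non-numeric `beta`/`se`
#' (reporting how many were dropped).
#'
#' @param path file to read.
#' @param scale scale of the effect column: `"percent-change"`,
#'   `"log-units"` or `"log-odds"`.
#' @param column_map named character vector mapping standard names
#'   (`rsid`, `effect_allele`, `other_allele`, `beta`, `se`, `eaf`, `n`,
#'   `p`) to the file's column names; unmentioned names are taken
#'   literally.
#' @param trait label stored in the `trait` column.
#' @param sep field separator; `NULL` (default) autodetects tab vs comma
#'   from the header line.
#' @return a `variant_associations` data frame; the number of rejected
#'   rows is available as `attr(x, "n_rejected")`.
#' @export
read_associations <- function(path, scale, column_map = NULL,
                              trait = NA_character_, sep = NULL) {
  scale <- match.arg(scale, .SCALES)
  if (is.null(sep)) {
    hdr <- readLines(path, n = 1L)
    sep <- if (grepl("\t", hdr)) "\t" else ","
  }
  raw <- read.delim(path, sep = sep, header = TRUE,
                    stringsAsFactors = FALSE, check.names = FALSE,
                    na.strings = c("NA", "", "."))
  std <- c("rsid", "effect_allele", "other_allele", "beta", "se",
           "eaf", "n", "p")
  map <- setNames(std, std)
  if (!is.null(column_map)) map[names(column_map)] <- column_map
  required <- c("rsid", "effect_allele", "other_allele", "beta", "se")
  for (s in required) {
    if (!map[[s]] %in% names(raw)) {
      stop(sprintf("format error: mapped column '%s' (for '%s') not found",
                   map[[s]], s), call. = FALSE)
    }
  }
  out <- data.frame(rsid = as.character(raw[[map["rsid"]]]),
                    effect_allele = as.character(raw[[map["effect_allele"]]]),
                    other_allele = as.character(raw[[map["other_allele"]]]),
                    beta = suppressWarnings(as.numeric(raw[[map["beta"]]])),
                    se = suppressWarnings(as.numeric(raw[[map["se"]]])),
                    stringsAsFactors = FALSE)
  for (opt in c("eaf", "n", "p")) {
    out[[opt]] <- if (map[[opt]] %in% names(raw)) {
      suppressWarnings(as.numeric(raw[[map[opt]]]))
    } else NA_real_
  }
  bad <- !is.finite(out$beta) | !is.finite(out$se) | out$se <= 0
  if (any(bad)) {
    message(sum(bad), " row(s) rejected for missing/invalid beta or se ",
            "(lines ", paste(which(bad) + 1L, collapse = ", "), ")")
  }
  out <- out[!bad, , drop = FALSE]
  rownames(out) <- NULL
  out$trait <- trait
  out$scale <- scale
  out <- validate_associations(out)
  attr(out, "n_rejected") <- sum(bad)
  out
}

#' Convert the effect scale of an association table
#'
#' Currently supports percent-change to log-units, applying the delta
#' method to the standard error (`se_log = se_pct / (100 + beta_pct)`).
#'
#' @param assoc a `variant_associations` data frame.
#' @param to target scale.
#' @return the table with `beta`, `se` and `scale` updated.
#' @export
convert_scale <- function(assoc, to = "log-units") {
  to <- match.arg(to, .SCALES)
  from <- unique(assoc$scale)
  if (length(from) != 1L) stop("mixed scales in one table", call. = FALSE)
  if (from == to) return(assoc)
  if (from == "percent-change" && to == "log-units") {
    assoc$se <- assoc$se / (100 + assoc$beta)
    assoc$beta <- percent_to_log(assoc$beta)
    assoc$scale <- to
    return(assoc)
  }
  stop(sprintf("no conversion from '%s' to '%s'", from, to), call. = FALSE)
}

#' Construct an instrument set
#'
#' An instrument set is a data frame of harmonized instruments (one row
#' per variant, exposure and outcome effects aligned to the same effect
#' allele) carrying the exposure SD used for per-SD rescaling.
#'
#' @param instruments data frame with columns `rsid`, `effect_allele`,
#'   `other_allele`, `beta_x`, `se_x`, `beta_y`, `se_y` and optionally
#'   `eaf`, `flipped`, `palindromic`.
#' @param sd_scale exposure standard deviation in the units of `beta_x`
#'   (default 0.65, serum GGT in log units).
#' @return an `instrument_set` data frame.
#' @export
instrument_set <- function(instruments, sd_scale = 0.65) {
  need <- c("rsid", "beta_x", "se_x", "beta_y", "se_y")
  miss <- setdiff(need, names(instruments))
  if (length(miss)) {
    stop("missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  }
  if (nrow(instruments) < 1L) stop("at least one instrument required",
                                   call. = FALSE)
  if (anyDuplicated(instruments$rsid)) stop("duplicate rsids", call. = FALSE)
  if (!all(instruments$se_x > 0) || !all(instruments$se_y > 0)) {
    stop("all standard errors must be > 0", call. = FALSE)
  }
  if (!is.finite(sd_scale) || sd_scale <= 0) {
    stop("sd_scale must be > 0", call. = FALSE)
  }
  if (is.null(instruments$flipped)) instruments$flipped <- FALSE
  if (is.null(instruments$palindromic) &&
      all(c("effect_allele", "other_allele") %in% names(instruments))) {
    instruments$palindromic <-
      .is_palindromic(instruments$effect_allele, instruments$other_allele)
  }
  attr(instruments, "sd_scale") <- sd_scale
  class(instruments) <- unique(c("instrument_set", class(instruments)))
  instruments
}

#' Exposure SD attached to an instrument set
#' @param x an `instrument_set`.
#' @return the `sd_scale` scalar.
#' @export
sd_scale <- function(x) {
  s <- attr(x, "sd_scale")
  if (is.null(s)) 1 else s
}

#' Number of instruments
#' @param x an `instrument_set`.
#' @return instrument count L.
#' @export
n_instruments <- function(x) nrow(x)

#' Harmonize exposure and outcome summary associations
#'
#' Intersects the two tables by variant identifier and aligns the outcome
#' effect to the exposure's effect allele.  Where the outcome reports the
#' alleles in reverse order the outcome beta sign is flipped; where the
#' alleles match only after strand complementing, the complement is taken
#' silently (SNP alleles only).  Palindromic variants (A/T or G/C), whose
#' strand cannot be resolved from the alleles alone, are handled per
#' `palindromic_policy`.  Allele comparison is case-insensitive.
#'
#' @param exposure `variant_associations` on the `log-units` scale.
#' @param outcome `variant_associations` on the `log-odds` scale.
#' @param palindromic_policy `"flag"` (keep, mark; default), `"drop"`
#'   (exclude, report), or `"keep"` (keep unmarked... kept but still
#'   marked in the `palindromic` column for audit).
#' @param sd_scale exposure SD carried into the resulting set.
#' @return an [instrument_set()] with columns `rsid`, `effect_allele`,
#'   `other_allele`, `beta_x`, `se_x`, `beta_y`, `se_y`, `eaf`,
#'   `flipped`, `palindromic`.
#' @export
harmonize <- function(exposure, outcome,
                      palindromic_policy = c("flag", "drop", "keep"),
                      sd_scale = 0.65) {
  palindromic_policy <- match.arg(palindromic_policy)
  if (unique(exposure$scale) != "log-units") {
    stop("exposure must be on the log-units scale (use convert_scale)",
         call. = FALSE)
  }
  if (unique(outcome$scale) != "log-odds") {
    stop("outcome must be on the log-odds scale", call. = FALSE)
  }
  shared <- intersect(exposure$rsid, outcome$rsid)
  dropped <- setdiff(exposure$rsid, shared)
  if (length(dropped)) {
    message(length(dropped), " exposure variant(s) absent from outcome: ",
            paste(dropped, collapse = ", "))
  }
  if (!length(shared)) stop("no shared variants to harmonize", call. = FALSE)
  ex <- exposure[match(shared, exposure$rsid), , drop = FALSE]
  ou <- outcome[match(shared, outcome$rsid), , drop = FALSE]

  ea_x <- toupper(ex$effect_allele); oa_x <- toupper(ex$other_allele)
  ea_y <- toupper(ou$effect_allele); oa_y <- toupper(ou$other_allele)

  # precedence: exact match, then swapped, then the complementary strand
  # (relevant for palindromic pairs, where several patterns match at once)
  same    <- ea_y == ea_x & oa_y == oa_x
  swapped <- !same & ea_y == oa_x & oa_y == ea_x
  c_ea_y <- toupper(.complement(ea_y)); c_oa_y <- toupper(.complement(oa_y))
  same_c    <- !same & !swapped & c_ea_y == ea_x & c_oa_y == oa_x
  swapped_c <- !same & !swapped & !same_c &
    c_ea_y == oa_x & c_oa_y == ea_x
  flip <- swapped | swapped_c
  unresolved <- !(same | swapped | same_c | swapped_c)
  if (any(unresolved)) {
    stop("allele mismatch at rsid(s): ",
         paste(shared[unresolved], collapse = ", "), call. = FALSE)
  }

  beta_y <- ifelse(flip, -ou$beta, ou$beta)
  palin <- .is_palindromic(ex$effect_allele, ex$other_allele)
  h <- data.frame(rsid = shared,
                  effect_allele = ex$effect_allele,
                  other_allele = ex$other_allele,
                  beta_x = ex$beta, se_x = ex$se,
                  beta_y = beta_y, se_y = ou$se,
                  eaf = if (is.null(ex$eaf)) NA_real_ else ex$eaf,
                  flipped = flip, palindromic = palin,
                  stringsAsFactors = FALSE)
  if (palindromic_policy == "drop" && any(palin)) {
    message(sum(palin), " palindromic variant(s) dropped: ",
            paste(h$rsid[palin], collapse = ", "))
    h <- h[!palin, , drop = FALSE]
    if (!nrow(h)) stop("all shared variants were palindromic", call. = FALSE)
  }
  rownames(h) <- NULL
  instrument_set(h, sd_scale = sd_scale)
}

#' Write a harmonized instrument table to tab-delimited text
#'
#' @param x an `instrument_set`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_instruments <- function(x, path) {
  cols <- intersect(c("rsid", "effect_allele", "other_allele", "beta_x",
                      "se_x", "beta_y", "se_y", "eaf", "flipped",
                      "palindromic"), names(x))
  write.table(as.data.frame(x)[, cols], path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write an association table to tab-delimited text
#' @param assoc a `variant_associations` data frame.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_associations <- function(assoc, path) {
  write.table(as.data.frame(assoc), path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}
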