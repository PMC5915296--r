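test_that("percent/log conversions are correct and mutually inverse", {
  expect_equal(percent_to_log(0), 0)
  expect_equal(percent_to_log(100), log(2))
  expect_equal(round(percent_to_log(92), 4), 0.6523)
  expect_equal(log_to_percent(0), 0)
  expect_equal(round(log_to_percent(0.65)), 92)
  x <- c(-98.7, -50, 0, 1, 37.2, 450, 9999)
  expect_equal(percent_to_log(log_to_percent(percent_to_log(x))),
               percent_to_log(x), tolerance = 1e-12)
  expect_equal(log_to_percent(percent_to_log(x)), x, tolerance = 1e-12)
  expect_error(percent_to_log(-100), "-100")
})

test_that("reading a well-formed table round-trips every field", {
  path <- write_temp_assoc(example_assoc())
  got <- read_associations(path, scale = "log-units", trait = "ggt")
  expect_equal(nrow(got), 3L)
  expect_equal(got$beta, example_assoc()$beta)
  expect_equal(got$se, example_assoc()$se)
  expect_equal(got$eaf, example_assoc()$eaf)
  expect_true(all(got$scale == "log-units"))
  expect_true(all(got$trait == "ggt"))
  expect_equal(attr(got, "n_rejected"), 0L)

  # comma-delimited autodetection
  pcsv <- write_temp_assoc(example_assoc(), sep = ",")
  expect_equal(read_associations(pcsv, "log-units")$beta,
               example_assoc()$beta)
})

test_that("rows with missing se are rejected and counted", {
  df <- example_assoc()
  df$se[2] <- NA
  path <- write_temp_assoc(df)
  expect_message(got <- read_associations(path, scale = "log-units"),
                 "1 row")
  expect_equal(nrow(got), 2L)
  expect_equal(attr(got, "n_rejected"), 1L)
  expect_false("rs2" %in% got$rsid)
})

test_that("a missing mapped column is a format error naming it", {
  df <- example_assoc()
  names(df)[names(df) == "se"] <- "stderr"
  path <- write_temp_assoc(df)
  expect_error(read_associations(path, scale = "log-units"), "se")
  got <- read_associations(path, scale = "log-units",
                           column_map = c(se = "stderr"))
  expect_equal(got$se, example_assoc()$se)
})

test_that("association invariants are enforced", {
  df <- example_assoc(); df$scale <- "log-units"; df$trait <- "x"
  df2 <- df; df2$rsid[2] <- "rs1"
  expect_error(validate_associations(df2), "duplicate")
  df3 <- df; df3$se[1] <- 0
  expect_error(validate_associations(df3), "se")
  df4 <- df; df4$effect_allele[1] <- "N"
  expect_error(validate_associations(df4), "allele")
  df5 <- df; df5$eaf[1] <- 1.2
  expect_error(validate_associations(df5), "eaf")
})

test_that("percent-change tables convert to log units with delta-method SEs", {
  df <- example_assoc(); df$scale <- "percent-change"; df$trait <- "x"
  df$beta <- c(10, -5, 40); df$se <- c(2, 1, 4)
  out <- convert_scale(validate_associations(df), "log-units")
  expect_equal(out$beta, log1p(c(10, -5, 40) / 100))
  expect_equal(out$se, c(2, 1, 4) / (100 + c(10, -5, 40)))
  expect_equal(unique(out$scale), "log-units")
})

make_pair <- function(ea_y, oa_y, beta_y = 0.02) {
  ex <- example_assoc()[1, ]; ex$scale <- "log-units"; ex$trait <- "x"
  ou <- ex; ou$scale <- "log-odds"; ou$trait <- "y"
  ou$effect_allele <- ea_y; ou$other_allele <- oa_y; ou$beta <- beta_y
  list(ex = validate_associations(ex), ou = validate_associations(ou))
}

test_that("harmonization aligns, flips and strand-complements alleles", {
  # exposure rs1 is A/G
  same <- make_pair("A", "G")
  h <- harmonize(same$ex, same$ou)
  expect_equal(h$beta_y, 0.02)
  expect_false(h$flipped)

  rev <- make_pair("G", "A")
  h <- harmonize(rev$ex, rev$ou)
  expect_equal(h$beta_y, -0.02)
  expect_true(h$flipped)

  # opposite strand: A/G reported as T/C
  strand <- make_pair("T", "C")
  h <- harmonize(strand$ex, strand$ou)
  expect_equal(h$beta_y, 0.02)
  expect_false(h$flipped)

  # opposite strand and swapped: C/T
  both <- make_pair("C", "T")
  h <- harmonize(both$ex, both$ou)
  expect_equal(h$beta_y, -0.02)
  expect_true(h$flipped)

  # lower case matches too
  lc <- make_pair("a", "g")
  expect_equal(harmonize(lc$ex, lc$ou)$beta_y, 0.02)

  # irreconcilable alleles name the rsid
  bad <- make_pair("A", "C")
  expect_error(harmonize(bad$ex, bad$ou), "rs1")
})

test_that("harmonization is idempotent and double flip restores the sign", {
  ex <- validate_associations(
    cbind(example_assoc(), scale = "log-units", trait = "x"))
  ou <- ex; ou$scale <- "log-odds"; ou$beta <- c(0.01, -0.02, 0.03)
  h1 <- harmonize(ex, validate_associations(ou))
  # feed the harmonized outcome back in: nothing changes
  ou2 <- ou; ou2$beta <- h1$beta_y
  h2 <- harmonize(ex, validate_associations(ou2))
  expect_equal(h2$beta_y, h1$beta_y)
  expect_false(any(h2$flipped))
  # swapping outcome alleles twice restores beta_y
  ou3 <- ou
  ou3$effect_allele <- ex$other_allele; ou3$other_allele <- ex$effect_allele
  ou3$beta <- -ou$beta
  h3 <- harmonize(ex, validate_associations(ou3))
  expect_equal(h3$beta_y, h1$beta_y)
})

test_that("palindromic variants follow the configured policy", {
  ex <- example_assoc()
  ex$effect_allele[1] <- "A"; ex$other_allele[1] <- "T"  # palindromic
  ex$scale <- "log-units"; ex$trait <- "x"
  ou <- ex; ou$scale <- "log-odds"
  ex <- validate_associations(ex); ou <- validate_associations(ou)

  h_flag <- harmonize(ex, ou, "flag")
  expect_equal(nrow(h_flag), 3L)
  expect_equal(h_flag$palindromic, c(TRUE, FALSE, FALSE))

  expect_message(h_drop <- harmonize(ex, ou, "drop"), "palindromic")
  expect_equal(nrow(h_drop), 2L)
  expect_false("rs1" %in% h_drop$rsid)

  h_keep <- harmonize(ex, ou, "keep")
  expect_equal(nrow(h_keep), 3L)
})

test_that("exposure variants missing from the outcome are dropped with a message", {
  ex <- validate_associations(
    cbind(example_assoc(), scale = "log-units", trait = "x"))
  ou <- ex[1:2, ]; ou$scale <- "log-odds"
  expect_message(h <- harmonize(ex, validate_associations(ou)), "rs3")
  expect_equal(nrow(h), 2L)
  # empty intersection errors
  ou2 <- ou; ou2$rsid <- c("rsX", "rsY")
  expect_error(suppressMessages(
    harmonize(ex, validate_associations(ou2))), "no shared")
})

test_that("per-SD rescaling scales estimate and CI but not the z or p", {
  est <- wald_ratio(0.10, 0.01, 0.02, 0.05)
  scaled <- rescale_per_sd(est, 0.65)
  expect_equal(scaled$beta, est$beta * 0.65)
  expect_equal(scaled$se, est$se * 0.65)
  expect_equal(scaled$ci_low, est$ci_low * 0.65)
  expect_equal(scaled$beta / scaled$se, est$beta / est$se)
  expect_equal(scaled$p, est$p)
  expect_equal(rescale_per_sd(est, 1), est)
  expect_error(rescale_per_sd(est, 0), "sd_scale")
})

test_that("instrument tables round-trip through the tab-delimited format", {
  x <- make_instruments(6, seed = 11)
  path <- tempfile(fileext = ".tsv")
  write_instruments(x, path)
  back <- read.delim(path)
  expect_equal(back$beta_x, x$beta_x)
  expect_equal(back$se_y, x$se_y)
  expect_equal(nrow(back), 6L)
})
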