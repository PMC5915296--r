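# Fixture builders and independent oracles shared across tests.

# Random harmonized instrument set with positive-definite SEs.
make_instruments <- function(l, seed, sd_scale = 1) {
  set.seed(seed)
  df <- data.frame(
    rsid = sprintf("rs%03d", seq_len(l)),
    effect_allele = sample(c("A", "C", "G", "T"), l, replace = TRUE),
    other_allele = rep("G", l),
    beta_x = rnorm(l, 0.05, 0.03),
    se_x = runif(l, 0.005, 0.02),
    beta_y = rnorm(l, 0, 0.02),
    se_y = runif(l, 0.01, 0.04),
    eaf = runif(l, 0.1, 0.45),
    stringsAsFactors = FALSE)
  df$beta_x[df$beta_x == 0] <- 0.01
  instrument_set(df, sd_scale = sd_scale)
}

# Independent WLS-through-origin oracle for IVW, via lm().
ivw_oracle <- function(x) {
  fit <- lm(beta_y ~ 0 + beta_x, data = as.data.frame(x),
            weights = 1 / x$se_y^2)
  s <- summary(fit)
  sigma <- s$sigma
  se_unit <- s$coefficients[1, 2] / sigma  # SE with residual scale fixed at 1
  list(theta = unname(coef(fit)[1]),
       se_fixed = se_unit,
       se_random = se_unit * max(1, sigma))
}

# Independent WLS-with-intercept oracle for MR-Egger, via lm().
egger_oracle <- function(x) {
  d <- as.data.frame(x)
  neg <- d$beta_x < 0
  d$beta_x[neg] <- -d$beta_x[neg]
  d$beta_y[neg] <- -d$beta_y[neg]
  fit <- lm(beta_y ~ beta_x, data = d, weights = 1 / d$se_y^2)
  s <- summary(fit)
  sigma <- s$sigma
  list(intercept = unname(coef(fit)[1]),
       slope = unname(coef(fit)[2]),
       se_intercept = s$coefficients[1, 2] / sigma * max(1, sigma),
       se_slope = s$coefficients[2, 2] / sigma * max(1, sigma),
       sigma = sigma)
}

# Write a variant association table to a temp file, return the path.
write_temp_assoc <- function(df, sep = "\t") {
  path <- tempfile(fileext = ".tsv")
  write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  path
}

example_assoc <- function() {
  data.frame(
    rsid = c("rs1", "rs2", "rs3"),
    effect_allele = c("A", "C", "T"),
    other_allele = c("G", "T", "C"),
    beta = c(0.05, -0.03, 0.08),
    se = c(0.01, 0.012, 0.02),
    eaf = c(0.3, 0.2, 0.4),
    stringsAsFactors = FALSE)
}
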