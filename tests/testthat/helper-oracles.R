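# Fixture builders and independent oracles shared across the suite.
# Oracles deliberately route through stats::lm / textbook formulas so they
# stay independent of the package's explicit normal-equation code paths.

make_table <- function(bx, by, sy, sx = rep(0.01, length(bx)),
                       exposure = "hdl", snp = paste0("rs", seq_along(bx)),
                       oriented = NA_character_) {
  df <- data.frame(snp = snp, effect_allele = "A", other_allele = "G",
                   eaf = 0.3, stringsAsFactors = FALSE)
  df[[paste0("beta_", exposure)]] <- bx
  df[[paste0("se_", exposure)]] <- sx
  df[[paste0("pval_", exposure)]] <- 2 * pnorm(-abs(bx / sx))
  df$beta_mat <- by
  df$se_mat <- sy
  df$beta_fet <- 0
  df$se_fet <- sy
  as_instrument_table(df, exposure, oriented = oriented)
}

rand_table <- function(n = 10, exposure = "hdl") {
  bx <- rnorm(n)
  bx[abs(bx) < 0.05] <- 0.05
  make_table(bx, by = rnorm(n, 0, 0.2), sy = runif(n, 0.01, 0.2),
             sx = runif(n, 0.005, 0.05), exposure = exposure)
}

# zero-intercept weighted least squares via lm
ivw_oracle <- function(bx, by, sy, random_effects = TRUE) {
  fit <- stats::lm(by ~ 0 + bx, weights = 1 / sy^2)
  s <- summary(fit)
  se_fe <- s$coefficients[1, 2] / s$sigma
  list(estimate = unname(coef(fit)[1]),
       se = se_fe * if (random_effects) max(1, s$sigma) else 1)
}

egger_oracle <- function(bx, by, sy, random_effects = TRUE) {
  fit <- stats::lm(by ~ bx, weights = 1 / sy^2)
  s <- summary(fit)
  se_fe <- s$coefficients[, 2] / s$sigma
  mult <- if (random_effects) max(1, s$sigma) else 1
  list(intercept = unname(coef(fit)[1]), slope = unname(coef(fit)[2]),
       se_intercept = se_fe[1] * mult, se_slope = se_fe[2] * mult)
}

# textbook simple-regression slope and SE
marginal_slope <- function(g, y) {
  gc <- g - mean(g); yc <- y - mean(y); sgg <- sum(gc^2)
  b <- sum(gc * yc) / sgg
  se <- sqrt((sum(yc^2) - b^2 * sgg) / (length(y) - 2) / sgg)
  c(beta = b, se = se)
}

# three-generation single-SNP duo world with direct genotype effects on BW;
# used by partition tests where the lipid layer is irrelevant
sim_duo_snp <- function(n, p, beta_mat, beta_fet) {
  g_gm <- rbinom(n, 2, p)
  g_mo <- (g_gm == 2) + (g_gm == 1) * rbinom(n, 1, 0.5) + rbinom(n, 1, p)
  g_of <- (g_mo == 2) + (g_mo == 1) * rbinom(n, 1, 0.5) + rbinom(n, 1, p)
  list(g_mother = g_mo, g_offspring = g_of,
       bw_mother = beta_mat * g_gm + beta_fet * g_mo + rnorm(n),
       bw_offspring = beta_mat * g_mo + beta_fet * g_of + rnorm(n))
}

# write a simulated summary corpus to disk in the pipeline's input formats;
# returns the run_config paths
write_corpus <- function(tab, dir, n_sample1 = 188577) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(hdl = file.path(dir, "hdl.tsv"), ldl = file.path(dir, "ldl.tsv"),
             tg = file.path(dir, "tg.tsv"))
  for (lip in c("hdl", "ldl", "tg")) {
    ss <- data.frame(snp = tab$snp, effect_allele = tab$effect_allele,
                     other_allele = tab$other_allele, eaf = tab$eaf,
                     beta = tab[[paste0("beta_", lip)]],
                     se = tab[[paste0("se_", lip)]],
                     pvalue = tab[[paste0("pval_", lip)]],
                     n = n_sample1, trait = lip, stringsAsFactors = FALSE)
    class(ss) <- c("summary_stats", "data.frame")
    write_summary_stats(ss, paths[[lip]])
  }
  out <- file.path(dir, "bw_partitioned.tsv")
  write_partitioned_effects(tab, out)
  list(sample1 = paths, sample2 = out)
}
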