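LIPIDS <- c("hdl", "ldl", "tg")

# non-ambiguous allele pairs (one purine/one pyrimidine) used when
# fabricating SNP identities, so harmonization never meets a palindrome
# unless a test builds one on purpose
SAFE_ALLELE_PAIRS <- matrix(c("A", "G", "A", "C", "T", "G", "T", "C"),
                            ncol = 2, byrow = TRUE)

#' Generative configuration for mother-offspring duo simulation
#'
#' Describes the assumed causal diagram: maternal genotypes under
#' Hardy-Weinberg equilibrium, Mendelian transmission (coefficient 1/2) to
#' the offspring, three correlated lipid exposures determined by genotype
#' plus correlated residuals (unit total variance per lipid), and birth
#' weight built from the maternal lipid path (`beta_mat_true`), the fetal
#' genetic analogue (`beta_fet_true`), optional per-SNP direct (pleiotropic)
#' maternal-path effects, and residual noise scaled to unit total variance.
#'
#' @param n_snps number of SNPs.
#' @param allele_freqs per-SNP effect-allele frequency in (0.01, 0.99).
#' @param exposure_effects `n_snps x 3` matrix of per-allele lipid effects
#'   (columns hdl, ldl, tg; lipid SD units).
#' @param exposure_corr 3x3 positive-definite residual correlation of the
#'   lipids.
#' @param beta_mat_true length-3 maternal causal effect of each lipid on
#'   offspring birth weight (BW SD per lipid SD).
#' @param beta_fet_true length-3 fetal-side analogue.
#' @param pleiotropy per-SNP direct effect of the maternal allele on birth
#'   weight, bypassing the lipids.
#' @param pleiotropy_mode label recording how `pleiotropy` was built
#'   (`none`, `balanced`, `directional`, `inside-violating`); informational.
#' @param n_sample1 size of the independent exposure-GWAS cohort.
#' @param n_duos number of mother-offspring duos (sample 2).
#' @param seed mandatory integer seed (< 2^31 - 16; nearby offsets are used
#'   to decouple the independent cohorts).
#' @param overlap_fraction fraction of sample-2 individuals shared between
#'   the own-BW and offspring-BW marginal GWAS; induces the sampling
#'   covariance consumed by [partition_effects()] (default 0).
#' @return list of class `sim_config`; SNP identities (`rs1`, `rs2`, ... and
#'   alleles) are fixed deterministically from the seed.
#' @export
sim_config <- function(n_snps, allele_freqs, exposure_effects,
                       exposure_corr = diag(3),
                       beta_mat_true = c(0, 0, 0),
                       beta_fet_true = c(0, 0, 0),
                       pleiotropy = rep(0, n_snps),
                       pleiotropy_mode = "none",
                       n_sample1 = 1000, n_duos = 1000, seed,
                       overlap_fraction = 0) {
  if (missing(seed)) stop2("seed is mandatory")
  if (seed >= 2^31 - 16) stop2("seed must stay below 2^31 - 16")
  exposure_effects <- as.matrix(exposure_effects)
  stopifnot(length(allele_freqs) == n_snps,
            nrow(exposure_effects) == n_snps, ncol(exposure_effects) == 3,
            length(beta_mat_true) == 3, length(beta_fet_true) == 3,
            length(pleiotropy) == n_snps,
            overlap_fraction >= 0, overlap_fraction <= 1)
  if (any(allele_freqs <= 0.01 | allele_freqs >= 0.99)) {
    stop2("allele_freqs must lie in (0.01, 0.99)")
  }
  ch <- tryCatch(chol(exposure_corr), error = function(e) NULL)
  if (is.null(ch)) stop2("exposure_corr must be positive-definite")
  colnames(exposure_effects) <- LIPIDS
  snps <- with_seed(seed, {
    pick <- sample.int(nrow(SAFE_ALLELE_PAIRS), n_snps, replace = TRUE)
    data.frame(snp = paste0("rs", seq_len(n_snps)),
               effect_allele = SAFE_ALLELE_PAIRS[pick, 1],
               other_allele = SAFE_ALLELE_PAIRS[pick, 2],
               stringsAsFactors = FALSE)
  })
  structure(list(n_snps = as.integer(n_snps), allele_freqs = allele_freqs,
                 exposure_effects = exposure_effects,
                 exposure_corr = exposure_corr,
                 beta_mat_true = beta_mat_true,
                 beta_fet_true = beta_fet_true,
                 pleiotropy = pleiotropy, pleiotropy_mode = pleiotropy_mode,
                 n_sample1 = as.integer(n_sample1),
                 n_duos = as.integer(n_duos), seed = as.integer(seed),
                 overlap_fraction = overlap_fraction, snps = snps),
            class = "sim_config")
}

hwe_genotypes <- function(n, freqs) {
  m <- length(freqs)
  matrix(stats::rbinom(n * m, 2L, rep(freqs, each = n)), nrow = n, ncol = m)
}

# one allele transmitted per locus: heterozygous parents transmit the
# effect allele with probability 1/2
transmit_alleles <- function(G) {
  het <- G == 1L
  out <- (G == 2L) * 1L
  out[het] <- stats::rbinom(sum(het), 1L, 0.5)
  out
}

child_genotypes <- function(G_parent, freqs) {
  n <- nrow(G_parent)
  other <- matrix(stats::rbinom(n * ncol(G_parent), 1L,
                                rep(freqs, each = n)),
                  nrow = n)
  transmit_alleles(G_parent) + other
}

genetic_lipid_variance <- function(config) {
  v2pq <- 2 * config$allele_freqs * (1 - config$allele_freqs)
  colSums(v2pq * config$exposure_effects^2)
}

make_lipids <- function(G, config) {
  score <- G %*% config$exposure_effects
  gvar <- genetic_lipid_variance(config)
  if (any(gvar >= 1)) {
    stop2("exposure effect sizes imply negative lipid residual variance")
  }
  n <- nrow(G)
  E <- matrix(stats::rnorm(n * 3), n, 3) %*% chol(config$exposure_corr)
  E <- sweep(E, 2, sqrt(1 - gvar), `*`)
  score + E
}

make_bw <- function(lipids_maternal, G_fetus, G_maternal, config) {
  signal <- drop(lipids_maternal %*% config$beta_mat_true +
                   (G_fetus %*% config$exposure_effects) %*% config$beta_fet_true +
                   G_maternal %*% config$pleiotropy)
  v <- stats::var(signal)
  if (v >= 1) {
    stop2("effect sizes imply negative birth-weight residual variance")
  }
  signal + stats::rnorm(length(signal), 0, sqrt(1 - v))
}

#' Simulate genotyped mother-offspring duos
#'
#' Draws three generations at each SNP — grandmaternal genotypes under
#' Hardy-Weinberg, maternal genotypes by Mendelian transmission plus a
#' random paternal allele, offspring genotypes likewise — so that both the
#' mothers' own birth weights (grandmaternal intrauterine path) and the
#' offspring birth weights (maternal path) exist in one coherent pedigree.
#' Lipids and birth weights follow the generative model of [sim_config()].
#'
#' @param config a `sim_config`.
#' @return list of class `duo_data`: genotype matrices `g_grandmother`,
#'   `g_mother`, `g_offspring` (`n_duos x n_snps`), lipid matrices
#'   `lipids_grandmother`, `lipids_mother`, vectors `bw_mother`,
#'   `bw_offspring`, and the `config`.
#' @export
simulate_duos <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    n <- config$n_duos
    p <- config$allele_freqs
    g_gm <- hwe_genotypes(n, p)
    g_mo <- child_genotypes(g_gm, p)
    g_of <- child_genotypes(g_mo, p)
    lip_gm <- make_lipids(g_gm, config)
    lip_mo <- make_lipids(g_mo, config)
    bw_mo <- make_bw(lip_gm, g_mo, g_gm, config)
    bw_of <- make_bw(lip_mo, g_of, g_mo, config)
    structure(list(g_grandmother = g_gm, g_mother = g_mo, g_offspring = g_of,
                   lipids_grandmother = lip_gm, lipids_mother = lip_mo,
                   bw_mother = bw_mo, bw_offspring = bw_of, config = config),
              class = "duo_data")
  })
}

#' Simulate an independent exposure-GWAS cohort (sample 1)
#'
#' @param config a `sim_config`.
#' @param n cohort size (default `config$n_sample1`).
#' @return list of class `cohort_data` with `genotypes` and `lipids`.
#' @export
simulate_cohort <- function(config, n = config$n_sample1) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed + 1L, {
    G <- hwe_genotypes(n, config$allele_freqs)
    structure(list(genotypes = G, lipids = make_lipids(G, config),
                   config = config), class = "cohort_data")
  })
}

# column-wise simple regression of y on each column of G
marginal_regression <- function(G, y) {
  n <- length(y)
  gc <- sweep(G, 2, colMeans(G))
  yc <- y - mean(y)
  sgg <- colSums(gc^2)
  mono <- sgg == 0
  beta <- rep(NA_real_, ncol(G))
  se <- rep(NA_real_, ncol(G))
  ok <- !mono
  beta[ok] <- colSums(gc[, ok, drop = FALSE] * yc) / sgg[ok]
  rv <- (sum(yc^2) - beta[ok]^2 * sgg[ok]) / (n - 2)
  se[ok] <- sqrt(rv / sgg[ok])
  p <- 2 * stats::pt(-abs(beta / se), df = n - 2)
  list(beta = beta, se = se, pvalue = p, monomorphic = mono)
}

#' Per-lipid SNP association summary statistics from a sample-1 cohort
#'
#' Simple per-SNP regression of each lipid on genotype dosage, emitted in
#' the standard summary dialect. Monomorphic SNPs are dropped with a
#' warning.
#'
#' @param config a `sim_config`.
#' @param cohort optional pre-built [simulate_cohort()] output.
#' @return named list (hdl, ldl, tg) of `summary_stats` data frames.
#' @export
summarize_sample1 <- function(config, cohort = simulate_cohort(config)) {
  G <- cohort$genotypes
  n <- nrow(G)
  eaf <- colMeans(G) / 2
  out <- lapply(seq_along(LIPIDS), function(k) {
    fit <- marginal_regression(G, cohort$lipids[, k])
    if (any(fit$monomorphic)) {
      warn2("dropping ", sum(fit$monomorphic), " monomorphic SNP(s)")
    }
    keep <- !fit$monomorphic
    df <- data.frame(snp = config$snps$snp[keep],
                     effect_allele = config$snps$effect_allele[keep],
                     other_allele = config$snps$other_allele[keep],
                     eaf = eaf[keep], beta = fit$beta[keep],
                     se = fit$se[keep], pvalue = fit$pvalue[keep],
                     n = n, trait = LIPIDS[k], stringsAsFactors = FALSE)
    class(df) <- c("summary_stats", "data.frame")
    df
  })
  stats::setNames(out, LIPIDS)
}

conditional_regression_all <- function(A, B, y) {
  n <- length(y)
  a <- sweep(A, 2, colMeans(A)); b <- sweep(B, 2, colMeans(B))
  yc <- y - mean(y)
  Saa <- colSums(a^2); Sbb <- colSums(b^2); Sab <- colSums(a * b)
  Say <- colSums(a * yc); Sby <- colSums(b * yc); Syy <- sum(yc^2)
  det <- Saa * Sbb - Sab^2
  bad <- det <= .Machine$double.eps * Saa * Sbb
  beta_mat <- (Sbb * Say - Sab * Sby) / det
  beta_fet <- (Saa * Sby - Sab * Say) / det
  sigma2 <- (Syy - beta_mat * Say - beta_fet * Sby) / (n - 3)
  beta_mat[bad] <- NA; beta_fet[bad] <- NA
  list(beta_mat = beta_mat, se_mat = sqrt(sigma2 * Sbb / det),
       beta_fet = beta_fet, se_fet = sqrt(sigma2 * Saa / det),
       cov_mat_fet = -sigma2 * Sab / det, collinear = bad)
}

#' Sample-2 summary statistics from simulated duos
#'
#' Emits, per SNP, the three association sets a biobank-style sample 2
#' provides: the marginal own-genotype-on-own-birth-weight regression (the
#' mothers, whose birth weights trace back to the grandmaternal
#' generation), the marginal maternal-genotype-on-offspring-birth-weight
#' regression, and the conditional two-covariate regression that is the
#' truth-level partition. The marginal pair feeds [partition_effects()];
#' the conditional table is its oracle.
#'
#' @param duos a `duo_data` object.
#' @return list with `pairs` (an `unpartitioned_pair` data frame:
#'   `beta_own`, `se_own`, `beta_offspring`, `se_offspring`, `overlap_cov`)
#'   and `conditional` (a `partitioned_effect` data frame).
#' @export
summarize_sample2 <- function(duos) {
  stopifnot(inherits(duos, "duo_data"))
  config <- duos$config
  own <- marginal_regression(duos$g_mother, duos$bw_mother)
  off <- marginal_regression(duos$g_mother, duos$bw_offspring)
  if (any(own$monomorphic)) {
    warn2("dropping ", sum(own$monomorphic), " monomorphic SNP(s)")
  }
  keep <- !own$monomorphic
  # both marginal GWAS use the same mothers here, so their estimates
  # covary; overlap_fraction scales the theoretical full-overlap value
  ov <- config$overlap_fraction * overlap_covariance(duos, keep)
  pairs <- data.frame(snp = config$snps$snp[keep],
                      effect_allele = config$snps$effect_allele[keep],
                      other_allele = config$snps$other_allele[keep],
                      eaf = colMeans(duos$g_mother)[keep] / 2,
                      beta_own = own$beta[keep], se_own = own$se[keep],
                      beta_offspring = off$beta[keep],
                      se_offspring = off$se[keep],
                      overlap_cov = ov, stringsAsFactors = FALSE)
  class(pairs) <- c("unpartitioned_pair", "data.frame")
  cond <- conditional_regression_all(duos$g_mother, duos$g_offspring,
                                     duos$bw_offspring)
  conditional <- data.frame(snp = config$snps$snp[keep],
                            effect_allele = config$snps$effect_allele[keep],
                            other_allele = config$snps$other_allele[keep],
                            eaf = colMeans(duos$g_mother)[keep] / 2,
                            beta_mat = cond$beta_mat[keep],
                            se_mat = cond$se_mat[keep],
                            beta_fet = cond$beta_fet[keep],
                            se_fet = cond$se_fet[keep],
                            cov_mat_fet = cond$cov_mat_fet[keep],
                            stringsAsFactors = FALSE)
  class(conditional) <- c("partitioned_effect", "data.frame")
  list(pairs = pairs, conditional = conditional)
}

# sampling covariance of the two marginal slopes when estimated on the same
# mothers: cov(b_own, b_off) = cov(bw_mother, bw_offspring | g) / S_gg,
# estimated from residual cross-products
overlap_covariance <- function(duos, keep) {
  gc <- sweep(duos$g_mother, 2, colMeans(duos$g_mother))
  sgg <- colSums(gc^2)
  y1 <- duos$bw_mother - mean(duos$bw_mother)
  y2 <- duos$bw_offspring - mean(duos$bw_offspring)
  b1 <- colSums(gc * y1) / sgg
  b2 <- colSums(gc * y2) / sgg
  n <- nrow(gc)
  r12 <- (sum(y1 * y2) - b1 * b2 * sgg) / (n - 2)
  (r12 / sgg)[keep]
}

#' Direct summary-level simulation of a harmonized two-sample corpus
#'
#' Bypasses individual-level simulation: exposure and partitioned outcome
#' betas are drawn from their asymptotic normal sampling distributions with
#' standard errors matched to the configured sample sizes
#' (`se_zx = 1/sqrt(2p(1-p) n_sample1)` for a unit-variance lipid;
#' maternal/fetal SEs carry the closed-form `sqrt(20/9)` partition
#' inflation over a plain GWAS at `n_duos`). This is what makes
#' replication-heavy calibration studies (coverage, power, breakdown)
#' affordable at biobank sample sizes.
#'
#' @param config a `sim_config`.
#' @return a harmonized (unoriented) `instrument_table` over all SNPs.
#' @export
simulate_summary <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed + 2L, {
    p <- config$allele_freqs
    v2pq <- 2 * p * (1 - p)
    se_zx <- sqrt(1 / (v2pq * config$n_sample1))
    B <- config$exposure_effects
    true_mat <- drop(B %*% config$beta_mat_true) + config$pleiotropy
    true_fet <- drop(B %*% config$beta_fet_true)
    se_part <- sqrt(20 / 9) * sqrt(1 / (v2pq * config$n_duos))
    df <- data.frame(snp = config$snps$snp,
                     effect_allele = config$snps$effect_allele,
                     other_allele = config$snps$other_allele,
                     eaf = p, stringsAsFactors = FALSE)
    for (k in seq_along(LIPIDS)) {
      b <- stats::rnorm(config$n_snps, B[, k], se_zx)
      df[[paste0("beta_", LIPIDS[k])]] <- b
      df[[paste0("se_", LIPIDS[k])]] <- se_zx
      df[[paste0("pval_", LIPIDS[k])]] <- 2 * stats::pnorm(-abs(b / se_zx))
    }
    # maternal and fetal estimates from a partition of the same two
    # marginals are negatively correlated: cov = -16/9 se_gwas^2, i.e.
    # correlation -0.8 given var = 20/9 se_gwas^2
    rho <- -0.8
    z1 <- stats::rnorm(config$n_snps)
    z2 <- stats::rnorm(config$n_snps)
    df$beta_mat <- true_mat + se_part * z1
    df$se_mat <- se_part
    df$beta_fet <- true_fet + se_part * (rho * z1 + sqrt(1 - rho^2) * z2)
    df$se_fet <- se_part
    df$cov_mat_fet <- rho * se_part^2
    new_instrument_table(df, LIPIDS)
  })
}

#' Names of the built-in simulation scenarios
#' @return character vector.
#' @export
scenario_names <- function() {
  c("paper-null", "maternal-positive", "directional-pleiotropy",
    "inside-violation", "invalid-40pct", "invalid-60pct")
}

# instrument-set membership emulating 185 lipid SNPs with marginal counts
# 96 (hdl), 82 (ldl), 60 (tg) and 50 SNPs on >= 2 lipids
scenario_membership <- function() {
  counts <- c(hdl_only = 58, ldl_only = 47, tg_only = 30, hdl_ldl = 20,
              hdl_tg = 15, ldl_tg = 12, all = 3)
  member <- matrix(FALSE, sum(counts), 3, dimnames = list(NULL, LIPIDS))
  i <- 0
  add <- function(k, which) {
    member[i + seq_len(k), which] <<- TRUE
    i <<- i + k
  }
  add(counts["hdl_only"], "hdl"); add(counts["ldl_only"], "ldl")
  add(counts["tg_only"], "tg"); add(counts["hdl_ldl"], c("hdl", "ldl"))
  add(counts["hdl_tg"], c("hdl", "tg")); add(counts["ldl_tg"], c("ldl", "tg"))
  add(counts["all"], LIPIDS)
  member
}

#' Built-in simulation scenario presets
#'
#' Each preset is a fully specified stated world sharing one skeleton: 185
#' SNPs whose per-lipid instrument-set sizes are 96 (HDL-C), 82 (LDL-C) and
#' 60 (triglycerides); allele frequencies uniform on (0.05, 0.95); Gaussian
#' per-SNP lipid effects rescaled so each lipid's instruments explain
#' exactly 10% of its variance; lipid residual correlations
#' (hdl-ldl 0.1, hdl-tg -0.4, ldl-tg 0.3); sample sizes 188,577
#' (exposure GWAS) and 230,069 (partitioned birth-weight GWAS).
#'
#' Presets differ only in the causal/pleiotropic structure:
#' \describe{
#'   \item{paper-null}{no maternal or fetal lipid effects, no pleiotropy.}
#'   \item{maternal-positive}{maternal effects (0, 0.1, 0): LDL-C raises
#'     birth weight by 0.1 SD per lipid SD.}
#'   \item{directional-pleiotropy}{null causal effects plus a +0.02 direct
#'     maternal-path effect at every SNP, signed relative to the
#'     HDL-C-raising allele so it survives orientation as a constant
#'     offset.}
#'   \item{inside-violation}{direct effects proportional to instrument
#'     strength (0.3 x the HDL-C beta), violating InSIDE.}
#'   \item{invalid-40pct / invalid-60pct}{true HDL-C maternal effect 0.1;
#'     HDL-C instruments carrying ~40% (resp. ~60%) of the total IVW weight
#'     receive a direct effect of 0.2 x their HDL-C beta, i.e. a +0.2
#'     Wald-ratio offset, bracketing the weighted median's breakdown
#'     point.}
#' }
#'
#' @param name one of [scenario_names()].
#' @param seed mandatory integer seed.
#' @param n_sample1,n_duos overrides for the two sample sizes (the defaults
#'   match the emulated consortia; shrink them for individual-level
#'   simulation, which is memory-hungry at biobank scale).
#' @return a `sim_config`.
#' @export
scenario <- function(name, seed, n_sample1 = 188577, n_duos = 230069) {
  if (missing(seed)) stop2("seed is mandatory")
  if (!name %in% scenario_names()) {
    stop2("unknown scenario '", name, "'; available: ",
          paste(scenario_names(), collapse = ", "))
  }
  member <- scenario_membership()
  n_snps <- nrow(member)
  skeleton <- with_seed(seed, {
    freqs <- stats::runif(n_snps, 0.05, 0.95)
    B <- matrix(0, n_snps, 3, dimnames = list(NULL, LIPIDS))
    v2pq <- 2 * freqs * (1 - freqs)
    # the emulated panel is GWAS-selected, so every member must be
    # detectable at P < 5e-8 in a sample of 188,577: per-SNP variance
    # explained gets an exponential spectrum above a floor that puts the
    # association z-score non-centrality at >= 9
    ve_floor <- 81 / 188577
    for (k in 1:3) {
      idx <- which(member[, k])
      m <- length(idx)
      e <- stats::rexp(m)
      ve <- ve_floor + e * (0.10 - m * ve_floor) / sum(e)
      B[idx, k] <- sample(c(-1, 1), m, replace = TRUE) *
        sqrt(ve / v2pq[idx])
    }
    list(freqs = freqs, B = B)
  })
  B <- skeleton$B
  freqs <- skeleton$freqs
  corr <- matrix(c(1, 0.1, -0.4,
                   0.1, 1, 0.3,
                   -0.4, 0.3, 1), 3, 3, dimnames = list(LIPIDS, LIPIDS))
  beta_mat <- c(0, 0, 0)
  alpha <- rep(0, n_snps)
  mode <- "none"
  if (name == "maternal-positive") {
    beta_mat <- c(0, 0.1, 0)
  } else if (name == "directional-pleiotropy") {
    alpha <- 0.02 * ifelse(B[, "hdl"] < 0, -1, 1)
    mode <- "directional"
  } else if (name == "inside-violation") {
    alpha <- 0.3 * B[, "hdl"]
    mode <- "inside-violating"
  } else if (name %in% c("invalid-40pct", "invalid-60pct")) {
    beta_mat <- c(0.1, 0, 0)
    frac <- if (name == "invalid-40pct") 0.4 else 0.6
    hdl_idx <- which(member[, "hdl"])
    # IVW weight of SNP j is proportional to 2p(1-p) beta_zx^2 when all
    # outcome SEs share the same sample size
    w <- 2 * freqs[hdl_idx] * (1 - freqs[hdl_idx]) * B[hdl_idx, "hdl"]^2
    ord <- with_seed(seed + 3L, sample(seq_along(hdl_idx)))
    cum <- cumsum(w[ord]) / sum(w)
    invalid <- hdl_idx[ord[cum <= frac]]
    alpha[invalid] <- 0.2 * B[invalid, "hdl"]
    mode <- "directional"
  }
  sim_config(n_snps = n_snps, allele_freqs = freqs, exposure_effects = B,
             exposure_corr = corr, beta_mat_true = beta_mat,
             beta_fet_true = c(0, 0, 0), pleiotropy = alpha,
             pleiotropy_mode = mode, n_sample1 = n_sample1, n_duos = n_duos,
             seed = seed)
}

#' Write a simulation config as a key-value text file
#' @param config a `sim_config`.
#' @param path output path.
#' @export
write_sim_config <- function(config, path) {
  num <- function(x) paste(sprintf("%.17g", x), collapse = ",")
  kv <- c(
    paste0("seed=", config$seed),
    paste0("n_snps=", config$n_snps),
    paste0("n_sample1=", config$n_sample1),
    paste0("n_duos=", config$n_duos),
    paste0("overlap_fraction=", config$overlap_fraction),
    paste0("pleiotropy_mode=", config$pleiotropy_mode),
    paste0("beta_mat_true=", num(config$beta_mat_true)),
    paste0("beta_fet_true=", num(config$beta_fet_true)),
    paste0("allele_freqs=", num(config$allele_freqs)),
    paste0("pleiotropy=", num(config$pleiotropy)),
    paste0("exposure_corr=", num(config$exposure_corr)),
    paste0("exposure_effects=", num(config$exposure_effects))
  )
  writeLines(kv, path)
  invisible(path)
}

#' Read a simulation config written by [write_sim_config()]
#' @param path file path.
#' @return a `sim_config`.
#' @export
read_sim_config <- function(path) {
  lines <- readLines(path)
  kv <- strsplit(lines[nzchar(lines)], "=", fixed = TRUE)
  vals <- stats::setNames(lapply(kv, function(x) x[2]),
                          vapply(kv, function(x) x[1], character(1)))
  num <- function(key) as.numeric(strsplit(vals[[key]], ",")[[1]])
  n_snps <- as.integer(vals$n_snps)
  sim_config(n_snps = n_snps, allele_freqs = num("allele_freqs"),
             exposure_effects = matrix(num("exposure_effects"), n_snps, 3),
             exposure_corr = matrix(num("exposure_corr"), 3, 3),
             beta_mat_true = num("beta_mat_true"),
             beta_fet_true = num("beta_fet_true"),
             pleiotropy = num("pleiotropy"),
             pleiotropy_mode = vals$pleiotropy_mode,
             n_sample1 = as.integer(vals$n_sample1),
             n_duos = as.integer(vals$n_duos),
             seed = as.integer(vals$seed),
             overlap_fraction = as.numeric(vals$overlap_fraction))
}
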