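#' Partition SNP-birth-weight associations into maternal and fetal components
#'
#' Biobank-style cohorts report two marginal associations per SNP: the
#' association of an individual's genotype with their *own* birth weight
#' (`beta_own`) and, for women, the association of their genotype with their
#' *offspring's* birth weight (`beta_offspring`). Under Mendelian
#' transmission (transmission coefficient 1/2, random mating, no paternal
#' path to the intrauterine environment) these marginals mix the
#' maternal-specific effect `beta_mat` (the intrauterine path) and the
#' fetal-specific effect `beta_fet`:
#' \deqn{E[\hat\beta_{own}] = \beta_{fet} + \tfrac12\beta_{mat}, \qquad
#'       E[\hat\beta_{off}] = \beta_{mat} + \tfrac12\beta_{fet}.}
#' Inverting gives the closed-form partition
#' \deqn{\beta_{mat} = \tfrac{4\hat\beta_{off} - 2\hat\beta_{own}}{3}, \qquad
#'       \beta_{fet} = \tfrac{4\hat\beta_{own} - 2\hat\beta_{off}}{3},}
#' which equals the regression of offspring birth weight on maternal genotype
#' conditional on offspring genotype, estimated from summary statistics.
#' Standard errors and the maternal-fetal covariance follow by linear error
#' propagation; `overlap_cov` carries any sampling covariance between the two
#' marginal estimates (non-zero when the two GWAS share individuals).
#'
#' @param pairs data frame with columns `snp` (or `snp_id`), `beta_own`,
#'   `se_own`, `beta_offspring`, `se_offspring` and optionally `overlap_cov`
#'   (default 0).
#' @return data frame of class `partitioned_effect` with columns `snp`,
#'   `beta_mat`, `se_mat`, `beta_fet`, `se_fet`, `cov_mat_fet`.
#' @seealso [conditional_duo_regression()] for the individual-level oracle.
#' @export
partition_effects <- function(pairs) {
  snp <- pairs$snp %||% pairs$snp_id
  if (is.null(snp)) stop2("pairs must carry a snp or snp_id column")
  bo <- pairs$beta_own; so <- pairs$se_own
  bf <- pairs$beta_offspring; sf <- pairs$se_offspring
  cv <- pairs$overlap_cov %||% rep(0, length(bo))
  if (any(so <= 0) || any(sf <= 0)) stop2("standard errors must be positive")

  beta_mat <- (4 * bf - 2 * bo) / 3
  beta_fet <- (4 * bo - 2 * bf) / 3
  # beta_mat = -2/3 bo + 4/3 bf ; beta_fet = 4/3 bo - 2/3 bf
  var_mat <- (4 / 9) * so^2 + (16 / 9) * sf^2 - (16 / 9) * cv
  var_fet <- (16 / 9) * so^2 + (4 / 9) * sf^2 - (16 / 9) * cv
  cov_mf <- -(8 / 9) * (so^2 + sf^2) + (20 / 9) * cv
  if (any(var_mat <= 0) || any(var_fet <= 0)) {
    stop2("overlap_cov implies non-positive partitioned variance")
  }
  out <- data.frame(snp = snp, beta_mat = beta_mat, se_mat = sqrt(var_mat),
                    beta_fet = beta_fet, se_fet = sqrt(var_fet),
                    cov_mat_fet = cov_mf, stringsAsFactors = FALSE)
  class(out) <- c("partitioned_effect", "data.frame")
  out
}

#' Forward map from maternal/fetal effects to expected marginal associations
#'
#' The expectation system inverted by [partition_effects()]; exposed for
#' round-trip checks and for constructing summary data with known truth.
#'
#' @param beta_mat,beta_fet numeric vectors.
#' @return data frame with `beta_own`, `beta_offspring`.
#' @export
expected_marginals <- function(beta_mat, beta_fet) {
  data.frame(beta_own = beta_fet + 0.5 * beta_mat,
             beta_offspring = beta_mat + 0.5 * beta_fet)
}

#' Conditional regression in genotyped mother-offspring duos
#'
#' Two-covariate least squares of offspring birth weight on maternal and
#' offspring genotype. The coefficient on maternal genotype is the
#' maternal-specific effect (intrauterine path, fetal genotype held fixed)
#' and the coefficient on offspring genotype the fetal-specific effect. This
#' is the individual-level quantity that the summary-level
#' [partition_effects()] reproduces, and serves as its oracle on simulated
#' duos.
#'
#' @param g_mother,g_offspring genotype dosage vectors (0/1/2).
#' @param bw offspring birth weight vector.
#' @param snp_id label for the returned row.
#' @return one-row `partitioned_effect` data frame.
#' @export
conditional_duo_regression <- function(g_mother, g_offspring, bw,
                                       snp_id = "snp") {
  n <- length(bw)
  if (n < 3) stop2("need at least 3 duos")
  if (stats::var(g_mother) == 0 || stats::var(g_offspring) == 0) {
    stop2("constant genotype; cannot regress")
  }
  a <- g_mother - mean(g_mother)
  b <- g_offspring - mean(g_offspring)
  y <- bw - mean(bw)
  Saa <- sum(a * a); Sbb <- sum(b * b); Sab <- sum(a * b)
  Say <- sum(a * y); Sby <- sum(b * y); Syy <- sum(y * y)
  det <- Saa * Sbb - Sab^2
  if (det <= .Machine$double.eps * Saa * Sbb) {
    stop2("collinear maternal and offspring genotypes")
  }
  beta_mat <- (Sbb * Say - Sab * Sby) / det
  beta_fet <- (Saa * Sby - Sab * Say) / det
  sigma2 <- (Syy - beta_mat * Say - beta_fet * Sby) / (n - 3)
  out <- data.frame(snp = snp_id,
                    beta_mat = beta_mat, se_mat = sqrt(sigma2 * Sbb / det),
                    beta_fet = beta_fet, se_fet = sqrt(sigma2 * Saa / det),
                    cov_mat_fet = -sigma2 * Sab / det,
                    stringsAsFactors = FALSE)
  class(out) <- c("partitioned_effect", "data.frame")
  out
}

#' Write a partitioned-effect table in the supplementary-table dialect
#' @param x `partitioned_effect` data frame (allele columns optional).
#' @param path output path.
#' @param header_lines optional comment lines.
#' @export
write_partitioned_effects <- function(x, path, header_lines = character()) {
  out <- data.frame(SNP = x$snp,
                    effect_allele = x$effect_allele %||% rep(NA, nrow(x)),
                    other_allele = x$other_allele %||% rep(NA, nrow(x)),
                    eaf = x$eaf %||% rep(NA, nrow(x)),
                    beta_mat = x$beta_mat, se_mat = x$se_mat,
                    beta_fet = x$beta_fet, se_fet = x$se_fet,
                    cov_mat_fet = x$cov_mat_fet %||% 0,
                    stringsAsFactors = FALSE)
  write_tsv(out, path, header_lines)
}
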