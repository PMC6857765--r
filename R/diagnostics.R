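#' I-squared(GX): regression-dilution diagnostic for MR-Egger
#'
#' MR-Egger assumes the exposure betas are measured without error (NOME).
#' The I2_GX statistic quantifies how far that assumption can be relaxed:
#' it is the heterogeneity of the exposure betas relative to their sampling
#' uncertainty,
#' \deqn{Q_{GX} = \sum_j w_j (\beta_{ZX,j} - \bar\beta_w)^2, \qquad
#'       I^2_{GX} = \max\!\left(0, \frac{Q_{GX} - (L-1)}{Q_{GX}}\right),}
#' with weights `1/se_zx^2` (unweighted variant) or the Egger regression
#' weights `1/se_zy^2` (egger-weighted variant). Values near 1 mean the
#' exposure-beta uncertainty is negligible relative to their spread and the
#' expected attenuation of the Egger slope is small (relative dilution
#' roughly `1 - I2_GX`).
#'
#' @param table an `instrument_table` with at least 2 SNPs.
#' @param exposure exposure label.
#' @param weighting `"unweighted"` (default) or `"egger"` (outcome-variance
#'   weights); the literature does not fix one variant, so both are exposed.
#' @param outcome outcome side supplying the Egger weights.
#' @return list of class `i2_report`: `exposure`, `weighting`, `n_snps`,
#'   `q_gx`, `i2_gx`.
#' @export
i2_gx <- function(table, exposure, weighting = c("unweighted", "egger"),
                  outcome = "maternal") {
  weighting <- match.arg(weighting)
  d <- estimator_input(table, exposure, outcome, drop_zero = FALSE)
  if (nrow(d) < 2) stop2("i2_gx needs >= 2 SNPs")
  if (anyNA(d$sx)) stop2("i2_gx needs exposure SEs")
  w <- if (weighting == "unweighted") 1 / d$sx^2 else 1 / d$sy^2
  bw <- sum(w * d$bx) / sum(w)
  q <- sum(w * (d$bx - bw)^2)
  i2 <- if (q <= 0) 0 else max(0, (q - (nrow(d) - 1)) / q)
  structure(list(exposure = exposure, weighting = weighting,
                 n_snps = nrow(d), q_gx = q, i2_gx = i2),
            class = "i2_report")
}

#' @export
print.i2_report <- function(x, ...) {
  cat(sprintf("I2_GX (%s, %s weights, %d SNPs): %.4f (Q_GX = %.1f)\n",
              x$exposure, x$weighting, x$n_snps, x$i2_gx, x$q_gx))
  invisible(x)
}

#' Funnel-plot data and asymmetry statistic
#'
#' Emits per-SNP Wald ratios against their precision (1/se) for funnel
#' plotting, plus a numerical asymmetry summary: a precision-weighted
#' regression of the ratio on its standard error. Under balanced pleiotropy
#' the ratios scatter symmetrically about the causal effect at every
#' precision and the slope is near zero; directional pleiotropy
#' concentrated in weak instruments tilts the funnel and the slope away
#' from zero.
#'
#' @param ratios data frame from [wald_ratios()] (>= 3 SNPs).
#' @return list of class `funnel_data`: `points` (snp, ratio, precision),
#'   `asymmetry` (slope, se, pvalue) and `degenerate` (TRUE when all
#'   precisions coincide, in which case the regression is undefined).
#' @export
funnel_data <- function(ratios) {
  if (nrow(ratios) < 3) stop2("funnel_data needs >= 3 SNPs")
  precision <- 1 / ratios$se_ratio
  pts <- data.frame(snp = ratios$snp, ratio = ratios$ratio,
                    precision = precision, stringsAsFactors = FALSE)
  degenerate <- stats::sd(ratios$se_ratio) == 0
  if (degenerate) {
    warn2("all instruments have identical precision; funnel asymmetry undefined")
    asym <- data.frame(slope = NA_real_, se = NA_real_, pvalue = NA_real_)
  } else {
    fit <- wls_fit(cbind(1, ratios$se_ratio), ratios$ratio, precision)
    n <- nrow(ratios)
    sigma2 <- fit$rss / (n - 2)
    se <- fit$se * sqrt(sigma2)
    tval <- fit$coef[2] / se[2]
    asym <- data.frame(slope = fit$coef[2], se = se[2],
                       pvalue = 2 * stats::pt(-abs(tval), df = n - 2))
  }
  structure(list(points = pts, asymmetry = asym, degenerate = degenerate),
            class = "funnel_data")
}

#' Scatter-plot data: per-SNP effects with fitted estimator lines
#'
#' Packages the per-SNP exposure and outcome betas (with 1-SE error bars),
#' one (intercept, slope) line per fitted estimator, and a leave-one-out
#' outlier flag marking SNPs whose removal shifts the IVW estimate by more
#' than `outlier_mult` times the median absolute leave-one-out shift.
#'
#' @param table an `instrument_table`.
#' @param fits list of `mr_estimate` rows (possibly empty); Egger lines use
#'   their intercept, all other methods pass through the origin.
#' @param exposure exposure label.
#' @param outcome outcome side.
#' @param outlier_mult threshold multiplier for the leave-one-out flag.
#' @return list of class `scatter_data` with `points` and `lines`.
#' @export
scatter_data <- function(table, fits = list(), exposure,
                         outcome = "maternal", outlier_mult = 3) {
  d <- estimator_input(table, exposure, outcome, drop_zero = FALSE)
  pts <- data.frame(snp = d$snp, beta_exposure = d$bx, se_exposure = d$sx,
                    beta_outcome = d$by, se_outcome = d$sy,
                    stringsAsFactors = FALSE)
  pts$outlier <- FALSE
  if (nrow(d) >= 3) {
    loo <- mr_loo(table, exposure, outcome)
    med <- stats::median(abs(loo$delta))
    if (med > 0) pts$outlier <- abs(loo$delta) > outlier_mult * med
  }
  if (inherits(fits, "mr_estimate")) fits <- list(fits)
  lines <- if (length(fits)) {
    do.call(rbind, lapply(fits, function(f) {
      data.frame(method = f$method, slope = f$estimate,
                 intercept = if (is.na(f$intercept)) 0 else f$intercept,
                 stringsAsFactors = FALSE)
    }))
  } else {
    data.frame(method = character(), slope = numeric(), intercept = numeric())
  }
  structure(list(points = pts, lines = lines), class = "scatter_data")
}

#' Convert an SD-scale estimate to grams
#'
#' MR estimates are expressed in standard deviations of birth weight per SD
#' of exposure; multiplying by the population SD of birth weight in grams
#' (454 g in the EGG consortium) converts them to grams for reporting.
#' Values are rounded to 2 decimals.
#'
#' @param estimate an `mr_estimate` row, or a numeric vector
#'   `c(point, ci_low, ci_high)` in SD units.
#' @param sd_grams grams per SD of birth weight (default 454).
#' @return named numeric vector `point`, `ci_low`, `ci_high` in grams.
#' @export
sd_to_grams <- function(estimate, sd_grams = 454) {
  if (sd_grams <= 0) stop2("sd_grams must be positive")
  v <- if (inherits(estimate, "data.frame")) {
    c(estimate$estimate, estimate$ci_low, estimate$ci_high)
  } else {
    estimate
  }
  if (length(v) != 3) stop2("expected point, ci_low, ci_high")
  round(stats::setNames(v * sd_grams, c("point", "ci_low", "ci_high")), 2)
}
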