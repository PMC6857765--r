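mr_estimate <- function(method, exposure, outcome, n_snps, estimate, se,
                        ci_low, ci_high, pvalue, intercept = NA_real_,
                        intercept_se = NA_real_, intercept_p = NA_real_) {
  out <- data.frame(method = method, exposure = exposure, outcome = outcome,
                    n_snps = n_snps, estimate = estimate, se = se,
                    ci_low = ci_low, ci_high = ci_high, pvalue = pvalue,
                    intercept = intercept, intercept_se = intercept_se,
                    intercept_p = intercept_p, stringsAsFactors = FALSE)
  class(out) <- c("mr_estimate", "data.frame")
  out
}

#' @export
print.mr_estimate <- function(x, ...) {
  for (i in seq_len(nrow(x))) {
    cat(sprintf("%s (%s, %s outcome, %d SNPs): %.4f (95%% CI %.4f, %.4f), p = %.3g\n",
                x$method[i], x$exposure[i], x$outcome[i], x$n_snps[i],
                x$estimate[i], x$ci_low[i], x$ci_high[i], x$pvalue[i]))
    if (!is.na(x$intercept[i])) {
      cat(sprintf("  intercept: %.4f (se %.4f), p = %.3g\n",
                  x$intercept[i], x$intercept_se[i], x$intercept_p[i]))
    }
  }
  invisible(x)
}

# Pull the (bx, sx, by, sy) quadruple for one exposure/outcome side out of an
# instrument table, dropping rows with missing or zero exposure betas.
estimator_input <- function(table, exposure, outcome, drop_zero = TRUE) {
  outcome <- match.arg(outcome, c("maternal", "fetal"))
  labs <- exposures_of(table)
  if (!exposure %in% labs) stop2("unknown exposure: ", exposure)
  bx <- table[[paste0("beta_", exposure)]]
  sx <- table[[paste0("se_", exposure)]]
  if (outcome == "maternal") {
    by <- table$beta_mat; sy <- table$se_mat
  } else {
    by <- table$beta_fet; sy <- table$se_fet
  }
  keep <- !is.na(bx) & !is.na(by) & !is.na(sy)
  if (drop_zero && any(bx[keep] == 0)) {
    warn2("excluding ", sum(bx[keep] == 0), " SNP(s) with zero ", exposure,
          " beta from ratio-based estimation")
    keep <- keep & bx != 0
  }
  data.frame(snp = table$snp[keep], bx = bx[keep], sx = sx[keep],
             by = by[keep], sy = sy[keep], stringsAsFactors = FALSE)
}

#' Per-SNP Wald ratio estimates
#'
#' The single-instrument causal estimate at SNP j is the ratio of its
#' outcome and exposure associations, `by/bx`, with first-order standard
#' error `sy/|bx|` (exposure-side uncertainty ignored, as in the classical
#' IVW description). The inverse-variance weight `bx^2/sy^2` equals
#' `1/se_ratio^2`.
#'
#' @param table an `instrument_table`.
#' @param exposure exposure label.
#' @param outcome `"maternal"` (default) or `"fetal"`.
#' @return data frame with `snp`, `ratio`, `se_ratio`, `weight`.
#' @export
wald_ratios <- function(table, exposure, outcome = "maternal") {
  d <- estimator_input(table, exposure, outcome)
  data.frame(snp = d$snp, ratio = d$by / d$bx, se_ratio = d$sy / abs(d$bx),
             weight = d$bx^2 / d$sy^2, stringsAsFactors = FALSE)
}

re_multiplier <- function(rss, df, random_effects) {
  if (!random_effects || df <= 0) return(1)
  sqrt(max(1, rss / df))
}

#' Inverse-variance weighted MR estimate
#'
#' The causal effect is the inverse-variance weighted average of the per-SNP
#' Wald ratios, algebraically identical to weighted least squares of the
#' outcome betas on the exposure betas through a zero intercept with weights
#' `1/sy^2` (no unbalanced horizontal pleiotropy assumed). By default the
#' standard error uses the multiplicative random-effects model: the
#' fixed-effect SE is inflated by the residual standard deviation when it
#' exceeds 1 (floored at 1, i.e. never deflated).
#'
#' @param table an `instrument_table` with at least 2 usable SNPs.
#' @param exposure exposure label.
#' @param outcome `"maternal"` or `"fetal"`.
#' @param random_effects logical; `FALSE` gives fixed-effect SEs.
#' @param conf_level confidence level for the normal-quantile interval.
#' @return an `mr_estimate` row, method `"ivw"`.
#' @export
mr_ivw <- function(table, exposure, outcome = "maternal",
                   random_effects = TRUE, conf_level = 0.95) {
  d <- estimator_input(table, exposure, outcome)
  n <- nrow(d)
  if (n < 2) {
    stop2("ivw needs >= 2 SNPs; use wald_ratios() for a single instrument")
  }
  w <- 1 / d$sy^2
  bhat <- sum(w * d$bx * d$by) / sum(w * d$bx^2)
  rss <- sum(w * (d$by - bhat * d$bx)^2)
  se <- sqrt(1 / sum(w * d$bx^2)) * re_multiplier(rss, n - 1, random_effects)
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  mr_estimate("ivw", exposure, outcome, n, bhat, se,
              bhat - z * se, bhat + z * se,
              2 * stats::pnorm(-abs(bhat / se)))
}

#' MR-Egger regression
#'
#' Weighted linear regression (weights `1/sy^2`) of outcome betas on exposure
#' betas with a free intercept. The slope is a causal estimate robust to
#' directional pleiotropy under the InSIDE assumption; a non-zero intercept
#' is evidence of directional pleiotropy. Because the intercept's sign
#' depends on allele orientation, the table must have been passed through
#' [orient_positive()] on the same exposure first. Inference uses the
#' t-distribution with `n_snps - 2` degrees of freedom and the same
#' multiplicative random-effects SE floor as [mr_ivw()].
#'
#' @inheritParams mr_ivw
#' @return an `mr_estimate` row, method `"egger"`, with intercept fields.
#' @export
mr_egger <- function(table, exposure, outcome = "maternal",
                     random_effects = TRUE, conf_level = 0.95) {
  ori <- attr(table, "oriented")
  if (is.na(ori) || ori != exposure) {
    stop2("mr_egger requires a table oriented on '", exposure,
          "'; call orient_positive() first")
  }
  d <- estimator_input(table, exposure, outcome)
  n <- nrow(d)
  if (n < 3) stop2("egger needs >= 3 SNPs")
  fit <- wls_fit(cbind(1, d$bx), d$by, 1 / d$sy^2)
  mult <- re_multiplier(fit$rss, n - 2, random_effects)
  se <- fit$se * mult
  tq <- stats::qt(1 - (1 - conf_level) / 2, df = n - 2)
  pv <- 2 * stats::pt(-abs(fit$coef / se), df = n - 2)
  mr_estimate("egger", exposure, outcome, n, fit$coef[2], se[2],
              fit$coef[2] - tq * se[2], fit$coef[2] + tq * se[2], pv[2],
              intercept = fit$coef[1], intercept_se = se[1],
              intercept_p = pv[1])
}

# Weighted least squares by explicit normal equations (kept independent of
# stats::lm so the test suite can use lm as an oracle).
wls_fit <- function(X, y, w) {
  sw <- sqrt(w)
  Xw <- X * sw
  yw <- y * sw
  XtX <- crossprod(Xw)
  qrX <- qr(XtX)
  if (qrX$rank < ncol(X)) stop2("rank-deficient design in weighted regression")
  coef <- drop(solve(XtX, crossprod(Xw, yw)))
  res <- yw - Xw %*% coef
  rss <- sum(res^2)
  XtXinv <- solve(XtX)
  list(coef = coef, se = sqrt(diag(XtXinv)), rss = rss, XtXinv = XtXinv)
}

# Weighted median of `x` with weights `w`: order x, form cumulative weight
# midpoints p_j = (S_j - w_j/2) / sum(w), linearly interpolate x over p at
# p = 0.5.
weighted_median_point <- function(x, w) {
  o <- order(x)
  x <- x[o]
  w <- w[o] / sum(w)
  p <- cumsum(w) - w / 2
  if (p[1] >= 0.5) return(x[1])
  n <- length(x)
  if (p[n] <= 0.5) return(x[n])
  stats::approx(p, x, xout = 0.5, ties = "ordered")$y
}

boot_se <- function(d, n_boot, seed, point_fun) {
  n <- nrow(d)
  with_seed(seed, {
    ests <- vapply(seq_len(n_boot), function(i) {
      bx <- stats::rnorm(n, d$bx, d$sx)
      by <- stats::rnorm(n, d$by, d$sy)
      point_fun(by / bx, bx^2 / d$sy^2, by, bx)
    }, numeric(1))
    stats::sd(ests)
  })
}

#' Weighted-median MR estimate
#'
#' Takes the inverse-variance weighted median of the per-SNP Wald ratios
#' instead of their weighted mean, giving a consistent causal estimate as
#' long as under 50% of the total weight comes from invalid instruments.
#' The standard error comes from a parametric bootstrap: exposure and
#' outcome betas are resampled from their normal sampling distributions and
#' the weighted median recomputed, `n_boot` times under `seed`.
#'
#' @inheritParams mr_ivw
#' @param n_boot bootstrap resamples (default 1000; below 100 warns).
#' @param seed integer seed for the bootstrap (mandatory).
#' @return an `mr_estimate` row, method `"weighted_median"`.
#' @export
mr_weighted_median <- function(table, exposure, outcome = "maternal",
                               n_boot = 1000, seed, conf_level = 0.95) {
  if (missing(seed)) stop2("seed is mandatory for bootstrap-based estimators")
  if (n_boot < 100) warn2("n_boot < 100 gives unstable bootstrap SEs")
  d <- estimator_input(table, exposure, outcome)
  n <- nrow(d)
  if (n < 3) stop2("weighted_median needs >= 3 SNPs")
  if (anyNA(d$sx)) stop2("weighted_median bootstrap needs exposure SEs")
  est <- weighted_median_point(d$by / d$bx, d$bx^2 / d$sy^2)
  se <- boot_se(d, n_boot, seed,
                function(r, w, by, bx) weighted_median_point(r, w))
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  mr_estimate("weighted_median", exposure, outcome, n, est, se,
              est - z * se, est + z * se, 2 * stats::pnorm(-abs(est / se)))
}

mode_bandwidth <- function(ratios, phi) {
  s <- c(stats::sd(ratios), stats::mad(ratios))
  s <- s[s > 0]
  if (!length(s)) return(0)
  phi * 0.9 * min(s) * length(ratios)^(-1 / 5)
}

mode_point <- function(ratios, w, h) {
  den <- stats::density(ratios, weights = w / sum(w), bw = h, n = 1024)
  den$x[which.max(den$y)]
}

#' Mode-based MR estimate
#'
#' Clusters SNPs by the similarity of their Wald ratios through a normal
#' kernel density (bandwidth = `phi` times a modified Silverman rule using
#' the smaller of SD and MAD of the ratios) and returns the density maximum:
#' the causal effect implied by the largest cluster. The simple variant
#' gives every SNP equal kernel mass; the weighted variant gives each SNP
#' its inverse-variance weight, so the estimate is driven by the cluster
#' with the largest *weighted* SNP count. Consistent when the largest
#' cluster consists of valid instruments (ZEMPA), even if they carry under
#' half the weight. Bootstrap SE as in [mr_weighted_median()].
#'
#' @inheritParams mr_weighted_median
#' @param weighted logical: weighted (`TRUE`) or simple (`FALSE`) mode.
#' @param phi bandwidth multiplier (default 1).
#' @return an `mr_estimate` row, method `"weighted_mode"` or `"simple_mode"`.
#' @export
mr_mode <- function(table, exposure, outcome = "maternal", weighted = FALSE,
                    phi = 1, n_boot = 1000, seed, conf_level = 0.95) {
  if (missing(seed)) stop2("seed is mandatory for bootstrap-based estimators")
  if (n_boot < 100) warn2("n_boot < 100 gives unstable bootstrap SEs")
  d <- estimator_input(table, exposure, outcome)
  n <- nrow(d)
  if (n < 3) stop2("mode estimator needs >= 3 SNPs")
  method <- if (weighted) "weighted_mode" else "simple_mode"
  ratios <- d$by / d$bx
  se_ratio <- d$sy / abs(d$bx)
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  h <- mode_bandwidth(ratios, phi)
  if (h == 0) {
    # all ratios identical: the mode is that common value; combine the
    # per-ratio variances as for a precision-weighted mean
    est <- ratios[1]
    se <- 1 / sqrt(sum(1 / se_ratio^2))
    return(mr_estimate(method, exposure, outcome, n, est, se, est - z * se,
                       est + z * se, 2 * stats::pnorm(-abs(est / se))))
  }
  wfun <- if (weighted) {
    function(r, w) mode_point(r, w, mode_bandwidth(r, phi))
  } else {
    function(r, w) mode_point(r, rep(1, length(r)), mode_bandwidth(r, phi))
  }
  est <- wfun(ratios, d$bx^2 / d$sy^2)
  if (anyNA(d$sx)) stop2("mode bootstrap needs exposure SEs")
  se <- boot_se(d, n_boot, seed, function(r, w, by, bx) wfun(r, w))
  mr_estimate(method, exposure, outcome, n, est, se, est - z * se,
              est + z * se, 2 * stats::pnorm(-abs(est / se)))
}

estimator_min_snps <- c(ivw = 2, egger = 3, weighted_median = 3,
                        simple_mode = 3, weighted_mode = 3)

run_estimator <- function(method, table, exposure, outcome, n_boot = 1000,
                          seed = NULL, phi = 1) {
  switch(method,
         ivw = mr_ivw(table, exposure, outcome),
         egger = mr_egger(table, exposure, outcome),
         weighted_median = mr_weighted_median(table, exposure, outcome,
                                              n_boot = n_boot, seed = seed),
         simple_mode = mr_mode(table, exposure, outcome, weighted = FALSE,
                               phi = phi, n_boot = n_boot, seed = seed),
         weighted_mode = mr_mode(table, exposure, outcome, weighted = TRUE,
                                 phi = phi, n_boot = n_boot, seed = seed),
         stop2("unknown estimator: ", method))
}

#' Re-run estimators after excluding named SNPs
#'
#' Outlier sensitivity check: every requested estimator is computed on the
#' full table and on the table with `snp_ids` removed, and the paired
#' results returned for comparison. Estimators whose minimum instrument
#' count is no longer met after exclusion are skipped with a warning.
#'
#' @param table an `instrument_table` (oriented if `egger` is requested).
#' @param snp_ids SNPs to exclude; all must be present.
#' @param estimators method labels among `ivw`, `egger`, `weighted_median`,
#'   `simple_mode`, `weighted_mode`.
#' @inheritParams mr_weighted_median
#' @param phi mode bandwidth multiplier.
#' @return data frame of `mr_estimate` rows with an extra `snp_set` column
#'   (`"original"` / `"excluded"`).
#' @export
exclude_and_rerun <- function(table, snp_ids, estimators = c("ivw"),
                              exposure, outcome = "maternal", n_boot = 1000,
                              seed = NULL, phi = 1) {
  missing_snps <- setdiff(tolower(snp_ids), tolower(table$snp))
  if (length(missing_snps)) {
    stop2("snp_ids not in table: ", paste(missing_snps, collapse = ", "))
  }
  reduced <- table[!(tolower(table$snp) %in% tolower(snp_ids)), , drop = FALSE]
  reduced <- new_instrument_table(as.data.frame(reduced), exposures_of(table),
                                  oriented = attr(table, "oriented"),
                                  selection = attr(table, "selection"),
                                  exclusions = exclusion_log(table))
  rows <- list()
  for (m in estimators) {
    orig <- run_estimator(m, table, exposure, outcome, n_boot, seed, phi)
    orig$snp_set <- "original"
    rows[[length(rows) + 1L]] <- orig
    if (nrow(reduced) < estimator_min_snps[[m]]) {
      warn2("skipping ", m, " after exclusion: fewer than ",
            estimator_min_snps[[m]], " SNPs remain")
      next
    }
    red <- run_estimator(m, reduced, exposure, outcome, n_boot, seed, phi)
    red$snp_set <- "excluded"
    rows[[length(rows) + 1L]] <- red
  }
  out <- do.call(rbind, rows)
  class(out) <- c("mr_estimate", "data.frame")
  out
}

#' Leave-one-out influence of each SNP on the IVW estimate
#'
#' @inheritParams mr_ivw
#' @return data frame with `snp`, `estimate_without` (IVW with that SNP
#'   removed) and `delta` (change from the full-table estimate).
#' @export
mr_loo <- function(table, exposure, outcome = "maternal") {
  full <- mr_ivw(table, exposure, outcome)$estimate
  labs <- exposures_of(table)
  deltas <- vapply(seq_len(nrow(table)), function(i) {
    sub <- new_instrument_table(as.data.frame(table[-i, , drop = FALSE]),
                                labs, oriented = attr(table, "oriented"))
    mr_ivw(sub, exposure, outcome)$estimate
  }, numeric(1))
  data.frame(snp = table$snp, estimate_without = deltas,
             delta = deltas - full, stringsAsFactors = FALSE)
}
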