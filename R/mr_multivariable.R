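mvmr_result <- function(method, df, n_snps, intercept = NA_real_,
                        intercept_se = NA_real_, intercept_p = NA_real_,
                        oriented_exposure = NA_character_) {
  structure(df,
            class = c("mvmr_result", "data.frame"),
            method = method, n_snps = n_snps, intercept = intercept,
            intercept_se = intercept_se, intercept_p = intercept_p,
            oriented_exposure = oriented_exposure)
}

#' @export
print.mvmr_result <- function(x, ...) {
  cat(attr(x, "method"), "on", attr(x, "n_snps"), "SNPs")
  oe <- attr(x, "oriented_exposure")
  if (!is.na(oe)) cat(", oriented on", oe)
  cat("\n")
  print.data.frame(x)
  if (!is.na(attr(x, "intercept"))) {
    cat(sprintf("intercept: %.4f (se %.4f), p = %.3g\n", attr(x, "intercept"),
                attr(x, "intercept_se"), attr(x, "intercept_p")))
  }
  invisible(x)
}

mv_design <- function(table, exposures, outcome) {
  outcome <- match.arg(outcome, c("maternal", "fetal"))
  labs <- exposures_of(table)
  bad <- setdiff(exposures, labs)
  if (length(bad)) stop2("unknown exposure(s): ", paste(bad, collapse = ", "))
  X <- as.matrix(as.data.frame(table)[paste0("beta_", exposures)])
  colnames(X) <- exposures
  y <- if (outcome == "maternal") table$beta_mat else table$beta_fet
  sy <- if (outcome == "maternal") table$se_mat else table$se_fet
  # SNPs missing any requested exposure beta are excluded (no
  # zero-imputation); instruments are expected to carry betas for all
  # exposures in the joint model
  keep <- stats::complete.cases(X) & !is.na(y) & !is.na(sy)
  list(X = X[keep, , drop = FALSE], y = y[keep], w = 1 / sy[keep]^2,
       n = sum(keep))
}

check_mv_rank <- function(X, w) {
  qrX <- qr(X * sqrt(w))
  if (qrX$rank < ncol(X)) {
    involved <- colnames(X)[qrX$pivot[seq(qrX$rank + 1, ncol(X))]]
    stop2("rank-deficient exposure matrix; collinear exposure(s): ",
          paste(involved, collapse = ", "))
  }
}

mv_fit <- function(X, y, w, intercept, exposures, random_effects = TRUE,
                   conf_level = 0.95) {
  n <- length(y)
  p <- ncol(X) + intercept
  if (n < p + 1) stop2("need at least ", p + 1, " SNPs for this joint model")
  check_mv_rank(X, w)
  D <- if (intercept) cbind(`(intercept)` = 1, X) else X
  fit <- wls_fit(D, y, w)
  mult <- re_multiplier(fit$rss, n - p, random_effects)
  se <- fit$se * mult
  idx <- if (intercept) seq_len(ncol(X)) + 1L else seq_len(ncol(X))
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  df <- data.frame(exposure = exposures,
                   estimate = fit$coef[idx], se = se[idx],
                   ci_low = fit$coef[idx] - z * se[idx],
                   ci_high = fit$coef[idx] + z * se[idx],
                   pvalue = 2 * stats::pnorm(-abs(fit$coef[idx] / se[idx])),
                   stringsAsFactors = FALSE)
  list(df = df, n = n,
       intercept = if (intercept) unname(fit$coef[1]) else NA_real_,
       intercept_se = if (intercept) unname(se[1]) else NA_real_,
       intercept_p = if (intercept) 2 * stats::pnorm(-abs(fit$coef[1] / se[1])) else NA_real_)
}

#' Multivariable IVW regression
#'
#' Regresses the partitioned outcome betas jointly on the exposure betas of
#' all requested exposures (weights `1/sy^2`, intercept fixed at zero by
#' default), accounting for instruments associated with more than one
#' exposure. Each coefficient is the direct causal effect of its exposure
#' with the others held fixed. SNPs missing a beta for any requested
#' exposure are excluded.
#'
#' @param table an `instrument_table`.
#' @param exposures exposure labels entering the joint model.
#' @param outcome `"maternal"` or `"fetal"`.
#' @param intercept free intercept (default `FALSE`: forced through zero).
#' @param random_effects,conf_level as in [mr_ivw()].
#' @return an `mvmr_result`: one row per exposure, attributes carry method,
#'   `n_snps` and (when freed) the intercept.
#' @export
mv_ivw <- function(table, exposures = exposures_of(table),
                   outcome = "maternal", intercept = FALSE,
                   random_effects = TRUE, conf_level = 0.95) {
  d <- mv_design(table, exposures, outcome)
  f <- mv_fit(d$X, d$y, d$w, intercept, exposures, random_effects, conf_level)
  mvmr_result("mv_ivw", f$df, f$n, f$intercept, f$intercept_se, f$intercept_p)
}

#' Multivariable MR-Egger regression
#'
#' As [mv_ivw()] but with a free intercept testing directional pleiotropy.
#' Because the intercept depends on allele orientation, the table is first
#' re-oriented so the `orient_to` exposure's betas are all positive; the
#' `orient_to` coefficient is that exposure's pleiotropy-adjusted causal
#' estimate, and one run per exposure of interest is the intended usage.
#'
#' @inheritParams mv_ivw
#' @param orient_to exposure whose effect-allele orientation anchors the
#'   intercept; must be among `exposures`.
#' @return an `mvmr_result` with intercept attributes and
#'   `oriented_exposure` set.
#' @export
mv_egger <- function(table, exposures = exposures_of(table), orient_to,
                     outcome = "maternal", random_effects = TRUE,
                     conf_level = 0.95) {
  if (!orient_to %in% exposures) {
    stop2("orient_to ('", orient_to, "') must be among the requested exposures")
  }
  # rows lacking any requested exposure beta are excluded anyway; drop them
  # before orientation so missing orient_to betas cannot block it
  complete <- stats::complete.cases(as.data.frame(table)[paste0("beta_", exposures)])
  table <- new_instrument_table(as.data.frame(table)[complete, , drop = FALSE],
                                exposures_of(table),
                                oriented = attr(table, "oriented"),
                                selection = attr(table, "selection"),
                                exclusions = exclusion_log(table))
  oriented <- orient_positive(table, orient_to)
  d <- mv_design(oriented, exposures, outcome)
  f <- mv_fit(d$X, d$y, d$w, TRUE, exposures, random_effects, conf_level)
  mvmr_result("mv_egger", f$df, f$n, f$intercept, f$intercept_se,
              f$intercept_p, oriented_exposure = orient_to)
}
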