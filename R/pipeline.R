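#' Configuration for a full analysis run
#'
#' @param sample1_paths named character vector of exposure summary files,
#'   one per lipid (names are the exposure labels).
#' @param sample2_path partitioned outcome table
#'   ([read_partitioned_outcome()] layout) or, with
#'   `sample2_prepartitioned = FALSE`, an unpartitioned own/offspring pair
#'   table to be run through [partition_effects()].
#' @param sample2_prepartitioned logical (default `TRUE`).
#' @param snp_sets subset of `c("unrestricted", "restricted")`.
#' @param estimators univariate estimator labels to run.
#' @param outcomes subset of `c("maternal", "fetal")`.
#' @param multivariable run `mv_ivw` and per-exposure `mv_egger` too.
#' @param n_boot bootstrap resamples for median/mode SEs.
#' @param seed mandatory when any bootstrap estimator is requested.
#' @param sd_grams grams per birth-weight SD for reporting (default 454);
#'   `NA` disables the gram columns.
#' @param min_instruments analyses on fewer SNPs than this are skipped with
#'   an explicit reason instead of being run underpowered (default 5).
#' @param palindromic_eaf_limit passed to [harmonize_instruments()].
#' @return list of class `run_config`.
#' @export
run_config <- function(sample1_paths, sample2_path,
                       sample2_prepartitioned = TRUE,
                       snp_sets = c("unrestricted", "restricted"),
                       estimators = c("ivw", "egger", "weighted_median",
                                      "simple_mode", "weighted_mode"),
                       outcomes = "maternal", multivariable = TRUE,
                       n_boot = 1000, seed = NULL, sd_grams = 454,
                       min_instruments = 5, palindromic_eaf_limit = 0.08) {
  stopifnot(length(sample1_paths) >= 1, !is.null(names(sample1_paths)))
  missing_files <- c(sample1_paths, sample2_path)
  missing_files <- missing_files[!file.exists(missing_files)]
  if (length(missing_files)) {
    stop2("input file(s) not found: ", paste(missing_files, collapse = ", "))
  }
  needs_seed <- any(c("weighted_median", "simple_mode", "weighted_mode")
                    %in% estimators)
  if (needs_seed && is.null(seed)) {
    stop2("seed is mandatory when bootstrap-based estimators are requested")
  }
  structure(list(sample1_paths = sample1_paths, sample2_path = sample2_path,
                 sample2_prepartitioned = sample2_prepartitioned,
                 snp_sets = match.arg(snp_sets, several.ok = TRUE),
                 estimators = estimators,
                 outcomes = match.arg(outcomes, c("maternal", "fetal"),
                                      several.ok = TRUE),
                 multivariable = multivariable, n_boot = n_boot, seed = seed,
                 sd_grams = sd_grams, min_instruments = min_instruments,
                 palindromic_eaf_limit = palindromic_eaf_limit),
            class = "run_config")
}

skip_row <- function(exposure, snp_set, outcome, method, n_snps, reason) {
  data.frame(exposure = exposure, snp_set = snp_set, outcome = outcome,
             method = method, n_snps = n_snps, estimate = NA_real_,
             se = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
             pvalue = NA_real_, intercept = NA_real_,
             intercept_se = NA_real_, intercept_p = NA_real_,
             status = "skipped", reason = reason, stringsAsFactors = FALSE)
}

result_row <- function(est, exposure, snp_set, outcome) {
  data.frame(exposure = exposure, snp_set = snp_set, outcome = outcome,
             method = est$method, n_snps = est$n_snps,
             estimate = est$estimate, se = est$se, ci_low = est$ci_low,
             ci_high = est$ci_high, pvalue = est$pvalue,
             intercept = est$intercept, intercept_se = est$intercept_se,
             intercept_p = est$intercept_p, status = "ok", reason = "",
             stringsAsFactors = FALSE)
}

#' Run the full maternal-effect MR analysis
#'
#' Executes load, harmonize, select, orient, estimate and diagnose for every
#' requested exposure x SNP-set x outcome x estimator combination, plus the
#' multivariable models on the pooled instrument set. Combinations that
#' cannot be run (too few instruments after restriction, estimator minimums
#' not met) appear in the results table with `status = "skipped"` and an
#' explicit reason rather than being dropped. All bootstrap randomness is
#' derived deterministically from the configured seed.
#'
#' @param config a [run_config()].
#' @return list of class `analysis_report`: `results` (long-format table),
#'   `mv_results`, `i2` (per analysis), `exclusions`, `instrument_counts`
#'   and a `provenance` block (config hash, seed, package version).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  stage <- "read"
  report <- tryCatch({
    exposures <- lapply(names(config$sample1_paths), function(lab) {
      read_summary_stats(config$sample1_paths[[lab]], trait = lab)
    })
    names(exposures) <- names(config$sample1_paths)
    outcome_tab <- if (config$sample2_prepartitioned) {
      read_partitioned_outcome(config$sample2_path)
    } else {
      con <- open_text(config$sample2_path)
      on.exit(close(con), add = TRUE)
      pairs <- utils::read.delim(con, comment.char = "#",
                                 stringsAsFactors = FALSE)
      names(pairs)[names(pairs) == "SNP"] <- "snp"
      part <- partition_effects(pairs)
      part$effect_allele <- pairs$effect_allele
      part$other_allele <- pairs$other_allele
      part$eaf <- pairs$eaf %||% NA_real_
      class(part) <- c("partitioned_outcome", "data.frame")
      part
    }
    stage <- "harmonize"
    table <- harmonize_instruments(exposures, outcome_tab,
                                   config$palindromic_eaf_limit)

    stage <- "estimate"
    rows <- list()
    i2_rows <- list()
    counts <- list()
    boot_counter <- 0L
    for (lab in names(exposures)) {
      for (set in config$snp_sets) {
        sel <- select_instruments(table, lab, mode = set)
        counts[[length(counts) + 1L]] <-
          data.frame(exposure = lab, snp_set = set, n_snps = nrow(sel),
                     stringsAsFactors = FALSE)
        for (side in config$outcomes) {
          if (nrow(sel) < config$min_instruments) {
            rows[[length(rows) + 1L]] <-
              skip_row(lab, set, side, paste(config$estimators, collapse = ";"),
                       nrow(sel), "insufficient instruments")
            next
          }
          ori <- orient_positive(sel, lab)
          for (m in config$estimators) {
            if (nrow(ori) < estimator_min_snps[[m]]) {
              rows[[length(rows) + 1L]] <-
                skip_row(lab, set, side, m, nrow(ori),
                         "below estimator minimum")
              next
            }
            boot_counter <- boot_counter + 1L
            est <- run_estimator(m, ori, lab, side,
                                 n_boot = config$n_boot,
                                 seed = if (is.null(config$seed)) NULL else
                                   config$seed + boot_counter)
            rows[[length(rows) + 1L]] <- result_row(est, lab, set, side)
          }
          if (nrow(ori) >= 2) {
            i2 <- i2_gx(ori, lab)
            i2_rows[[length(i2_rows) + 1L]] <-
              data.frame(exposure = lab, snp_set = set,
                         weighting = i2$weighting, n_snps = i2$n_snps,
                         q_gx = i2$q_gx, i2_gx = i2$i2_gx,
                         stringsAsFactors = FALSE)
          }
        }
      }
    }
    results <- do.call(rbind, rows)
    if (!is.na(config$sd_grams)) {
      results$estimate_g <- round(results$estimate * config$sd_grams, 2)
      results$ci_low_g <- round(results$ci_low * config$sd_grams, 2)
      results$ci_high_g <- round(results$ci_high * config$sd_grams, 2)
    }

    mv_results <- NULL
    if (config$multivariable && length(exposures) >= 2) {
      stage <- "multivariable"
      for (side in config$outcomes) {
        ivw <- mv_ivw(table, names(exposures), outcome = side)
        mv_rows <- data.frame(method = "mv_ivw", outcome = side,
                              oriented_exposure = NA_character_,
                              n_snps = attr(ivw, "n_snps"),
                              as.data.frame(ivw),
                              intercept = NA_real_, intercept_se = NA_real_,
                              intercept_p = NA_real_,
                              stringsAsFactors = FALSE)
        for (lab in names(exposures)) {
          eg <- mv_egger(table, names(exposures), orient_to = lab,
                         outcome = side)
          mv_rows <- rbind(mv_rows,
                           data.frame(method = "mv_egger", outcome = side,
                                      oriented_exposure = lab,
                                      n_snps = attr(eg, "n_snps"),
                                      as.data.frame(eg),
                                      intercept = attr(eg, "intercept"),
                                      intercept_se = attr(eg, "intercept_se"),
                                      intercept_p = attr(eg, "intercept_p"),
                                      stringsAsFactors = FALSE))
        }
        mv_results <- rbind(mv_results, mv_rows)
      }
    }

    list(results = results,
         mv_results = mv_results,
         i2 = if (length(i2_rows)) do.call(rbind, i2_rows) else NULL,
         exclusions = exclusion_log(table),
         instrument_counts = do.call(rbind, counts),
         table = table)
  }, error = function(e) {
    stop2("pipeline failed at stage '", stage, "': ", conditionMessage(e))
  })
  report$provenance <- c(
    package = paste0("duomr ", as.character(utils::packageVersion("duomr"))),
    seed = as.character(config$seed %||% "none"),
    config_hash = fnv1a(serialize(unclass(config), NULL)),
    inputs = paste(c(config$sample1_paths, config$sample2_path),
                   collapse = "; ")
  )
  class(report) <- "analysis_report"
  report
}

#' Write an analysis report to disk
#'
#' Emits the long-format results table, multivariable results, diagnostics,
#' exclusion log and provenance block as tab-delimited text, and (with
#' `format = "forest-plot"`) one forest-plot PDF per exposure. Skipped
#' analyses are annotated, not dropped.
#'
#' @param report an `analysis_report`.
#' @param dir output directory (created if needed).
#' @param format `"table"` or `"forest-plot"` (which also writes the tables).
#' @return invisibly, the paths written.
#' @export
render_report <- function(report, dir, format = c("table", "forest-plot")) {
  format <- match.arg(format)
  if (is.null(report$results) || nrow(report$results) == 0) {
    stop2("empty report")
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  hdr <- paste0(names(report$provenance), ": ", report$provenance)
  p <- file.path(dir, "results.tsv")
  write_tsv(report$results, p, hdr); paths <- c(paths, p)
  if (!is.null(report$mv_results)) {
    p <- file.path(dir, "mv_results.tsv")
    write_tsv(report$mv_results, p, hdr); paths <- c(paths, p)
  }
  if (!is.null(report$i2)) {
    p <- file.path(dir, "i2_gx.tsv")
    write_tsv(report$i2, p, hdr); paths <- c(paths, p)
  }
  if (!is.null(report$exclusions) && nrow(report$exclusions)) {
    p <- file.path(dir, "exclusions.tsv")
    write_tsv(report$exclusions, p, hdr); paths <- c(paths, p)
  }
  p <- file.path(dir, "instrument_counts.tsv")
  write_tsv(report$instrument_counts, p, hdr); paths <- c(paths, p)
  p <- file.path(dir, "provenance.txt")
  writeLines(hdr, p); paths <- c(paths, p)
  if (format == "forest-plot") {
    for (lab in unique(report$results$exposure)) {
      p <- file.path(dir, paste0("forest_", lab, ".pdf"))
      grDevices::pdf(p, width = 7, height = 5)
      tryCatch(forest_plot(report, lab), finally = grDevices::dev.off())
      paths <- c(paths, p)
    }
  }
  invisible(paths)
}

#' Forest plot of causal estimates for one exposure
#'
#' Point estimates with 95% CIs for every method x SNP-set combination;
#' skipped analyses are annotated in the margin.
#'
#' @param report an `analysis_report`.
#' @param exposure exposure label.
#' @export
forest_plot <- function(report, exposure) {
  res <- report$results[report$results$exposure == exposure, , drop = FALSE]
  if (!nrow(res)) stop2("no results for exposure ", exposure)
  res$label <- paste(res$method, res$snp_set, sep = ", ")
  ok <- res$status == "ok"
  y <- rev(seq_len(nrow(res)))
  xlim <- range(c(res$ci_low[ok], res$ci_high[ok], 0), na.rm = TRUE)
  graphics::plot(NULL, xlim = xlim, ylim = c(0.5, nrow(res) + 0.5),
                 yaxt = "n", xlab = "BW SD per exposure SD", ylab = "",
                 main = paste("Causal estimates:", exposure))
  graphics::axis(2, at = y, labels = res$label, las = 2, cex.axis = 0.6)
  graphics::abline(v = 0, lty = 2, col = "grey")
  graphics::segments(res$ci_low[ok], y[ok], res$ci_high[ok], y[ok])
  graphics::points(res$estimate[ok], y[ok], pch = 15)
  if (any(!ok)) {
    graphics::text(mean(xlim), y[!ok], labels = paste0("skipped: ", res$reason[!ok]),
                   cex = 0.6, col = "grey40")
  }
  invisible(NULL)
}
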