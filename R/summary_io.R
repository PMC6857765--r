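#' Column-name mapping for GWAS summary-statistic files
#'
#' GWAS summary files name their columns inconsistently; a dialect maps the
#' canonical field names used throughout duomr onto the column headers of a
#' particular file. The default matches the dialect written by
#' [write_summary_stats()].
#'
#' @param snp,effect_allele,other_allele,eaf,beta,se,pvalue,n column header
#'   carrying each canonical field.
#' @return Named character vector (names are canonical fields).
#' @export
summary_dialect <- function(snp = "SNP", effect_allele = "effect_allele",
                            other_allele = "other_allele", eaf = "eaf",
                            beta = "beta", se = "se", pvalue = "pval",
                            n = "n") {
  c(snp = snp, effect_allele = effect_allele, other_allele = other_allele,
    eaf = eaf, beta = beta, se = se, pvalue = pvalue, n = n)
}

MANDATORY_FIELDS <- c("snp", "effect_allele", "other_allele", "beta", "se", "pvalue")
VALID_ALLELES <- c("A", "C", "G", "T")

open_text <- function(path) {
  if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
}

#' Read a GWAS summary-statistics table
#'
#' Reads a tab-delimited summary file (optionally gzip-compressed, header
#' row required, `#` lines ignored) into a validated `summary_stats`
#' data frame with canonical column names. Malformed numeric fields and
#' invariant violations (non-positive SE, alleles outside A/C/G/T, equal
#' alleles, frequencies outside \[0,1\]) are reported with the offending
#' file line number.
#'
#' @param path file path.
#' @param dialect column mapping from [summary_dialect()].
#' @param trait trait label attached to the records.
#' @return data frame of class `summary_stats` with columns `snp`,
#'   `effect_allele`, `other_allele`, `eaf`, `beta`, `se`, `pvalue`, `n`,
#'   `trait`.
#' @export
read_summary_stats <- function(path, dialect = summary_dialect(),
                               trait = NA_character_) {
  if (!file.exists(path)) stop2("file not found: ", path)
  con <- open_text(path)
  on.exit(close(con))
  raw <- utils::read.delim(con, header = TRUE, stringsAsFactors = FALSE,
                           check.names = FALSE, comment.char = "#",
                           colClasses = "character")
  missing_cols <- setdiff(unname(dialect[MANDATORY_FIELDS]), names(raw))
  if (length(missing_cols)) {
    stop2("format error: missing mandatory column(s): ",
          paste(missing_cols, collapse = ", "))
  }
  # data line i sits on file line i + 1 (header); comment lines above the
  # header would shift this, which we accept as approximate in that case
  line_of <- function(i) i + 1L

  get_chr <- function(field) {
    col <- dialect[[field]]
    if (!is.null(col) && col %in% names(raw)) raw[[col]] else rep(NA_character_, nrow(raw))
  }
  get_num <- function(field, required) {
    x <- get_chr(field)
    out <- suppressWarnings(as.numeric(x))
    bad <- which(!is.na(x) & x != "" & is.na(out))
    if (length(bad)) {
      stop2("parse error: non-numeric ", field, " at line ",
            paste(line_of(bad), collapse = ", "), " of ", path)
    }
    if (required && anyNA(out)) {
      stop2("parse error: missing ", field, " at line ",
            paste(line_of(which(is.na(out))), collapse = ", "), " of ", path)
    }
    out
  }

  out <- data.frame(
    snp = get_chr("snp"),
    effect_allele = toupper(trimws(get_chr("effect_allele"))),
    other_allele = toupper(trimws(get_chr("other_allele"))),
    eaf = get_num("eaf", required = FALSE),
    beta = get_num("beta", required = TRUE),
    se = get_num("se", required = TRUE),
    pvalue = get_num("pvalue", required = TRUE),
    n = get_num("n", required = FALSE),
    stringsAsFactors = FALSE
  )
  out$trait <- trait

  check <- function(bad, what) {
    if (any(bad)) {
      stop2("invalid record: ", what, " at line ",
            paste(line_of(which(bad)), collapse = ", "), " of ", path)
    }
  }
  check(is.na(out$snp) | out$snp == "", "missing SNP id")
  check(!(out$effect_allele %in% VALID_ALLELES) |
          !(out$other_allele %in% VALID_ALLELES), "allele not one of A/C/G/T")
  check(out$effect_allele == out$other_allele, "effect allele equals other allele")
  check(out$se <= 0, "se must be positive")
  check(!is.na(out$eaf) & (out$eaf < 0 | out$eaf > 1), "eaf outside [0,1]")
  check(out$pvalue <= 0 | out$pvalue > 1, "p-value outside (0,1]")
  class(out) <- c("summary_stats", "data.frame")
  out
}

#' Write a GWAS summary-statistics table
#'
#' Inverse of [read_summary_stats()]. `header_lines` (e.g. a seed record)
#' are written as `#`-prefixed comments before the header row.
#'
#' @param x `summary_stats` data frame.
#' @param path output path; a `.gz` suffix triggers gzip compression.
#' @param dialect column mapping used for the header.
#' @param header_lines optional character vector of comment lines.
#' @export
write_summary_stats <- function(x, path, dialect = summary_dialect(),
                                header_lines = character()) {
  out <- data.frame(x$snp, x$effect_allele, x$other_allele, x$eaf, x$beta,
                    x$se, x$pvalue, x$n, stringsAsFactors = FALSE)
  names(out) <- unname(dialect[c("snp", "effect_allele", "other_allele", "eaf",
                                 "beta", "se", "pvalue", "n")])
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
  on.exit(close(con))
  if (length(header_lines)) writeLines(paste0("# ", header_lines), con)
  utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a pre-partitioned maternal/fetal outcome table
#'
#' Reads a tab-delimited table carrying, per SNP, the maternal-specific and
#' fetal-specific associations with birth weight (the supplementary-table
#' layout: alleles, eaf, `beta_mat`, `se_mat`, `beta_fet`, `se_fet`).
#'
#' @param path file path.
#' @return data frame of class `partitioned_outcome`.
#' @export
read_partitioned_outcome <- function(path) {
  if (!file.exists(path)) stop2("file not found: ", path)
  con <- open_text(path)
  on.exit(close(con))
  raw <- utils::read.delim(con, header = TRUE, stringsAsFactors = FALSE,
                           comment.char = "#")
  need <- c("SNP", "effect_allele", "other_allele", "beta_mat", "se_mat",
            "beta_fet", "se_fet")
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols)) {
    stop2("format error: missing mandatory column(s): ",
          paste(missing_cols, collapse = ", "))
  }
  out <- data.frame(
    snp = as.character(raw$SNP),
    effect_allele = toupper(raw$effect_allele),
    other_allele = toupper(raw$other_allele),
    eaf = if ("eaf" %in% names(raw)) as.numeric(raw$eaf) else NA_real_,
    beta_mat = as.numeric(raw$beta_mat),
    se_mat = as.numeric(raw$se_mat),
    beta_fet = as.numeric(raw$beta_fet),
    se_fet = as.numeric(raw$se_fet),
    cov_mat_fet = if ("cov_mat_fet" %in% names(raw)) as.numeric(raw$cov_mat_fet) else 0,
    stringsAsFactors = FALSE
  )
  if (any(out$se_mat <= 0, na.rm = TRUE) || any(out$se_fet <= 0, na.rm = TRUE)) {
    stop2("invalid record: non-positive SE in partitioned outcome table")
  }
  class(out) <- c("partitioned_outcome", "data.frame")
  out
}

complement_allele <- function(a) {
  chartr("ACGT", "TGCA", a)
}

is_palindromic <- function(ea, oa) ea == complement_allele(oa)

# Orientation of candidate alleles (ea2, oa2) relative to reference
# (ea, oa): +1 same, -1 swapped (beta sign must flip), NA irreconcilable.
# Strand flips are resolved by complementing; palindromic pairs cannot be
# resolved this way and are handled separately via allele frequency.
allele_orientation <- function(ea, oa, ea2, oa2) {
  if (ea2 == ea && oa2 == oa) return(1)
  if (ea2 == oa && oa2 == ea) return(-1)
  ea2c <- complement_allele(ea2)
  oa2c <- complement_allele(oa2)
  if (ea2c == ea && oa2c == oa) return(1)
  if (ea2c == oa && oa2c == ea) return(-1)
  NA_real_
}

new_instrument_table <- function(df, exposures, oriented = NA_character_,
                                 selection = NULL, exclusions = NULL) {
  rownames(df) <- NULL
  structure(df,
            class = c("instrument_table", "data.frame"),
            exposures = exposures,
            oriented = oriented,
            selection = selection,
            exclusions = exclusions %||%
              data.frame(snp = character(), reason = character(),
                         stringsAsFactors = FALSE))
}

#' Exposure labels of an instrument table
#' @param table an `instrument_table`.
#' @return character vector of exposure labels.
#' @export
exposures_of <- function(table) attr(table, "exposures")

#' Exclusion log of an instrument table
#'
#' One row per SNP dropped during harmonization or filtering, with a reason
#' code (`palindromic`, `irreconcilable_alleles`, `zero_exposure_beta`, ...).
#'
#' @param table an `instrument_table`.
#' @return data frame with columns `snp`, `reason`.
#' @export
exclusion_log <- function(table) attr(table, "exclusions")

#' Harmonize exposure and outcome summary statistics into an instrument table
#'
#' Joins one or more exposure summary tables (sample 1) with a partitioned
#' maternal/fetal outcome table (sample 2) on rsID (case-insensitive).
#' Alleles are aligned to the first exposure table that carries each SNP:
#' swapped alleles flip the candidate table's beta sign (and eaf), strand
#' flips are resolved by complementing. Strand-ambiguous (A/T, C/G) SNPs are
#' aligned by allele frequency when it is informative and dropped when the
#' reference eaf is missing or within `palindromic_eaf_limit` of 0.5;
#' irreconcilable allele pairs are dropped with a warning. All exclusions
#' are logged (see [exclusion_log()]).
#'
#' @param exposures a `summary_stats` data frame or a named list of them
#'   (names become exposure labels; otherwise `trait` is used).
#' @param outcome a `partitioned_outcome` data frame.
#' @param palindromic_eaf_limit drop strand-ambiguous SNPs whose reference
#'   eaf lies within this distance of 0.5 (default 0.08).
#' @return an `instrument_table`: per SNP, `beta_<exposure>`, `se_<exposure>`,
#'   `pval_<exposure>` per exposure plus `beta_mat`, `se_mat`, `beta_fet`,
#'   `se_fet`, `cov_mat_fet`.
#' @export
harmonize_instruments <- function(exposures, outcome,
                                  palindromic_eaf_limit = 0.08) {
  if (is.data.frame(exposures)) {
    lab <- attr(exposures, "trait") %||% exposures$trait[1] %||% "exposure"
    exposures <- stats::setNames(list(exposures), lab)
  }
  if (is.null(names(exposures)) || any(names(exposures) == "")) {
    names(exposures) <- vapply(exposures, function(e) {
      tr <- e$trait[1]
      if (is.null(tr) || is.na(tr)) "exposure" else tr
    }, character(1))
  }
  labs <- names(exposures)
  if (anyDuplicated(labs)) stop2("duplicate exposure labels")
  for (e in exposures) {
    if (anyDuplicated(tolower(e$snp))) stop2("duplicate snp_id in an exposure table")
  }
  if (anyDuplicated(tolower(outcome$snp))) stop2("duplicate snp_id in outcome table")

  keys <- lapply(exposures, function(e) tolower(e$snp))
  okey <- tolower(outcome$snp)
  all_exp <- unique(unlist(keys))
  common <- intersect(all_exp, okey)

  excl <- list()
  note <- function(snp, reason) excl[[length(excl) + 1L]] <<- c(snp, reason)

  rows <- vector("list", length(common))
  kept <- 0L
  for (key in common) {
    # reference alleles: first exposure table containing the SNP
    ref_i <- which(vapply(keys, function(k) key %in% k, logical(1)))[1]
    ref_row <- exposures[[ref_i]][keys[[ref_i]] == key, , drop = FALSE]
    ea <- ref_row$effect_allele; oa <- ref_row$other_allele
    ref_eaf <- ref_row$eaf

    palindrome <- is_palindromic(ea, oa)
    if (palindrome &&
        (is.na(ref_eaf) || abs(ref_eaf - 0.5) <= palindromic_eaf_limit)) {
      note(ref_row$snp, "palindromic")
      next
    }

    align <- function(ea2, oa2, eaf2) {
      if (palindrome) {
        # allele letters cannot distinguish strand from swap; use frequency
        if (is.na(eaf2)) return(NA_real_)
        if ((eaf2 > 0.5) == (ref_eaf > 0.5)) 1 else -1
      } else {
        allele_orientation(ea, oa, ea2, oa2)
      }
    }

    row <- list(snp = ref_row$snp, effect_allele = ea, other_allele = oa,
                eaf = ref_eaf)
    ok <- TRUE
    for (j in seq_along(exposures)) {
      lab <- labs[j]
      hit <- keys[[j]] == key
      if (!any(hit)) {
        row[[paste0("beta_", lab)]] <- NA_real_
        row[[paste0("se_", lab)]] <- NA_real_
        row[[paste0("pval_", lab)]] <- NA_real_
        next
      }
      e <- exposures[[j]][hit, , drop = FALSE]
      flip <- align(e$effect_allele, e$other_allele, e$eaf)
      if (is.na(flip)) { ok <- FALSE; break }
      row[[paste0("beta_", lab)]] <- e$beta * flip
      row[[paste0("se_", lab)]] <- e$se
      row[[paste0("pval_", lab)]] <- e$pvalue
    }
    if (!ok) {
      note(ref_row$snp, "irreconcilable_alleles")
      warn2("dropping ", ref_row$snp, ": alleles irreconcilable across exposure tables")
      next
    }
    o <- outcome[okey == key, , drop = FALSE]
    flip <- align(o$effect_allele, o$other_allele, o$eaf)
    if (is.na(flip)) {
      note(ref_row$snp, "irreconcilable_alleles")
      warn2("dropping ", ref_row$snp, ": outcome alleles irreconcilable")
      next
    }
    row$beta_mat <- o$beta_mat * flip
    row$se_mat <- o$se_mat
    row$beta_fet <- o$beta_fet * flip
    row$se_fet <- o$se_fet
    row$cov_mat_fet <- o$cov_mat_fet
    kept <- kept + 1L
    rows[[kept]] <- as.data.frame(row, stringsAsFactors = FALSE)
  }

  excl_df <- if (length(excl)) {
    data.frame(snp = vapply(excl, `[`, "", 1),
               reason = vapply(excl, `[`, "", 2), stringsAsFactors = FALSE)
  } else NULL
  if (kept == 0L) {
    cols <- c("snp", "effect_allele", "other_allele", "eaf",
              as.vector(t(outer(c("beta_", "se_", "pval_"), labs, paste0))),
              "beta_mat", "se_mat", "beta_fet", "se_fet", "cov_mat_fet")
    df <- as.data.frame(stats::setNames(rep(list(numeric(0)), length(cols)), cols))
    df$snp <- character(0); df$effect_allele <- character(0)
    df$other_allele <- character(0)
    return(new_instrument_table(df, labs, exclusions = excl_df))
  }
  df <- do.call(rbind, rows[seq_len(kept)])
  bad <- apply(df[paste0("beta_", labs)], 1, function(z) all(is.na(z))) |
    is.na(df$beta_mat)
  df <- df[!bad, , drop = FALSE]
  new_instrument_table(df, labs, exclusions = excl_df)
}

#' Filter an instrument table by association strength
#'
#' Unrestricted mode keeps SNPs with `pval_<exposure>` below the genome-wide
#' threshold. Restricted mode additionally requires a p-value above
#' `restricted_other_threshold` for every *other* exposure in the table, so
#' that the kept instruments show strong evidence of association with the
#' designated exposure only.
#'
#' @param table an `instrument_table`.
#' @param exposure designated exposure label.
#' @param mode `"unrestricted"` or `"restricted"`.
#' @param genome_wide_threshold default `5e-8`.
#' @param restricted_other_threshold default `0.05`; must exceed the
#'   genome-wide threshold.
#' @return the filtered `instrument_table`; the applied rule is recorded in
#'   its `selection` attribute.
#' @export
select_instruments <- function(table, exposure,
                               mode = c("unrestricted", "restricted"),
                               genome_wide_threshold = 5e-8,
                               restricted_other_threshold = 0.05) {
  mode <- match.arg(mode)
  if (genome_wide_threshold >= restricted_other_threshold) {
    stop2("genome_wide_threshold must be below restricted_other_threshold")
  }
  labs <- exposures_of(table)
  if (!exposure %in% labs) stop2("unknown exposure: ", exposure)
  p <- table[[paste0("pval_", exposure)]]
  keep <- !is.na(p) & p < genome_wide_threshold
  if (mode == "restricted") {
    others <- setdiff(labs, exposure)
    if (!length(others)) stop2("restricted mode needs other exposures in the table")
    for (lab in others) {
      po <- table[[paste0("pval_", lab)]]
      if (any(keep & is.na(po))) {
        stop2("restricted mode: missing ", lab,
              " p-values; cannot verify the restriction rule")
      }
      keep <- keep & po > restricted_other_threshold
    }
  }
  out <- table[keep, , drop = FALSE]
  new_instrument_table(as.data.frame(out), labs,
                       oriented = attr(table, "oriented"),
                       selection = list(exposure = exposure, mode = mode,
                                        genome_wide_threshold = genome_wide_threshold,
                                        restricted_other_threshold = restricted_other_threshold),
                       exclusions = exclusion_log(table))
}

#' Orient instruments so the designated exposure betas are non-negative
#'
#' The sign of the MR-Egger intercept depends on which allele is declared the
#' effect allele, so prior to Egger-type analyses every instrument is
#' re-coded to the allele that increases the designated exposure. Rows with a
#' negative designated-exposure beta have all betas (every exposure plus the
#' maternal and fetal outcome) sign-flipped, alleles swapped and eaf
#' reflected. Rows with an exactly zero exposure beta have no defined
#' orientation and are dropped with a warning.
#'
#' @param table an `instrument_table`.
#' @param exposure exposure label to orient on.
#' @return oriented `instrument_table` (its `oriented` attribute records the
#'   exposure).
#' @export
orient_positive <- function(table, exposure) {
  labs <- exposures_of(table)
  if (!exposure %in% labs) stop2("unknown exposure: ", exposure)
  b <- table[[paste0("beta_", exposure)]]
  if (anyNA(b)) stop2("orient_positive: missing ", exposure, " betas")
  excl <- exclusion_log(table)
  zero <- b == 0
  if (any(zero)) {
    warn2("dropping ", sum(zero), " SNP(s) with zero ", exposure,
          " beta (orientation undefined)")
    excl <- rbind(excl, data.frame(snp = table$snp[zero],
                                   reason = "zero_exposure_beta",
                                   stringsAsFactors = FALSE))
    table <- table[!zero, , drop = FALSE]
    b <- b[!zero]
  }
  flip <- b < 0
  df <- as.data.frame(table)
  if (any(flip)) {
    beta_cols <- c(paste0("beta_", labs), "beta_mat", "beta_fet")
    for (col in beta_cols) df[[col]][flip] <- -df[[col]][flip]
    ea <- df$effect_allele[flip]
    df$effect_allele[flip] <- df$other_allele[flip]
    df$other_allele[flip] <- ea
    df$eaf[flip] <- 1 - df$eaf[flip]
  }
  new_instrument_table(df, labs, oriented = exposure,
                       selection = attr(table, "selection"), exclusions = excl)
}

#' Construct an instrument table from a plain data frame
#'
#' Convenience constructor used by simulators and tests: the data frame must
#' already carry the harmonized column layout (`beta_<exposure>` etc. plus
#' `beta_mat`/`se_mat`/`beta_fet`/`se_fet`).
#'
#' @param df data frame in the harmonized layout.
#' @param exposures character vector of exposure labels.
#' @param oriented exposure the table is already oriented on, if any.
#' @return an `instrument_table`.
#' @export
as_instrument_table <- function(df, exposures, oriented = NA_character_) {
  need <- c("snp", paste0("beta_", exposures), paste0("se_", exposures),
            "beta_mat", "se_mat")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop2("missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (anyDuplicated(tolower(df$snp))) stop2("duplicate snp_id")
  if (!"cov_mat_fet" %in% names(df)) df$cov_mat_fet <- 0
  new_instrument_table(as.data.frame(df), exposures, oriented = oriented)
}

#' Write an instrument table (or any result data frame) as TSV
#' @param x data frame.
#' @param path output path.
#' @param header_lines optional `#`-prefixed comment lines.
#' @export
write_tsv <- function(x, path, header_lines = character()) {
  con <- file(path, "wt")
  on.exit(close(con))
  if (length(header_lines)) writeLines(paste0("# ", header_lines), con)
  utils::write.table(as.data.frame(x), con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
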