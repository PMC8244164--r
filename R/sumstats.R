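#' @keywords internal
"_PACKAGE"

VALID_STRATA <- c("both", "men", "women")
VALID_ALLELES <- c("A", "C", "G", "T")

#' Default column-name synonym map for summary-statistic tables
#'
#' Maps each canonical field to the header names accepted for it when reading
#' tab-separated GWAS summary statistics. The default dialect covers the
#' Neale-lab UK Biobank style (`variant`, `beta`, `se`, `pval`,
#' `n_complete_samples`) alongside common alternatives (`rsid`, `a1`/`a2`,
#' `effect`, `stderr`, `p_value`, ...). Matching is case-insensitive.
#'
#' @return Named list of character vectors, one per canonical column.
#' @export
default_col_synonyms <- function() {
  list(
    variant_id    = c("variant_id", "variant", "rsid", "snp", "markername", "id"),
    effect_allele = c("effect_allele", "ea", "a1", "alt", "allele1", "minor_allele"),
    other_allele  = c("other_allele", "oa", "a2", "ref", "allele2", "nea", "major_allele"),
    eaf           = c("eaf", "effect_allele_frequency", "af", "minor_af", "freq", "maf"),
    beta          = c("beta", "b", "effect", "est"),
    se            = c("se", "standard_error", "stderr", "sebeta"),
    pval          = c("pval", "p", "p_value", "pvalue", "p.value"),
    log10_pval    = c("log10_pval", "log10p", "log_pval", "lp"),
    n             = c("n", "n_complete_samples", "samplesize", "n_total"),
    n_cases       = c("n_cases", "ncase", "cases", "n_case")
  )
}

#' Construct and validate a table of summary associations
#'
#' A summary-association table holds one row per variant for a single
#' phenotype and stratum: the variant id, effect and other alleles, optional
#' effect-allele frequency, the per-allele effect (`beta`), its standard error
#' (`se`), the two-sided p-value, sample size and (for binary traits) case
#' count. Continuous-trait betas are in SD units; binary-trait betas are on
#' the linear-probability scale as produced by linear-model GWAS.
#'
#' @param variant_id Character vector of rsIDs.
#' @param effect_allele,other_allele Single-base alleles (A/C/G/T).
#' @param beta,se Per-allele effect and its standard error (`se > 0`).
#' @param pval Two-sided p-values in (0, 1]; if omitted, computed from
#'   `beta/se` under the standard normal.
#' @param eaf Optional effect-allele frequencies in \[0, 1\].
#' @param n Sample sizes (default `NA`).
#' @param n_cases Case counts for binary traits (default `NA`).
#' @param stratum One of `"both"`, `"men"`, `"women"`.
#' @param log10_pval Optional log10 p-values for associations below double
#'   underflow; carried alongside `pval`.
#'
#' @return A `data.frame` with class `"sumstats"`.
#' @export
sumstats <- function(variant_id, effect_allele, other_allele, beta, se,
                     pval = NULL, eaf = NA_real_, n = NA_real_,
                     n_cases = NA_real_, stratum = "both",
                     log10_pval = NA_real_) {
  if (is.null(pval)) {
    z <- abs(beta / se)
    pval <- 2 * stats::pnorm(-z)
    if (all(is.na(log10_pval))) {
      # keep precision below double underflow on the log scale
      log10_pval <- (log(2) + stats::pnorm(-z, log.p = TRUE)) / log(10)
    }
    pval[pval == 0] <- .Machine$double.xmin
  }
  df <- data.frame(
    variant_id = as.character(variant_id),
    effect_allele = toupper(as.character(effect_allele)),
    other_allele = toupper(as.character(other_allele)),
    eaf = as.numeric(eaf),
    beta = as.numeric(beta),
    se = as.numeric(se),
    pval = as.numeric(pval),
    log10_pval = as.numeric(log10_pval),
    n = as.numeric(n),
    n_cases = as.numeric(n_cases),
    stratum = as.character(stratum),
    stringsAsFactors = FALSE
  )
  validate_sumstats(df)
}

#' @rdname sumstats
#' @param x A data.frame to validate as a summary-association table.
#' @export
validate_sumstats <- function(x) {
  stopifnot(is.data.frame(x))
  required <- c("variant_id", "effect_allele", "other_allele", "beta", "se")
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols)) {
    stop("summary-statistic table is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (any(!x$effect_allele %in% VALID_ALLELES) ||
      any(!x$other_allele %in% VALID_ALLELES)) {
    stop("alleles must be single bases A/C/G/T", call. = FALSE)
  }
  if (any(x$effect_allele == x$other_allele)) {
    stop("effect_allele must differ from other_allele", call. = FALSE)
  }
  if (any(!is.finite(x$se)) || any(x$se <= 0)) {
    stop("se must be finite and > 0", call. = FALSE)
  }
  if ("pval" %in% names(x) && any(!is.na(x$pval) & (x$pval <= 0 | x$pval > 1))) {
    stop("pval must lie in (0, 1]", call. = FALSE)
  }
  if ("eaf" %in% names(x) && any(!is.na(x$eaf) & (x$eaf < 0 | x$eaf > 1))) {
    stop("eaf must lie in [0, 1]", call. = FALSE)
  }
  if (all(c("n", "n_cases") %in% names(x))) {
    bad <- !is.na(x$n_cases) & !is.na(x$n) & (x$n_cases <= 0 | x$n_cases >= x$n)
    if (any(bad)) stop("n_cases must satisfy 0 < n_cases < n", call. = FALSE)
  }
  if ("stratum" %in% names(x) && any(!x$stratum %in% VALID_STRATA)) {
    stop("stratum must be one of: ", paste(VALID_STRATA, collapse = ", "),
         call. = FALSE)
  }
  class(x) <- unique(c("sumstats", class(x)))
  x
}

match_column <- function(header, synonyms) {
  hit <- which(tolower(header) %in% tolower(synonyms))
  if (length(hit)) hit[1] else NA_integer_
}

parse_numeric_col <- function(values, colname, lines) {
  out <- suppressWarnings(as.numeric(values))
  blank <- is.na(values) | trimws(values) %in% c("", "NA", "na", ".")
  bad <- is.na(out) & !blank
  if (any(bad)) {
    i <- which(bad)[1]
    stop(sprintf("line %d: cannot parse '%s' as numeric in column '%s'",
                 lines[i], values[i], colname), call. = FALSE)
  }
  out
}

#' Read a tab-separated GWAS summary-statistic file
#'
#' Reads one phenotype x stratum table. Column headers are resolved through a
#' synonym map (see [default_col_synonyms()]); gzip-compressed files are read
#' transparently. Rows missing `beta` or `se` are dropped and counted; the
#' number dropped is attached as the `"n_dropped"` attribute and reported via
#' `message()`.
#'
#' @param path Path to a TSV (optionally `.gz`).
#' @param stratum Stratum label to stamp on the records
#'   (`"both"`, `"men"` or `"women"`).
#' @param col_map Optional synonym map overriding [default_col_synonyms()]
#'   entries.
#' @param quiet Suppress the dropped-row message.
#'
#' @return A `sumstats` data.frame; attribute `"n_dropped"` holds the count of
#'   rows dropped for missing beta/se.
#' @export
read_sumstats <- function(path, stratum = "both", col_map = NULL, quiet = FALSE) {
  stratum <- match.arg(stratum, VALID_STRATA)
  syn <- default_col_synonyms()
  if (!is.null(col_map)) syn[names(col_map)] <- col_map
  raw <- utils::read.delim(path, colClasses = "character",
                           check.names = FALSE, na.strings = c("NA", ""))
  header <- names(raw)
  idx <- vapply(syn, function(s) match_column(header, s), integer(1))
  required <- c("variant_id", "effect_allele", "other_allele", "beta", "se",
                "pval", "n")
  # a pval column may be replaced by a log10 p column
  if (is.na(idx[["pval"]]) && !is.na(idx[["log10_pval"]])) {
    required <- setdiff(required, "pval")
  }
  miss <- required[is.na(idx[required])]
  if (length(miss)) {
    stop("missing required column(s): ", paste(miss, collapse = ", "),
         " (accepted names: ",
         paste(vapply(miss, function(m) paste(syn[[m]], collapse = "/"),
                      character(1)), collapse = "; "), ")",
         call. = FALSE)
  }
  lines <- seq_len(nrow(raw)) + 1L  # physical line numbers incl. header
  col <- function(field) if (is.na(idx[[field]])) NULL else raw[[idx[[field]]]]
  num <- function(field) {
    v <- col(field)
    if (is.null(v)) rep(NA_real_, nrow(raw)) else parse_numeric_col(v, field, lines)
  }
  beta <- num("beta"); se <- num("se")
  keep <- !is.na(beta) & !is.na(se)
  n_dropped <- sum(!keep)
  if (n_dropped && !quiet) {
    message(sprintf("read_sumstats: dropped %d row(s) missing beta or se from %s",
                    n_dropped, path))
  }
  pval <- num("pval"); log10p <- num("log10_pval")
  if (all(is.na(pval)) && any(!is.na(log10p))) pval <- 10^log10p
  out <- data.frame(
    variant_id = as.character(col("variant_id")),
    effect_allele = toupper(as.character(col("effect_allele"))),
    other_allele = toupper(as.character(col("other_allele"))),
    eaf = num("eaf"),
    beta = beta,
    se = se,
    pval = pval,
    log10_pval = log10p,
    n = num("n"),
    n_cases = num("n_cases"),
    stratum = stratum,
    stringsAsFactors = FALSE
  )[keep, , drop = FALSE]
  rownames(out) <- NULL
  out <- validate_sumstats(out)
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Write a summary-association table to TSV
#'
#' Inverse of [read_sumstats()]: canonical column names, tab delimiters,
#' `NA` for missing, gzip when `path` ends in `.gz`.
#'
#' @param x A `sumstats` data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sumstats <- function(x, path) {
  cols <- intersect(c("variant_id", "effect_allele", "other_allele", "eaf",
                      "beta", "se", "pval", "log10_pval", "n", "n_cases",
                      "stratum"), names(x))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  utils::write.table(format_num_df(x[, cols, drop = FALSE]), con, sep = "\t",
                     quote = FALSE, row.names = FALSE, na = "NA")
  invisible(path)
}

# deterministic plain-text numeric formatting (up to 15 significant digits)
format_num_df <- function(df) {
  for (j in seq_along(df)) {
    if (is.numeric(df[[j]])) {
      v <- df[[j]]
      s <- vapply(v, function(x) {
        if (is.na(x)) NA_character_ else sprintf("%.15g", x)
      }, character(1))
      df[[j]] <- s
    }
  }
  df
}

#' Recover a standard error from a printed beta and p-value
#'
#' Published tables often report only the effect size and its two-sided
#' p-value. Under the normal reference distribution the implied standard
#' error is `|beta| / z` where `z` is the upper `p/2` quantile of the
#' standard normal. For p-values below double underflow (tables print values
#' down to ~1e-324), supply `log10_pval` instead and the quantile is taken on
#' the log scale.
#'
#' @param beta Nonzero effect estimate.
#' @param pval Two-sided p-value in (0, 1).
#' @param log10_pval Alternative to `pval`: log10 of the two-sided p-value.
#' @return The implied standard error (same units as `beta`).
#' @export
#' @examples
#' se_from_beta_p(2.0, 0.0455)   # ~1.0, since z ~ 2
#' se_from_beta_p(-0.89, log10_pval = -112 + log10(1.02))
se_from_beta_p <- function(beta, pval = NULL, log10_pval = NULL) {
  if (any(beta == 0)) stop("beta must be nonzero", call. = FALSE)
  if (is.null(pval) && is.null(log10_pval)) {
    stop("supply pval or log10_pval", call. = FALSE)
  }
  if (!is.null(pval)) {
    if (any(pval <= 0 | pval >= 1)) stop("pval must lie in (0, 1)", call. = FALSE)
    z <- stats::qnorm(pval / 2, lower.tail = FALSE)
  } else {
    if (any(log10_pval >= 0)) stop("log10_pval must be negative", call. = FALSE)
    # log(p/2) = log10p * log(10) - log(2)
    z <- stats::qnorm(log10_pval * log(10) - log(2),
                      lower.tail = FALSE, log.p = TRUE)
  }
  abs(beta) / z
}
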