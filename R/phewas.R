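#' Configuration for a phenome-wide MR scan
#'
#' Holds the inclusion/exclusion rules and testing parameters. Defaults
#' follow common practice for summary-statistic phenome scans: binary
#' phenotypes need at least 100 cases; continuous or ordered phenotypes need
#' at least 10,000 observations; ICD-coded phenotypes with external-cause
#' codes (Z00-Z99) are excluded; family-wise control is Bonferroni at
#' `alpha = 0.05` over the number of phenotypes actually tested.
#'
#' @param min_cases_binary Minimum case count for binary phenotypes.
#' @param min_n_quantitative Minimum sample size for continuous/ordered
#'   phenotypes.
#' @param excluded_icd_range Length-2 character vector giving an inclusive
#'   ICD code range to exclude, e.g. `c("Z00", "Z99")`.
#' @param excluded_subcategories Category names excluded outright (e.g.
#'   family history, hospital administration, lifestyle).
#' @param alpha Family-wise significance level.
#' @param strata Strata to scan; subset of `"both"`, `"men"`, `"women"`.
#' @param palindrome_eaf_window Passed to [harmonize()].
#' @return An object of class `"phewas_config"`.
#' @export
phewas_config <- function(min_cases_binary = 100,
                          min_n_quantitative = 10000,
                          excluded_icd_range = c("Z00", "Z99"),
                          excluded_subcategories = character(0),
                          alpha = 0.05,
                          strata = c("both", "men", "women"),
                          palindrome_eaf_window = 0.08) {
  stopifnot(min_cases_binary >= 1, min_n_quantitative >= 1,
            is.numeric(alpha), alpha > 0, alpha < 1,
            all(strata %in% VALID_STRATA), length(strata) >= 1)
  if (!is.null(excluded_icd_range)) {
    stopifnot(length(excluded_icd_range) == 2,
              all(grepl("^[A-Za-z][0-9]+$", excluded_icd_range)))
  }
  structure(
    list(min_cases_binary = min_cases_binary,
         min_n_quantitative = min_n_quantitative,
         excluded_icd_range = excluded_icd_range,
         excluded_subcategories = excluded_subcategories,
         alpha = alpha, strata = strata,
         palindrome_eaf_window = palindrome_eaf_window),
    class = "phewas_config"
  )
}

#' @export
print.phewas_config <- function(x, ...) {
  cat("<phewas_config>\n")
  cat("  min_cases_binary:      ", x$min_cases_binary, "\n")
  cat("  min_n_quantitative:    ", x$min_n_quantitative, "\n")
  cat("  excluded_icd_range:    ",
      if (is.null(x$excluded_icd_range)) "none"
      else paste(x$excluded_icd_range, collapse = "-"), "\n")
  cat("  excluded_subcategories:",
      if (length(x$excluded_subcategories))
        paste(x$excluded_subcategories, collapse = ", ") else "none", "\n")
  cat("  alpha:                 ", x$alpha, "\n")
  cat("  strata:                ", paste(x$strata, collapse = ", "), "\n")
  cat("  palindrome_eaf_window: ", x$palindrome_eaf_window, "\n")
  invisible(x)
}

#' @rdname phewas_config
#' @param path YAML file with any subset of the config fields.
#' @export
read_phewas_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(phewas_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown)) {
    stop("unknown config field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  do.call(phewas_config, vals)
}

icd_sort_key <- function(code) {
  # (letter, number) tuple as a sortable numeric; NA for malformed codes
  ok <- grepl("^[A-Za-z][0-9]+(\\.[0-9]+)?$", code)
  letter <- ifelse(ok, toupper(substr(code, 1, 1)), NA)
  num <- ifelse(ok, suppressWarnings(as.numeric(sub("^[A-Za-z]", "", code))), NA)
  match(letter, LETTERS) * 1000 + num
}

icd_in_range <- function(code, range) {
  key <- icd_sort_key(code)
  lo <- icd_sort_key(range[1]); hi <- icd_sort_key(range[2])
  !is.na(key) & key >= lo & key <= hi
}

#' Filter a phenotype manifest for a phenome scan
#'
#' Applies the inclusion/exclusion rules in a fixed, documented order, each
#' exclusion recorded with its *first* matching reason:
#'
#' 1. `duplicate` — repeated `phenotype_id` (first occurrence kept) or a
#'    non-missing `duplicate_of` field;
#' 2. `min_cases` — binary phenotypes with fewer than
#'    `min_cases_binary` cases;
#' 3. `min_n` — continuous/ordered phenotypes with sample size strictly
#'    below `min_n_quantitative`;
#' 4. `no_main_icd` / `icd_excluded_range` — ICD-coded binary phenotypes
#'    lacking a main code, or with a code in the excluded (external-cause)
#'    range;
#' 5. `excluded_subcategory` — categories on the exclusion list.
#'
#' The rule order affects only the recorded reasons, not the kept set. The
#' number of phenotypes kept is `Np`, the Bonferroni denominator.
#'
#' @param manifest Data.frame with columns `phenotype_id`, `label`,
#'   `category`, `trait_type` (`binary`/`ordered`/`continuous`), `n`,
#'   `n_cases`, and optionally `icd_code`, `icd_coded` (logical; defaults to
#'   `!is.na(icd_code)`), `duplicate_of`.
#' @param config A [phewas_config()].
#' @return List with `kept` (manifest subset), `exclusions` (data.frame of
#'   `phenotype_id`, `reason`), and `np` (number kept).
#' @export
filter_phenotypes <- function(manifest, config = phewas_config()) {
  stopifnot(is.data.frame(manifest))
  req <- c("phenotype_id", "category", "trait_type", "n")
  miss <- setdiff(req, names(manifest))
  if (length(miss)) stop("manifest missing column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  if (!"n_cases" %in% names(manifest)) manifest$n_cases <- NA_real_
  if (!"icd_code" %in% names(manifest)) manifest$icd_code <- NA_character_
  if (!"icd_coded" %in% names(manifest)) {
    manifest$icd_coded <- !is.na(manifest$icd_code)
  }
  if (!"duplicate_of" %in% names(manifest)) {
    manifest$duplicate_of <- NA_character_
  }
  bad_type <- !manifest$trait_type %in% c("binary", "ordered", "continuous")
  if (any(bad_type)) stop("unknown trait_type: ",
                          paste(unique(manifest$trait_type[bad_type]),
                                collapse = ", "), call. = FALSE)
  binary <- manifest$trait_type == "binary"
  if (any(binary & is.na(manifest$n_cases))) {
    stop("binary phenotypes must carry n_cases", call. = FALSE)
  }

  reason <- rep(NA_character_, nrow(manifest))
  mark <- function(cond, code) {
    cond <- cond & is.na(reason)
    reason[cond] <<- code
  }
  # order-stable duplicate rule: keep the first id in phenotype_id sort order
  # of appearance; duplicated() on the original order after an id sort makes
  # the kept set invariant to row permutations
  ord <- order(manifest$phenotype_id)
  dup_sorted <- duplicated(manifest$phenotype_id[ord])
  dup <- logical(nrow(manifest)); dup[ord] <- dup_sorted
  mark(dup | !is.na(manifest$duplicate_of), "duplicate")
  mark(binary & manifest$n_cases < config$min_cases_binary, "min_cases")
  mark(!binary & manifest$n < config$min_n_quantitative, "min_n")
  mark(binary & manifest$icd_coded & is.na(manifest$icd_code), "no_main_icd")
  if (!is.null(config$excluded_icd_range)) {
    in_range <- !is.na(manifest$icd_code) &
      icd_in_range(manifest$icd_code, config$excluded_icd_range)
    mark(binary & manifest$icd_coded & in_range, "icd_excluded_range")
  }
  mark(manifest$category %in% config$excluded_subcategories,
       "excluded_subcategory")

  kept <- manifest[is.na(reason), , drop = FALSE]
  rownames(kept) <- NULL
  exclusions <- data.frame(
    phenotype_id = manifest$phenotype_id[!is.na(reason)],
    reason = reason[!is.na(reason)], stringsAsFactors = FALSE)
  list(kept = kept, exclusions = exclusions, np = nrow(kept))
}

#' Bonferroni threshold for a phenome scan
#'
#' `alpha / Np` where `Np` is the number of phenotypes tested, reported at
#' full precision and rounded to two significant figures (the convention for
#' quoting the corrected level, e.g. 2.9e-05 for 1701 phenotypes at 0.05).
#'
#' @param np Number of phenotypes tested (>= 1).
#' @param alpha Family-wise level.
#' @return List with `threshold`, `threshold_2sf`, `np`, `alpha`.
#' @export
bonferroni_threshold <- function(np, alpha = 0.05) {
  if (!is.numeric(np) || length(np) != 1 || is.na(np) || np < 1) {
    stop("np must be a positive count", call. = FALSE)
  }
  thr <- alpha / np
  list(threshold = thr, threshold_2sf = signif(thr, 2),
       np = as.integer(np), alpha = alpha)
}

#' Two-sided z-test for a difference between two independent estimates
#'
#' `z = (beta_m - beta_w) / sqrt(se_m^2 + se_w^2)`, p from the standard
#' normal. Used both to compare men's and women's estimates and (via
#' [compare_replication()]) primary vs replication estimates. The test
#' operates on unscaled, SE-bearing estimates, never on anchor-scaled
#' relative effects.
#'
#' @param beta_m,se_m First estimate and its standard error.
#' @param beta_w,se_w Second estimate and its standard error.
#' @return List with vectors `z` and `pval`.
#' @export
sexdiff_ztest <- function(beta_m, se_m, beta_w, se_w) {
  if (any(!is.finite(se_m) | se_m <= 0) || any(!is.finite(se_w) | se_w <= 0)) {
    stop("standard errors must be finite and > 0", call. = FALSE)
  }
  z <- (beta_m - beta_w) / sqrt(se_m^2 + se_w^2)
  list(z = z, pval = 2 * stats::pnorm(-abs(z)))
}

#' @rdname sexdiff_ztest
#' @param primary,replication `mr_estimate`s to compare.
#' @export
compare_replication <- function(primary, replication) {
  sexdiff_ztest(primary$beta_hat, primary$se_hat,
                replication$beta_hat, replication$se_hat)
}

#' Scale scan effects relative to an anchor phenotype
#'
#' Expresses every effect as a multiple of the absolute effect on an anchor
#' phenotype in the same target and stratum — conventionally LDL-cholesterol,
#' so a scaled beta of -0.9 reads "90% of the effect on LDL-c, in the
#' lowering direction". The anchor's own scaled value is `sign(beta) * 1`.
#' Scaling is per target and per stratum; strata lacking an anchor estimate
#' get `NA` with a warning.
#'
#' @param results Scan results data.frame with columns `target`,
#'   `phenotype_id`, `stratum`, `beta`.
#' @param anchor_id `phenotype_id` of the anchor.
#' @return `results` with a `scaled_beta` column added/overwritten.
#' @export
scale_to_anchor <- function(results, anchor_id) {
  stopifnot(all(c("target", "phenotype_id", "stratum", "beta") %in%
                  names(results)))
  results$scaled_beta <- NA_real_
  for (tg in unique(results$target)) {
    for (st in unique(results$stratum)) {
      sel <- results$target == tg & results$stratum == st
      a <- which(sel & results$phenotype_id == anchor_id)
      if (!length(a) || is.na(results$beta[a[1]]) || results$beta[a[1]] == 0) {
        warning(sprintf("no usable anchor '%s' for target %s stratum %s; %s",
                        anchor_id, tg, st, "scaled_beta left NA"),
                call. = FALSE)
        next
      }
      results$scaled_beta[sel] <- results$beta[sel] / abs(results$beta[a[1]])
    }
  }
  results
}

fetch_sumstats <- function(store, phenotype_id, stratum) {
  if (is.character(store)) {
    path <- file.path(store, sprintf("%s.%s.tsv", phenotype_id, stratum))
    if (!file.exists(path)) return(NULL)
    read_sumstats(path, stratum = stratum, quiet = TRUE)
  } else {
    store[[phenotype_id]][[stratum]]
  }
}

#' Run a sex-stratified drug-target MR phenome scan
#'
#' For every target x kept-phenotype x stratum combination: harmonize the
#' outcome summary statistics to the target's instruments, estimate the
#' causal effect with the instrument-count-appropriate method
#' ([mr_estimate_auto()]), convert binary-trait estimates to odds ratios for
#' presentation, and flag significance at the Bonferroni level
#' `alpha / Np`. Binary traits are flagged on the linear-scale p-value; the
#' odds ratio is presentation only.
#'
#' @param manifest Phenotype manifest (see [filter_phenotypes()]).
#' @param store Either a directory containing files named
#'   `<phenotype_id>.<stratum>.tsv`, or a nested list
#'   `store[[phenotype_id]][[stratum]]` of `sumstats` tables.
#' @param instruments An [instrument_set()] or a named list of them (one per
#'   target).
#' @param config A [phewas_config()].
#' @param anchor_id Optional anchor `phenotype_id` for relative-effect
#'   scaling (see [scale_to_anchor()]).
#' @return An object of class `"phewas_scan"`: a list with
#'   * `results` — one row per target x phenotype x stratum (estimate, CI,
#'     p, dispersion, OR columns for binary traits, `neglog10_p`,
#'     `scaled_beta`, `significant`);
#'   * `sexdiff` — two-sided z-test comparing men vs women per target x
#'     phenotype;
#'   * `category_counts` — significant-hit counts by target and category;
#'   * `manhattan` — `(target, category, phenotype_id, stratum, neglog10_p)`
#'     ordered by category;
#'   * `exclusions`, `scan_log` — filter ledger and skipped combinations;
#'   * `summary` — `np`, threshold, significant row/phenotype counts.
#' @export
run_phewas <- function(manifest, store, instruments,
                       config = phewas_config(), anchor_id = NULL) {
  if (inherits(instruments, "instrument_set")) {
    instruments <- stats::setNames(list(instruments),
                                   instruments$target_label)
  }
  stopifnot(length(instruments) >= 1, !is.null(names(instruments)))

  filt <- filter_phenotypes(manifest, config)
  if (filt$np == 0) {
    stop("no phenotypes left after filtering; see the exclusion ledger",
         call. = FALSE)
  }
  thr <- bonferroni_threshold(filt$np, config$alpha)
  kept <- filt$kept

  n_max <- length(instruments) * filt$np * length(config$strata)
  col_chr <- function() character(n_max)
  col_num <- function() rep(NA_real_, n_max)
  res <- list(target = col_chr(), phenotype_id = col_chr(),
              category = col_chr(), trait_type = col_chr(),
              stratum = col_chr(), method = col_chr(),
              n_snps = integer(n_max), beta = col_num(), se = col_num(),
              ci_low = col_num(), ci_high = col_num(), pval = col_num(),
              phi = col_num(), q = col_num(), egger_intercept = col_num(),
              egger_intercept_p = col_num(), case_fraction = col_num(),
              or = col_num(), or_ci_low = col_num(), or_ci_high = col_num())
  log_rows <- list()
  ri <- 0L
  for (tg in names(instruments)) {
    ins <- instruments[[tg]]
    for (i in seq_len(nrow(kept))) {
      pid <- kept$phenotype_id[i]
      for (st in config$strata) {
        out <- fetch_sumstats(store, pid, st)
        if (is.null(out)) {
          log_rows[[length(log_rows) + 1L]] <- data.frame(
            target = tg, phenotype_id = pid, stratum = st,
            event = "missing_stratum_file", stringsAsFactors = FALSE)
          next
        }
        h <- harmonize(ins$members, out, config$palindrome_eaf_window)
        if (nrow(h$exposure) == 0) {
          log_rows[[length(log_rows) + 1L]] <- data.frame(
            target = tg, phenotype_id = pid, stratum = st,
            event = "no_variants_after_harmonization",
            stringsAsFactors = FALSE)
          next
        }
        sub <- instrument_subset(ins, h$exposure$variant_id)
        est <- mr_estimate_auto(sub, h$outcome)
        ri <- ri + 1L
        res$target[ri] <- tg; res$phenotype_id[ri] <- pid
        res$category[ri] <- kept$category[i]
        res$trait_type[ri] <- kept$trait_type[i]
        res$stratum[ri] <- st; res$method[ri] <- est$method
        res$n_snps[ri] <- est$n_snps
        res$beta[ri] <- est$beta_hat; res$se[ri] <- est$se_hat
        res$ci_low[ri] <- est$ci_low; res$ci_high[ri] <- est$ci_high
        res$pval[ri] <- est$pval
        res$phi[ri] <- est$dispersion_phi
        res$q[ri] <- est$heterogeneity_q
        res$egger_intercept[ri] <- est$egger_intercept
        res$egger_intercept_p[ri] <- est$egger_intercept_p
        if (kept$trait_type[i] == "binary" &&
            !is.na(kept$n_cases[i]) && !is.na(kept$n[i])) {
          k <- kept$n_cases[i] / kept$n[i]
          orr <- linear_beta_to_or(est, k)
          res$case_fraction[ri] <- k
          res$or[ri] <- orr$odds_ratio
          res$or_ci_low[ri] <- orr$ci_low
          res$or_ci_high[ri] <- orr$ci_high
        }
      }
    }
  }
  if (ri == 0L) {
    stop("scan produced no estimates; see scan log", call. = FALSE)
  }
  results <- data.frame(lapply(res, function(v) v[seq_len(ri)]),
                        stringsAsFactors = FALSE)
  results$neglog10_p <- -log10(results$pval)
  results$significant <- results$pval < thr$threshold
  if (!is.null(anchor_id)) results <- scale_to_anchor(results, anchor_id)

  sexdiff <- NULL
  if (all(c("men", "women") %in% config$strata)) {
    men <- results[results$stratum == "men", ]
    women <- results[results$stratum == "women", ]
    key_m <- paste(men$target, men$phenotype_id)
    key_w <- paste(women$target, women$phenotype_id)
    common <- intersect(key_m, key_w)
    m <- men[match(common, key_m), ]
    w <- women[match(common, key_w), ]
    zt <- sexdiff_ztest(m$beta, m$se, w$beta, w$se)
    sexdiff <- data.frame(
      target = m$target, phenotype_id = m$phenotype_id,
      beta_men = m$beta, se_men = m$se,
      beta_women = w$beta, se_women = w$se,
      z = zt$z, pval = zt$pval, stringsAsFactors = FALSE)
  }

  sig <- results[results$significant, , drop = FALSE]
  category_counts <- if (nrow(sig)) {
    agg <- stats::aggregate(list(n_significant = sig$pval),
                            by = list(target = sig$target,
                                      category = sig$category),
                            FUN = length)
    agg[order(agg$target, agg$category), , drop = FALSE]
  } else {
    data.frame(target = character(0), category = character(0),
               n_significant = integer(0))
  }

  manhattan <- results[order(results$target, results$category,
                             results$phenotype_id, results$stratum),
                       c("target", "category", "phenotype_id", "stratum",
                         "neglog10_p")]
  rownames(manhattan) <- NULL

  scan_log <- if (length(log_rows)) do.call(rbind, log_rows) else
    data.frame(target = character(0), phenotype_id = character(0),
               stratum = character(0), event = character(0))

  structure(
    list(results = results, sexdiff = sexdiff,
         category_counts = category_counts, manhattan = manhattan,
         exclusions = filt$exclusions, scan_log = scan_log,
         summary = list(
           np = filt$np, alpha = config$alpha,
           threshold = thr$threshold, threshold_2sf = thr$threshold_2sf,
           n_significant_rows = sum(results$significant),
           n_significant_phenotypes =
             length(unique(results$phenotype_id[results$significant])),
           n_skipped = nrow(scan_log))),
    class = "phewas_scan"
  )
}

# subset an instrument set to the given variant ids, preserving member order
instrument_subset <- function(ins, variant_ids) {
  if (length(variant_ids) == nrow(ins$members) &&
      all(variant_ids == ins$members$variant_id)) return(ins)
  idx <- match(variant_ids, ins$members$variant_id)
  instrument_set(ins$target_label, ins$members[idx, , drop = FALSE],
                 if (is.null(ins$correlation)) NULL else
                   ins$correlation[idx, idx, drop = FALSE],
                 ins$r2_prune_threshold)
}

#' @export
print.phewas_scan <- function(x, ...) {
  s <- x$summary
  cat("<phewas_scan>\n")
  cat(sprintf("  phenotypes tested (Np): %d, Bonferroni threshold %.2g\n",
              s$np, s$threshold_2sf))
  cat(sprintf("  estimates: %d rows; significant: %d rows over %d phenotype(s)\n",
              nrow(x$results), s$n_significant_rows,
              s$n_significant_phenotypes))
  cat(sprintf("  excluded phenotypes: %d; skipped combinations: %d\n",
              nrow(x$exclusions), s$n_skipped))
  invisible(x)
}
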