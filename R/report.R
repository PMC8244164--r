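#' Run manifest: provenance header for output tables
#'
#' Captures the tool version, a digest of the configuration, digests of the
#' input files, the seed(s), timestamps and ledger counts. Identical inputs,
#' config and seed give an identical config/input digest (timestamps are
#' excluded from the hash). Every table written by [write_phewas_tables()]
#' names the manifest hash in a leading `#` comment line.
#'
#' @param config A [phewas_config()] (or any serializable list).
#' @param input_paths Character vector of input files to digest.
#' @param seed Integer seed(s) used in the run.
#' @return An object of class `"run_manifest"`.
#' @export
run_manifest <- function(config = NULL, input_paths = character(0),
                         seed = NA_integer_) {
  digest_obj <- function(x) {
    f <- tempfile()
    on.exit(unlink(f))
    saveRDS(x, f, compress = FALSE)
    unname(tools::md5sum(f))
  }
  input_digests <- if (length(input_paths)) {
    stats::setNames(unname(tools::md5sum(input_paths)), basename(input_paths))
  } else character(0)
  core <- list(version = as.character(utils::packageVersion("mrphewas")),
               config = unclass(config), inputs = input_digests, seed = seed)
  structure(
    c(core, list(hash = digest_obj(core),
                 started = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))),
    class = "run_manifest"
  )
}

manifest_header <- function(rm) {
  sprintf("# run_manifest: %s | mrphewas %s | seed %s",
          rm$hash, rm$version, paste(rm$seed, collapse = ","))
}

write_tsv_with_header <- function(df, path, header) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  utils::write.table(format_pvals(format_num_df(df)), con, sep = "\t",
                     quote = FALSE, row.names = FALSE, na = "NA")
  invisible(path)
}

# serialize p-value-like columns in 3-significant-digit scientific notation
format_pvals <- function(df) {
  for (nm in intersect(c("pval", "egger_intercept_p"), names(df))) {
    v <- suppressWarnings(as.numeric(df[[nm]]))
    df[[nm]] <- ifelse(is.na(v), NA_character_, sprintf("%.2e", v))
  }
  df
}

#' Write the output tables of a phenome scan
#'
#' Emits `results.tsv`, `exclusions.tsv`, `category_counts.tsv`,
#' `manhattan.tsv` and (when present) `sexdiff.tsv` into `dir`, each headed
#' by a `# run_manifest:` comment line. Tab-delimited, UTF-8, period
#' decimals, `NA` for missing; p-values in 3-significant-digit scientific
#' notation.
#'
#' @param scan A `phewas_scan` from [run_phewas()].
#' @param dir Output directory (created if needed).
#' @param manifest A [run_manifest()]; a default one is built if omitted.
#' @return `dir`, invisibly.
#' @export
write_phewas_tables <- function(scan, dir, manifest = run_manifest()) {
  stopifnot(inherits(scan, "phewas_scan"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  hdr <- manifest_header(manifest)
  write_tsv_with_header(scan$results, file.path(dir, "results.tsv"), hdr)
  write_tsv_with_header(scan$exclusions, file.path(dir, "exclusions.tsv"), hdr)
  write_tsv_with_header(scan$category_counts,
                        file.path(dir, "category_counts.tsv"), hdr)
  write_tsv_with_header(scan$manhattan, file.path(dir, "manhattan.tsv"), hdr)
  if (!is.null(scan$sexdiff)) {
    write_tsv_with_header(scan$sexdiff, file.path(dir, "sexdiff.tsv"), hdr)
  }
  invisible(dir)
}

#' Wide per-phenotype comparison table across drug targets
#'
#' Pivots long scan results into the conventional presentation layout: one
#' row per phenotype, and for each target x stratum a scaled-beta column and
#' a p-value column, followed by the men-vs-women z-test p-value per target.
#' Requires anchor-scaled results (run the scan with `anchor_id`, or call
#' [scale_to_anchor()] first). Phenotypes missing for a target leave blank
#' (`NA`) cells.
#'
#' @param scan A `phewas_scan`, or a results data.frame with a `scaled_beta`
#'   column (then `sexdiff` may be passed separately).
#' @param sexdiff Optional sex-difference table when `scan` is a plain
#'   data.frame.
#' @param phenotypes Optional phenotype subset/order.
#' @return A wide data.frame: `phenotype_id`, then
#'   `<target>.<stratum>.scaled_beta`, `<target>.<stratum>.pval` for each
#'   target and stratum, then `<target>.sexdiff_p`.
#' @export
build_table1 <- function(scan, sexdiff = NULL, phenotypes = NULL) {
  if (inherits(scan, "phewas_scan")) {
    results <- scan$results
    sexdiff <- scan$sexdiff
  } else {
    results <- scan
  }
  if (!"scaled_beta" %in% names(results)) {
    stop("results carry no scaled_beta; run the scan with an anchor_id or ",
         "call scale_to_anchor first", call. = FALSE)
  }
  targets <- unique(results$target)
  strata <- intersect(VALID_STRATA, unique(results$stratum))
  if (is.null(phenotypes)) phenotypes <- unique(results$phenotype_id)
  out <- data.frame(phenotype_id = phenotypes, stringsAsFactors = FALSE)
  key <- paste(results$target, results$stratum, results$phenotype_id)
  for (tg in targets) {
    for (st in strata) {
      idx <- match(paste(tg, st, phenotypes), key)
      out[[paste(tg, st, "scaled_beta", sep = ".")]] <- results$scaled_beta[idx]
      out[[paste(tg, st, "pval", sep = ".")]] <- results$pval[idx]
    }
    if (!is.null(sexdiff)) {
      sd_key <- paste(sexdiff$target, sexdiff$phenotype_id)
      out[[paste(tg, "sexdiff_p", sep = ".")]] <-
        sexdiff$pval[match(paste(tg, phenotypes), sd_key)]
    }
  }
  out
}

#' Manhattan-style plot of a phenome scan (optional decoration)
#'
#' Convenience wrapper around ggplot2 for a quick look at
#' `-log10(p)` by category. Requires ggplot2; returns the plot object.
#'
#' @param scan A `phewas_scan`.
#' @param stratum Stratum to plot.
#' @param target Target to plot (default: first).
#' @return A ggplot object.
#' @export
plot_manhattan <- function(scan, stratum = "both",
                           target = scan$results$target[1]) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting", call. = FALSE)
  }
  d <- scan$results[scan$results$stratum == stratum &
                      scan$results$target == target, ]
  d <- d[order(d$category, d$phenotype_id), ]
  d$x <- seq_len(nrow(d))
  x <- neglog10_p <- category <- NULL  # soothe R CMD check for aes()
  ggplot2::ggplot(d, ggplot2::aes(x = x, y = neglog10_p,
                                  colour = category)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = -log10(scan$summary$threshold),
                        linetype = "dashed") +
    ggplot2::labs(x = "phenotype (by category)",
                  y = expression(-log[10](p)),
                  title = paste(target, stratum, sep = " / ")) +
    ggplot2::theme_minimal()
}
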