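#' Construct an instrument set for a drug target
#'
#' Bundles the variants proxying a drug target (e.g. HMGCR variants mimicking
#' statins, PCSK9 variants mimicking PCSK9 inhibitors, or an LDL-cholesterol
#' SNP score) together with their exposure associations, an optional signed
#' pairwise correlation matrix, and the r-squared threshold used for pruning.
#'
#' @param target_label Label for the target, e.g. `"HMGCR-statins"`.
#' @param members A `sumstats` table of exposure associations, one row per
#'   instrument variant.
#' @param correlation Optional square matrix of signed pairwise correlations;
#'   must be symmetric with unit diagonal and entries in \[-1, 1\]. Row and
#'   column names, when present, must match `members$variant_id`; unnamed
#'   matrices are taken to be in member order.
#' @param r2_prune_threshold Maximum allowed squared correlation between kept
#'   instruments, in (0, 1]. Default 0.01 (the "independent variants from
#'   different genomic regions" convention).
#'
#' @return An object of class `"instrument_set"`.
#' @export
instrument_set <- function(target_label, members, correlation = NULL,
                           r2_prune_threshold = 0.01) {
  members <- validate_sumstats(as.data.frame(members))
  if (anyDuplicated(members$variant_id)) {
    stop("duplicate variant_id in instrument members", call. = FALSE)
  }
  if (!is.null(correlation)) {
    correlation <- as.matrix(correlation)
    J <- nrow(members)
    if (!is.numeric(correlation) || nrow(correlation) != ncol(correlation)) {
      stop("correlation must be a square numeric matrix", call. = FALSE)
    }
    if (nrow(correlation) != J) {
      stop("correlation dimension (", nrow(correlation),
           ") does not match instrument count (", J, ")", call. = FALSE)
    }
    if (!is.null(rownames(correlation))) {
      if (!setequal(rownames(correlation), members$variant_id)) {
        stop("correlation row names do not match member variant ids",
             call. = FALSE)
      }
      correlation <- correlation[members$variant_id, members$variant_id,
                                 drop = FALSE]
    } else {
      dimnames(correlation) <- list(members$variant_id, members$variant_id)
    }
    if (max(abs(correlation - t(correlation))) > 1e-8) {
      stop("correlation matrix must be symmetric", call. = FALSE)
    }
    if (max(abs(diag(correlation) - 1)) > 1e-8) {
      stop("correlation matrix must have unit diagonal", call. = FALSE)
    }
    if (any(abs(correlation) > 1 + 1e-12)) {
      stop("correlation entries must lie in [-1, 1]", call. = FALSE)
    }
  }
  if (!is.numeric(r2_prune_threshold) || r2_prune_threshold <= 0 ||
      r2_prune_threshold > 1) {
    stop("r2_prune_threshold must lie in (0, 1]", call. = FALSE)
  }
  structure(
    list(target_label = as.character(target_label), members = members,
         correlation = correlation, r2_prune_threshold = r2_prune_threshold),
    class = "instrument_set"
  )
}

#' @export
print.instrument_set <- function(x, ...) {
  cat("<instrument_set> ", x$target_label, ": ", nrow(x$members),
      " variant(s), ",
      if (is.null(x$correlation)) "no correlation matrix"
      else "with correlation matrix",
      ", r2 prune threshold ", x$r2_prune_threshold, "\n", sep = "")
  invisible(x)
}

#' Read / write a square variant correlation matrix
#'
#' The on-disk format is a tab-separated table whose header row and first
#' column both carry variant ids (the "correlation coefficient matrix"
#' layout used for correlated-instrument sensitivity analyses).
#'
#' @param path Path to the TSV.
#' @return A named square numeric matrix.
#' @export
read_correlation <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, row.names = 1)
  m <- as.matrix(df)
  if (nrow(m) != ncol(m)) {
    stop("correlation file is not square: ", nrow(m), " x ", ncol(m),
         call. = FALSE)
  }
  storage.mode(m) <- "double"
  m
}

#' @rdname read_correlation
#' @param m Named square correlation matrix.
#' @export
write_correlation <- function(m, path) {
  df <- data.frame(variant_id = rownames(m),
                   format_num_df(as.data.frame(m)),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Prune an instrument set to approximate linkage independence
#'
#' Greedy selection in ascending exposure p-value order (ties broken by
#' variant id): a variant is kept iff its squared correlation with every
#' already-kept variant is below the set's `r2_prune_threshold`. This is the
#' standard construction of an "independent" instrument panel (r-squared
#' below 0.01 for variants from different genomic regions).
#'
#' @param instruments An [instrument_set()] with a correlation matrix.
#' @return A pruned `instrument_set`; members are in greedy (ascending
#'   p-value) order and the correlation matrix is subset accordingly.
#' @export
ld_prune <- function(instruments) {
  stopifnot(inherits(instruments, "instrument_set"))
  rho <- instruments$correlation
  if (is.null(rho)) {
    stop("ld_prune requires a correlation matrix; if the instruments are ",
         "already independent, skip pruning explicitly rather than calling ",
         "ld_prune without one", call. = FALSE)
  }
  m <- instruments$members
  thr <- instruments$r2_prune_threshold
  ord <- order(m$pval, m$variant_id)
  kept <- integer(0)
  for (i in ord) {
    if (all(rho[i, kept]^2 < thr)) kept <- c(kept, i)
  }
  instrument_set(instruments$target_label,
                 m[kept, , drop = FALSE],
                 rho[kept, kept, drop = FALSE],
                 thr)
}
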