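new_mr_estimate <- function(beta_hat, se_hat, method, n_snps,
                            dispersion_phi = NA_real_,
                            heterogeneity_q = NA_real_,
                            egger_intercept = NA_real_,
                            egger_intercept_se = NA_real_,
                            egger_intercept_p = NA_real_,
                            correlation_adjusted = FALSE) {
  stopifnot(is.finite(beta_hat), is.finite(se_hat), se_hat > 0)
  z975 <- stats::qnorm(0.975)
  structure(
    list(beta_hat = beta_hat, se_hat = se_hat,
         ci_low = beta_hat - z975 * se_hat,
         ci_high = beta_hat + z975 * se_hat,
         pval = max(2 * stats::pnorm(-abs(beta_hat / se_hat)),
                    .Machine$double.xmin),
         n_snps = as.integer(n_snps), method = method,
         dispersion_phi = dispersion_phi,
         heterogeneity_q = heterogeneity_q,
         egger_intercept = egger_intercept,
         egger_intercept_se = egger_intercept_se,
         egger_intercept_p = egger_intercept_p,
         correlation_adjusted = correlation_adjusted),
    class = "mr_estimate"
  )
}

#' @export
print.mr_estimate <- function(x, ...) {
  cat(sprintf("<mr_estimate> %s (J = %d%s)\n", x$method, x$n_snps,
              if (isTRUE(x$correlation_adjusted)) ", correlation-adjusted" else ""))
  cat(sprintf("  beta %.4g (se %.4g), 95%% CI [%.4g, %.4g], p %.3g\n",
              x$beta_hat, x$se_hat, x$ci_low, x$ci_high, x$pval))
  if (!is.na(x$dispersion_phi)) {
    cat(sprintf("  dispersion phi %.3g, Q %.3g\n",
                x$dispersion_phi, x$heterogeneity_q))
  }
  if (!is.na(x$egger_intercept)) {
    cat(sprintf("  Egger intercept %.4g (se %.4g), p %.3g\n",
                x$egger_intercept, x$egger_intercept_se, x$egger_intercept_p))
  }
  invisible(x)
}

#' @export
as.data.frame.mr_estimate <- function(x, ...) {
  data.frame(method = x$method, n_snps = x$n_snps, beta = x$beta_hat,
             se = x$se_hat, ci_low = x$ci_low, ci_high = x$ci_high,
             pval = x$pval, phi = x$dispersion_phi, q = x$heterogeneity_q,
             egger_intercept = x$egger_intercept,
             egger_intercept_p = x$egger_intercept_p,
             stringsAsFactors = FALSE)
}

#' Wald ratio: single-instrument causal estimate
#'
#' The variant-outcome association divided by the variant-exposure
#' association, with the first-order standard error
#' `se_out / |beta_exp|` (exposure uncertainty ignored, the usual
#' no-measurement-error convention for strong instruments).
#'
#' @param outcome,exposure Single-row `sumstats` tables (or lists carrying
#'   `beta`/`se`) for the same, already harmonized, variant.
#' @return An `mr_estimate` with `method = "wald"`.
#' @export
wald_ratio <- function(outcome, exposure) {
  b_out <- outcome$beta[1]; se_out <- outcome$se[1]
  b_exp <- exposure$beta[1]
  if (is.na(b_exp) || b_exp == 0) {
    stop("exposure beta is zero: Wald ratio undefined (weak instrument)",
         call. = FALSE)
  }
  new_mr_estimate(b_out / b_exp, se_out / abs(b_exp),
                  method = "wald", n_snps = 1L)
}

# Align outcome rows to instrument members by variant id; returns the pieces
# every multi-SNP estimator needs.
align_instruments <- function(instruments, outcomes) {
  stopifnot(inherits(instruments, "instrument_set"), is.data.frame(outcomes))
  m <- instruments$members
  idx <- match(m$variant_id, outcomes$variant_id)
  if (anyNA(idx)) {
    stop("outcome table is missing instrument variant(s): ",
         paste(m$variant_id[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  J <- nrow(m)
  rho <- instruments$correlation
  if (is.null(rho)) rho <- diag(J)
  list(bx = m$beta, bxse = m$se,
       by = outcomes$beta[idx], byse = outcomes$se[idx],
       rho = rho, J = J, ids = m$variant_id,
       correlated = !is.null(instruments$correlation) &&
         J > 1 && max(abs(instruments$correlation[upper.tri(rho)])) > 0)
}

check_omega <- function(omega, ids, rho) {
  sv <- svd(omega, nu = 0, nv = 0)$d
  if (min(sv) <= 0 || max(sv) / min(sv) > 1e8) {
    off <- abs(rho); diag(off) <- 0
    worst <- which(off == max(off), arr.ind = TRUE)[1, ]
    stop(sprintf(paste0("outcome covariance is near-singular (condition ",
                        "number > 1e8); near-duplicate instruments %s and %s ",
                        "(rho = %.4f) — prune before estimating"),
                 ids[worst[1]], ids[worst[2]], rho[worst[1], worst[2]]),
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Inverse-variance-weighted estimate with correlated instruments
#'
#' Generalized weighted least squares of outcome betas on exposure betas
#' through the origin. With outcome standard errors `se_i` and signed
#' instrument correlations `rho_ij`, the weight matrix is the inverse of
#' `Omega_ij = se_i se_j rho_ij`, giving
#' `beta_hat = (X' Omega^-1 X)^-1 X' Omega^-1 Y`. With an identity
#' correlation this reduces exactly to the classical fixed-effect IVW
#' weighted mean of Wald ratios with weights `1/se_i^2`.
#'
#' Under multiplicative random effects (the default, applied when `J >= 3`)
#' the standard error is inflated by `sqrt(phi)` where
#' `phi = max(1, Q/(J-1))` and `Q` is the generalized residual sum of
#' squares; `phi` is floored at 1 so that homogeneous data fall back to the
#' fixed-effect error.
#'
#' @param instruments An [instrument_set()]; its correlation matrix, when
#'   present, is used as `rho`.
#' @param outcomes Harmonized `sumstats` table containing every instrument
#'   variant.
#' @param random_effects Use multiplicative random effects when `J >= 3`
#'   (default `TRUE`).
#' @return An `mr_estimate` with `method` `"ivw_mre"` or `"ivw_fixed"`.
#' @export
mr_ivw <- function(instruments, outcomes, random_effects = TRUE) {
  a <- align_instruments(instruments, outcomes)
  if (a$J < 2) {
    stop("IVW requires at least 2 instruments; use wald_ratio for J = 1",
         call. = FALSE)
  }
  omega <- tcrossprod(a$byse) * a$rho
  check_omega(omega, a$ids, a$rho)
  oi <- chol2inv(chol(omega))
  xt_oi <- crossprod(a$bx, oi)                 # 1 x J
  v0 <- 1 / as.numeric(xt_oi %*% a$bx)         # (X' Omega^-1 X)^-1
  beta_hat <- v0 * as.numeric(xt_oi %*% a$by)
  resid <- a$by - a$bx * beta_hat
  q <- as.numeric(crossprod(resid, oi %*% resid))
  mre <- random_effects && a$J >= 3
  phi <- if (mre) max(1, q / (a$J - 1)) else 1
  new_mr_estimate(beta_hat, sqrt(phi * v0),
                  method = if (mre) "ivw_mre" else "ivw_fixed",
                  n_snps = a$J, dispersion_phi = phi, heterogeneity_q = q,
                  correlation_adjusted = a$correlated)
}

#' MR-Egger regression with the directional-pleiotropy intercept test
#'
#' Weighted regression of outcome betas on exposure betas *with* an
#' intercept, after orienting every pair so the exposure beta is positive
#' (both betas are negated where needed). A nonzero intercept indicates
#' directional pleiotropy — instruments acting on the outcome through
#' pathways other than the exposure with a systematic component — and the
#' slope remains a consistent causal estimate under such violations of the
#' exclusion restriction. Weights come from the same `Omega` as [mr_ivw()];
#' the residual dispersion is `phi = max(1, Q/(J-2))`.
#'
#' @inheritParams mr_ivw
#' @return An `mr_estimate` with `method = "egger"` and the intercept slots
#'   (`egger_intercept`, `egger_intercept_se`, `egger_intercept_p`) filled.
#' @export
mr_egger <- function(instruments, outcomes) {
  a <- align_instruments(instruments, outcomes)
  if (a$J < 3) {
    stop("MR-Egger requires at least 3 instruments (intercept and slope ",
         "with J - 2 residual df)", call. = FALSE)
  }
  flip <- a$bx < 0
  bx <- ifelse(flip, -a$bx, a$bx)
  by <- ifelse(flip, -a$by, a$by)
  # flipping (x, y) -> (-x, -y) rescales nothing in Omega
  omega <- tcrossprod(a$byse) * a$rho
  check_omega(omega, a$ids, a$rho)
  oi <- chol2inv(chol(omega))
  Z <- cbind(intercept = 1, slope = bx)
  ztoz <- crossprod(Z, oi %*% Z)
  cov0 <- solve(ztoz)
  coefs <- as.numeric(cov0 %*% crossprod(Z, oi %*% by))
  resid <- by - as.numeric(Z %*% coefs)
  q <- as.numeric(crossprod(resid, oi %*% resid))
  phi <- max(1, q / (a$J - 2))
  covb <- phi * cov0
  int_se <- sqrt(covb[1, 1])
  new_mr_estimate(coefs[2], sqrt(covb[2, 2]),
                  method = "egger", n_snps = a$J,
                  dispersion_phi = phi, heterogeneity_q = q,
                  egger_intercept = coefs[1], egger_intercept_se = int_se,
                  egger_intercept_p = 2 * stats::pnorm(-abs(coefs[1] / int_se)),
                  correlation_adjusted = a$correlated)
}

#' Multivariable MR: joint direct effects of several exposures
#'
#' Weighted least-squares regression of outcome betas on the exposure-beta
#' columns of several exposures, without intercept, weights `1/se_out^2`.
#' Separates direct effects when instruments act on more than one exposure
#' (e.g. a drug-target effect on basal metabolic rate adjusted for BMI).
#' Residual dispersion `phi = max(1, Q/(J-E))` inflates every standard
#' error.
#'
#' @param exposure_beta Numeric `J x E` matrix of per-variant exposure betas
#'   (named columns, one per exposure), harmonized to a common effect allele.
#' @param exposure_se Matching `J x E` matrix of standard errors (carried for
#'   provenance; the fit conditions on the exposure betas).
#' @param outcomes Harmonized `sumstats` table with `J` rows in the same
#'   variant order, or carrying `variant_id`s matching
#'   `rownames(exposure_beta)`.
#' @return Named list of `mr_estimate`s, one per exposure
#'   (`method = "mvmr"`). Exposures whose instrument-effect column is all
#'   zeros are dropped from the fit with a warning and returned as `NA`
#'   (their direct effect is unidentified); with one usable column the fit
#'   reduces to univariable IVW.
#' @export
mr_mvmr <- function(exposure_beta, exposure_se, outcomes) {
  X <- as.matrix(exposure_beta)
  if (is.null(colnames(X))) colnames(X) <- paste0("exposure", seq_len(ncol(X)))
  J <- nrow(X); E <- ncol(X)
  if (E < 2) stop("multivariable MR needs E >= 2 exposures", call. = FALSE)
  if (J <= E) stop("multivariable MR needs more instruments than exposures ",
                   "(J > E)", call. = FALSE)
  if (!is.null(rownames(X)) && "variant_id" %in% names(outcomes)) {
    idx <- match(rownames(X), outcomes$variant_id)
    if (anyNA(idx)) stop("outcome table missing instrument variant(s)",
                         call. = FALSE)
    outcomes <- outcomes[idx, , drop = FALSE]
  }
  stopifnot(nrow(outcomes) == J)
  # an exposure none of the instruments associates with contributes nothing:
  # drop it (its direct effect is unidentified) and fit the rest
  zero_col <- colSums(X != 0) == 0
  if (any(zero_col)) {
    warning("dropping exposure column(s) with all-zero instrument effects: ",
            paste(colnames(X)[zero_col], collapse = ", "), call. = FALSE)
  }
  Xf <- X[, !zero_col, drop = FALSE]
  Ef <- ncol(Xf)
  if (Ef < 1) stop("no usable exposure columns", call. = FALSE)
  if (qr(Xf)$rank < Ef) {
    cm <- suppressWarnings(stats::cor(Xf))
    diag(cm) <- 0
    worst <- which(abs(cm) == max(abs(cm)), arr.ind = TRUE)[1, ]
    stop(sprintf("exposure matrix is rank-deficient: columns '%s' and '%s' ",
                 colnames(Xf)[worst[1]], colnames(Xf)[worst[2]]),
         "are collinear", call. = FALSE)
  }
  w <- 1 / outcomes$se^2
  xtwx <- crossprod(Xf, w * Xf)
  cov0 <- solve(xtwx)
  coefs <- as.numeric(cov0 %*% crossprod(Xf, w * outcomes$beta))
  resid <- outcomes$beta - as.numeric(Xf %*% coefs)
  q <- sum(w * resid^2)
  phi <- max(1, q / (J - Ef))
  ses <- unname(sqrt(phi * diag(cov0)))
  fit <- lapply(seq_len(Ef), function(e) {
    new_mr_estimate(coefs[e], ses[e], method = "mvmr", n_snps = J,
                    dispersion_phi = phi, heterogeneity_q = q)
  })
  names(fit) <- colnames(Xf)
  out <- stats::setNames(vector("list", E), colnames(X))
  out[colnames(Xf)] <- fit
  out[colnames(X)[zero_col]] <- NA
  out
}

#' Convert a linear-probability estimate for a binary trait to an odds ratio
#'
#' GWAS of binary traits fitted by linear regression report betas on the
#' probability scale. For presentation these are converted to odds ratios
#' with the case-fraction approximation `log OR = beta / (k(1-k))` where `k`
#' is the proportion of cases; the standard error scales identically, so the
#' confidence interval is symmetric on the log-odds scale.
#'
#' @param estimate An `mr_estimate` on the linear-probability scale.
#' @param case_fraction Case fraction `k` in (0, 1).
#' @return An object of class `"or_result"`: `odds_ratio`, `ci_low`,
#'   `ci_high`, `pval`, `case_fraction`.
#' @seealso [or_to_linear_beta()] for the exact inverse.
#' @export
linear_beta_to_or <- function(estimate, case_fraction) {
  k <- case_fraction
  if (!is.numeric(k) || is.na(k) || k <= 0 || k >= 1) {
    stop("case_fraction must lie in (0, 1)", call. = FALSE)
  }
  denom <- k * (1 - k)
  log_or <- estimate$beta_hat / denom
  se_log_or <- estimate$se_hat / denom
  z975 <- stats::qnorm(0.975)
  structure(
    list(odds_ratio = exp(log_or),
         ci_low = exp(log_or - z975 * se_log_or),
         ci_high = exp(log_or + z975 * se_log_or),
         log_or = log_or, se_log_or = se_log_or,
         pval = estimate$pval, case_fraction = k),
    class = "or_result"
  )
}

#' @rdname linear_beta_to_or
#' @param or_result An `or_result`.
#' @return For `or_to_linear_beta()`: the linear-probability `beta` and `se`
#'   implied by the odds ratio (exact inverse of the conversion).
#' @export
or_to_linear_beta <- function(or_result) {
  k <- or_result$case_fraction
  denom <- k * (1 - k)
  list(beta = or_result$log_or * denom, se = or_result$se_log_or * denom)
}

#' @export
print.or_result <- function(x, ...) {
  cat(sprintf("<or_result> OR %.4g, 95%% CI [%.4g, %.4g] (case fraction %.3g)\n",
              x$odds_ratio, x$ci_low, x$ci_high, x$case_fraction))
  invisible(x)
}

#' Estimate a causal effect with the instrument-count-appropriate method
#'
#' Dispatch used by the phenome scan: a single instrument gives the Wald
#' ratio; two instruments give fixed-effect IVW (too few residual degrees of
#' freedom for a dispersion estimate); three or more give IVW with
#' multiplicative random effects. The instrument correlation matrix is used
#' whenever present.
#'
#' @inheritParams mr_ivw
#' @return An `mr_estimate`.
#' @export
mr_estimate_auto <- function(instruments, outcomes) {
  J <- nrow(instruments$members)
  if (J == 0) stop("empty instrument set", call. = FALSE)
  if (J == 1) {
    idx <- match(instruments$members$variant_id, outcomes$variant_id)
    if (is.na(idx)) stop("outcome table is missing the instrument variant ",
                         instruments$members$variant_id, call. = FALSE)
    wald_ratio(outcomes[idx, , drop = FALSE], instruments$members)
  } else if (J == 2) {
    mr_ivw(instruments, outcomes, random_effects = FALSE)
  } else {
    mr_ivw(instruments, outcomes, random_effects = TRUE)
  }
}
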