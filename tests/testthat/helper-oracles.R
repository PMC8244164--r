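# Independent oracles used across tests. These deliberately avoid the code
# paths of the package functions they check.

# linear solve by Gaussian elimination with partial pivoting (no solve())
gauss_solve <- function(A, b) {
  n <- nrow(A)
  M <- cbind(A, b)
  for (k in seq_len(n - 1)) {
    piv <- which.max(abs(M[k:n, k])) + k - 1
    if (piv != k) M[c(k, piv), ] <- M[c(piv, k), ]
    for (i in (k + 1):n) {
      f <- M[i, k] / M[k, k]
      M[i, ] <- M[i, ] - f * M[k, ]
    }
  }
  x <- numeric(n)
  for (i in n:1) {
    x[i] <- (M[i, n + 1] - sum(M[i, seq_len(n)][-seq_len(i)] *
                                 x[-seq_len(i)])) / M[i, i]
  }
  x
}

# GLS through the origin via the normal equations and Gaussian elimination
oracle_gls <- function(bx, by, omega) {
  oi_x <- gauss_solve(omega, bx)
  oi_y <- gauss_solve(omega, by)
  beta <- sum(bx * oi_y) / sum(bx * oi_x)
  v0 <- 1 / sum(bx * oi_x)
  resid <- by - bx * beta
  q <- sum(resid * gauss_solve(omega, resid))
  list(beta = beta, v0 = v0, q = q)
}

# upper-tail standard-normal quantile by bisection on pnorm (log scale)
oracle_upper_quantile <- function(log_p_upper) {
  lo <- 0; hi <- 50
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (pnorm(mid, lower.tail = FALSE, log.p = TRUE) > log_p_upper) {
      lo <- mid
    } else {
      hi <- mid
    }
  }
  (lo + hi) / 2
}

# random positive-definite correlation matrix
random_corr <- function(J) {
  A <- matrix(rnorm(J * (J + 2)), J + 2, J)
  S <- crossprod(A)
  d <- 1 / sqrt(diag(S))
  outer(d, d) * S
}

# quick sumstats builder with defaults
mk_ss <- function(id, beta, se, ea = "A", oa = "G", eaf = NA_real_,
                  pval = NULL, n = 10000, n_cases = NA_real_,
                  stratum = "both") {
  sumstats(id, ea, oa, beta, se, pval = pval, eaf = eaf, n = n,
           n_cases = n_cases, stratum = stratum)
}
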