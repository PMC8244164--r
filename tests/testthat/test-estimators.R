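test_that("the Wald ratio divides outcome by exposure with a first-order SE", {
  out <- mk_ss("rs1", -0.5, 0.1)
  ex <- mk_ss("rs1", 0.5, 0.02)
  w <- wald_ratio(out, ex)
  expect_equal(w$beta_hat, -1.0)
  expect_equal(w$se_hat, 0.2)
  expect_equal(w$method, "wald")
  expect_equal(w$n_snps, 1L)

  expect_equal(wald_ratio(mk_ss("rs1", 0.37, 0.1),
                          mk_ss("rs1", 0.37, 0.05))$beta_hat, 1.0)
  expect_error(wald_ratio(out, mk_ss("rs1", 0, 0.02)), "zero")
})

test_that("Wald first-order SE matches the leading delta-method term", {
  out <- mk_ss("rs1", 0.3, 0.05)
  ex <- mk_ss("rs1", -0.6, 0.02)
  w <- wald_ratio(out, ex)
  expect_equal(w$beta_hat, -0.5)
  expect_equal(w$se_hat, 0.05 / 0.6)
  # second-order delta oracle: var = se_y^2/bx^2 + by^2 se_x^2 / bx^4
  se2 <- sqrt(0.05^2 / 0.6^2 + 0.3^2 * 0.02^2 / 0.6^4)
  expect_gt(se2, w$se_hat)
  expect_lt((se2 - w$se_hat) / w$se_hat, 0.02)  # strong-instrument regime
})

test_that("identity-correlation IVW equals the scalar weighted-mean formula", {
  set.seed(5)
  for (J in c(2, 3, 5, 10, 56)) {
    bx <- runif(J, 0.05, 0.2)
    by <- -1 * bx + rnorm(J, 0, 0.02)
    byse <- rexp(J) / 20 + 0.005
    ins <- instrument_set("t", mk_ss(paste0("rs", 1:J), bx, rep(0.01, J)))
    out <- mk_ss(paste0("rs", 1:J), by, byse)
    est <- mr_ivw(ins, out, random_effects = FALSE)
    # independent scalar route: per-variant Wald ratios, weights 1/se^2
    r <- by / bx
    wts <- bx^2 / byse^2
    expect_equal(est$beta_hat, sum(wts * r) / sum(wts), tolerance = 1e-10)
    expect_equal(est$se_hat, sqrt(1 / sum(wts)), tolerance = 1e-10)
    # Q against the scalar residual formula
    expect_equal(est$heterogeneity_q,
                 sum((by - bx * est$beta_hat)^2 / byse^2), tolerance = 1e-8)
  }
})

test_that("two identical Wald ratios with equal weights meta-analyze to themselves", {
  ins <- instrument_set("t", mk_ss(c("rs1", "rs2"), c(0.1, 0.2), c(0.01, 0.01)))
  out <- mk_ss(c("rs1", "rs2"), c(-0.05, -0.10), c(0.01, 0.01))
  # both ratios are -0.5: the meta-analysis returns the common ratio with
  # zero residual heterogeneity
  est <- mr_ivw(ins, out)
  expect_equal(est$beta_hat, -0.5, tolerance = 1e-12)
  expect_equal(est$heterogeneity_q, 0, tolerance = 1e-10)
})

test_that("correlated IVW equals an independent Gaussian-elimination GLS solve", {
  set.seed(8)
  for (rep in 1:20) {
    J <- sample(3:6, 1)
    rho <- random_corr(J)
    bx <- runif(J, 0.05, 0.2)
    byse <- rexp(J) / 20 + 0.005
    by <- -0.8 * bx + as.numeric(t(chol(tcrossprod(byse) * rho)) %*% rnorm(J))
    ins <- instrument_set("t", mk_ss(paste0("rs", 1:J), bx, rep(0.01, J)), rho)
    out <- mk_ss(paste0("rs", 1:J), by, byse)
    est <- mr_ivw(ins, out)
    orc <- oracle_gls(bx, by, tcrossprod(byse) * rho)
    expect_equal(est$beta_hat, orc$beta, tolerance = 1e-10)
    expect_equal(est$heterogeneity_q, orc$q, tolerance = 1e-8)
    phi <- max(1, orc$q / (J - 1))
    expect_equal(est$se_hat, sqrt(phi * orc$v0), tolerance = 1e-10)
  }
})

test_that("IVW is invariant under joint permutation of variants and correlation", {
  set.seed(13)
  J <- 5
  rho <- random_corr(J)
  bx <- runif(J, 0.05, 0.2)
  byse <- rexp(J) / 20 + 0.005
  by <- -1 * bx + rnorm(J, 0, 0.01)
  ids <- paste0("rs", 1:J)
  dimnames(rho) <- list(ids, ids)
  ins <- instrument_set("t", mk_ss(ids, bx, rep(0.01, J)), rho)
  out <- mk_ss(ids, by, byse)
  ref <- mr_ivw(ins, out)
  for (r in 1:5) {
    p <- sample(J)
    ins_p <- instrument_set("t", mk_ss(ids[p], bx[p], rep(0.01, J)),
                            rho[p, p])
    est <- mr_ivw(ins_p, out[p, ])
    expect_equal(est$beta_hat, ref$beta_hat, tolerance = 1e-10)
    expect_equal(est$se_hat, ref$se_hat, tolerance = 1e-10)
  }
})

test_that("rescaling exposure betas by c rescales estimates by 1/c", {
  set.seed(17)
  J <- 8
  bx <- runif(J, 0.05, 0.2)
  byse <- rep(0.01, J)
  by <- 0.5 * bx + rnorm(J, 0, 0.02)
  ids <- paste0("rs", 1:J)
  out <- mk_ss(ids, by, byse)
  for (cc in c(2, 10, 0.25)) {
    a <- mr_ivw(instrument_set("t", mk_ss(ids, bx, rep(0.01, J))), out)
    b <- mr_ivw(instrument_set("t", mk_ss(ids, cc * bx, rep(0.01, J))), out)
    expect_equal(b$beta_hat, a$beta_hat / cc, tolerance = 1e-10)
    expect_equal(b$se_hat, a$se_hat / cc, tolerance = 1e-10)
    ea <- mr_egger(instrument_set("t", mk_ss(ids, bx, rep(0.01, J))), out)
    eb <- mr_egger(instrument_set("t", mk_ss(ids, cc * bx, rep(0.01, J))), out)
    expect_equal(eb$beta_hat, ea$beta_hat / cc, tolerance = 1e-10)
    w1 <- wald_ratio(out[1, ], mk_ss(ids[1], bx[1], 0.01))
    w2 <- wald_ratio(out[1, ], mk_ss(ids[1], cc * bx[1], 0.01))
    expect_equal(w2$beta_hat, w1$beta_hat / cc, tolerance = 1e-12)
  }
})

test_that("near-duplicate instruments trigger a condition-number error", {
  rho <- matrix(c(1, 1 - 1e-12, 1 - 1e-12, 1), 2, 2)
  ins <- instrument_set("t", mk_ss(c("rsA", "rsB"), c(0.1, 0.1), c(0.01, 0.01)),
                        rho)
  out <- mk_ss(c("rsA", "rsB"), c(0.05, 0.05), c(0.01, 0.01))
  expect_error(mr_ivw(ins, out), "rsA.*rsB|near-singular")
  expect_error(mr_ivw(instrument_set("t", mk_ss("rs1", 0.1, 0.01)),
                      mk_ss("rs1", 0.05, 0.01)), "wald_ratio")
})

test_that("Egger recovers an exact linear relationship with intercept", {
  bx <- c(0.05, 0.10, 0.20)
  by <- 0.5 * bx + 0.1
  ins <- instrument_set("t", mk_ss(paste0("rs", 1:3), bx, rep(0.01, 3)))
  out <- mk_ss(paste0("rs", 1:3), by, rep(0.01, 3))
  e <- mr_egger(ins, out)
  expect_equal(e$beta_hat, 0.5, tolerance = 1e-10)
  expect_equal(e$egger_intercept, 0.1, tolerance = 1e-10)
  expect_equal(e$heterogeneity_q, 0, tolerance = 1e-10)
  expect_error(mr_egger(instrument_set("t", mk_ss(c("rs1", "rs2"),
                                                  c(0.1, 0.2), c(0.01, 0.01))),
                        mk_ss(c("rs1", "rs2"), c(0.1, 0.2), c(0.01, 0.01))),
               "3")
})

test_that("Egger equals an independently coded weighted regression (lm oracle)", {
  set.seed(23)
  J <- 10
  bx <- runif(J, 0.05, 0.2) * sample(c(-1, 1), J, replace = TRUE)
  byse <- rexp(J) / 20 + 0.005
  by <- 0.7 * bx + 0.05 + rnorm(J, 0, 0.05)   # overdispersed: phi > 1
  ins <- instrument_set("t", mk_ss(paste0("rs", 1:J), bx, rep(0.01, J)))
  out <- mk_ss(paste0("rs", 1:J), by, byse)
  e <- mr_egger(ins, out)
  # oracle: orient to positive exposure effects, then weighted lm
  sgn <- sign(bx)
  fit <- lm(I(sgn * by) ~ I(sgn * bx), weights = 1 / byse^2)
  sm <- summary(fit)$coefficients
  expect_equal(e$egger_intercept, unname(sm[1, 1]), tolerance = 1e-8)
  expect_equal(e$beta_hat, unname(sm[2, 1]), tolerance = 1e-8)
  # with phi above 1 the lm sigma-rescaled SEs coincide with ours
  expect_gt(e$dispersion_phi, 1)
  expect_equal(e$se_hat, unname(sm[2, 2]), tolerance = 1e-8)
  expect_equal(e$egger_intercept_se, unname(sm[1, 2]), tolerance = 1e-8)
})

test_that("multivariable MR separates direct effects and detects degeneracy", {
  set.seed(29)
  J <- 20
  x1 <- runif(J, 0.05, 0.2)
  x2 <- runif(J, -0.1, 0.1)
  byse <- rep(0.01, J)
  by <- -1 * x1 + 0.5 * x2 + rnorm(J, 0, 0.01)
  out <- mk_ss(paste0("rs", 1:J), by, byse)
  X <- cbind(statins = x1, bmi = x2)
  fit <- mr_mvmr(X, cbind(rep(0.01, J), rep(0.01, J)), out)
  expect_lt(abs(fit$statins$beta_hat - (-1)), 2 * fit$statins$se_hat)
  expect_lt(abs(fit$bmi$beta_hat - 0.5), 2 * fit$bmi$se_hat)

  # duplicated column -> named rank error
  expect_error(mr_mvmr(cbind(a = x1, b = x1), cbind(byse, byse), out),
               "collinear")
  # all-zero second column reduces to univariable IVW
  expect_warning(
    red <- mr_mvmr(cbind(statins = x1, null = rep(0, J)),
                   cbind(byse, byse), out),
    "all-zero")
  uni <- mr_ivw(instrument_set("t", mk_ss(paste0("rs", 1:J), x1,
                                          rep(0.01, J))), out)
  expect_equal(red$statins$beta_hat, uni$beta_hat, tolerance = 1e-10)
  expect_equal(red$statins$se_hat, uni$se_hat, tolerance = 1e-10)
  expect_true(is.na(red$null))
})

test_that("odds-ratio conversion applies the case-fraction approximation", {
  est0 <- wald_ratio(mk_ss("rs1", 0, 0.01, pval = 1), mk_ss("rs1", 0.1, 0.01))
  expect_equal(linear_beta_to_or(est0, 0.37)$odds_ratio, 1.0)

  est <- wald_ratio(mk_ss("rs1", 0.01, 0.004), mk_ss("rs1", 1, 0.01))
  orr <- linear_beta_to_or(est, 0.5)
  expect_equal(orr$log_or, 0.04, tolerance = 1e-12)
  # log-scale CI symmetry
  expect_equal(log(orr$ci_high / orr$odds_ratio),
               log(orr$odds_ratio / orr$ci_low), tolerance = 1e-12)
  expect_error(linear_beta_to_or(est, 0), "case_fraction")
  expect_error(linear_beta_to_or(est, 1), "case_fraction")
  # exact inverse
  for (k in c(0.1, 0.3, 0.5)) {
    o <- linear_beta_to_or(est, k)
    back <- or_to_linear_beta(o)
    expect_equal(back$beta, est$beta_hat, tolerance = 1e-12)
    expect_equal(back$se, est$se_hat, tolerance = 1e-12)
  }
})

test_that("the automatic estimator dispatches on instrument count", {
  set.seed(31)
  tr <- synthetic_truth(n_instruments = 6,
                        ld_blocks = data.frame(size = 6, rho = 0.6),
                        seed = 31)
  sp <- simulate_pair(tr)
  direct <- mr_ivw(sp$instruments, sp$outcomes)
  auto <- mr_estimate_auto(sp$instruments, sp$outcomes)
  expect_equal(auto, direct)
  expect_equal(auto$method, "ivw_mre")

  one <- instrument_set("t", sp$instruments$members[1, ])
  expect_equal(mr_estimate_auto(one, sp$outcomes)$method, "wald")
  two <- instrument_set("t", sp$instruments$members[1:2, ],
                        sp$instruments$correlation[1:2, 1:2])
  a2 <- mr_estimate_auto(two, sp$outcomes)
  expect_equal(a2$method, "ivw_fixed")
  expect_equal(a2$dispersion_phi, 1)
})

test_that("the dispersion floor keeps phi at 1 for homogeneous data", {
  bx <- c(0.1, 0.15, 0.2)
  by <- 2 * bx + c(1e-5, -1e-5, 1e-5)   # nearly exact fit: Q/(J-1) << 1
  ins <- instrument_set("t", mk_ss(paste0("rs", 1:3), bx, rep(0.01, 3)))
  out <- mk_ss(paste0("rs", 1:3), by, rep(0.01, 3))
  est <- mr_ivw(ins, out)
  expect_lt(est$heterogeneity_q / 2, 1)
  expect_equal(est$dispersion_phi, 1)
})

test_that("Egger and IVW slopes agree without pleiotropy at large J", {
  tr <- synthetic_truth(n_instruments = 200, seed = 37)
  nrep <- 500
  d <- numeric(nrep)
  for (r in 1:nrep) {
    sp <- simulate_pair(tr, replicate = r)
    d[r] <- mr_egger(sp$instruments, sp$outcomes)$beta_hat -
      mr_ivw(sp$instruments, sp$outcomes)$beta_hat
  }
  expect_lt(abs(mean(d)), 3 * sd(d) / sqrt(nrep))
})
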