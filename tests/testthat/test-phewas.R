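mk_manifest <- function() {
  data.frame(
    phenotype_id = c("ldl", "apob", "dup", "dup", "rare", "small", "bound",
                     "zc", "noicd", "fam"),
    label = paste("trait", 1:10),
    category = c("blood biochemistry", "blood biochemistry", "circulatory",
                 "circulatory", "endocrine", "physical measures",
                 "physical measures", "circulatory", "digestive",
                 "family history"),
    trait_type = c("continuous", "continuous", "binary", "binary", "binary",
                   "continuous", "continuous", "binary", "binary",
                   "continuous"),
    n = c(3e5, 3e5, 3e5, 3e5, 3e5, 9999, 10000, 3e5, 3e5, 3e5),
    n_cases = c(NA, NA, 5000, 5000, 99, NA, NA, 4000, 4000, NA),
    icd_code = c(NA, NA, "I25", "I25", "E11", NA, NA, "Z51", NA, NA),
    icd_coded = c(FALSE, FALSE, TRUE, TRUE, TRUE, FALSE, FALSE, TRUE, TRUE,
                  FALSE),
    stringsAsFactors = FALSE
  )
}

test_that("manifest filtering matches the hand-enumerated truth table", {
  cfg <- phewas_config(excluded_subcategories = "family history")
  f <- filter_phenotypes(mk_manifest(), cfg)
  truth <- data.frame(
    phenotype_id = c("dup", "rare", "small", "zc", "noicd", "fam"),
    reason = c("duplicate", "min_cases", "min_n", "icd_excluded_range",
               "no_main_icd", "excluded_subcategory"),
    stringsAsFactors = FALSE)
  got <- f$exclusions[order(f$exclusions$phenotype_id), ]
  want <- truth[order(truth$phenotype_id), ]
  rownames(got) <- rownames(want) <- NULL
  expect_equal(got, want)
  expect_equal(f$np, 4)
  # boundary: n = 10000 is kept, the rule is strictly "less than"
  expect_true("bound" %in% f$kept$phenotype_id)
  # a 99-case binary phenotype is out
  expect_false("rare" %in% f$kept$phenotype_id)
})

test_that("filtering is stable under manifest row permutation", {
  cfg <- phewas_config(excluded_subcategories = "family history")
  ref <- filter_phenotypes(mk_manifest(), cfg)
  set.seed(5)
  for (r in 1:10) {
    m <- mk_manifest()[sample(10), ]
    f <- filter_phenotypes(m, cfg)
    expect_equal(f$np, ref$np)
    expect_setequal(f$kept$phenotype_id, ref$kept$phenotype_id)
  }
})

test_that("the Bonferroni threshold divides alpha by the phenotype count", {
  t1 <- bonferroni_threshold(1701, 0.05)
  expect_equal(t1$threshold, 0.05 / 1701)
  expect_equal(t1$threshold_2sf, 2.9e-5)
  expect_equal(bonferroni_threshold(1)$threshold, 0.05)
  expect_equal(bonferroni_threshold(20)$threshold_2sf, 2.5e-3)
  expect_error(bonferroni_threshold(0), "np")
})

test_that("the sex-difference z-test matches the normal-CDF oracle", {
  expect_equal(sexdiff_ztest(0.5, 0.1, 0.5, 0.2)$z, 0)
  expect_equal(sexdiff_ztest(0.5, 0.1, 0.5, 0.2)$pval, 1)
  u <- sexdiff_ztest(1, 1 / sqrt(2), 0, 1 / sqrt(2))
  expect_equal(u$z, 1)
  expect_equal(u$pval, 0.3173, tolerance = 1e-4)
  expect_error(sexdiff_ztest(1, 0, 0, 1), "standard errors")

  set.seed(2)
  for (r in 1:25) {
    bm <- rnorm(1); bw <- rnorm(1); sm <- rexp(1) + 0.01; sw <- rexp(1) + 0.01
    zt <- sexdiff_ztest(bm, sm, bw, sw)
    z <- (bm - bw) / sqrt(sm^2 + sw^2)
    # independent route via the chi-square tail
    p_oracle <- pchisq(z^2, df = 1, lower.tail = FALSE)
    expect_equal(zt$pval, p_oracle, tolerance = 1e-10)
  }
})

test_that("replication comparison composes with printed-table SE recovery", {
  beta <- 0.21
  se <- se_from_beta_p(beta, 1.94e-7)
  prim <- wald_ratio(mk_ss("rs1", beta, se), mk_ss("rs1", 1, 0.01))
  expect_equal(compare_replication(prim, prim)$z, 0)
  expect_equal(compare_replication(prim, prim)$pval, 1)
  # sign-flipped replication with equal SE: |z| = |beta| sqrt(2) / se
  flip <- wald_ratio(mk_ss("rs1", -beta, se), mk_ss("rs1", 1, 0.01))
  zt <- compare_replication(prim, flip)
  expect_equal(abs(zt$z), 2 * beta / sqrt(2 * prim$se_hat^2), tolerance = 1e-6)
})

test_that("anchor scaling is exact, sign-aware and scale-free", {
  res <- data.frame(
    target = "t", phenotype_id = c("ldl", "apob", "cal"),
    stratum = "both", beta = c(-0.04, -0.036, 0.02),
    stringsAsFactors = FALSE)
  s <- scale_to_anchor(res, "ldl")
  expect_equal(s$scaled_beta, c(-1.0, -0.9, 0.5))
  # positive anchor scales to +1
  res$beta <- c(0.04, -0.036, 0.02)
  expect_equal(scale_to_anchor(res, "ldl")$scaled_beta[1], 1.0)
  # scale-free: multiplying every beta by c leaves scaled values unchanged
  res$beta <- c(-0.04, -0.036, 0.02)
  for (cc in c(3, 0.1)) {
    res2 <- res; res2$beta <- res2$beta * cc
    expect_equal(scale_to_anchor(res2, "ldl")$scaled_beta,
                 scale_to_anchor(res, "ldl")$scaled_beta, tolerance = 1e-12)
  }
  expect_warning(scale_to_anchor(res, "nope"), "anchor")
})

test_that("a one-phenotype one-variant scan yields a single Wald row", {
  tr <- synthetic_truth(n_instruments = 1, seed = 41)
  fx <- simulate_phewas_fixture(n_phenotypes = 1, n_signals = 1, truth = tr,
                                seed = 41, sexdiff_signal = FALSE,
                                include_filter_traps = FALSE,
                                strata = "both")
  scan <- run_phewas(fx$manifest, fx$store, fx$instruments["statin_lead"],
                     fx$config, anchor_id = fx$anchor_id)
  expect_equal(nrow(scan$results), 1)
  expect_equal(scan$results$method, "wald")
  expect_equal(scan$results$n_snps, 1L)
  expect_equal(scan$summary$np, 1)
})

test_that("the scan flags exactly the generator's non-null phenotypes", {
  hits <- 0L
  for (s in 1:5) {
    fx <- simulate_phewas_fixture(n_phenotypes = 50, n_signals = 5, seed = s)
    scan <- run_phewas(fx$manifest, fx$store, fx$instruments["statin_lead"],
                       fx$config, anchor_id = fx$anchor_id)
    truth_ids <- fx$truth_table$phenotype_id
    flagged <- unique(scan$results$phenotype_id[scan$results$significant])
    ok <- setequal(flagged, truth_ids)
    hits <- hits + ok
    # per-stratum: a null stratum of a signal phenotype must not be forced
    men <- scan$results[scan$results$stratum == "men" &
                          scan$results$phenotype_id == "shbg", ]
    expect_false(men$significant)     # theta_men = 0 for the women-only trait
  }
  expect_gte(hits, 5 * 0.95 - 1)      # >= 95% of seeded runs (allow 1 miss)
})

test_that("per-category hit counts equal a hand recount of the results", {
  fx <- simulate_phewas_fixture(n_phenotypes = 30, n_signals = 5, seed = 9)
  scan <- run_phewas(fx$manifest, fx$store, fx$instruments["ldl_score"],
                     fx$config, anchor_id = fx$anchor_id)
  sig <- scan$results[scan$results$significant, ]
  recount <- table(sig$category)
  for (cat in names(recount)) {
    expect_equal(
      scan$category_counts$n_significant[scan$category_counts$category == cat],
      as.integer(recount[[cat]]))
  }
  expect_equal(sum(scan$category_counts$n_significant), nrow(sig))
  # open ambiguity: both counting conventions are reported
  expect_equal(scan$summary$n_significant_rows, nrow(sig))
  expect_equal(scan$summary$n_significant_phenotypes,
               length(unique(sig$phenotype_id)))
})

test_that("missing stratum data is skipped loudly, never silently", {
  fx <- simulate_phewas_fixture(n_phenotypes = 5, n_signals = 2, seed = 3,
                                strata = c("both", "men", "women"))
  fx$store[["apob"]][["women"]] <- NULL
  scan <- run_phewas(fx$manifest, fx$store, fx$instruments["statin_lead"],
                     fx$config, anchor_id = fx$anchor_id)
  expect_equal(scan$scan_log$phenotype_id, "apob")
  expect_equal(scan$scan_log$event, "missing_stratum_file")
  expect_equal(sum(scan$results$phenotype_id == "apob"), 2)
})

test_that("ICD chapters map onto scan categories with external causes as others", {
  got <- assign_category(c("I25", "E11", "J45", "C50", "K21", "Z51", "Q90"))
  expect_equal(got, c("circulatory", "endocrine", "respiratory", "neoplasms",
                      "digestive", "others", "others"))
  # range bounds are inclusive on both ends
  expect_equal(assign_category(c("A00", "B99")),
               rep("infectious diseases", 2))
  expect_equal(assign_category("bad-code"), "others")
})
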