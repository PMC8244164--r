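hash_chr <- function(s) {
  if (is.null(s) || !nzchar(s)) return(0)
  sum(utf8ToInt(s) * seq_along(utf8ToInt(s))) %% 1000003
}

# counter-based substream seed: one global integer seed plus integer/string
# counters give a reproducible per-draw seed strictly below 2^31
substream_seed <- function(seed, ...) {
  parts <- list(...)
  s <- as.double(seed) %% 2147483647
  for (p in parts) {
    k <- if (is.character(p)) hash_chr(p) else as.double(p)
    s <- (s * 48271 + k + 1) %% 2147483647
  }
  as.integer(s)
}

#' Ground-truth parameters for a synthetic two-sample MR scenario
#'
#' Encodes the generative model behind every simulated dataset: `J`
#' instruments in LD blocks, per-stratum true causal effects, directional
#' pleiotropy with mean `pleiotropy_mean` and SD `pleiotropy_sd`, exposure
#' effect sizes at a stated scale, and GWAS sample sizes that drive the
#' standard-error magnitudes. Identical seed and parameters give
#' bit-identical output.
#'
#' Defaults emulate the scale of a large biobank phenome scan: a 56-variant
#' independent instrument panel, exposure effects around 0.1 SD per allele,
#' an exposure GWAS of ~190k and sex-stratified outcome GWAS of ~360k (both),
#' ~167k (men) and ~194k (women), and a true causal effect of -1 per SD of
#' exposure in every stratum (the convention for a lipid-lowering target
#' scaled to its LDL-c effect).
#'
#' @param n_instruments Number of instruments `J`.
#' @param ld_blocks Data.frame with columns `size` and `rho` describing
#'   consecutive LD blocks (sizes must sum to `J`, `|rho| < 1`);
#'   `NULL` means all-independent.
#' @param theta Named numeric: true causal effect per stratum
#'   (`both`, `men`, `women`). For binary traits `theta` is the log odds
#'   ratio per exposure unit.
#' @param pleiotropy_mean,pleiotropy_sd Directional-pleiotropy parameters
#'   (per-variant direct effects `alpha_j ~ N(mean, sd^2)`).
#' @param exposure_beta_scale Scale of per-variant exposure effects; effects
#'   are drawn uniformly in `scale * [0.5, 1.5]` and sorted descending so
#'   the first variant is the lead (strongest) instrument.
#' @param n_exposure Exposure GWAS sample size.
#' @param n_outcome Outcome GWAS sample size; scalar or named per-stratum
#'   vector.
#' @param case_fraction Case fraction `k` for binary traits.
#' @param seed Integer seed; all randomness flows through counter-based
#'   substreams of it.
#' @return An object of class `"synthetic_truth"`.
#' @export
synthetic_truth <- function(n_instruments = 56,
                            ld_blocks = NULL,
                            theta = c(both = -1, men = -1, women = -1),
                            pleiotropy_mean = 0,
                            pleiotropy_sd = 0,
                            exposure_beta_scale = 0.1,
                            n_exposure = 188577,
                            n_outcome = c(both = 361194, men = 167020,
                                          women = 194174),
                            case_fraction = 0.1,
                            seed = 1L) {
  J <- as.integer(n_instruments)
  stopifnot(J >= 1, pleiotropy_sd >= 0, exposure_beta_scale > 0,
            n_exposure >= 1, all(n_outcome >= 1),
            case_fraction > 0, case_fraction < 1)
  if (is.null(ld_blocks)) {
    ld_blocks <- data.frame(size = rep(1L, J), rho = 0)
  }
  stopifnot(is.data.frame(ld_blocks),
            all(c("size", "rho") %in% names(ld_blocks)),
            sum(ld_blocks$size) == J, all(abs(ld_blocks$rho) < 1))
  if (length(n_outcome) == 1 && is.null(names(n_outcome))) {
    n_outcome <- stats::setNames(rep(n_outcome, 3), VALID_STRATA)
  }
  stopifnot(all(VALID_STRATA %in% names(n_outcome)),
            all(VALID_STRATA %in% names(theta)))
  structure(
    list(n_instruments = J, ld_blocks = ld_blocks, theta = theta,
         pleiotropy_mean = pleiotropy_mean, pleiotropy_sd = pleiotropy_sd,
         exposure_beta_scale = exposure_beta_scale,
         n_exposure = n_exposure, n_outcome = n_outcome,
         case_fraction = case_fraction, seed = as.integer(seed)),
    class = "synthetic_truth"
  )
}

block_correlation <- function(ld_blocks) {
  mats <- lapply(seq_len(nrow(ld_blocks)), function(b) {
    s <- ld_blocks$size[b]; r <- ld_blocks$rho[b]
    m <- matrix(r, s, s); diag(m) <- 1; m
  })
  J <- sum(ld_blocks$size)
  out <- matrix(0, J, J)
  at <- 0L
  for (m in mats) {
    s <- nrow(m)
    out[at + seq_len(s), at + seq_len(s)] <- m
    at <- at + s
  }
  out
}

# exposure-side structure is conditioned on: identical across replicates,
# strata and traits for a given truth (two-sample convention)
exposure_structure <- function(truth) {
  J <- truth$n_instruments
  old <- globalenv()$.Random.seed
  on.exit(restore_rng(old))
  set.seed(substream_seed(truth$seed, 0))
  eaf <- stats::runif(J, 0.1, 0.9)
  bx <- sort(truth$exposure_beta_scale * stats::runif(J, 0.5, 1.5),
             decreasing = TRUE)
  se_x <- 1 / sqrt(2 * eaf * (1 - eaf) * truth$n_exposure)
  rho <- block_correlation(truth$ld_blocks)
  list(variant_id = sprintf("rs%07d", 1000000L + seq_len(J)),
       eaf = eaf, bx = bx, se_x = se_x, rho = rho,
       independent = all(rho == diag(J)))
}

restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv())) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

# outcome draw shared by simulate_pair and the fixture generator; `es` is a
# precomputed exposure_structure(truth)
sim_outcome_draw <- function(truth, es, trait_type, stratum, replicate) {
  J <- truth$n_instruments
  theta <- unname(truth$theta[[stratum]])
  n_out <- unname(truth$n_outcome[[stratum]])
  k <- truth$case_fraction
  se_y <- 1 / sqrt(2 * es$eaf * (1 - es$eaf) * n_out)
  is_binary <- trait_type == "binary"
  theta_eff <- theta
  n_cases <- NA_real_
  if (is_binary) {
    se_y <- se_y * sqrt(k * (1 - k))       # residual variance k(1-k)
    theta_eff <- theta * k * (1 - k)       # linear-probability scale
    n_cases <- round(k * n_out)
  }
  old <- globalenv()$.Random.seed
  on.exit(restore_rng(old))
  set.seed(substream_seed(truth$seed, trait_type, stratum, replicate, 1))
  alpha <- if (truth$pleiotropy_sd > 0 || truth$pleiotropy_mean != 0) {
    stats::rnorm(J, truth$pleiotropy_mean, truth$pleiotropy_sd)
  } else rep(0, J)
  z <- stats::rnorm(J)
  eps <- if (es$independent) {
    se_y * z
  } else {
    omega <- tcrossprod(se_y) * es$rho
    as.numeric(t(chol(omega)) %*% z)
  }
  list(by = theta_eff * es$bx + alpha + eps, se_y = se_y, n_out = n_out,
       n_cases = n_cases, theta = theta, theta_eff = theta_eff)
}

# plain (unvalidated, validity holds by construction) sumstats data.frame
fast_sumstats <- function(variant_id, beta, se, eaf, n, n_cases, stratum) {
  z <- abs(beta / se)
  pval <- 2 * stats::pnorm(-z)
  log10p <- (log(2) + stats::pnorm(-z, log.p = TRUE)) / log(10)
  pval[pval == 0] <- .Machine$double.xmin
  out <- data.frame(variant_id = variant_id, effect_allele = "A",
                    other_allele = "G", eaf = eaf, beta = beta, se = se,
                    pval = pval, log10_pval = log10p, n = n,
                    n_cases = n_cases, stratum = stratum,
                    stringsAsFactors = FALSE)
  class(out) <- c("sumstats", class(out))
  out
}

#' Simulate a harmonized two-sample exposure/outcome pair
#'
#' Draws one replicate of GWAS summary statistics under the linear causal
#' model `beta_out,j = theta * beta_exp,j + alpha_j + eps_j`, with
#' `alpha_j ~ N(pleiotropy_mean, pleiotropy_sd^2)` and `eps` multivariate
#' normal with the LD-block correlation and per-variant standard errors
#' `1/sqrt(2 p (1-p) n_outcome)`. Exposure betas are fixed (conditioned on)
#' across replicates. Binary traits emit linear-probability betas
#' `theta * k(1-k)` — `theta` being the log odds ratio — with residual
#' variance scaled by `k(1-k)` and `n_cases = round(k * n)`.
#'
#' @param truth A [synthetic_truth()].
#' @param trait_type `"continuous"`, `"ordered"` or `"binary"`.
#' @param stratum Stratum to simulate.
#' @param replicate Replicate counter; varies the outcome noise substream
#'   only.
#' @param target_label Label for the returned instrument set.
#' @return List with `instruments` (an [instrument_set()] carrying the block
#'   correlation), `outcomes` (a `sumstats` table) and `truth_row` (the true
#'   `theta` and, for binary traits, the implied linear-scale effect).
#' @export
simulate_pair <- function(truth, trait_type = "continuous", stratum = "both",
                          replicate = 1, target_label = "synthetic-target") {
  stopifnot(inherits(truth, "synthetic_truth"),
            trait_type %in% c("continuous", "ordered", "binary"),
            stratum %in% VALID_STRATA)
  es <- exposure_structure(truth)
  d <- sim_outcome_draw(truth, es, trait_type, stratum, replicate)
  exposure <- sumstats(es$variant_id, "A", "G", es$bx, es$se_x,
                       eaf = es$eaf, n = truth$n_exposure, stratum = "both")
  outcomes <- sumstats(es$variant_id, "A", "G", d$by, d$se_y,
                       eaf = es$eaf, n = d$n_out, n_cases = d$n_cases,
                       stratum = stratum)
  list(
    instruments = instrument_set(target_label, exposure, es$rho),
    outcomes = outcomes,
    truth_row = list(theta = d$theta, theta_linear = d$theta_eff,
                     trait_type = trait_type, stratum = stratum)
  )
}

#' Simulate individual-level data for one biallelic variant and a binary trait
#'
#' Small validation helper linking the summary-statistic generator to the
#' odds-ratio conversion: genotypes `g ~ Binomial(2, eaf)` and case status
#' drawn from a logistic model with per-allele log odds ratio `log_or`,
#' intercept chosen so the marginal case fraction is approximately
#' `prevalence`.
#'
#' @param n Number of individuals.
#' @param eaf Effect-allele frequency.
#' @param log_or Per-allele log odds ratio.
#' @param prevalence Target case fraction.
#' @param seed Integer seed.
#' @return Data.frame with columns `g` (0/1/2) and `y` (0/1).
#' @export
simulate_binary_individual <- function(n, eaf, log_or, prevalence, seed = 1L) {
  stopifnot(n >= 1, eaf > 0, eaf < 1, prevalence > 0, prevalence < 1)
  old <- globalenv()$.Random.seed
  on.exit(restore_rng(old))
  set.seed(substream_seed(seed, "individual", 1))
  g <- stats::rbinom(n, 2, eaf)
  # centre the genotype so the intercept pins the marginal prevalence
  eta <- stats::qlogis(prevalence) + log_or * (g - 2 * eaf)
  y <- stats::rbinom(n, 1, stats::plogis(eta))
  data.frame(g = g, y = y)
}

fixture_categories <- c("blood biochemistry", "blood count",
                        "physical measures", "circulatory", "endocrine",
                        "respiratory", "digestive", "neoplasms")

#' Simulate a complete phenome-scan fixture with known ground truth
#'
#' Builds a manifest spanning binary, ordered and continuous phenotypes over
#' several categories; per-stratum summary-statistic tables for every
#' phenotype over a shared instrument panel; three nested drug-target
#' instrument regimes (a single lead variant; six correlated variants in one
#' LD block; a 56-variant independent score); an LDL-c anchor phenotype with
#' true effect -1 in every stratum; optionally a women-only signal
#' (`theta_women != 0 = theta_men`) to exercise the sex-difference test; and
#' rows engineered to be dropped by each manifest filter rule. A truth table
#' names every non-null phenotype and its per-stratum effect.
#'
#' Signal phenotypes (beyond the anchor) have |effect| between 0.5 and 0.9
#' on the anchor-relative scale; everything else is null. The same seed
#' regenerates byte-identical files.
#'
#' @param n_phenotypes Number of phenotypes that survive filtering.
#' @param n_signals Number of non-null phenotypes, anchor included
#'   (>= 1; the anchor is always a signal).
#' @param truth A [synthetic_truth()] template; its `theta` is overridden
#'   per phenotype. Defaults to a 62-variant panel: one block of 6 at
#'   rho 0.6 (the correlated drug-target proxies, the first being the lead
#'   variant) plus 56 independent variants (the exposure score).
#' @param seed Integer seed (overrides `truth$seed`).
#' @param sexdiff_signal Add a women-only phenotype at a quarter of the
#'   anchor effect.
#' @param include_filter_traps Append manifest rows tripping each exclusion
#'   rule (they never reach estimation).
#' @param strata Strata to emit.
#' @param replicate Outcome-noise replicate counter (exposure structure and
#'   manifest are unchanged across replicates).
#' @param dir Optional directory: when given, writes `manifest.tsv`,
#'   `instruments.tsv`, `correlation.tsv`, `truth.tsv` and per
#'   phenotype x stratum `<id>.<stratum>.tsv` files.
#' @return List with `manifest`, `store` (nested list of `sumstats`),
#'   `instruments` (named list of the three [instrument_set()] regimes),
#'   `truth_table`, `anchor_id`, `config` (a [phewas_config()] matching the
#'   fixture's exclusion list), and `seed`.
#' @export
simulate_phewas_fixture <- function(n_phenotypes = 50, n_signals = 5,
                                    truth = NULL, seed = 1L,
                                    sexdiff_signal = TRUE,
                                    include_filter_traps = TRUE,
                                    strata = c("both", "men", "women"),
                                    replicate = 1, dir = NULL) {
  stopifnot(n_signals >= 0, n_signals <= n_phenotypes,
            all(strata %in% VALID_STRATA))
  if (is.null(truth)) {
    truth <- synthetic_truth(
      n_instruments = 62,
      ld_blocks = data.frame(size = c(6, rep(1L, 56)),
                             rho = c(0.6, rep(0, 56))),
      seed = seed)
  }
  truth$seed <- as.integer(seed)
  es <- exposure_structure(truth)
  J <- truth$n_instruments

  # three nested instrument regimes over the shared panel
  exposure <- sumstats(es$variant_id, "A", "G", es$bx, es$se_x,
                       eaf = es$eaf, n = truth$n_exposure)
  block1 <- seq_len(min(truth$ld_blocks$size[1], J))
  score_idx <- if (J > max(block1)) (max(block1) + 1L):J else block1
  instruments <- list(
    statin_lead = instrument_set("statin_lead",
                                 exposure[1, , drop = FALSE],
                                 matrix(1, 1, 1,
                                        dimnames = list(es$variant_id[1],
                                                        es$variant_id[1]))),
    statin_proxies = instrument_set("statin_proxies",
                                    exposure[block1, , drop = FALSE],
                                    es$rho[block1, block1, drop = FALSE]),
    ldl_score = instrument_set("ldl_score",
                               exposure[score_idx, , drop = FALSE],
                               es$rho[score_idx, score_idx, drop = FALSE])
  )

  # --- manifest ---------------------------------------------------------
  anchor_id <- "ldl_c"
  theta_anchor <- c(both = -1, men = -1, women = -1)
  signal_defs <- list(
    list(id = anchor_id, label = "LDL cholesterol",
         category = "blood biochemistry", type = "continuous",
         theta = theta_anchor),
    list(id = "apob", label = "Apolipoprotein B",
         category = "blood biochemistry", type = "continuous",
         theta = c(both = -0.9, men = -0.88, women = -0.9)),
    list(id = "hba1c", label = "Glycated haemoglobin",
         category = "blood biochemistry", type = "continuous",
         theta = c(both = 0.6, men = 0.6, women = 0.6)),
    list(id = "platelet_count", label = "Platelet count",
         category = "blood count", type = "ordered",
         theta = c(both = -0.5, men = -0.5, women = -0.5)),
    list(id = "chol_med", label = "Cholesterol-lowering medication",
         category = "endocrine", type = "binary",
         theta = c(both = -0.8, men = -0.8, women = -0.8))
  )
  signal_defs <- if (n_signals == 0) list() else
    signal_defs[seq_len(min(n_signals, length(signal_defs)))]
  if (n_signals == 0) anchor_id <- NA_character_
  if (sexdiff_signal && n_signals > 0) {
    signal_defs <- c(signal_defs, list(
      list(id = "shbg", label = "Sex hormone-binding globulin",
           category = "endocrine", type = "continuous",
           theta = c(both = -0.125, men = 0, women = -0.25))))
  }
  n_null <- n_phenotypes - length(signal_defs)
  stopifnot(n_null >= 0)
  null_types <- rep(c("binary", "continuous", "ordered"), length.out = n_null)
  null_defs <- lapply(seq_len(n_null), function(i) {
    list(id = sprintf("null_%03d", i),
         label = sprintf("Null phenotype %03d", i),
         category = fixture_categories[1 + (i %% length(fixture_categories))],
         type = null_types[i],
         theta = c(both = 0, men = 0, women = 0))
  })
  defs <- c(signal_defs, null_defs)

  n_both <- unname(truth$n_outcome[["both"]])
  manifest <- do.call(rbind, lapply(seq_along(defs), function(i) {
    d <- defs[[i]]
    is_bin <- d$type == "binary"
    # per-phenotype case fraction, deterministic in the seed
    k <- if (is_bin) 0.02 + 0.28 * ((substream_seed(seed, d$id) %% 1000) / 999)
         else NA_real_
    data.frame(
      phenotype_id = d$id, label = d$label, category = d$category,
      trait_type = d$type, n = n_both,
      n_cases = if (is_bin) round(k * n_both) else NA_real_,
      icd_code = if (is_bin) sprintf("K%02d", (i * 7) %% 90) else NA_character_,
      icd_coded = is_bin,
      duplicate_of = NA_character_,
      stringsAsFactors = FALSE)
  }))

  if (include_filter_traps) {
    traps <- data.frame(
      phenotype_id = c(defs[[length(defs)]]$id, "trap_min_cases",
                       "trap_min_n", "trap_zcode", "trap_no_main_icd",
                       "trap_subcategory"),
      label = c("Duplicate of last null", "Too few cases",
                "Too small sample", "External-cause code",
                "No main ICD code", "Excluded subcategory"),
      category = c("digestive", "circulatory", "physical measures",
                   "circulatory", "digestive", "family history"),
      trait_type = c("continuous", "binary", "continuous", "binary",
                     "binary", "continuous"),
      n = c(n_both, n_both, 9999, n_both, n_both, n_both),
      n_cases = c(NA, 99, NA, 5000, 5000, NA),
      icd_code = c(NA, "K40", NA, "Z51", NA, NA),
      icd_coded = c(FALSE, TRUE, FALSE, TRUE, TRUE, FALSE),
      duplicate_of = NA_character_,
      stringsAsFactors = FALSE)
    manifest <- rbind(manifest, traps)
  }
  rownames(manifest) <- NULL

  # --- summary statistics ----------------------------------------------
  store <- list()
  truth_rows <- list()
  for (i in seq_along(defs)) {
    d <- defs[[i]]
    k_i <- if (d$type == "binary") {
      manifest$n_cases[manifest$phenotype_id == d$id][1] / n_both
    } else truth$case_fraction
    t_i <- truth
    t_i$theta <- d$theta
    t_i$case_fraction <- if (is.na(k_i)) truth$case_fraction else k_i
    per_stratum <- list()
    for (st in strata) {
      dr <- sim_outcome_draw(t_i, es, d$type, st,
                             substream_seed(seed, d$id, replicate))
      per_stratum[[st]] <- fast_sumstats(es$variant_id, dr$by, dr$se_y,
                                         es$eaf, dr$n_out, dr$n_cases, st)
    }
    store[[d$id]] <- per_stratum
    if (any(d$theta != 0)) {
      truth_rows[[length(truth_rows) + 1L]] <- data.frame(
        phenotype_id = d$id, trait_type = d$type,
        theta_both = unname(d$theta[["both"]]),
        theta_men = unname(d$theta[["men"]]),
        theta_women = unname(d$theta[["women"]]),
        stringsAsFactors = FALSE)
    }
  }
  truth_table <- if (length(truth_rows)) do.call(rbind, truth_rows) else
    data.frame(phenotype_id = character(0), trait_type = character(0),
               theta_both = numeric(0), theta_men = numeric(0),
               theta_women = numeric(0))

  config <- phewas_config(excluded_subcategories = "family history",
                          strata = strata)
  out <- list(manifest = manifest, store = store, instruments = instruments,
              truth_table = truth_table, anchor_id = anchor_id,
              config = config, seed = as.integer(seed))

  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.table(format_num_df(manifest),
                       file.path(dir, "manifest.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE, na = "NA")
    write_sumstats(exposure, file.path(dir, "instruments.tsv"))
    write_correlation(structure(es$rho, dimnames = list(es$variant_id,
                                                        es$variant_id)),
                      file.path(dir, "correlation.tsv"))
    utils::write.table(format_num_df(truth_table),
                       file.path(dir, "truth.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE, na = "NA")
    yaml::write_yaml(unclass(config), file.path(dir, "config.yaml"))
    for (pid in names(store)) {
      for (st in names(store[[pid]])) {
        write_sumstats(store[[pid]][[st]],
                       file.path(dir, sprintf("%s.%s.tsv", pid, st)))
      }
    }
  }
  out
}
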