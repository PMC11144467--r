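#' Configuration for the two-sample summary-statistics generator
#'
#' Describes a two-sample design with a quantitative exposure (GWAS of
#' `n_exposure` individuals) and a rare binary outcome (case/control GWAS),
#' the regime of a drug-target MR study: a very large lipid GWAS paired
#' with a biobank disease outcome with few cases. Defaults mirror that
#' regime: exposure sample size 1,320,016; outcome 360 cases vs 307,206
#' controls; 100 candidate variants jointly explaining 10% of exposure
#' variance; no pleiotropy; independent variants.
#'
#' @param seed integer seed; the whole simulation is reproducible from it.
#' @param k_variants number of variants.
#' @param maf_range minor-allele-frequency range, drawn uniformly.
#' @param n_exposure exposure GWAS sample size.
#' @param n_outcome_cases,n_outcome_controls outcome GWAS case/control counts.
#' @param theta true causal effect of the exposure on the outcome
#'   (log-odds per exposure SD).
#' @param exposure_r2 total exposure variance explained by the variants,
#'   in (0, 1).
#' @param pleiotropy_mode `"none"`, `"balanced"` (direct effects with mean
#'   zero) or `"directional"` (mean `pleiotropy_mean`). Direct effects are
#'   drawn independently of instrument strength, so the InSIDE condition
#'   holds by construction.
#' @param pleiotropy_sd SD of the per-variant direct effect.
#' @param pleiotropy_mean mean direct effect under `"directional"`.
#' @param ld_block_size variants per LD block (1 = independent).
#' @param ld_rho within-block correlation in `[0, 1)`.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(seed = 1, k_variants = 100, maf_range = c(0.05, 0.5),
                       n_exposure = 1320016, n_outcome_cases = 360,
                       n_outcome_controls = 307206, theta = 0,
                       exposure_r2 = 0.1,
                       pleiotropy_mode = c("none", "balanced", "directional"),
                       pleiotropy_sd = 0, pleiotropy_mean = 0,
                       ld_block_size = 1, ld_rho = 0) {
  pleiotropy_mode <- match.arg(pleiotropy_mode)
  stopifnot(k_variants >= 1, n_exposure > 0, n_outcome_cases > 0,
            n_outcome_controls > 0, exposure_r2 > 0, exposure_r2 < 1,
            length(maf_range) == 2, maf_range[1] > 0, maf_range[2] <= 0.5,
            maf_range[1] <= maf_range[2], pleiotropy_sd >= 0,
            ld_block_size >= 1, ld_rho >= 0, ld_rho < 1)
  structure(list(seed = as.integer(seed), k_variants = as.integer(k_variants),
                 maf_range = maf_range, n_exposure = n_exposure,
                 n_outcome_cases = n_outcome_cases,
                 n_outcome_controls = n_outcome_controls, theta = theta,
                 exposure_r2 = exposure_r2, pleiotropy_mode = pleiotropy_mode,
                 pleiotropy_sd = pleiotropy_sd, pleiotropy_mean = pleiotropy_mean,
                 ld_block_size = as.integer(ld_block_size), ld_rho = ld_rho),
            class = "sim_config")
}

# deterministic per-stage sub-seed from the global seed (kept below 2^31)
stage_seed <- function(seed, stage) {
  (as.numeric(seed) * 48271 + stage * 16807) %% 2147483647
}

block_ld <- function(ids, block_size, rho) {
  k <- length(ids)
  r <- diag(k)
  if (block_size > 1 && rho > 0) {
    for (start in seq(1, k, by = block_size)) {
      idx <- start:min(start + block_size - 1, k)
      r[idx, idx] <- rho
      diag(r)[idx] <- 1
    }
  }
  ld_matrix(ids, r)
}

#' Simulate paired two-sample GWAS summary statistics
#'
#' Generates exposure and outcome summary datasets with known ground truth.
#' Minor-allele frequencies are uniform on `maf_range`; true per-allele
#' exposure effects are drawn normal and rescaled so that
#' `sum(2 * maf * (1 - maf) * beta^2) = exposure_r2` (exposure variance 1).
#' Observed exposure effects are `N(beta, se)` with the standard
#' normal-theory `se = 1 / sqrt(2 * maf * (1 - maf) * n_exposure)`. True
#' outcome log-odds are `theta * beta_x + alpha` with per-variant direct
#' effects `alpha` set by the pleiotropy mode, and observed with the
#' binary-trait approximation
#' `se = 1 / sqrt(2 * maf * (1 - maf) * n_eff * phi * (1 - phi))`, where
#' `phi` is the case fraction and `n_eff = cases + controls`. P-values are
#' two-sided normal. The LD matrix is block-diagonal with correlation
#' `ld_rho` inside blocks of `ld_block_size`. Summary statistics are drawn
#' independently across variants; the LD matrix states the correlation
#' structure assumed for pruning rather than being injected into the noise.
#'
#' @param config a [sim_config()].
#' @return list of class `sim_output`: `exposure` and `outcome`
#'   ([summary_dataset()]s sharing variant ids), `ld` ([ld_matrix()]), and
#'   `truth` (list: `theta`, `beta_x` true exposure effects, `alpha`
#'   pleiotropic direct effects, `maf`).
#' @export
simulate_two_sample <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  k <- config$k_variants
  ids <- sprintf("rs%07d", seq_len(k))
  pos <- 55505221 + (seq_len(k) - 1) * 100

  maf <- withr_seed(stage_seed(config$seed, 1),
                    stats::runif(k, config$maf_range[1], config$maf_range[2]))
  # effect alleles are coded exposure-increasing (beta_x >= 0), the usual
  # convention for drug-target instrument tables; directional pleiotropy is
  # therefore defined relative to the exposure-raising allele
  raw <- abs(withr_seed(stage_seed(config$seed, 2), stats::rnorm(k)))
  het <- 2 * maf * (1 - maf)
  beta_x <- raw * sqrt(config$exposure_r2 / sum(het * raw^2))

  se_x <- 1 / sqrt(het * config$n_exposure)
  bhat_x <- withr_seed(stage_seed(config$seed, 3),
                       stats::rnorm(k, beta_x, se_x))

  alpha <- switch(config$pleiotropy_mode,
    none = rep(0, k),
    balanced = withr_seed(stage_seed(config$seed, 4),
                          stats::rnorm(k, 0, config$pleiotropy_sd)),
    directional = withr_seed(stage_seed(config$seed, 4),
                             stats::rnorm(k, config$pleiotropy_mean,
                                          config$pleiotropy_sd)))
  n_eff <- config$n_outcome_cases + config$n_outcome_controls
  phi <- config$n_outcome_cases / n_eff
  beta_y <- config$theta * beta_x + alpha
  se_y <- 1 / sqrt(het * n_eff * phi * (1 - phi))
  bhat_y <- withr_seed(stage_seed(config$seed, 5),
                       stats::rnorm(k, beta_y, se_y))

  mk_records <- function(bhat, se, n) {
    data.frame(variant_id = ids, chrom = "1", pos = pos,
               effect_allele = "A", other_allele = "G", eaf = maf,
               beta = bhat, se = se,
               pvalue = pmax(wald_pvalue(bhat, se), .Machine$double.xmin),
               n = n, stringsAsFactors = FALSE)
  }
  exposure <- summary_dataset(mk_records(bhat_x, se_x, config$n_exposure),
                              trait_name = "sim_exposure",
                              trait_type = "quantitative",
                              n_total = config$n_exposure)
  outcome <- summary_dataset(mk_records(bhat_y, se_y, n_eff),
                             trait_name = "sim_outcome", trait_type = "binary",
                             n_total = n_eff, n_cases = config$n_outcome_cases)
  structure(list(exposure = exposure, outcome = outcome,
                 ld = block_ld(ids, config$ld_block_size, config$ld_rho),
                 truth = list(theta = config$theta, beta_x = beta_x,
                              alpha = alpha, maf = maf),
                 config = config),
            class = "sim_output")
}

#' Simulate a regional dataset pair for colocalization
#'
#' Plants single causal variants in a region shared by two traits and
#' propagates their effects through an exchangeable LD structure
#' (correlation `ld_rho` between every pair). Expected z-scores are
#' `R %*% e_causal * effect_z`; observed z-scores add correlated unit
#' noise (`z = mu + L eps` with `L L' = R`). Betas are recovered as
#' `z * se` with fixed per-variant standard errors (0.02 for the
#' quantitative trait, 0.05 for the binary-scale trait).
#'
#' Configurations: `"shared"` — one causal variant for both traits (middle
#' of the region); `"distinct"` — different causal variants (first and
#' last); `"trait1_only"` / `"none"` — as named.
#'
#' @param n_variants number of variants (`>= 1`).
#' @param causal_config `"shared"`, `"distinct"`, `"trait1_only"`, `"none"`.
#' @param effect_z expected |z| at the causal variant (default 10).
#' @param ld_rho pairwise correlation in `[0, 1)` (default 0).
#' @param seed integer seed.
#' @return list with elements `trait1` and `trait2`
#'   ([summary_dataset()]s) and `truth` (causal indices per trait).
#' @export
simulate_coloc_region <- function(n_variants,
                                  causal_config = c("shared", "distinct",
                                                    "trait1_only", "none"),
                                  effect_z = 10, ld_rho = 0, seed = 1) {
  causal_config <- match.arg(causal_config)
  stopifnot(n_variants >= 1, ld_rho >= 0, ld_rho < 1)
  m <- n_variants
  mid <- (m + 1) %/% 2
  causal1 <- switch(causal_config, shared = mid, distinct = 1,
                    trait1_only = mid, none = integer(0))
  causal2 <- switch(causal_config, shared = mid, distinct = m,
                    trait1_only = integer(0), none = integer(0))
  if (causal_config == "distinct" && m < 2) {
    stop("distinct configuration needs at least 2 variants")
  }
  R <- matrix(ld_rho, m, m); diag(R) <- 1
  L <- chol(R)
  mu_z <- function(idx) {
    if (length(idx) == 0) rep(0, m) else as.numeric(R[, idx] * effect_z)
  }
  draw_z <- function(idx, sub) {
    eps <- withr_seed(stage_seed(seed, sub), stats::rnorm(m))
    mu_z(idx) + as.numeric(crossprod(L, eps))
  }
  z1 <- draw_z(causal1, 11)
  z2 <- draw_z(causal2, 12)

  ids <- sprintf("rs%07d", seq_len(m))
  pos <- 55505221 + (seq_len(m) - 1) * 500
  mk <- function(z, se1, type, name, n) {
    records <- data.frame(variant_id = ids, chrom = "1", pos = pos,
                          effect_allele = "A", other_allele = "G", eaf = 0.3,
                          beta = z * se1, se = se1,
                          pvalue = pmax(wald_pvalue(z, 1), .Machine$double.xmin),
                          n = n, stringsAsFactors = FALSE)
    summary_dataset(records, trait_name = name, trait_type = type, n_total = n)
  }
  list(trait1 = mk(z1, 0.02, "quantitative", "coloc_trait1", 100000),
       trait2 = mk(z2, 0.05, "binary", "coloc_trait2", 300000),
       truth = list(causal1 = causal1, causal2 = causal2))
}
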