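# Shared fixture builders; everything is generated in code.

make_records <- function(k, beta = rep(0.1, k), se = rep(0.02, k),
                         eaf = rep(0.3, k), n = rep(1e5, k),
                         effect_allele = rep("A", k), other_allele = rep("G", k),
                         ids = sprintf("rs%04d", seq_len(k)),
                         pos = 1000 + seq_len(k)) {
  data.frame(variant_id = ids, chrom = "1", pos = pos,
             effect_allele = effect_allele, other_allele = other_allele,
             eaf = eaf, beta = beta, se = se,
             pvalue = pmax(2 * pnorm(-abs(beta / se)), 1e-300), n = n,
             stringsAsFactors = FALSE)
}

make_dataset <- function(k, ..., trait_name = "trait",
                         trait_type = "quantitative", n_total = NULL) {
  summary_dataset(make_records(k, ...), trait_name = trait_name,
                  trait_type = trait_type, n_total = n_total)
}

# harmonized-instruments frame built directly (bypasses allele bookkeeping)
make_instruments <- function(beta_exp, beta_out, se_out,
                             se_exp = rep(1e-4, length(beta_exp))) {
  k <- length(beta_exp)
  structure(data.frame(variant_id = sprintf("rs%04d", seq_len(k)),
                       beta_exp = beta_exp, se_exp = se_exp,
                       eaf_exp = 0.3, beta_out = beta_out, se_out = se_out,
                       eaf_out = 0.3, action = "none",
                       stringsAsFactors = FALSE),
            class = c("harmonized_instruments", "data.frame"))
}

# linear-space enumeration oracle for the five colocalization hypotheses;
# safe only for moderate z-scores (no log-sum-exp)
coloc_enum_oracle <- function(labf1, labf2, priors) {
  bf1 <- exp(labf1); bf2 <- exp(labf2)
  s <- c(h0 = 1,
         h1 = priors$p1 * sum(bf1),
         h2 = priors$p2 * sum(bf2),
         h3 = priors$p1 * priors$p2 * (sum(bf1) * sum(bf2) - sum(bf1 * bf2)),
         h4 = priors$p12 * sum(bf1 * bf2))
  s / sum(s)
}

# 1-exposure x n-outcome grid built from independent null/alt simulations
make_grid_config <- function(seed = 1, n_outcomes = 3, theta = 0, k = 40,
                             n_boot = 0) {
  sims <- lapply(seq_len(n_outcomes), function(j) {
    simulate_two_sample(sim_config(seed = seed * 1000 + j, k_variants = k,
                                   theta = theta, exposure_r2 = 0.08))
  })
  exposure <- sims[[1]]$exposure
  analysis_config(
    exposures = list(list(name = "ldl", data = exposure)),
    outcomes = lapply(seq_len(n_outcomes), function(j) {
      list(name = paste0("outcome", j), data = sims[[j]]$outcome)
    }),
    ld = sims[[1]]$ld, n_boot = n_boot, seed = seed)
}

published_sensitivity <- function() {
  read.delim(system.file("extdata", "published_sensitivity_estimates.tsv",
                         package = "mrtarget"), stringsAsFactors = FALSE)
}

published_replication <- function() {
  read.delim(system.file("extdata", "published_replication_or.tsv",
                         package = "mrtarget"), stringsAsFactors = FALSE)
}
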