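test_that("summary-statistics files round-trip through write/read", {
  ds <- make_dataset(5, beta = c(0.1, -0.2, 0.05, 0, 0.3),
                     se = c(0.01, 0.02, 0.05, 0.04, 0.1),
                     eaf = c(0.1, 0.2, 0.3, 0.4, 0.49))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_summary_stats(ds, path)
  back <- read_summary_stats(path, trait_name = ds$trait_name)
  expect_equal(back$records, ds$records, tolerance = 1e-12)
  expect_equal(length(back), 5L)

  # empty dataset -> header-only file
  empty <- ds
  empty$records <- ds$records[0, ]
  write_summary_stats(empty, path)
  expect_length(readLines(path), 1L)
})

test_that("invalid rows are rejected with a count, bad columns error", {
  rec <- make_records(4)
  rec$se[2] <- 0                 # invariant violation
  rec$pvalue[3] <- 1.5           # invariant violation
  path <- withr::local_tempfile(fileext = ".tsv")
  names(rec) <- default_names <- c("variant_id", "chromosome", "base_pair_location",
                                   "effect_allele", "other_allele",
                                   "effect_allele_frequency", "beta",
                                   "standard_error", "p_value", "n")
  write.table(rec, path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_warning(ds <- read_summary_stats(path), "2 of 4 rows rejected")
  expect_equal(length(ds), 2L)

  # missing mandatory column
  write.table(rec[, -7], path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_summary_stats(path), "mandatory column")

  # zero valid rows
  rec2 <- make_records(1); rec2$se <- -1
  names(rec2) <- default_names
  write.table(rec2, path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_warning(expect_error(read_summary_stats(path), "no valid rows"))
})

test_that("constructor enforces dataset-level invariants", {
  rec <- make_records(3)
  expect_error(summary_dataset(rbind(rec, rec[1, ]), "t"), "unique")
  rec$se[1] <- 0
  expect_error(summary_dataset(rec, "t"), "invariant")
  expect_error(summary_dataset(make_records(3), "t", trait_type = "binary",
                               n_total = 100, n_cases = 100), "smaller")
})

test_that("gene regions use closed flanked windows", {
  r <- gene_region("1", 55505221, 55530525, flank = 10000)
  expect_true(in_region(r, "1", 55505221 - 10000))
  expect_false(in_region(r, "1", 55505221 - 10001))
  expect_true(in_region(r, "1", 55530525 + 10000))
  expect_false(in_region(r, "2", 55505221))
  expect_error(gene_region("1", 10, 5), "start")
})

test_that("harmonize resolves all compatible allele-pair configurations", {
  # exposure fixed at A/G, beta 0.1; enumerated outcome orientations
  ex <- make_dataset(1, beta = 0.1, eaf = 0.2)
  cases <- list(
    list(ea = "A", oa = "G", beta = -0.05, exp_beta = -0.05, action = "none"),
    list(ea = "G", oa = "A", beta = 0.05, exp_beta = -0.05, action = "swapped"),
    list(ea = "T", oa = "C", beta = 0.05, exp_beta = 0.05, action = "strand_flipped"),
    list(ea = "C", oa = "T", beta = 0.05, exp_beta = -0.05, action = "strand_flipped"))
  for (cs in cases) {
    ou <- make_dataset(1, beta = cs$beta, eaf = 0.2,
                       effect_allele = cs$ea, other_allele = cs$oa,
                       trait_type = "binary")
    h <- harmonize(ex, ou)
    expect_equal(h$beta_out, cs$exp_beta, info = paste(cs$ea, cs$oa))
    expect_equal(h$action, cs$action, info = paste(cs$ea, cs$oa))
  }
  # swapped orientation also flips the reported frequency
  ou <- make_dataset(1, beta = 0.05, eaf = 0.8,
                     effect_allele = "G", other_allele = "A",
                     trait_type = "binary")
  expect_equal(harmonize(ex, ou)$eaf_out, 0.2)
  # incompatible pair dropped with warning, and may empty the set
  ou <- make_dataset(1, effect_allele = "A", other_allele = "C",
                     trait_type = "binary")
  expect_warning(expect_error(harmonize(ex, ou), "no instruments"),
                 "incompatible")
})

test_that("palindromic variants follow the frequency window rule", {
  pal_exp <- make_dataset(1, beta = 0.1, eaf = 0.50,
                          effect_allele = "A", other_allele = "T")
  pal_out <- make_dataset(1, beta = 0.05, eaf = 0.50,
                          effect_allele = "A", other_allele = "T",
                          trait_type = "binary")
  h <- harmonize(pal_exp, pal_out, palindromic_eaf_window = 0.08)
  expect_error(retained_instruments(h)[1, ], NA)   # frame exists
  expect_equal(h$action, "dropped_palindromic")
  expect_error(ivw(h), "no instruments|No instruments|k")

  # informative frequencies resolve orientation: both on same side -> aligned
  a <- make_dataset(2, beta = c(0.1, 0.1), eaf = c(0.2, 0.2),
                    effect_allele = c("A", "G"), other_allele = c("T", "C"))
  b_rec <- make_records(2, beta = c(0.05, -0.05), eaf = c(0.2, 0.8),
                        effect_allele = c("A", "G"), other_allele = c("T", "C"))
  b <- summary_dataset(b_rec, "out", trait_type = "binary")
  h <- harmonize(a, b)
  expect_equal(h$action, c("none", "swapped"))
  expect_equal(h$beta_out, c(0.05, 0.05))

  # missing frequency on either side always drops a palindromic variant
  b2 <- b; b2$records$eaf <- NA_real_
  h2 <- suppressWarnings(tryCatch(harmonize(a, b2), error = identity))
  if (inherits(h2, "error")) {
    expect_match(conditionMessage(h2), "no instruments retained")
  } else {
    expect_true(all(h2$action == "dropped_palindromic"))
  }
})

test_that("harmonization invariants hold on simulated data", {
  sim <- simulate_two_sample(sim_config(seed = 11, k_variants = 40))
  # involution: dataset against itself reproduces its own betas
  h <- harmonize(sim$exposure, sim$exposure)
  expect_equal(h$beta_out, h$beta_exp)
  expect_true(all(h$action == "none"))

  # flipping both alleles and negating beta leaves results unchanged
  flipped <- sim$outcome
  flipped$records$effect_allele <- sim$outcome$records$other_allele
  flipped$records$other_allele <- sim$outcome$records$effect_allele
  flipped$records$beta <- -sim$outcome$records$beta
  flipped$records$eaf <- 1 - sim$outcome$records$eaf
  h1 <- harmonize(sim$exposure, sim$outcome)
  h2 <- harmonize(sim$exposure, flipped)
  expect_equal(h2$beta_out, h1$beta_out)
  expect_equal(h2$eaf_out, h1$eaf_out)

  # retained + dropped = id intersection
  expect_equal(nrow(h1), length(intersect(sim$exposure$records$variant_id,
                                          sim$outcome$records$variant_id)))
})
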