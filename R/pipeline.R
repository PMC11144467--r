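#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment: sort the m p-values ascending, form
#' `p_(i) * m / i`, enforce monotone non-decreasing from the largest rank
#' downwards, cap at 1, and return the adjusted values in the input order.
#'
#' @param pvalues numeric vector of raw p-values in (0, 1].
#' @return adjusted p-values, same length and order as the input.
#' @export
bh_adjust <- function(pvalues) {
  if (length(pvalues) == 0) stop("empty p-value vector")
  if (any(is.na(pvalues)) || any(pvalues <= 0 | pvalues > 1)) {
    stop("p-values must lie in (0, 1]")
  }
  m <- length(pvalues)
  ord <- order(pvalues)
  scaled <- pvalues[ord] * m / seq_len(m)
  adj <- rev(cummin(rev(scaled)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[ord] <- adj
  out
}

as_dataset_input <- function(x, ...) {
  if (inherits(x, "summary_dataset")) x else read_summary_stats(x, ...)
}

#' Configuration for a multi-exposure, multi-outcome MR analysis
#'
#' Encodes the full study grid: each exposure is instrumented once
#' (significance threshold, LD pruning, optional cis region) and tested
#' against every outcome. Exposures and outcomes may be given either as
#' in-memory [summary_dataset()] objects or as file paths readable by
#' [read_summary_stats()]; the LD matrix likewise as an [ld_matrix()] or a
#' path for [read_ld_matrix()].
#'
#' @param exposures list of exposure specifications; each a list with
#'   `name`, `data` (dataset or path), optional `region` ([gene_region()]),
#'   optional `p_threshold` (default 5e-8), optional `r2_threshold`
#'   (default 0.1), optional `trait_type` (default `"quantitative"`, used
#'   when reading from file).
#' @param outcomes list of outcome specifications; each a list with
#'   `name`, `data` (dataset or path), optional `trait_type` (default
#'   `"binary"`).
#' @param ld an [ld_matrix()] or path to one.
#' @param fdr_alpha FDR significance level (default 0.05).
#' @param fdr_family `"per_exposure"` (BH applied within each exposure's
#'   outcome panel, the default) or `"global"` (one family across all
#'   cells).
#' @param report_lowering report odds ratios per unit *lower* exposure
#'   (default `TRUE`).
#' @param variance_model IVW variance model, see [ivw()].
#' @param n_boot weighted-median bootstrap replicates.
#' @param palindromic_eaf_window,allow_strand_flip harmonization settings,
#'   see [harmonize()].
#' @param seed integer seed driving the weighted-median bootstrap.
#' @return list of class `analysis_config`.
#' @export
analysis_config <- function(exposures, outcomes, ld, fdr_alpha = 0.05,
                            fdr_family = c("per_exposure", "global"),
                            report_lowering = TRUE,
                            variance_model = "multiplicative_random",
                            n_boot = 1000, palindromic_eaf_window = 0.08,
                            allow_strand_flip = TRUE, seed = 2024) {
  fdr_family <- match.arg(fdr_family)
  stopifnot(length(exposures) >= 1, length(outcomes) >= 1,
            fdr_alpha > 0, fdr_alpha < 1)
  structure(list(exposures = exposures, outcomes = outcomes, ld = ld,
                 fdr_alpha = fdr_alpha, fdr_family = fdr_family,
                 report_lowering = report_lowering,
                 variance_model = variance_model, n_boot = n_boot,
                 palindromic_eaf_window = palindromic_eaf_window,
                 allow_strand_flip = allow_strand_flip,
                 seed = as.integer(seed)),
            class = "analysis_config")
}

estimate_row <- function(exposure, outcome, est) {
  if (is_unavailable(est)) {
    data.frame(exposure = exposure, outcome = outcome, method = est$method,
               beta = NA_real_, se = NA_real_, pvalue = NA_real_,
               ci_low = NA_real_, ci_high = NA_real_, k = NA_integer_,
               cochran_Q = NA_real_, status = paste0("unavailable (", est$reason, ")"),
               stringsAsFactors = FALSE)
  } else {
    data.frame(exposure = exposure, outcome = outcome, method = est$method,
               beta = est$beta, se = est$se, pvalue = est$pvalue,
               ci_low = est$ci_low, ci_high = est$ci_high, k = est$k,
               cochran_Q = est$cochran_Q, status = "ok",
               stringsAsFactors = FALSE)
  }
}

#' Run the full MR analysis grid
#'
#' For each exposure: select instruments ([select_instruments()]), then for
#' each outcome harmonize ([harmonize()]), estimate the primary
#' inverse-variance-weighted effect (Wald ratio when only one instrument
#' survives), run the sensitivity estimators (MR-Egger and weighted
#' median; marked unavailable when fewer than 3 instruments), and compute
#' instrument-strength diagnostics with the weak-instrument flag at
#' `F < 10`. Benjamini-Hochberg adjustment is applied to the primary
#' p-values within each exposure's outcome family (or globally, per the
#' config). Per-cell failures are recorded in the report rather than
#' aborting the run; the run is reproducible bit-for-bit from the config
#' seed.
#'
#' @param config an [analysis_config()].
#' @return list of class `analysis_report`: `primary` (one row per
#'   exposure x outcome: IVW beta/se/p, BH-adjusted p, OR with 95% CI,
#'   `k`, weak flag, status), `sensitivity` (long table of Egger slope /
#'   intercept and weighted-median rows), `strength` (per exposure), and
#'   `config`.
#' @export
run_analysis <- function(config) {
  stopifnot(inherits(config, "analysis_config"))
  ld <- if (inherits(config$ld, "ld_matrix")) config$ld else read_ld_matrix(config$ld)
  outcomes <- lapply(config$outcomes, function(o) {
    as_dataset_input(o$data, trait_name = o$name,
                     trait_type = o$trait_type %||% "binary")
  })
  primary <- NULL; sensitivity <- NULL; strength <- NULL
  for (ex in config$exposures) {
    exd <- as_dataset_input(ex$data, trait_name = ex$name,
                            trait_type = ex$trait_type %||% "quantitative")
    inst <- tryCatch(
      select_instruments(exd, ld,
                         p_threshold = ex$p_threshold %||% 5e-8,
                         r2_threshold = ex$r2_threshold %||% 0.1,
                         region = ex$region),
      error = function(e) e)
    if (inherits(inst, "error")) {
      primary <- rbind(primary, data.frame(
        exposure = ex$name, outcome = vapply(config$outcomes, `[[`, "", "name"),
        method = NA_character_, beta = NA_real_, se = NA_real_,
        pvalue = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
        k = 0L, cochran_Q = NA_real_,
        status = paste("selection failed:", conditionMessage(inst)),
        stringsAsFactors = FALSE))
      next
    }
    st <- combined_strength(inst)
    strength <- rbind(strength, data.frame(
      exposure = ex$name, k = st$k, n = st$n, combined_r2 = st$combined_r2,
      combined_F = st$combined_F, weak = st$weak, stringsAsFactors = FALSE))
    for (j in seq_along(outcomes)) {
      oname <- config$outcomes[[j]]$name
      cell <- tryCatch({
        h <- harmonize(inst, outcomes[[j]],
                       palindromic_eaf_window = config$palindromic_eaf_window,
                       allow_strand_flip = config$allow_strand_flip)
        r <- retained_instruments(h)
        prim <- if (nrow(r) == 1) wald_ratio(h) else ivw(h, config$variance_model)
        egger <- mr_egger(h)
        wm <- weighted_median(h, n_boot = config$n_boot,
                              seed = stage_seed(config$seed, j))
        list(prim = prim, egger = egger, wm = wm)
      }, error = function(e) e)
      if (inherits(cell, "error")) {
        primary <- rbind(primary, data.frame(
          exposure = ex$name, outcome = oname, method = NA_character_,
          beta = NA_real_, se = NA_real_, pvalue = NA_real_,
          ci_low = NA_real_, ci_high = NA_real_, k = 0L, cochran_Q = NA_real_,
          status = paste("failed:", conditionMessage(cell)),
          stringsAsFactors = FALSE))
        next
      }
      primary <- rbind(primary, estimate_row(ex$name, oname, cell$prim))
      sensitivity <- rbind(sensitivity,
                           estimate_row(ex$name, oname, cell$egger$slope),
                           estimate_row(ex$name, oname, cell$egger$intercept),
                           estimate_row(ex$name, oname, cell$wm))
    }
  }
  rownames(primary) <- NULL
  if (!is.null(sensitivity)) rownames(sensitivity) <- NULL

  ok <- primary$status == "ok" & !is.na(primary$pvalue)
  primary$p_adj <- NA_real_
  if (any(ok)) {
    if (config$fdr_family == "global") {
      primary$p_adj[ok] <- bh_adjust(primary$pvalue[ok])
    } else {
      for (exname in unique(primary$exposure)) {
        idx <- ok & primary$exposure == exname
        if (any(idx)) primary$p_adj[idx] <- bh_adjust(primary$pvalue[idx])
      }
    }
  }
  primary$fdr_significant <- !is.na(primary$p_adj) & primary$p_adj < config$fdr_alpha
  dirsign <- if (config$report_lowering) -1 else 1
  primary$or <- exp(dirsign * primary$beta)
  primary$or_low <- exp(dirsign * primary$beta - 1.96 * primary$se)
  primary$or_high <- exp(dirsign * primary$beta + 1.96 * primary$se)
  swap <- !is.na(primary$or_low) & primary$or_low > primary$or_high
  if (any(swap)) {
    tmp <- primary$or_low[swap]
    primary$or_low[swap] <- primary$or_high[swap]
    primary$or_high[swap] <- tmp
  }
  primary$weak_instruments <- strength$weak[match(primary$exposure, strength$exposure)]
  structure(list(primary = primary, sensitivity = sensitivity,
                 strength = strength, config = config),
            class = "analysis_report")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.analysis_report <- function(x, ...) {
  cat(sprintf("<analysis_report> %d exposure(s) x %d outcome(s)\n",
              length(unique(x$primary$exposure)),
              length(unique(x$primary$outcome))))
  cat(sprintf("  %d cells ok, %d FDR-significant (alpha = %g)\n",
              sum(x$primary$status == "ok"), sum(x$primary$fdr_significant),
              x$config$fdr_alpha))
  invisible(x)
}

#' Write an analysis report to disk
#'
#' Emits `report.tsv` (primary estimates with OR scale and FDR-adjusted
#' p-values), `sensitivity.tsv`, `strength.tsv`, and a machine-readable
#' `report.json` into `dir`.
#'
#' @param report an `analysis_report` from [run_analysis()].
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "analysis_report"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.table(report$primary, file.path(dir, "report.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(report$sensitivity)) {
    utils::write.table(report$sensitivity, file.path(dir, "sensitivity.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  utils::write.table(report$strength, file.path(dir, "strength.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(primary = report$primary,
                            sensitivity = report$sensitivity,
                            strength = report$strength),
                       file.path(dir, "report.json"),
                       dataframe = "rows", na = "null", auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}
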