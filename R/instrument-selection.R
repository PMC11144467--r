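#' Pairwise LD correlation matrix
#'
#' Square matrix of pairwise correlations `r` (not r-squared) between
#' variants, with unit diagonal; the selection step prunes on `r^2`.
#'
#' @param variant_ids character vector naming rows/columns.
#' @param r numeric square matrix of correlations in `[-1, 1]`.
#' @return An object of class `ld_matrix`.
#' @export
ld_matrix <- function(variant_ids, r) {
  r <- as.matrix(r)
  variant_ids <- as.character(variant_ids)
  if (nrow(r) != ncol(r) || nrow(r) != length(variant_ids)) {
    stop("r must be square with one row per variant_id")
  }
  if (max(abs(r - t(r))) > 1e-8) stop("r must be symmetric")
  if (max(abs(diag(r) - 1)) > 1e-8) stop("r must have unit diagonal")
  if (any(abs(r) > 1 + 1e-8)) stop("correlations must lie in [-1, 1]")
  dimnames(r) <- list(variant_ids, variant_ids)
  structure(list(variant_ids = variant_ids, r = r), class = "ld_matrix")
}

#' @export
print.ld_matrix <- function(x, ...) {
  cat(sprintf("<ld_matrix> %d variants\n", length(x$variant_ids)))
  invisible(x)
}

#' Read / write an LD matrix as TSV
#'
#' Format: a header row of variant identifiers followed by the square
#' numeric correlation body, tab-separated.
#'
#' @param path file path.
#' @return [read_ld_matrix()] returns an `ld_matrix`;
#'   [write_ld_matrix()] returns `path` invisibly.
#' @export
read_ld_matrix <- function(path) {
  m <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE)
  ld_matrix(colnames(m), as.matrix(m))
}

#' @rdname read_ld_matrix
#' @param ld an `ld_matrix`.
#' @export
write_ld_matrix <- function(ld, path) {
  stopifnot(inherits(ld, "ld_matrix"))
  utils::write.table(ld$r, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Select uncorrelated genome-wide-significant instruments
#'
#' Standard greedy clumping on summary statistics: candidates are variants
#' with `pvalue < p_threshold` (strict), optionally restricted to the
#' flanked window of a cis [gene_region()]. Candidates are processed in
#' order of ascending p-value (ties broken by ascending `variant_id`); a
#' candidate is kept iff its squared correlation with every already-kept
#' variant is below `r2_threshold`. Candidates absent from `ld` are
#' excluded with a warning rather than assumed independent.
#'
#' @param dataset a [summary_dataset()].
#' @param p_threshold significance threshold, default `5e-8`.
#' @param ld an [ld_matrix()] covering the candidates.
#' @param r2_threshold LD pruning threshold on r-squared, default `0.1`.
#' @param region optional [gene_region()] restricting candidates to a cis
#'   window.
#' @return A [summary_dataset()] containing the selected instruments in the
#'   input dataset's row order.
#' @export
select_instruments <- function(dataset, ld, p_threshold = 5e-8,
                               r2_threshold = 0.1, region = NULL) {
  stopifnot(inherits(dataset, "summary_dataset"), inherits(ld, "ld_matrix"))
  rec <- dataset$records
  cand <- rep(TRUE, nrow(rec))
  if (!is.null(region)) cand <- cand & in_region(region, rec$chrom, rec$pos)
  cand <- cand & rec$pvalue < p_threshold
  in_ld <- rec$variant_id %in% ld$variant_ids
  if (any(cand & !in_ld)) {
    warning(sum(cand & !in_ld),
            " significant candidate(s) absent from the LD matrix; excluded")
  }
  cand <- cand & in_ld
  if (!any(cand)) stop("no instruments pass the selection thresholds")

  cc <- rec[cand, , drop = FALSE]
  ord <- order(cc$pvalue, cc$variant_id)
  cc <- cc[ord, , drop = FALSE]
  kept <- character(0)
  for (i in seq_len(nrow(cc))) {
    vid <- cc$variant_id[i]
    if (length(kept) == 0 ||
        all(ld$r[vid, kept]^2 < r2_threshold)) {
      kept <- c(kept, vid)
    }
  }
  sel <- rec[rec$variant_id %in% kept, , drop = FALSE]
  summary_dataset(sel, trait_name = dataset$trait_name,
                  trait_type = dataset$trait_type,
                  n_total = dataset$n_total, n_cases = dataset$n_cases)
}

#' Per-SNP instrument strength
#'
#' For one variant with effect `beta`, standard error `se` and sample size
#' `n`: `F = (beta/se)^2` and the variance explained
#' `r2 = F / (n - 2 + F)`.
#'
#' @param beta,se,n vectors of effect sizes, standard errors (`> 0`) and
#'   sample sizes (`> 2`); recycled to a common length.
#' @return data.frame with columns `F` and `r2`.
#' @export
snp_strength <- function(beta, se, n) {
  if (any(se <= 0)) stop("se must be > 0")
  if (any(n <= 2)) stop("n must exceed 2")
  f <- (beta / se)^2
  data.frame(F = f, r2 = f / (n - 2 + f))
}

#' Combined instrument strength for a set of instruments
#'
#' Aggregates per-SNP strength into the usual diagnostics: combined
#' `R^2` is the sum of per-SNP variance explained, and the combined
#' F-statistic is `((n - k - 1) / k) * R^2 / (1 - R^2)` with `n` the
#' study sample size (the dataset's `n_total`) and `k` the number of
#' instruments. Instruments with combined `F < 10` are flagged weak by
#' the usual rule of thumb.
#'
#' @param instruments a [summary_dataset()] of selected instruments
#'   (`k >= 1`).
#' @return An object of class `instrument_strength`: list with `per_snp`
#'   (data.frame `variant_id`, `F`, `r2`), `combined_r2`, `combined_F`,
#'   `n`, `k`, and logical `weak` (`combined_F < 10`).
#' @export
combined_strength <- function(instruments) {
  stopifnot(inherits(instruments, "summary_dataset"))
  rec <- instruments$records
  k <- nrow(rec)
  if (k < 1) stop("need at least one instrument")
  n <- instruments$n_total
  per <- snp_strength(rec$beta, rec$se, rec$n)
  r2 <- sum(per$r2)
  if (r2 >= 1) stop("combined R^2 >= 1: inconsistent inputs")
  f <- ((n - k - 1) / k) * r2 / (1 - r2)
  structure(list(per_snp = cbind(variant_id = rec$variant_id, per),
                 combined_r2 = r2, combined_F = f, n = n, k = k,
                 weak = f < 10),
            class = "instrument_strength")
}

#' @export
print.instrument_strength <- function(x, ...) {
  cat(sprintf("<instrument_strength> k = %d, n = %s, R2 = %.4g, F = %.2f%s\n",
              x$k, format(x$n, big.mark = ","), x$combined_r2, x$combined_F,
              if (x$weak) " [WEAK: F < 10]" else ""))
  invisible(x)
}
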