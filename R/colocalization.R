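#' Priors for Bayesian colocalization
#'
#' `p1` / `p2` are the prior probabilities that any one variant in the
#' region is causal for trait 1 / trait 2; `p12` that it is causal for
#' both. `W1` / `W2` are the prior variances of the (non-zero) effect per
#' trait; the defaults correspond to prior effect SDs of 0.15 for a
#' quantitative trait and 0.20 on the log-odds scale for a binary trait —
#' the canonical defaults of the approximate-Bayes-factor method.
#'
#' @param p1,p2,p12 per-variant prior probabilities, `0 < p12 <= p1, p2 < 1`.
#' @param W1,W2 prior effect variances (`> 0`).
#' @return list of class `coloc_priors`.
#' @export
coloc_priors <- function(p1 = 1e-4, p2 = 1e-4, p12 = 1e-5,
                         W1 = 0.15^2, W2 = 0.20^2) {
  if (!(p12 > 0 && p12 <= p1 && p12 <= p2 && p1 < 1 && p2 < 1)) {
    stop("require 0 < p12 <= p1, p2 < 1")
  }
  if (W1 <= 0 || W2 <= 0) stop("prior variances must be positive")
  structure(list(p1 = p1, p2 = p2, p12 = p12, W1 = W1, W2 = W2),
            class = "coloc_priors")
}

#' Per-variant log approximate Bayes factor
#'
#' Wakefield's asymptotic Bayes factor for a single association: with
#' `V = se^2`, `z = beta/se` and prior effect variance `W`,
#' `log ABF = 0.5 * log(V / (V + W)) + 0.5 * z^2 * W / (V + W)`,
#' comparing the alternative (effect ~ N(0, W)) against the null of no
#' effect. Vectorized over variants.
#'
#' @param beta,se effect estimates and standard errors (`se > 0`).
#' @param W prior effect variance (`> 0`).
#' @return log Bayes factor(s).
#' @export
log_abf <- function(beta, se, W) {
  if (any(se <= 0)) stop("se must be > 0")
  if (W <= 0) stop("W must be > 0")
  V <- se^2
  z2 <- (beta / se)^2
  0.5 * log(V / (V + W)) + 0.5 * z2 * W / (V + W)
}

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Bayesian colocalization of two regional association signals
#'
#' Enumerates the five single-causal-variant configurations for a region
#' shared by two traits: H0 no association with either trait, H1/H2
#' association with one trait only, H3 two distinct causal variants, H4 one
#' shared causal variant. Per-variant evidence is Wakefield's approximate
#' Bayes factor ([log_abf()]); configuration sums are accumulated in log
#' space (log-sum-exp) so genome-wide-significant z-scores do not overflow.
#' Variants are matched across traits by `variant_id` only — the ABF
#' depends on `z^2`, so allele orientation does not matter.
#'
#' @param region_exp,region_out [summary_dataset()] objects restricted to
#'   one region (trait 1 and trait 2); at least one shared variant.
#' @param priors a [coloc_priors()].
#' @return list of class `coloc_result`: `pp_h0` ... `pp_h4` (posterior
#'   probabilities summing to 1), `labf1`, `labf2` (per-variant log ABFs,
#'   named by variant), `n_variants`, `priors`.
#' @export
colocalize <- function(region_exp, region_out, priors = coloc_priors()) {
  stopifnot(inherits(region_exp, "summary_dataset"),
            inherits(region_out, "summary_dataset"),
            inherits(priors, "coloc_priors"))
  e <- region_exp$records
  o <- region_out$records
  shared <- intersect(e$variant_id, o$variant_id)
  if (length(shared) == 0) stop("no shared variants in region")
  e <- e[match(shared, e$variant_id), ]
  o <- o[match(shared, o$variant_id), ]
  b1 <- log_abf(e$beta, e$se, priors$W1)
  b2 <- log_abf(o$beta, o$se, priors$W2)
  names(b1) <- names(b2) <- shared

  l1 <- logsumexp(b1)           # log sum_j ABF1_j
  l2 <- logsumexp(b2)
  l12 <- logsumexp(b1 + b2)     # log sum_j ABF1_j * ABF2_j
  logS <- c(h0 = 0,
            h1 = log(priors$p1) + l1,
            h2 = log(priors$p2) + l2,
            h3 = NA_real_,
            h4 = log(priors$p12) + l12)
  # S3 = p1 p2 (sum1 * sum2 - sum12); guard the subtraction in log space
  cross <- l1 + l2
  if (length(shared) == 1 || l12 >= cross) {
    if (length(shared) > 1 && l12 > cross + 1e-9) {
      warning("H3 sum negative by rounding; clamped to 0")
    }
    logS["h3"] <- -Inf
  } else {
    logS["h3"] <- log(priors$p1) + log(priors$p2) + cross +
      log1p(-exp(l12 - cross))
  }
  denom <- logsumexp(logS)
  pp <- exp(logS - denom)
  structure(list(pp_h0 = pp[["h0"]], pp_h1 = pp[["h1"]], pp_h2 = pp[["h2"]],
                 pp_h3 = pp[["h3"]], pp_h4 = pp[["h4"]],
                 labf1 = b1, labf2 = b2,
                 n_variants = length(shared), priors = priors),
            class = "coloc_result")
}

#' @export
print.coloc_result <- function(x, ...) {
  cat(sprintf("<coloc_result> %d variants\n", x$n_variants))
  pp <- c(x$pp_h0, x$pp_h1, x$pp_h2, x$pp_h3, x$pp_h4)
  cat(sprintf("  PP(H%d) = %6.2f%%\n", 0:4, 100 * pp), sep = "")
  invisible(x)
}
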