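new_mr_estimate <- function(method, beta, se, k, df = Inf, cochran_Q = NA_real_) {
  crit <- if (is.finite(df)) stats::qt(0.975, df) else stats::qnorm(0.975)
  p <- wald_pvalue(beta, se, df = df)
  structure(list(method = method, beta = beta, se = se, pvalue = p,
                 ci_low = beta - crit * se, ci_high = beta + crit * se,
                 k = k, cochran_Q = cochran_Q, df_used = df),
            class = "mr_estimate")
}

mr_unavailable <- function(method, reason) {
  structure(list(method = method, reason = reason),
            class = c("mr_unavailable", "mr_estimate"))
}

#' @export
print.mr_estimate <- function(x, ...) {
  if (inherits(x, "mr_unavailable")) {
    cat(sprintf("<mr_estimate> %s: unavailable (%s)\n", x$method, x$reason))
    return(invisible(x))
  }
  cat(sprintf("<mr_estimate> %s: beta = %.4f (SE %.4f), 95%% CI [%.4f, %.4f], p = %.3g, k = %d\n",
              x$method, x$beta, x$se, x$ci_low, x$ci_high, x$pvalue, x$k))
  invisible(x)
}

#' Is a sensitivity estimate available?
#' @param x an `mr_estimate`.
#' @return `FALSE` when the estimator declined to run (e.g. fewer than 3
#'   instruments), `TRUE` otherwise.
#' @export
is_unavailable <- function(x) inherits(x, "mr_unavailable")

#' Two-sided Wald p-value
#'
#' `p = 2 * (1 - CDF(|beta/se|))` under a standard normal (default) or a
#' t reference with `df` degrees of freedom.
#'
#' @param beta,se estimate and standard error (`se > 0`); vectorized.
#' @param df degrees of freedom of the t reference; `Inf` (default) gives
#'   the normal reference.
#' @return two-sided p-value(s) in (0, 1].
#' @export
wald_pvalue <- function(beta, se, df = Inf) {
  if (any(se <= 0)) stop("se must be > 0")
  z <- abs(beta / se)
  if (is.finite(df)) 2 * stats::pt(z, df, lower.tail = FALSE)
  else 2 * stats::pnorm(z, lower.tail = FALSE)
}

as_instrument_frame <- function(instruments) {
  if (inherits(instruments, "harmonized_instruments")) {
    instruments <- retained_instruments(instruments)
  }
  need <- c("beta_exp", "se_exp", "beta_out", "se_out")
  stopifnot(all(need %in% names(instruments)))
  as.data.frame(instruments)
}

#' Wald ratio estimate from a single instrument
#'
#' `beta = beta_out / beta_exp` with the first-order standard error
#' `se_out / |beta_exp|`; normal inference.
#'
#' @param instruments harmonized instruments containing exactly one
#'   retained variant (or a one-row data.frame with `beta_exp`, `se_exp`,
#'   `beta_out`, `se_out`).
#' @return An `mr_estimate` with method `"wald"`.
#' @export
wald_ratio <- function(instruments) {
  d <- as_instrument_frame(instruments)
  if (nrow(d) != 1) stop("wald_ratio requires exactly one instrument")
  if (d$beta_exp == 0) stop("degenerate instrument: beta_exp = 0")
  new_mr_estimate("wald", beta = d$beta_out / d$beta_exp,
                  se = d$se_out / abs(d$beta_exp), k = 1L, cochran_Q = 0)
}

#' Inverse-variance weighted causal estimate
#'
#' The primary two-sample MR estimator: the weighted-least-squares slope of
#' outcome effects on exposure effects through the origin, with weights
#' `1 / se_out^2`. The fixed-effect standard error is
#' `(sum(beta_exp^2 / se_out^2))^(-1/2)`; under the default multiplicative
#' random-effects model it is inflated by `max(1, sqrt(Q / (k - 1)))` where
#' `Q` is Cochran's heterogeneity statistic. Inference is normal.
#'
#' @param instruments harmonized instruments (`k >= 1` retained).
#' @param variance_model `"multiplicative_random"` (default) or `"fixed"`.
#'   With a single instrument the two coincide.
#' @return An `mr_estimate` with method `"ivw"` and `cochran_Q` filled in.
#' @export
ivw <- function(instruments, variance_model = c("multiplicative_random", "fixed")) {
  variance_model <- match.arg(variance_model)
  d <- as_instrument_frame(instruments)
  k <- nrow(d)
  if (k < 1) stop("no instruments")
  w <- 1 / d$se_out^2
  denom <- sum(d$beta_exp^2 * w)
  beta <- sum(d$beta_exp * d$beta_out * w) / denom
  se <- sqrt(1 / denom)
  q <- sum((d$beta_out - beta * d$beta_exp)^2 * w)
  if (variance_model == "multiplicative_random" && k > 1) {
    se <- se * max(1, sqrt(q / (k - 1)))
  }
  new_mr_estimate("ivw", beta = beta, se = se, k = k, cochran_Q = q)
}

#' MR-Egger regression
#'
#' Weighted linear regression of outcome effects on exposure effects with a
#' free intercept and weights `1 / se_out^2`, after orienting every
#' instrument so that `beta_exp >= 0` (negating both members of a pair
#' leaves the causal slope unchanged but makes the intercept identifiable).
#' The intercept estimates the average directional pleiotropy; its p-value
#' is the directional-pleiotropy test. Standard errors use the
#' multiplicative random-effects convention (residual dispersion floored at
#' 1) and inference is t with `k - 2` degrees of freedom.
#'
#' @param instruments harmonized instruments; requires `k >= 3` retained,
#'   otherwise an unavailable marker is returned (see [is_unavailable()]).
#' @return list with elements `slope` and `intercept`, each an
#'   `mr_estimate` (methods `"egger_slope"`, `"egger_intercept"`).
#' @export
mr_egger <- function(instruments) {
  d <- as_instrument_frame(instruments)
  k <- nrow(d)
  if (k < 3) {
    return(list(slope = mr_unavailable("egger_slope", "<3 SNPs available"),
                intercept = mr_unavailable("egger_intercept", "<3 SNPs available")))
  }
  flip <- d$beta_exp < 0
  bx <- ifelse(flip, -d$beta_exp, d$beta_exp)
  by <- ifelse(flip, -d$beta_out, d$beta_out)
  if (stats::var(bx) == 0) stop("degenerate exposure effects: all beta_exp equal")
  w <- 1 / d$se_out^2
  sw <- sum(w); swx <- sum(w * bx); swx2 <- sum(w * bx^2)
  det <- sw * swx2 - swx^2
  slope <- (sw * sum(w * bx * by) - swx * sum(w * by)) / det
  inter <- (swx2 * sum(w * by) - swx * sum(w * bx * by)) / det
  resid <- by - inter - slope * bx
  sigma2 <- sum(w * resid^2) / (k - 2)
  infl <- max(1, sigma2)
  se_slope <- sqrt(infl * sw / det)
  se_inter <- sqrt(infl * swx2 / det)
  q <- sum(w * resid^2)
  list(slope = new_mr_estimate("egger_slope", slope, se_slope, k, df = k - 2,
                               cochran_Q = q),
       intercept = new_mr_estimate("egger_intercept", inter, se_inter, k,
                                   df = k - 2, cochran_Q = q))
}

# point estimate only; used by weighted_median() and its bootstrap
weighted_median_point <- function(bx, by, sey) {
  ratio <- by / bx
  w <- bx^2 / sey^2
  w <- w / sum(w)
  ord <- order(ratio)
  ratio <- ratio[ord]; w <- w[ord]
  s <- cumsum(w) - w / 2
  if (s[1] >= 0.5) return(ratio[1])
  if (s[length(s)] <= 0.5) return(ratio[length(s)])
  hi <- which(s >= 0.5)[1]
  lo <- hi - 1
  ratio[lo] + (ratio[hi] - ratio[lo]) * (0.5 - s[lo]) / (s[hi] - s[lo])
}

#' Weighted-median causal estimate
#'
#' The weighted median of the per-instrument Wald ratios, with weights
#' proportional to `beta_exp^2 / se_out^2` (inverse variance of each
#' ratio, first order). Consistent when at least half of the total weight
#' comes from valid instruments. The estimate interpolates linearly between
#' the two order statistics whose cumulative midpoint weights bracket 0.5.
#' The standard error comes from a parametric bootstrap: both exposure and
#' outcome effects are redrawn from `N(beta, se)` and the weighted median
#' recomputed; normal inference on the result.
#'
#' @param instruments harmonized instruments; requires `k >= 3` retained.
#' @param n_boot bootstrap replicates (default 1000). `n_boot = 0` skips
#'   the bootstrap and returns `NA` standard error and p-value (useful in
#'   simulation loops that only need the point estimate).
#' @param seed integer seed for the bootstrap stream (default 2024).
#' @return An `mr_estimate` with method `"weighted_median"`, or an
#'   unavailable marker when `k < 3`.
#' @export
weighted_median <- function(instruments, n_boot = 1000, seed = 2024) {
  d <- as_instrument_frame(instruments)
  k <- nrow(d)
  if (k < 3) return(mr_unavailable("weighted_median", "<3 SNPs available"))
  if (any(d$beta_exp == 0)) stop("degenerate instrument: beta_exp = 0")
  est <- weighted_median_point(d$beta_exp, d$beta_out, d$se_out)
  if (n_boot == 0) {
    res <- new_mr_estimate("weighted_median", est, se = 1, k = k)
    res$se <- NA_real_; res$pvalue <- NA_real_
    res$ci_low <- NA_real_; res$ci_high <- NA_real_
    return(res)
  }
  boots <- withr_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      bx <- stats::rnorm(k, d$beta_exp, d$se_exp)
      by <- stats::rnorm(k, d$beta_out, d$se_out)
      weighted_median_point(bx, by, d$se_out)
    }, numeric(1))
  })
  se <- stats::sd(boots)
  if (se == 0) se <- .Machine$double.eps
  new_mr_estimate("weighted_median", est, se, k = k)
}

# evaluate expr under a local RNG seed without disturbing the caller's stream
withr_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Convert a log-odds MR estimate to an odds ratio
#'
#' Exponentiates a log-odds-scale estimate into an odds ratio with a 95%
#' confidence interval computed as `exp(beta +/- 1.96 * se)`. With
#' `report_lowering = TRUE` the sign of beta is flipped first, so the OR is
#' expressed per 1 unit (or 1 SD) *lower* genetically predicted exposure —
#' the reporting convention for a lipid-lowering drug target.
#'
#' @param estimate an `mr_estimate` on the log-odds scale.
#' @param report_lowering flip the direction of effect (default `TRUE`).
#' @return list of class `or_result`: `or_point`, `or_low`, `or_high`,
#'   `pvalue` (carried over), `direction`.
#' @export
to_odds_ratio <- function(estimate, report_lowering = TRUE) {
  stopifnot(inherits(estimate, "mr_estimate"), !is_unavailable(estimate))
  b <- if (report_lowering) -estimate$beta else estimate$beta
  structure(list(or_point = exp(b),
                 or_low = exp(b - 1.96 * estimate$se),
                 or_high = exp(b + 1.96 * estimate$se),
                 pvalue = estimate$pvalue,
                 direction = if (report_lowering) "per-unit-lower" else "per-unit-higher"),
            class = "or_result")
}

#' @export
print.or_result <- function(x, ...) {
  cat(sprintf("<or_result> OR %.2f (95%% CI %.2f-%.2f), p = %.3g [%s]\n",
              x$or_point, x$or_low, x$or_high, x$pvalue, x$direction))
  invisible(x)
}

#' P-value implied by an odds ratio and its 95% confidence interval
#'
#' Recovers the log-scale standard error from a symmetric-on-log-scale 95%
#' CI, `se = (log(or_high) - log(or_low)) / (2 * 1.96)`, and returns the
#' two-sided normal p-value of `log(or) / se`. Useful for auditing
#' published OR/CI/p rows.
#'
#' @param or,or_low,or_high odds ratio and 95% CI bounds (all `> 0`);
#'   vectorized.
#' @return two-sided p-value(s).
#' @export
or_implied_pvalue <- function(or, or_low, or_high) {
  if (any(c(or, or_low, or_high) <= 0)) stop("odds ratios must be positive")
  se <- (log(or_high) - log(or_low)) / (2 * stats::qnorm(0.975))
  wald_pvalue(log(or), se)
}
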