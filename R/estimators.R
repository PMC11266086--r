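.mr_row <- function(method, nsnp, beta, se, pval = NULL) {
  tibble::tibble(
    method = method,
    nsnp = as.integer(nsnp),
    beta = beta,
    se = se,
    ci_low = beta - 1.96 * se,
    ci_high = beta + 1.96 * se,
    # floor at the smallest positive double so extreme z never underflows to 0
    pval = pmax(if (is.null(pval)) 2 * stats::pnorm(-abs(beta / se)) else pval,
                .Machine$double.xmin)
  )
}

.mr_data <- function(data, min_snp = 1, what = "MR estimation") {
  data <- harmonized_kept(data)
  if (nrow(data) < min_snp) {
    stop(sprintf("%s requires at least %d SNP(s), got %d",
                 what, min_snp, nrow(data)), call. = FALSE)
  }
  data
}

#' Per-SNP Wald ratio estimate
#'
#' The single-SNP causal estimate `Gamma / gamma` with first-order standard
#' error `|se_Gamma / gamma|`. The second-order variant additionally
#' propagates the exposure-side uncertainty,
#' `sqrt(se_Gamma^2 / gamma^2 + Gamma^2 se_gamma^2 / gamma^4)`, and is never
#' smaller than the first-order SE.
#'
#' @param gamma,se_gamma SNP-exposure effect and its SE; `gamma` must be
#'   nonzero.
#' @param Gamma,se_Gamma SNP-outcome effect and its SE.
#' @param second_order Use the second-order SE.
#' @return One-row estimate tibble (method `"Wald"`).
#' @export
wald_ratio <- function(gamma, se_gamma, Gamma, se_Gamma, second_order = FALSE) {
  if (any(gamma == 0)) stop("Wald ratio undefined for gamma = 0", call. = FALSE)
  beta <- Gamma / gamma
  se <- if (second_order) {
    sqrt(se_Gamma^2 / gamma^2 + Gamma^2 * se_gamma^2 / gamma^4)
  } else {
    abs(se_Gamma / gamma)
  }
  .mr_row("Wald", length(gamma), beta, se)
}

.ivw_beta <- function(g, G, s) {
  w <- 1 / s^2
  sum(w * g * G) / sum(w * g^2)
}

.q_statistic <- function(g, G, s, beta) {
  w <- g^2 / s^2
  ratios <- G / g
  sum(w * (ratios - beta)^2)
}

#' Inverse-variance-weighted causal estimate
#'
#' Combines per-SNP Wald ratios with inverse-variance weights; equivalently,
#' weighted regression of the outcome effects on the exposure effects
#' through the origin with weights `1 / se_outcome^2`. The fixed-effect SE
#' is `sqrt(1 / sum(gamma^2 / se_outcome^2))`; the multiplicative
#' random-effects (MRE) SE inflates it by `sqrt(max(1, Q / (k - 1)))`, so it
#' never shrinks below the fixed SE. `mode = "auto"` applies the
#' heterogeneity rule: MRE when the Cochran Q p-value is below 0.05, fixed
#' otherwise. A single SNP degenerates to the Wald ratio.
#'
#' @param data Harmonized dataset (only `keep` rows are used).
#' @param mode `"fixed"`, `"mre"`, or `"auto"`.
#' @return One-row estimate tibble, method `"IVW-fixed"` or `"IVW-MRE"`,
#'   with attributes `q_stat`, `q_df`, `q_pval`.
#' @export
mr_ivw <- function(data, mode = c("auto", "fixed", "mre")) {
  mode <- match.arg(mode)
  data <- .mr_data(data, 1, "IVW")
  g <- data$beta_exposure; G <- data$beta_outcome; s <- data$se_outcome
  k <- length(g)
  beta <- .ivw_beta(g, G, s)
  se_fixed <- sqrt(1 / sum(g^2 / s^2))
  if (k == 1) {
    out <- .mr_row("IVW-fixed", 1, beta, se_fixed)
    attr(out, "q_stat") <- NA_real_; attr(out, "q_df") <- 0L
    attr(out, "q_pval") <- NA_real_
    return(out)
  }
  q <- .q_statistic(g, G, s, beta)
  q_pval <- stats::pchisq(q, k - 1, lower.tail = FALSE)
  use_mre <- switch(mode, fixed = FALSE, mre = TRUE, auto = q_pval < 0.05)
  se <- if (use_mre) se_fixed * sqrt(max(1, q / (k - 1))) else se_fixed
  out <- .mr_row(if (use_mre) "IVW-MRE" else "IVW-fixed", k, beta, se)
  attr(out, "q_stat") <- q
  attr(out, "q_df") <- k - 1L
  attr(out, "q_pval") <- q_pval
  out
}

#' MR-Egger regression
#'
#' Weighted linear regression of outcome effects on exposure effects with an
#' intercept, after orienting each SNP so its exposure effect is
#' non-negative. The slope is the causal estimate (consistent under the
#' InSIDE assumption); a nonzero intercept indicates directional horizontal
#' pleiotropy. Coefficient SEs from the weighted fit are scaled by
#' `max(1, sqrt(RSS / (k - 2)))` so they never fall below the
#' unit-dispersion SEs.
#'
#' @param data Harmonized dataset with at least 3 kept SNPs.
#' @param p_reference `"normal"` (default) or `"t"` reference distribution
#'   for the coefficient p-values.
#' @return Two-row estimate tibble: methods `"Egger-slope"` and
#'   `"Egger-intercept"`.
#' @export
mr_egger <- function(data, p_reference = c("normal", "t")) {
  p_reference <- match.arg(p_reference)
  data <- .mr_data(data, 3, "MR-Egger")
  flip <- sign(data$beta_exposure)
  flip[flip == 0] <- 1
  g <- data$beta_exposure * flip
  G <- data$beta_outcome * flip
  w <- 1 / data$se_outcome^2
  k <- length(g)
  fit <- stats::lm(G ~ g, weights = w)
  sm <- summary(fit)
  sigma_hat <- sm$sigma # sqrt(RSS / (k - 2)) on the weighted scale
  scale <- max(1, sigma_hat)
  coefs <- sm$coefficients
  se <- coefs[, "Std. Error"] / sigma_hat * scale
  est <- coefs[, "Estimate"]
  pval <- if (p_reference == "normal") {
    2 * stats::pnorm(-abs(est / se))
  } else {
    2 * stats::pt(-abs(est / se), df = k - 2)
  }
  dplyr::bind_rows(
    .mr_row("Egger-slope", k, est[["g"]], se[["g"]], pval[["g"]]),
    .mr_row("Egger-intercept", k, est[["(Intercept)"]], se[["(Intercept)"]],
            pval[["(Intercept)"]])
  )
}

.weighted_median_point <- function(ratios, weights) {
  ord <- order(ratios)
  b <- ratios[ord]
  w <- weights[ord] / sum(weights)
  s <- cumsum(w) - w / 2
  if (0.5 <= s[1]) return(b[1])
  if (0.5 >= s[length(s)]) return(b[length(b)])
  stats::approx(s, b, xout = 0.5, ties = "ordered")$y
}

#' Weighted median causal estimate
#'
#' Consistent when valid instruments carry at least half of the weight.
#' Per-SNP Wald ratios are sorted; with normalized inverse-variance weights
#' `w_j = gamma_j^2 / se_outcome_j^2`, the estimate is the linear
#' interpolation of the sorted ratios at cumulative weight 1/2 (using the
#' midpoint convention `s_j = sum_{i<=j} w_i - w_j / 2`). The SE is the
#' standard deviation of the estimate over `n_boot` parametric-bootstrap
#' resamples in which both effect sides are perturbed by their Gaussian
#' standard errors.
#'
#' @param data Harmonized dataset with at least 3 kept SNPs.
#' @param n_boot Number of bootstrap resamples for the SE; default 1000.
#' @param seed Optional seed for the bootstrap stream.
#' @return One-row estimate tibble, method `"WeightedMedian"`.
#' @export
mr_weighted_median <- function(data, n_boot = 1000, seed = NULL) {
  data <- .mr_data(data, 3, "weighted median")
  if (!is.null(seed)) set.seed(seed)
  g <- data$beta_exposure; G <- data$beta_outcome
  sg <- data$se_exposure; sG <- data$se_outcome
  k <- length(g)
  point <- .weighted_median_point(G / g, g^2 / sG^2)
  boots <- vapply(seq_len(n_boot), function(i) {
    gb <- stats::rnorm(k, g, sg)
    Gb <- stats::rnorm(k, G, sG)
    ok <- gb != 0
    .weighted_median_point(Gb[ok] / gb[ok], gb[ok]^2 / sG[ok]^2)
  }, numeric(1))
  .mr_row("WeightedMedian", k, point, stats::sd(boots))
}

#' Convert log-odds estimates to odds ratios
#'
#' Exponentiates the causal estimate and its confidence bounds; meaningful
#' for binary outcomes analysed on the log-odds scale.
#'
#' @param est Estimate tibble with `beta`, `ci_low`, `ci_high` columns.
#' @return The tibble with `or`, `or_ci_low`, `or_ci_high` columns added.
#' @examples
#' to_odds_ratio(wald_ratio(0.25, 0.01, 0.5, 0.1))
#' @export
to_odds_ratio <- function(est) {
  dplyr::mutate(est,
                or = exp(.data$beta),
                or_ci_low = exp(.data$ci_low),
                or_ci_high = exp(.data$ci_high))
}

#' Fit all three MR estimators to a harmonized dataset
#'
#' Runs IVW (heterogeneity-selected fixed/MRE by default), MR-Egger and the
#' weighted median on one harmonized dataset and bundles the estimates with
#' the data and settings.
#'
#' @param data Harmonized dataset.
#' @param mode IVW mode, see [mr_ivw()].
#' @param n_boot,seed Weighted-median bootstrap settings.
#' @param exposure,outcome Optional trait labels carried into the estimates.
#' @return An object of class `mr_result`; see [tidy.mr_result()],
#'   [glance.mr_result()], [autoplot.mr_result()].
#' @export
mr_all <- function(data, mode = "auto", n_boot = 1000, seed = NULL,
                   exposure = NA_character_, outcome = NA_character_) {
  kept <- .mr_data(data, 3, "the three-estimator analysis")
  ivw <- mr_ivw(kept, mode = mode)
  estimates <- dplyr::bind_rows(
    ivw,
    mr_egger(kept),
    mr_weighted_median(kept, n_boot = n_boot, seed = seed)
  )
  estimates <- dplyr::mutate(estimates,
                             exposure = exposure, outcome = outcome,
                             .before = 1)
  structure(
    list(
      estimates = estimates,
      data = kept,
      q_stat = attr(ivw, "q_stat"),
      q_df = attr(ivw, "q_df"),
      q_pval = attr(ivw, "q_pval"),
      exposure = exposure,
      outcome = outcome
    ),
    class = "mr_result"
  )
}

#' @export
print.mr_result <- function(x, ...) {
  cat(sprintf("Two-sample MR: %s -> %s (%d SNPs)\n",
              x$exposure, x$outcome, nrow(x$data)))
  print(x$estimates)
  if (!is.na(x$q_pval)) {
    cat(sprintf("Cochran Q = %.3f (df %d, p = %.3g)\n",
                x$q_stat, x$q_df, x$q_pval))
  }
  invisible(x)
}

#' Tidy the estimates of an `mr_result`
#'
#' @param x An `mr_result` from [mr_all()].
#' @param ... Unused.
#' @return The per-method estimate tibble.
#' @export
tidy.mr_result <- function(x, ...) {
  x$estimates
}

#' One-row summary of an `mr_result`
#'
#' @param x An `mr_result` from [mr_all()].
#' @param ... Unused.
#' @return A one-row tibble with the primary (IVW) estimate, the
#'   heterogeneity test and the Egger intercept test.
#' @export
glance.mr_result <- function(x, ...) {
  ivw <- dplyr::filter(x$estimates, startsWith(.data$method, "IVW"))
  intercept <- dplyr::filter(x$estimates, .data$method == "Egger-intercept")
  tibble::tibble(
    exposure = x$exposure, outcome = x$outcome,
    nsnp = ivw$nsnp, ivw_model = ivw$method,
    beta_ivw = ivw$beta, se_ivw = ivw$se, pval_ivw = ivw$pval,
    q_stat = x$q_stat, q_df = x$q_df, q_pval = x$q_pval,
    egger_intercept = intercept$beta, egger_intercept_pval = intercept$pval
  )
}
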