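#' Cochran Q heterogeneity test
#'
#' Heterogeneity of the per-SNP Wald ratios around a pooled estimate:
#' `Q = sum_j w_j (ratio_j - beta)^2` with IVW weights
#' `w_j = gamma_j^2 / se_outcome_j^2`, referred to a chi-square distribution
#' with k - 1 degrees of freedom. Algebraically, Q equals the weighted
#' residual sum of squares of the origin regression at the IVW estimate.
#'
#' @param data Harmonized dataset with at least 2 kept SNPs.
#' @param beta_ivw Pooled estimate around which heterogeneity is measured;
#'   defaults to the IVW estimate of `data`.
#' @return A one-row tibble with `q_stat`, `q_df`, `q_pval`.
#' @export
cochran_q <- function(data, beta_ivw = NULL) {
  data <- .mr_data(data, 2, "the Cochran Q test")
  g <- data$beta_exposure; G <- data$beta_outcome; s <- data$se_outcome
  if (is.null(beta_ivw)) beta_ivw <- .ivw_beta(g, G, s)
  q <- .q_statistic(g, G, s, beta_ivw)
  df <- length(g) - 1L
  tibble::tibble(q_stat = q, q_df = df,
                 q_pval = stats::pchisq(q, df, lower.tail = FALSE))
}

#' MR-Egger intercept test for directional pleiotropy
#'
#' The intercept component of the MR-Egger regression; deviation from zero
#' indicates directional horizontal pleiotropy.
#'
#' @param data Harmonized dataset with at least 3 kept SNPs.
#' @param ... Passed to [mr_egger()].
#' @return A one-row tibble with `intercept`, `se`, `pval`.
#' @export
egger_intercept_test <- function(data, ...) {
  est <- mr_egger(data, ...)
  row <- dplyr::filter(est, .data$method == "Egger-intercept")
  tibble::tibble(intercept = row$beta, se = row$se, pval = row$pval)
}

#' MR-PRESSO global, outlier and distortion tests
#'
#' Residual-sum-of-squares test for horizontal pleiotropy with per-SNP
#' outlier identification. The observed global statistic is
#' `RSS = sum_j (Gamma_j - beta_(-j) gamma_j)^2 / se_outcome_j^2`, where
#' `beta_(-j)` is the IVW estimate with SNP j left out. Its null
#' distribution is built by parametric resampling: outcome effects are
#' redrawn as `Normal(beta_(-j) gamma_j, se_outcome_j^2)` and the statistic
#' recomputed (including the leave-one-out refits) `n_sim` times. Empirical
#' p-values use the (r + 1) / (n_sim + 1) estimator so they are bounded away
#' from zero. Per-SNP outlier p-values compare each SNP's observed RSS term
#' with its own simulated terms and are Bonferroni-adjusted by the SNP
#' count; SNPs below `outlier_alpha` after adjustment are flagged. The
#' distortion test compares the shift in the IVW estimate after removing
#' the flagged outliers with the shifts produced by removing random SNP
#' subsets of the same size.
#'
#' @param data Harmonized dataset with at least 4 kept SNPs.
#' @param n_sim Number of parametric resamples; must be positive.
#' @param outlier_alpha Significance threshold on the adjusted per-SNP
#'   p-values.
#' @param seed Optional seed making the resampling reproducible.
#' @return An object of class `presso_result`: `global_rss`, `global_pval`,
#'   `outlier_pvals` (adjusted, one per SNP), `outlier_indices`,
#'   `outlier_snps`, `distortion_pval` (NA when no outliers are flagged),
#'   `n_sim`, `seed`.
#' @export
mr_presso <- function(data, n_sim = 1000, outlier_alpha = 0.05, seed = NULL) {
  if (n_sim < 1) stop("n_sim must be a positive integer", call. = FALSE)
  data <- .mr_data(data, 4, "MR-PRESSO")
  if (nrow(data) / (n_sim + 1) >= outlier_alpha) {
    warning(sprintf(paste("with %d SNPs and %d resamples the smallest",
                          "Bonferroni-adjusted outlier p-value is %.3f;",
                          "no SNP can be flagged at alpha = %.3g --",
                          "increase n_sim"),
                    nrow(data), n_sim, nrow(data) / (n_sim + 1), outlier_alpha),
            call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  g <- data$beta_exposure; G <- data$beta_outcome; s <- data$se_outcome
  k <- length(g)
  w <- 1 / s^2
  sxx <- sum(w * g^2)
  sxy <- sum(w * g * G)
  beta_loo <- (sxy - w * g * G) / (sxx - w * g^2)
  t_obs <- (G - beta_loo * g)^2 / s^2
  rss_obs <- sum(t_obs)

  mu <- beta_loo * g
  g_sim <- matrix(stats::rnorm(k * n_sim, mean = mu, sd = s), nrow = k)
  sxy_sim <- colSums(w * g * g_sim)
  beta_loo_sim <- (matrix(sxy_sim, nrow = k, ncol = n_sim, byrow = TRUE) -
                     (w * g) * g_sim) / (sxx - w * g^2)
  t_sim <- (g_sim - beta_loo_sim * g)^2 / s^2
  rss_sim <- colSums(t_sim)

  global_pval <- (sum(rss_sim >= rss_obs) + 1) / (n_sim + 1)
  snp_pvals <- (rowSums(t_sim >= t_obs) + 1) / (n_sim + 1)
  adj_pvals <- pmin(1, snp_pvals * k)
  outlier_idx <- which(adj_pvals < outlier_alpha)

  distortion_pval <- NA_real_
  if (length(outlier_idx) > 0 && length(outlier_idx) < k - 1) {
    beta_all <- .ivw_beta(g, G, s)
    beta_clean <- .ivw_beta(g[-outlier_idx], G[-outlier_idx], s[-outlier_idx])
    d_obs <- beta_clean - beta_all
    d_null <- vapply(seq_len(n_sim), function(i) {
      drop <- sample.int(k, length(outlier_idx))
      .ivw_beta(g[-drop], G[-drop], s[-drop]) - beta_all
    }, numeric(1))
    distortion_pval <- (sum(abs(d_null) >= abs(d_obs)) + 1) / (n_sim + 1)
  }

  structure(
    list(
      global_rss = rss_obs,
      global_pval = global_pval,
      outlier_pvals = adj_pvals,
      outlier_indices = outlier_idx,
      outlier_snps = data$snp[outlier_idx],
      distortion_pval = distortion_pval,
      n_sim = n_sim,
      seed = seed
    ),
    class = "presso_result"
  )
}

#' @export
print.presso_result <- function(x, ...) {
  cat(sprintf("MR-PRESSO: global RSS = %.3f, p = %.4g (%d resamples)\n",
              x$global_rss, x$global_pval, x$n_sim))
  if (length(x$outlier_indices) > 0) {
    cat("Outliers:", paste(x$outlier_snps, collapse = ", "),
        sprintf("(distortion p = %.3g)\n", x$distortion_pval))
  } else {
    cat("No outliers flagged\n")
  }
  invisible(x)
}

#' Iterative intercept-triggered outlier removal
#'
#' Implements the pleiotropy clean-up loop: while the MR-Egger intercept
#' test rejects (p < `alpha`), run MR-PRESSO, drop the flagged outliers and
#' repeat. The loop stops when the intercept is no longer significant, when
#' MR-PRESSO flags nothing, when fewer than 4 SNPs remain (warning state),
#' or after `max_rounds` rounds.
#'
#' @param data Harmonized dataset.
#' @param max_rounds Maximum clean-up rounds; default 5.
#' @param alpha Egger-intercept significance threshold triggering a round.
#' @param n_sim,outlier_alpha MR-PRESSO settings.
#' @param seed Optional base seed; round r uses `seed + r - 1`.
#' @return A list with `data` (the cleaned dataset), `log` (one row per
#'   round: intercept p, SNPs removed), `removed_snps`, and `status`
#'   (`"clean"`, `"max_rounds"`, or `"too_few_snps"`).
#' @export
remove_outliers_until_clean <- function(data, max_rounds = 5, alpha = 0.05,
                                        n_sim = 1000, outlier_alpha = 0.05,
                                        seed = NULL) {
  data <- .mr_data(data, 3, "outlier removal")
  log <- tibble::tibble(round = integer(), intercept_pval = numeric(),
                        n_removed = integer(), removed = character())
  removed_all <- character(0)
  status <- "clean"
  for (r in seq_len(max_rounds)) {
    it <- egger_intercept_test(data)
    if (it$pval >= alpha) {
      status <- "clean"
      break
    }
    if (nrow(data) < 4) {
      warning("fewer than 4 SNPs remain; stopping outlier removal",
              call. = FALSE)
      status <- "too_few_snps"
      break
    }
    pr <- mr_presso(data, n_sim = n_sim, outlier_alpha = outlier_alpha,
                    seed = if (is.null(seed)) NULL else seed + r - 1)
    log <- dplyr::bind_rows(log, tibble::tibble(
      round = r, intercept_pval = it$pval,
      n_removed = length(pr$outlier_indices),
      removed = paste(pr$outlier_snps, collapse = ",")
    ))
    if (length(pr$outlier_indices) == 0) {
      status <- "clean"
      break
    }
    removed_all <- c(removed_all, pr$outlier_snps)
    data <- data[-pr$outlier_indices, ]
    if (r == max_rounds) status <- "max_rounds"
    if (nrow(data) < 4) {
      warning("fewer than 4 SNPs remain; stopping outlier removal",
              call. = FALSE)
      status <- "too_few_snps"
      break
    }
  }
  list(data = data, log = log, removed_snps = removed_all, status = status)
}

#' Leave-one-out IVW analysis
#'
#' Repeats the IVW analysis omitting one SNP at a time; a result that
#' changes materially when a single SNP is dropped indicates that SNP
#' drives the estimate.
#'
#' @param data Harmonized dataset with at least 3 kept SNPs.
#' @param mode IVW mode, see [mr_ivw()].
#' @return A tibble with one row per omitted SNP (`snp_omitted`) plus the
#'   estimate columns.
#' @export
leave_one_out <- function(data, mode = "auto") {
  data <- .mr_data(data, 3, "leave-one-out analysis")
  purrr::map_dfr(seq_len(nrow(data)), function(j) {
    est <- mr_ivw(data[-j, ], mode = mode)
    dplyr::mutate(est, snp_omitted = data$snp[j], .before = 1)
  })
}

#' Full sensitivity report for one harmonized dataset
#'
#' Bundles the Cochran Q test, the Egger intercept test, MR-PRESSO and the
#' leave-one-out analysis.
#'
#' @param data Harmonized dataset with at least 4 kept SNPs.
#' @param n_sim,outlier_alpha,seed MR-PRESSO settings.
#' @return An object of class `mr_sensitivity` with elements `q`,
#'   `egger_intercept`, `presso`, `loo`, `nsnp`.
#' @export
sensitivity_report <- function(data, n_sim = 1000, outlier_alpha = 0.05,
                               seed = NULL) {
  data <- .mr_data(data, 4, "the sensitivity report")
  structure(
    list(
      q = cochran_q(data),
      egger_intercept = egger_intercept_test(data),
      presso = mr_presso(data, n_sim = n_sim, outlier_alpha = outlier_alpha,
                         seed = seed),
      loo = leave_one_out(data),
      nsnp = nrow(data)
    ),
    class = "mr_sensitivity"
  )
}

#' Tidy a sensitivity report into one row
#'
#' @param x An `mr_sensitivity` object.
#' @param ... Unused.
#' @return A one-row tibble with the Q test, intercept test, MR-PRESSO
#'   global p and outlier count, and the spread of leave-one-out estimates.
#' @export
tidy.mr_sensitivity <- function(x, ...) {
  tibble::tibble(
    nsnp = x$nsnp,
    q_stat = x$q$q_stat, q_df = x$q$q_df, q_pval = x$q$q_pval,
    egger_intercept = x$egger_intercept$intercept,
    egger_intercept_se = x$egger_intercept$se,
    egger_intercept_pval = x$egger_intercept$pval,
    presso_global_pval = x$presso$global_pval,
    presso_n_outliers = length(x$presso$outlier_indices),
    presso_distortion_pval = x$presso$distortion_pval,
    loo_beta_min = min(x$loo$beta),
    loo_beta_max = max(x$loo$beta)
  )
}

#' @export
print.mr_sensitivity <- function(x, ...) {
  print(tidy.mr_sensitivity(x))
  invisible(x)
}
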