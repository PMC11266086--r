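#' Indirect (mediated) effect with delta-method confidence interval
#'
#' Product-of-coefficients indirect effect `beta_a * beta_b` with the
#' first-order delta-method standard error
#' `sqrt(beta_a^2 se_b^2 + beta_b^2 se_a^2)` and a normal 95% CI. The
#' second-order variant adds the `se_a^2 se_b^2` cross term and is never
#' smaller.
#'
#' @param beta_a,se_a Exposure-to-mediator effect and SE.
#' @param beta_b,se_b Mediator-to-outcome effect and SE.
#' @param second_order Use the second-order delta-method SE.
#' @return A one-row tibble with `indirect`, `se`, `ci_low`, `ci_high`.
#' @examples
#' indirect_effect(0.04, 0.015, 0.663, 0.031)
#' @export
indirect_effect <- function(beta_a, se_a, beta_b, se_b, second_order = FALSE) {
  stopifnot(se_a > 0, se_b > 0)
  indirect <- beta_a * beta_b
  var1 <- beta_a^2 * se_b^2 + beta_b^2 * se_a^2
  se <- if (second_order) sqrt(var1 + se_a^2 * se_b^2) else sqrt(var1)
  tibble::tibble(indirect = indirect, se = se,
                 ci_low = indirect - 1.96 * se,
                 ci_high = indirect + 1.96 * se)
}

#' Sobel test of the mediated effect
#'
#' z-test of the product of coefficients using the first-order delta-method
#' standard error, so z equals the indirect effect divided by its SE and the
#' test is internally consistent with [indirect_effect()].
#'
#' @inheritParams indirect_effect
#' @return A one-row tibble with `z` and `pval` (two-sided normal).
#' @export
sobel_test <- function(beta_a, se_a, beta_b, se_b) {
  stopifnot(se_a > 0, se_b > 0)
  denom <- sqrt(beta_a^2 * se_b^2 + beta_b^2 * se_a^2)
  z <- if (denom == 0) 0 else (beta_a * beta_b) / denom
  tibble::tibble(z = z, pval = 2 * stats::pnorm(-abs(z)))
}

#' Proportion of the total effect that is mediated
#'
#' `proportion = indirect / beta_c`, reported as a percentage, with a
#' delta-method CI for a ratio of independent estimates:
#' `se = |proportion| * sqrt(indirect_se^2 / indirect^2 + se_c^2 / beta_c^2)`.
#' Independence of numerator and denominator reflects a design in which the
#' three pairwise analyses use non-overlapping GWAS samples.
#'
#' @param indirect,indirect_se Indirect effect and its SE.
#' @param beta_c,se_c Total effect and its SE; `beta_c` must be nonzero.
#' @return A one-row tibble with `proportion`, `ci_low`, `ci_high`
#'   (percent).
#' @export
proportion_mediated <- function(indirect, indirect_se, beta_c, se_c) {
  if (beta_c == 0) stop("total effect beta_c must be nonzero", call. = FALSE)
  prop <- indirect / beta_c
  se <- if (indirect == 0) {
    abs(indirect_se / beta_c)
  } else {
    abs(prop) * sqrt(indirect_se^2 / indirect^2 + se_c^2 / beta_c^2)
  }
  tibble::tibble(proportion = 100 * prop,
                 ci_low = 100 * (prop - 1.96 * se),
                 ci_high = 100 * (prop + 1.96 * se))
}

#' Assemble a two-step MR mediation result
#'
#' Combines the three pairwise IVW estimates of a two-step mediation design
#' — total effect (exposure on outcome), `beta_a` (exposure on mediator) and
#' `beta_b` (mediator on outcome) — into the mediation quantities: indirect
#' effect `beta_a * beta_b` with delta-method CI, Sobel p-value, and
#' proportion mediated. When the total effect is not significant at
#' `total_alpha` the proportion is suppressed (reported NA) while the
#' indirect effect is still reported, mirroring the convention for
#' exposures that act on the outcome only through the mediator.
#'
#' @param total Estimate tibble (one row) for the exposure-outcome total
#'   effect.
#' @param step_a Estimate tibble for the exposure-mediator effect.
#' @param step_b Estimate tibble for the mediator-outcome effect.
#' @param total_alpha Significance threshold on the total effect below
#'   which the proportion mediated is reported; default 0.05.
#' @param labels Optional named list/vector with `exposure`, `mediator`,
#'   `outcome` labels.
#' @return A one-row mediation tibble: the three path estimates with SEs
#'   and CIs, `indirect`, `indirect_se`, `indirect_ci_low/high`, `sobel_z`,
#'   `sobel_p`, `proportion`, `proportion_ci_low/high` (percent, NA when
#'   suppressed), and `proportion_suppressed`.
#' @export
two_step_mediation <- function(total, step_a, step_b, total_alpha = 0.05,
                               labels = NULL) {
  for (nm in c("total", "step_a", "step_b")) {
    est <- get(nm, inherits = FALSE)
    if (is.null(est) || !is.data.frame(est) || nrow(est) != 1) {
      stop(sprintf("'%s' must be a one-row estimate tibble", nm), call. = FALSE)
    }
  }
  ind <- indirect_effect(step_a$beta, step_a$se, step_b$beta, step_b$se)
  sob <- sobel_test(step_a$beta, step_a$se, step_b$beta, step_b$se)
  suppress <- total$pval >= total_alpha
  prop <- if (!suppress && total$beta != 0) {
    proportion_mediated(ind$indirect, ind$se, total$beta, total$se)
  } else {
    tibble::tibble(proportion = NA_real_, ci_low = NA_real_, ci_high = NA_real_)
  }
  tibble::tibble(
    exposure = labels[["exposure"]] %||% NA_character_,
    mediator = labels[["mediator"]] %||% NA_character_,
    outcome = labels[["outcome"]] %||% NA_character_,
    beta_c = total$beta, se_c = total$se,
    beta_c_ci_low = total$ci_low, beta_c_ci_high = total$ci_high,
    pval_c = total$pval,
    beta_a = step_a$beta, se_a = step_a$se,
    beta_a_ci_low = step_a$ci_low, beta_a_ci_high = step_a$ci_high,
    beta_b = step_b$beta, se_b = step_b$se,
    beta_b_ci_low = step_b$ci_low, beta_b_ci_high = step_b$ci_high,
    indirect = ind$indirect, indirect_se = ind$se,
    indirect_ci_low = ind$ci_low, indirect_ci_high = ind$ci_high,
    sobel_z = sob$z, sobel_p = sob$pval,
    proportion = prop$proportion,
    proportion_ci_low = prop$ci_low, proportion_ci_high = prop$ci_high,
    proportion_suppressed = suppress
  )
}
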