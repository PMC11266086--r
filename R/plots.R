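#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Scatter plot of a fitted MR analysis
#'
#' Per-SNP exposure effects against outcome effects with error bars and the
#' fitted IVW (through the origin) and MR-Egger lines. SNPs are oriented to
#' non-negative exposure effects, matching the Egger convention.
#'
#' @param object An `mr_result` from [mr_all()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mr_result <- function(object, ...) {
  d <- object$data
  flip <- ifelse(d$beta_exposure < 0, -1, 1)
  d <- dplyr::mutate(d,
                     beta_exposure = .data$beta_exposure * flip,
                     beta_outcome = .data$beta_outcome * flip)
  est <- object$estimates
  ivw <- dplyr::filter(est, startsWith(.data$method, "IVW"))
  slope <- dplyr::filter(est, .data$method == "Egger-slope")
  intercept <- dplyr::filter(est, .data$method == "Egger-intercept")
  lines <- tibble::tibble(
    method = c(ivw$method, "MR-Egger"),
    intercept = c(0, intercept$beta),
    slope = c(ivw$beta, slope$beta)
  )
  ggplot2::ggplot(d, ggplot2::aes(x = .data$beta_exposure, y = .data$beta_outcome)) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$beta_outcome - .data$se_outcome,
                                        ymax = .data$beta_outcome + .data$se_outcome),
                           linewidth = 0.2, colour = "grey60") +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$beta_exposure - .data$se_exposure,
                                         xmax = .data$beta_exposure + .data$se_exposure),
                            linewidth = 0.2, colour = "grey60") +
    ggplot2::geom_point(size = 1) +
    ggplot2::geom_abline(data = lines,
                         ggplot2::aes(intercept = .data$intercept,
                                      slope = .data$slope,
                                      colour = .data$method)) +
    ggplot2::labs(x = "SNP effect on exposure", y = "SNP effect on outcome",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Forest plot of MR estimates
#'
#' @param estimates Estimate tibble (e.g. `tidy()` of one or more
#'   [mr_all()] fits, or the `estimates` table of a pipeline run).
#' @param label Column used for the row labels; default `method`.
#' @return A ggplot object.
#' @export
plot_forest <- function(estimates, label = "method") {
  estimates$.label <- estimates[[label]]
  if ("step" %in% names(estimates)) {
    estimates$.label <- paste(estimates$step, estimates$.label, sep = ": ")
  }
  ggplot2::ggplot(estimates,
                  ggplot2::aes(x = .data$beta, y = .data$.label)) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed", colour = "grey50") +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$ci_low,
                                         xmax = .data$ci_high),
                            height = 0.2) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Causal estimate (95% CI)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Forest plot of leave-one-out estimates
#'
#' @param loo Tibble from [leave_one_out()].
#' @param all_estimate Optional one-row estimate tibble for the all-SNP
#'   reference line.
#' @return A ggplot object.
#' @export
plot_leave_one_out <- function(loo, all_estimate = NULL) {
  p <- ggplot2::ggplot(loo, ggplot2::aes(x = .data$beta, y = .data$snp_omitted)) +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$ci_low,
                                         xmax = .data$ci_high),
                            height = 0.2, colour = "grey40") +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "IVW estimate omitting one SNP", y = "Omitted SNP") +
    ggplot2::theme_minimal()
  if (!is.null(all_estimate)) {
    p <- p + ggplot2::geom_vline(xintercept = all_estimate$beta,
                                 colour = "firebrick")
  }
  p
}

#' Mediation path diagram summary plot
#'
#' Forest-style display of the three path estimates and the indirect effect
#' of a two-step mediation result.
#'
#' @param mediation One-row tibble from [two_step_mediation()].
#' @return A ggplot object.
#' @export
plot_mediation <- function(mediation) {
  rows <- tibble::tibble(
    label = factor(c("Total effect", "Exposure → mediator (a)",
                     "Mediator → outcome (b)", "Indirect (a×b)"),
                   levels = rev(c("Total effect", "Exposure → mediator (a)",
                                  "Mediator → outcome (b)", "Indirect (a×b)"))),
    beta = c(mediation$beta_c, mediation$beta_a, mediation$beta_b,
             mediation$indirect),
    ci_low = c(mediation$beta_c_ci_low, mediation$beta_a_ci_low,
               mediation$beta_b_ci_low, mediation$indirect_ci_low),
    ci_high = c(mediation$beta_c_ci_high, mediation$beta_a_ci_high,
                mediation$beta_b_ci_high, mediation$indirect_ci_high)
  )
  ggplot2::ggplot(rows, ggplot2::aes(x = .data$beta, y = .data$label)) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed", colour = "grey50") +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$ci_low,
                                         xmax = .data$ci_high),
                            height = 0.2) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Effect (95% CI)", y = NULL) +
    ggplot2::theme_minimal()
}
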