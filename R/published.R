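#' Published two-step MR effect estimates for IGF-1, BMI and osteoarthritis
#'
#' Point estimates and 95% CIs, as published, for the three paths of a
#' two-step Mendelian-randomization mediation analysis of circulating IGF-1
#' on osteoarthritis at four sites (knee, hip, spine, hand) with body-mass
#' index as the mediator: the total effect `beta_c` (log-odds per SD of
#' IGF-1; NA for the spine, where no significant total effect was found),
#' the exposure-mediator path `beta_a`, and the mediator-outcome path
#' `beta_b`, together with the published indirect effects, Sobel p-values
#' and mediation proportions. These serve as worked-example inputs to the
#' mediation arithmetic ([indirect_effect()], [to_odds_ratio()],
#' [proportion_mediated()]).
#'
#' @return A tibble with one row per osteoarthritis site.
#' @examples
#' pub <- published_mediation_inputs()
#' with(pub[1, ], beta_a * beta_b) # knee indirect effect
#' @export
published_mediation_inputs <- function() {
  path <- system.file("extdata", "published_mediation_inputs.tsv",
                      package = "mrmediate", mustWork = TRUE)
  readr::read_tsv(path, col_types = readr::cols(
    exposure = readr::col_character(),
    mediator = readr::col_character(),
    outcome = readr::col_character(),
    .default = readr::col_double()
  ), progress = FALSE, na = "NA")
}

# normal-CI half width to SE
.se_from_ci <- function(lo, hi) (hi - lo) / (2 * 1.96)
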