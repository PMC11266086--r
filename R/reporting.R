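#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up q-values: on the sorted scale,
#' `q_(i) = min over j >= i of m p_(j) / j`, mapped back to the input order.
#' Delegates to [stats::p.adjust()] after validating that every p-value
#' lies in (0, 1].
#'
#' @param pvals Numeric vector of p-values in (0, 1].
#' @return q-values in the input order.
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03))
#' @export
bh_adjust <- function(pvals) {
  if (length(pvals) == 0) return(numeric(0))
  if (any(!is.finite(pvals) | pvals <= 0 | pvals > 1)) {
    stop("p-values must lie in (0, 1]", call. = FALSE)
  }
  stats::p.adjust(pvals, method = "BH")
}

.pipeline_defaults <- function() {
  list(
    thresholds = list(p_primary = 5e-8, p_fallback = 5e-6, min_ivs = 3,
                      r2_max = 0.001, window_kb = 10000,
                      ambiguity_window = c(0.42, 0.58)),
    estimators = list(mode = "auto", n_boot = 1000),
    sensitivity = list(n_sim = 1000, outlier_alpha = 0.05, run = TRUE),
    labels = list(exposure = "exposure", mediator = "mediator",
                  outcome = "outcome")
  )
}

.merge_config <- function(defaults, user) {
  for (nm in names(user)) {
    if (is.list(defaults[[nm]]) && is.list(user[[nm]])) {
      defaults[[nm]] <- .merge_config(defaults[[nm]], user[[nm]])
    } else {
      defaults[[nm]] <- user[[nm]]
    }
  }
  defaults
}

# one pairwise two-sample MR analysis: select, clump, harmonize, estimate,
# diagnose; returns NULL-heavy record when the instrument set is unusable
.run_analysis <- function(label, exposure, outcome, cfg, seed) {
  th <- cfg$thresholds
  sel <- select_by_pvalue(exposure, primary = th$p_primary,
                          fallback = th$p_fallback, min_ivs = th$min_ivs)
  rec <- list(label = label,
              n_input = nrow(exposure),
              n_selected = nrow(sel),
              p_threshold_used = attr(sel, "p_threshold_used"),
              usable = attr(sel, "usable"))
  if (!rec$usable) {
    rec$skip_reason <- "instrument set unusable (too few IVs at both thresholds)"
    return(rec)
  }
  clumped <- if (all(c("chrom", "pos") %in% names(sel))) {
    clump_instruments(sel, ld = cfg$ld, r2_max = th$r2_max,
                      window_kb = th$window_kb)
  } else {
    sel
  }
  rec$n_clumped <- nrow(clumped)
  harm <- harmonize(clumped, outcome, ambiguity_window = th$ambiguity_window)
  kept <- harmonized_kept(harm)
  rec$n_shared <- nrow(harm)
  rec$n_kept <- nrow(kept)
  if (nrow(kept) < th$min_ivs) {
    rec$skip_reason <- "too few SNPs after harmonization"
    rec$harmonized <- harm
    return(rec)
  }
  fit <- mr_all(kept, mode = cfg$estimators$mode,
                n_boot = cfg$estimators$n_boot, seed = seed,
                exposure = label$exposure %||% NA_character_,
                outcome = label$outcome %||% NA_character_)
  rec$harmonized <- harm
  rec$fit <- fit
  rec$instrument_summary <- instrument_summary(clumped)
  if (isTRUE(cfg$sensitivity$run) && nrow(kept) >= 4) {
    rec$sensitivity <- sensitivity_report(kept, n_sim = cfg$sensitivity$n_sim,
                                          outlier_alpha = cfg$sensitivity$outlier_alpha,
                                          seed = seed)
  }
  rec
}

#' Run the four-step bidirectional plus two-step MR design
#'
#' Orchestrates the full analysis plan on one exposure/mediator/outcome
#' triple: step 1 exposure on outcome, step 2 outcome on exposure
#' (bidirectional pair), step 3 exposure on mediator, step 4 mediator on
#' outcome, then the two-step mediation combining steps 1, 3 and 4. Each
#' pairwise analysis runs instrument selection (with the fallback-threshold
#' rule), greedy clumping when positions are available, harmonization, the
#' three estimators, and the sensitivity battery. Benjamini-Hochberg
#' q-values are computed within each method family across the analyses of
#' the run. Analyses with unusable instrument sets are skipped with the
#' reason recorded in the run log. The run is deterministic under a fixed
#' seed.
#'
#' @param config A YAML file path or a list. Recognised blocks:
#'   `simulation` (arguments to [sim_config()]; generates the three dataset
#'   pairs), or `datasets` (named list `xy`, `xm`, `my`, each with
#'   `exposure`/`outcome` file paths read via [read_summary_stats()]),
#'   `thresholds` (`p_primary`, `p_fallback`, `min_ivs`, `r2_max`,
#'   `window_kb`, `ambiguity_window`), `estimators` (`mode`, `n_boot`),
#'   `sensitivity` (`run`, `n_sim`, `outlier_alpha`), `labels`
#'   (`exposure`, `mediator`, `outcome`), `seed`.
#' @param out_dir Optional directory to which the result TSVs (MR
#'   estimates, sensitivity, mediation, harmonization drop logs, run log)
#'   are written.
#' @param seed Overrides the config seed.
#' @return An object of class `mr_pipeline`: `estimates` (all methods, all
#'   analyses, with q-values), `sensitivity`, `mediation`, `analyses` (the
#'   per-step records), `log` (SNP-count bookkeeping tibble), `config`.
#' @export
run_mr_pipeline <- function(config, out_dir = NULL, seed = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- .merge_config(.pipeline_defaults(), config)
  seed <- as.integer(seed %||% cfg$seed %||% 1L)
  lab <- cfg$labels

  if (!is.null(cfg$simulation)) {
    sim_args <- cfg$simulation
    sim_args$seed <- seed
    trip <- do.call(simulate_mediation_triplet, list(do.call(sim_config, sim_args)))
    pairs <- list(
      step1 = list(exposure = trip$xy$exposure, outcome = trip$xy$outcome),
      step2 = list(exposure = trip$xy$outcome, outcome = trip$xy$exposure),
      step3 = list(exposure = trip$xm$exposure, outcome = trip$xm$outcome),
      step4 = list(exposure = trip$my$exposure, outcome = trip$my$outcome)
    )
    truth <- trip$truth
  } else if (!is.null(cfg$datasets)) {
    ds <- cfg$datasets
    read_pair <- function(p) {
      dialect <- if (is.null(p$dialect)) sumstats_dialect() else unlist(p$dialect)
      list(exposure = read_summary_stats(p$exposure, dialect = dialect),
           outcome = read_summary_stats(p$outcome, dialect = dialect))
    }
    xy <- read_pair(ds$xy)
    pairs <- list(
      step1 = xy,
      step2 = list(exposure = xy$outcome, outcome = xy$exposure),
      step3 = if (!is.null(ds$xm)) read_pair(ds$xm),
      step4 = if (!is.null(ds$my)) read_pair(ds$my)
    )
    truth <- NULL
  } else {
    stop("config must contain a 'simulation' or 'datasets' block", call. = FALSE)
  }

  direction <- list(
    step1 = c(lab$exposure, lab$outcome),
    step2 = c(lab$outcome, lab$exposure),
    step3 = c(lab$exposure, lab$mediator),
    step4 = c(lab$mediator, lab$outcome)
  )

  analyses <- list()
  for (step in names(pairs)) {
    if (is.null(pairs[[step]])) {
      analyses[[step]] <- list(label = list(step = step),
                               skip_reason = "dataset not provided")
      next
    }
    analyses[[step]] <- .run_analysis(
      list(step = step, exposure = direction[[step]][1],
           outcome = direction[[step]][2]),
      pairs[[step]]$exposure, pairs[[step]]$outcome, cfg, seed
    )
  }

  estimates <- purrr::map_dfr(names(analyses), function(step) {
    a <- analyses[[step]]
    if (is.null(a$fit)) return(tibble::tibble())
    dplyr::mutate(tidy(a$fit), step = step, .before = 1)
  })
  if (nrow(estimates) > 0) {
    # FDR family: one method across the analyses of the run
    estimates <- dplyr::mutate(
      dplyr::group_by(estimates, .data$method),
      q = bh_adjust(.data$pval)
    )
    estimates <- dplyr::ungroup(estimates)
  }

  sens <- purrr::map_dfr(names(analyses), function(step) {
    a <- analyses[[step]]
    if (is.null(a$sensitivity)) return(tibble::tibble())
    dplyr::mutate(tidy(a$sensitivity), step = step, .before = 1)
  })

  mediation <- NULL
  get_ivw <- function(step) {
    a <- analyses[[step]]
    if (is.null(a$fit)) return(NULL)
    dplyr::filter(a$fit$estimates, startsWith(.data$method, "IVW"))
  }
  ivw1 <- get_ivw("step1"); ivw3 <- get_ivw("step3"); ivw4 <- get_ivw("step4")
  if (!is.null(ivw1) && !is.null(ivw3) && !is.null(ivw4)) {
    mediation <- two_step_mediation(ivw1, ivw3, ivw4,
                                    labels = list(exposure = lab$exposure,
                                                  mediator = lab$mediator,
                                                  outcome = lab$outcome))
  }

  log <- purrr::map_dfr(names(analyses), function(step) {
    a <- analyses[[step]]
    tibble::tibble(
      step = step,
      exposure = a$label$exposure %||% NA_character_,
      outcome = a$label$outcome %||% NA_character_,
      n_input = a$n_input %||% NA_integer_,
      n_selected = a$n_selected %||% NA_integer_,
      p_threshold_used = a$p_threshold_used %||% NA_real_,
      n_clumped = a$n_clumped %||% NA_integer_,
      n_shared = a$n_shared %||% NA_integer_,
      n_kept = a$n_kept %||% NA_integer_,
      ivw_model = if (!is.null(a$fit)) {
        dplyr::filter(a$fit$estimates, startsWith(.data$method, "IVW"))$method
      } else {
        NA_character_
      },
      skip_reason = a$skip_reason %||% NA_character_
    )
  })

  bundle <- structure(
    list(estimates = estimates, sensitivity = sens, mediation = mediation,
         analyses = analyses, log = log, truth = truth, config = cfg,
         seed = seed),
    class = "mr_pipeline"
  )
  if (!is.null(out_dir)) write_pipeline_bundle(bundle, out_dir)
  bundle
}

#' Write all pipeline result tables to a directory
#'
#' @param bundle An `mr_pipeline` object.
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_pipeline_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (nrow(bundle$estimates) > 0) {
    write_results_table(to_odds_ratio(bundle$estimates),
                        file.path(out_dir, "mr_results.tsv"))
  }
  if (nrow(bundle$sensitivity) > 0) {
    readr::write_tsv(bundle$sensitivity, file.path(out_dir, "sensitivity.tsv"),
                     progress = FALSE)
  }
  if (!is.null(bundle$mediation)) {
    readr::write_tsv(bundle$mediation, file.path(out_dir, "mediation.tsv"),
                     progress = FALSE)
  }
  for (step in names(bundle$analyses)) {
    h <- bundle$analyses[[step]]$harmonized
    if (!is.null(h)) {
      write_harmonization_log(h, file.path(out_dir, paste0(step, "_harmonization.tsv")))
    }
    loo <- bundle$analyses[[step]]$sensitivity$loo
    if (!is.null(loo)) {
      readr::write_tsv(loo, file.path(out_dir, paste0(step, "_leave_one_out.tsv")),
                       progress = FALSE)
    }
  }
  readr::write_tsv(bundle$log, file.path(out_dir, "run_log.tsv"),
                   progress = FALSE)
  invisible(out_dir)
}

#' @export
print.mr_pipeline <- function(x, ...) {
  cat("Four-step MR pipeline (seed", x$seed, ")\n")
  print(x$log)
  if (!is.null(x$mediation)) {
    cat("\nMediation:\n")
    print(dplyr::select(x$mediation, "exposure", "mediator", "outcome",
                        "indirect", "sobel_p", "proportion"))
  }
  invisible(x)
}
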