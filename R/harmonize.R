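.complement <- c(A = "T", T = "A", C = "G", G = "C")

.is_palindromic <- function(a, b) .complement[a] == b

#' Harmonize exposure and outcome summary statistics
#'
#' Aligns every variant shared by the exposure and outcome tables onto the
#' exposure's effect allele so that per-SNP effect pairs (gamma_j, Gamma_j)
#' refer to the same allele:
#'
#' * alleles already match: kept as-is;
#' * alleles reported in swapped order: outcome beta negated and its EAF
#'   reflected (`flipped`);
#' * alleles match only after strand complement: complemented, then the
#'   above (`strand_flipped`);
#' * palindromic variants (A/T or C/G): allele labels cannot resolve strand,
#'   so orientation is inferred from allele-frequency sidedness in the two
#'   studies; the variant is dropped (`dropped_palindromic`) whenever either
#'   study's EAF lies inside `ambiguity_window` or is missing;
#' * any other allele pair is `dropped_incompatible`.
#'
#' This reproduces the conservative "drop ambiguous palindromes" behaviour
#' (the "action = 2" convention of harmonization software).
#'
#' @param exposure Exposure summary-statistics tibble (typically an
#'   instrument set).
#' @param outcome Outcome summary-statistics tibble.
#' @param ambiguity_window Closed EAF interval within which a palindromic
#'   variant's strand is considered unresolvable; default `c(0.42, 0.58)`.
#' @return A tibble with one row per shared variant: exposure-oriented
#'   alleles, `beta_exposure`/`se_exposure`/`eaf_exposure`/`pval_exposure`,
#'   aligned `beta_outcome`/`se_outcome`/`eaf_outcome`, an `action` flag
#'   (`kept`, `flipped`, `strand_flipped`, `dropped_palindromic`,
#'   `dropped_incompatible`) and a logical `keep`. Dropped variants stay in
#'   the table as the drop log; [harmonized_kept()] filters them out.
#' @export
harmonize <- function(exposure, outcome, ambiguity_window = c(0.42, 0.58)) {
  shared <- dplyr::inner_join(
    dplyr::select(tibble::as_tibble(exposure), "snp",
                  ea_x = "effect_allele", oa_x = "other_allele",
                  eaf_exposure = "eaf", beta_exposure = "beta",
                  se_exposure = "se", pval_exposure = "pval",
                  dplyr::any_of(c("chrom", "pos"))),
    dplyr::select(tibble::as_tibble(outcome), "snp",
                  ea_y = "effect_allele", oa_y = "other_allele",
                  eaf_outcome = "eaf", beta_outcome = "beta",
                  se_outcome = "se", pval_outcome = "pval"),
    by = "snp"
  )
  n <- nrow(shared)
  action <- character(n)
  beta <- shared$beta_outcome
  eaf <- shared$eaf_outcome

  for (i in seq_len(n)) {
    ea_x <- shared$ea_x[i]; oa_x <- shared$oa_x[i]
    ea_y <- shared$ea_y[i]; oa_y <- shared$oa_y[i]
    if (.is_palindromic(ea_x, oa_x)) {
      # palindrome: the exposure pair and its complement are identical, so
      # allele labels carry no strand information
      if (!identical(sort(c(ea_y, oa_y)), sort(c(ea_x, oa_x)))) {
        action[i] <- "dropped_incompatible"
        next
      }
      fx <- shared$eaf_exposure[i]; fy <- shared$eaf_outcome[i]
      if (is.na(fx) || is.na(fy) ||
          (fx >= ambiguity_window[1] && fx <= ambiguity_window[2]) ||
          (fy >= ambiguity_window[1] && fy <= ambiguity_window[2])) {
        action[i] <- "dropped_palindromic"
        next
      }
      # nominal alignment by label, then frequency sidedness decides strand
      if (ea_y == ea_x) {
        b <- shared$beta_outcome[i]; f <- fy; flag <- "kept"
      } else {
        b <- -shared$beta_outcome[i]; f <- 1 - fy; flag <- "flipped"
      }
      if ((fx < 0.5) != (f < 0.5)) {
        # frequencies disagree: the outcome is on the opposite strand, which
        # for a palindrome is equivalent to an allele swap
        b <- -b; f <- 1 - f; flag <- "strand_flipped"
      }
      beta[i] <- b; eaf[i] <- f; action[i] <- flag
      next
    }
    if (ea_y == ea_x && oa_y == oa_x) {
      action[i] <- "kept"
    } else if (ea_y == oa_x && oa_y == ea_x) {
      beta[i] <- -beta[i]; eaf[i] <- 1 - eaf[i]
      action[i] <- "flipped"
    } else {
      cea <- unname(.complement[ea_y]); coa <- unname(.complement[oa_y])
      if (identical(cea, ea_x) && identical(coa, oa_x)) {
        action[i] <- "strand_flipped"
      } else if (identical(cea, oa_x) && identical(coa, ea_x)) {
        beta[i] <- -beta[i]; eaf[i] <- 1 - eaf[i]
        action[i] <- "strand_flipped"
      } else {
        action[i] <- "dropped_incompatible"
      }
    }
  }

  out <- tibble::tibble(
    snp = shared$snp,
    effect_allele = shared$ea_x,
    other_allele = shared$oa_x,
    beta_exposure = shared$beta_exposure,
    se_exposure = shared$se_exposure,
    eaf_exposure = shared$eaf_exposure,
    pval_exposure = shared$pval_exposure,
    beta_outcome = beta,
    se_outcome = shared$se_outcome,
    eaf_outcome = eaf,
    action = action,
    keep = !startsWith(action, "dropped")
  )
  if ("chrom" %in% names(shared)) {
    out$chrom <- shared$chrom
    out$pos <- shared$pos
  }
  out
}

#' Kept rows of a harmonized dataset
#'
#' @param x Tibble from [harmonize()].
#' @return The subset with `keep == TRUE`.
#' @export
harmonized_kept <- function(x) {
  if ("keep" %in% names(x)) dplyr::filter(x, .data$keep) else x
}

#' Write the harmonization drop log as TSV
#'
#' @param x Tibble from [harmonize()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_harmonization_log <- function(x, path) {
  readr::write_tsv(dplyr::select(x, "snp", "effect_allele", "other_allele",
                                 "action", "keep"),
                   path, progress = FALSE)
  invisible(path)
}
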