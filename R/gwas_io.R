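#' Canonical summary-statistics column dialect
#'
#' The package's internal schema for GWAS summary statistics is a tibble with
#' columns `snp`, `effect_allele`, `other_allele`, `eaf`, `beta`, `se`,
#' `pval`, `n`. On disk the canonical dialect is a tab-separated file with a
#' header row `SNP/EA/OA/EAF/BETA/SE/P/N`; exports from other providers are
#' adapted by passing a different mapping to [read_summary_stats()].
#'
#' @return Named character vector mapping internal column names to file
#'   header names.
#' @examples
#' sumstats_dialect()
#' @export
sumstats_dialect <- function() {
  c(
    snp = "SNP", effect_allele = "EA", other_allele = "OA",
    eaf = "EAF", beta = "BETA", se = "SE", pval = "P", n = "N"
  )
}

#' Read GWAS summary statistics from a delimited file
#'
#' Reads a tab-separated summary-statistics file into the canonical tibble
#' schema, mapping file headers through `dialect`. Extra unmapped columns are
#' ignored and row order is preserved. The table is validated on read: allele
#' codes must be single bases A/C/G/T (indels are rejected), standard errors
#' must be positive, allele frequencies strictly inside (0, 1), p-values in
#' (0, 1], and variant IDs unique.
#'
#' @param path Path to a tab-separated file with a header row.
#' @param dialect Named character vector mapping the internal names
#'   (`snp`, `effect_allele`, `other_allele`, `eaf`, `beta`, `se`, `pval`,
#'   `n`) to the file's column headers. Defaults to [sumstats_dialect()].
#' @param trait Optional trait label attached as the `"trait"` attribute.
#' @return A validated summary-statistics tibble.
#' @seealso [validate_sumstats()], [write_results_table()]
#' @export
read_summary_stats <- function(path, dialect = sumstats_dialect(), trait = NULL) {
  if (!file.exists(path)) {
    stop("summary-statistics file not found: ", path, call. = FALSE)
  }
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  missing <- setdiff(unname(dialect), names(raw))
  if (length(missing) > 0) {
    stop("summary-statistics file is missing mapped column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  out <- tibble::as_tibble(stats::setNames(raw[unname(dialect)], names(dialect)))

  num_cols <- c("eaf", "beta", "se", "pval", "n")
  for (col in num_cols) {
    parsed <- suppressWarnings(as.numeric(out[[col]]))
    bad <- which(is.na(parsed) & !is.na(out[[col]]))
    if (length(bad) > 0) {
      stop(sprintf("non-numeric value '%s' in column '%s' at row %d",
                   out[[col]][bad[1]], col, bad[1]), call. = FALSE)
    }
    out[[col]] <- parsed
  }
  out$effect_allele <- toupper(out$effect_allele)
  out$other_allele <- toupper(out$other_allele)
  out <- validate_sumstats(out)
  attr(out, "trait") <- trait
  out
}

#' Validate a summary-statistics tibble
#'
#' Enforces the schema invariants: unique variant IDs, biallelic single-base
#' alleles with effect != other, `eaf` in (0,1), `se > 0`, `pval` in (0,1],
#' `n > 0`. A p-value grossly inconsistent with the normal two-sided tail of
#' `beta/se` raises a warning (published tables are rounded, so this is not
#' an error).
#'
#' @param x A data frame with the canonical columns.
#' @return `x` as a tibble, invisibly validated.
#' @export
validate_sumstats <- function(x) {
  x <- tibble::as_tibble(x)
  required <- names(sumstats_dialect())
  missing <- setdiff(required, names(x))
  if (length(missing) > 0) {
    stop("summary-statistics table is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  dup <- x$snp[duplicated(x$snp)]
  if (length(dup) > 0) {
    stop("duplicate variant IDs: ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }
  bases <- c("A", "C", "G", "T")
  bad_allele <- which(!(x$effect_allele %in% bases) | !(x$other_allele %in% bases))
  if (length(bad_allele) > 0) {
    stop(sprintf("invalid allele code at row %d (only biallelic SNPs A/C/G/T are supported)",
                 bad_allele[1]), call. = FALSE)
  }
  same <- which(x$effect_allele == x$other_allele)
  if (length(same) > 0) {
    stop(sprintf("effect and other allele identical at row %d", same[1]),
         call. = FALSE)
  }
  checks <- list(
    se = which(!is.finite(x$se) | x$se <= 0),
    eaf = which(!is.finite(x$eaf) | x$eaf <= 0 | x$eaf >= 1),
    pval = which(!is.finite(x$pval) | x$pval <= 0 | x$pval > 1),
    n = which(!is.finite(x$n) | x$n <= 0)
  )
  for (col in names(checks)) {
    if (length(checks[[col]]) > 0) {
      stop(sprintf("invalid %s at row %d", col, checks[[col]][1]), call. = FALSE)
    }
  }
  # published p-values are rounded; flag only order-of-magnitude disagreement
  z <- abs(x$beta / x$se)
  p_expected <- 2 * stats::pnorm(-z)
  inconsistent <- p_expected > 1e-12 & (x$pval / p_expected > 10 | x$pval / p_expected < 0.1)
  if (any(inconsistent, na.rm = TRUE)) {
    warning(sprintf("%d p-value(s) inconsistent with |beta/se| under a normal reference (first at row %d)",
                    sum(inconsistent, na.rm = TRUE), which(inconsistent)[1]),
            call. = FALSE)
  }
  x
}

#' Write a summary-statistics tibble in the canonical dialect
#'
#' @param x Summary-statistics tibble.
#' @param path Output path.
#' @param dialect Column mapping used for the file headers.
#' @return `path`, invisibly.
#' @export
write_summary_stats <- function(x, path, dialect = sumstats_dialect()) {
  x <- validate_sumstats(x)
  out <- x[names(dialect)]
  names(out) <- unname(dialect)
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

results_columns <- c("exposure", "outcome", "method", "nsnp", "beta", "or",
                     "ci_low", "ci_high", "or_ci_low", "or_ci_high", "p", "q")

mediation_columns <- c("exposure", "mediator", "outcome", "beta_c", "beta_a",
                       "beta_b", "indirect", "indirect_se", "indirect_ci_low",
                       "indirect_ci_high", "sobel_p", "proportion",
                       "proportion_ci_low", "proportion_ci_high")

results_kind <- function(x) {
  if (all(c("method", "beta") %in% names(x))) return("mr_estimates")
  if (all(c("indirect", "sobel_p") %in% names(x))) return("mediation")
  stop("unrecognised results table: expected MR-estimate or mediation columns",
       call. = FALSE)
}

#' Write MR or mediation results to a TSV file
#'
#' MR estimates are written with the fixed column set exposure / outcome /
#' method / nsnp / beta / OR / CI bounds / p / q; mediation results with the
#' Table-2-style mediation column set. A heterogeneous collection (both
#' kinds) is an error unless `sections = TRUE`, in which case each kind is
#' written as its own section introduced by a `# section:` comment line.
#' Values round-trip through [read_results_table()] to at least 6
#' significant digits.
#'
#' @param results A results tibble, or a list of results tibbles.
#' @param path Output path.
#' @param sections Allow mixed result kinds, written as named sections.
#' @return `path`, invisibly.
#' @export
write_results_table <- function(results, path, sections = FALSE) {
  if (is.data.frame(results)) results <- list(results)
  if (length(results) == 0 || any(vapply(results, nrow, 1L) == 0)) {
    stop("cannot write an empty results collection", call. = FALSE)
  }
  kinds <- vapply(results, results_kind, character(1))
  blocks <- lapply(results, function(x) {
    cols <- if (results_kind(x) == "mr_estimates") results_columns else mediation_columns
    for (col in setdiff(cols, names(x))) x[[col]] <- NA
    x[cols]
  })
  if (length(unique(kinds)) > 1 && !sections) {
    stop("mixed result kinds; pass sections = TRUE to write them as sections",
         call. = FALSE)
  }
  if (length(unique(kinds)) == 1 && !sections) {
    merged <- dplyr::bind_rows(blocks)
    readr::write_tsv(merged, path, progress = FALSE)
  } else {
    lines <- unlist(lapply(seq_along(blocks), function(i) {
      c(paste0("# section: ", kinds[i]),
        sub("\n$", "", readr::format_tsv(blocks[[i]])))
    }))
    writeLines(unlist(strsplit(lines, "\n")), path)
  }
  invisible(path)
}

#' Read back a results TSV written by [write_results_table()]
#'
#' @param path Path to the results file.
#' @return A tibble, or a named list of tibbles when the file has sections.
#' @export
read_results_table <- function(path) {
  lines <- readLines(path)
  starts <- grep("^# section: ", lines)
  parse_block <- function(txt) {
    readr::read_tsv(I(paste(txt, collapse = "\n")),
                    col_types = readr::cols(), progress = FALSE)
  }
  if (length(starts) == 0) return(parse_block(lines))
  ends <- c(starts[-1] - 1, length(lines))
  out <- lapply(seq_along(starts), function(i) {
    parse_block(lines[(starts[i] + 1):ends[i]])
  })
  names(out) <- sub("^# section: ", "", lines[starts])
  out
}
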