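#' Instrument-strength F-statistic
#'
#' Aggregate instrument strength for a set of k instruments jointly
#' explaining a fraction `r2` of exposure variance in a sample of size `n`:
#' `F = r2 * (n - k - 1) / ((1 - r2) * k)`. Instrument sets with F >= 10 are
#' conventionally considered strong enough to limit weak-instrument bias.
#'
#' @param r2 Fraction of exposure variance explained, in (0, 1).
#' @param n GWAS sample size; must exceed `k + 1`.
#' @param k Number of instruments, >= 1.
#' @return The F-statistic.
#' @examples
#' f_statistic(0.5, 103, 1) # 101
#' @export
f_statistic <- function(r2, n, k) {
  if (any(r2 <= 0 | r2 >= 1)) stop("r2 must lie strictly in (0, 1)", call. = FALSE)
  if (any(k < 1)) stop("k must be >= 1", call. = FALSE)
  if (any(n <= k + 1)) stop("n must exceed k + 1", call. = FALSE)
  r2 * (n - k - 1) / ((1 - r2) * k)
}

#' Per-SNP instrument strength
#'
#' The single-SNP chi-square statistic `(beta / se)^2`, which approximates
#' the per-SNP F-statistic at large n.
#'
#' @param x A summary-statistics tibble (or any data frame with `beta` and
#'   `se` columns).
#' @return Numeric vector of per-SNP strengths.
#' @export
per_snp_strength <- function(x) {
  (x$beta / x$se)^2
}

# aggregate R^2 on a standardized trait: sum_j 2 p_j (1 - p_j) beta_j^2
.aggregate_r2 <- function(x) {
  sum(2 * x$eaf * (1 - x$eaf) * x$beta^2)
}

.with_strength <- function(x, p_threshold_used, usable) {
  x$f_per_snp <- if (nrow(x) > 0) per_snp_strength(x) else numeric(0)
  attr(x, "p_threshold_used") <- p_threshold_used
  attr(x, "usable") <- usable
  if (nrow(x) > 0) {
    r2 <- .aggregate_r2(x)
    n <- stats::median(x$n)
    attr(x, "r2_explained") <- r2
    attr(x, "f_aggregate") <- if (r2 < 1 && n > nrow(x) + 1) {
      f_statistic(r2, n, nrow(x))
    } else {
      NA_real_
    }
  } else {
    attr(x, "r2_explained") <- 0
    attr(x, "f_aggregate") <- NA_real_
  }
  attr(x, "retained") <- isTRUE(usable) && isTRUE(attr(x, "f_aggregate") >= 10)
  x
}

#' Select instruments by p-value with a fallback threshold
#'
#' Keeps variants associated with the exposure at the genome-wide
#' significance threshold (`primary`, default 5e-8). When fewer than
#' `min_ivs` variants survive, the selection is repeated at the relaxed
#' `fallback` threshold (default 5e-6); if the relaxed set is still smaller
#' than `min_ivs`, the set is flagged unusable rather than raising an error.
#'
#' The returned tibble carries a `f_per_snp` column and the attributes
#' `p_threshold_used`, `usable`, `r2_explained` (aggregate
#' `sum 2 p (1-p) beta^2` on the standardized scale), `f_aggregate` and
#' `retained` (usable and aggregate F >= 10).
#'
#' @param table Summary-statistics tibble for the exposure.
#' @param primary Genome-wide significance threshold.
#' @param fallback Relaxed threshold used when `primary` yields too few IVs.
#' @param min_ivs Minimum number of instruments for a usable analysis.
#' @return The selected subset as a tibble with strength metadata.
#' @seealso [clump_instruments()], [instrument_summary()]
#' @export
select_by_pvalue <- function(table, primary = 5e-8, fallback = 5e-6, min_ivs = 3) {
  if (nrow(table) == 0) stop("empty summary-statistics table", call. = FALSE)
  sel <- dplyr::filter(table, .data$pval <= primary)
  if (nrow(sel) >= min_ivs) {
    return(.with_strength(sel, primary, TRUE))
  }
  sel <- dplyr::filter(table, .data$pval <= fallback)
  .with_strength(sel, fallback, nrow(sel) >= min_ivs)
}

#' One-row summary of an instrument set
#'
#' @param x A tibble returned by [select_by_pvalue()] or
#'   [clump_instruments()].
#' @return A one-row tibble with SNP count, threshold used, aggregate R^2,
#'   aggregate F, the per-SNP F range, and the usable/retained flags.
#' @export
instrument_summary <- function(x) {
  tibble::tibble(
    n_snp = nrow(x),
    p_threshold_used = attr(x, "p_threshold_used") %||% NA_real_,
    r2_explained = attr(x, "r2_explained") %||% NA_real_,
    f_aggregate = attr(x, "f_aggregate") %||% NA_real_,
    f_min = if (nrow(x) > 0) min(x$f_per_snp) else NA_real_,
    f_max = if (nrow(x) > 0) max(x$f_per_snp) else NA_real_,
    usable = isTRUE(attr(x, "usable")),
    retained = isTRUE(attr(x, "retained"))
  )
}

.ld_r2 <- function(ld, a, b) {
  if (is.null(ld)) return(0) # no LD supplied: instruments treated as independent
  if (!(a %in% rownames(ld)) || !(b %in% colnames(ld))) {
    stop(sprintf("LD entry missing for pair (%s, %s)", a, b), call. = FALSE)
  }
  v <- ld[a, b]
  if (is.na(v)) {
    stop(sprintf("LD entry missing for pair (%s, %s)", a, b), call. = FALSE)
  }
  v
}

#' Greedy LD clumping of an instrument set
#'
#' Prunes instruments to approximate independence: variants are visited in
#' ascending p-value order (ties broken by variant ID) and a variant is
#' accepted only if its LD r-squared with every already-accepted variant
#' within `window_kb` kilobases on the same chromosome is below `r2_max`.
#' The output rows are in acceptance order; the result is independent of
#' the input row order.
#'
#' @param set Instrument tibble (from [select_by_pvalue()]); must carry
#'   `chrom` and `pos` columns or have them supplied via `positions`.
#' @param ld Square r-squared matrix with variant IDs as dimnames, or NULL
#'   for mutually independent variants (the post-clumping world the
#'   synthetic generator emulates).
#' @param positions Optional data frame with columns `snp`, `chrom`, `pos`
#'   overriding position columns in `set`.
#' @param r2_max LD threshold; default 0.001.
#' @param window_kb Clumping window in kilobases; default 10000. Variants on
#'   different chromosomes are always outside the window.
#' @return The clumped instrument tibble with refreshed strength metadata.
#' @export
clump_instruments <- function(set, ld = NULL, positions = NULL,
                              r2_max = 0.001, window_kb = 10000) {
  if (nrow(set) == 0) return(set)
  if (!is.null(positions)) {
    set$chrom <- positions$chrom[match(set$snp, positions$snp)]
    set$pos <- positions$pos[match(set$snp, positions$snp)]
  }
  if (!all(c("chrom", "pos") %in% names(set)) || anyNA(set$chrom) || anyNA(set$pos)) {
    stop("clumping requires chrom and pos for every variant", call. = FALSE)
  }
  ord <- order(set$pval, set$snp)
  candidate <- set[ord, ]
  accepted <- integer(0)
  for (i in seq_len(nrow(candidate))) {
    ok <- TRUE
    for (j in accepted) {
      same_chrom <- candidate$chrom[i] == candidate$chrom[j]
      in_window <- same_chrom &&
        abs(candidate$pos[i] - candidate$pos[j]) <= window_kb * 1000
      if (in_window &&
          .ld_r2(ld, candidate$snp[i], candidate$snp[j]) >= r2_max) {
        ok <- FALSE
        break
      }
    }
    if (ok) accepted <- c(accepted, i)
  }
  .with_strength(candidate[accepted, ],
                 attr(set, "p_threshold_used") %||% NA_real_,
                 attr(set, "usable") %||% TRUE)
}

#' Read a square LD r-squared matrix from TSV
#'
#' Expects a tab-separated file whose first column and header row both hold
#' variant IDs.
#'
#' @param path File path.
#' @return A numeric matrix with variant-ID dimnames.
#' @export
read_ld_matrix <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE)
  m <- as.matrix(df[, -1])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  m
}

#' Read variant positions from a 3-column TSV
#'
#' @param path File with columns `snp`, `chrom`, `pos` (any header names;
#'   taken positionally).
#' @return A tibble with columns `snp`, `chrom`, `pos`.
#' @export
read_snp_positions <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE)
  out <- tibble::tibble(snp = as.character(df[[1]]),
                        chrom = df[[2]], pos = as.numeric(df[[3]]))
  out
}
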