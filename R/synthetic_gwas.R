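#' Configuration for the synthetic GWAS summary-statistics generator
#'
#' Defines the causal model under which two-sample summary statistics are
#' simulated: independent biallelic SNPs instrument a standardized exposure
#' X; the outcome Y receives a direct effect `theta` from X and an indirect
#' path through a mediator M (`beta_a` for X to M, `beta_b` for M to Y), so
#' the total causal effect is `theta + beta_a * beta_b`. Each SNP may carry
#' a direct (pleiotropic) effect on Y drawn from
#' Normal(`pleiotropy_mean`, `pleiotropy_sd`^2); `n_outliers` SNPs have that
#' effect replaced by `outlier_effect` to emulate gross invalid instruments.
#'
#' Defaults mirror a large-biobank setting: around 300 genome-wide
#' significant instruments explaining about 10% of exposure variance, with
#' GWAS sample sizes in the hundreds of thousands, and knee-osteoarthritis
#' scale effects (total effect 0.067 on the log-odds scale split as
#' direct 0.042 plus indirect 0.04 * 0.663).
#'
#' @param n_snps Number of instruments for the exposure.
#' @param n_exposure,n_outcome,n_mediator GWAS sample sizes for the
#'   exposure, outcome and mediator studies.
#' @param theta True direct causal effect of X on Y.
#' @param beta_a True effect of X on the mediator M.
#' @param beta_b True effect of M on Y.
#' @param pleiotropy_mean,pleiotropy_sd Mean and SD of per-SNP direct
#'   effects on Y (directional pleiotropy when the mean is nonzero).
#' @param n_outliers Number of SNPs given the fixed pleiotropic effect
#'   `outlier_effect`.
#' @param outlier_effect Pleiotropic effect assigned to outlier SNPs.
#' @param maf_range Interval within (0, 0.5] from which minor-allele
#'   frequencies are drawn uniformly.
#' @param exposure_h2 Total exposure variance explained by the instruments
#'   (traits are standardized, so this is the aggregate instrument R^2).
#' @param n_snps_mediator,mediator_h2 Size and aggregate R^2 of the disjoint
#'   SNP panel instrumenting the mediator (defaults follow the exposure
#'   panel).
#' @param seed Integer seed; one seed governs every draw.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_snps = 300,
                       n_exposure = 435516,
                       n_outcome = 400000,
                       n_mediator = 681275,
                       theta = 0.042,
                       beta_a = 0.04,
                       beta_b = 0.663,
                       pleiotropy_mean = 0,
                       pleiotropy_sd = 0,
                       n_outliers = 0,
                       outlier_effect = 0,
                       maf_range = c(0.05, 0.5),
                       exposure_h2 = 0.1,
                       n_snps_mediator = n_snps,
                       mediator_h2 = exposure_h2,
                       seed = 1L) {
  cfg <- list(
    n_snps = as.integer(n_snps), n_exposure = n_exposure,
    n_outcome = n_outcome, n_mediator = n_mediator,
    theta = theta, beta_a = beta_a, beta_b = beta_b,
    pleiotropy_mean = pleiotropy_mean, pleiotropy_sd = pleiotropy_sd,
    n_outliers = as.integer(n_outliers), outlier_effect = outlier_effect,
    maf_range = maf_range, exposure_h2 = exposure_h2,
    n_snps_mediator = as.integer(n_snps_mediator), mediator_h2 = mediator_h2,
    seed = as.integer(seed)
  )
  stopifnot(
    cfg$n_snps >= 1,
    cfg$n_exposure >= 100, cfg$n_outcome >= 100, cfg$n_mediator >= 100,
    cfg$exposure_h2 > 0, cfg$exposure_h2 < 1,
    cfg$mediator_h2 > 0, cfg$mediator_h2 < 1,
    cfg$n_outliers <= cfg$n_snps, cfg$n_outliers >= 0,
    length(cfg$maf_range) == 2,
    cfg$maf_range[1] > 0, cfg$maf_range[2] <= 0.5,
    cfg$maf_range[1] <= cfg$maf_range[2],
    cfg$pleiotropy_sd >= 0
  )
  class(cfg) <- "sim_config"
  cfg
}

# non-palindromic ordered allele pairs; palindromes (A/T, C/G) are what
# clumped, harmonized instrument panels have already shed
.allele_pairs <- matrix(c(
  "A", "C", "A", "G", "C", "A", "C", "T",
  "G", "A", "G", "T", "T", "C", "T", "G"
), ncol = 2, byrow = TRUE)

# true per-SNP effects scaled so the aggregate R^2 on a standardized trait
# equals h2: sum_j 2 p_j (1 - p_j) gamma_j^2 = h2
.scaled_effects <- function(n, maf, h2) {
  raw <- stats::rnorm(n)
  denom <- sum(2 * maf * (1 - maf) * raw^2)
  if (!is.finite(denom) || denom <= 0) {
    stop("infeasible variance-explained allocation", call. = FALSE)
  }
  raw * sqrt(h2 / denom)
}

# observed summary statistics for one GWAS sample of size n, given true
# per-allele effects; se = 1/sqrt(2 p (1-p) n) for a standardized trait
.observe <- function(ids, alleles, maf, true_beta, n, chrom, pos) {
  se <- 1 / sqrt(2 * maf * (1 - maf) * n)
  beta <- stats::rnorm(length(true_beta), true_beta, se)
  tibble::tibble(
    snp = ids,
    effect_allele = alleles[, 1],
    other_allele = alleles[, 2],
    eaf = maf,
    beta = beta,
    se = se,
    # floored so extreme associations never underflow to an invalid p of 0
    pval = pmax(2 * stats::pnorm(-abs(beta / se)), .Machine$double.xmin),
    n = n,
    chrom = chrom,
    pos = pos
  )
}

.snp_panel <- function(cfg, n, h2, prefix) {
  maf <- stats::runif(n, cfg$maf_range[1], cfg$maf_range[2])
  list(
    ids = sprintf("%s%06d", prefix, seq_len(n)),
    alleles = .allele_pairs[sample.int(nrow(.allele_pairs), n, replace = TRUE), , drop = FALSE],
    maf = maf,
    chrom = sample.int(22, n, replace = TRUE),
    pos = sample.int(2.4e8, n, replace = TRUE),
    gamma = .scaled_effects(n, maf, h2)
  )
}

# pleiotropic effects are oriented relative to the exposure-increasing
# allele (sign(gamma)), the frame in which "directional" pleiotropy is
# defined for the Egger intercept; a nonzero mean is therefore directional
.pleiotropy <- function(cfg, gamma) {
  orient <- sign(gamma)
  orient[orient == 0] <- 1
  alpha <- orient * stats::rnorm(cfg$n_snps, cfg$pleiotropy_mean,
                                 cfg$pleiotropy_sd)
  outlier_idx <- integer(0)
  if (cfg$n_outliers > 0) {
    outlier_idx <- sample.int(cfg$n_snps, cfg$n_outliers)
    alpha[outlier_idx] <- orient[outlier_idx] * cfg$outlier_effect
  }
  list(alpha = alpha, outlier_idx = outlier_idx)
}

#' Simulate a two-sample GWAS summary-statistics pair
#'
#' Draws, under the configured causal model, an exposure table (sample size
#' `n_exposure`) and an outcome table (`n_outcome`) over the same SNP panel
#' in two non-overlapping samples. The outcome's true per-SNP effect is
#' `total_effect * gamma_j + alpha_j`, where `total_effect = theta +
#' beta_a * beta_b` and `alpha_j` is the pleiotropic effect. Observed betas
#' are the truth plus Normal(0, se^2) noise with
#' `se = 1 / sqrt(2 p (1 - p) n)`. The same seed reproduces the tables
#' bit-for-bit.
#'
#' @param config A [sim_config()].
#' @return A list with elements `exposure`, `outcome` (summary-statistics
#'   tibbles) and `truth` (true effects, pleiotropy, outlier indices and
#'   `total_effect`).
#' @examples
#' sim <- simulate_two_sample(sim_config(n_snps = 50, seed = 7))
#' head(sim$exposure)
#' sim$truth$total_effect
#' @export
simulate_two_sample <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  panel <- .snp_panel(config, config$n_snps, config$exposure_h2, "rs")
  pl <- .pleiotropy(config, panel$gamma)
  total <- config$theta + config$beta_a * config$beta_b
  gamma_y <- total * panel$gamma + pl$alpha
  exposure <- .observe(panel$ids, panel$alleles, panel$maf, panel$gamma,
                       config$n_exposure, panel$chrom, panel$pos)
  outcome <- .observe(panel$ids, panel$alleles, panel$maf, gamma_y,
                      config$n_outcome, panel$chrom, panel$pos)
  truth <- list(
    total_effect = total, theta = config$theta,
    beta_a = config$beta_a, beta_b = config$beta_b,
    gamma = panel$gamma, alpha = pl$alpha,
    outlier_idx = pl$outlier_idx, maf = panel$maf
  )
  list(exposure = exposure, outcome = outcome, truth = truth)
}

#' Simulate the three dataset pairs of a two-step mediation design
#'
#' Generates summary statistics for the three pairwise MR analyses of a
#' two-step mediation study: exposure on outcome (total effect), exposure on
#' mediator (`beta_a`) and mediator on outcome (`beta_b`). The exposure-on-Y
#' and exposure-on-M pairs share the exposure SNP panel's true effects; the
#' mediator-on-Y pair uses a disjoint SNP panel that instruments the
#' mediator directly, so its Wald ratios estimate `beta_b` rather than a
#' mixture of paths. Every study is an independent sample (fresh observation
#' noise).
#'
#' @param config A [sim_config()] with `beta_a` and `beta_b` set.
#' @return A list with elements `xy`, `xm`, `my` (each a list with
#'   `exposure` and `outcome` tibbles) and `truth`.
#' @export
simulate_mediation_triplet <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  xp <- .snp_panel(config, config$n_snps, config$exposure_h2, "rs")
  mp <- .snp_panel(config, config$n_snps_mediator, config$mediator_h2, "rs9")
  pl <- .pleiotropy(config, xp$gamma)
  total <- config$theta + config$beta_a * config$beta_b

  xy <- list(
    exposure = .observe(xp$ids, xp$alleles, xp$maf, xp$gamma,
                        config$n_exposure, xp$chrom, xp$pos),
    outcome = .observe(xp$ids, xp$alleles, xp$maf, total * xp$gamma + pl$alpha,
                       config$n_outcome, xp$chrom, xp$pos)
  )
  xm <- list(
    exposure = .observe(xp$ids, xp$alleles, xp$maf, xp$gamma,
                        config$n_exposure, xp$chrom, xp$pos),
    outcome = .observe(xp$ids, xp$alleles, xp$maf, config$beta_a * xp$gamma,
                       config$n_mediator, xp$chrom, xp$pos)
  )
  my <- list(
    exposure = .observe(mp$ids, mp$alleles, mp$maf, mp$gamma,
                        config$n_mediator, mp$chrom, mp$pos),
    outcome = .observe(mp$ids, mp$alleles, mp$maf, config$beta_b * mp$gamma,
                       config$n_outcome, mp$chrom, mp$pos)
  )
  truth <- list(
    total_effect = total, theta = config$theta,
    beta_a = config$beta_a, beta_b = config$beta_b,
    indirect = config$beta_a * config$beta_b,
    gamma = xp$gamma, gamma_mediator = mp$gamma,
    alpha = pl$alpha, outlier_idx = pl$outlier_idx
  )
  list(xy = xy, xm = xm, my = my, truth = truth)
}
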