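# Independent oracles used to cross-check the estimators. These deliberately
# take a different computational route from the package implementation.

# weighted least squares by explicit normal equations: beta = (X'WX)^-1 X'Wy,
# unscaled coefficient covariance (X'WX)^-1
wls_oracle <- function(X, y, w) {
  XtWX <- t(X) %*% (X * w)
  XtWy <- t(X) %*% (w * y)
  beta <- solve(XtWX, XtWy)
  list(beta = drop(beta), cov_unscaled = solve(XtWX),
       rss = sum(w * (y - drop(X %*% beta))^2))
}

# weighted median by direct scan of the midpoint-cumulative-weight function
weighted_quantile_oracle <- function(x, w, q = 0.5) {
  ord <- order(x)
  x <- x[ord]; w <- w[ord] / sum(w)
  s <- cumsum(w) - w / 2
  if (q <= s[1]) return(x[1])
  if (q >= s[length(s)]) return(x[length(x)])
  i <- max(which(s <= q))
  if (s[i] == q) return(x[i])
  x[i] + (x[i + 1] - x[i]) * (q - s[i]) / (s[i + 1] - s[i])
}

# BH step-up by literal enumeration of the definition:
# q_(i) = min_{j >= i} m * p_(j) / j, mapped back to input order
bh_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  q_sorted <- vapply(seq_len(m), function(i) {
    min(m * p[ord][i:m] / seq_len(m)[i:m])
  }, numeric(1))
  q <- numeric(m)
  q[ord] <- pmin(1, q_sorted)
  q
}

# greedy-clump characterisation: S is the greedy result iff every variant v
# is in S exactly when no earlier-ranked member of S conflicts with it
clump_subset_oracle <- function(snp, pval, chrom, pos, ld, r2_max, window_kb) {
  k <- length(snp)
  rank <- order(pval, snp)
  conflicts <- function(i, j) {
    chrom[i] == chrom[j] &&
      abs(pos[i] - pos[j]) <= window_kb * 1000 &&
      ld[snp[i], snp[j]] >= r2_max
  }
  for (bits in 0:(2^k - 1)) {
    S <- which(bitwAnd(bits, 2^(seq_len(k) - 1)) > 0)
    ok <- TRUE
    for (ri in seq_len(k)) {
      v <- rank[ri]
      earlier <- intersect(rank[seq_len(ri - 1)], S)
      blocked <- any(vapply(earlier, function(u) conflicts(v, u), logical(1)))
      if ((v %in% S) == blocked) {
        ok <- FALSE
        break
      }
    }
    if (ok) return(sort(S))
  }
  stop("no greedy-consistent subset found")
}

# small harmonized dataset built directly from effect arrays
make_harmonized <- function(g, G, sg = rep(0.05, length(g)),
                            sG = rep(0.05, length(g))) {
  tibble::tibble(
    snp = sprintf("rs%03d", seq_along(g)),
    beta_exposure = g, se_exposure = sg,
    beta_outcome = G, se_outcome = sG,
    keep = TRUE
  )
}

# canonical summary-stats tibble for io tests
make_sumstats <- function(n = 3, seed = 1) {
  set.seed(seed)
  eaf <- runif(n, 0.1, 0.9)
  beta <- rnorm(n, 0, 0.05)
  se <- runif(n, 0.005, 0.02)
  tibble::tibble(
    snp = sprintf("rs%05d", seq_len(n)),
    effect_allele = rep(c("A", "C", "G"), length.out = n),
    other_allele = rep(c("G", "T", "A"), length.out = n),
    eaf = eaf, beta = beta, se = se,
    pval = 2 * pnorm(-abs(beta / se)), n = 100000
  )
}
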