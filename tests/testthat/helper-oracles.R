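# Independent brute-force oracles used to cross-check the estimators.
# These deliberately avoid the package's code paths: direct summation,
# generic lm() fits, exhaustive scans and dense grids.

# Origin-constrained weighted least squares by direct summation.
oracle_ivw <- function(bx, by, se_y) {
  w <- 1 / se_y^2
  beta <- sum(w * bx * by) / sum(w * bx^2)
  list(beta = beta, se_fixed = sqrt(1 / sum(w * bx^2)))
}

# Weighted regression with intercept via generic lm() on oriented data.
oracle_egger <- function(bx, by, se_y) {
  sgn <- ifelse(bx < 0, -1, 1)
  fit <- stats::lm(I(sgn * by) ~ I(sgn * bx), weights = 1 / se_y^2)
  stats::coef(fit)
}

# Exhaustive weighted-median definition: scan sorted ratios for the
# cumulative-weight crossing and interpolate.
oracle_weighted_median <- function(r, w) {
  ord <- order(r)
  r <- r[ord]
  w <- w[ord] / sum(w)
  s <- cumsum(w) - w / 2
  if (s[1] >= 0.5) return(r[1])
  i <- max(which(s < 0.5))
  if (i == length(r)) return(r[length(r)])
  r[i] + (r[i + 1] - r[i]) * (0.5 - s[i]) / (s[i + 1] - s[i])
}

# Dense-grid kernel-density maximization over the ratios.
oracle_mode <- function(r, w, phi = 1) {
  k <- length(r)
  bw <- phi * 0.9 * min(stats::sd(r), stats::IQR(r) / 1.349) * k^(-1 / 5)
  grid <- seq(min(r), max(r), length.out = 20000)
  dens <- sapply(grid, function(x) sum(w * stats::dnorm(x, r, bw)))
  grid[which.max(dens)]
}

# A random harmonized set with a known slope and optional intercept.
make_hs <- function(k, theta = 0.5, intercept = 0, se_y = 0.05,
                    se_x = 0.01, noise = TRUE, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  bx <- runif(k, 0.1, 0.6) * sample(c(-1, 1), k, replace = TRUE)
  sey <- rep(se_y, k)
  eps <- if (noise) rnorm(k, 0, se_y) else 0
  sgn <- ifelse(bx < 0, -1, 1)
  by <- intercept * sgn + theta * bx + eps
  HarmonizedSet(bx = bx, se_x = rep(se_x, k), by = by, se_y = sey)
}

# Subset a SummaryStats by ids without touching package internals.
.ssSubset_test <- function(ss, ids) {
  rec <- records(ss)
  SummaryStats(traitId(ss), rec[match(ids, rec$snp_id), ])
}

# A tidy record block for building SummaryStats fixtures in tests.
rec_df <- function(snp_id, beta, se, pval = NULL,
                   chrom = "1", pos = seq_along(snp_id) * 1e5,
                   ea = "A", oa = "G", eaf = 0.3, n = 1000) {
  if (is.null(pval)) pval <- 2 * pnorm(-abs(beta / se))
  data.frame(snp_id = snp_id, chrom = chrom, pos = pos,
             effect_allele = ea, other_allele = oa, eaf = eaf,
             beta = beta, se = se, pval = pmax(pval, 1e-300), n = n)
}
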