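#' @include instruments.R
NULL

## Shared constructor: fills OR and 95% CI from beta/se, p from the
## requested reference distribution (normal, or t when df is given).
.mkEstimate <- function(method, beta, se, nsnp, df = NULL,
                        flags = character()) {
  pval <- if (se > 0) {
    z <- beta / se
    if (is.null(df)) 2 * stats::pnorm(-abs(z)) else 2 * stats::pt(-abs(z), df)
  } else if (beta == 0) 1 else .Machine$double.xmin
  new("MREstimate", method = method, beta = beta, se = se,
      pval = min(pval, 1), or_ = exp(beta),
      ci_low = exp(beta - 1.96 * se), ci_high = exp(beta + 1.96 * se),
      nsnp = as.integer(nsnp), flags = flags)
}

.ratios <- function(h) h@by / h@bx

#' Wald ratio: single-instrument causal estimate
#'
#' beta = by / bx with the first-order standard error se_y / |bx|.
#'
#' @param bx,se_x exposure effect and SE (se_x unused by the first-order
#'   SE but kept for interface symmetry).
#' @param by,se_y outcome effect and SE.
#' @return an [MREstimate-class] with method `"Wald"`.
#' @export
waldRatio <- function(bx, se_x, by, se_y) {
  if (bx == 0) stop("Wald ratio undefined: exposure effect is zero")
  .mkEstimate("Wald", beta = by / bx, se = se_y / abs(bx), nsnp = 1L)
}

#' Inverse-variance weighted (IVW) estimator
#'
#' Weighted least squares of the outcome effects on the exposure effects
#' through the origin with weights 1/se_y^2:
#' beta = sum(w bx by) / sum(w bx^2). The fixed-effect SE is
#' sqrt(1 / sum(w bx^2)); the multiplicative random-effects model
#' (default) multiplies it by sqrt(max(Q / (k - 1), 1)) with Q Cochran's
#' Q, so the SE is never deflated below the fixed-effect value.
#'
#' @param h a [HarmonizedSet-class]; a single variant delegates to
#'   [waldRatio()].
#' @param model `"multiplicative_random"` (default) or `"fixed"`.
#' @return an [MREstimate-class].
#' @export
mrIVW <- function(h, model = c("multiplicative_random", "fixed")) {
  stopifnot(is(h, "HarmonizedSet"))
  model <- match.arg(model)
  k <- length(h@bx)
  if (k == 1L)
    return(waldRatio(h@bx, h@se_x, h@by, h@se_y))
  if (all(h@bx == 0)) stop("degenerate: every exposure effect is zero")
  w <- 1 / h@se_y^2
  sxx <- sum(w * h@bx^2)
  beta <- sum(w * h@bx * h@by) / sxx
  se <- sqrt(1 / sxx)
  flags <- character()
  if (model == "multiplicative_random") {
    q <- sum(w * (h@by - beta * h@bx)^2)
    se <- se * sqrt(max(q / (k - 1), 1))
  }
  .mkEstimate("IVW", beta, se, k, flags = flags)
}

#' MR-Egger regression
#'
#' Weighted regression of outcome effects on exposure effects with a free
#' intercept (weights 1/se_y^2), after orienting every variant so its
#' exposure effect is non-negative. The slope is the causal estimate; a
#' non-zero intercept signals directional pleiotropy. Standard errors use
#' the multiplicative random-effects convention (residual dispersion
#' floored at 1); p-values are two-sided t on nsnp - 2 df.
#'
#' @param h a [HarmonizedSet-class] with at least 3 variants and spread in
#'   |bx|.
#' @return list with elements `estimate` ([MREstimate-class], method
#'   `"MR-Egger"`) and `pleiotropy` ([PleiotropyResult-class]).
#' @export
mrEgger <- function(h) {
  stopifnot(is(h, "HarmonizedSet"))
  k <- length(h@bx)
  if (k < 3L) stop("MR-Egger needs at least 3 instruments, got ", k)
  sgn <- ifelse(h@bx < 0, -1, 1)
  bx <- sgn * h@bx
  by <- sgn * h@by
  if (diff(range(bx)) == 0)
    stop("MR-Egger unidentified: no spread in |exposure effects|")
  w <- 1 / h@se_y^2
  x <- cbind(intercept = 1, slope = bx)
  xtwx <- crossprod(x, w * x)
  coefs <- drop(solve(xtwx, crossprod(x, w * by)))
  fitted <- drop(x %*% coefs)
  sigma2 <- sum(w * (by - fitted)^2) / (k - 2)
  se_fixed <- sqrt(diag(solve(xtwx)))
  se <- se_fixed * sqrt(max(sigma2, 1))
  est <- .mkEstimate("MR-Egger", coefs[["slope"]], se[["slope"]], k,
                     df = k - 2)
  intercept <- coefs[["intercept"]]
  int_se <- se[["intercept"]]
  int_p <- if (int_se > 0)
    2 * stats::pt(-abs(intercept / int_se), k - 2) else 1
  list(estimate = est,
       pleiotropy = new("PleiotropyResult", intercept = intercept,
                        se = int_se, pval = int_p))
}

## Interpolated weighted median of ratios r with weights w (sum 1):
## cumulative weight minus half each variant's own weight, linear
## interpolation where it crosses 0.5.
.weightedMedian <- function(r, w) {
  ord <- order(r)
  r <- r[ord]
  w <- w[ord] / sum(w)
  s <- cumsum(w) - 0.5 * w
  if (s[1L] >= 0.5) return(r[1L])
  below <- max(which(s < 0.5))
  if (below == length(r)) return(r[length(r)])
  r[below] + (r[below + 1L] - r[below]) *
    (0.5 - s[below]) / (s[below + 1L] - s[below])
}

#' Weighted-median estimator
#'
#' The interpolated weighted median of the per-variant Wald ratios
#' by_j/bx_j with weights (bx_j/se_y_j)^2, consistent when at least half
#' the weight comes from valid instruments. The SE is a seeded parametric
#' bootstrap: effects are redrawn from normal(bx_j, se_x_j) and
#' normal(by_j, se_y_j) and the median recomputed.
#'
#' @param h a [HarmonizedSet-class] with at least 3 variants.
#' @param n_boot bootstrap draws (default 1000).
#' @param seed integer seed for the bootstrap.
#' @return an [MREstimate-class] with method `"weighted_median"`.
#' @export
mrWeightedMedian <- function(h, n_boot = 1000, seed = 1) {
  stopifnot(is(h, "HarmonizedSet"))
  k <- length(h@bx)
  if (k < 3L) stop("weighted median needs at least 3 instruments, got ", k)
  r <- .ratios(h)
  w <- (h@bx / h@se_y)^2
  beta <- .weightedMedian(r, w / sum(w))
  boots <- .withSeed(seed, vapply(seq_len(n_boot), function(b) {
    bx <- stats::rnorm(k, h@bx, h@se_x)
    by <- stats::rnorm(k, h@by, h@se_y)
    .weightedMedian(by / bx, (bx / h@se_y)^2)
  }, numeric(1)))
  se <- stats::sd(boots)
  .mkEstimate("weighted_median", beta, se, k)
}

## Mode machinery shared by the simple and weighted variants.
.modePoint <- function(r, w, phi) {
  k <- length(r)
  bw <- phi * 0.9 * min(stats::sd(r), stats::IQR(r) / 1.349) * k^(-1 / 5)
  if (!is.finite(bw) || bw <= 0)
    bw <- phi * 0.9 * stats::sd(r) * k^(-1 / 5)
  if (!is.finite(bw) || bw <= 0) return(list(mode = r[1L], degenerate = TRUE))
  grid <- sort(unique(c(r, seq(min(r), max(r), length.out = 1000L))))
  dens <- vapply(grid,
                 function(x) sum(w * stats::dnorm(x, mean = r, sd = bw)),
                 numeric(1))
  list(mode = grid[which.max(dens)], degenerate = FALSE)
}

#' Mode-based estimators (simple and weighted mode)
#'
#' The causal estimate is the argmax of a Gaussian-kernel density over the
#' per-variant Wald ratios: uniform kernel weights for the simple mode,
#' inverse-variance ratio weights 1/se_ratio^2 (se_ratio = se_y/|bx|) for
#' the weighted mode. The bandwidth is
#' phi * 0.9 * min(sd, IQR/1.349) * k^(-1/5) over the ratios; the density
#' is maximized over the ratios refined by a 1000-point grid across their
#' range. SE by seeded parametric bootstrap.
#'
#' @param h a [HarmonizedSet-class] with at least 3 variants.
#' @param weighted TRUE for the weighted mode, FALSE for the simple mode.
#' @param phi bandwidth inflation factor (default 1).
#' @param n_boot,seed bootstrap draws and seed.
#' @return an [MREstimate-class] (`"weighted_mode"` or `"simple_mode"`);
#'   when all ratios coincide the common ratio is returned with se 0 and a
#'   `"degenerate: all ratios equal"` flag.
#' @export
mrMode <- function(h, weighted = TRUE, phi = 1, n_boot = 1000, seed = 1) {
  stopifnot(is(h, "HarmonizedSet"), phi > 0)
  k <- length(h@bx)
  if (k < 3L) stop("mode estimators need at least 3 instruments, got ", k)
  method <- if (weighted) "weighted_mode" else "simple_mode"
  r <- .ratios(h)
  wts <- function(bx) {
    if (weighted) {
      w <- (abs(bx) / h@se_y)^2
      w / sum(w)
    } else rep(1 / k, k)
  }
  fit <- .modePoint(r, wts(h@bx), phi)
  if (fit$degenerate)
    return(.mkEstimate(method, fit$mode, 0, k,
                       flags = "degenerate: all ratios equal"))
  boots <- .withSeed(seed, vapply(seq_len(n_boot), function(b) {
    bx <- stats::rnorm(k, h@bx, h@se_x)
    by <- stats::rnorm(k, h@by, h@se_y)
    .modePoint(by / bx, wts(bx), phi)$mode
  }, numeric(1)))
  .mkEstimate(method, fit$mode, stats::sd(boots), k)
}

#' Run the five-method MR panel with diagnostics
#'
#' Dispatches by instrument count: a single variant yields only the Wald
#' ratio; two variants yield IVW; three or more yield IVW, MR-Egger,
#' weighted median, simple mode and weighted mode. Cochran's Q (IVW
#' reference, and Egger reference when available) and the Egger-intercept
#' pleiotropy test are attached. Methods not run are listed in the
#' panel's `skipped` field with the reason.
#'
#' @param h a [HarmonizedSet-class] (or [InstrumentSet-class]).
#' @param n_boot,seed bootstrap settings for the median/mode methods.
#' @param phi mode bandwidth factor.
#' @param ivw_model IVW error model (see [mrIVW()]).
#' @return an [MRPanel-class].
#' @export
runPanel <- function(h, n_boot = 1000, seed = 1, phi = 1,
                     ivw_model = "multiplicative_random") {
  if (is(h, "InstrumentSet")) h <- h@harmonized
  stopifnot(is(h, "HarmonizedSet"))
  k <- length(h@bx)
  est <- list()
  skipped <- character()
  het <- list()
  plt <- NULL

  if (k == 1L) {
    est$Wald <- waldRatio(h@bx, h@se_x, h@by, h@se_y)
    skipped <- c(IVW = "needs >= 2 instruments",
                 `MR-Egger` = "needs >= 3 instruments",
                 weighted_median = "needs >= 3 instruments",
                 simple_mode = "needs >= 3 instruments",
                 weighted_mode = "needs >= 3 instruments")
  } else {
    est$IVW <- mrIVW(h, model = ivw_model)
    het$ivw <- cochranQ(h, reference = "ivw")
    if (k >= 3L) {
      egger <- tryCatch(mrEgger(h), error = function(e) e)
      if (inherits(egger, "error")) {
        skipped <- c(skipped, `MR-Egger` = conditionMessage(egger))
      } else {
        est$`MR-Egger` <- egger$estimate
        plt <- egger$pleiotropy
        het$egger <- cochranQ(h, reference = "egger")
      }
      est$weighted_median <- mrWeightedMedian(h, n_boot = n_boot,
                                              seed = seed)
      est$simple_mode <- mrMode(h, weighted = FALSE, phi = phi,
                                n_boot = n_boot, seed = seed + 1L)
      est$weighted_mode <- mrMode(h, weighted = TRUE, phi = phi,
                                  n_boot = n_boot, seed = seed + 2L)
    } else {
      skipped <- c(skipped,
                   `MR-Egger` = "needs >= 3 instruments",
                   weighted_median = "needs >= 3 instruments",
                   simple_mode = "needs >= 3 instruments",
                   weighted_mode = "needs >= 3 instruments")
    }
  }
  new("MRPanel", exposure_id = h@exposure_id, outcome_id = h@outcome_id,
      estimates = est, heterogeneity = het, pleiotropy = plt,
      skipped = skipped)
}

#' Format an estimate the way MR studies report it
#'
#' `"OR (CI low, CI high)"` at a fixed number of decimals, e.g.
#' `"1.962 (1.298, 2.965)"`.
#'
#' @param est an [MREstimate-class].
#' @param digits decimals (default 3).
#' @return a character scalar.
#' @export
formatOR <- function(est, digits = 3) {
  stopifnot(is(est, "MREstimate"))
  fmt <- paste0("%.", digits, "f")
  sprintf(paste0(fmt, " (", fmt, ", ", fmt, ")"),
          est@or_, est@ci_low, est@ci_high)
}

#' @rdname accessors
#' @param method for `estimates(x, method)` on a panel: a method name to
#'   extract a single [MREstimate-class].
#' @export
setMethod("estimates", "MRPanel", function(x, method = NULL) {
  if (is.null(method)) return(x@estimates)
  if (!method %in% names(x@estimates))
    stop("panel holds no '", method, "' estimate")
  x@estimates[[method]]
})

#' @rdname accessors
#' @param reference for `heterogeneity(x, reference)`: `"ivw"` or
#'   `"egger"`.
#' @export
setMethod("heterogeneity", "MRPanel", function(x, reference = "ivw") {
  x@heterogeneity[[reference]]
})

#' @rdname accessors
#' @export
setMethod("pleiotropy", "MRPanel", function(x) x@pleiotropy)

#' @rdname accessors
#' @export
setMethod("nsnp", "MRPanel", function(x) x@estimates[[1L]]@nsnp)

#' @rdname asTable
#' @export
setMethod("asTable", "MREstimate", function(x, ...) {
  data.frame(method = x@method, nsnp = x@nsnp, beta = x@beta, se = x@se,
             pval = x@pval, or = x@or_, ci_low = x@ci_low,
             ci_high = x@ci_high, row.names = NULL)
})

#' @rdname asTable
#' @export
setMethod("asTable", "MRPanel", function(x, ...) {
  rows <- do.call(rbind, lapply(x@estimates, asTable))
  cbind(data.frame(exposure = x@exposure_id, outcome = x@outcome_id),
        rows, row.names = NULL)
})

setMethod("show", "MREstimate", function(object) {
  cat(object@method, ": beta = ", format(object@beta, digits = 4),
      " (se ", format(object@se, digits = 4), "), OR = ",
      formatOR(object), ", p = ", format(object@pval, digits = 3),
      ", nsnp = ", object@nsnp, "\n", sep = "")
})

setMethod("show", "MRPanel", function(object) {
  cat("MRPanel: '", object@exposure_id, "' -> '", object@outcome_id,
      "'\n", sep = "")
  for (e in object@estimates)
    cat("  ", format(e@method, width = 16), formatOR(e),
        " p =", format(e@pval, digits = 3), "\n")
  if (!is.null(object@pleiotropy))
    cat("  Egger intercept p =",
        format(object@pleiotropy@pval, digits = 3), "\n")
  if (length(object@skipped))
    cat("  skipped:", paste(names(object@skipped), collapse = ", "), "\n")
})
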