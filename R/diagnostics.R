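#' @include estimators.R
NULL

#' Cochran's Q heterogeneity test
#'
#' On the ratio scale with first-order weights w_j = (bx_j / se_y_j)^2,
#' Q = sum w_j (r_j - beta_ref)^2, which is identical to the weighted
#' residual sum of squares of the reference regression. The `"ivw"`
#' reference uses the fixed-effect IVW slope (the WLS minimizer) on
#' nsnp - 1 df; the `"egger"` reference uses the Egger fit's residuals on
#' nsnp - 2 df. Upper-tail chi-square p.
#'
#' @param h a [HarmonizedSet-class].
#' @param reference `"ivw"` (nsnp >= 2) or `"egger"` (nsnp >= 3).
#' @return a [HeterogeneityResult-class].
#' @export
cochranQ <- function(h, reference = c("ivw", "egger")) {
  stopifnot(is(h, "HarmonizedSet"))
  reference <- match.arg(reference)
  k <- length(h@bx)
  w <- 1 / h@se_y^2
  if (reference == "ivw") {
    if (k < 2L) stop("Cochran's Q (IVW) needs at least 2 instruments")
    beta <- sum(w * h@bx * h@by) / sum(w * h@bx^2)
    q <- sum(w * (h@by - beta * h@bx)^2)
    df <- k - 1L
  } else {
    if (k < 3L) stop("Cochran's Q (Egger) needs at least 3 instruments")
    sgn <- ifelse(h@bx < 0, -1, 1)
    bx <- sgn * h@bx
    by <- sgn * h@by
    x <- cbind(1, bx)
    coefs <- drop(solve(crossprod(x, w * x), crossprod(x, w * by)))
    q <- sum(w * (by - drop(x %*% coefs))^2)
    df <- k - 2L
  }
  new("HeterogeneityResult", reference = reference, q = q,
      df = as.integer(df),
      pval = stats::pchisq(q, df, lower.tail = FALSE))
}

#' Leave-one-out sensitivity analysis
#'
#' Recomputes the IVW estimate with each variant omitted in turn, plus
#' the all-variant row, to expose single-variant influence.
#'
#' @param h a [HarmonizedSet-class] with at least 3 variants.
#' @param ivw_model passed to [mrIVW()].
#' @return data.frame with nsnp + 1 rows: `omitted` (variant id or
#'   `"none (all variants)"`), `beta`, `se`, `pval`.
#' @export
leaveOneOut <- function(h, ivw_model = "multiplicative_random") {
  stopifnot(is(h, "HarmonizedSet"))
  k <- length(h@bx)
  if (k < 3L) stop("leave-one-out needs at least 3 instruments, got ", k)
  one <- function(est, label)
    data.frame(omitted = label, beta = est@beta, se = est@se,
               pval = est@pval, row.names = NULL)
  rows <- lapply(seq_len(k), function(i) {
    sub <- .hsSubset(h, h@snp_id[-i])
    one(mrIVW(sub, model = ivw_model), h@snp_id[i])
  })
  rows <- c(rows, list(one(mrIVW(h, model = ivw_model),
                           "none (all variants)")))
  do.call(rbind, rows)
}

#' Plot-ready funnel and scatter tables
#'
#' The funnel table pairs each variant's Wald ratio with its precision
#' (1 / se of the ratio); asymmetry around the IVW estimate suggests
#' directional pleiotropy. The scatter table carries the harmonized
#' effect pairs with their error bars, and a companion line table gives
#' one fitted line per method (the IVW line passes through the origin;
#' the Egger line keeps its intercept).
#'
#' @param h a [HarmonizedSet-class].
#' @param panel the matching [MRPanel-class].
#' @return list of data.frames `funnel`, `scatter`, `lines`.
#' @export
funnelScatterData <- function(h, panel) {
  stopifnot(is(h, "HarmonizedSet"), is(panel, "MRPanel"))
  r <- h@by / h@bx
  se_ratio <- h@se_y / abs(h@bx)
  funnel <- data.frame(snp_id = h@snp_id, ratio = r,
                       precision = 1 / se_ratio, row.names = NULL)
  scatter <- data.frame(snp_id = h@snp_id, bx = h@bx, se_x = h@se_x,
                        by = h@by, se_y = h@se_y, row.names = NULL)
  lines <- do.call(rbind, lapply(panel@estimates, function(e) {
    intercept <- if (e@method == "MR-Egger" &&
                     !is.null(panel@pleiotropy))
      panel@pleiotropy@intercept else 0
    data.frame(method = e@method, intercept = intercept, slope = e@beta,
               row.names = NULL)
  }))
  list(funnel = funnel, scatter = scatter, lines = lines)
}

#' Write per-pair diagnostics tables
#'
#' Emits the heterogeneity, pleiotropy and leave-one-out TSVs for one
#' exposure-outcome pair.
#'
#' @param h a [HarmonizedSet-class]; @param panel its [MRPanel-class].
#' @param dir output directory; @param prefix file-name prefix.
#' @return invisible character vector of files written.
#' @export
writeDiagnostics <- function(h, panel, dir, prefix) {
  het <- do.call(rbind, lapply(names(panel@heterogeneity), function(nm) {
    x <- panel@heterogeneity[[nm]]
    data.frame(reference = nm, q = x@q, df = x@df, pval = x@pval)
  }))
  files <- character()
  wt <- function(df, name) {
    path <- file.path(dir, paste0(prefix, "_", name, ".tsv"))
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, fileEncoding = "UTF-8")
    path
  }
  if (!is.null(het)) files <- c(files, wt(het, "heterogeneity"))
  if (!is.null(panel@pleiotropy)) {
    p <- panel@pleiotropy
    files <- c(files, wt(data.frame(intercept = p@intercept, se = p@se,
                                    pval = p@pval), "pleiotropy"))
  }
  if (length(h@bx) >= 3L)
    files <- c(files, wt(leaveOneOut(h), "leave_one_out"))
  invisible(files)
}

setMethod("show", "HeterogeneityResult", function(object) {
  cat("Cochran's Q (", object@reference, "): Q = ",
      format(object@q, digits = 4), " on ", object@df, " df, p = ",
      format(object@pval, digits = 3), "\n", sep = "")
})

setMethod("show", "PleiotropyResult", function(object) {
  cat("Egger intercept = ", format(object@intercept, digits = 4),
      " (se ", format(object@se, digits = 4), "), p = ",
      format(object@pval, digits = 3), "\n", sep = "")
})
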