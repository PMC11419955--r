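#' @include ld-matrix.R
NULL

#' Select candidate instruments by association p-value
#'
#' @param stats a [SummaryStats-class].
#' @param p_threshold retain records with `pval < p_threshold`
#'   (default 1e-5, the conventional relaxed genome-wide screen).
#' @return a [SummaryStats-class] subset, original order preserved;
#'   errors when nothing passes.
#' @export
selectCandidates <- function(stats, p_threshold = 1e-5) {
  stopifnot(is(stats, "SummaryStats"),
            p_threshold > 0, p_threshold < 1)
  keep <- stats@records$pval < p_threshold
  if (!any(keep))
    stop("no candidate instruments for '", stats@trait_id,
         "' at p < ", format(p_threshold))
  .ssSubset(stats, stats@records$snp_id[keep])
}

#' Greedy LD clumping
#'
#' Sorts candidates by ascending p-value (ties broken by variant id),
#' then repeatedly keeps the best remaining variant and discards every
#' remaining variant on the same chromosome within `window_kb` of it whose
#' squared correlation with it exceeds `r2_max`. The returned order is the
#' greedy (p-value) order, so the result does not depend on input row
#' order.
#'
#' @param candidates a [SummaryStats-class] with chrom/pos available.
#' @param ld an [LDMatrix-class] covering every candidate.
#' @param r2_max independence threshold (default 0.001).
#' @param window_kb clumping window in kilobases (default 10000).
#' @return the clumped [SummaryStats-class].
#' @export
clumpVariants <- function(candidates, ld, r2_max = 0.001,
                          window_kb = 10000) {
  stopifnot(is(candidates, "SummaryStats"), is(ld, "LDMatrix"))
  rec <- candidates@records
  missing_ld <- setdiff(rec$snp_id, ld@snp_ids)
  if (length(missing_ld))
    stop("candidates absent from the LD matrix: ",
         paste(missing_ld, collapse = ", "))
  if (any(is.na(rec$chrom)) || any(is.na(rec$pos)))
    stop("clumping needs chromosome and position for every candidate")

  ord <- order(rec$pval, rec$snp_id)
  rec <- rec[ord, ]
  r2 <- ld@r2[rec$snp_id, rec$snp_id, drop = FALSE]
  window_bp <- window_kb * 1000

  alive <- rep(TRUE, nrow(rec))
  kept <- logical(nrow(rec))
  for (i in seq_len(nrow(rec))) {
    if (!alive[i]) next
    kept[i] <- TRUE
    alive[i] <- FALSE
    prune <- alive &
      rec$chrom == rec$chrom[i] &
      abs(rec$pos - rec$pos[i]) <= window_bp &
      r2[i, ] > r2_max
    alive[prune] <- FALSE
  }
  .ssSubset(candidates, rec$snp_id[kept])
}

#' Minor-allele-frequency filter
#'
#' Retains records whose minor-allele frequency min(eaf, 1 - eaf) strictly
#' exceeds `maf_min`. Records with missing eaf are retained and tallied in
#' the attached report (`attr(result, "maf_report")` is not used; the count
#' is appended to the object's load report).
#'
#' @param stats a [SummaryStats-class].
#' @param maf_min threshold in (0, 0.5); default 0.01.
#' @return the filtered [SummaryStats-class]; warns when empty.
#' @export
mafFilter <- function(stats, maf_min = 0.01) {
  stopifnot(is(stats, "SummaryStats"), maf_min > 0, maf_min < 0.5)
  eaf <- stats@records$eaf
  maf <- pmin(eaf, 1 - eaf)
  keep <- is.na(maf) | maf > maf_min
  n_missing <- sum(is.na(maf))
  if (!any(keep)) {
    warning("MAF filter at ", maf_min, " removed every record of '",
            stats@trait_id, "'")
  }
  out <- .ssSubset(stats, stats@records$snp_id[keep])
  if (n_missing)
    out@load_report <- rbind(out@load_report,
      data.frame(reason = "missing eaf retained through MAF filter",
                 n = as.integer(n_missing)))
  out
}

#' Overall instrument-strength F statistic
#'
#' F = R^2 (N - K - 1) / (K (1 - R^2)), with R^2 the cumulative variance
#' of the exposure explained by the K instruments and N the exposure
#' sample size. F > 10 is the conventional weak-instrument bar.
#'
#' @param r2_total cumulative variance explained, in [0, 1).
#' @param n exposure sample size; must exceed k + 1.
#' @param k instrument count.
#' @return the F value.
#' @export
#' @examples
#' fStatistic(0.05, 10000, 10)  # 52.5737
fStatistic <- function(r2_total, n, k) {
  stopifnot(r2_total >= 0, r2_total < 1, k >= 1)
  if (n <= k + 1)
    stop("degenerate design: sample size ", n,
         " does not exceed k + 1 = ", k + 1)
  r2_total * (n - k - 1) / (k * (1 - r2_total))
}

#' Per-variant variance in the exposure explained
#'
#' Treating the exposure as variance-standardized, a variant with
#' effect-allele frequency p and per-allele effect beta explains
#' 2 p (1 - p) beta^2 of its variance. When the frequency is missing the
#' standard summary-statistic approximation beta^2 / (beta^2 + n se^2) is
#' used instead and the result is flagged (`attr(., "eaf_fallback")`).
#'
#' @param eaf effect-allele frequency (may be NA).
#' @param beta per-allele effect.
#' @param se,n standard error and sample size, used only by the fallback.
#' @return vector of per-variant R^2 values.
#' @export
perSnpR2 <- function(eaf, beta, se = NULL, n = NULL) {
  r2 <- 2 * eaf * (1 - eaf) * beta^2
  fallback <- is.na(eaf)
  if (any(fallback)) {
    if (is.null(se) || is.null(n))
      stop("missing eaf needs se and n for the fallback R^2")
    r2[fallback] <- beta[fallback]^2 /
      (beta[fallback]^2 + n[fallback] * se[fallback]^2)
    attr(r2, "eaf_fallback") <- which(fallback)
  }
  r2
}

#' Assemble the final instrument set with weak-instrument filtering
#'
#' Computes each harmonized variant's exposure R^2, removes variants whose
#' single-instrument F statistic (k = 1) falls below `f_min`, and reports
#' the retained count, the cumulative R^2 (capped below 1) and the overall
#' F over the retained set.
#'
#' @param harmonized a [HarmonizedSet-class].
#' @param exposure_n exposure GWAS sample size.
#' @param f_min weak-instrument bar (default 10).
#' @return an [InstrumentSet-class]; errors when every variant is weak.
#' @export
buildInstrumentSet <- function(harmonized, exposure_n, f_min = 10) {
  stopifnot(is(harmonized, "HarmonizedSet"), exposure_n > 2)
  k0 <- length(harmonized@snp_id)
  n_vec <- rep(exposure_n, k0)
  r2 <- perSnpR2(harmonized@eaf, harmonized@bx,
                 se = harmonized@se_x, n = n_vec)
  r2 <- pmin(r2, 1 - 1e-12)
  f_single <- vapply(r2, fStatistic, numeric(1), n = exposure_n, k = 1)
  weak <- f_single < f_min
  if (all(weak))
    stop("no instruments with F >= ", f_min, " for '",
         harmonized@exposure_id, "' -> '", harmonized@outcome_id, "'")
  removed <- data.frame(snp_id = harmonized@snp_id[weak],
                        f = f_single[weak], row.names = NULL)
  h <- .hsSubset(harmonized, harmonized@snp_id[!weak])
  k <- length(h@snp_id)
  r2_total <- min(sum(r2[!weak]), 1 - 1e-12)
  f_stat <- if (exposure_n > k + 1)
    fStatistic(r2_total, exposure_n, k) else NA_real_
  new("InstrumentSet", harmonized = h, k = as.integer(k),
      r2_total = r2_total, f_stat = f_stat,
      exposure_n = as.numeric(exposure_n), removed = removed)
}

#' @rdname accessors
#' @export
setMethod("nsnp", "InstrumentSet", function(x) x@k)

#' @rdname accessors
#' @export
setMethod("snpIds", "InstrumentSet", function(x) x@harmonized@snp_id)

#' Extract the harmonized effect pairs of an instrument set
#'
#' @param x an [InstrumentSet-class].
#' @return the underlying [HarmonizedSet-class].
#' @export
harmonizedSet <- function(x) {
  stopifnot(is(x, "InstrumentSet"))
  x@harmonized
}

setMethod("show", "InstrumentSet", function(object) {
  cat("InstrumentSet: ", object@k, " instruments, cumulative R2 = ",
      format(object@r2_total, digits = 4), ", F = ",
      format(object@f_stat, digits = 5), "\n", sep = "")
  if (nrow(object@removed))
    cat("  removed as weak (F < threshold):",
        nrow(object@removed), "variants\n")
})
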