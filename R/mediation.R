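#' @include diagnostics.R
NULL

#' Two-step MR mediation decomposition
#'
#' Combines three causal log-effects — exposure on mediator (beta1),
#' mediator on outcome (beta2) and exposure on outcome (beta_all, the
#' total effect) — by the product-of-coefficients rule: the indirect
#' (mediated) effect is beta1 * beta2 with delta-method standard error
#' sqrt(beta1^2 se2^2 + beta2^2 se1^2); the direct effect is
#' beta_all - indirect; the proportion mediated is indirect / beta_all.
#' The proportion's 95% interval propagates se_indirect / |beta_all| with
#' beta_all treated as fixed (set `full_delta = TRUE` to also propagate
#' se_all). The indirect effect is tested against zero with a two-sided
#' normal test.
#'
#' @param beta1,se1 exposure -> mediator effect and SE.
#' @param beta2,se2 mediator -> outcome effect and SE.
#' @param beta_all,se_all exposure -> outcome total effect and SE.
#' @param full_delta if TRUE the proportion CI also carries the total
#'   effect's uncertainty,
#'   sqrt(se_ind^2 / beta_all^2 + ind^2 se_all^2 / beta_all^4).
#' @return a [MediationResult-class]; when the indirect and total effects
#'   disagree in sign the result carries an `"inconsistent mediation"`
#'   flag (the proportion can then fall outside [0, 1]).
#' @export
#' @examples
#' twoStep(log(1.059), 0.028, log(4.295), 0.48, log(1.962), 0.21)
twoStep <- function(beta1, se1, beta2, se2, beta_all, se_all,
                    full_delta = FALSE) {
  stopifnot(se1 > 0, se2 > 0, se_all > 0)
  if (beta_all == 0)
    stop("total effect is zero: proportion mediated undefined")
  indirect <- beta1 * beta2
  se_indirect <- sqrt(beta1^2 * se2^2 + beta2^2 * se1^2)
  direct <- beta_all - indirect
  proportion <- indirect / beta_all
  se_prop <- if (full_delta)
    sqrt(se_indirect^2 / beta_all^2 +
         indirect^2 * se_all^2 / beta_all^4)
  else se_indirect / abs(beta_all)
  ci <- proportion + c(-1.96, 1.96) * se_prop
  pval <- if (se_indirect > 0)
    2 * stats::pnorm(-abs(indirect / se_indirect)) else
      as.numeric(indirect == 0)
  flags <- character()
  if (indirect != 0 && sign(indirect) != sign(beta_all))
    flags <- "inconsistent mediation"
  new("MediationResult", beta1 = beta1, se1 = se1, beta2 = beta2,
      se2 = se2, beta_all = beta_all, se_all = se_all,
      indirect = indirect, se_indirect = se_indirect, direct = direct,
      proportion = proportion, proportion_ci = ci,
      pval_indirect = pval, flags = flags)
}

## One full IVW analysis: candidate screen -> clump -> MAF filter ->
## harmonize -> weak-instrument filter -> IVW. Returns the estimate and
## the instrument set; internal to the pipeline front-ends.
.ivwAnalysis <- function(exposure, outcome, ld, settings) {
  s <- settings
  cand <- selectCandidates(exposure, p_threshold = s$p_threshold)
  cand <- clumpVariants(cand, ld, r2_max = s$r2_max,
                        window_kb = s$window_kb)
  cand <- mafFilter(cand, maf_min = s$maf_min)
  h <- harmonize(cand, outcome, palindrome_policy = s$palindrome_policy,
                 ambiguity_maf = s$ambiguity_maf)
  exposure_n <- stats::median(records(exposure)$n, na.rm = TRUE)
  iv <- buildInstrumentSet(h, exposure_n = exposure_n, f_min = s$f_min)
  list(ivw = mrIVW(iv@harmonized, model = s$ivw_model), instruments = iv)
}

#' Default analysis settings
#'
#' The thresholds every pipeline stage shares: candidate p < 1e-5 in a
#' 10000 kb clumping window at r^2 < 0.001, MAF > 0.01, per-variant
#' F >= 10, frequency-inferred palindrome orientation with ambiguity MAF
#' 0.42, multiplicative random-effects IVW, 1000 bootstrap draws.
#'
#' @param ... overrides by name.
#' @return named list of settings.
#' @export
defaultSettings <- function(...) {
  s <- list(p_threshold = 1e-5, window_kb = 10000, r2_max = 0.001,
            maf_min = 0.01, f_min = 10,
            palindrome_policy = "infer_by_eaf", ambiguity_maf = 0.42,
            ivw_model = "multiplicative_random",
            n_boot = 1000, phi = 1, seed = 1L,
            ivw_p_max = 0.01, mediator_ivw_p_max = 0.001,
            pleiotropy_p_min = 0.05, reverse_p_min = 0.05,
            full_delta = FALSE)
  override <- list(...)
  s[names(override)] <- override
  s
}

#' End-to-end two-step mediation from three summary-statistics tables
#'
#' Runs three full MR analyses — exposure on mediator (beta1), mediator
#' on outcome (beta2) and exposure on outcome (beta_all), each with
#' instrument selection, clumping, MAF and weak-instrument filtering,
#' harmonization and IVW — and combines the three IVW estimates with
#' [twoStep()]. A prerequisite of the decomposition is that the mediator
#' does not cause the exposure: a reverse MR of the mediator's
#' instruments on the exposure is run first, and a significant reverse
#' effect flags the result
#' (`"reverse causation: mediator affects exposure"`) rather than raising
#' an error.
#'
#' @param exposure,mediator,outcome [SummaryStats-class] tables.
#' @param ld an [LDMatrix-class] covering the shared panel.
#' @param settings see [defaultSettings()].
#' @return a [MediationResult-class]; the three [InstrumentSet-class]
#'   objects are attached as `attr(., "instruments")`.
#' @export
mediationPipeline <- function(exposure, mediator, outcome, ld,
                              settings = defaultSettings()) {
  step1 <- .ivwAnalysis(exposure, mediator, ld, settings)
  step2 <- .ivwAnalysis(mediator, outcome, ld, settings)
  total <- .ivwAnalysis(exposure, outcome, ld, settings)

  res <- twoStep(step1$ivw@beta, step1$ivw@se,
                 step2$ivw@beta, step2$ivw@se,
                 total$ivw@beta, total$ivw@se,
                 full_delta = isTRUE(settings$full_delta))

  rev_flag <- tryCatch({
    rev <- .ivwAnalysis(mediator, exposure, ld, settings)
    if (rev$ivw@pval < settings$reverse_p_min)
      "reverse causation: mediator affects exposure" else NULL
  }, error = function(e) "reverse check untestable: no instruments")
  if (!is.null(rev_flag)) res@flags <- c(res@flags, rev_flag)

  attr(res, "instruments") <- list(exposure_mediator = step1$instruments,
                                   mediator_outcome = step2$instruments,
                                   exposure_outcome = total$instruments)
  res
}

#' @rdname asTable
#' @export
setMethod("asTable", "MediationResult", function(x, ...) {
  data.frame(beta1 = x@beta1, se1 = x@se1, beta2 = x@beta2, se2 = x@se2,
             beta_all = x@beta_all, se_all = x@se_all,
             indirect = x@indirect, se_indirect = x@se_indirect,
             direct = x@direct, proportion = x@proportion,
             proportion_ci_low = x@proportion_ci[1L],
             proportion_ci_high = x@proportion_ci[2L],
             pval_indirect = x@pval_indirect,
             flags = paste(x@flags, collapse = "; "), row.names = NULL)
})

setMethod("show", "MediationResult", function(object) {
  cat("Two-step MR mediation\n",
      "  beta1 (exposure -> mediator)  = ",
      format(object@beta1, digits = 4), "\n",
      "  beta2 (mediator -> outcome)   = ",
      format(object@beta2, digits = 4), "\n",
      "  beta_all (total effect)       = ",
      format(object@beta_all, digits = 4), "\n",
      "  indirect = ", format(object@indirect, digits = 4),
      " (se ", format(object@se_indirect, digits = 4), "), direct = ",
      format(object@direct, digits = 4), "\n",
      "  proportion mediated = ",
      sprintf("%.2f%%", 100 * object@proportion),
      " [", sprintf("%.2f%%", 100 * object@proportion_ci[1L]), ", ",
      sprintf("%.2f%%", 100 * object@proportion_ci[2L]), "], p(indirect) = ",
      format(object@pval_indirect, digits = 3), "\n", sep = "")
  if (length(object@flags))
    cat("  flags:", paste(object@flags, collapse = "; "), "\n")
})
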