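#' @import methods
NULL

REC_COLS <- c("snp_id", "chrom", "pos", "effect_allele", "other_allele",
              "eaf", "beta", "se", "pval", "n")

#' SummaryStats: one GWAS trait's per-SNP association records
#'
#' Container for a single trait's summary statistics: one row per variant
#' with alleles, effect-allele frequency, per-allele effect (log-odds for
#' binary traits), its standard error, p-value and sample size.
#'
#' @slot trait_id single character label for the trait.
#' @slot records data.frame with columns `snp_id`, `chrom`, `pos`,
#'   `effect_allele`, `other_allele`, `eaf`, `beta`, `se`, `pval`, `n`.
#' @slot load_report data.frame (`reason`, `n`) counting records rejected
#'   while reading or constructing the object.
#' @export
setClass("SummaryStats",
  representation(trait_id = "character", records = "data.frame",
                 load_report = "data.frame"),
  prototype(trait_id = NA_character_,
            records = data.frame(),
            load_report = data.frame(reason = character(), n = integer())))

setValidity("SummaryStats", function(object) {
  msg <- character()
  r <- object@records
  if (length(object@trait_id) != 1L)
    msg <- c(msg, "trait_id must be a single string")
  miss <- setdiff(REC_COLS, names(r))
  if (length(miss))
    return(paste("records missing columns:", paste(miss, collapse = ", ")))
  if (nrow(r)) {
    if (anyDuplicated(r$snp_id))
      msg <- c(msg, "variant identifiers must be unique within a table")
    if (!all(is.finite(r$beta)))
      msg <- c(msg, "all betas must be finite")
    if (!all(is.finite(r$se) & r$se > 0))
      msg <- c(msg, "all standard errors must be > 0")
    if (!all(is.finite(r$pval) & r$pval > 0 & r$pval <= 1))
      msg <- c(msg, "p-values must lie in (0, 1]")
    ok_eaf <- is.na(r$eaf) | (r$eaf > 0 & r$eaf < 1)
    if (!all(ok_eaf))
      msg <- c(msg, "eaf must lie in (0, 1) or be missing")
    if (!all(r$effect_allele %in% c("A", "C", "G", "T")) ||
        !all(r$other_allele %in% c("A", "C", "G", "T")))
      msg <- c(msg, "alleles must be single bases A/C/G/T")
    if (any(r$effect_allele == r$other_allele))
      msg <- c(msg, "effect and other allele must differ")
    if (!all(is.na(r$pos) | r$pos >= 1))
      msg <- c(msg, "positions are 1-based (pos >= 1)")
  }
  if (length(msg)) msg else TRUE
})

#' HarmonizedSet: exposure-outcome effect pairs on a shared effect allele
#'
#' The aligned input to every MR estimator: for each retained variant the
#' exposure and outcome effects refer to the same effect allele.
#'
#' @slot exposure_id,outcome_id trait labels.
#' @slot snp_id,chrom,pos variant identity (chrom/pos retained for reports).
#' @slot bx,se_x exposure effects and standard errors.
#' @slot by,se_y outcome effects and standard errors.
#' @slot eaf aligned effect-allele frequency (exposure study).
#' @slot dropped data.frame (`snp_id`, `reason`) of shared variants removed
#'   during harmonization.
#' @export
setClass("HarmonizedSet",
  representation(exposure_id = "character", outcome_id = "character",
                 snp_id = "character", chrom = "character", pos = "numeric",
                 bx = "numeric", se_x = "numeric",
                 by = "numeric", se_y = "numeric", eaf = "numeric",
                 dropped = "data.frame"))

setValidity("HarmonizedSet", function(object) {
  k <- length(object@snp_id)
  lens <- c(length(object@chrom), length(object@pos), length(object@bx),
            length(object@se_x), length(object@by), length(object@se_y),
            length(object@eaf))
  if (k < 1L) return("a HarmonizedSet must retain at least one variant")
  if (any(lens != k)) return("all per-variant vectors must share one length")
  if (!all(is.finite(object@se_x) & object@se_x > 0) ||
      !all(is.finite(object@se_y) & object@se_y > 0))
    return("standard errors must be > 0")
  TRUE
})

#' LDMatrix: squared-correlation matrix over a variant panel
#'
#' @slot snp_ids ordered variant identifiers.
#' @slot r2 symmetric matrix of squared correlations in [0, 1] with unit
#'   diagonal, dimnames equal to `snp_ids`.
#' @export
setClass("LDMatrix",
  representation(snp_ids = "character", r2 = "matrix"))

setValidity("LDMatrix", function(object) {
  m <- object@r2
  k <- length(object@snp_ids)
  if (!is.numeric(m) || nrow(m) != k || ncol(m) != k)
    return("r2 must be a numeric matrix matching snp_ids")
  if (!isTRUE(all.equal(m, t(m), tolerance = 1e-10)))
    return("r2 must be symmetric")
  if (any(abs(diag(m) - 1) > 1e-10))
    return("r2 diagonal must be exactly 1")
  if (any(m < -1e-12 | m > 1 + 1e-12))
    return("r2 values must lie in [0, 1]")
  TRUE
})

#' InstrumentSet: harmonized variants retained as instruments
#'
#' @slot harmonized [HarmonizedSet-class] restricted to selected variants.
#' @slot k instrument count.
#' @slot r2_total cumulative variance of the exposure explained.
#' @slot f_stat overall F statistic, R^2 (N - K - 1) / (K (1 - R^2)).
#' @slot exposure_n exposure sample size used for F.
#' @slot removed data.frame (`snp_id`, `f`) of weak instruments removed.
#' @export
setClass("InstrumentSet",
  representation(harmonized = "HarmonizedSet", k = "integer",
                 r2_total = "numeric", f_stat = "numeric",
                 exposure_n = "numeric", removed = "data.frame"))

setValidity("InstrumentSet", function(object) {
  if (object@k < 1L) return("an InstrumentSet needs k >= 1 instruments")
  if (object@r2_total < 0 || object@r2_total >= 1)
    return("r2_total must lie in [0, 1)")
  if (object@f_stat < 0) return("f_stat must be >= 0")
  TRUE
})

#' MREstimate: one method's causal estimate
#'
#' @slot method one of "IVW", "MR-Egger", "weighted_median", "simple_mode",
#'   "weighted_mode", "Wald".
#' @slot beta,se,pval causal log-effect, standard error, two-sided p.
#' @slot or_,ci_low,ci_high exp(beta) and its 95% interval
#'   exp(beta -/+ 1.96 se).
#' @slot nsnp instrument count used.
#' @slot flags character notes (e.g. degenerate-input markers).
#' @export
setClass("MREstimate",
  representation(method = "character", beta = "numeric", se = "numeric",
                 pval = "numeric", or_ = "numeric", ci_low = "numeric",
                 ci_high = "numeric", nsnp = "integer", flags = "character"),
  prototype(flags = character()))

setValidity("MREstimate", function(object) {
  if (object@nsnp < 1L) return("nsnp must be >= 1")
  if (!is.finite(object@or_) || object@or_ <= 0)
    return("odds ratio must be positive")
  if (object@se > 0 &&
      !(object@ci_low < object@or_ && object@or_ < object@ci_high))
    return("confidence interval must bracket the odds ratio")
  TRUE
})

#' HeterogeneityResult: Cochran's Q heterogeneity test
#'
#' @slot reference "ivw" (df = nsnp - 1) or "egger" (df = nsnp - 2).
#' @slot q Q statistic; @slot df degrees of freedom;
#' @slot pval upper-tail chi-square p.
#' @export
setClass("HeterogeneityResult",
  representation(reference = "character", q = "numeric", df = "integer",
                 pval = "numeric"))

setValidity("HeterogeneityResult", function(object) {
  if (object@q < 0) return("Q must be >= 0")
  if (object@df < 1L) return("df must be >= 1")
  if (!(object@pval > 0 && object@pval <= 1)) return("p must lie in (0, 1]")
  TRUE
})

#' PleiotropyResult: MR-Egger intercept test for directional pleiotropy
#'
#' @slot intercept Egger intercept; @slot se its standard error;
#' @slot pval two-sided t p-value.
#' @export
setClass("PleiotropyResult",
  representation(intercept = "numeric", se = "numeric", pval = "numeric"))

setValidity("PleiotropyResult", function(object) {
  if (is.finite(object@se) && object@se <= 0)
    return("intercept standard error must be > 0 when defined")
  TRUE
})

#' MRPanel: the five-method causal-estimate bundle with diagnostics
#'
#' @slot exposure_id,outcome_id trait labels.
#' @slot estimates named list of [MREstimate-class] objects.
#' @slot heterogeneity named list of [HeterogeneityResult-class] objects
#'   ("ivw" and, when available, "egger").
#' @slot pleiotropy [PleiotropyResult-class] or NULL when MR-Egger was not
#'   estimable.
#' @slot skipped named character vector of method -> reason for methods not
#'   run at this instrument count.
#' @export
setClass("MRPanel",
  representation(exposure_id = "character", outcome_id = "character",
                 estimates = "list", heterogeneity = "list",
                 pleiotropy = "ANY", skipped = "character"),
  prototype(skipped = character()))

setValidity("MRPanel", function(object) {
  if (!length(object@estimates)) return("panel must hold >= 1 estimate")
  if (!all(vapply(object@estimates, is, TRUE, class2 = "MREstimate")))
    return("estimates must all be MREstimate objects")
  k <- object@estimates[[1L]]@nsnp
  if (k == 1L && !identical(names(object@estimates), "Wald"))
    return("a single-instrument panel holds only the Wald ratio")
  TRUE
})

#' MediationResult: two-step MR decomposition of a total effect
#'
#' @slot beta1,se1 exposure -> mediator log-effect and SE.
#' @slot beta2,se2 mediator -> outcome log-effect and SE.
#' @slot beta_all,se_all exposure -> outcome total log-effect and SE.
#' @slot indirect product beta1 * beta2; @slot se_indirect delta-method SE.
#' @slot direct beta_all - indirect.
#' @slot proportion indirect / beta_all.
#' @slot proportion_ci 95% interval for the proportion (beta_all fixed).
#' @slot pval_indirect two-sided normal test of indirect = 0.
#' @slot flags character notes ("inconsistent mediation",
#'   "reverse causation: mediator affects exposure", ...).
#' @export
setClass("MediationResult",
  representation(beta1 = "numeric", se1 = "numeric",
                 beta2 = "numeric", se2 = "numeric",
                 beta_all = "numeric", se_all = "numeric",
                 indirect = "numeric", se_indirect = "numeric",
                 direct = "numeric", proportion = "numeric",
                 proportion_ci = "numeric", pval_indirect = "numeric",
                 flags = "character"),
  prototype(flags = character()))

setValidity("MediationResult", function(object) {
  if (abs((object@direct + object@indirect) - object@beta_all) > 1e-12)
    return("direct + indirect must equal beta_all exactly")
  TRUE
})

#' ScreenCriteria: candidate-selection rules for multi-exposure screening
#'
#' @slot ivw_p_max IVW p-value must be below this.
#' @slot pleiotropy_p_min Egger-intercept p must be above this.
#' @slot require_direction_consistency all methods' odds ratios must share
#'   a direction.
#' @export
setClass("ScreenCriteria",
  representation(ivw_p_max = "numeric", pleiotropy_p_min = "numeric",
                 require_direction_consistency = "logical"))

setValidity("ScreenCriteria", function(object) {
  if (!(object@ivw_p_max > 0 && object@ivw_p_max <= 1))
    return("ivw_p_max must lie in (0, 1]")
  if (!(object@pleiotropy_p_min >= 0 && object@pleiotropy_p_min < 1))
    return("pleiotropy_p_min must lie in [0, 1)")
  TRUE
})

#' ScreenResult: outcome of screening many exposures against one outcome
#'
#' @slot table per-exposure summary with pass flags, ordered by IVW p.
#' @slot panels named list of the screened [MRPanel-class] objects.
#' @slot selected exposure ids passing every criterion.
#' @slot reverse named list of reverse-MR results for selected exposures.
#' @export
setClass("ScreenResult",
  representation(table = "data.frame", panels = "list",
                 selected = "character", reverse = "list"),
  prototype(reverse = list()))

setValidity("ScreenResult", function(object) {
  if (!all(object@selected %in% object@table$exposure_id))
    return("selected exposures must be a subset of screened exposures")
  TRUE
})

#' SimulationConfig: the causal diagram and sampling design the generator
#' realizes
#'
#' Defaults mirror a lipidomics exposure cohort (n = 771), a metabolite
#' mediator GWAS (n = 8000) and a rare binary outcome
#' (98 cases / 218,694 controls).
#'
#' @slot n_snps candidate variant panel size.
#' @slot n_exposure,n_mediator exposure/mediator GWAS sample sizes.
#' @slot n_outcome_cases,n_outcome_controls binary-outcome counts; the
#'   log-odds SE uses n_eff = 4 / (1/cases + 1/controls).
#' @slot theta_xm,theta_my,theta_xy_direct true causal log-effects
#'   (exposure->mediator, mediator->outcome, direct exposure->outcome).
#' @slot prop_causal fraction of variants with a true exposure effect
#'   (spike-and-slab); @slot slab_range magnitude interval of their
#'   effects (uniform magnitude, random sign).
#' @slot prop_mediator_specific fraction with mediator-only effects;
#' @slot mediator_slab_range magnitude interval of those effects.
#' @slot pleiotropy_sd sd of balanced per-variant direct outcome effects.
#' @slot directional_pleiotropy_mean mean shift of those effects
#'   (0 = balanced).
#' @slot maf_range interval the simulated effect-allele frequencies are
#'   drawn from, within (0, 0.5].
#' @slot ld_blocks list of c(size, r2) block definitions recycled over the
#'   panel.
#' @slot seed integer seed fully determining the draw.
#' @export
setClass("SimulationConfig",
  representation(n_snps = "integer", n_exposure = "integer",
                 n_mediator = "integer", n_outcome_cases = "integer",
                 n_outcome_controls = "integer",
                 theta_xm = "numeric", theta_my = "numeric",
                 theta_xy_direct = "numeric",
                 prop_causal = "numeric", slab_range = "numeric",
                 prop_mediator_specific = "numeric",
                 mediator_slab_range = "numeric",
                 pleiotropy_sd = "numeric",
                 directional_pleiotropy_mean = "numeric",
                 maf_range = "numeric", ld_blocks = "list",
                 seed = "integer"))

setValidity("SimulationConfig", function(object) {
  n <- c(object@n_snps, object@n_exposure, object@n_mediator,
         object@n_outcome_cases, object@n_outcome_controls)
  if (any(n < 1L)) return("panel and sample sizes must be positive")
  if (length(object@maf_range) != 2L ||
      object@maf_range[1L] <= 0 || object@maf_range[2L] > 0.5 ||
      object@maf_range[1L] > object@maf_range[2L])
    return("maf_range must be an interval within (0, 0.5]")
  if (object@pleiotropy_sd < 0) return("pleiotropy_sd must be >= 0")
  if (object@prop_causal <= 0 || object@prop_causal > 1)
    return("prop_causal must lie in (0, 1]")
  TRUE
})

#' SyntheticStudy: a linked exposure/mediator/outcome triplet with known
#' truth
#'
#' @slot exposure,mediator,outcome [SummaryStats-class] tables sharing one
#'   variant panel.
#' @slot ld the generated [LDMatrix-class].
#' @slot truth list echoing the config plus derived quantities: the true
#'   total effect theta_xm * theta_my + theta_xy_direct and the true
#'   proportion mediated.
#' @export
setClass("SyntheticStudy",
  representation(exposure = "SummaryStats", mediator = "SummaryStats",
                 outcome = "SummaryStats", ld = "LDMatrix",
                 truth = "list"))

setValidity("SyntheticStudy", function(object) {
  ids <- object@exposure@records$snp_id
  if (!identical(ids, object@mediator@records$snp_id) ||
      !identical(ids, object@outcome@records$snp_id))
    return("the three tables must share one variant panel")
  if (!identical(ids, object@ld@snp_ids))
    return("the LD matrix must cover the shared panel")
  TRUE
})
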