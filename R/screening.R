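#' @include mediation.R
NULL

#' Construct screening criteria
#'
#' @param ivw_p_max IVW p-value ceiling (0.01 for the lipid-style screen,
#'   0.001 for the metabolite-style screen).
#' @param pleiotropy_p_min Egger-intercept p floor (default 0.05).
#' @param require_direction_consistency require all methods' odds ratios
#'   on one side of 1 (default TRUE).
#' @return a [ScreenCriteria-class].
#' @export
ScreenCriteria <- function(ivw_p_max = 0.01, pleiotropy_p_min = 0.05,
                           require_direction_consistency = TRUE) {
  new("ScreenCriteria", ivw_p_max = ivw_p_max,
      pleiotropy_p_min = pleiotropy_p_min,
      require_direction_consistency = require_direction_consistency)
}

#' Are all methods' effect directions consistent?
#'
#' TRUE iff every estimate in the panel has a beta of one strict sign
#' (equivalently all odds ratios above 1 or all below 1); a beta of
#' exactly zero counts as inconsistent. A single-method panel is
#' vacuously consistent and carries `attr(., "low_information") = TRUE`.
#'
#' @param panel an [MRPanel-class].
#' @return logical flag.
#' @export
directionConsistent <- function(panel) {
  stopifnot(is(panel, "MRPanel"))
  betas <- vapply(panel@estimates, function(e) e@beta, numeric(1))
  out <- all(betas > 0) || all(betas < 0)
  if (length(betas) < 2L) {
    out <- all(betas != 0)
    attr(out, "low_information") <- TRUE
  }
  out
}

#' Screen many exposures against one outcome
#'
#' Applies the three selection rules to each panel — IVW p below
#' `ivw_p_max`, Egger-intercept p above `pleiotropy_p_min`, and (when
#' required) direction consistency across the five methods — and returns
#' every panel with its pass flags plus the selected subset, ordered by
#' IVW p ascending (ties by exposure id). A Benjamini-Hochberg FDR column
#' over the IVW p-values is emitted for transparency but takes no part in
#' selection.
#'
#' @param panels list of [MRPanel-class] objects (one per exposure).
#' @param criteria a [ScreenCriteria-class].
#' @return a [ScreenResult-class].
#' @export
screenExposures <- function(panels, criteria = ScreenCriteria()) {
  stopifnot(length(panels) > 0,
            all(vapply(panels, is, TRUE, class2 = "MRPanel")),
            is(criteria, "ScreenCriteria"))
  rows <- lapply(panels, function(p) {
    primary <- if ("IVW" %in% names(p@estimates))
      p@estimates$IVW else p@estimates[[1L]]
    plt_p <- if (is.null(p@pleiotropy)) NA_real_ else p@pleiotropy@pval
    pass_ivw <- primary@pval < criteria@ivw_p_max
    ## an untestable intercept (< 3 instruments) cannot certify absence
    ## of pleiotropy, so it fails the screen rather than passing silently
    pass_plt <- !is.na(plt_p) && plt_p > criteria@pleiotropy_p_min
    dir_ok <- directionConsistent(p)
    pass_dir <- !criteria@require_direction_consistency || isTRUE(dir_ok)
    data.frame(exposure_id = p@exposure_id, outcome_id = p@outcome_id,
               nsnp = primary@nsnp, ivw_beta = primary@beta,
               ivw_se = primary@se, ivw_pval = primary@pval,
               ivw_or = primary@or_, pleiotropy_pval = plt_p,
               direction_consistent = isTRUE(dir_ok),
               pass_ivw = pass_ivw, pass_pleiotropy = pass_plt,
               pass_direction = pass_dir,
               selected = pass_ivw && pass_plt && pass_dir,
               row.names = NULL)
  })
  tab <- do.call(rbind, rows)
  tab$ivw_fdr <- stats::p.adjust(tab$ivw_pval, method = "BH")
  ord <- order(tab$ivw_pval, tab$exposure_id)
  tab <- tab[ord, ]
  rownames(tab) <- NULL
  panels <- panels[ord]
  names(panels) <- tab$exposure_id
  new("ScreenResult", table = tab, panels = panels,
      selected = tab$exposure_id[tab$selected])
}

#' Reverse MR: outcome as exposure, exposure as outcome
#'
#' Runs the full pipeline with the roles reversed. The pair passes (no
#' evidence of reverse causation) when the reverse IVW p-value is at or
#' above `reverse_p_min`. When no instrument can be derived for the
#' reversed exposure — typical for an under-powered binary trait — the
#' pair is flagged `"untestable"` and passes, but never silently.
#'
#' @param outcome_as_exposure,exposure_as_outcome [SummaryStats-class]
#'   tables in their reversed roles.
#' @param ld an [LDMatrix-class].
#' @param settings see [defaultSettings()].
#' @return list with `panel` ([MRPanel-class] or NULL), `pass` (logical),
#'   `flag` (`"ok"`, `"reverse causation"` or `"untestable"`), and
#'   `pval`.
#' @export
reverseMR <- function(outcome_as_exposure, exposure_as_outcome, ld,
                      settings = defaultSettings()) {
  out <- tryCatch({
    res <- .ivwAnalysis(outcome_as_exposure, exposure_as_outcome, ld,
                        settings)
    panel <- runPanel(res$instruments, n_boot = settings$n_boot,
                      seed = settings$seed, phi = settings$phi,
                      ivw_model = settings$ivw_model)
    p <- res$ivw@pval
    list(panel = panel, pass = p >= settings$reverse_p_min,
         flag = if (p >= settings$reverse_p_min) "ok"
                else "reverse causation",
         pval = p)
  }, error = function(e) {
    list(panel = NULL, pass = TRUE, flag = "untestable",
         pval = NA_real_)
  })
  out
}

#' @rdname accessors
#' @export
setMethod("selectedExposures", "ScreenResult", function(x) x@selected)

#' @rdname asTable
#' @export
setMethod("asTable", "ScreenResult", function(x, ...) x@table)

setMethod("show", "ScreenResult", function(object) {
  cat("ScreenResult:", nrow(object@table), "exposures screened,",
      length(object@selected), "selected\n")
  if (length(object@selected))
    cat("  selected:", paste(object@selected, collapse = ", "), "\n")
})
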