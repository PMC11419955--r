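#' @include screening.R
NULL

#' Read a study configuration file
#'
#' YAML or JSON, by extension. Recognized keys: `exposures`, `mediators`
#' (named lists of summary-statistics file paths), `outcome`, `ld` (file
#' paths), `dialect`, `seed`, and any [defaultSettings()] name as an
#' override.
#'
#' @param path configuration file.
#' @return the configuration list.
#' @export
readStudyConfig <- function(path) {
  if (!file.exists(path)) stop("no such config file: ", path)
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path)
  else jsonlite::fromJSON(path, simplifyVector = TRUE)
}

.loadTraits <- function(x, dialect) {
  if (is(x, "SummaryStats")) return(list(x))
  if (is.list(x) && all(vapply(x, is, TRUE, class2 = "SummaryStats")))
    return(x)
  stats::setNames(
    lapply(x, readSummaryStats, dialect = dialect),
    vapply(x, function(p) sub("\\.[^.]*$", "", basename(p)), ""))
}

.writeTsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  path
}

## Full five-method analysis of one exposure against one outcome.
.panelAnalysis <- function(exposure, outcome, ld, settings) {
  res <- .ivwAnalysis(exposure, outcome, ld, settings)
  panel <- runPanel(res$instruments, n_boot = settings$n_boot,
                    seed = settings$seed, phi = settings$phi,
                    ivw_model = settings$ivw_model)
  list(panel = panel, instruments = res$instruments)
}

#' Run a full screening-and-mediation study
#'
#' Orchestrates the pipeline end to end: (1) every exposure is analysed
#' against the outcome with the five-method panel and screened (IVW
#' p < `ivw_p_max`, pleiotropy p > `pleiotropy_p_min`, direction
#' consistency); (2) selected exposures are gated by reverse MR (outcome
#' as exposure); (3) every mediator candidate is screened against the
#' outcome at the stricter `mediator_ivw_p_max`; (4) each gated exposure
#' is analysed against each selected mediator; pairs with a significant
#' exposure -> mediator effect enter (5) the two-step mediation
#' decomposition, whose prerequisite reverse check (mediator on exposure)
#' is also run. All reports are written as TSVs plus a plain-text run
#' log; identical config and seed give byte-identical outputs.
#'
#' @param config list or path to a YAML/JSON file (see
#'   [readStudyConfig()]): `exposures`, `mediators`, `outcome`, `ld`,
#'   optional `dialect`, `seed` and settings overrides. In-memory
#'   [SummaryStats-class]/[LDMatrix-class] objects are accepted in place
#'   of paths.
#' @param out_dir directory for the TSV reports (created if absent).
#' @return invisibly, a list: `screen_exposures`, `reverse`,
#'   `screen_mediators`, `mediation` (list of [MediationResult-class]),
#'   `errors` (data.frame), `files`.
#' @export
runStudy <- function(config, out_dir) {
  if (is.character(config) && length(config) == 1L)
    config <- readStudyConfig(config)
  stopifnot(is.list(config))
  dialect <- config$dialect %||% "generic"
  overrides <- config[intersect(names(config), names(defaultSettings()))]
  settings <- do.call(defaultSettings, overrides)
  if (!is.null(config$seed)) settings$seed <- as.integer(config$seed)

  exposures <- .loadTraits(config$exposures, dialect)
  mediators <- if (length(config$mediators))
    .loadTraits(config$mediators, dialect) else list()
  outcome <- if (is(config$outcome, "SummaryStats")) config$outcome
             else readSummaryStats(config$outcome, dialect = dialect)
  ld <- if (is(config$ld, "LDMatrix")) config$ld
        else readLDMatrix(config$ld)

  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  errors <- data.frame(stage = character(), trait = character(),
                       message = character())
  note <- function(stage, trait, e) {
    errors <<- rbind(errors, data.frame(stage = stage, trait = trait,
                                        message = conditionMessage(e)))
    NULL
  }

  ## stage 1: exposures vs outcome
  exp_runs <- lapply(exposures, function(ex)
    tryCatch(.panelAnalysis(ex, outcome, ld, settings),
             error = function(e) note("exposure_screen", traitId(ex), e)))
  exp_runs <- Filter(Negate(is.null), exp_runs)
  if (!length(exp_runs)) stop("no exposure could be analysed")
  screen_exp <- screenExposures(
    lapply(exp_runs, `[[`, "panel"),
    ScreenCriteria(ivw_p_max = settings$ivw_p_max,
                   pleiotropy_p_min = settings$pleiotropy_p_min))

  ## stage 2: reverse-MR gate on selected exposures
  reverse <- list()
  gated <- character()
  for (id in selectedExposures(screen_exp)) {
    ex <- exposures[[which(vapply(exposures, traitId, "") == id)]]
    rev <- reverseMR(outcome, ex, ld, settings)
    reverse[[id]] <- rev
    if (rev$pass) gated <- c(gated, id)
  }
  screen_exp@reverse <- reverse

  ## stage 3: mediator candidates vs outcome
  med_runs <- lapply(mediators, function(md)
    tryCatch(.panelAnalysis(md, outcome, ld, settings),
             error = function(e) note("mediator_screen", traitId(md), e)))
  med_runs <- Filter(Negate(is.null), med_runs)
  screen_med <- if (length(med_runs))
    screenExposures(
      lapply(med_runs, `[[`, "panel"),
      ScreenCriteria(ivw_p_max = settings$mediator_ivw_p_max,
                     pleiotropy_p_min = settings$pleiotropy_p_min))
  else NULL

  ## stages 4-5: exposure -> mediator MR and mediation decomposition
  mediation <- list()
  xm_rows <- list()
  if (!is.null(screen_med)) {
    for (ex_id in gated) {
      ex <- exposures[[which(vapply(exposures, traitId, "") == ex_id)]]
      for (md_id in selectedExposures(screen_med)) {
        md <- mediators[[which(vapply(mediators, traitId, "") == md_id)]]
        key <- paste(ex_id, md_id, sep = " -> ")
        res <- tryCatch({
          xm <- .ivwAnalysis(ex, md, ld, settings)
          xm_rows[[key]] <- cbind(
            data.frame(exposure = ex_id, mediator = md_id),
            asTable(xm$ivw))
          if (xm$ivw@pval >= 0.05) NULL else
            mediationPipeline(ex, md, outcome, ld, settings)
        }, error = function(e) note("mediation", key, e))
        if (!is.null(res)) mediation[[key]] <- res
      }
    }
  }

  ## reports
  files <- character()
  all_panels <- c(lapply(exp_runs, `[[`, "panel"),
                  lapply(med_runs, `[[`, "panel"))
  mr_tab <- do.call(rbind, lapply(all_panels, asTable))
  files <- c(files, .writeTsv(mr_tab, file.path(out_dir,
                                                "mr_results.tsv")))
  files <- c(files, .writeTsv(asTable(screen_exp),
                              file.path(out_dir, "screen_exposures.tsv")))
  rev_tab <- if (length(reverse)) data.frame(
    exposure_id = names(reverse),
    pass = vapply(reverse, `[[`, TRUE, "pass"),
    flag = vapply(reverse, `[[`, "", "flag"),
    pval = vapply(reverse, `[[`, 1, "pval"), row.names = NULL)
  else data.frame(exposure_id = character(), pass = logical(),
                  flag = character(), pval = numeric())
  files <- c(files, .writeTsv(rev_tab,
                              file.path(out_dir, "reverse_mr.tsv")))
  if (!is.null(screen_med))
    files <- c(files, .writeTsv(asTable(screen_med),
                                file.path(out_dir,
                                          "screen_mediators.tsv")))
  if (length(xm_rows))
    files <- c(files, .writeTsv(do.call(rbind, c(xm_rows,
                                                 make.row.names = FALSE)),
                                file.path(out_dir,
                                          "exposure_mediator_mr.tsv")))
  med_tab <- if (length(mediation)) cbind(
    data.frame(pair = names(mediation)),
    do.call(rbind, lapply(mediation, asTable)))
  else data.frame(pair = character())
  rownames(med_tab) <- NULL
  files <- c(files, .writeTsv(med_tab,
                              file.path(out_dir, "mediation.tsv")))
  het_tab <- do.call(rbind, lapply(all_panels, function(p) {
    do.call(rbind, lapply(names(p@heterogeneity), function(nm) {
      x <- p@heterogeneity[[nm]]
      data.frame(exposure = p@exposure_id, outcome = p@outcome_id,
                 reference = nm, q = x@q, df = x@df, pval = x@pval)
    }))
  }))
  if (!is.null(het_tab))
    files <- c(files, .writeTsv(het_tab,
                                file.path(out_dir, "heterogeneity.tsv")))
  plt_tab <- do.call(rbind, lapply(all_panels, function(p) {
    if (is.null(p@pleiotropy)) return(NULL)
    data.frame(exposure = p@exposure_id, outcome = p@outcome_id,
               intercept = p@pleiotropy@intercept,
               se = p@pleiotropy@se, pval = p@pleiotropy@pval)
  }))
  if (!is.null(plt_tab))
    files <- c(files, .writeTsv(plt_tab,
                                file.path(out_dir, "pleiotropy.tsv")))
  if (nrow(errors))
    files <- c(files, .writeTsv(errors,
                                file.path(out_dir, "errors.tsv")))

  log_lines <- c(
    paste0("TwoStepMR version: ",
           as.character(utils::packageVersion("TwoStepMR"))),
    paste0("seed: ", settings$seed),
    "settings:",
    paste0("  ", names(settings), " = ",
           vapply(settings, function(v) paste(format(v), collapse = ","),
                  "")),
    paste0("exposures: ", length(exposures)),
    paste0("mediators: ", length(mediators)),
    paste0("selected exposures: ",
           paste(selectedExposures(screen_exp), collapse = ", ")),
    paste0("reverse-MR gated exposures: ",
           paste(gated, collapse = ", ")),
    paste0("selected mediators: ",
           if (is.null(screen_med)) "none attempted (no mediators given)"
           else paste(selectedExposures(screen_med), collapse = ", ")),
    paste0("mediation results: ", length(mediation)))
  log_path <- file.path(out_dir, "run_log.txt")
  writeLines(log_lines, log_path)
  files <- c(files, log_path)

  invisible(list(screen_exposures = screen_exp, reverse = reverse,
                 screen_mediators = screen_med, mediation = mediation,
                 errors = errors, files = files))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
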