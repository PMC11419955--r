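#' @include AllClasses.R
NULL

#' Accessors for pipeline objects
#'
#' Small accessor generics so downstream code never touches slots directly:
#' `traitId()` and `records()` for [SummaryStats-class], `snpIds()` and
#' `nsnp()` for anything carrying a variant panel, `loadReport()` and
#' `droppedRecords()` for the bookkeeping of rejected rows, `estimates()`,
#' `heterogeneity()` and `pleiotropy()` for [MRPanel-class], `ldR2()` for
#' [LDMatrix-class], `selectedExposures()` for [ScreenResult-class], and
#' `studyTruth()` for [SyntheticStudy-class].
#'
#' @param x an object of the documented class.
#' @param ... passed to methods.
#' @return the slot contents as plain base-R objects.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("traitId", function(x) standardGeneric("traitId"))

#' @rdname accessors
#' @export
setGeneric("records", function(x) standardGeneric("records"))

#' @rdname accessors
#' @export
setGeneric("loadReport", function(x) standardGeneric("loadReport"))

#' @rdname accessors
#' @export
setGeneric("snpIds", function(x) standardGeneric("snpIds"))

#' @rdname accessors
#' @export
setGeneric("nsnp", function(x) standardGeneric("nsnp"))

#' @rdname accessors
#' @export
setGeneric("droppedRecords", function(x) standardGeneric("droppedRecords"))

#' @rdname accessors
#' @export
setGeneric("estimates", function(x, ...) standardGeneric("estimates"))

#' @rdname accessors
#' @export
setGeneric("heterogeneity", function(x, ...) standardGeneric("heterogeneity"))

#' @rdname accessors
#' @export
setGeneric("pleiotropy", function(x) standardGeneric("pleiotropy"))

#' @rdname accessors
#' @export
setGeneric("ldR2", function(x) standardGeneric("ldR2"))

#' @rdname accessors
#' @export
setGeneric("selectedExposures",
           function(x) standardGeneric("selectedExposures"))

#' @rdname accessors
#' @export
setGeneric("studyTruth", function(x) standardGeneric("studyTruth"))

#' Tidy one-row-per-method summaries
#'
#' `asTable()` flattens an estimate, panel, mediation or screening object
#' into the tidy data.frame the pipeline writes to its TSV reports.
#'
#' @param x an [MREstimate-class], [MRPanel-class], [MediationResult-class]
#'   or [ScreenResult-class] object.
#' @param ... passed to methods.
#' @return a data.frame.
#' @export
setGeneric("asTable", function(x, ...) standardGeneric("asTable"))
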