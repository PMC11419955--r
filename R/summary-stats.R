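#' @include AllGenerics.R
NULL

## Evaluate expr under a fixed RNG seed, restoring the caller's RNG state.
.withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

.DIALECTS <- list(
  generic = c(snp_id = "snp_id", chrom = "chrom", pos = "pos",
              effect_allele = "effect_allele",
              other_allele = "other_allele", eaf = "eaf",
              beta = "beta", se = "se", pval = "pval", n = "n"),
  gwascat = c(snp_id = "hm_rsid", chrom = "hm_chrom", pos = "hm_pos",
              effect_allele = "hm_effect_allele",
              other_allele = "hm_other_allele",
              eaf = "hm_effect_allele_frequency",
              beta = "hm_beta", se = "standard_error",
              pval = "p_value", n = "n"))

.MANDATORY <- c("snp_id", "effect_allele", "other_allele", "beta", "se",
                "pval")

## Row-level screen: returns the clean rows plus a reason-tally of the rest.
.screenRecords <- function(df) {
  df$snp_id <- as.character(df$snp_id)
  df$chrom <- as.character(df$chrom)
  df$effect_allele <- toupper(as.character(df$effect_allele))
  df$other_allele <- toupper(as.character(df$other_allele))
  for (col in c("pos", "eaf", "beta", "se", "pval", "n"))
    df[[col]] <- suppressWarnings(as.numeric(df[[col]]))

  bases <- c("A", "C", "G", "T")
  reason <- rep(NA_character_, nrow(df))
  mark <- function(bad, why) ifelse(is.na(reason) & bad, why, reason)
  reason <- mark(!(df$effect_allele %in% bases) |
                 !(df$other_allele %in% bases) |
                 df$effect_allele == df$other_allele,
                 "invalid alleles (indel, multi-allelic or identical)")
  reason <- mark(!is.finite(df$beta), "non-finite beta")
  reason <- mark(!is.finite(df$se) | df$se <= 0, "se not > 0")
  reason <- mark(!is.finite(df$pval) | df$pval <= 0 | df$pval > 1,
                 "p-value outside (0, 1]")
  reason <- mark(!is.na(df$eaf) & (df$eaf <= 0 | df$eaf >= 1),
                 "eaf outside (0, 1)")
  reason <- mark(!is.na(df$pos) & df$pos < 1, "position < 1")
  reason <- mark(is.na(df$snp_id) | df$snp_id == "", "missing variant id")
  reason <- mark(duplicated(df$snp_id), "duplicate variant id")

  tab <- table(reason[!is.na(reason)])
  list(records = df[is.na(reason), REC_COLS, drop = FALSE],
       report = data.frame(reason = names(tab), n = as.integer(tab),
                           row.names = NULL))
}

#' Construct a SummaryStats object from a data.frame
#'
#' Rows violating the record invariants (non-ACGT or identical alleles,
#' non-finite beta, se <= 0, p outside (0, 1], eaf outside (0, 1),
#' duplicate or missing ids) are dropped and tallied in the load report.
#'
#' @param trait_id single character trait label.
#' @param records data.frame with (a superset of) the generic columns
#'   `snp_id`, `chrom`, `pos`, `effect_allele`, `other_allele`, `eaf`,
#'   `beta`, `se`, `pval`, `n`; missing optional columns are filled with NA.
#' @return a validated [SummaryStats-class]; error when no row survives.
#' @export
#' @examples
#' SummaryStats("toy", data.frame(
#'   snp_id = "rs1", chrom = "1", pos = 100, effect_allele = "A",
#'   other_allele = "G", eaf = 0.3, beta = 0.1, se = 0.02,
#'   pval = 1e-6, n = 771))
SummaryStats <- function(trait_id, records) {
  stopifnot(is.character(trait_id), length(trait_id) == 1L)
  for (col in setdiff(REC_COLS, names(records)))
    records[[col]] <- NA
  miss <- setdiff(.MANDATORY, names(records))
  if (length(miss))
    stop("records lack mandatory columns: ", paste(miss, collapse = ", "))
  scr <- .screenRecords(records)
  if (!nrow(scr$records))
    stop("no valid records for trait '", trait_id,
         "' after invariant screening")
  rownames(scr$records) <- NULL
  new("SummaryStats", trait_id = trait_id, records = scr$records,
      load_report = scr$report)
}

#' Read a GWAS summary-statistics table
#'
#' Reads a tab-separated file under a column-name dialect: `"generic"`
#' (the package's own explicit names), `"gwascat"` (GWAS-Catalog
#' harmonized-file naming: hm_rsid, hm_effect_allele, hm_beta,
#' standard_error, p_value, ...), or a named character vector mapping
#' generic names to file column names.
#'
#' @param path path to a TSV file with a header row.
#' @param dialect `"generic"`, `"gwascat"`, or a named mapping
#'   `c(snp_id = "...", beta = "...", ...)`.
#' @param trait_id trait label; defaults to the file name without extension.
#' @return a [SummaryStats-class]; rejected rows are counted in
#'   `loadReport()`.
#' @seealso [writeSummaryStats()], [harmonize()]
#' @export
readSummaryStats <- function(path, dialect = "generic", trait_id = NULL) {
  if (!file.exists(path)) stop("cannot read '", path, "': no such file")
  map <- if (is.character(dialect) && length(dialect) == 1L) {
    if (!dialect %in% names(.DIALECTS))
      stop("unknown dialect '", dialect, "'")
    .DIALECTS[[dialect]]
  } else {
    stopifnot(is.character(dialect), !is.null(names(dialect)))
    dialect
  }
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE,
                           colClasses = "character", quote = "",
                           fileEncoding = "UTF-8")
  if (!nrow(raw)) stop("'", path, "' holds zero data rows")
  need <- map[.MANDATORY]
  miss <- need[!(need %in% names(raw))]
  if (length(miss))
    stop("'", path, "' lacks mandatory columns: ",
         paste(miss, collapse = ", "))
  df <- data.frame(row.names = seq_len(nrow(raw)))
  for (target in REC_COLS) {
    src <- map[[target]]
    df[[target]] <- if (!is.null(src) && src %in% names(raw))
      raw[[src]] else NA
  }
  if (is.null(trait_id))
    trait_id <- sub("\\.[^.]*$", "", basename(path))
  SummaryStats(trait_id, df)
}

#' Write a SummaryStats table in the generic dialect
#'
#' Emits a UTF-8 tab-separated file with the generic header; the file
#' round-trips through [readSummaryStats()] unchanged.
#'
#' @param x a [SummaryStats-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeSummaryStats <- function(x, path) {
  stopifnot(is(x, "SummaryStats"))
  utils::write.table(x@records, file = path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

## Restrict a SummaryStats to a subset of variant ids, preserving order of
## the ids given (internal; callers guarantee the ids exist).
.ssSubset <- function(x, ids) {
  idx <- match(ids, x@records$snp_id)
  stopifnot(!anyNA(idx))
  rec <- x@records[idx, , drop = FALSE]
  rownames(rec) <- NULL
  initialize(x, records = rec)
}

#' @rdname accessors
#' @export
setMethod("traitId", "SummaryStats", function(x) x@trait_id)

#' @rdname accessors
#' @export
setMethod("records", "SummaryStats", function(x) x@records)

#' @rdname accessors
#' @export
setMethod("loadReport", "SummaryStats", function(x) x@load_report)

#' @rdname accessors
#' @export
setMethod("snpIds", "SummaryStats", function(x) x@records$snp_id)

#' @rdname accessors
#' @export
setMethod("nsnp", "SummaryStats", function(x) nrow(x@records))

setMethod("show", "SummaryStats", function(object) {
  cat("SummaryStats for trait '", object@trait_id, "': ",
      nrow(object@records), " variants\n", sep = "")
  if (nrow(object@load_report)) {
    cat("  rejected at load:\n")
    for (i in seq_len(nrow(object@load_report)))
      cat("    ", object@load_report$n[i], " x ",
          object@load_report$reason[i], "\n", sep = "")
  }
})
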