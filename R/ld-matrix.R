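#' @include harmonize.R
NULL

#' Construct an LDMatrix
#'
#' @param r2 symmetric matrix of squared correlations with unit diagonal;
#'   row/column names are taken as the variant ids when `snp_ids` is NULL.
#' @param snp_ids variant identifiers in matrix order.
#' @return an [LDMatrix-class].
#' @export
LDMatrix <- function(r2, snp_ids = rownames(r2)) {
  if (is.null(snp_ids)) stop("snp_ids required (or name the matrix)")
  dimnames(r2) <- list(snp_ids, snp_ids)
  new("LDMatrix", snp_ids = as.character(snp_ids), r2 = r2)
}

#' Read / write a squared-correlation matrix file
#'
#' The file format is a square tab-separated matrix with a header row of
#' variant ids and the ids again in the first column.
#'
#' @param path file path.
#' @return `readLDMatrix` an [LDMatrix-class]; `writeLDMatrix` the path,
#'   invisibly.
#' @export
readLDMatrix <- function(path) {
  if (!file.exists(path)) stop("cannot read '", path, "': no such file")
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          row.names = 1, check.names = FALSE,
                          fileEncoding = "UTF-8")
  m <- as.matrix(df)
  storage.mode(m) <- "double"
  m <- (m + t(m)) / 2          # text round-trips symmetrically
  diag(m) <- 1
  LDMatrix(m, rownames(df))
}

#' @rdname readLDMatrix
#' @param x an [LDMatrix-class].
#' @export
writeLDMatrix <- function(x, path) {
  stopifnot(is(x, "LDMatrix"))
  df <- data.frame(snp_id = x@snp_ids,
                   format(x@r2, digits = 10, trim = TRUE),
                   check.names = FALSE)
  names(df) <- c("snp_id", x@snp_ids)
  utils::write.table(df, file = path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname accessors
#' @export
setMethod("snpIds", "LDMatrix", function(x) x@snp_ids)

#' @rdname accessors
#' @export
setMethod("ldR2", "LDMatrix", function(x) x@r2)

setMethod("show", "LDMatrix", function(object) {
  cat("LDMatrix over", length(object@snp_ids), "variants;",
      "mean off-diagonal r2 =",
      format(mean(object@r2[upper.tri(object@r2)]), digits = 3), "\n")
})
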