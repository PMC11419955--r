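#' @include summary-stats.R
NULL

.COMPLEMENT <- c(A = "T", T = "A", C = "G", G = "C")

.isPalindromic <- function(a1, a2) a2 == unname(.COMPLEMENT[a1])

#' Harmonize exposure and outcome effects onto a shared effect allele
#'
#' For every variant present in both tables, aligns the outcome record to
#' the exposure's effect allele: a direct allele match is kept as is; a
#' swapped match (outcome effect allele equals the exposure other allele)
#' negates the outcome beta and complements its frequency; alleles that
#' match only after complementary-strand flipping are flipped and treated
#' the same way. Palindromic variants (A/T or C/G) cannot be resolved from
#' alleles alone: under `"infer_by_eaf"` they are oriented by comparing
#' which side of 0.5 the two studies' frequencies fall on, and dropped as
#' ambiguous when either study's minor-allele frequency exceeds
#' `ambiguity_maf` (or when a frequency is missing); under `"drop_all"`
#' every palindromic variant is dropped. Incompatible allele sets are
#' dropped. Every drop is recorded with its reason.
#'
#' @param exposure,outcome [SummaryStats-class] tables.
#' @param palindrome_policy `"infer_by_eaf"` (default) or `"drop_all"`.
#' @param ambiguity_maf palindromic variants with min(eaf, 1 - eaf) above
#'   this in either study are considered unorientable; default 0.42.
#' @return a [HarmonizedSet-class]; errors when the tables share no
#'   variant or no shared variant survives.
#' @export
#' @examples
#' ex <- SummaryStats("x", data.frame(snp_id = "rs1", chrom = "1",
#'   pos = 1e5, effect_allele = "A", other_allele = "G", eaf = 0.3,
#'   beta = 0.10, se = 0.02, pval = 1e-8, n = 771))
#' out <- SummaryStats("y", data.frame(snp_id = "rs1", chrom = "1",
#'   pos = 1e5, effect_allele = "G", other_allele = "A", eaf = 0.7,
#'   beta = -0.05, se = 0.03, pval = 0.1, n = 2e5))
#' harmonize(ex, out)  # outcome beta flipped to +0.05
harmonize <- function(exposure, outcome,
                      palindrome_policy = c("infer_by_eaf", "drop_all"),
                      ambiguity_maf = 0.42) {
  stopifnot(is(exposure, "SummaryStats"), is(outcome, "SummaryStats"))
  palindrome_policy <- match.arg(palindrome_policy)
  ex <- exposure@records
  ou <- outcome@records
  shared <- intersect(ex$snp_id, ou$snp_id)
  if (!length(shared))
    stop("exposure '", exposure@trait_id, "' and outcome '",
         outcome@trait_id, "' share no variants")
  ex <- ex[match(shared, ex$snp_id), ]
  ou <- ou[match(shared, ou$snp_id), ]

  ea_x <- ex$effect_allele; oa_x <- ex$other_allele
  ea_y <- ou$effect_allele; oa_y <- ou$other_allele
  by <- ou$beta
  eaf_y <- ou$eaf

  pal_x <- .isPalindromic(ea_x, oa_x)
  pal_y <- .isPalindromic(ea_y, oa_y)
  keep <- rep(TRUE, length(shared))
  reason <- rep(NA_character_, length(shared))
  flip <- rep(FALSE, length(shared))

  same_set <- (ea_y == ea_x & oa_y == oa_x)
  swap_set <- (ea_y == oa_x & oa_y == ea_x)
  comp_same <- (unname(.COMPLEMENT[ea_y]) == ea_x &
                unname(.COMPLEMENT[oa_y]) == oa_x)
  comp_swap <- (unname(.COMPLEMENT[ea_y]) == oa_x &
                unname(.COMPLEMENT[oa_y]) == ea_x)

  ## palindromic pairs with a compatible allele set: a reported label swap
  ## is indistinguishable from a strand flip, so labels are first aligned
  ## and orientation is then inferred from frequency (or the pair dropped)
  pal <- pal_x & pal_y & (same_set | swap_set)

  idx_pal <- which(pal & keep)
  if (length(idx_pal)) {
    if (palindrome_policy == "drop_all") {
      keep[idx_pal] <- FALSE
      reason[idx_pal] <- "palindromic (policy drop_all)"
    } else {
      for (i in idx_pal) {
        fx <- ex$eaf[i]; fy <- eaf_y[i]
        if (swap_set[i] && !is.na(fy)) fy <- 1 - fy   # label alignment
        if (is.na(fx) || is.na(fy)) {
          keep[i] <- FALSE
          reason[i] <- "palindromic with missing eaf"
        } else if (min(fx, 1 - fx) > ambiguity_maf ||
                   min(fy, 1 - fy) > ambiguity_maf) {
          keep[i] <- FALSE
          reason[i] <- "palindromic, frequency too close to 0.5"
        } else {
          strand_flip <- (fx < 0.5) != (fy < 0.5)
          ## net sign flip: label swap XOR inferred strand flip
          flip[i] <- xor(isTRUE(swap_set[i]), strand_flip)
        }
      }
    }
  }

  idx_rest <- which(!pal & keep)
  for (i in idx_rest) {
    if (same_set[i] || comp_same[i]) {
      # aligned (possibly after strand flip): keep as is
    } else if (swap_set[i] || comp_swap[i]) {
      flip[i] <- TRUE
    } else {
      keep[i] <- FALSE
      reason[i] <- "incompatible alleles"
    }
  }

  by[flip] <- -by[flip]
  eaf_y[flip] <- 1 - eaf_y[flip]

  if (!any(keep))
    stop("no shared variant survived harmonization between '",
         exposure@trait_id, "' and '", outcome@trait_id, "'")

  dropped <- data.frame(snp_id = shared[!keep], reason = reason[!keep],
                        row.names = NULL, stringsAsFactors = FALSE)
  new("HarmonizedSet",
      exposure_id = exposure@trait_id, outcome_id = outcome@trait_id,
      snp_id = shared[keep], chrom = ex$chrom[keep], pos = ex$pos[keep],
      bx = ex$beta[keep], se_x = ex$se[keep],
      by = by[keep], se_y = ou$se[keep], eaf = ex$eaf[keep],
      dropped = dropped)
}

## Restrict a HarmonizedSet to variant ids (internal).
.hsSubset <- function(h, ids) {
  idx <- match(ids, h@snp_id)
  stopifnot(!anyNA(idx))
  initialize(h, snp_id = h@snp_id[idx], chrom = h@chrom[idx],
             pos = h@pos[idx], bx = h@bx[idx], se_x = h@se_x[idx],
             by = h@by[idx], se_y = h@se_y[idx], eaf = h@eaf[idx])
}

#' Build a HarmonizedSet directly from aligned vectors
#'
#' Constructor for already-aligned effect pairs, used by simulations and
#' tests that bypass the allele-matching step.
#'
#' @param bx,se_x,by,se_y aligned exposure/outcome effects and SEs.
#' @param snp_id optional variant ids (defaults to snp1..snpK).
#' @param eaf,chrom,pos optional annotation.
#' @param exposure_id,outcome_id trait labels.
#' @return a [HarmonizedSet-class].
#' @export
HarmonizedSet <- function(bx, se_x, by, se_y,
                          snp_id = paste0("snp", seq_along(bx)),
                          eaf = rep(NA_real_, length(bx)),
                          chrom = rep(NA_character_, length(bx)),
                          pos = rep(NA_real_, length(bx)),
                          exposure_id = "exposure",
                          outcome_id = "outcome") {
  k <- length(bx)
  rec <- function(v) rep(v, length.out = k)   # scalar recycling
  new("HarmonizedSet", exposure_id = exposure_id, outcome_id = outcome_id,
      snp_id = as.character(rec(snp_id)), chrom = as.character(rec(chrom)),
      pos = as.numeric(rec(pos)), bx = as.numeric(bx),
      se_x = as.numeric(rec(se_x)), by = as.numeric(rec(by)),
      se_y = as.numeric(rec(se_y)), eaf = as.numeric(rec(eaf)),
      dropped = data.frame(snp_id = character(), reason = character()))
}

#' @rdname accessors
#' @export
setMethod("snpIds", "HarmonizedSet", function(x) x@snp_id)

#' @rdname accessors
#' @export
setMethod("nsnp", "HarmonizedSet", function(x) length(x@snp_id))

#' @rdname accessors
#' @export
setMethod("droppedRecords", "HarmonizedSet", function(x) x@dropped)

#' @rdname accessors
#' @export
setMethod("records", "HarmonizedSet", function(x)
  data.frame(snp_id = x@snp_id, chrom = x@chrom, pos = x@pos,
             bx = x@bx, se_x = x@se_x, by = x@by, se_y = x@se_y,
             eaf = x@eaf, row.names = NULL, stringsAsFactors = FALSE))

setMethod("show", "HarmonizedSet", function(object) {
  cat("HarmonizedSet: '", object@exposure_id, "' -> '", object@outcome_id,
      "', ", length(object@snp_id), " aligned variants (",
      nrow(object@dropped), " dropped)\n", sep = "")
})
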