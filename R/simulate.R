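#' @include run-study.R
NULL

#' Construct a simulation configuration
#'
#' Defaults realize the study conditions the pipeline is built for: a
#' lipid-species exposure GWAS (n = 7174), a plasma-metabolite mediator
#' GWAS (n = 8000) and a rare binary disease outcome
#' (98 cases / 218,694 controls, log-odds scale with effective sample
#' size 4 / (1/cases + 1/controls)). Variant effects on the exposure
#' follow a spike-and-slab architecture: a fraction `prop_causal` of
#' variants carries an effect whose magnitude is uniform over
#' `slab_range` with random sign — the large-effect QTL regime of
#' specialized molecular-trait GWAS. An independent fraction
#' `prop_mediator_specific` carries mediator-only effects, so mediator
#' instruments exist that are not exposure instruments. LD is
#' block-diagonal: `ld_blocks` entries c(size, r2) are recycled across
#' the panel, each block on its own stretch of genome.
#'
#' @param n_snps panel size (default 400).
#' @param n_exposure,n_mediator continuous-trait GWAS sample sizes.
#' @param n_outcome_cases,n_outcome_controls binary-outcome counts.
#' @param theta_xm,theta_my,theta_xy_direct true causal log-effects.
#' @param prop_causal,slab_range exposure genetic architecture.
#' @param prop_mediator_specific,mediator_slab_range mediator-only
#'   architecture.
#' @param pleiotropy_sd,directional_pleiotropy_mean per-variant direct
#'   outcome effects: sd and mean (0/0 = none).
#' @param maf_range effect-allele frequency interval.
#' @param ld_blocks list of c(size, within-block r2).
#' @param seed integer seed.
#' @return a validated [SimulationConfig-class].
#' @export
SimulationConfig <- function(n_snps = 400L, n_exposure = 7174L,
                             n_mediator = 8000L,
                             n_outcome_cases = 98L,
                             n_outcome_controls = 218694L,
                             theta_xm = 0.2, theta_my = 0.6,
                             theta_xy_direct = 0.1,
                             prop_causal = 0.085,
                             slab_range = c(0.10, 0.25),
                             prop_mediator_specific = 0.055,
                             mediator_slab_range = c(0.12, 0.30),
                             pleiotropy_sd = 0,
                             directional_pleiotropy_mean = 0,
                             maf_range = c(0.10, 0.40),
                             ld_blocks = list(c(5, 0.3)),
                             seed = 1L) {
  new("SimulationConfig", n_snps = as.integer(n_snps),
      n_exposure = as.integer(n_exposure),
      n_mediator = as.integer(n_mediator),
      n_outcome_cases = as.integer(n_outcome_cases),
      n_outcome_controls = as.integer(n_outcome_controls),
      theta_xm = theta_xm, theta_my = theta_my,
      theta_xy_direct = theta_xy_direct,
      prop_causal = prop_causal, slab_range = slab_range,
      prop_mediator_specific = prop_mediator_specific,
      mediator_slab_range = mediator_slab_range,
      pleiotropy_sd = pleiotropy_sd,
      directional_pleiotropy_mean = directional_pleiotropy_mean,
      maf_range = maf_range, ld_blocks = ld_blocks,
      seed = as.integer(seed))
}

.ALLELE_PAIRS <- {
  b <- c("A", "C", "G", "T")
  p <- expand.grid(effect = b, other = b, stringsAsFactors = FALSE)
  p[p$effect != p$other, ]
}

## Lay ld_blocks out over the panel: each block on its own chromosome
## stretch, members 10 kb apart, blocks 50 Mb apart so the clumping
## window never spans blocks.
.layoutBlocks <- function(n_snps, ld_blocks) {
  sizes <- vapply(ld_blocks, `[`, numeric(1), 1L)
  r2s <- vapply(ld_blocks, `[`, numeric(1), 2L)
  block <- integer(0); block_r2 <- numeric(0)
  b <- 0L
  while (length(block) < n_snps) {
    i <- (b %% length(sizes)) + 1L
    b <- b + 1L
    block <- c(block, rep(b, sizes[i]))
    block_r2 <- c(block_r2, rep(r2s[i], sizes[i]))
  }
  block <- block[seq_len(n_snps)]
  block_r2 <- block_r2[seq_len(n_snps)]
  chrom <- as.character(((block - 1L) %% 22L) + 1L)
  tier <- (block - 1L) %/% 22L           # blocks stacked along a chromosome
  within <- stats::ave(block, block, FUN = seq_along)
  pos <- 1e6 + tier * 5e7 + (within - 1L) * 1e4
  list(block = block, block_r2 = block_r2, chrom = chrom, pos = pos)
}

#' Simulate a linked exposure/mediator/outcome summary-statistics triplet
#'
#' Draws effect-allele frequencies uniformly over `maf_range`, plants
#' spike-and-slab exposure effects and mediator-specific effects, and
#' emits the three GWAS tables on their native scales: exposure effects
#' with se = 1/sqrt(2 p (1-p) n_exposure); mediator effects
#' theta_xm * beta_x_true + alpha_m at the mediator sample size; binary
#' outcome log-odds (theta_xm theta_my + theta_xy_direct) * beta_x_true +
#' theta_my * alpha_m + pleiotropy, with
#' se = 1/sqrt(2 p (1-p) n_eff), n_eff = 4/(1/cases + 1/controls).
#' P-values are two-sided normal from beta/se. The LD matrix is
#' block-diagonal per `ld_blocks`. Fully determined by `config@seed`.
#'
#' @param config a [SimulationConfig-class].
#' @return a [SyntheticStudy-class].
#' @export
simulateStudy <- function(config) {
  stopifnot(is(config, "SimulationConfig"))
  validObject(config)
  c_ <- config
  n <- c_@n_snps
  lay <- .layoutBlocks(n, c_@ld_blocks)

  .withSeed(c_@seed, {
    eaf <- stats::runif(n, c_@maf_range[1L], c_@maf_range[2L])
    pair <- .ALLELE_PAIRS[sample.int(nrow(.ALLELE_PAIRS), n,
                                     replace = TRUE), ]
    n_causal <- max(1L, round(c_@prop_causal * n))
    causal <- sample.int(n, n_causal)
    beta_x_true <- numeric(n)
    beta_x_true[causal] <- sample(c(-1, 1), n_causal, replace = TRUE) *
      stats::runif(n_causal, c_@slab_range[1L], c_@slab_range[2L])

    n_medspec <- round(c_@prop_mediator_specific * n)
    medspec <- if (n_medspec > 0)
      sample(setdiff(seq_len(n), causal), min(n_medspec, n - n_causal))
    else integer(0)
    alpha_m <- numeric(n)
    alpha_m[medspec] <- sample(c(-1, 1), length(medspec),
                               replace = TRUE) *
      stats::runif(length(medspec), c_@mediator_slab_range[1L],
                   c_@mediator_slab_range[2L])

    var_snp <- 2 * eaf * (1 - eaf)
    se_x <- 1 / sqrt(var_snp * c_@n_exposure)
    se_m <- 1 / sqrt(var_snp * c_@n_mediator)
    n_eff <- 4 / (1 / c_@n_outcome_cases + 1 / c_@n_outcome_controls)
    se_y <- 1 / sqrt(var_snp * n_eff)

    theta_total <- c_@theta_xm * c_@theta_my + c_@theta_xy_direct
    pleio <- if (c_@pleiotropy_sd > 0 ||
                 c_@directional_pleiotropy_mean != 0)
      stats::rnorm(n, c_@directional_pleiotropy_mean, c_@pleiotropy_sd)
    else numeric(n)

    bx <- beta_x_true + stats::rnorm(n, 0, se_x)
    bm <- c_@theta_xm * beta_x_true + alpha_m + stats::rnorm(n, 0, se_m)
    by <- theta_total * beta_x_true + c_@theta_my * alpha_m + pleio +
      stats::rnorm(n, 0, se_y)

    mk <- function(trait_id, beta, se, n_sample) {
      p <- pmax(2 * stats::pnorm(-abs(beta / se)), .Machine$double.xmin)
      SummaryStats(trait_id, data.frame(
        snp_id = sprintf("rs%05d", seq_len(n)), chrom = lay$chrom,
        pos = lay$pos, effect_allele = pair$effect,
        other_allele = pair$other, eaf = eaf, beta = beta, se = se,
        pval = p, n = n_sample))
    }
    exposure <- mk("exposure", bx, se_x, c_@n_exposure)
    mediator <- mk("mediator", bm, se_m, c_@n_mediator)
    outcome <- mk("outcome", by, se_y,
                  c_@n_outcome_cases + c_@n_outcome_controls)

    r2 <- diag(1, n)
    for (b in unique(lay$block)) {
      idx <- which(lay$block == b)
      if (length(idx) > 1L)
        r2[idx, idx] <- lay$block_r2[idx[1L]] +
          diag(1 - lay$block_r2[idx[1L]], length(idx))
    }
    ld <- LDMatrix(r2, snp_ids = sprintf("rs%05d", seq_len(n)))

    truth <- list(
      config = list(
        n_snps = n, n_exposure = c_@n_exposure,
        n_mediator = c_@n_mediator,
        n_outcome_cases = c_@n_outcome_cases,
        n_outcome_controls = c_@n_outcome_controls,
        theta_xm = c_@theta_xm, theta_my = c_@theta_my,
        theta_xy_direct = c_@theta_xy_direct,
        prop_causal = c_@prop_causal, slab_range = c_@slab_range,
        prop_mediator_specific = c_@prop_mediator_specific,
        mediator_slab_range = c_@mediator_slab_range,
        pleiotropy_sd = c_@pleiotropy_sd,
        directional_pleiotropy_mean = c_@directional_pleiotropy_mean,
        maf_range = c_@maf_range, seed = c_@seed),
      theta_total = theta_total,
      proportion = if (theta_total != 0)
        c_@theta_xm * c_@theta_my / theta_total else NA_real_,
      n_eff = n_eff,
      causal_ids = sprintf("rs%05d", sort(causal)),
      mediator_specific_ids = sprintf("rs%05d", sort(medspec)),
      beta_x_true = beta_x_true, alpha_m = alpha_m)

    new("SyntheticStudy", exposure = exposure, mediator = mediator,
        outcome = outcome, ld = ld, truth = truth)
  })
}

#' Simulate an unlinked trait on an existing study's variant panel
#'
#' Generates a further exposure-like trait with its own planted
#' instruments and no causal connection to the study's outcome; used to
#' assemble multi-exposure screening designs.
#'
#' @param study a [SyntheticStudy-class].
#' @param trait_id label for the new trait.
#' @param n_sample GWAS sample size.
#' @param n_instruments planted instrument count.
#' @param slab_range magnitude interval of planted effects.
#' @param seed integer seed.
#' @return a [SummaryStats-class] on the shared panel.
#' @export
simulateNullTrait <- function(study, trait_id, n_sample = 7174L,
                              n_instruments = 15L,
                              slab_range = c(0.10, 0.25), seed = 1L) {
  stopifnot(is(study, "SyntheticStudy"))
  rec <- study@exposure@records
  n <- nrow(rec)
  .withSeed(seed, {
    se_t <- 1 / sqrt(2 * rec$eaf * (1 - rec$eaf) * n_sample)
    beta_true <- numeric(n)
    idx <- sample.int(n, n_instruments)
    beta_true[idx] <- sample(c(-1, 1), n_instruments, replace = TRUE) *
      stats::runif(n_instruments, slab_range[1L], slab_range[2L])
    beta <- beta_true + stats::rnorm(n, 0, se_t)
    p <- pmax(2 * stats::pnorm(-abs(beta / se_t)), .Machine$double.xmin)
    SummaryStats(trait_id, data.frame(
      snp_id = rec$snp_id, chrom = rec$chrom, pos = rec$pos,
      effect_allele = rec$effect_allele, other_allele = rec$other_allele,
      eaf = rec$eaf, beta = beta, se = se_t, pval = p, n = n_sample))
  })
}

#' Write a synthetic study to disk
#'
#' Emits the three generic-dialect TSVs, the LD matrix file and a truth
#' JSON into `dir`.
#'
#' @param study a [SyntheticStudy-class].
#' @param dir output directory (created if absent).
#' @return invisible character vector of files written.
#' @export
writeStudy <- function(study, dir) {
  stopifnot(is(study, "SyntheticStudy"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  files <- c(
    writeSummaryStats(study@exposure, file.path(dir, "exposure.tsv")),
    writeSummaryStats(study@mediator, file.path(dir, "mediator.tsv")),
    writeSummaryStats(study@outcome, file.path(dir, "outcome.tsv")),
    writeLDMatrix(study@ld, file.path(dir, "ld_matrix.tsv")))
  truth <- study@truth
  truth$beta_x_true <- NULL   # keep the JSON compact; tables carry the rest
  truth$alpha_m <- NULL
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(c(files, file.path(dir, "truth.json")))
}

#' @rdname accessors
#' @export
setMethod("studyTruth", "SyntheticStudy", function(x) x@truth)

setMethod("show", "SyntheticStudy", function(object) {
  t <- object@truth
  cat("SyntheticStudy: ", nsnp(object@exposure), " variants; true",
      " theta_xm = ", t$config$theta_xm, ", theta_my = ",
      t$config$theta_my, ", direct = ", t$config$theta_xy_direct,
      "; true proportion mediated = ",
      format(t$proportion, digits = 4), "\n", sep = "")
})

setMethod("show", "SimulationConfig", function(object) {
  cat("SimulationConfig: ", object@n_snps, " variants, exposure n = ",
      object@n_exposure, ", mediator n = ", object@n_mediator,
      ", outcome ", object@n_outcome_cases, "/",
      object@n_outcome_controls, " cases/controls, seed ", object@seed,
      "\n", sep = "")
})
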