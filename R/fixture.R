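#' @include simulate.R
NULL

.FIXTURE_SEED <- 104729L

#' The bundled benchmark study
#'
#' A fixed-seed synthetic study shaped like a lipid -> metabolite ->
#' melanoma mediation analysis: true causal log-effects are set so the
#' three true odds ratios are 1.059 (exposure on mediator), 4.295
#' (mediator on outcome) and 1.962 (total effect on outcome), giving a
#' true proportion mediated of 12.40%; the planted genetic architecture
#' is sized so the default selection pipeline retains close to 28
#' exposure instruments and 18 mediator instruments. Used as the
#' integration-test fixture throughout the package.
#'
#' @param seed integer seed (fixed by default; change it to draw a
#'   different realization of the same design).
#' @return a [SyntheticStudy-class].
#' @export
#' @examples
#' st <- exampleStudy()
#' studyTruth(st)$proportion   # 0.124
exampleStudy <- function(seed = .FIXTURE_SEED) {
  theta_xm <- log(1.059)
  theta_my <- log(4.295)
  theta_total <- log(1.962)
  cfg <- SimulationConfig(
    theta_xm = theta_xm, theta_my = theta_my,
    theta_xy_direct = theta_total - theta_xm * theta_my,
    prop_mediator_specific = 0.0475,
    seed = seed)
  st <- simulateStudy(cfg)
  st@exposure <- initialize(st@exposure, trait_id = "synthetic_lipid")
  st@mediator <- initialize(st@mediator,
                            trait_id = "synthetic_metabolite")
  st@outcome <- initialize(st@outcome, trait_id = "synthetic_melanoma")
  validObject(st)
  st
}

#' Configuration for the bundled multi-exposure toy study
#'
#' Wraps [exampleStudy()] into a [runStudy()] configuration with extra
#' unlinked traits: 5 exposures (the causal lipid plus 4 null lipids)
#' and 3 mediator candidates (the causal metabolite plus 2 null
#' metabolites), all on the shared variant panel. Only the causal pair
#' should survive screening, so the full run yields exactly one
#' mediation decomposition.
#'
#' @param seed integer seed for the study draw (null-trait seeds are
#'   derived from it).
#' @return a configuration list for [runStudy()].
#' @export
exampleRunConfig <- function(seed = .FIXTURE_SEED) {
  st <- exampleStudy(seed)
  nulls_x <- lapply(1:4, function(i)
    simulateNullTrait(st, paste0("null_lipid_", i),
                      seed = seed + i))
  nulls_m <- lapply(1:2, function(i)
    simulateNullTrait(st, paste0("null_metabolite_", i),
                      n_sample = 8000L, n_instruments = 12L,
                      slab_range = c(0.12, 0.30), seed = seed + 10L + i))
  list(exposures = c(list(st@exposure), nulls_x),
       mediators = c(list(st@mediator), nulls_m),
       outcome = st@outcome, ld = st@ld, seed = seed)
}
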