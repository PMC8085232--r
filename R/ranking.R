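# Scenario ranking against the bias-corrected archaeological arrival
# surface: Spearman rank correlation of the two maps and marginal
# relative-change summaries per scenario factor.

#' Convert a modelled first-arrival map to years BP
#'
#' First arrival is recorded in generations since entry; for comparison with
#' the archaeological surface it is converted to
#' `entryAgeKa * 1000 - generation * generationYears`.
#'
#' @param arrivalGenerations matrix of first-arrival generations (`NA`
#'   unreached).
#' @param entryAgeKa scenario entry age (ka).
#' @param generationYears generation length (years).
#' @return Matrix of arrival ages in years BP.
#' @export
arrivalYearsBP <- function(arrivalGenerations, entryAgeKa,
                           generationYears = 27.9) {
  entryAgeKa * 1000 - arrivalGenerations * generationYears
}

#' Spearman rank correlation between two arrival maps
#'
#' Computed over the intersection of cells defined (non-`NA`) in both maps,
#' with ties mid-ranked; fewer than 3 common cells is an error.
#'
#' @param modelMap,archaeoMap numeric matrices on the same grid.
#' @return Spearman's rho.
#' @export
spearmanMapCorrelation <- function(modelMap, archaeoMap) {
  stopifnot(identical(dim(modelMap), dim(archaeoMap)))
  common <- !is.na(modelMap) & !is.na(archaeoMap)
  if (sum(common) < 3)
    stop("need at least 3 cells defined in both maps (got ", sum(common), ")")
  cor(modelMap[common], archaeoMap[common], method = "spearman")
}

#' Rank scenarios by relative change in Spearman's rho
#'
#' Computes each scenario's relative change versus the top-ranked scenario,
#' `dRho = (rho - rho_top) / |rho_top|` (0 for the top scenario), and
#' marginal means with standard errors per factor level.
#'
#' @param scores data.frame with a `rho` column plus any factor columns
#'   (e.g. `entryAgeKa`, `sequence`, `kModel`).
#' @param factors character names of the factor columns to marginalize over.
#' @return List with `scores` (the input plus `dRho`, sorted by `rho`
#'   descending) and `marginals` (a data.frame of factor, level, mean dRho,
#'   SE and n).
#' @export
rankScenarios <- function(scores, factors = intersect(
                            c("entryAgeKa", "sequence", "kModel"),
                            names(scores))) {
  if (nrow(scores) < 2) stop("need at least 2 scenarios to rank")
  rhoTop <- max(scores$rho)
  scores$dRho <- if (abs(rhoTop) > 0) (scores$rho - rhoTop) / abs(rhoTop)
                 else scores$rho - rhoTop
  scores <- scores[order(-scores$rho), ]
  marg <- do.call(rbind, lapply(factors, function(f) {
    lv <- split(scores$dRho, scores[[f]])
    data.frame(
      factor = f,
      level = names(lv),
      meanDRho = vapply(lv, mean, 0),
      se = vapply(lv, function(v) if (length(v) > 1) sd(v) / sqrt(length(v)) else 0, 0),
      n = vapply(lv, length, 0L),
      row.names = NULL
    )
  }))
  list(scores = scores, marginals = marg)
}

#' Score an ensemble against an arrival surface
#'
#' Convenience wrapper: converts the ensemble's mean arrival map to years BP
#' and correlates it with the corrected archaeological surface.
#'
#' @param ensemble an [EnsembleResult-class].
#' @param surface an [ArrivalSurface-class].
#' @param generationYears generation length (years).
#' @return Spearman's rho.
#' @export
scoreEnsemble <- function(ensemble, surface, generationYears = 27.9) {
  modelBP <- arrivalYearsBP(ensemble@meanArrival,
                            ensemble@scenario@entryAgeKa, generationYears)
  spearmanMapCorrelation(modelBP, arrivalEstimate(surface))
}
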