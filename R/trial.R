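#' Build an alpha-lattice-style trial layout
#'
#' Each replicate contains every genotype exactly once; within a replicate
#' genotypes are allocated to incomplete blocks by a seeded random
#' permutation (the downstream adjustment model only needs the replicate and
#' block-within-replicate factors, not a formal alpha-design generator).
#'
#' @param lines character genotype ids.
#' @param env environment id.
#' @param nReps replicates (2 in the standard two-replicate lattice).
#' @param blockSize plots per incomplete block.
#' @param seed integer seed.
#' @return data.frame with columns env, rep, block, genotype.
#' @export
makeTrialLayout <- function(lines, env = "E1", nReps = 2L, blockSize = NULL,
                            seed = 1L) {
  n <- length(lines)
  if (is.null(blockSize)) {
    blockSize <- max(2L, round(sqrt(n)))
  }
  withSeed(seed, {
    do.call(rbind, lapply(seq_len(nReps), function(r) {
      ord <- sample(lines)
      blk <- ceiling(seq_along(ord) / blockSize)
      data.frame(env = env, rep = r, block = blk, genotype = ord,
                 stringsAsFactors = FALSE)
    }))
  })
}

#' Simulate plot-level yields for one environment
#'
#' Plot yield = environment mean + genotype value + replicate effect +
#' block-within-replicate effect + dhEffect * (DH - mean DH) + residual.
#' The residual variance is solved from the line-mean heritability identity
#' `H2 = varG / (varG + varE / r)`, i.e. `varE = r varG (1 - H2) / H2`
#' with r the replicate count. Because the heading-date covariate is itself
#' heritable, the adjustment model removes the genetic variance collinear
#' with it; `varG` is therefore taken as the variance of the genetic values
#' residualized on the covariate — the genotypic variance the adjustment
#' model actually estimates — so the model recovers the requested H2 in
#' expectation.
#'
#' @param values named per-line genetic values for this environment.
#' @param dh named per-line days-to-heading covariate values.
#' @param layout a layout from [makeTrialLayout()].
#' @param targetH2 target line-mean heritability in (0, 1).
#' @param dhEffect covariate effect on yield per day.
#' @param envMean intercept (t/ha).
#' @param repSD,blockSD standard deviations of replicate and block effects,
#'   expressed as fractions of the genetic SD.
#' @param dhPlotSD plot-to-plot noise on the recorded covariate (days).
#' @param seed integer seed.
#' @return A plot table data.frame: env, rep, block, genotype, DH, GY.
#' @export
simulateTrial <- function(values, dh, layout, targetH2 = 0.6,
                          dhEffect = -0.05, envMean = 5,
                          repSD = 0.3, blockSD = 0.5, dhPlotSD = 0.3,
                          seed = 1L) {
  if (targetH2 <= 0 || targetH2 >= 1) stop("targetH2 must be in (0, 1)")
  g <- values[layout$genotype]
  if (anyNA(g)) stop("layout genotypes missing from values")
  nReps <- length(unique(layout$rep))
  gAdj <- stats::resid(stats::lm(values ~ dh[names(values)]))
  varG <- stats::var(gAdj)
  varE <- nReps * varG * (1 - targetH2) / targetH2
  withSeed(seed, {
    repEff <- rnorm(nReps, 0, repSD * sqrt(varG))
    blkKey <- paste(layout$rep, layout$block)
    ub <- unique(blkKey)
    blkEff <- setNames(rnorm(length(ub), 0, blockSD * sqrt(varG)), ub)
    dhPlot <- dh[layout$genotype] + rnorm(nrow(layout), 0, dhPlotSD)
    gy <- envMean + g + repEff[layout$rep] + blkEff[blkKey] +
      dhEffect * (dhPlot - mean(dh)) +
      rnorm(nrow(layout), 0, sqrt(varE))
    data.frame(env = layout$env, rep = layout$rep, block = layout$block,
               genotype = layout$genotype, DH = round(dhPlot, 1), GY = gy,
               stringsAsFactors = FALSE)
  })
}

#' Simulate a complete multi-environment MAGIC experiment
#'
#' Chains the population simulator, trait architecture, layouts and trial
#' noise into one call: the standard study conditions are 352 DH lines from
#' 8 founders, two-replicate alpha lattices, and the nine-environment
#' heritability spectrum of [defaultTraitArchitecture()].
#'
#' @param nLines,nMarkers population size and marker panel size.
#' @param arch optional [TraitArchitecture]; default
#'   [defaultTraitArchitecture()].
#' @param nReps replicates per trial.
#' @param seed master seed; all stages derive their seeds from it.
#' @return list with `pop`, `arch`, `values`, `dh`, and `plots` (stacked
#'   plot table over all environments).
#' @export
simulateMagicExperiment <- function(nLines = 352L, nMarkers = 2000L,
                                    arch = NULL, nReps = 2L, seed = 1L) {
  pop <- simulateMagic(nLines, nMarkers, seed = seed)
  if (is.null(arch)) arch <- defaultTraitArchitecture(nMarkers, seed = seed + 10L)
  gv <- simulateGeneticValues(pop, arch, seed = seed + 20L)
  plots <- do.call(rbind, lapply(seq_along(arch@envs), function(j) {
    env <- arch@envs[j]
    lay <- makeTrialLayout(rownames(gv$values), env = env, nReps = nReps,
                           seed = seed + 30L + j)
    simulateTrial(gv$values[, j], gv$dh, lay, targetH2 = arch@H2[j],
                  dhEffect = arch@dhEffect, seed = seed + 60L + j)
  }))
  rownames(plots) <- NULL
  list(pop = pop, arch = arch, values = gv$values, dh = gv$dh, plots = plots)
}
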