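#' Define a trait architecture with GxE deviations
#'
#' The effect of QTL k in environment j is `b0_k + b_jk`: a main effect
#' shared by all environments plus an independent environment-specific
#' deviation. With deviation variance `gxeRatio * main variance` the expected
#' genetic correlation between two environments with ratios r1 and r2 is
#' `1 / sqrt((1 + r1)(1 + r2))`; a large ratio therefore makes an
#' environment nearly uncorrelated with the rest (a stress site), small
#' ratios give the 0.4-0.6 correlations typical of repeated temperate
#' trials.
#'
#' @param nMarkers marker panel size (QTL indices are drawn from it).
#' @param envs environment labels.
#' @param nQTL number of QTL.
#' @param gxeRatio deviation-to-main variance ratio, recycled per
#'   environment.
#' @param H2 target line-mean heritability per environment (recycled).
#' @param dhEffect yield effect (t/ha) of one day of heading difference.
#' @param seed integer seed.
#' @return A [TraitArchitecture].
#' @export
makeTraitArchitecture <- function(nMarkers, envs, nQTL = 300L,
                                  gxeRatio = 1, H2 = 0.6,
                                  dhEffect = -0.05, seed = 1L) {
  nQTL <- min(nQTL, nMarkers)
  gxeRatio <- rep_len(gxeRatio, length(envs))
  H2 <- rep_len(H2, length(envs))
  withSeed(seed, {
    qtl <- sort(sample.int(nMarkers, nQTL))
    main <- rnorm(nQTL)
    dev <- vapply(seq_along(envs),
                  function(j) rnorm(nQTL, 0, sqrt(gxeRatio[j])),
                  numeric(nQTL))
    dev <- matrix(dev, nrow = nQTL)
    colnames(dev) <- envs
    dhq <- sort(sample.int(nMarkers, min(20L, nMarkers)))
    dhe <- rnorm(length(dhq))
    new("TraitArchitecture", qtl = as.integer(qtl), mainEffects = main,
        devEffects = dev, envs = as.character(envs), H2 = H2,
        dhQTL = as.integer(dhq), dhEffects = dhe, dhEffect = dhEffect)
  })
}

#' Default nine-environment architecture
#'
#' Mirrors the structure of a Mediterranean multi-environment trial series:
#' eight temperate-like environments with heritabilities spanning roughly
#' 0.4-0.8 and one stress environment with very low heritability (0.12) that
#' is nearly decorrelated from the rest through a large GxE deviation
#' variance.
#'
#' @param nMarkers marker panel size.
#' @param seed integer seed.
#' @return A [TraitArchitecture] over environments `E1`-`E9`; `E7` is the
#'   stress site.
#' @export
defaultTraitArchitecture <- function(nMarkers, seed = 1L) {
  H2 <- c(0.660, 0.472, 0.532, 0.395, 0.652, 0.663, 0.122, 0.737, 0.805)
  ratio <- c(0.8, 0.8, 0.8, 1.2, 0.8, 0.8, 20, 1.0, 1.0)
  makeTraitArchitecture(nMarkers, envs = paste0("E", 1:9), nQTL = 300L,
                        gxeRatio = ratio, H2 = H2, seed = seed)
}

#' Simulate true genetic values and the heading-date covariate
#'
#' Genetic value of line i in environment j is
#' `sum_k dosage_ik (b0_k + b_jk)`. The days-to-heading covariate is
#' genotype-level, built from its own small marker set and scaled to a
#' narrow spread (SD about 1 day around 210, matching founders that differ
#' by under 4 days).
#'
#' @param pop a [MagicPopulation] (or lines x markers dosage matrix).
#' @param arch a [TraitArchitecture].
#' @param seed integer seed (covariate noise only; genetic values are
#'   deterministic given pop and arch).
#' @return list with `values` (lines x environments matrix of genetic
#'   values) and `dh` (named per-line covariate).
#' @export
simulateGeneticValues <- function(pop, arch, seed = 1L) {
  X <- if (is(pop, "MagicPopulation")) markerMatrix(pop) else as.matrix(pop)
  if (max(arch@qtl) > ncol(X)) stop("QTL index out of marker range")
  Q <- X[, arch@qtl, drop = FALSE]
  vals <- vapply(seq_along(arch@envs), function(j)
    drop(Q %*% (arch@mainEffects + arch@devEffects[, j])),
    numeric(nrow(X)))
  vals <- matrix(vals, nrow = nrow(X),
                 dimnames = list(rownames(X), arch@envs))
  dh_gen <- drop(X[, arch@dhQTL, drop = FALSE] %*% arch@dhEffects)
  s <- stats::sd(dh_gen)
  if (s > 0) dh_gen <- dh_gen / s
  dh <- withSeed(seed, 210 + dh_gen + rnorm(nrow(X), 0, 0.3))
  names(dh) <- rownames(X)
  list(values = vals, dh = dh)
}
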