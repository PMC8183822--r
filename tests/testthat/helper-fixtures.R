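# Shared fixtures, built once per test run. Sizes are desk-scale: large
# enough for the statistical properties under test, small enough to keep the
# suite fast.

fixtureMap <- function(p = 140, seed = 1) simulateGeneticMap(p, seed = seed)

# small cached population reused by several files
.smallPop <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- simulateMagic(nLines = 80, nMarkers = 420,
                                                seed = 42)
    cache
  }
})

# a 200-line MAGIC panel reused by the regression/model tests (LD-structured
# genotypes, as the models expect)
.medPop <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- simulateMagic(nLines = 200,
                                                nMarkers = 450, seed = 7)
    cache
  }
})

# sparse trait on MAGIC genotypes: nQTL markers carry effects
sparseTrait <- function(nQTL = 20, h2 = 0.6, seed = 1, pop = .medPop()) {
  mm <- qcAndStandardize(markerMatrix(pop))
  set.seed(seed)
  qtl <- sample.int(ncol(mm@X), nQTL)
  b <- rep(0, ncol(mm@X))
  b[qtl] <- rnorm(nQTL)
  g <- drop(mm@X %*% b)
  g <- g / sd(g) * sqrt(h2)
  y <- as.numeric(scale(g + rnorm(nrow(mm@X), 0, sqrt(1 - h2))))
  list(mm = mm, y = y, qtl = qtl, g = g)
}

# a standardized marker matrix + polygenic phenotype with known h2
fixturePanel <- function(n = 80, p = 300, h2 = 0.6, seed = 1) {
  set.seed(seed)
  X <- matrix(rbinom(n * p, 2, runif(p, 0.15, 0.5)[rep(1:p, each = n)]),
              n, p)
  rownames(X) <- sprintf("L%03d", 1:n)
  mm <- qcAndStandardize(X)
  b <- rnorm(ncol(mm@X)) / sqrt(ncol(mm@X))
  g <- drop(mm@X %*% b)
  g <- g / sd(g) * sqrt(h2)
  y <- g + rnorm(n, 0, sqrt(1 - h2))
  list(mm = mm, y = as.numeric(scale(y)), g = g)
}

fastMCMC <- function(seed = 1) mcmcConfig("custom", iterations = 1500,
                                          burnin = 300, thin = 3,
                                          seed = seed)

# genotype-x-environment phenotype panel straight from the simulator:
# standardized "adjusted means" per environment with chosen GxE and noise
gxePanel <- function(gxeRatio, H2 = 0.6, nEnv = 4, seed = 1,
                     pop = .smallPop()) {
  arch <- makeTraitArchitecture(nrow(pop), envs = paste0("E", seq_len(nEnv)),
                                nQTL = 80, gxeRatio = gxeRatio, H2 = H2,
                                seed = seed)
  gv <- simulateGeneticValues(pop, arch, seed = seed)
  set.seed(seed + 500)
  M <- apply(gv$values, 2, function(g) {
    g <- scale(g)
    as.numeric(scale(g + rnorm(length(g), 0, sqrt((1 - H2) / H2))))
  })
  rownames(M) <- rownames(gv$values)
  M
}

kernelFor <- function(pop = .smallPop()) grm(qcAndStandardize(
  markerMatrix(pop)))


toyCtx <- function(n = 12, lambda = 1, seed = 3) {
  set.seed(seed)
  X <- matrix(rbinom(n * 60, 2, 0.4), n, 60)
  rownames(X) <- sprintf("L%02d", seq_len(n))
  criterionContext(grm(qcAndStandardize(X)), lambda = lambda)
}

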