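test_that("funnel design distributes lines over valid eight-way funnels", {
  fp <- simulateFounders(fixtureMap(40), seed = 1)
  des <- buildFunnelDesign(fp, nLines = 352, seed = 1)
  expect_s4_class(des, "FunnelDesign")
  expect_identical(sum(des@linesPerFunnel), 352L)
  # every funnel unites all 8 founders exactly once (validity enforces it)
  expect_true(validObject(des))
  # even split when the count divides the number of funnels
  des6 <- buildFunnelDesign(fp, nLines = 6, seed = 2)
  expect_identical(sort(des6@linesPerFunnel), c(2L, 2L, 2L))
  expect_error(buildFunnelDesign(fp, nLines = 0), "empty population")
})

test_that("founder simulation honours MAF bounds and is seed-stable", {
  map <- fixtureMap(1000)
  fp <- simulateFounders(map, mafRange = c(0.1, 0.5), seed = 3)
  expect_identical(dim(fp@haplotypes), c(8L, 1000L))
  expect_true(all(fp@haplotypes %in% c(0L, 1L)))
  fp2 <- simulateFounders(map, mafRange = c(0.1, 0.5), seed = 3)
  expect_identical(fp@haplotypes, fp2@haplotypes)
  # forced MAF = 0.5: exactly 4 copies of each allele at every marker
  fp5 <- simulateFounders(map, mafRange = c(0.5, 0.5), seed = 4)
  expect_true(all(colSums(fp5@haplotypes) == 4L))
  expect_error(simulateFounders(map, mafRange = c(0, 0.6)), "mafRange")
})

test_that("meiosis follows the Haldane model", {
  # identical parents: gamete equals them regardless of crossovers
  map <- fixtureMap(60)
  h <- rbinom(60, 1, 0.5)
  g <- simulateGamete(h, h, rep(1L, 60), rep(1L, 60), map, seed = 1)
  expect_identical(g$hap, h)

  # 1-Morgan chromosome: observed origin switches ~ Poisson(1) in mean,
  # and the recombination fraction at 50 cM matches (1 - exp(-2d))/2
  dense <- makeGeneticMap(paste0("m", 1:201), rep("1", 201),
                          seq(0, 100, by = 0.5), seq_len(201) * 1e5)
  h1 <- rep(0L, 201); h2 <- rep(1L, 201)
  set.seed(99)
  nG <- 8000
  switches <- numeric(nG)
  rec50 <- logical(nG)
  i50 <- c(1L, 101L) # 0 and 50 cM
  for (g in seq_len(nG)) {
    gm <- simulateGamete(h1, h2, rep(1L, 201), rep(2L, 201), dense)
    switches[g] <- sum(diff(gm$origin) != 0)
    rec50[g] <- gm$origin[i50[1]] != gm$origin[i50[2]]
  }
  se <- sd(switches) / sqrt(nG)
  expect_lt(abs(mean(switches) - 1), 3 * se + 0.01)
  # variance also ~1 (Poisson), generous band
  expect_lt(abs(var(switches) - 1), 0.15)
  theta <- (1 - exp(-2 * 0.5)) / 2
  seR <- sqrt(theta * (1 - theta) / nG)
  expect_lt(abs(mean(rec50) - theta), 3 * seR)

  expect_error(simulateGamete(h1[1:10], h2, 1:10, 1:201, dense), "length")
})

test_that("DH populations are homozygous with consistent founder mosaics", {
  pop <- .smallPop()
  d <- dosage(pop); m <- founderMosaic(pop)
  expect_true(all(d %in% c(0L, 2L)))          # zero heterozygosity
  # mosaic/allele consistency: allele at marker k of line i equals the
  # originating founder's allele
  H <- S4Vectors::metadata(pop)$founders@haplotypes
  founderAllele <- matrix(H[cbind(as.vector(m), rep(seq_len(nrow(d)),
                                                    ncol(d)))],
                          nrow(d), ncol(d))
  expect_true(all(d == 2L * founderAllele))
  # founder genome shares near 1/8
  expect_true(all(abs(founderShares(pop) - 0.125) < 0.04))
  # determinism
  pop2 <- simulateMagic(nLines = 80, nMarkers = 420, seed = 42)
  expect_identical(dosage(pop2), d)
})

test_that("genetic values follow the main-plus-deviation decomposition", {
  pop <- .smallPop()
  p <- nrow(pop)
  # no deviations: identical values across environments
  a0 <- makeTraitArchitecture(p, envs = c("A", "B", "C"), nQTL = 60,
                              gxeRatio = 0, seed = 1)
  gv0 <- simulateGeneticValues(pop, a0, seed = 1)
  expect_equal(gv0$values[, 1], gv0$values[, 2])
  expect_equal(gv0$values[, 1], gv0$values[, 3])

  # deviation variance = main variance: expected cross-env genetic
  # correlation 1/(1+ratio) = 0.5 (averaged over architectures)
  cors <- vapply(1:8, function(s) {
    a1 <- makeTraitArchitecture(p, envs = c("A", "B", "C"), nQTL = 60,
                                gxeRatio = 1, seed = s)
    gv <- simulateGeneticValues(pop, a1, seed = s)
    mean(cor(gv$values)[upper.tri(diag(3))])
  }, numeric(1))
  expect_lt(abs(mean(cors) - 0.5), 0.1)
  expect_error(
    simulateGeneticValues(pop,
      makeTraitArchitecture(10 * p, envs = "A", nQTL = 5 * p, seed = 1)),
    "out of marker range")
})

test_that("trial simulation hits the target heritability", {
  pop <- .smallPop()
  arch <- makeTraitArchitecture(nrow(pop), envs = "E1", nQTL = 60,
                                gxeRatio = 0, H2 = 0.805, seed = 2)
  gv <- simulateGeneticValues(pop, arch, seed = 2)
  h2hat <- vapply(1:6, function(s) {
    lay <- makeTrialLayout(rownames(gv$values), env = "E1", seed = s)
    pt <- simulateTrial(gv$values[, 1], gv$dh, lay, targetH2 = 0.805,
                        seed = 100 + s)
    heritability(fitLatticeModel(pt))
  }, numeric(1))
  expect_lt(abs(mean(h2hat) - 0.805), 0.1)
  expect_error(simulateTrial(gv$values[, 1], gv$dh,
                             makeTrialLayout(rownames(gv$values)),
                             targetH2 = 1.2), "targetH2")
})

test_that("trial tables are reproducible and covariate-neutral when null", {
  pop <- .smallPop()
  arch <- makeTraitArchitecture(nrow(pop), envs = "E1", nQTL = 60,
                                seed = 3)
  gv <- simulateGeneticValues(pop, arch, seed = 3)
  lay <- makeTrialLayout(rownames(gv$values), env = "E1", seed = 7)
  p1 <- simulateTrial(gv$values[, 1], gv$dh, lay, targetH2 = 0.6,
                      dhEffect = 0, seed = 11)
  p2 <- simulateTrial(gv$values[, 1], gv$dh, lay, targetH2 = 0.6,
                      dhEffect = 0, seed = 11)
  expect_identical(p1, p2)
  # with a null covariate effect, fits with/without DH rank BLUPs the same
  fWith <- fitLatticeModel(p1, useDhCovariate = TRUE)
  fWithout <- fitLatticeModel(p1, useDhCovariate = FALSE)
  expect_gt(cor(blups(fWith)[names(blups(fWithout))], blups(fWithout)),
            0.999)
})
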