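test_that("random partitions are uniform, disjoint and reproducible", {
  ps <- makeRandomPartitions(352, 90, nReps = 5, seed = 3)
  expect_identical(ps@nReps, 5L)
  for (p in ps@partitions) {
    expect_identical(length(p$train), 90L)
    expect_identical(length(intersect(p$train, p$validation)), 0L)
    expect_identical(sort(c(p$train, p$validation)), 1:352)
  }
  ps2 <- makeRandomPartitions(352, 90, nReps = 5, seed = 3)
  expect_identical(ps@partitions, ps2@partitions)
  singleton <- makeRandomPartitions(10, 9, nReps = 2, seed = 1)
  expect_identical(length(singleton@partitions[[1]]$validation), 1L)
  expect_error(makeRandomPartitions(10, 10), "tpSize")
})

test_that("leave-one-out hits the high-signal limit and the null", {
  # near-noiseless dense trait on a compact, high-LD genome: LOO r is high
  map <- simulateGeneticMap(150, nChrom = 2, chromLengthCM = 25, seed = 61)
  fp <- simulateFounders(map, seed = 62)
  pop <- simulateMagicPopulation(buildFunnelDesign(fp, 120, seed = 63),
                                 fp, map, seed = 64)
  mm <- qcAndStandardize(markerMatrix(pop))
  set.seed(65)
  b <- rnorm(ncol(mm@X))
  g <- drop(mm@X %*% b); g <- g / sd(g)
  h2 <- 0.99
  y <- as.numeric(scale(g + rnorm(120, 0, sqrt((1 - h2) / h2))))
  K <- grm(mm)
  cv <- looCV(y, K = K, model = "GB", mcmc = fastMCMC(1))
  expect_gt(cv@mean, 0.9)
  expect_identical(nrow(cv@detail), 120L)
  # permuted phenotype: no signal
  set.seed(32)
  cv0 <- looCV(sample(y), K = K, model = "GB", mcmc = fastMCMC(2))
  expect_lt(abs(cv0@mean), 3 / sqrt(120) + 0.1)
})

test_that("CV1 masks whole lines and CV2 keeps a foothold per line", {
  M <- matrix(rnorm(90 * 4), 90, 4,
              dimnames = list(sprintf("L%02d", 1:90), paste0("E", 1:4)))
  data <- meDataset(M)
  cv1 <- makeMEPartitions(data, "CV1", nReps = 4, seed = 5)
  for (m in cv1@partitions) {
    maskedLines <- which(rowSums(m) > 0)
    expect_identical(length(maskedLines), 9L) # 10% of 90
    expect_true(all(rowSums(m[maskedLines, , drop = FALSE]) == 4))
  }
  cv2 <- makeMEPartitions(data, "CV2", nReps = 4, seed = 6)
  for (m in cv2@partitions) {
    expect_true(any(m))
    masked <- which(rowSums(m) > 0)
    expect_true(all(rowSums(!m)[masked] >= 1))
  }
  expect_identical(makeMEPartitions(data, "CV2", nReps = 2, seed = 7),
                   makeMEPartitions(data, "CV2", nReps = 2, seed = 7))
  one <- meDataset(M[, 1, drop = FALSE])
  expect_error(makeMEPartitions(one, "CV2"), "at least 2 environments")
})

test_that("predictive-ability summaries follow the Pearson formula", {
  obs <- c(1.2, -0.3, 0.5, 2.0, -1.1)
  expect_equal(predictiveAbilitySummary(obs, obs)$r, 1)
  expect_equal(predictiveAbilitySummary(-obs, obs)$r, -1)
  pred <- c(0.8, 0.1, -0.2, 1.5, -0.9)
  hand <- sum((pred - mean(pred)) * (obs - mean(obs))) /
    sqrt(sum((pred - mean(pred))^2) * sum((obs - mean(obs))^2))
  expect_equal(predictiveAbilitySummary(pred, obs)$r, hand,
               tolerance = 1e-10)
  expect_warning(predictiveAbilitySummary(pred[1:2], obs[1:2]),
                 "fewer than 3")
})

test_that("Welch comparisons match hand computation and detect real gaps", {
  a <- c(0.50, 0.52, 0.48)
  b <- c(0.30, 0.35, 0.31)
  w <- welchCompare(a, b)
  # hand-computed Welch statistic
  tHand <- (mean(a) - mean(b)) / sqrt(var(a) / 3 + var(b) / 3)
  expect_equal(w$statistic, tHand, tolerance = 1e-10)
  dfHand <- (var(a) / 3 + var(b) / 3)^2 /
    ((var(a) / 3)^2 / 2 + (var(b) / 3)^2 / 2)
  expect_equal(w$df, dfHand, tolerance = 1e-10)
  expect_equal(welchCompare(a, a)$p.value, 1)
  set.seed(8)
  big <- welchCompare(rnorm(100, 0.5, 0.01), rnorm(100, 0.3, 0.01))
  expect_lt(big$p.value, 1e-6)
})

test_that("PCA separates structured subpanels but not arbitrary labels", {
  # rank-1 matrix: PC1 carries everything
  X1 <- outer(rnorm(20), rnorm(10))
  pc1 <- runPCA(X1, 3)
  expect_gt(pc1$varianceFraction[1], 0.999)
  # duplicated lines project identically
  dat <- fixturePanel(n = 30, p = 60, seed = 33)
  Xd <- rbind(dat$mm@X, dat$mm@X[1, ])
  pcd <- runPCA(Xd, 2)
  expect_equal(pcd$scores[1, ], pcd$scores[31, ], tolerance = 1e-10)

  # three MAGIC subpanels from different founder sets: the true labels
  # silhouette beats random labels
  map <- simulateGeneticMap(300, seed = 41)
  panels <- lapply(1:3, function(i) {
    fp <- simulateFounders(map, seed = 50 + i)
    des <- buildFunnelDesign(fp, 40, seed = i)
    markerMatrix(simulateMagicPopulation(des, fp, map, seed = 60 + i))
  })
  X <- do.call(rbind, panels)
  rownames(X) <- sprintf("S%03d", seq_len(nrow(X)))
  lab <- rep(1:3, each = 40)
  pc <- runPCA(qcAndStandardize(X), 2)
  sil <- function(S, lab) {
    D <- as.matrix(dist(S))
    mean(vapply(seq_along(lab), function(i) {
      own <- which(lab == lab[i]); own <- setdiff(own, i)
      a <- mean(D[i, own])
      b <- min(vapply(setdiff(unique(lab), lab[i]),
                      function(l) mean(D[i, lab == l]), numeric(1)))
      (b - a) / max(a, b)
    }, numeric(1)))
  }
  true <- sil(pc$scores, lab)
  set.seed(42)
  perm <- mean(vapply(1:5, function(i) sil(pc$scores, sample(lab)),
                      numeric(1)))
  expect_gt(true, perm + 0.1)
  expect_error(runPCA(matrix(1, 5, 4)), "constant")
})

test_that("LD r2 matches the allele-frequency formula and decays with
           distance", {
  # 4-line toy, hand-computed D^2/(p1 q1 p2 q2)
  h1 <- c(1, 1, 0, 0); h2 <- c(1, 0, 1, 0); h3 <- c(1, 1, 1, 0)
  X <- cbind(m1 = 2 * h1, m2 = 2 * h2, m3 = 2 * h3)
  rownames(X) <- paste0("L", 1:4)
  map <- makeGeneticMap(c("m1", "m2", "m3"), rep("1H", 3), c(0, 1, 2),
                        c(0, 5e4, 2e5))
  ld <- ldDecay(X, map, pCut = 1)
  r2_12 <- ld$pairs$r2[ld$pairs$m1 == "m1" & ld$pairs$m2 == "m2"]
  pA <- mean(h1); pB <- mean(h2)
  Dab <- mean(h1 * h2) - pA * pB
  expect_equal(r2_12, Dab^2 / (pA * (1 - pA) * pB * (1 - pB)),
               tolerance = 1e-10)
  r2_13 <- ld$pairs$r2[ld$pairs$m1 == "m1" & ld$pairs$m2 == "m3"]
  expect_equal(r2_13, cor(h1, h3)^2, tolerance = 1e-10)

  # perfectly correlated pair survives the p-value filter
  Xp <- cbind(m1 = 2 * rbinom(100, 1, 0.5))
  Xp <- cbind(Xp, m2 = Xp[, 1])
  rownames(Xp) <- paste0("L", 1:100)
  mp <- makeGeneticMap(c("m1", "m2"), c("1H", "1H"), c(0, 1), c(0, 1e4))
  lp <- ldDecay(Xp, mp)
  expect_equal(lp$bins$r2[1], 1)
  # independent markers mostly filtered at p <= 0.001
  set.seed(43)
  Xi <- matrix(2 * rbinom(100 * 30, 1, 0.5), 100, 30)
  colnames(Xi) <- paste0("m", 1:30)
  rownames(Xi) <- paste0("L", 1:100)
  mi <- makeGeneticMap(colnames(Xi), rep("1H", 30), seq(0, 29),
                       seq(1e5, 30e5, by = 1e5))
  li <- ldDecay(Xi, mi)
  expect_lt(nrow(li$pairs[li$pairs$p <= 0.001 & !is.na(li$pairs$r2), ]) /
              nrow(li$pairs), 0.05)

  # MAGIC panel: LD decays with physical distance
  pop <- .medPop()
  ldm <- ldDecay(pop)
  gw <- ldm$bins[ldm$bins$chrom == "genome", ]
  gw <- gw[order(gw$binStartBp), ]
  expect_gt(gw$r2[1], gw$r2[nrow(gw)])
})

test_that("the TP-size sweep produces the full size x model x partition
           grid", {
  dat <- sparseTrait(nQTL = 60, h2 = 0.7, seed = 35)
  sw <- tpSizeSweep(dat$mm, dat$y, sizes = c(60, 120),
                    models = c("GB", "BayesA"), nReps = 3,
                    mcmc = fastMCMC(1), seed = 9)
  expect_identical(nrow(sw$results), 2L * 2L * 3L)
  expect_true(all(abs(sw$results$r) <= 1))
  expect_identical(length(sw$summary), 4L)
  m <- sw$summary[[1]]
  expect_s4_class(m, "CVResult")
  expect_identical(m@nReps, 3L)
})
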