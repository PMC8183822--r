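test_that("the linear-kernel sampler reproduces closed-form ridge BLUP", {
  dat <- fixturePanel(n = 60, p = 200, h2 = 0.6, seed = 21)
  K <- grm(dat$mm)
  fit <- fitSEKernel(K, dat$y, mcmcConfig("test", seed = 2))
  vc <- varComp(fit)
  vu <- vc$estimate[vc$component == "varU"]
  ve <- vc$estimate[vc$component == "varE"]
  Km <- kernelMatrix(K)
  n <- nrow(Km)
  ublup <- drop(vu * Km %*% solve(vu * Km + ve * diag(n),
                                  dat$y - mean(dat$y)))
  expect_gt(cor(drop(gebv(fit)), ublup), 0.99)
})

test_that("an identity kernel shares no information with held-out lines", {
  dat <- fixturePanel(n = 70, p = 100, h2 = 0.8, seed = 22)
  y <- dat$y
  y[51:70] <- NA
  fit <- fitSEKernel(new("GenomicKernel", K = diag(70), kind = "GB",
                         h = NA_real_, jitter = 0), y, fastMCMC(3))
  g <- drop(gebv(fit))
  expect_lt(max(abs(g[51:70])), 0.1) # pure shrinkage, no signal flow
})

test_that("the SE sampler recovers the simulated heritability", {
  ratio <- vapply(1:10, function(s) {
    dat <- fixturePanel(n = 150, p = 300, h2 = 0.6, seed = 30 + s)
    fit <- fitSEKernel(grm(dat$mm), dat$y, fastMCMC(s))
    vc <- varComp(fit)
    vu <- vc$estimate[vc$component == "varU"]
    ve <- vc$estimate[vc$component == "varE"]
    vu / (vu + ve)
  }, numeric(1))
  expect_lt(abs(mean(ratio) - 0.6), 0.15)
})

test_that("MM equals the mean-phenotype single-environment fit", {
  M <- gxePanel(gxeRatio = 0.6, seed = 3)
  K <- kernelFor()
  data <- meDataset(M)
  fmm <- fitMM(data, K, mcmcConfig("test", seed = 4))
  fse <- fitSEKernel(K, rowMeans(M), mcmcConfig("test", seed = 4))
  expect_gt(cor(gebv(fmm)[, 1], drop(gebv(fse))), 0.98)
})

test_that("single-environment MM degenerates to the SE fit", {
  M <- gxePanel(gxeRatio = 0, nEnv = 1, seed = 5)
  K <- kernelFor()
  fmm <- fitMM(meDataset(M), K, mcmcConfig("test", seed = 6))
  fse <- fitSEKernel(K, M[, 1], mcmcConfig("test", seed = 6))
  expect_gt(cor(gebv(fmm)[, 1], drop(gebv(fse))), 0.999)
})

test_that("identical environments get matching fixed effects", {
  M <- gxePanel(gxeRatio = 0, nEnv = 1, seed = 7)
  M2 <- cbind(E1 = M[, 1], E2 = M[, 1])
  fit <- fitMM(meDataset(M2), kernelFor(), fastMCMC(8))
  ee <- envEffects(fit)
  expect_lt(abs(ee["E1"] - ee["E2"]), 0.05)
})

test_that("the per-environment deviation representation realizes the
           Hadamard covariance", {
  # Monte-Carlo oracle: simulate y(i,j) = u_i + ue_(i,j) from the component
  # representation and compare empirical covariances with
  # s2u0 K_ii' + 1(j = j') s2ue K_ii'
  set.seed(9)
  n <- 5
  A <- matrix(rnorm(n * n), n)
  K <- tcrossprod(A) / n
  L <- t(chol(K))
  s2u0 <- 0.7; s2ue <- 0.4
  reps <- 30000
  y11 <- y12 <- y21 <- matrix(0, reps, 2)
  for (r in seq_len(reps)) {
    u <- sqrt(s2u0) * drop(L %*% rnorm(n))
    ue1 <- sqrt(s2ue) * drop(L %*% rnorm(n))
    ue2 <- sqrt(s2ue) * drop(L %*% rnorm(n))
    y11[r, ] <- c(u[1] + ue1[1], u[2] + ue1[2]) # lines 1,2 in env 1
    y12[r, ] <- c(u[1] + ue1[1], u[1] + ue2[1]) # line 1 in envs 1,2
    y21[r, ] <- c(u[1] + ue1[1], u[2] + ue2[2]) # line 1 env 1, line 2 env 2
  }
  expect_lt(abs(var(y11[, 1]) - (s2u0 + s2ue) * K[1, 1]), 0.05)
  expect_lt(abs(cov(y11[, 1], y11[, 2]) - (s2u0 + s2ue) * K[1, 2]), 0.05)
  expect_lt(abs(cov(y12[, 1], y12[, 2]) - s2u0 * K[1, 1]), 0.05)
  expect_lt(abs(cov(y21[, 1], y21[, 2]) - s2u0 * K[1, 2]), 0.05)
})

test_that("MDs interaction variance tracks the simulated GxE level", {
  K <- kernelFor()
  nullHits <- numeric(10); strongHits <- logical(10)
  for (s in 1:10) {
    Mnull <- gxePanel(gxeRatio = 0, seed = 100 + s)
    f0 <- fitMDs(meDataset(Mnull), K, fastMCMC(s))
    vc0 <- varComp(f0)
    nullHits[s] <- vc0$estimate[vc0$component == "varUE"]
    Mstrong <- gxePanel(gxeRatio = 2, seed = 200 + s)
    f2 <- fitMDs(meDataset(Mstrong), K, fastMCMC(s))
    vc2 <- varComp(f2)
    strongHits[s] <- vc2$estimate[vc2$component == "varUE"] >
      vc2$estimate[vc2$component == "varU0"]
  }
  expect_lt(median(nullHits), 0.15)
  expect_gte(sum(strongHits), 8)
})

test_that("MDe attributes the largest specific variance to the
           discordant environment", {
  K <- kernelFor()
  hits <- vapply(1:10, function(s) {
    M <- gxePanel(gxeRatio = c(0.3, 0.3, 0.3, 8), seed = 300 + s)
    f <- fitMDe(meDataset(M), K, mcmc = fastMCMC(s))
    vc <- varComp(f)
    uej <- vc$estimate[grepl("^varUE_", vc$component)]
    which.max(uej) == 4
  }, logical(1))
  expect_gte(sum(hits), 8)
  # all-null deviations: every environment-specific variance is small
  meds <- vapply(1:6, function(s) {
    M <- gxePanel(gxeRatio = 0, seed = 400 + s)
    f <- fitMDe(meDataset(M), K, mcmc = fastMCMC(s))
    vc <- varComp(f)
    max(vc$estimate[grepl("^varUE_", vc$component)])
  }, numeric(1))
  expect_lt(median(meds), 0.15)
})

test_that("modelling GxE reduces the residual variance relative to MM", {
  K <- kernelFor()
  wins <- vapply(1:10, function(s) {
    M <- gxePanel(gxeRatio = 1.5, seed = 500 + s)
    data <- meDataset(M)
    vMM <- varComp(fitMM(data, K, fastMCMC(s)))
    vMDe <- varComp(fitMDe(data, K, mcmc = fastMCMC(s)))
    vMDe$estimate[vMDe$component == "varE"] <
      vMM$estimate[vMM$component == "varE"]
  }, logical(1))
  expect_gte(sum(wins), 8)
})

test_that("MM variance components sum near one on standardized inputs", {
  K <- kernelFor()
  sums <- vapply(1:5, function(s) {
    M <- gxePanel(gxeRatio = 0.5, seed = 600 + s)
    vc <- varComp(fitMM(meDataset(M), K, fastMCMC(s)))
    sum(vc$estimate[vc$component %in% c("varU0", "varE")])
  }, numeric(1))
  expect_true(all(sums > 0.8 & sums < 1.2))
})
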