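test_that("marker QC applies the 10% missingness rule and mode imputation", {
  set.seed(1)
  X <- matrix(rbinom(100 * 40, 2, 0.4), 100, 40)
  colnames(X) <- paste0("m", 1:40)
  X[sample(100, 11), 1] <- NA   # 11% missing -> dropped
  X[sample(100, 10), 2] <- NA   # 10% missing -> kept
  X[, 3] <- 2                    # monomorphic -> dropped
  mm <- qcAndStandardize(X)
  expect_true("m1" %in% mm@dropped$marker)
  expect_true("m3" %in% mm@dropped$marker)
  expect_false("m2" %in% mm@dropped$marker)
  expect_equal(unname(colMeans(mm@X)), rep(0, ncol(mm@X)), tolerance = 1e-12)
  expect_equal(unname(apply(mm@X, 2, sd)), rep(1, ncol(mm@X)),
               tolerance = 1e-12)

  # hand-checked toy: one monomorphic column dropped, single NA filled with
  # the column mode
  toy <- rbind(c(0, 2, 1), c(0, 2, NA), c(2, 2, 1), c(2, 2, 0))
  colnames(toy) <- c("a", "b", "c")
  mt <- qcAndStandardize(toy, maxMissing = 0.3)
  expect_identical(colnames(mt@X), c("a", "c"))
  expect_identical(unname(mt@raw[2, "c"]), 1) # mode of (1, 1, 0)
  expect_error(qcAndStandardize(matrix(1, 4, 2)), "all markers removed")
})

test_that("the GB kernel is the scaled Gram matrix", {
  X <- rbind(c(1, -1), c(-1, 1))
  K <- grm(X)
  expect_equal(kernelMatrix(K), rbind(c(1, -1), c(-1, 1)),
               tolerance = 1e-12, ignore_attr = TRUE)
  # naive double-loop oracle
  set.seed(2)
  Xs <- fixturePanel(n = 10, p = 20, seed = 2)$mm@X
  Kn <- matrix(0, 10, 10)
  for (i in 1:10) for (j in 1:10)
    Kn[i, j] <- sum(Xs[i, ] * Xs[j, ]) / ncol(Xs)
  expect_equal(unname(kernelMatrix(grm(Xs))), Kn, tolerance = 1e-12)
  # duplicated lines give identical rows/columns
  Xd <- rbind(Xs, Xs[1, ])
  Kd <- kernelMatrix(grm(Xd))
  expect_equal(Kd[1, ], Kd[11, ], tolerance = 1e-12)
  # trace/n near 1 for standardized markers
  big <- fixturePanel(n = 50, p = 500, seed = 3)$mm
  expect_lt(abs(mean(diag(kernelMatrix(grm(big)))) - 1), 0.1)
})

test_that("squared Euclidean distances and the Gaussian kernel agree with
           closed forms", {
  X <- rbind(a = c(0, 0), b = c(3, 4))
  D <- squaredEuclidean(X, scaleByMean = FALSE)
  expect_equal(D["a", "b"], 25)
  expect_equal(diag(D), c(a = 0, b = 0))
  Ds <- squaredEuclidean(fixturePanel(n = 12, p = 30, seed = 4)$mm)
  expect_equal(mean(Ds[upper.tri(Ds)]), 1, tolerance = 1e-12)

  K <- gaussianKernel(rbind(c(0, 1), c(1, 0)), h = 1)
  expect_equal(kernelMatrix(K)[1, 2], exp(-1), tolerance = 1e-12)
  expect_equal(diag(kernelMatrix(K)), c(1, 1))
  # large h on distinct lines -> identity
  Kbig <- gaussianKernel(Ds, h = 500)
  expect_equal(unname(kernelMatrix(Kbig)), diag(nrow(Ds)),
               tolerance = 1e-6)
  expect_error(gaussianKernel(Ds, h = 0), "h must be > 0")
  # monotone non-increasing in distance
  Kv <- kernelMatrix(gaussianKernel(Ds, h = 0.8))
  ut <- upper.tri(Ds)
  expect_true(all(diff(Kv[ut][order(Ds[ut])]) <= 1e-12))
})

test_that("bandwidth selection recovers the generating bandwidth", {
  set.seed(5)
  mm <- fixturePanel(n = 150, p = 250, seed = 5)$mm
  D <- squaredEuclidean(mm)
  grid <- c(0.25, 0.5, 1, 2, 4)
  hits <- vapply(1:6, function(s) {
    set.seed(100 + s)
    K <- kernelMatrix(gaussianKernel(D, h = 1))
    L <- t(chol(K + diag(1e-6, nrow(K))))
    y <- drop(L %*% rnorm(nrow(K))) * sqrt(0.9) +
      rnorm(nrow(K), 0, sqrt(0.1))
    est <- estimateBandwidth(D, as.numeric(scale(y)), grid = grid)
    est$h
  }, numeric(1))
  # selected h within one grid neighbour of the truth in most runs
  expect_gte(sum(hits %in% c(0.5, 1, 2)), 5)
  # single-candidate grid returns it
  yy <- rnorm(nrow(D))
  expect_equal(estimateBandwidth(D, yy, grid = 3)$h, 3)
  # pure-noise phenotype: no strong preference across the grid
  prof <- estimateBandwidth(D, as.numeric(scale(rnorm(nrow(D)))),
                            grid = grid)$profile
  expect_lt(diff(range(prof$logEvidence)), 4)
  expect_error(estimateBandwidth(D, rep(1, nrow(D))), "zero variance")
})

test_that("PSD repair jitters only when needed and fails beyond the cap", {
  K <- diag(3)
  expect_identical(magicGP:::ensurePSD(K)$jitter, 0)
  bad <- matrix(0.5, 3, 3) + diag(0.5, 3)
  bad[1, 2] <- bad[2, 1] <- 1.2 # indefinite
  expect_error(magicGP:::ensurePSD(bad), "not positive semidefinite")
})
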