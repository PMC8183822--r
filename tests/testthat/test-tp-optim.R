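test_that("modified Rogers distance matches its closed form", {
  X <- rbind(a = c(0, 0, 0), b = c(0, 0, 0), c = c(2, 2, 2))
  D <- modifiedRogersDistance(X)
  expect_equal(D["a", "b"], 0)
  expect_equal(D["a", "c"], 1 / sqrt(2), tolerance = 1e-12)
  # brute-force per-marker summation oracle on a random toy
  set.seed(1)
  Y <- matrix(rbinom(15, 2, 0.5), 3, 5)
  rownames(Y) <- c("x", "y", "z")
  Dy <- suppressWarnings(modifiedRogersDistance(Y))
  for (i in 1:2) for (j in (i + 1):3) {
    f <- Y / 2
    expect_equal(Dy[i, j],
                 sqrt(sum((f[i, ] - f[j, ])^2) / (2 * ncol(Y))),
                 tolerance = 1e-12)
  }
  expect_warning(modifiedRogersDistance(rbind(c(0, 1), c(2, 1))),
                 "heterozygous")
})

test_that("CDmean matches a direct mixed-model-equation evaluation", {
  ctx <- toyCtx(n = 10)
  train <- c(1, 2, 4, 6, 9)
  # direct per-contrast computation (independent of the vectorized path)
  n <- ctx$n; t <- length(train)
  ZMZ <- matrix(0, n, n)
  ZMZ[train, train] <- -1 / t
  diag(ZMZ)[train] <- diag(ZMZ)[train] + 1
  B <- solve(ZMZ + ctx$lambda * ctx$Kinv)
  vals <- vapply(setdiff(1:n, train), function(i) {
    ci <- rep(-1 / n, n); ci[i] <- 1 - 1 / n
    drop(ci %*% (ctx$K - ctx$lambda * B) %*% ci / (ci %*% ctx$K %*% ci))
  }, numeric(1))
  expect_equal(cdmeanCriterion(ctx, train), mean(pmin(1, pmax(0, vals))),
               tolerance = 1e-8)
  expect_gte(cdmeanCriterion(ctx, train), 0)
  expect_lte(cdmeanCriterion(ctx, train), 1)
  # identity kernel: no information flows to non-training lines
  ctxI <- list(K = diag(10), Kinv = diag(10), lambda = 1, n = 10)
  expect_lt(cdmeanCriterion(ctxI, train), 0.05)
})

test_that("PEV matches brute force and improves with more training lines", {
  ctx <- toyCtx(n = 10, seed = 4)
  train <- c(2, 3, 5, 7)
  targets <- c(1, 4, 6)
  n <- ctx$n; t <- length(train)
  ZMZ <- matrix(0, n, n)
  ZMZ[train, train] <- -1 / t
  diag(ZMZ)[train] <- diag(ZMZ)[train] + 1
  B <- solve(ZMZ + ctx$lambda * ctx$Kinv)
  vals <- vapply(targets, function(i) {
    ci <- rep(-1 / n, n); ci[i] <- 1 - 1 / n
    drop(ci %*% B %*% ci)
  }, numeric(1))
  expect_equal(pevCriterion(ctx, train, targets), mean(vals),
               tolerance = 1e-8)
  # enlarging the training set never hurts a fixed target set
  for (add in c(8, 9, 10)) {
    expect_lte(pevCriterion(ctx, sort(c(train, add)), targets),
               pevCriterion(ctx, train, targets) + 1e-10)
  }
  expect_error(pevCriterion(ctx, train, integer()), "empty target")
})

test_that("rScore follows the kernel-block accuracy formula", {
  ctx <- toyCtx(n = 10, seed = 5)
  train <- c(1, 3, 5, 7, 9)
  targets <- setdiff(1:10, train)
  direct <- mean(vapply(targets, function(j) {
    kT <- ctx$K[train, j]
    S <- solve(ctx$K[train, train] + diag(ctx$lambda, length(train)))
    sqrt(max(0, min(1, drop(kT %*% S %*% kT) / ctx$K[j, j])))
  }, numeric(1)))
  expect_equal(rscoreCriterion(ctx, train), direct, tolerance = 1e-8)
  expect_gte(direct, 0); expect_lte(direct, 1)
  # identity kernel carries no predictive information
  ctxI <- list(K = diag(10), Kinv = diag(10), lambda = 1, n = 10)
  expect_equal(rscoreCriterion(ctxI, train), 0, tolerance = 1e-12)
})

test_that("criteria are invariant to line relabelling", {
  ctx <- toyCtx(n = 15, seed = 6)
  set.seed(9)
  perm <- sample(15)
  ctxP <- list(K = ctx$K[perm, perm], Kinv = ctx$Kinv[perm, perm],
               lambda = ctx$lambda, n = 15)
  train <- c(1, 4, 8, 11, 14)
  trainP <- match(train, perm)
  expect_equal(cdmeanCriterion(ctx, train), cdmeanCriterion(ctxP, trainP),
               tolerance = 1e-10)
  expect_equal(pevCriterion(ctx, train), pevCriterion(ctxP, trainP),
               tolerance = 1e-10)
  expect_equal(rscoreCriterion(ctx, train), rscoreCriterion(ctxP, trainP),
               tolerance = 1e-10)
})

test_that("exchange optimization beats random sets with a monotone
           trajectory", {
  ctx <- toyCtx(n = 30, seed = 7)
  sel <- exchangeOptimize("CDmean", ctx, nSelect = 10, seed = 11)
  expect_true(all(diff(sel@trajectory) >= -1e-12))
  expect_identical(length(selectedLines(sel)), 10L)
  set.seed(12)
  randBest <- max(vapply(1:200, function(i)
    cdmeanCriterion(ctx, sort(sample.int(30, 10))), numeric(1)))
  expect_gte(sel@value, randBest - 1e-10)
  # reproducibility
  sel2 <- exchangeOptimize("CDmean", ctx, nSelect = 10, seed = 11)
  expect_identical(selectedLines(sel), selectedLines(sel2))
  # PEV trajectories decrease (minimized criterion)
  selP <- exchangeOptimize("PEV", ctx, nSelect = 10, seed = 13)
  expect_true(all(diff(selP@trajectory) <= 1e-12))
  # near-full selection converges quickly
  selF <- exchangeOptimize("rScore", ctx, nSelect = 29, maxIters = 30,
                           seed = 14)
  expect_identical(length(selectedLines(selF)), 29L)
  expect_error(exchangeOptimize("CDmean", ctx, nSelect = 30), "nSelect")
})

test_that("entry-to-nearest-entry selection solves the line toy exactly", {
  D <- as.matrix(dist(c(a = 0, b = 1, c = 2, d = 10)))
  sel <- entryToNearestEntrySelect(D, 2, seed = 1)
  expect_setequal(selectedLines(sel), c("a", "d"))
  expect_equal(sel@value, 10)
  # select all: objective equals the mean nearest-neighbour distance
  all4 <- entryToNearestEntrySelect(D, 4, seed = 1)
  nn <- apply(`diag<-`(D, Inf), 1, min)
  expect_equal(all4@value, mean(nn))
  # dominance over random subsets on a larger panel
  set.seed(2)
  X <- matrix(2 * rbinom(40 * 80, 1, 0.4), 40, 80)
  rownames(X) <- sprintf("L%02d", 1:40)
  Dm <- modifiedRogersDistance(X)
  obj <- function(sel) {
    sub <- Dm[sel, sel]; diag(sub) <- Inf; mean(apply(sub, 1, min))
  }
  s <- entryToNearestEntrySelect(Dm, 10, seed = 3)
  rand <- vapply(1:200, function(i) obj(sample.int(40, 10)), numeric(1))
  expect_gte(s@value, max(rand) - 1e-10)
  # forced inclusion is honoured
  sf <- entryToNearestEntrySelect(Dm, 10, alwaysInclude = c(1, 2), seed = 4)
  expect_true(all(c("L01", "L02") %in% selectedLines(sf)))
  expect_error(entryToNearestEntrySelect(Dm, 1), "nSelect")
})
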