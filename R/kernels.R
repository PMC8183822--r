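#' Marker quality control and standardization
#'
#' Drops markers with more than `maxMissing` missing calls (a marker at
#' exactly the threshold is kept) and monomorphic markers, imputes the
#' remaining missing cells with the per-marker mode (ties broken toward the
#' lower dosage), and standardizes each column to mean 0, SD 1 with the
#' sample standard deviation.
#'
#' @param raw lines x markers dosage matrix with values in 0/1/2 or NA.
#' @param maxMissing missingness threshold per marker (default 0.10).
#' @param impute impute remaining missing calls by the marker mode
#'   (default TRUE; with FALSE any residual NA is an error).
#' @return A [MarkerMatrix].
#' @export
qcAndStandardize <- function(raw, maxMissing = 0.10, impute = TRUE) {
  raw <- as.matrix(raw)
  if (is.null(colnames(raw))) colnames(raw) <- paste0("m", seq_len(ncol(raw)))
  if (is.null(rownames(raw))) rownames(raw) <- paste0("L", seq_len(nrow(raw)))
  ok <- raw %in% c(0, 1, 2) | is.na(raw)
  if (!all(ok)) stop("dosages must be 0, 1, 2 or missing")
  missFrac <- colMeans(is.na(raw))
  dropped <- data.frame(marker = character(), reason = character(),
                        stringsAsFactors = FALSE)
  hi <- missFrac > maxMissing + 1e-12
  if (any(hi)) dropped <- rbind(dropped,
    data.frame(marker = colnames(raw)[hi], reason = "missingness"))
  X <- raw[, !hi, drop = FALSE]
  mono <- apply(X, 2, function(x) {
    u <- unique(x[!is.na(x)])
    length(u) <= 1L
  })
  if (any(mono)) dropped <- rbind(dropped,
    data.frame(marker = colnames(X)[mono], reason = "monomorphic"))
  X <- X[, !mono, drop = FALSE]
  if (ncol(X) == 0L) stop("all markers removed by QC")
  if (anyNA(X)) {
    if (!impute) stop("missing genotypes present and impute = FALSE")
    for (k in which(colSums(is.na(X)) > 0)) {
      x <- X[, k]
      tab <- table(x)
      mode <- as.numeric(names(tab)[which.max(tab)]) # ties: lower dosage
      X[is.na(x), k] <- mode
    }
  }
  ctr <- colMeans(X)
  scl <- apply(X, 2, stats::sd)
  degenerate <- scl <= 0
  if (any(degenerate)) { # monomorphic after imputation
    dropped <- rbind(dropped,
      data.frame(marker = colnames(X)[degenerate], reason = "monomorphic"))
    X <- X[, !degenerate, drop = FALSE]
    ctr <- ctr[!degenerate]; scl <- scl[!degenerate]
    if (ncol(X) == 0L) stop("all markers removed by QC")
  }
  Xs <- sweep(sweep(X, 2, ctr), 2, scl, "/")
  new("MarkerMatrix", X = Xs, raw = X, centers = ctr, scales = scl,
      dropped = dropped)
}

#' Standardize new genotypes with training constants
#'
#' @param raw lines x markers dosage matrix restricted to the training
#'   marker set.
#' @param mm the training [MarkerMatrix].
#' @return Standardized matrix aligned to the training markers.
#' @export
standardizeWith <- function(raw, mm) {
  raw <- as.matrix(raw)
  mk <- colnames(mm@X)
  if (!all(mk %in% colnames(raw))) stop("marker set mismatch")
  sweep(sweep(raw[, mk, drop = FALSE], 2, mm@centers), 2, mm@scales, "/")
}

#' Genomic relationship (GBLUP) kernel
#'
#' `K = X X' / p` over the standardized marker matrix; the mean diagonal is
#' approximately 1.
#'
#' @param mm a [MarkerMatrix] (or an already standardized matrix).
#' @return A [GenomicKernel] of kind `"GB"`.
#' @export
grm <- function(mm) {
  X <- if (is(mm, "MarkerMatrix")) mm@X else as.matrix(mm)
  if (ncol(X) == 0L) stop("no markers")
  K <- tcrossprod(X) / ncol(X)
  K <- (K + t(K)) / 2
  k <- ensurePSD(K)
  new("GenomicKernel", K = k$K, kind = "GB", h = NA_real_, jitter = k$jitter)
}

#' Squared Euclidean distances between lines
#'
#' `D_ii' = sum_k (x_ik - x_i'k)^2` on standardized markers; with
#' `scaleByMean = TRUE` the matrix is divided by its off-diagonal mean so
#' the Gaussian bandwidth is comparable across panels.
#'
#' @param mm a [MarkerMatrix] or standardized matrix.
#' @param scaleByMean scale distances by their off-diagonal mean.
#' @return Symmetric distance matrix with attribute `"scaled"`.
#' @export
squaredEuclidean <- function(mm, scaleByMean = TRUE) {
  X <- if (is(mm, "MarkerMatrix")) mm@X else as.matrix(mm)
  D <- as.matrix(stats::dist(X))^2
  if (scaleByMean) {
    m <- mean(D[upper.tri(D)])
    if (m > 0) D <- D / m
  }
  attr(D, "scaled") <- scaleByMean
  D
}

#' Gaussian kernel from squared distances
#'
#' `K = exp(-h D)` entrywise: unit diagonal, entries in (0, 1].
#'
#' @param D squared-Euclidean distance matrix.
#' @param h positive bandwidth.
#' @return A [GenomicKernel] of kind `"GK"`.
#' @export
gaussianKernel <- function(D, h) {
  if (h <= 0) stop("bandwidth h must be > 0")
  K <- exp(-h * as.matrix(D))
  attr(K, "scaled") <- NULL
  K <- (K + t(K)) / 2
  k <- ensurePSD(K)
  new("GenomicKernel", K = k$K, kind = "GK", h = h, jitter = k$jitter)
}

#' Empirical-Bayes bandwidth selection for the Gaussian kernel
#'
#' For each candidate h the marginal likelihood of
#' `y = mu + u + e, u ~ N(0, s2u K(h))` is profiled over a coarse inner grid
#' of variance ratios via the eigendecomposition of `K(h)` (mu and the
#' residual variance are profiled analytically). Returns the candidate with
#' the highest evidence; ties break toward the smaller h.
#'
#' @param D squared-distance matrix (ideally mean-scaled).
#' @param y phenotype vector aligned to D's rows (standardized).
#' @param grid candidate bandwidths.
#' @param ratioGrid inner grid of s2u/s2e ratios.
#' @return list with `h`, `profile` (data.frame h, logEvidence) and the
#'   inner ratio chosen at the optimum.
#' @export
estimateBandwidth <- function(D, y,
                              grid = c(0.1, 0.25, 0.5, 0.75, 1, 1.5, 2, 3, 5),
                              ratioGrid = exp(seq(log(0.05), log(20),
                                                  length.out = 13)),
                              priorShape = 3, priorRate = 1.5) {
  if (!length(grid)) stop("empty bandwidth grid")
  y <- as.numeric(y)
  if (stats::sd(y) == 0) stop("degenerate phenotype: zero variance")
  n <- length(y)
  ev <- vapply(grid, function(h) {
    K <- exp(-h * as.matrix(D))
    eg <- eigen((K + t(K)) / 2, symmetric = TRUE)
    U <- eg$vectors; d <- pmax(eg$values, 0)
    ys <- crossprod(U, y)
    os <- crossprod(U, rep(1, n))
    best <- -Inf
    for (r in ratioGrid) {
      w <- r * d + 1
      muh <- sum(os * ys / w) / sum(os^2 / w)
      rss <- sum((ys - os * muh)^2 / w)
      ll <- -0.5 * (sum(log(w)) + n * log(rss / n) + n)
      if (ll > best) best <- ll
    }
    best + stats::dgamma(h, priorShape, priorRate, log = TRUE)
  }, numeric(1))
  ord <- order(grid)
  gridO <- grid[ord]; evO <- ev[ord]
  h <- gridO[which.max(evO)] # which.max takes the first (smallest h) on ties
  list(h = h, profile = data.frame(h = gridO, logEvidence = evO))
}

# PSD repair: add escalating diagonal jitter (1e-8 x10 up to 1e-4) until the
# smallest eigenvalue clears -1e-8; fail beyond that.
ensurePSD <- function(K, tol = 1e-8) {
  ev <- min(eigen(K, symmetric = TRUE, only.values = TRUE)$values)
  jitter <- 0
  if (ev < -tol) {
    j <- 1e-8
    repeat {
      if (min(eigen(K + diag(j, nrow(K)), symmetric = TRUE,
                    only.values = TRUE)$values) >= -tol) {
        K <- K + diag(j, nrow(K)); jitter <- j; break
      }
      j <- j * 10
      if (j > 1e-4) stop("kernel not positive semidefinite after repair")
    }
  }
  list(K = K, jitter = jitter)
}

# eigendecomposition used by the samplers, dropping numerically null modes
eigenKernel <- function(K, tol = 1e-8) {
  if (is(K, "GenomicKernel")) K <- K@K
  eg <- eigen((K + t(K)) / 2, symmetric = TRUE)
  keep <- eg$values > tol * max(eg$values)
  list(U = eg$vectors[, keep, drop = FALSE], d = eg$values[keep])
}
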