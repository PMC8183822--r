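#' Modified Rogers distance between inbred lines
#'
#' `MRD_ij = sqrt( sum_k (f_ik - f_jk)^2 / (2p) )` with `f = dosage/2` the
#' within-line allele frequency (0 or 1 for DH lines). Lies in [0, 1]; two
#' lines opposite at every marker are 1/sqrt(2) apart.
#'
#' @param X lines x markers dosage matrix (0/1/2) or a [MarkerMatrix]
#'   (its raw post-QC dosages are used).
#' @return Symmetric distance matrix.
#' @export
modifiedRogersDistance <- function(X) {
  raw <- if (is(X, "MarkerMatrix")) X@raw else as.matrix(X)
  if (any(raw == 1))
    warning("heterozygous calls present; using f = dosage/2")
  f <- raw / 2
  D2 <- as.matrix(stats::dist(f))^2 / (2 * ncol(f))
  sqrt(D2)
}

#' Criterion context for training-set optimization
#'
#' Bundles the kernel and the variance ratio
#' `lambda = s2e / s2g` the mixed-model criteria need. When `lambda` is not
#' given, it defaults to `(1 - h2) / h2` with h2 from a preliminary GBLUP
#' fit to `y` (or 0.5/0.5 = 1 if no phenotype is supplied).
#'
#' @param K a [GenomicKernel] or PSD matrix.
#' @param lambda variance ratio (> 0), or NULL to derive from `y`.
#' @param y optional phenotype vector for deriving lambda.
#' @param mcmc MCMC settings for the preliminary fit.
#' @return list with `K`, `Kinv`, `lambda`, `n`.
#' @export
criterionContext <- function(K, lambda = NULL, y = NULL,
                             mcmc = mcmcConfig("test", seed = 1L)) {
  Km <- .kernelOf(K)
  Km <- ensurePSD(Km)$K
  if (is.null(lambda)) {
    if (is.null(y)) {
      lambda <- 1
    } else {
      fit <- fitSEKernel(K, as.numeric(scale(y)), mcmc = mcmc)
      vc <- fit@varComp
      vu <- vc$estimate[vc$component == "varU"]
      ve <- vc$estimate[vc$component == "varE"]
      h2 <- vu / (vu + ve)
      lambda <- (1 - h2) / h2
    }
  }
  if (lambda <= 0) stop("lambda must be > 0")
  Kinv <- tryCatch(solve(Km), error = function(e) {
    solve(Km + diag(1e-6, nrow(Km)))
  })
  list(K = Km, Kinv = Kinv, lambda = lambda, n = nrow(Km))
}

# core matrix pieces shared by CDmean / PEV:
# A = Z'MZ + lambda K^-1 with Z the incidence of training observations and
# M the projection removing the intercept over training obs.
.criterionCore <- function(ctx, train) {
  n <- ctx$n
  t <- length(train)
  ZMZ <- matrix(0, n, n)
  ZMZ[train, train] <- -1 / t
  diag(ZMZ)[train] <- diag(ZMZ)[train] + 1
  A <- ZMZ + ctx$lambda * ctx$Kinv
  B <- tryCatch(solve(A), error = function(e)
    solve(A + diag(1e-8, n)))
  B
}

# mean over target contrasts (line minus population mean) of a quadratic
# form c' Q c, vectorized over targets
.contrastQuad <- function(Q, targets, n) {
  u <- rep(1 / n, n)
  Qu <- drop(Q %*% u)
  uQu <- sum(u * Qu)
  diag(Q)[targets] - 2 * Qu[targets] + uQu
}

#' Mean coefficient of determination (CDmean) of a training set
#'
#' For each non-training line i, the coefficient of determination of the
#' contrast c_i = (line i - population mean) is
#' `CD(c_i) = c_i'(K - lambda B)c_i / (c_i' K c_i)` with
#' `B = (Z'MZ + lambda K^-1)^-1`; the criterion (to maximize) is the mean
#' over non-training lines.
#'
#' @param ctx a [criterionContext()].
#' @param train integer indices of the training set.
#' @param targets indices to evaluate on (default: the complement,
#'   untargeted mode).
#' @return Mean CD, in [0, 1].
#' @export
cdmeanCriterion <- function(ctx, train, targets = NULL) {
  if (!length(train)) stop("training set is empty")
  if (is.null(targets)) targets <- setdiff(seq_len(ctx$n), train)
  if (!length(targets)) stop("empty target set")
  B <- .criterionCore(ctx, train)
  num <- .contrastQuad(ctx$K - ctx$lambda * B, targets, ctx$n)
  den <- .contrastQuad(ctx$K, targets, ctx$n)
  mean(pmin(1, pmax(0, num / den)))
}

#' Mean prediction error variance (PEV) of a training set
#'
#' `mean over targets of c_i' B c_i` (in residual-variance units); smaller
#' is better.
#'
#' @inheritParams cdmeanCriterion
#' @return Mean PEV (>= 0), to minimize.
#' @export
pevCriterion <- function(ctx, train, targets = NULL) {
  if (!length(train)) stop("training set is empty")
  if (is.null(targets)) targets <- setdiff(seq_len(ctx$n), train)
  if (!length(targets)) stop("empty target set")
  B <- .criterionCore(ctx, train)
  mean(pmax(0, .contrastQuad(B, targets, ctx$n)))
}

#' Expected-accuracy score (rScore) of a training set
#'
#' Kernel-block estimate of the expected predictive correlation for each
#' non-training line j:
#' `acc_j = sqrt( k_jT (K_TT + lambda I)^-1 k_Tj / k_jj )`; the criterion is
#' the mean over targets.
#'
#' @inheritParams cdmeanCriterion
#' @return Mean expected accuracy, in [0, 1].
#' @export
rscoreCriterion <- function(ctx, train, targets = NULL) {
  if (!length(train)) stop("training set is empty")
  if (is.null(targets)) targets <- setdiff(seq_len(ctx$n), train)
  if (!length(targets)) stop("empty target set")
  KTT <- ctx$K[train, train, drop = FALSE]
  S <- solve(KTT + diag(ctx$lambda, length(train)))
  kT <- ctx$K[train, targets, drop = FALSE]
  acc2 <- colSums(kT * (S %*% kT)) / diag(ctx$K)[targets]
  mean(sqrt(pmin(1, pmax(0, acc2))))
}

#' Exchange optimization of a training set
#'
#' Seeded random start, then repeated first-improvement single swaps between
#' selected and unselected lines until a full pass brings no improvement or
#' `maxIters` passes elapse. The criterion-value trajectory is monotone.
#'
#' @param criterion `"CDmean"`, `"PEV"` or `"rScore"` (PEV is minimized,
#'   the others maximized), or a function(ctx, train).
#' @param ctx a [criterionContext()].
#' @param nSelect training-set size (< n).
#' @param maxIters maximum full passes.
#' @param seed integer seed for the start.
#' @param lines optional line ids for reporting.
#' @return A [TPSelection].
#' @export
exchangeOptimize <- function(criterion, ctx, nSelect, maxIters = 20L,
                             seed = 1L, lines = NULL) {
  n <- ctx$n
  if (nSelect >= n) stop("nSelect must be < n")
  if (is.null(lines)) lines <- rownames(ctx$K)
  if (is.null(lines)) lines <- paste0("L", seq_len(n))
  minimize <- identical(criterion, "PEV")
  fun <- if (is.function(criterion)) criterion
  else switch(criterion, CDmean = cdmeanCriterion, PEV = pevCriterion,
              rScore = rscoreCriterion,
              stop("unknown criterion: ", criterion))
  sgn <- if (minimize) -1 else 1
  withSeed(seed, {
    sel <- sort(sample.int(n, nSelect))
    val <- fun(ctx, sel)
    traj <- val
    for (pass in seq_len(maxIters)) {
      improved <- FALSE
      for (si in seq_along(sel)) {
        out <- setdiff(seq_len(n), sel)
        for (cand in out) {
          trial <- sel
          trial[si] <- cand
          v <- fun(ctx, sort(trial))
          if (sgn * v > sgn * val + 1e-12) {
            sel <- sort(trial)
            val <- v
            traj <- c(traj, val)
            improved <- TRUE
            break # first improvement
          }
        }
      }
      if (!improved) break
    }
    new("TPSelection",
        criterion = if (is.function(criterion)) "custom" else criterion,
        selected = lines[sel], value = val, trajectory = traj,
        seed = as.integer(seed))
  })
}

#' Entry-to-nearest-entry training-set selection
#'
#' Maximizes the mean, over selected entries, of the (modified Rogers)
#' distance to the closest other selected entry: a pure diversity objective.
#' Greedy max-min seeding followed by first-improvement swap refinement;
#' `alwaysInclude` forces entries (e.g. the founder parents) into the set.
#'
#' @param D distance matrix (e.g. [modifiedRogersDistance()]).
#' @param nSelect total entries to select (>= 2, including forced ones).
#' @param alwaysInclude ids or indices that must be selected.
#' @param maxIters swap-refinement passes.
#' @param seed integer seed (tie-breaking).
#' @return A [TPSelection] with criterion `"E-NE"`.
#' @export
entryToNearestEntrySelect <- function(D, nSelect, alwaysInclude = NULL,
                                      maxIters = 20L, seed = 1L) {
  D <- as.matrix(D)
  n <- nrow(D)
  if (nSelect < 2) stop("nSelect must be >= 2")
  if (nSelect > n) stop("nSelect must be <= n")
  ids <- rownames(D)
  if (is.null(ids)) ids <- paste0("L", seq_len(n))
  forced <- if (is.character(alwaysInclude)) match(alwaysInclude, ids)
  else as.integer(alwaysInclude)
  if (anyNA(forced)) stop("alwaysInclude ids not found")
  objective <- function(sel) {
    if (length(sel) < 2) return(0)
    sub <- D[sel, sel, drop = FALSE]
    diag(sub) <- Inf
    mean(apply(sub, 1, min))
  }
  withSeed(seed, {
    sel <- unique(forced)
    if (length(sel) == 0L) {
      # seed with the most distant pair
      w <- which(D == max(D), arr.ind = TRUE)[1, ]
      sel <- as.integer(w)
    }
    while (length(sel) < nSelect) {
      out <- setdiff(seq_len(n), sel)
      # add the entry with the largest distance to its nearest selected
      dmin <- apply(D[out, sel, drop = FALSE], 1, min)
      sel <- c(sel, out[which.max(dmin)])
    }
    sel <- sort(sel[seq_len(nSelect)])
    val <- objective(sel)
    traj <- val
    swappable <- setdiff(sel, forced)
    for (pass in seq_len(maxIters)) {
      improved <- FALSE
      for (s in swappable) {
        for (cand in setdiff(seq_len(n), sel)) {
          trial <- sort(c(setdiff(sel, s), cand))
          v <- objective(trial)
          if (v > val + 1e-12) {
            sel <- trial
            swappable <- setdiff(sel, forced)
            val <- v
            traj <- c(traj, val)
            improved <- TRUE
            break
          }
        }
        if (improved) break
      }
      if (!improved) break
    }
    new("TPSelection", criterion = "E-NE", selected = ids[sel],
        value = val, trajectory = traj, seed = as.integer(seed))
  })
}
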