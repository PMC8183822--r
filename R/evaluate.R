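#' Random training/validation partitions
#'
#' Each replicate draws `tpSize` training lines uniformly without
#' replacement; the remainder is the validation set.
#'
#' @param n number of lines.
#' @param tpSize training-set size (< n).
#' @param nReps number of partitions (100 in the standard protocol).
#' @param seed integer seed.
#' @return A [PartitionSet] of scheme `"random"`.
#' @export
makeRandomPartitions <- function(n, tpSize, nReps = 100L, seed = 1L) {
  if (tpSize >= n) stop("tpSize must be < n")
  withSeed(seed, {
    parts <- lapply(seq_len(nReps), function(r) {
      tr <- sort(sample.int(n, tpSize))
      list(train = tr, validation = setdiff(seq_len(n), tr))
    })
    new("PartitionSet", scheme = "random", partitions = parts,
        nReps = as.integer(nReps), seed = as.integer(seed))
  })
}

# Fit one single-environment model on a training set and predict everyone.
# Returns a GEBV vector over all lines.
.fitPredictSE <- function(model, train, y, X = NULL, K = NULL, D = NULL,
                          ek = NULL, mcmc = mcmcConfig("test"),
                          bandwidthGrid = c(0.1, 0.25, 0.5, 0.75, 1,
                                            1.5, 2, 3, 5)) {
  n <- length(y)
  if (model %in% c("GB", "GK")) {
    if (model == "GK") {
      h <- estimateBandwidth(D[train, train], y[train],
                             grid = bandwidthGrid)$h
      K <- gaussianKernel(D, h)
      ek <- NULL
    }
    ym <- rep(NA_real_, n)
    ym[train] <- y[train]
    fit <- fitSEKernel(K, ym, mcmc = mcmc, ek = ek)
    drop(gebv(fit))
  } else {
    Xs <- if (is(X, "MarkerMatrix")) X@X else X
    prior <- wgrPriorConfig(model)
    fit <- fitWGR(Xs[train, , drop = FALSE], y[train], prior, mcmc)
    predictGEBV(fit, Xs)
  }
}

#' Predictive-ability sweep over training-population sizes
#'
#' For each size x model x partition: train on the training population,
#' predict the validation population, record the Pearson correlation
#' between GEBVs and adjusted means.
#'
#' @param X a [MarkerMatrix] for the whole panel.
#' @param y standardized adjusted means aligned to X.
#' @param sizes training-set sizes (the standard sweep is 80-160 by 10).
#' @param models subset of `c("GB", "GK", "BayesA", "BayesB", "BL")`.
#' @param nReps partitions per size.
#' @param mcmc an [mcmcConfig()].
#' @param seed integer seed.
#' @return list with `results` (data.frame size, model, partition, r) and
#'   `summary` (mean/sd per size x model as [CVResult]s).
#' @export
tpSizeSweep <- function(X, y, sizes = seq(80, 160, by = 10),
                        models = c("GB", "GK", "BayesA", "BayesB", "BL"),
                        nReps = 100L, mcmc = mcmcConfig("test"),
                        seed = 1L) {
  n <- length(y)
  K <- grm(X)
  ek <- eigenKernel(K@K)
  D <- if ("GK" %in% models) squaredEuclidean(X) else NULL
  rows <- list()
  for (s in seq_along(sizes)) {
    ps <- makeRandomPartitions(n, sizes[s], nReps, seed = seed + s)
    for (r in seq_len(ps@nReps)) {
      part <- ps@partitions[[r]]
      for (m in models) {
        g <- .fitPredictSE(m, part$train, y, X = X, K = K, D = D, ek = ek,
                           mcmc = mcmcConfig("custom",
                                             iterations = mcmc$iterations,
                                             burnin = mcmc$burnin,
                                             thin = mcmc$thin,
                                             seed = mcmc$seed + 1000L * s +
                                               10L * r))
        rows[[length(rows) + 1L]] <- data.frame(
          size = sizes[s], model = m, partition = r,
          r = stats::cor(g[part$validation], y[part$validation]))
      }
    }
  }
  results <- do.call(rbind, rows)
  summ <- lapply(split(results, list(results$size, results$model),
                       drop = TRUE), function(df)
    new("CVResult", scheme = "random",
        model = paste0(df$model[1], "@", df$size[1]),
        correlations = df$r, detail = df, mean = mean(df$r),
        sd = stats::sd(df$r), nReps = nrow(df)))
  list(results = results, summary = summ)
}

#' Leave-one-out cross-validation of a single-environment model
#'
#' Fits n models, each excluding one line, and reports the single Pearson
#' correlation between the n held-out GEBVs and the adjusted means.
#'
#' @param y adjusted means (standardized).
#' @param X marker matrix (Bayesian models).
#' @param K kernel (GB/GK models).
#' @param model one of `"GB"`, `"GK"`, `"BayesA"`, `"BayesB"`, `"BL"`.
#' @param mcmc an [mcmcConfig()].
#' @return A [CVResult] with one correlation.
#' @export
looCV <- function(y, X = NULL, K = NULL, model = "GB",
                  mcmc = mcmcConfig("test")) {
  n <- length(y)
  if (n < 3) stop("need n >= 3")
  D <- NULL
  ek <- NULL
  if (model %in% c("GB", "GK")) {
    if (is.null(K)) {
      if (is.null(X)) stop("supply X or K")
      K <- if (model == "GB") grm(X) else NULL
    }
    if (model == "GK") {
      D <- squaredEuclidean(X)
    } else ek <- eigenKernel(.kernelOf(K))
  }
  preds <- vapply(seq_len(n), function(i) {
    g <- .fitPredictSE(model, setdiff(seq_len(n), i), y, X = X, K = K,
                       D = D, ek = ek,
                       mcmc = mcmcConfig("custom",
                                         iterations = mcmc$iterations,
                                         burnin = mcmc$burnin,
                                         thin = mcmc$thin,
                                         seed = mcmc$seed + i))
    g[i]
  }, numeric(1))
  if (stats::sd(preds) == 0) {
    warning("constant predictions: correlation undefined")
    r <- NA_real_
  } else r <- stats::cor(preds, y)
  new("CVResult", scheme = "LOO", model = model,
      correlations = if (is.na(r)) numeric() else r,
      detail = data.frame(line = seq_len(n), pred = preds, obs = y),
      mean = r, sd = NA_real_, nReps = 1L)
}

#' CV1 / CV2 partitions for multi-environment data
#'
#' CV1 masks the sampled lines in every environment (newly genotyped,
#' never phenotyped lines). CV2 masks line x environment cells, stratified
#' by environment at the same rate, while guaranteeing every masked line
#' stays observed in at least one environment (sparse-testing prediction).
#'
#' @param data a [meDataset()] (only its dimensions/mask are used).
#' @param scheme `"CV1"` or `"CV2"`.
#' @param trainFraction fraction of lines kept for training (0.9).
#' @param nReps number of partitions.
#' @param seed integer seed.
#' @return A [PartitionSet] whose partitions are logical line x environment
#'   masks (TRUE = held out).
#' @export
makeMEPartitions <- function(data, scheme = c("CV1", "CV2"),
                             trainFraction = 0.9, nReps = 100L, seed = 1L) {
  scheme <- match.arg(scheme)
  n <- length(data$lines); J <- length(data$envs)
  observed <- !data$mask
  if (scheme == "CV2" && J < 2)
    stop("CV2 requires at least 2 environments")
  nVal <- max(1L, round((1 - trainFraction) * n))
  withSeed(seed, {
    parts <- lapply(seq_len(nReps), function(r) {
      m <- matrix(FALSE, n, J, dimnames = list(data$lines, data$envs))
      if (scheme == "CV1") {
        v <- sample.int(n, nVal)
        m[v, ] <- TRUE
      } else {
        for (j in seq_len(J)) {
          inEnv <- which(observed[, j])
          nv <- max(1L, round((1 - trainFraction) * length(inEnv)))
          m[sample(inEnv, nv), j] <- TRUE
        }
        # every masked line must keep >= 1 observed environment
        gone <- which(rowSums(observed & !m) == 0 & rowSums(m) > 0)
        for (i in gone) {
          j <- sample(which(m[i, ] & observed[i, ]), 1)
          m[i, j] <- FALSE
        }
      }
      m & observed # only observed cells can be held out
    })
    new("PartitionSet", scheme = scheme, partitions = parts,
        nReps = as.integer(nReps), seed = as.integer(seed))
  })
}

#' Cross-validate multi-environment models
#'
#' For each partition, refits the model with the partition's cells masked
#' and computes, per environment, the Pearson correlation between GEBVs and
#' the held-out adjusted means; the partition-level predictive ability is
#' the mean over environments with enough held-out cells.
#'
#' @param means genotype x environment matrix (standardized adjusted means).
#' @param K main kernel.
#' @param model `"MM"`, `"MDs"` or `"MDe"`.
#' @param partitions a [PartitionSet] from [makeMEPartitions()].
#' @param mcmc an [mcmcConfig()].
#' @param envKernels optional per-environment kernels for MDe.
#' @return A [CVResult]; `detail` holds per-partition, per-environment
#'   correlations.
#' @export
runMECV <- function(means, K, model = c("MM", "MDs", "MDe"), partitions,
                    mcmc = mcmcConfig("test"), envKernels = NULL) {
  model <- match.arg(model)
  M <- if (is(means, "AdjustedMeansTable")) means@means else as.matrix(means)
  ek <- eigenKernel(.kernelOf(K))
  envEk <- if (model == "MDe") {
    if (is.null(envKernels)) NULL else lapply(envKernels, function(k)
      eigenKernel(.kernelOf(k)))
  } else NULL
  rows <- list()
  for (r in seq_len(partitions@nReps)) {
    mask <- partitions@partitions[[r]]
    data <- meDataset(M, mask = mask)
    mc <- mcmcConfig("custom", iterations = mcmc$iterations,
                     burnin = mcmc$burnin, thin = mcmc$thin,
                     seed = mcmc$seed + r)
    fit <- switch(model,
      MM = fitMM(data, K, mc, ek = ek),
      MDs = fitMDs(data, K, mc, ek = ek),
      MDe = if (is.null(envKernels))
        fitMDe(data, K, mcmc = mc, ek = ek,
               envKernels = NULL,
               envEk = rep(list(ek), length(data$envs)))
      else fitMDe(data, K, envKernels = envKernels, mcmc = mc, ek = ek,
                  envEk = envEk))
    G <- gebv(fit)
    for (j in seq_len(ncol(M))) {
      held <- which(mask[, j] & is.finite(M[, j]))
      if (length(held) >= 3) {
        rows[[length(rows) + 1L]] <- data.frame(
          partition = r, env = colnames(M)[j],
          r = stats::cor(G[held, j], M[held, j]))
      }
    }
  }
  detail <- do.call(rbind, rows)
  perPart <- vapply(split(detail$r, detail$partition), mean, numeric(1))
  new("CVResult", scheme = partitions@scheme, model = model,
      correlations = as.numeric(perPart), detail = detail,
      mean = mean(perPart), sd = stats::sd(perPart),
      nReps = partitions@nReps)
}

#' Summarize predictive ability from predictions and observations
#'
#' @param pred,obs aligned vectors (or matrices over environments).
#' @param by optional grouping (e.g. partition labels).
#' @return data.frame of Pearson correlations (with a warning for groups
#'   of fewer than 3 points, which are skipped).
#' @export
predictiveAbilitySummary <- function(pred, obs, by = NULL) {
  if (is.null(by)) by <- rep(1L, NROW(pred))
  groups <- split(seq_along(by), by)
  out <- lapply(names(groups), function(g) {
    i <- groups[[g]]
    if (length(i) < 3) {
      warning("fewer than 3 points in group ", g, "; correlation skipped")
      return(NULL)
    }
    data.frame(group = g, r = stats::cor(pred[i], obs[i]))
  })
  do.call(rbind, out)
}

#' Welch comparison of two predictive-ability samples
#'
#' Two-sided unequal-variance t-test on the per-partition correlations.
#'
#' @param a,b [CVResult]s or numeric vectors of correlations.
#' @return list with `statistic`, `df`, `p.value`, and the two means.
#' @export
welchCompare <- function(a, b) {
  xa <- if (is(a, "CVResult")) a@correlations else as.numeric(a)
  xb <- if (is(b, "CVResult")) b@correlations else as.numeric(b)
  if (length(xa) < 2 || length(xb) < 2) stop("need >= 2 values per side")
  if (stats::sd(xa) == 0 && stats::sd(xb) == 0) {
    return(list(statistic = 0, df = NA_real_,
                p.value = if (isTRUE(all.equal(mean(xa), mean(xb)))) 1 else 0,
                meanA = mean(xa), meanB = mean(xb)))
  }
  tt <- stats::t.test(xa, xb, var.equal = FALSE)
  list(statistic = unname(tt$statistic), df = unname(tt$parameter),
       p.value = tt$p.value, meanA = mean(xa), meanB = mean(xb))
}

#' Principal component analysis of the marker matrix
#'
#' Centred PCA via singular value decomposition.
#'
#' @param X a [MarkerMatrix] or numeric matrix (lines x markers).
#' @param nComponents components to return.
#' @return list with `scores` (lines x components) and `varianceFraction`.
#' @export
runPCA <- function(X, nComponents = 2L) {
  Xs <- if (is(X, "MarkerMatrix")) X@X else as.matrix(X)
  if (nrow(Xs) < 2) stop("need at least 2 lines")
  if (all(apply(Xs, 2, stats::sd) == 0)) stop("constant matrix")
  pc <- stats::prcomp(Xs, center = TRUE, scale. = FALSE)
  k <- min(nComponents, ncol(pc$x))
  vf <- pc$sdev^2 / sum(pc$sdev^2)
  list(scores = pc$x[, seq_len(k), drop = FALSE],
       varianceFraction = vf[seq_len(k)])
}

#' Linkage-disequilibrium decay profile
#'
#' Within-chromosome pairwise r2 (squared allelic correlation; for DH lines
#' the genotype columns are haplotypes), association p-value from the
#' chi-square statistic n r2 with 1 df, pairs with p above the cutoff
#' filtered out, and the rest binned by physical distance into half-open
#' 100-kb windows and averaged per chromosome.
#'
#' @param X dosage matrix (lines x markers), [MarkerMatrix] raw dosages or
#'   [MagicPopulation].
#' @param map genetic map (needs `bp`); defaults to the population's map.
#' @param pCut association p-value cutoff (pairs with p > pCut dropped).
#' @param binBp bin width in bp.
#' @param maxPairsPerChrom optional cap: marker pairs beyond it are
#'   subsampled (seeded).
#' @param seed seed for the optional subsampling.
#' @return list with `pairs` (marker pair records) and `bins`
#'   (per-chromosome and genome-wide mean r2 per distance bin).
#' @export
ldDecay <- function(X, map = NULL, pCut = 0.001, binBp = 1e5,
                    maxPairsPerChrom = 50000L, seed = 1L) {
  if (is(X, "MagicPopulation")) {
    if (is.null(map)) map <- geneticMap(X)
    X <- markerMatrix(X)
  } else if (is(X, "MarkerMatrix")) X <- X@raw
  X <- as.matrix(X)
  if (is.null(map)) stop("a genetic map with bp positions is required")
  n <- nrow(X)
  keep <- intersect(colnames(X), map$marker)
  if (length(keep) < 2) stop("no mapped markers")
  map <- map[match(keep, map$marker), ]
  X <- X[, keep, drop = FALSE]
  allPairs <- list()
  for (ch in unique(map$chrom)) {
    idx <- which(map$chrom == ch)
    if (length(idx) < 2) next
    pr <- t(utils::combn(idx, 2L))
    if (nrow(pr) > maxPairsPerChrom) {
      pr <- withSeed(seed,
        pr[sample.int(nrow(pr), maxPairsPerChrom), , drop = FALSE])
    }
    sub <- X[, idx, drop = FALSE]
    sds <- apply(sub, 2, stats::sd)
    C <- suppressWarnings(stats::cor(sub))
    r2 <- C[cbind(match(pr[, 1], idx), match(pr[, 2], idx))]^2
    bad <- sds[match(pr[, 1], idx)] == 0 | sds[match(pr[, 2], idx)] == 0
    r2[bad] <- NA
    p <- stats::pchisq(n * r2, df = 1, lower.tail = FALSE)
    allPairs[[ch]] <- data.frame(
      chrom = ch, m1 = map$marker[pr[, 1]], m2 = map$marker[pr[, 2]],
      distBp = abs(map$bp[pr[, 2]] - map$bp[pr[, 1]]),
      r2 = r2, p = p)
  }
  pairs <- do.call(rbind, allPairs)
  rownames(pairs) <- NULL
  kept <- pairs[!is.na(pairs$r2) & pairs$p <= pCut, , drop = FALSE]
  if (nrow(kept)) {
    kept$bin <- floor(kept$distBp / binBp)
    bins <- aggregate(r2 ~ chrom + bin, data = kept, FUN = mean)
    counts <- aggregate(r2 ~ chrom + bin, data = kept, FUN = length)
    bins$nPairs <- counts$r2
    bins$binStartBp <- bins$bin * binBp
    gw <- do.call(rbind, lapply(split(bins, bins$bin), function(df)
      data.frame(chrom = "genome", bin = df$bin[1],
                 r2 = sum(df$r2 * df$nPairs) / sum(df$nPairs),
                 nPairs = sum(df$nPairs),
                 binStartBp = df$bin[1] * binBp)))
    bins <- rbind(bins[, colnames(gw)], gw)
  } else bins <- data.frame(chrom = character(), bin = integer(),
                            r2 = numeric(), nPairs = integer(),
                            binStartBp = numeric())
  list(pairs = pairs, bins = bins)
}
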