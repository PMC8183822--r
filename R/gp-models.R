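#' Assemble a multi-environment dataset
#'
#' Stacks a genotype x environment table of (standardized) adjusted means
#' into the observation vector used by the multi-environment models,
#' tracking which line and environment each observation belongs to. Cells
#' can be masked (held out): they are excluded from the likelihood but
#' GEBVs are still produced for them.
#'
#' @param means an [AdjustedMeansTable] or genotype x environment matrix.
#' @param mask optional logical matrix of the same shape, TRUE = hold out.
#' @return list with components `y`, `line`, `env` (parallel vectors over
#'   observations), `lines`, `envs`, `mask`.
#' @export
meDataset <- function(means, mask = NULL) {
  M <- if (is(means, "AdjustedMeansTable")) means@means else as.matrix(means)
  if (is.null(rownames(M))) rownames(M) <- paste0("L", seq_len(nrow(M)))
  if (is.null(colnames(M))) colnames(M) <- paste0("E", seq_len(ncol(M)))
  if (is.null(mask)) mask <- matrix(FALSE, nrow(M), ncol(M))
  mask <- mask | is.na(M)
  obs <- which(!mask, arr.ind = TRUE)
  if (nrow(obs) == 0L) stop("no observed cells")
  envCounts <- table(factor(obs[, 2], levels = seq_len(ncol(M))))
  if (any(envCounts == 0))
    stop("an environment has zero observations: ",
         colnames(M)[which(envCounts == 0)[1]])
  list(y = M[obs], line = obs[, 1], env = obs[, 2],
       lines = rownames(M), envs = colnames(M), mask = mask)
}

# shared machinery -----------------------------------------------------------

.kernelOf <- function(K) if (is(K, "GenomicKernel")) K@K else as.matrix(K)
.kindOf <- function(K) if (is(K, "GenomicKernel")) K@kind else "GB"

# Run the eigenbasis Gibbs sampler and package a GPFit.
# comps: list of list(map, ek, group, label, env (NA for main))
.runKernelModel <- function(model, kind, y, W, comps, ngroups, groupLabels,
                            mcmc, lines, envs, gebvFun, df = 5, R2 = 0.5) {
  vy <- stats::var(y)
  ngen <- ngroups
  Sg <- rep(R2 * vy / ngen * (df + 2) / df, ngroups)
  # normalise by mean kernel diagonal per group (first comp in group)
  for (g in seq_len(ngroups)) {
    r <- which(vapply(comps, function(cp) cp$group == g, logical(1)))[1]
    mdiag <- mean(comps[[r]]$meanDiag)
    Sg[g] <- Sg[g] / max(mdiag, 1e-8)
  }
  Se <- (1 - R2) * vy * (df + 2) / df
  cpp <- lapply(comps, function(cp)
    list(map = as.integer(cp$map), U = cp$ek$U, d = cp$ek$d,
         group = as.integer(cp$group)))
  res <- withSeed(mcmc$seed,
    kernel_gibbs(y, W, cpp, as.integer(ngroups), rep(df, ngroups), Sg,
                 df, Se, mcmc$iterations, mcmc$burnin, mcmc$thin))
  chain <- res$chain
  colnames(chain) <- c(groupLabels, "varE")
  g <- lapply(res$g, as.numeric)
  out <- gebvFun(g, res$beta)
  vc <- data.frame(component = colnames(chain),
                   environment = c(vapply(seq_len(ngroups), function(gr) {
                     r <- which(vapply(comps, function(cp)
                       cp$group == gr, logical(1)))
                     ev <- unique(vapply(comps[r], function(cp)
                       as.character(cp$env), character(1)))
                     if (length(ev) == 1 && !is.na(ev)) ev else NA_character_
                   }, character(1)), NA_character_),
                   estimate = colMeans(chain),
                   sd = apply(chain, 2, stats::sd))
  rownames(vc) <- NULL
  dg <- data.frame(parameter = colnames(chain),
                   ess = apply(chain, 2, essBasic),
                   gewekeZ = apply(chain, 2, gewekeZ))
  new("GPFit", model = model, kind = kind,
      beta = setNames(as.numeric(res$beta), colnames(W)),
      u0 = out$u0, uE = out$uE, varComp = vc, gebv = out$gebv,
      chain = chain, diagnostics = dg, lines = lines, envs = envs)
}

#' Fit a single-environment kernel model
#'
#' `y = 1 mu + u + e`, `u ~ N(0, s2u K)`, `e ~ N(0, I s2e)`, sampled in the
#' eigenbasis of K. Lines with missing (masked) phenotypes still receive a
#' GEBV through their kernel relationships, which is how held-out lines are
#' predicted. With the genomic relationship matrix this is GBLUP; with a
#' Gaussian kernel it is RKHS regression.
#'
#' @param K a [GenomicKernel] (or PSD matrix) over all lines.
#' @param y named phenotype vector aligned to K, NA = masked.
#' @param mcmc an [mcmcConfig()].
#' @param ek optional precomputed [eigenKernel()] of K (reused across
#'   cross-validation partitions).
#' @return A [GPFit] with a one-column GEBV matrix.
#' @export
fitSEKernel <- function(K, y, mcmc = mcmcConfig("test"), ek = NULL) {
  Km <- .kernelOf(K)
  n <- nrow(Km)
  y <- as.numeric(y)
  obs <- which(is.finite(y))
  if (length(obs) < 3) stop("need at least 3 observed phenotypes")
  if (is.null(ek)) ek <- eigenKernel(Km)
  lines <- rownames(Km)
  if (is.null(lines)) lines <- paste0("L", seq_len(n))
  comps <- list(list(map = obs, ek = ek, group = 1L, label = "varU",
                     env = NA, meanDiag = mean(diag(Km))))
  # map must be per-observation level indices
  comps[[1]]$map <- obs
  W <- matrix(1, length(obs), 1, dimnames = list(NULL, "(Intercept)"))
  .runKernelModel("SE", .kindOf(K), y[obs], W, comps, 1L, "varU", mcmc,
                  lines, "E1", function(g, beta) {
                    u <- g[[1]]
                    list(u0 = u, uE = matrix(0, n, 1),
                         gebv = matrix(u, n, 1,
                                       dimnames = list(lines, "E1")))
                  })
}

#' Fit the multi-environment main-effect (MM) model
#'
#' `y = 1 mu + Ze be + Zu u + e` with fixed environment effects (flat
#' priors) and one genetic effect per line, constant across environments:
#' `u ~ N(0, s2u0 K)`. Equivalent, for balanced data, to a
#' single-environment fit on per-line environment means.
#'
#' @param data a [meDataset()].
#' @param K kernel over all lines.
#' @param mcmc an [mcmcConfig()].
#' @param ek optional precomputed eigendecomposition.
#' @return A [GPFit]; the GEBV matrix repeats `u` across environments.
#' @export
fitMM <- function(data, K, mcmc = mcmcConfig("test"), ek = NULL) {
  Km <- .kernelOf(K)
  if (is.null(ek)) ek <- eigenKernel(Km)
  W <- .envDesign(data)
  comps <- list(list(map = data$line, ek = ek, group = 1L, label = "varU0",
                     env = NA, meanDiag = mean(diag(Km))))
  n <- length(data$lines); J <- length(data$envs)
  .runKernelModel("MM", .kindOf(K), data$y, W, comps, 1L, "varU0", mcmc,
                  data$lines, data$envs, function(g, beta) {
                    u <- g[[1]]
                    list(u0 = u, uE = matrix(0, n, J),
                         gebv = matrix(u, n, J,
                                       dimnames = list(data$lines,
                                                       data$envs)))
                  })
}

#' Fit the single-variance GxE deviation (MDs) model
#'
#' Adds to MM an interaction effect with covariance
#' `s2ue [Zu K Zu'] o [Ze Ze']` (Hadamard product): realized as one
#' independent kernel-distributed deviation per environment, all sharing the
#' single interaction variance, which is the same covariance structure
#' without forming the N x N product.
#'
#' @inheritParams fitMM
#' @return A [GPFit]; GEBV(i,j) = u_i + ue_(i,j).
#' @export
fitMDs <- function(data, K, mcmc = mcmcConfig("test"), ek = NULL) {
  Km <- .kernelOf(K)
  if (is.null(ek)) ek <- eigenKernel(Km)
  W <- .envDesign(data)
  n <- length(data$lines); J <- length(data$envs)
  md <- mean(diag(Km))
  comps <- c(
    list(list(map = data$line, ek = ek, group = 1L, label = "varU0",
              env = NA, meanDiag = md)),
    lapply(seq_len(J), function(j)
      list(map = ifelse(data$env == j, data$line, 0L), ek = ek, group = 2L,
           label = "varUE", env = data$envs[j], meanDiag = md)))
  .runKernelModel("MDs", .kindOf(K), data$y, W, comps, 2L,
                  c("varU0", "varUE"), mcmc, data$lines, data$envs,
                  function(g, beta) {
                    u <- g[[1]]
                    uE <- vapply(seq_len(J), function(j) g[[j + 1]],
                                 numeric(n))
                    uE <- matrix(uE, n, J)
                    list(u0 = u, uE = uE,
                         gebv = matrix(u, n, J) + uE)
                  })
}

#' Fit the environment-specific variance GxE deviation (MDe) model
#'
#' `y = 1 mu + Ze be + Zu u0 + uE1 + ... + uEj + e`: a main genetic effect
#' `u0 ~ N(0, s2u0 K)` plus an independent environment-specific effect
#' `uEj ~ N(0, s2uEj Kj)` per environment, each with its own variance (the
#' block-diagonal K_E structure). With Gaussian kernels, `Kj` can carry an
#' environment-specific bandwidth.
#'
#' @param data a [meDataset()].
#' @param K main-effect kernel over all lines.
#' @param envKernels either NULL (reuse `K` per environment), a single
#'   kernel, or a list of one kernel per environment.
#' @param mcmc an [mcmcConfig()].
#' @param ek,envEk optional precomputed eigendecompositions.
#' @return A [GPFit] with one interaction variance per environment.
#' @export
fitMDe <- function(data, K, envKernels = NULL, mcmc = mcmcConfig("test"),
                   ek = NULL, envEk = NULL) {
  Km <- .kernelOf(K)
  if (is.null(ek)) ek <- eigenKernel(Km)
  J <- length(data$envs)
  if (is.null(envKernels)) envKernels <- rep(list(K), J)
  if (!is.list(envKernels)) envKernels <- rep(list(envKernels), J)
  if (length(envKernels) != J)
    stop("kernel/environment count mismatch: need one kernel per environment")
  if (is.null(envEk)) envEk <- lapply(envKernels, function(k)
    eigenKernel(.kernelOf(k)))
  W <- .envDesign(data)
  n <- length(data$lines)
  comps <- c(
    list(list(map = data$line, ek = ek, group = 1L, label = "varU0",
              env = NA, meanDiag = mean(diag(Km)))),
    lapply(seq_len(J), function(j)
      list(map = ifelse(data$env == j, data$line, 0L), ek = envEk[[j]],
           group = j + 1L, label = paste0("varUE_", data$envs[j]),
           env = data$envs[j],
           meanDiag = mean(diag(.kernelOf(envKernels[[j]]))))))
  labels <- c("varU0", paste0("varUE_", data$envs))
  kind <- paste(unique(c(.kindOf(K),
                         vapply(envKernels, .kindOf, character(1)))),
                collapse = "/")
  .runKernelModel("MDe", kind, data$y, W, comps, J + 1L, labels, mcmc,
                  data$lines, data$envs, function(g, beta) {
                    u <- g[[1]]
                    uE <- vapply(seq_len(J), function(j) g[[j + 1]],
                                 numeric(n))
                    uE <- matrix(uE, n, J)
                    list(u0 = u, uE = uE, gebv = matrix(u, n, J) + uE)
                  })
}

# fixed design: intercept + environment dummies (treatment coding)
.envDesign <- function(data) {
  J <- length(data$envs)
  W <- matrix(0, length(data$y), J)
  W[, 1] <- 1
  if (J > 1)
    for (j in 2:J) W[data$env == j, j] <- 1
  colnames(W) <- c("(Intercept)", if (J > 1) data$envs[-1])
  W
}

#' Environment-level fixed-effect means of a multi-environment fit
#'
#' @param fit a [GPFit] from [fitMM()], [fitMDs()] or [fitMDe()].
#' @return Named vector: intercept plus environment contrast per
#'   environment.
#' @export
envEffects <- function(fit) {
  b <- fit@beta
  J <- length(fit@envs)
  out <- rep(b[1], J)
  if (J > 1) out[2:J] <- b[1] + b[2:J]
  setNames(out, fit@envs)
}
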