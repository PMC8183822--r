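#' MCMC run-length configuration
#'
#' The `"test"` profile (5,000 iterations, 1,000 burn-in, thin 5) is the
#' desk-scale default; the `"production"` profile runs analysis-grade
#' chains (500,000 iterations, 10,000 burn-in, thin 5).
#'
#' @param profile `"test"`, `"production"`, or `"custom"`.
#' @param iterations,burnin,thin used when `profile = "custom"`.
#' @param seed integer seed for the chain.
#' @return list with iterations, burnin, thin, seed.
#' @export
mcmcConfig <- function(profile = c("test", "production", "custom"),
                       iterations = 5000L, burnin = 1000L, thin = 5L,
                       seed = 1L) {
  profile <- match.arg(profile)
  cfg <- switch(profile,
    test = list(iterations = 5000L, burnin = 1000L, thin = 5L),
    production = list(iterations = 500000L, burnin = 10000L, thin = 5L),
    custom = list(iterations = as.integer(iterations),
                  burnin = as.integer(burnin), thin = as.integer(thin)))
  if (cfg$burnin >= cfg$iterations) stop("burn-in must be < iterations")
  if (cfg$thin < 1L) stop("thinning must be >= 1")
  cfg$seed <- as.integer(seed)
  cfg
}

#' Prior configuration for whole-genome regression
#'
#' Variance priors are scaled-inverse-chi-square with `df` degrees of
#' freedom; scales are set by partitioning the phenotypic variance with an
#' assumed model R2 (default 0.5). For BayesB, `probIn` is the prior
#' probability that a marker has a nonzero effect: 0.5 by default (the
#' convention of general-purpose Bayesian-alphabet software); set it low,
#' e.g. 0.05, for the classical sparse BayesB prior in which most markers
#' contribute nothing.
#' The Bayesian LASSO regularization parameter lambda^2 gets a diffuse
#' Gamma hyper-prior centred on the value implied by R2.
#'
#' @param model `"BayesA"`, `"BayesB"` or `"BL"`.
#' @param df prior degrees of freedom for marker and residual variances.
#' @param R2 assumed proportion of variance captured by markers.
#' @param probIn BayesB prior inclusion probability.
#' @param lambdaShape Gamma shape of the lambda^2 hyper-prior.
#' @return list of prior settings.
#' @export
wgrPriorConfig <- function(model = c("BayesA", "BayesB", "BL"), df = 5,
                           R2 = 0.5, probIn = 0.5, lambdaShape = 1.1) {
  model <- match.arg(model)
  if (df <= 0) stop("df must be > 0")
  if (probIn <= 0 || probIn >= 1) stop("probIn must be in (0,1)")
  if (R2 <= 0 || R2 >= 1) stop("R2 must be in (0,1)")
  list(model = model, df = df, R2 = R2, probIn = probIn,
       lambdaShape = lambdaShape)
}

#' Fit a Bayesian whole-genome marker regression
#'
#' Gibbs samplers for the Bayesian alphabet: BayesA (scaled-t prior via
#' per-marker variances), BayesB (spike at zero plus per-marker slab
#' variances, prior inclusion `probIn`) and the Bayesian LASSO
#' (double-exponential prior via the exponential mixture with a Gamma
#' hyper-prior on lambda^2). Chains are bit-reproducible given the seed in
#' `mcmc`.
#'
#' @param X a [MarkerMatrix] or standardized lines x markers matrix.
#' @param y phenotype vector aligned to rows of X, standardized.
#' @param prior a [wgrPriorConfig()] list.
#' @param mcmc an [mcmcConfig()] list.
#' @return A [WGRFit].
#' @export
fitWGR <- function(X, y, prior = wgrPriorConfig("BayesA"),
                   mcmc = mcmcConfig("test")) {
  Xs <- if (is(X, "MarkerMatrix")) X@X else as.matrix(X)
  y <- as.numeric(y)
  if (length(y) != nrow(Xs)) stop("rows of X must align with y")
  vy <- stats::var(y)
  if (abs(mean(y)) > 0.5 * sqrt(vy) + 1e-8 || abs(vy - 1) > 0.5)
    warning("y does not look standardized; priors assume unit variance")
  p <- ncol(Xs)
  msx <- sum(apply(Xs, 2, stats::var))
  df <- prior$df
  # scale so the prior mode of each variance matches the R2 partition
  Sb <- prior$R2 * vy / msx * (df + 2) / df
  if (prior$model == "BayesB") Sb <- Sb / prior$probIn
  Se <- (1 - prior$R2) * vy * (df + 2) / df
  lambda20 <- 2 * msx * (1 - prior$R2) / prior$R2
  lrate <- prior$lambdaShape / lambda20
  code <- match(prior$model, c("BayesA", "BayesB", "BL")) - 1L
  res <- withSeed(mcmc$seed,
    wgr_gibbs(y, Xs, code, mcmc$iterations, mcmc$burnin, mcmc$thin,
              df, Sb, df, Se, prior$probIn, prior$lambdaShape, lrate))
  chain <- res$chain
  colnames(chain) <- c("varE", "varG", "lambda2")
  eff <- setNames(as.numeric(res$b), colnames(Xs))
  g <- drop(Xs %*% eff)
  diag <- data.frame(
    parameter = c("varE", "varG"),
    ess = c(essBasic(chain[, 1]), essBasic(chain[, 2])),
    gewekeZ = c(gewekeZ(chain[, 1]), gewekeZ(chain[, 2])))
  new("WGRFit", model = prior$model, mu = res$mu, effects = eff,
      inclusion = setNames(as.numeric(res$d), colnames(Xs)),
      gebv = setNames(g, rownames(Xs)), chain = chain,
      diagnostics = diag,
      mcmc = mcmc[c("iterations", "burnin", "thin", "seed")])
}

#' Predict GEBVs for new genotypes
#'
#' `X_new %*% effects` (+ intercept on request). `X_new` must be
#' standardized with the training constants ([standardizeWith()]).
#'
#' @param fit a [WGRFit].
#' @param Xnew standardized matrix over the training marker set.
#' @param addIntercept add the posterior-mean intercept.
#' @return Named GEBV vector.
#' @export
predictGEBV <- function(fit, Xnew, addIntercept = FALSE) {
  Xnew <- as.matrix(Xnew)
  mk <- names(fit@effects)
  if (!is.null(colnames(Xnew))) {
    if (!all(mk %in% colnames(Xnew))) stop("marker set mismatch")
    Xnew <- Xnew[, mk, drop = FALSE]
  } else if (ncol(Xnew) != length(mk)) stop("marker set mismatch")
  g <- drop(Xnew %*% fit@effects)
  if (addIntercept) g <- g + fit@mu
  g
}

# naive effective sample size from the positive-lag autocorrelation sum
essBasic <- function(x) {
  n <- length(x)
  if (n < 10 || stats::sd(x) == 0) return(n)
  ac <- stats::acf(x, lag.max = min(50, n - 2), plot = FALSE)$acf[-1]
  pos <- which(ac < 0.05)
  cut <- if (length(pos)) pos[1] - 1 else length(ac)
  max(1, n / (1 + 2 * sum(ac[seq_len(cut)])))
}

# Geweke convergence z: first 10% vs last 50% of the chain
gewekeZ <- function(x) {
  n <- length(x)
  if (n < 20 || stats::sd(x) == 0) return(0)
  a <- x[seq_len(max(2, floor(0.1 * n)))]
  b <- x[seq.int(floor(0.5 * n) + 1, n)]
  se2 <- stats::var(a) / length(a) + stats::var(b) / length(b)
  if (se2 <= 0) return(0)
  (mean(a) - mean(b)) / sqrt(se2)
}
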