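#' Fit the alpha-lattice adjustment model for one environment
#'
#' Fits, by REML,
#' `GY = mu + Rep_i + Block_j(Rep_i) + Gen_k + beta_DH * DH + e` with
#' replicate fixed, block-within-replicate random, genotype random and the
#' days-to-heading covariate fixed. Genotype BLUPs are the adjusted means
#' used as genomic-prediction phenotypes; the genotype and residual variance
#' components feed the broad-sense heritability.
#'
#' @param plots plot table (env, rep, block, genotype, DH, GY); missing GY
#'   values are allowed and dropped from the likelihood.
#' @param useDhCovariate include the DH covariate (default TRUE).
#' @return A [LatticeFit].
#' @export
fitLatticeModel <- function(plots, useDhCovariate = TRUE) {
  plots <- validatePlotTable(plots)
  plots <- plots[is.finite(plots$GY), , drop = FALSE]
  if (length(unique(plots$genotype)) < 2L) stop("need at least 2 genotypes")
  plots$rep <- factor(plots$rep)
  plots$genotype <- factor(plots$genotype)
  plots$repblock <- factor(paste(plots$rep, plots$block, sep = "."))
  # aliasing check on the fixed part
  fx <- if (useDhCovariate) model.matrix(~rep + DH, plots)
        else model.matrix(~rep, plots)
  qr_fx <- qr(fx)
  if (qr_fx$rank < ncol(fx)) {
    bad <- colnames(fx)[qr_fx$pivot[(qr_fx$rank + 1):ncol(fx)]]
    stop("singular fixed design; aliased: ", paste(bad, collapse = ", "))
  }
  form <- if (useDhCovariate)
    GY ~ rep + DH + (1 | repblock) + (1 | genotype)
  else
    GY ~ rep + (1 | repblock) + (1 | genotype)
  fit <- suppressMessages(suppressWarnings(
    lme4::lmer(form, data = plots, REML = TRUE,
               control = lme4::lmerControl(check.nobs.vs.nlev = "ignore",
                                           check.nobs.vs.nRE = "ignore"))))
  vc <- as.data.frame(lme4::VarCorr(fit))
  getv <- function(g) {
    v <- vc$vcov[vc$grp == g]
    if (length(v)) v[1] else 0
  }
  varG <- getv("genotype")
  varB <- getv("repblock")
  varE <- getv("Residual")
  re <- lme4::ranef(fit)$genotype
  bl <- setNames(re[, 1], rownames(re))
  bl <- bl - mean(bl)
  nReps <- length(unique(plots$rep))
  msgs <- unlist(fit@optinfo$conv$lme4$messages)
  if (is.null(msgs)) msgs <- character()
  new("LatticeFit",
      fixef = lme4::fixef(fit), varG = varG, varBlock = varB,
      varE = max(varE, 1e-12), blups = bl,
      H2 = computeHeritability(varG, varE, nReps),
      nReps = as.integer(nReps),
      converged = length(msgs) == 0L, messages = msgs)
}

#' Broad-sense heritability on a line-mean basis
#'
#' `H2 = varG / (varG + varE / nReps)`, clipped to `[0, 1]`.
#'
#' @param varG,varE genotype and residual variance components (or a
#'   [LatticeFit] as first argument, in which case `varE` is ignored).
#' @param nReps replicate count (defaults to the fit's replicate count when
#'   a [LatticeFit] is given, else 2).
#' @return Heritability in `[0, 1]`.
#' @export
computeHeritability <- function(varG, varE = NULL, nReps = NULL) {
  if (is(varG, "LatticeFit")) {
    fit <- varG
    if (is.null(nReps)) nReps <- fit@nReps
    varE <- fit@varE
    varG <- fit@varG
  }
  if (is.null(nReps)) nReps <- 2L
  if (nReps < 1) stop("nReps must be >= 1")
  if (varG <= 0) return(0)
  min(1, max(0, varG / (varG + varE / nReps)))
}

#' Adjusted means across environments
#'
#' Fits [fitLatticeModel()] per environment and assembles the genotype x
#' environment BLUP matrix plus per-environment heritability.
#'
#' @param plots stacked plot table over environments.
#' @param useDhCovariate passed through.
#' @return An [AdjustedMeansTable] (not yet standardized).
#' @export
adjustedMeans <- function(plots, useDhCovariate = TRUE) {
  plots <- validatePlotTable(plots)
  envs <- unique(plots$env)
  fits <- lapply(envs, function(e)
    fitLatticeModel(plots[plots$env == e, , drop = FALSE], useDhCovariate))
  genos <- sort(unique(plots$genotype))
  M <- matrix(NA_real_, length(genos), length(envs),
              dimnames = list(genos, envs))
  for (j in seq_along(envs)) {
    b <- blups(fits[[j]])
    M[names(b), j] <- b
  }
  new("AdjustedMeansTable", means = M,
      H2 = setNames(vapply(fits, heritability, numeric(1)), envs),
      centers = setNames(rep(0, length(envs)), envs),
      scales = setNames(rep(1, length(envs)), envs),
      standardized = FALSE)
}

#' Standardize adjusted means per environment
#'
#' Centres each environment column by its mean and divides by its sample
#' standard deviation, storing the constants for back-transformation.
#' Idempotent on already standardized columns.
#'
#' @param means an [AdjustedMeansTable] (or plain genotype x environment
#'   matrix).
#' @return A standardized [AdjustedMeansTable].
#' @export
standardizePhenotypes <- function(means) {
  if (is.matrix(means))
    means <- new("AdjustedMeansTable", means = means,
                 H2 = setNames(rep(NA_real_, ncol(means)), colnames(means)),
                 centers = setNames(rep(0, ncol(means)), colnames(means)),
                 scales = setNames(rep(1, ncol(means)), colnames(means)),
                 standardized = FALSE)
  M <- means@means
  ctr <- means@centers; scl <- means@scales
  for (j in seq_len(ncol(M))) {
    x <- M[, j]
    s <- stats::sd(x, na.rm = TRUE)
    if (!is.finite(s) || s == 0)
      stop("zero-variance column: ", colnames(M)[j])
    m <- mean(x, na.rm = TRUE)
    M[, j] <- (x - m) / s
    ctr[j] <- ctr[j] + m * scl[j]
    scl[j] <- scl[j] * s
  }
  new("AdjustedMeansTable", means = M, H2 = means@H2, centers = ctr,
      scales = scl, standardized = TRUE)
}

validatePlotTable <- function(plots) {
  need <- c("env", "rep", "block", "genotype", "DH", "GY")
  miss <- setdiff(need, colnames(plots))
  if (length(miss)) stop("plot table missing column(s): ",
                         paste(miss, collapse = ", "))
  key <- paste(plots$env, plots$rep, plots$block, plots$genotype)
  if (anyDuplicated(key))
    stop("duplicated plot key (env, rep, block, genotype)")
  plots
}
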