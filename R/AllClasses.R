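#' @include magicGP-package.R
NULL

# ---------------------------------------------------------------------------
# Simulation-side classes
# ---------------------------------------------------------------------------

#' FounderPanel: haplotypes of the eight founder varieties
#'
#' Eight founder inbreds, four "old" and four "modern", each represented by a
#' single binary haplotype over the marker panel (founders are fully inbred,
#' so one haplotype per founder suffices).
#'
#' @slot haplotypes 8 x p binary matrix (rows = founders, cols = markers).
#' @slot group character vector of length 8, `"old"` or `"modern"`.
#' @slot traits data.frame of optional per-founder trait parameters (e.g.
#'   mean days-to-heading, mean yield); may have zero rows.
#' @slot monomorphic logical flag per marker: no variation across the panel.
#' @exportClass FounderPanel
setClass("FounderPanel",
  slots = c(haplotypes = "matrix", group = "character",
            traits = "data.frame", monomorphic = "logical"))

setValidity("FounderPanel", function(object) {
  h <- object@haplotypes
  if (nrow(h) != 8L) return("exactly 8 founders are required")
  if (!all(h %in% c(0L, 1L))) return("haplotype alleles must be 0/1")
  if (length(object@group) != 8L ||
      !all(object@group %in% c("old", "modern")))
    return("group must be length-8 'old'/'modern'")
  if (sum(object@group == "old") != 4L)
    return("founder panel must contain 4 old and 4 modern varieties")
  if (length(object@monomorphic) != ncol(h))
    return("monomorphic flag must have one entry per marker")
  poly <- apply(h, 2, function(x) length(unique(x)) > 1L)
  if (any(poly == object@monomorphic))
    return("monomorphic flags inconsistent with haplotypes")
  TRUE
})

#' FunnelDesign: the two-stage MAGIC crossing scheme
#'
#' Stage 1 pairs each old founder with a modern founder (4 F1s); stage 2
#' performs the half-diallel among the 4 F1s (6 four-way sets); stage 3 unites
#' two founder-disjoint four-way sets so every funnel carries all 8 founders.
#'
#' @slot stage1 4 x 2 matrix of founder indices (old, modern).
#' @slot stage2 6 x 2 matrix of F1 indices (all unordered pairs).
#' @slot stage3 matrix of stage-2 set indices, one row per eight-way funnel.
#' @slot linesPerFunnel integer vector, DH lines derived from each funnel.
#' @slot seed integer seed used to allocate lines.
#' @exportClass FunnelDesign
setClass("FunnelDesign",
  slots = c(stage1 = "matrix", stage2 = "matrix", stage3 = "matrix",
            linesPerFunnel = "integer", seed = "integer"))

setValidity("FunnelDesign", function(object) {
  s1 <- object@stage1; s2 <- object@stage2; s3 <- object@stage3
  if (nrow(s1) != 4L) return("stage 1 must contain 4 crosses")
  if (nrow(s2) != 6L) return("stage 2 must enumerate all 6 F1 pairs")
  if (any(duplicated(t(apply(s2, 1, sort))))) return("duplicated stage-2 pair")
  if (length(object@linesPerFunnel) != nrow(s3))
    return("linesPerFunnel must match the number of funnels")
  if (any(object@linesPerFunnel < 0L)) return("negative line counts")
  for (i in seq_len(nrow(s3))) {
    f1a <- s2[s3[i, 1], ]; f1b <- s2[s3[i, 2], ]
    founders <- sort(c(s1[f1a, ], s1[f1b, ]))
    if (!identical(founders, 1:8))
      return("each funnel must unite all 8 founders exactly once")
  }
  TRUE
})

#' MagicPopulation: simulated DH lines with founder mosaics
#'
#' Extends [SummarizedExperiment::SummarizedExperiment] with two assays over
#' markers (rows) x lines (columns): `dosage` (0/2 alternate-allele dosage of
#' the fully homozygous doubled-haploid lines) and `mosaic` (founder-of-origin
#' index 1-8 at every marker). `rowData` carries the genetic map (chrom, cM,
#' bp); `metadata` stores the generating seed, the [FunnelDesign] and the
#' [FounderPanel].
#'
#' @exportClass MagicPopulation
setClass("MagicPopulation", contains = "SummarizedExperiment")

setValidity("MagicPopulation", function(object) {
  an <- names(assays(object))
  if (!all(c("dosage", "mosaic") %in% an))
    return("assays 'dosage' and 'mosaic' are required")
  d <- assay(object, "dosage")
  if (!all(d %in% c(0, 2)))
    return("DH lines must be fully homozygous (dosage 0 or 2)")
  m <- assay(object, "mosaic")
  if (!all(m %in% 1:8)) return("mosaic entries must be founder indices 1-8")
  rd <- rowData(object)
  if (!all(c("chrom", "cM", "bp") %in% colnames(rd)))
    return("rowData must carry the genetic map (chrom, cM, bp)")
  TRUE
})

#' TraitArchitecture: QTL effects with environment-specific deviations
#'
#' Marker effects are split into a main effect common to all environments and
#' an independent deviation per environment; the deviation-to-main variance
#' ratio governs the genetic correlation between environments.
#'
#' @slot qtl integer marker indices carrying effects.
#' @slot mainEffects numeric main additive effect per QTL.
#' @slot devEffects QTL x environment matrix of deviations.
#' @slot envs environment labels.
#' @slot H2 target line-mean heritability per environment, in (0, 1].
#' @slot dhQTL,dhEffects markers and effects behind the days-to-heading
#'   covariate.
#' @slot dhEffect effect of one day of heading difference on plot yield.
#' @exportClass TraitArchitecture
setClass("TraitArchitecture",
  slots = c(qtl = "integer", mainEffects = "numeric", devEffects = "matrix",
            envs = "character", H2 = "numeric",
            dhQTL = "integer", dhEffects = "numeric", dhEffect = "numeric"))

setValidity("TraitArchitecture", function(object) {
  if (ncol(object@devEffects) != length(object@envs))
    return("one deviation column per environment is required")
  if (length(object@mainEffects) != length(object@qtl))
    return("one main effect per QTL is required")
  if (length(object@H2) != length(object@envs))
    return("one target H2 per environment is required")
  if (any(object@H2 <= 0 | object@H2 > 1)) return("target H2 must be in (0,1]")
  TRUE
})

# ---------------------------------------------------------------------------
# Marker / kernel classes
# ---------------------------------------------------------------------------

#' MarkerMatrix: quality-controlled, standardized marker genotypes
#'
#' @slot X n x p column-standardized dosage matrix used by all models.
#' @slot raw n x p imputed dosage matrix (0/1/2) after QC.
#' @slot centers,scales per-marker standardization constants.
#' @slot dropped data.frame of removed markers and reasons.
#' @exportClass MarkerMatrix
setClass("MarkerMatrix",
  slots = c(X = "matrix", raw = "matrix", centers = "numeric",
            scales = "numeric", dropped = "data.frame"))

setValidity("MarkerMatrix", function(object) {
  if (!identical(dim(object@X), dim(object@raw)))
    return("X and raw must have identical dimensions")
  if (length(object@centers) != ncol(object@X) ||
      length(object@scales) != ncol(object@X))
    return("one center and scale per marker is required")
  if (any(object@scales <= 0)) return("scales must be positive")
  TRUE
})

#' GenomicKernel: a relationship matrix for kernel regression
#'
#' Either the genomic relationship matrix `K = XX'/p` (kind `"GB"`) or a
#' Gaussian kernel `K = exp(-h d^2)` (kind `"GK"` with bandwidth `h`).
#'
#' @slot K n x n symmetric positive semidefinite matrix.
#' @slot kind `"GB"` or `"GK"`.
#' @slot h Gaussian bandwidth (NA for GB).
#' @slot jitter diagonal jitter added during PSD repair (0 if none).
#' @exportClass GenomicKernel
setClass("GenomicKernel",
  slots = c(K = "matrix", kind = "character", h = "numeric",
            jitter = "numeric"))

setValidity("GenomicKernel", function(object) {
  K <- object@K
  if (nrow(K) != ncol(K)) return("K must be square")
  if (max(abs(K - t(K))) > 1e-8) return("K must be symmetric")
  if (!object@kind %in% c("GB", "GK")) return("kind must be 'GB' or 'GK'")
  TRUE
})

# ---------------------------------------------------------------------------
# Fit / result classes
# ---------------------------------------------------------------------------

#' LatticeFit: alpha-lattice mixed-model fit for one environment
#'
#' @slot fixef named fixed-effect estimates (intercept/replicates, DH slope).
#' @slot varG,varBlock,varE variance components (genotype, block-within-rep,
#'   residual).
#' @slot blups named genotype BLUPs (adjusted means, centred).
#' @slot H2 broad-sense line-mean heritability.
#' @slot nReps replicate count used for H2.
#' @slot converged logical; `messages` carries optimizer notes.
#' @exportClass LatticeFit
setClass("LatticeFit",
  slots = c(fixef = "numeric", varG = "numeric", varBlock = "numeric",
            varE = "numeric", blups = "numeric", H2 = "numeric",
            nReps = "integer", converged = "logical", messages = "character"))

setValidity("LatticeFit", function(object) {
  if (object@varG < 0 || object@varE <= 0)
    return("variance components out of range")
  if (length(object@blups) &&
      abs(mean(object@blups)) > 1e-6 * max(stats::sd(object@blups), 1e-12))
    return("BLUPs must be centred")
  if (object@H2 < 0 || object@H2 > 1) return("H2 must lie in [0,1]")
  TRUE
})

#' AdjustedMeansTable: genotype x environment adjusted means
#'
#' @slot means genotype x environment matrix of BLUPs.
#' @slot H2 per-environment heritability.
#' @slot centers,scales standardization constants per environment.
#' @slot standardized logical.
#' @exportClass AdjustedMeansTable
setClass("AdjustedMeansTable",
  slots = c(means = "matrix", H2 = "numeric", centers = "numeric",
            scales = "numeric", standardized = "logical"))

#' WGRFit: posterior summaries of a whole-genome marker regression
#'
#' @slot model `"BayesA"`, `"BayesB"` or `"BL"`.
#' @slot mu posterior-mean intercept.
#' @slot effects posterior-mean marker effects.
#' @slot inclusion posterior inclusion probability per marker (1 except
#'   BayesB).
#' @slot gebv fitted genomic values `X effects` for the training lines.
#' @slot chain kept samples of (residual variance, genetic variance, lambda2).
#' @slot diagnostics per-chain effective sample size and Geweke z.
#' @slot mcmc iterations/burn-in/thinning actually used.
#' @exportClass WGRFit
setClass("WGRFit",
  slots = c(model = "character", mu = "numeric", effects = "numeric",
            inclusion = "numeric", gebv = "numeric", chain = "matrix",
            diagnostics = "data.frame", mcmc = "list"))

setValidity("WGRFit", function(object) {
  if (any(!is.finite(object@effects))) return("non-finite marker effects")
  if (any(object@chain[, 1] < 0)) return("negative variance draws")
  TRUE
})

#' GPFit: a fitted kernel genomic-prediction model
#'
#' Covers the single-environment model and the multi-environment MM, MDs and
#' MDe models. GEBVs are reported for every line in every environment,
#' including lines whose phenotypes were masked.
#'
#' @slot model `"SE"`, `"MM"`, `"MDs"` or `"MDe"`.
#' @slot kind kernel kind(s) used (`"GB"`/`"GK"`).
#' @slot beta named fixed effects (intercept and environment effects).
#' @slot u0 main genetic effect per line.
#' @slot uE line x environment matrix of interaction effects (zero columns
#'   for models without them).
#' @slot varComp data.frame: component, environment, posterior mean and SD.
#' @slot gebv line x environment GEBV matrix.
#' @slot chain kept variance-component samples.
#' @slot diagnostics per-chain ESS and Geweke z.
#' @slot lines,envs identifiers.
#' @exportClass GPFit
setClass("GPFit",
  slots = c(model = "character", kind = "character", beta = "numeric",
            u0 = "numeric", uE = "matrix", varComp = "data.frame",
            gebv = "matrix", chain = "matrix", diagnostics = "data.frame",
            lines = "character", envs = "character"))

setValidity("GPFit", function(object) {
  if (!object@model %in% c("SE", "MM", "MDs", "MDe"))
    return("unknown model type")
  if (nrow(object@gebv) != length(object@lines) ||
      ncol(object@gebv) != length(object@envs))
    return("GEBV matrix must cover all lines x environments")
  if (any(object@varComp$estimate < 0)) return("negative variance estimate")
  TRUE
})

#' TPSelection: an optimized training population
#'
#' @slot criterion criterion name (`"CDmean"`, `"PEV"`, `"rScore"`, `"E-NE"`).
#' @slot selected selected line ids.
#' @slot value final criterion value.
#' @slot trajectory criterion value after each accepted optimizer move.
#' @slot seed integer seed.
#' @exportClass TPSelection
setClass("TPSelection",
  slots = c(criterion = "character", selected = "character",
            value = "numeric", trajectory = "numeric", seed = "integer"))

setValidity("TPSelection", function(object) {
  if (anyDuplicated(object@selected)) return("selected ids must be unique")
  TRUE
})

#' CVResult: cross-validated predictive ability
#'
#' @slot scheme `"random"`, `"LOO"`, `"CV1"` or `"CV2"`.
#' @slot model model label.
#' @slot correlations per-partition Pearson correlations (pooled over
#'   environments for ME schemes).
#' @slot detail data.frame with per-partition, per-environment correlations.
#' @slot mean,sd summary over partitions.
#' @slot nReps partitions used.
#' @exportClass CVResult
setClass("CVResult",
  slots = c(scheme = "character", model = "character",
            correlations = "numeric", detail = "data.frame",
            mean = "numeric", sd = "numeric", nReps = "integer"))

setValidity("CVResult", function(object) {
  ok <- is.finite(object@correlations)
  if (any(object@correlations[ok] < -1 | object@correlations[ok] > 1))
    return("correlations must lie in [-1, 1]")
  TRUE
})

#' PartitionSet: training/validation partitions for cross-validation
#'
#' @slot scheme `"random"`, `"LOO"`, `"CV1"` or `"CV2"`.
#' @slot partitions list; random/LOO schemes hold `train`/`validation` index
#'   vectors, CV1/CV2 hold logical line x environment masks (TRUE = held out).
#' @slot nReps,seed bookkeeping.
#' @exportClass PartitionSet
setClass("PartitionSet",
  slots = c(scheme = "character", partitions = "list", nReps = "integer",
            seed = "integer"))
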