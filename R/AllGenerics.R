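#' @include AllClasses.R
NULL

#' Accessors for magicGP objects
#'
#' Small generic family giving read access to the slots users need:
#' `dosage()` and `founderMosaic()` return the assays of a
#' [MagicPopulation]; `markerMatrix()` returns a lines x markers dosage
#' matrix ready for [qcAndStandardize()]; `kernelMatrix()` extracts the
#' numeric matrix of a [GenomicKernel]; `gebv()` returns genomic estimated
#' breeding values; `blups()` the genotype adjusted means of a [LatticeFit];
#' `heritability()` broad-sense H2; `varComp()` the variance-component table;
#' `selectedLines()` the ids chosen by a training-population optimizer.
#'
#' @param object a magicGP object.
#' @param ... unused.
#' @return See the individual method descriptions.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("dosage", function(object, ...) standardGeneric("dosage"))

#' @rdname accessors
#' @export
setGeneric("founderMosaic",
           function(object, ...) standardGeneric("founderMosaic"))

#' @rdname accessors
#' @export
setGeneric("markerMatrix",
           function(object, ...) standardGeneric("markerMatrix"))

#' @rdname accessors
#' @export
setGeneric("kernelMatrix",
           function(object, ...) standardGeneric("kernelMatrix"))

#' @rdname accessors
#' @export
setGeneric("gebv", function(object, ...) standardGeneric("gebv"))

#' @rdname accessors
#' @export
setGeneric("blups", function(object, ...) standardGeneric("blups"))

#' @rdname accessors
#' @export
setGeneric("heritability",
           function(object, ...) standardGeneric("heritability"))

#' @rdname accessors
#' @export
setGeneric("varComp", function(object, ...) standardGeneric("varComp"))

#' @rdname accessors
#' @export
setGeneric("selectedLines",
           function(object, ...) standardGeneric("selectedLines"))

# -- methods ---------------------------------------------------------------

#' @rdname accessors
#' @export
setMethod("dosage", "MagicPopulation",
          function(object, ...) assay(object, "dosage"))

#' @rdname accessors
#' @export
setMethod("founderMosaic", "MagicPopulation",
          function(object, ...) assay(object, "mosaic"))

#' @rdname accessors
#' @export
setMethod("markerMatrix", "MagicPopulation",
          function(object, ...) t(assay(object, "dosage")))

#' @rdname accessors
#' @export
setMethod("markerMatrix", "MarkerMatrix", function(object, ...) object@X)

#' @rdname accessors
#' @export
setMethod("kernelMatrix", "GenomicKernel", function(object, ...) object@K)

#' @rdname accessors
#' @export
setMethod("gebv", "WGRFit", function(object, ...) object@gebv)

#' @rdname accessors
#' @export
setMethod("gebv", "GPFit", function(object, ...) object@gebv)

#' @rdname accessors
#' @export
setMethod("blups", "LatticeFit", function(object, ...) object@blups)

#' @rdname accessors
#' @export
setMethod("heritability", "LatticeFit", function(object, ...) object@H2)

#' @rdname accessors
#' @export
setMethod("heritability", "AdjustedMeansTable", function(object, ...) object@H2)

#' @rdname accessors
#' @export
setMethod("varComp", "LatticeFit", function(object, ...)
  data.frame(component = c("genotype", "block", "residual"),
             estimate = c(object@varG, object@varBlock, object@varE)))

#' @rdname accessors
#' @export
setMethod("varComp", "GPFit", function(object, ...) object@varComp)

#' @rdname accessors
#' @export
setMethod("selectedLines", "TPSelection", function(object, ...)
  object@selected)

# -- show ------------------------------------------------------------------

#' @export
setMethod("show", "FounderPanel", function(object) {
  cat("FounderPanel: 8 founders (4 old, 4 modern),",
      ncol(object@haplotypes), "markers;",
      sum(object@monomorphic), "monomorphic\n")
})

#' @export
setMethod("show", "FunnelDesign", function(object) {
  cat("FunnelDesign:", nrow(object@stage3), "eight-way funnels,",
      sum(object@linesPerFunnel), "DH lines\n")
})

#' @export
setMethod("show", "GenomicKernel", function(object) {
  cat(sprintf("GenomicKernel (%s): %d x %d", object@kind, nrow(object@K),
              ncol(object@K)))
  if (object@kind == "GK") cat(sprintf(", h = %.4g", object@h))
  if (object@jitter > 0) cat(sprintf(", jitter = %g", object@jitter))
  cat("\n")
})

#' @export
setMethod("show", "MarkerMatrix", function(object) {
  cat(sprintf("MarkerMatrix: %d lines x %d markers (%d dropped in QC)\n",
              nrow(object@X), ncol(object@X), nrow(object@dropped)))
})

#' @export
setMethod("show", "LatticeFit", function(object) {
  cat(sprintf(
    "LatticeFit: %d genotypes, varG = %.4g, varE = %.4g, H2 = %.3f\n",
    length(object@blups), object@varG, object@varE, object@H2))
})

#' @export
setMethod("show", "WGRFit", function(object) {
  cat(sprintf("WGRFit (%s): %d markers, %d kept samples\n", object@model,
              length(object@effects), nrow(object@chain)))
})

#' @export
setMethod("show", "GPFit", function(object) {
  cat(sprintf("GPFit (%s-%s): %d lines x %d environments\n", object@model,
              object@kind, length(object@lines), length(object@envs)))
})

#' @export
setMethod("show", "TPSelection", function(object) {
  cat(sprintf("TPSelection (%s): %d lines, value = %.5g\n",
              object@criterion, length(object@selected), object@value))
})

#' @export
setMethod("show", "CVResult", function(object) {
  cat(sprintf("CVResult (%s, %s): mean r = %.3f (sd %.3f) over %d partitions\n",
              object@scheme, object@model, object@mean, object@sd,
              object@nReps))
})
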