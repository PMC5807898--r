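#' Accessors
#'
#' Small accessor generics for the package's S4 containers: abundance bounds,
#' nucleic-acid type, profile counts, PCA scores and loadings, and report
#' tables.
#'
#' @param object an object of the documented class.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("abundanceLow", function(object) standardGeneric("abundanceLow"))
#' @rdname accessors
#' @export
setGeneric("abundanceHigh", function(object) standardGeneric("abundanceHigh"))
#' @rdname accessors
#' @export
setGeneric("naType", function(object) standardGeneric("naType"))
#' @rdname accessors
#' @export
setGeneric("sizeAssumption", function(object) standardGeneric("sizeAssumption"))
#' @rdname accessors
#' @export
setGeneric("taxNodes", function(object) standardGeneric("taxNodes"))
#' @rdname accessors
#' @export
setGeneric("profileCounts", function(object) standardGeneric("profileCounts"))
#' @rdname accessors
#' @export
setGeneric("viralReads", function(object) standardGeneric("viralReads"))
#' @rdname accessors
#' @export
setGeneric("totalReads", function(object) standardGeneric("totalReads"))
#' @rdname accessors
#' @export
setGeneric("libraryId", function(object) standardGeneric("libraryId"))
#' @rdname accessors
#' @export
setGeneric("sampleScores", function(object) standardGeneric("sampleScores"))
#' @rdname accessors
#' @export
setGeneric("componentLoadings",
           function(object) standardGeneric("componentLoadings"))
#' @rdname accessors
#' @export
setGeneric("explainedVariance",
           function(object) standardGeneric("explainedVariance"))
#' @rdname accessors
#' @export
setGeneric("reportTable", function(object) standardGeneric("reportTable"))
#' @rdname accessors
#' @export
setGeneric("reportDisplay", function(object) standardGeneric("reportDisplay"))
#' @rdname accessors
#' @export
setGeneric("truthFamilies", function(object) standardGeneric("truthFamilies"))

#' @rdname accessors
setMethod("abundanceLow", "AbundanceInterval", function(object) object@low)
#' @rdname accessors
setMethod("abundanceHigh", "AbundanceInterval", function(object) object@high)
#' @rdname accessors
setMethod("naType", "AbundanceInterval", function(object) object@naType)
#' @rdname accessors
setMethod("sizeAssumption", "AbundanceInterval",
          function(object) object@sizeAssumption)
#' @rdname accessors
setMethod("taxNodes", "ViralTaxonomy", function(object) object@nodes)
#' @rdname accessors
setMethod("profileCounts", "TaxonomicProfile", function(object) object@counts)
#' @rdname accessors
setMethod("viralReads", "TaxonomicProfile", function(object) object@viralReads)
#' @rdname accessors
setMethod("totalReads", "TaxonomicProfile", function(object) object@totalReads)
#' @rdname accessors
setMethod("libraryId", "TaxonomicProfile", function(object) object@libraryId)
#' @rdname accessors
setMethod("sampleScores", "PcaModel", function(object) object@scores)
#' @rdname accessors
setMethod("componentLoadings", "PcaModel", function(object) object@loadings)
#' @rdname accessors
setMethod("explainedVariance", "PcaModel",
          function(object) object@explainedVariance)
#' @rdname accessors
setMethod("reportTable", "ApportionReport", function(object) object@table)
#' @rdname accessors
setMethod("reportDisplay", "ApportionReport", function(object) object@display)
#' @rdname accessors
setMethod("truthFamilies", "GroundTruth", function(object) object@families)

setMethod("show", "GenomeSizeRange", function(object) {
  cat(sprintf("GenomeSizeRange: %g-%g kb\n", object@minKb, object@maxKb))
})

setMethod("show", "AbundanceInterval", function(object) {
  cat(sprintf("AbundanceInterval (%s): [%.3g, %.3g] copies/cm^3 assuming %g-%g kb\n",
              object@naType, object@low, object@high,
              object@sizeAssumption@minKb, object@sizeAssumption@maxKb))
})

setMethod("show", "ViralTaxonomy", function(object) {
  nd <- object@nodes
  cat(sprintf("ViralTaxonomy: %d node(s), %d family(ies), root '%s'\n",
              nrow(nd), sum(nd$rank == "family"),
              nd$name[is.na(nd$parent)]))
})

setMethod("show", "SedimentSampleSet", function(object) {
  cat(sprintf("SedimentSampleSet: %d sample(s)\n", nrow(object@samples)))
  print(object@samples)
})

setMethod("show", "ApportionReport", function(object) {
  cat(sprintf("ApportionReport: %d sample(s); ssDNA %g-%g kb, dsDNA %g-%g kb\n",
              nrow(object@table), object@ssRange@minKb, object@ssRange@maxKb,
              object@dsRange@minKb, object@dsRange@maxKb))
  print(object@display)
})

setMethod("show", "TaxonomicProfile", function(object) {
  cat(sprintf("TaxonomicProfile '%s': %d categories, %d viral / %d total reads\n",
              object@libraryId, length(object@counts),
              as.integer(object@viralReads), as.integer(object@totalReads)))
})

setMethod("show", "PcaModel", function(object) {
  cat(sprintf("PcaModel: %d component(s), explained variance %s\n",
              ncol(object@loadings),
              paste(sprintf("%.1f%%", 100 * object@explainedVariance),
                    collapse = ", ")))
})

setMethod("show", "GroundTruth", function(object) {
  f <- object@families
  cat(sprintf("GroundTruth: %d families (%d ssDNA, %d dsDNA), total %.3g copies/cm^3\n",
              nrow(f), sum(f$na_type == "ssDNA"), sum(f$na_type == "dsDNA"),
              sum(f$abundance)))
})

setMethod("show", "SimulationConfig", function(object) {
  cat(sprintf(paste0("SimulationConfig: seed %d; %d ssDNA + %d dsDNA families; ",
                     "mass CV %.2g; MDA bias %.3g; S1 carryover %.2g; ",
                     "stain eff ss %.3g / ds %.3g; depth %d reads\n"),
              object@seed, object@nSsFamilies, object@nDsFamilies,
              object@massNoiseCv, object@mdaSsBias, object@s1CarryoverF,
              object@stainEfficiencySs, object@stainEfficiencyDs,
              object@readDepth))
})
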