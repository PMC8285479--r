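#' @include AllClasses.R
NULL

#' Accessors for gcDormancy data classes
#'
#' Small accessor family: \code{plateWells} returns the long-format well
#' table of a \code{PlateGrid}; \code{isNormalized} reports whether NPI
#' normalisation has been applied; \code{exprMatrix}, \code{accMatrix},
#' \code{enhancerRanges} and \code{sampleInfo} expose the components of a
#' \code{CohortData}; \code{fragmentRanges}, \code{contactSignal} and
#' \code{signalInfo} those of a \code{FourCProfile}; \code{intensityMatrix},
#' \code{sampleGroups} and \code{missingMask} those of an \code{LFQMatrix};
#' \code{labelMap} and \code{nucleusTable} those of a
#' \code{SegmentationResult}.
#'
#' @param x an object of the corresponding class.
#' @return the requested component.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("plateWells", function(x) standardGeneric("plateWells"))
#' @rdname accessors
#' @export
setMethod("plateWells", "PlateGrid", function(x) x@wells)

#' @rdname accessors
#' @export
setGeneric("isNormalized", function(x) standardGeneric("isNormalized"))
#' @rdname accessors
#' @export
setMethod("isNormalized", "PlateGrid", function(x) x@normalized)

#' @rdname accessors
#' @export
setGeneric("exprMatrix", function(x) standardGeneric("exprMatrix"))
#' @rdname accessors
#' @export
setMethod("exprMatrix", "CohortData", function(x) x@exprs)

#' @rdname accessors
#' @export
setGeneric("accMatrix", function(x) standardGeneric("accMatrix"))
#' @rdname accessors
#' @export
setMethod("accMatrix", "CohortData", function(x) x@accessibility)

#' @rdname accessors
#' @export
setGeneric("enhancerRanges", function(x) standardGeneric("enhancerRanges"))
#' @rdname accessors
#' @export
setMethod("enhancerRanges", "CohortData", function(x) x@enhancers)

#' @rdname accessors
#' @export
setGeneric("sampleInfo", function(x) standardGeneric("sampleInfo"))
#' @rdname accessors
#' @export
setMethod("sampleInfo", "CohortData", function(x) x@sampleData)

#' @rdname accessors
#' @export
setGeneric("fragmentRanges", function(x) standardGeneric("fragmentRanges"))
#' @rdname accessors
#' @export
setMethod("fragmentRanges", "FourCProfile", function(x) x@fragments)

#' @rdname accessors
#' @export
setGeneric("contactSignal", function(x) standardGeneric("contactSignal"))
#' @rdname accessors
#' @export
setMethod("contactSignal", "FourCProfile", function(x) x@signal)

#' @rdname accessors
#' @export
setGeneric("signalInfo", function(x) standardGeneric("signalInfo"))
#' @rdname accessors
#' @export
setMethod("signalInfo", "FourCProfile", function(x) x@colData)

#' @rdname accessors
#' @export
setGeneric("intensityMatrix", function(x) standardGeneric("intensityMatrix"))
#' @rdname accessors
#' @export
setMethod("intensityMatrix", "LFQMatrix", function(x) x@intensities)

#' @rdname accessors
#' @export
setGeneric("sampleGroups", function(x) standardGeneric("sampleGroups"))
#' @rdname accessors
#' @export
setMethod("sampleGroups", "LFQMatrix", function(x) x@groups)

#' @rdname accessors
#' @export
setGeneric("missingMask", function(x) standardGeneric("missingMask"))
#' @rdname accessors
#' @export
setMethod("missingMask", "LFQMatrix", function(x) x@missing)

#' @rdname accessors
#' @export
setGeneric("labelMap", function(x) standardGeneric("labelMap"))
#' @rdname accessors
#' @export
setMethod("labelMap", "SegmentationResult", function(x) x@labels)

#' @rdname accessors
#' @export
setGeneric("nucleusTable", function(x) standardGeneric("nucleusTable"))
#' @rdname accessors
#' @export
setMethod("nucleusTable", "SegmentationResult", function(x) x@nuclei)

#' @rdname accessors
#' @export
setGeneric("positivityThreshold",
           function(x) standardGeneric("positivityThreshold"))
#' @rdname accessors
#' @export
setMethod("positivityThreshold", "SegmentationResult", function(x) x@threshold)

## show methods -------------------------------------------------------------

setMethod("show", "PlateGrid", function(object) {
  w <- object@wells
  cat("PlateGrid with", length(unique(w$plate)), "plate(s),",
      nrow(w), "wells",
      if (object@normalized) "(NPI-normalised)" else "(raw)", "\n")
  cat("  arms:", paste(unique(w$arm), collapse = ", "), "\n")
  cat("  compounds:", length(unique(w$compound[w$role == "compound"])),
      " concentrations:",
      paste(sort(unique(w$concentration_uM[w$role == "compound"])),
            collapse = ", "), "uM\n")
})

setMethod("show", "CohortData", function(object) {
  cat("CohortData:", nrow(object@exprs), "genes x", ncol(object@exprs),
      "samples;", nrow(object@accessibility), "enhancers\n")
})

setMethod("show", "FourCProfile", function(object) {
  cat("FourCProfile for viewpoint '", object@viewpoint, "': ",
      length(object@fragments), " fragments on ",
      as.character(GenomicRanges::seqnames(object@fragments)@values[1L]),
      "; conditions: ",
      paste(unique(object@colData$condition), collapse = " vs "), "\n",
      sep = "")
})

setMethod("show", "LFQMatrix", function(object) {
  cat("LFQMatrix:", nrow(object@intensities), "proteins x",
      ncol(object@intensities), "samples; groups:",
      paste(levels(object@groups), collapse = ", "), ";",
      sprintf("%.1f%% missing", 100 * mean(object@missing)), "\n")
})

setMethod("show", "SegmentationResult", function(object) {
  n <- nrow(object@nuclei)
  npos <- if (n) sum(object@nuclei$positive, na.rm = TRUE) else 0L
  cat("SegmentationResult:", n, "nuclei,", npos, "positive",
      if (!is.na(object@threshold))
        sprintf("(threshold %.3g)", object@threshold) else "", "\n")
  if (n) cat("  expression index:",
             format(expressionIndex(object), digits = 6), "\n")
})
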