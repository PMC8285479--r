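#' @include gcDormancy-package.R
NULL

## ---------------------------------------------------------------------------
## PlateGrid
## ---------------------------------------------------------------------------

#' PlateGrid: a set of 384-well viability plates in long format
#'
#' Holds raw or NPI-normalised viability readouts for one or more 384-well
#' plates (16 rows x 24 columns). Each well record carries its plate, position,
#' role (positive control, negative control, compound or empty), compound
#' assignment, concentration, treatment arm and replicate index.
#'
#' @slot wells a \code{DataFrame} with columns \code{plate}, \code{row},
#'   \code{column}, \code{role}, \code{compound}, \code{concentration_uM},
#'   \code{arm}, \code{replicate}, \code{value}.
#' @slot normalized logical; \code{TRUE} after \code{\link{npiNormalize}}.
#'
#' @seealso \code{\link{simulatePlates}}, \code{\link{npiNormalize}},
#'   \code{\link{scoreScreen}}
#' @export
setClass("PlateGrid",
  representation(wells = "DataFrame", normalized = "logical"),
  prototype(normalized = FALSE))

.plate_cols <- c("plate", "row", "column", "role", "compound",
                 "concentration_uM", "arm", "replicate", "value")
.plate_roles <- c("pos_ctrl", "neg_ctrl", "compound", "empty")

setValidity("PlateGrid", function(object) {
  w <- object@wells
  miss <- setdiff(.plate_cols, colnames(w))
  if (length(miss))
    return(paste("missing well columns:", paste(miss, collapse = ", ")))
  if (!all(w$role %in% .plate_roles))
    return("well roles must be pos_ctrl, neg_ctrl, compound or empty")
  if (any(w$row < 1L | w$row > 16L | w$column < 1L | w$column > 24L))
    return("well positions must lie in a 16x24 grid")
  if (any(!is.finite(w$value[w$role != "empty"])))
    return("non-empty wells must carry finite values")
  for (p in unique(w$plate)) {
    r <- w$role[w$plate == p]
    if (sum(r == "pos_ctrl") < 2L || sum(r == "neg_ctrl") < 2L)
      return(sprintf("plate '%s' needs >=2 wells of each control role", p))
  }
  TRUE
})

#' Construct a PlateGrid from a long-format well table
#'
#' @param wells a data.frame or DataFrame of well records (see
#'   \code{\linkS4class{PlateGrid}} for required columns).
#' @param normalized logical; whether values are already NPI-normalised.
#' @return a \code{PlateGrid}.
#' @export
PlateGrid <- function(wells, normalized = FALSE) {
  new("PlateGrid", wells = DataFrame(as.data.frame(wells)),
      normalized = normalized)
}

## ---------------------------------------------------------------------------
## CohortData
## ---------------------------------------------------------------------------

#' CohortData: paired expression and enhancer-accessibility matrices
#'
#' The substrate of signature scoring and enhancer-linkage analysis: a
#' gene x sample expression matrix, an enhancer x sample chromatin
#' accessibility matrix over the same samples, genomic coordinates for the
#' enhancers, and per-sample metadata.
#'
#' @slot exprs numeric matrix, genes x samples (log-scale expected).
#' @slot accessibility numeric matrix, enhancers x samples.
#' @slot enhancers \code{GRanges} named by enhancer id, parallel to the rows
#'   of \code{accessibility}.
#' @slot sampleData \code{DataFrame} of per-sample metadata (rownames are
#'   sample ids).
#'
#' @seealso \code{\link{simulateCohort}}, \code{\link{signatureScore}},
#'   \code{\link{backgroundNull}}
#' @export
setClass("CohortData",
  representation(exprs = "matrix", accessibility = "matrix",
                 enhancers = "GRanges", sampleData = "DataFrame"))

setValidity("CohortData", function(object) {
  e <- object@exprs; a <- object@accessibility
  if (!identical(colnames(e), colnames(a)))
    return("expression and accessibility matrices must share sample columns")
  if (anyDuplicated(rownames(e)) || anyDuplicated(colnames(e)))
    return("duplicate gene or sample ids in expression matrix")
  if (anyDuplicated(rownames(a)))
    return("duplicate enhancer ids in accessibility matrix")
  if (length(object@enhancers) != nrow(a))
    return("enhancer ranges must be parallel to accessibility rows")
  if (!identical(names(object@enhancers), rownames(a)))
    return("enhancer range names must match accessibility rownames")
  if (nrow(object@sampleData) && !identical(rownames(object@sampleData),
                                            colnames(e)))
    return("sampleData rownames must match sample columns")
  TRUE
})

#' Construct a CohortData object
#'
#' @param exprs gene x sample numeric matrix.
#' @param accessibility enhancer x sample numeric matrix (same samples).
#' @param enhancers \code{GRanges} named by enhancer id.
#' @param sampleData optional per-sample \code{DataFrame}.
#' @return a \code{CohortData}.
#' @export
CohortData <- function(exprs, accessibility, enhancers,
                       sampleData = DataFrame(row.names = colnames(exprs))) {
  new("CohortData", exprs = exprs, accessibility = accessibility,
      enhancers = enhancers, sampleData = sampleData)
}

## ---------------------------------------------------------------------------
## FourCProfile
## ---------------------------------------------------------------------------

#' FourCProfile: a viewpoint-anchored 4C contact profile
#'
#' Ordered, non-overlapping restriction fragments on one chromosome with
#' normalised contact signal per condition and replicate for a single 4C
#' viewpoint. Both conditions cover the same fragment grid, which is what
#' makes the paired region comparison of \code{\link{regionCompare}} well
#' defined.
#'
#' @slot viewpoint character id of the 4C viewpoint.
#' @slot fragments \code{GRanges} of fragments, sorted and non-overlapping.
#' @slot signal numeric matrix, fragments x (condition:replicate) columns,
#'   non-negative.
#' @slot colData \code{DataFrame} with columns \code{condition} and
#'   \code{replicate} describing the signal columns.
#'
#' @seealso \code{\link{simulateFourC}}, \code{\link{regionCompare}}
#' @export
setClass("FourCProfile",
  representation(viewpoint = "character", fragments = "GRanges",
                 signal = "matrix", colData = "DataFrame"))

setValidity("FourCProfile", function(object) {
  fr <- object@fragments
  if (length(fr) != nrow(object@signal))
    return("signal rows must be parallel to fragments")
  if (nrow(object@colData) != ncol(object@signal))
    return("colData rows must describe signal columns")
  if (!all(c("condition", "replicate") %in% colnames(object@colData)))
    return("colData needs 'condition' and 'replicate' columns")
  if (length(fr) > 1L) {
    s <- GenomicRanges::start(fr); e <- GenomicRanges::end(fr)
    if (is.unsorted(s)) return("fragments must be sorted by start")
    if (any(s[-1L] <= e[-length(e)]))
      return("fragments must be non-overlapping")
  }
  if (any(object@signal < 0)) return("signals must be non-negative")
  if (length(unique(object@colData$condition)) != 2L)
    return("a FourCProfile holds exactly two conditions")
  TRUE
})

#' Construct a FourCProfile
#'
#' @param viewpoint viewpoint id.
#' @param fragments sorted, non-overlapping \code{GRanges}.
#' @param signal non-negative fragments x samples matrix.
#' @param condition,replicate vectors describing the signal columns.
#' @return a \code{FourCProfile}.
#' @export
FourCProfile <- function(viewpoint, fragments, signal, condition, replicate) {
  new("FourCProfile", viewpoint = viewpoint, fragments = fragments,
      signal = signal,
      colData = DataFrame(condition = condition, replicate = replicate))
}

## ---------------------------------------------------------------------------
## LFQMatrix
## ---------------------------------------------------------------------------

#' LFQMatrix: log2 label-free quantification intensities
#'
#' A protein x sample matrix of log2 LFQ intensities with explicit
#' missingness. The missingness mask observed before imputation is kept as a
#' slot so that downstream calls (on/off flags, valid-value filters) can
#' refer to the original observation pattern even after
#' \code{\link{imputeDownshift}} has completed the matrix.
#'
#' @slot intensities numeric matrix, proteins x samples; \code{NA} = missing.
#' @slot groups factor of per-sample group labels (e.g. IP vs IgG).
#' @slot missing logical matrix marking entries that were missing before
#'   imputation.
#'
#' @seealso \code{\link{simulateLFQ}}, \code{\link{filterValid}},
#'   \code{\link{differentialTest}}, \code{\link{enrichmentCall}}
#' @export
setClass("LFQMatrix",
  representation(intensities = "matrix", groups = "factor",
                 missing = "matrix"))

setValidity("LFQMatrix", function(object) {
  x <- object@intensities
  if (length(object@groups) != ncol(x))
    return("one group label per sample column required")
  if (!length(levels(object@groups)))
    return("group labels must be non-empty")
  if (!identical(dim(object@missing), dim(x)))
    return("missing mask must match the intensity matrix")
  if (any(is.finite(x) == FALSE & !is.na(x)))
    return("observed intensities must be finite")
  TRUE
})

#' Construct an LFQMatrix
#'
#' @param intensities proteins x samples log2 matrix, \code{NA} = missing.
#' @param groups per-sample group labels.
#' @param missing optional logical mask of pre-imputation missingness;
#'   defaults to \code{is.na(intensities)}.
#' @return an \code{LFQMatrix}.
#' @export
LFQMatrix <- function(intensities, groups, missing = is.na(intensities)) {
  if (!is.factor(groups))   # keep first-appearance order, not alphabetical
    groups <- factor(groups, levels = unique(as.character(groups)))
  new("LFQMatrix", intensities = intensities, groups = groups,
      missing = missing)
}

## ---------------------------------------------------------------------------
## SegmentationResult
## ---------------------------------------------------------------------------

#' SegmentationResult: segmented nuclei with marker measurements
#'
#' The output of the single-nucleus immunofluorescence pipeline: a label map
#' (0 = background, 1..K = nuclei), per-nucleus area and marker statistics,
#' positivity calls against a control-calibrated threshold and the summary
#' protein expression index (number of positive cells x average marker signal
#' of positive cells).
#'
#' @slot labels integer matrix label map.
#' @slot nuclei \code{DataFrame} with one row per nucleus: \code{label},
#'   \code{area_um2}, \code{mean_intensity}, \code{positive}.
#' @slot threshold numeric positivity threshold used (NA before calling).
#' @slot pixelSize numeric, micrometres per pixel.
#' @export
setClass("SegmentationResult",
  representation(labels = "matrix", nuclei = "DataFrame",
                 threshold = "numeric", pixelSize = "numeric"))

setValidity("SegmentationResult", function(object) {
  k <- nrow(object@nuclei)
  lab <- object@labels
  if (k > 0L && !identical(sort(unique(as.integer(lab[lab > 0L]))),
                           seq_len(k)))
    return("labels must be contiguous 1..K matching the nucleus table")
  if (k == 0L && any(lab > 0L))
    return("empty nucleus table but non-empty label map")
  if (length(object@pixelSize) != 1L || object@pixelSize <= 0)
    return("pixelSize must be a positive scalar")
  TRUE
})
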