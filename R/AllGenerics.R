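#' @include AllClasses.R
NULL

#' Accessors for triohet S4 objects
#'
#' @param x a \linkS4class{TrioCallset}, \linkS4class{VafVector} or
#'   \linkS4class{MathResult}.
#' @param condition one of \code{"Normal"}, \code{"Tumor"},
#'   \code{"Culture"}.
#' @return \code{patientID}: the patient identifier; \code{sites}: the
#'   \code{GRanges} of candidate sites; \code{siteKeys}: character vector of
#'   site keys; \code{snvSet}: the accepted SNV key set for one condition
#'   (error if \code{\link{callSnvSets}} has not been run);
#'   \code{filterLog}: named list of read/filter counters.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("patientID", function(x) standardGeneric("patientID"))

#' @rdname accessors
#' @export
setGeneric("sites", function(x) standardGeneric("sites"))

#' @rdname accessors
#' @export
setGeneric("siteKeys", function(x) standardGeneric("siteKeys"))

#' @rdname accessors
#' @export
setGeneric("snvSet", function(x, condition) standardGeneric("snvSet"))

#' @rdname accessors
#' @export
setGeneric("filterLog", function(x) standardGeneric("filterLog"))

#' @rdname accessors
#' @export
setMethod("patientID", "TrioCallset", function(x) x@patientID)

#' @rdname accessors
#' @export
setMethod("sites", "TrioCallset", function(x) x@sites)

#' @rdname accessors
#' @export
setMethod("siteKeys", "TrioCallset", function(x) names(x@sites))

#' @rdname accessors
#' @export
setMethod("snvSet", "TrioCallset", function(x, condition) {
  .checkCondition(condition)
  if (!length(x@snvSets))
    stop("SNV sets not computed yet; run callSnvSets() first")
  x@snvSets[[condition]]
})

#' @rdname accessors
#' @export
setMethod("filterLog", "TrioCallset", function(x) x@filterLog)

#' @rdname accessors
#' @export
setMethod("patientID", "VafVector", function(x) x@patientID)

#' @rdname accessors
#' @export
setMethod("patientID", "MathResult", function(x) x@patientID)

#' Extract variant allele fractions
#' @param x a \linkS4class{VafVector}.
#' @return named numeric vector of VAFs (names = site keys).
#' @export
setGeneric("vafs", function(x) standardGeneric("vafs"))

#' @rdname vafs
#' @export
setMethod("vafs", "VafVector",
          function(x) setNames(x@vaf, x@keys))

#' MATH score of a VAF distribution
#'
#' MATH (mutant-allele tumor heterogeneity) is
#' \code{100 * MAD / median} of the tumor-specific variant allele
#' fractions; larger values indicate greater intra-tumor heterogeneity.
#'
#' @param vafs a numeric vector of VAFs in (0, 1], or a
#'   \linkS4class{VafVector}.
#' @param scaleFactor MAD scale factor; 1.4826 (default) for consistency
#'   with the standard deviation under normality, 1.0 for the raw median
#'   absolute deviation.
#' @param minSites below this many sites the result is flagged unreliable
#'   (default 5).
#' @param ... passed between methods.
#' @return a \linkS4class{MathResult}.
#' @examples
#' mathScore(c(0.2, 0.25, 0.3, 0.35, 0.4), scaleFactor = 1)
#' @export
setGeneric("mathScore", function(vafs, ...) standardGeneric("mathScore"))

## show methods -------------------------------------------------------------

setMethod("show", "TrioCallset", function(object) {
  cat("TrioCallset for patient", object@patientID, "with",
      length(object@sites), "candidate sites\n")
  if (length(object@snvSets)) {
    n <- vapply(TRIO_CONDITIONS, function(cc)
      length(object@snvSets[[cc]]), integer(1))
    cat("  accepted SNVs:",
        paste(sprintf("%s=%d", TRIO_CONDITIONS, n), collapse = ", "), "\n")
  } else cat("  SNV sets not yet computed (run callSnvSets)\n")
})

setMethod("show", "TrioSimConfig", function(object) {
  cat("TrioSimConfig:", object@nPatients, "patients,",
      object@germlineSnvCount, "germline SNVs each\n")
  cat(sprintf("  purity %.2f, culture normal fraction %.2f, depth %s(%g)\n",
              object@tumorPurity, object@cultureNormalFraction,
              object@depthModel, object@meanDepth))
  cat(sprintf("  low-quality read rate %.2f, strand bias %.2f, seed %d\n",
              object@lowQualityReadRate, object@strandBias, object@seed))
})

setMethod("show", "VafVector", function(object) {
  cat(sprintf("VafVector: %d tumor-specific sites (%s, %s)\n",
              length(object@vaf), object@patientID, object@sample))
})

setMethod("show", "MathResult", function(object) {
  cat(sprintf(
    "MathResult %s/%s: MATH = %.2f (n = %d, median VAF %.4f, MAD %.4f, scale %.4f)%s\n",
    object@patientID, object@sample, object@math, object@nSites,
    object@medianVaf, object@madVaf, object@scaleFactor,
    if (object@reliable) "" else " [unreliable: too few sites]"))
})

setMethod("show", "PcaResult", function(object) {
  cat(sprintf("PcaResult: %d samples x %d components; explained variance %s\n",
              nrow(object@coordinates), ncol(object@coordinates),
              paste(sprintf("%.3f", object@explainedVariance),
                    collapse = ", ")))
})
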