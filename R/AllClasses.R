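#' @include triohet-package.R
NULL

## ---------------------------------------------------------------------------
## TrioCallset
## ---------------------------------------------------------------------------

#' TrioCallset: per-patient trio variant table and derived SNV sets
#'
#' Holds one patient's candidate SNVs as a \code{GRanges} (width-1 sites,
#' names = site keys \code{"chrom:pos_ref/alt"}) whose metadata columns carry,
#' per condition \code{c} in Normal/Tumor/Culture, the raw read depth
#' (\code{rawDepth_c}) and the base-quality-filtered (Q > 30) allele counts by
#' strand (\code{qRefFwd_c}, \code{qRefRev_c}, \code{qAltFwd_c},
#' \code{qAltRev_c}).  After \code{\link{callSnvSets}} the \code{snvSets} slot
#' holds the per-condition accepted SNV key sets.
#'
#' @slot patientID single character identifier.
#' @slot sites \code{GRanges} of candidate sites with the count columns above.
#' @slot snvSets named list of character vectors (site keys), one per
#'   condition, filled by \code{\link{callSnvSets}}; empty until then.
#' @slot filterLog named list of integer counters (records skipped on read,
#'   per-rule rejection counts).
#'
#' @seealso \code{\link{readTrioVcf}}, \code{\link{callSnvSets}},
#'   \code{\link{snvSet}}
#' @exportClass TrioCallset
setClass("TrioCallset",
  representation(
    patientID = "character",
    sites     = "GRanges",
    snvSets   = "list",
    filterLog = "list"
  ),
  prototype(snvSets = list(), filterLog = list())
)

.countCols <- function() {
  as.vector(outer(
    c("rawDepth", "qRefFwd", "qRefRev", "qAltFwd", "qAltRev"),
    TRIO_CONDITIONS, paste, sep = "_"))
}

setValidity("TrioCallset", function(object) {
  msg <- character()
  if (length(object@patientID) != 1L || is.na(object@patientID))
    msg <- c(msg, "patientID must be a single non-NA string")
  gr <- object@sites
  if (length(gr)) {
    if (is.null(names(gr)) || anyDuplicated(names(gr)))
      msg <- c(msg, "site keys (names of sites) must be present and unique")
    need <- c("ref", "alt", .countCols())
    missing <- setdiff(need, colnames(mcols(gr)))
    if (length(missing))
      msg <- c(msg, paste("missing site columns:",
                          paste(missing, collapse = ", ")))
    if (!length(missing)) {
      if (any(mcols(gr)$ref == mcols(gr)$alt))
        msg <- c(msg, "ref and alt allele must differ at every site")
      cnt <- as.matrix(mcols(gr)[, .countCols()])
      if (any(cnt < 0)) msg <- c(msg, "all counts must be non-negative")
      for (cond in TRIO_CONDITIONS) {
        qsum <- mcols(gr)[[paste0("qRefFwd_", cond)]] +
          mcols(gr)[[paste0("qRefRev_", cond)]] +
          mcols(gr)[[paste0("qAltFwd_", cond)]] +
          mcols(gr)[[paste0("qAltRev_", cond)]]
        if (any(qsum > mcols(gr)[[paste0("rawDepth_", cond)]]))
          msg <- c(msg, paste0("quality-filtered counts exceed rawDepth_",
                               cond))
      }
    }
  }
  if (length(object@snvSets) &&
      !all(names(object@snvSets) %in% TRIO_CONDITIONS))
    msg <- c(msg, "snvSets names must be trio conditions")
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## TrioSimConfig
## ---------------------------------------------------------------------------

#' TrioSimConfig: parameters of the synthetic trio-cohort simulator
#'
#' Ground-truth subclone structure and read-sampling parameters for
#' \code{\link{simulateTrioCohort}}.  Construct with the
#' \code{\link{TrioSimConfig}} constructor, which fills documented defaults
#' and validates ranges.
#'
#' @slot nPatients number of patients (trios) to simulate.
#' @slot germlineSnvCount germline heterozygous SNVs per patient (true VAF
#'   0.5 in all three conditions).
#' @slot clones list of length \code{nPatients}; each element a data.frame of
#'   clone specifications with columns \code{clone_id}, \code{ccf}
#'   (cancer-cell fraction in (0,1]; at least one clone per patient must be
#'   truncal, ccf = 1), \code{n_private_mutations},
#'   \code{present_in_tumor}, \code{present_in_culture}.
#' @slot tumorPurity cancer-cell fraction of the tumor sample, in (0, 1].
#' @slot cultureNormalFraction normal-cell fraction of the culture sample,
#'   in [0, 1); default 0.5, the contamination level typical of
#'   conditionally reprogrammed cultures.
#' @slot meanDepth mean sequencing depth per site and sample.
#' @slot depthModel \code{"poisson"} (depth ~ Poisson(meanDepth)) or
#'   \code{"fixed"}.
#' @slot lowQualityReadRate fraction of reads below the base-quality
#'   threshold (counted in raw depth, excluded from quality-filtered
#'   counts), in [0, 1).
#' @slot strandBias probability a read maps to the forward strand, in (0, 1).
#' @slot seed integer seed; all simulator randomness flows from it.
#'
#' @seealso \code{\link{simulateTrioCohort}},
#'   \code{\link{defaultCloneScenarios}}
#' @exportClass TrioSimConfig
setClass("TrioSimConfig",
  representation(
    nPatients             = "integer",
    germlineSnvCount      = "integer",
    clones                = "list",
    tumorPurity           = "numeric",
    cultureNormalFraction = "numeric",
    meanDepth             = "numeric",
    depthModel            = "character",
    lowQualityReadRate    = "numeric",
    strandBias            = "numeric",
    seed                  = "integer"
  )
)

.validateCloneFrame <- function(cl, i) {
  msg <- character()
  need <- c("clone_id", "ccf", "n_private_mutations",
            "present_in_tumor", "present_in_culture")
  if (!is.data.frame(cl) || !all(need %in% names(cl)))
    return(paste0("clones[[", i, "]] must be a data.frame with columns ",
                  paste(need, collapse = ", ")))
  if (nrow(cl) == 0L)
    msg <- c(msg, paste0("clones[[", i, "]]: at least one clone required"))
  if (any(cl$ccf <= 0 | cl$ccf > 1))
    msg <- c(msg, paste0("clones[[", i, "]]: ccf must lie in (0, 1]"))
  if (nrow(cl) && !any(cl$ccf == 1))
    msg <- c(msg, paste0("clones[[", i,
                         "]]: at least one truncal clone (ccf = 1) required"))
  if (any(cl$n_private_mutations < 0))
    msg <- c(msg, paste0("clones[[", i,
                         "]]: n_private_mutations must be >= 0"))
  if (anyDuplicated(cl$clone_id))
    msg <- c(msg, paste0("clones[[", i, "]]: clone_id must be unique"))
  msg
}

setValidity("TrioSimConfig", function(object) {
  msg <- character()
  chk <- function(cond, text) if (!isTRUE(cond)) msg <<- c(msg, text)
  chk(object@nPatients >= 1L, "nPatients must be >= 1")
  chk(object@germlineSnvCount >= 0L, "germlineSnvCount must be >= 0")
  chk(object@tumorPurity > 0 && object@tumorPurity <= 1,
      "tumorPurity must lie in (0, 1]")
  chk(object@cultureNormalFraction >= 0 && object@cultureNormalFraction < 1,
      "cultureNormalFraction must lie in [0, 1)")
  chk(object@meanDepth > 0, "meanDepth must be positive")
  chk(length(object@depthModel) == 1L &&
        object@depthModel %in% c("poisson", "fixed"),
      "depthModel must be 'poisson' or 'fixed'")
  chk(object@lowQualityReadRate >= 0 && object@lowQualityReadRate < 1,
      "lowQualityReadRate must lie in [0, 1)")
  chk(object@strandBias > 0 && object@strandBias < 1,
      "strandBias must lie in (0, 1)")
  chk(length(object@seed) == 1L && !is.na(object@seed),
      "seed must be a single integer")
  if (length(object@clones) != object@nPatients)
    msg <- c(msg, "clones must be a list with one element per patient")
  else
    for (i in seq_along(object@clones))
      msg <- c(msg, .validateCloneFrame(object@clones[[i]], i))
  if (length(msg)) msg else TRUE
})

#' Construct a simulator configuration
#'
#' @param nPatients number of trios.
#' @param germlineSnvCount germline heterozygous SNVs per patient.
#' @param clones a single clone data.frame (recycled to all patients) or a
#'   list of one data.frame per patient; see \linkS4class{TrioSimConfig}.
#'   Defaults to \code{\link{defaultCloneScenarios}(nPatients)}.
#' @param tumorPurity cancer-cell fraction of the tumor sample.
#' @param cultureNormalFraction normal-cell fraction of the culture sample.
#' @param meanDepth mean read depth.
#' @param depthModel \code{"poisson"} or \code{"fixed"}.
#' @param lowQualityReadRate fraction of reads below the base-quality cut.
#' @param strandBias forward-strand probability per read.
#' @param seed mandatory integer seed.
#' @return a validated \linkS4class{TrioSimConfig}.
#' @examples
#' cfg <- TrioSimConfig(nPatients = 2, germlineSnvCount = 100, seed = 1)
#' @export
TrioSimConfig <- function(nPatients = 2L,
                          germlineSnvCount = 2000L,
                          clones = defaultCloneScenarios(nPatients),
                          tumorPurity = 0.7,
                          cultureNormalFraction = 0.5,
                          meanDepth = 80,
                          depthModel = c("poisson", "fixed"),
                          lowQualityReadRate = 0.05,
                          strandBias = 0.5,
                          seed) {
  if (missing(seed)) stop("seed is mandatory in a TrioSimConfig")
  depthModel <- match.arg(depthModel)
  if (is.data.frame(clones)) clones <- rep(list(clones), nPatients)
  if (length(clones) == 1L && nPatients > 1L)
    clones <- rep(clones, nPatients)
  new("TrioSimConfig",
      nPatients = as.integer(nPatients),
      germlineSnvCount = as.integer(germlineSnvCount),
      clones = clones,
      tumorPurity = tumorPurity,
      cultureNormalFraction = cultureNormalFraction,
      meanDepth = meanDepth,
      depthModel = depthModel,
      lowQualityReadRate = lowQualityReadRate,
      strandBias = strandBias,
      seed = as.integer(seed))
}

## ---------------------------------------------------------------------------
## VafVector / MathResult
## ---------------------------------------------------------------------------

#' VafVector: tumor-specific variant allele fractions for one sample
#'
#' Site keys and VAFs (quality-filtered alt / (alt + ref), summed over
#' strands) of sites accepted in the given sample and absent from the
#' patient's Normal SNV set.
#'
#' @slot patientID patient identifier.
#' @slot sample \code{"Tumor"} or \code{"Culture"}.
#' @slot keys site keys.
#' @slot vaf numeric VAFs in (0, 1], parallel to \code{keys}.
#' @seealso \code{\link{tumorSpecificVafs}}, \code{\link{mathScore}}
#' @exportClass VafVector
setClass("VafVector",
  representation(patientID = "character", sample = "character",
                 keys = "character", vaf = "numeric"))

setValidity("VafVector", function(object) {
  msg <- character()
  if (length(object@keys) != length(object@vaf))
    msg <- c(msg, "keys and vaf must have equal length")
  if (length(object@vaf) && (any(object@vaf <= 0) || any(object@vaf > 1)))
    msg <- c(msg, "vaf values must lie in (0, 1]")
  if (!object@sample %in% c("Tumor", "Culture"))
    msg <- c(msg, "sample must be 'Tumor' or 'Culture'")
  if (length(msg)) msg else TRUE
})

#' MathResult: MATH score of one sample's tumor-specific VAF distribution
#'
#' MATH = 100 * MAD / median of the VAFs, where MAD is the median absolute
#' deviation (scaled by \code{scaleFactor}, default 1.4826).
#'
#' @slot patientID patient identifier (may be \code{NA}).
#' @slot sample sample label (may be \code{NA}).
#' @slot nSites number of VAFs used.
#' @slot medianVaf median VAF.
#' @slot madVaf scaled median absolute deviation of the VAFs.
#' @slot math the MATH score, \code{100 * madVaf / medianVaf}.
#' @slot scaleFactor MAD scale factor used.
#' @slot reliable \code{FALSE} when \code{nSites} is below the configured
#'   minimum (default 5).
#' @seealso \code{\link{mathScore}}, \code{\link{cohortMathTable}}
#' @exportClass MathResult
setClass("MathResult",
  representation(patientID = "character", sample = "character",
                 nSites = "integer", medianVaf = "numeric",
                 madVaf = "numeric", math = "numeric",
                 scaleFactor = "numeric", reliable = "logical"))

setValidity("MathResult", function(object) {
  msg <- character()
  if (object@nSites < 1L) msg <- c(msg, "nSites must be >= 1")
  if (!is.na(object@math) && object@math < 0)
    msg <- c(msg, "math must be non-negative")
  ok <- isTRUE(all.equal(object@math,
                         100 * object@madVaf / object@medianVaf))
  if (!ok) msg <- c(msg, "math must equal 100 * madVaf / medianVaf")
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## PcaResult
## ---------------------------------------------------------------------------

#' PcaResult: principal components of a cohort genotype matrix
#'
#' Column-mean-centered SVD of the binary sample-by-SNV matrix.  Component
#' signs follow the convention that each component's largest-magnitude
#' loading is positive, making results deterministic.
#'
#' @slot coordinates samples-by-k matrix of PC scores (rownames = samples).
#' @slot explainedVariance fraction of total variance per retained
#'   component; non-increasing, sums to at most 1.
#' @slot center column means removed before decomposition.
#' @slot rotation variable loadings (columns = components).
#' @seealso \code{\link{runPca}}, \code{\link{tripletGroupingScore}}
#' @exportClass PcaResult
setClass("PcaResult",
  representation(coordinates = "matrix", explainedVariance = "numeric",
                 center = "numeric", rotation = "matrix"))

setValidity("PcaResult", function(object) {
  msg <- character()
  ev <- object@explainedVariance
  if (length(ev)) {
    if (any(diff(ev) > 1e-8))
      msg <- c(msg, "explainedVariance must be non-increasing")
    if (sum(ev) > 1 + 1e-8)
      msg <- c(msg, "explainedVariance must sum to at most 1")
  }
  if (ncol(object@coordinates) != length(ev))
    msg <- c(msg, "one explainedVariance entry per retained component")
  if (length(msg)) msg else TRUE
})
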