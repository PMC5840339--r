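#' Tumor-specific variant allele fractions
#'
#' Extracts, for the Tumor or Culture sample of one patient, the VAFs of
#' sites accepted in that sample but absent from the patient's Normal SNV
#' set — the "tumor-specific" mutations on which intra-tumor
#' heterogeneity is measured.  Excluding the matched-normal set removes
#' germline polymorphisms by set subtraction, mirroring how heterogeneity
#' scoring excludes SNVs found in the corresponding normal sample.  Each
#' VAF is quality-filtered alt / (alt + ref), counts summed over strands
#' in that sample.
#'
#' @param x a \linkS4class{TrioCallset} with computed SNV sets.
#' @param sample \code{"Tumor"} or \code{"Culture"} (\code{"Normal"} is
#'   rejected: normal-specific VAFs have no meaning here).
#' @return a \linkS4class{VafVector}.
#' @export
tumorSpecificVafs <- function(x, sample = c("Tumor", "Culture")) {
  stopifnot(is(x, "TrioCallset"))
  sample <- match.arg(sample)
  if (!length(x@snvSets))
    stop("SNV sets not computed yet; run callSnvSets() first")
  keys <- setdiff(snvSet(x, sample), snvSet(x, "Normal"))
  idx <- match(keys, siteKeys(x))
  qAlt <- mcols(x@sites)[[paste0("qAltFwd_", sample)]][idx] +
    mcols(x@sites)[[paste0("qAltRev_", sample)]][idx]
  qRef <- mcols(x@sites)[[paste0("qRefFwd_", sample)]][idx] +
    mcols(x@sites)[[paste0("qRefRev_", sample)]][idx]
  new("VafVector", patientID = patientID(x), sample = sample,
      keys = keys, vaf = qAlt / (qAlt + qRef))
}

#' Scaled median absolute deviation
#'
#' \code{scaleFactor * median(|x - median(x)|)}.  The default scale
#' factor 1.4826 makes the MAD a consistent estimator of the standard
#' deviation under normality and matches the original MATH definition;
#' set \code{scaleFactor = 1} for the raw MAD.
#'
#' @param values non-empty numeric vector.
#' @param scaleFactor multiplicative constant (default 1.4826).
#' @return the scaled MAD.
#' @examples
#' scaledMad(c(0.2, 0.25, 0.3, 0.35, 0.4), scaleFactor = 1)  # 0.05
#' @export
scaledMad <- function(values, scaleFactor = 1.4826) {
  if (!length(values)) stop("scaledMad requires a non-empty vector")
  mad(values, constant = scaleFactor)
}

#' @rdname mathScore
#' @param patientID,sample labels carried into the result (numeric
#'   method only).
#' @export
setMethod("mathScore", "numeric",
  function(vafs, scaleFactor = 1.4826, minSites = 5L,
           patientID = NA_character_, sample = NA_character_) {
    if (!length(vafs)) stop("mathScore requires at least one VAF")
    if (any(vafs <= 0) || any(vafs > 1))
      stop("VAFs must lie in (0, 1]")
    med <- median(vafs)
    madv <- scaledMad(vafs, scaleFactor)
    new("MathResult", patientID = patientID, sample = sample,
        nSites = length(vafs), medianVaf = med, madVaf = madv,
        math = 100 * madv / med, scaleFactor = scaleFactor,
        reliable = length(vafs) >= minSites)
  })

#' @rdname mathScore
#' @export
setMethod("mathScore", "VafVector",
  function(vafs, scaleFactor = 1.4826, minSites = 5L) {
    mathScore(vafs@vaf, scaleFactor = scaleFactor, minSites = minSites,
              patientID = vafs@patientID, sample = vafs@sample)
  })

#' Cohort MATH table: tumor and culture heterogeneity per patient
#'
#' Computes the MATH score of the tumor-specific VAF distribution for the
#' Tumor and the Culture sample of every patient.  Patients whose VAF
#' vector is empty, or below the reliability minimum, are kept in the
#' table with \code{NA} scores / \code{reliable = FALSE} rather than
#' dropped.
#'
#' @param cohort list of \linkS4class{TrioCallset} objects with computed
#'   SNV sets.
#' @param scaleFactor MAD scale factor (see \code{\link{scaledMad}}).
#' @param minSites minimum tumor-specific sites for a reliable score.
#' @return data.frame with one row per patient and sample
#'   (\code{patient_id}, \code{sample}, \code{n_sites},
#'   \code{median_vaf}, \code{mad_vaf}, \code{math},
#'   \code{scale_factor}, \code{reliable}).
#' @export
cohortMathTable <- function(cohort, scaleFactor = 1.4826, minSites = 5L) {
  rows <- list()
  for (cs in cohort) {
    for (smp in c("Tumor", "Culture")) {
      vv <- tumorSpecificVafs(cs, smp)
      if (length(vv@vaf)) {
        mr <- mathScore(vv, scaleFactor = scaleFactor, minSites = minSites)
        rows[[length(rows) + 1L]] <- data.frame(
          patient_id = patientID(cs), sample = smp,
          n_sites = mr@nSites, median_vaf = mr@medianVaf,
          mad_vaf = mr@madVaf, math = mr@math,
          scale_factor = scaleFactor, reliable = mr@reliable,
          stringsAsFactors = FALSE)
      } else {
        rows[[length(rows) + 1L]] <- data.frame(
          patient_id = patientID(cs), sample = smp,
          n_sites = 0L, median_vaf = NA_real_, mad_vaf = NA_real_,
          math = NA_real_, scale_factor = scaleFactor, reliable = FALSE,
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
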