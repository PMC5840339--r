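#' Build the cohort sample-by-SNV presence/absence matrix
#'
#' Rows are the three samples of each patient (named
#' \code{"<patient>:<Condition>"}), columns the union of accepted site
#' keys across the cohort (sorted, so column order is deterministic),
#' cells 1 when the key is in that sample's SNV set.  Columns constant
#' across all samples carry no variance and are dropped by default.
#'
#' @param cohort list of \linkS4class{TrioCallset} objects with computed
#'   SNV sets (at least 2 samples total).
#' @param panel optional \code{GRanges} gene panel restricting the
#'   columns.
#' @param dropConstant drop zero-variance columns (default \code{TRUE}).
#' @return binary numeric matrix with informative dimnames.
#' @export
buildGenotypeMatrix <- function(cohort, panel = NULL,
                                dropConstant = TRUE) {
  sets <- list()
  for (cs in cohort) {
    stopifnot(is(cs, "TrioCallset"))
    for (cond in TRIO_CONDITIONS) {
      s <- snvSet(cs, cond)
      if (!is.null(panel)) s <- restrictToPanel(s, panel)
      sets[[paste(patientID(cs), cond, sep = ":")]] <- s
    }
  }
  if (length(sets) < 2L)
    stop("at least 2 samples required to build a genotype matrix")
  keys <- sort(unique(unlist(sets, use.names = FALSE)))
  m <- vapply(sets, function(s) as.numeric(keys %in% s),
              numeric(length(keys)))
  m <- t(matrix(m, nrow = length(keys), ncol = length(sets),
                dimnames = list(keys, names(sets))))
  if (dropConstant && ncol(m)) {
    keep <- apply(m, 2L, function(col) length(unique(col)) > 1L)
    m <- m[, keep, drop = FALSE]
  }
  m
}

#' Principal component analysis of a genotype matrix
#'
#' Column-mean-centers the matrix and decomposes it by singular value
#' decomposition; sample coordinates are the projections on the top-k
#' right singular directions.  Component signs are fixed by the
#' convention that each component's largest-magnitude loading is
#' positive, so results are deterministic and invariant (up to that
#' convention) under row reordering.  Explained-variance fractions are
#' relative to the total variance of all components (zero when the
#' matrix has no variance at all).
#'
#' @param m numeric matrix (samples x variables), e.g. from
#'   \code{\link{buildGenotypeMatrix}}.
#' @param k number of components to retain, at most
#'   \code{min(nrow(m) - 1, ncol(m))}; default 2.
#' @return a \linkS4class{PcaResult}.
#' @export
runPca <- function(m, k = 2L) {
  if (!is.matrix(m) || nrow(m) < 2L)
    stop("m must be a matrix with at least 2 rows")
  kmax <- min(nrow(m) - 1L, ncol(m))
  if (k < 1L || k > kmax)
    stop("k must lie in [1, ", kmax, "] for a ", nrow(m), " x ", ncol(m),
         " matrix")
  pc <- prcomp(m, center = TRUE, scale. = FALSE)
  rot <- pc$rotation
  scores <- pc$x
  for (j in seq_len(ncol(rot))) {
    lead <- which.max(abs(rot[, j]))
    if (rot[lead, j] < 0) {
      rot[, j] <- -rot[, j]
      scores[, j] <- -scores[, j]
    }
  }
  totVar <- sum(pc$sdev^2)
  ev <- if (totVar > 0) pc$sdev^2 / totVar else rep(0, length(pc$sdev))
  new("PcaResult",
      coordinates = scores[, seq_len(k), drop = FALSE],
      explainedVariance = ev[seq_len(k)],
      center = pc$center,
      rotation = rot[, seq_len(k), drop = FALSE])
}

#' Within- vs between-patient spread of trio samples in PCA space
#'
#' Ratio of the mean pairwise Euclidean distance between samples of the
#' same patient to the mean pairwise distance between samples of
#' different patients, computed in the first \code{k} PCA dimensions.  A
#' ratio below 1 means each patient's Normal/Tumor/Culture triplet
#' groups together more tightly than samples from different patients —
#' the pattern expected when patients differ mostly by germline
#' background.
#'
#' @param result a \linkS4class{PcaResult}.
#' @param patients character vector assigning each coordinate row to a
#'   patient; defaults to the part of the rowname before \code{":"}.
#' @param k number of leading components to use (default: all retained).
#' @return the within/between distance ratio.
#' @export
tripletGroupingScore <- function(result, patients = NULL, k = NULL) {
  stopifnot(is(result, "PcaResult"))
  coords <- result@coordinates
  if (is.null(patients))
    patients <- sub(":[^:]*$", "", rownames(coords))
  if (length(patients) != nrow(coords))
    stop("one patient label per coordinate row required")
  if (length(unique(patients)) < 2L)
    stop("at least 2 patients required (between-patient distance ",
         "undefined otherwise)")
  if (is.null(k)) k <- ncol(coords)
  if (k < 1L || k > ncol(coords))
    stop("k must lie in [1, ", ncol(coords), "]")
  d <- as.matrix(dist(coords[, seq_len(k), drop = FALSE]))
  same <- outer(patients, patients, `==`)
  upper <- upper.tri(d)
  within <- d[upper & same]
  between <- d[upper & !same]
  mean(within) / mean(between)
}
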