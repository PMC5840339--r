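#' Diagnostic plots for the trio analysis
#'
#' \code{plotSimilarity} draws the per-patient Jaccard similarity of the
#' culture to its normal (x) versus its tumor (y), with the identity
#' line: points above the diagonal are cultures more similar to their
#' tumor of origin than to normal tissue.  \code{plotMathPaired} draws
#' each patient's tumor and culture MATH scores as paired points
#' connected by a line.  \code{plotPca} draws the first two PCA
#' coordinates coloured by patient, so trio grouping is visible at a
#' glance.
#'
#' @param simTable output of \code{\link{cohortSimilarityTable}}.
#' @return a \code{ggplot} object.
#' @name trioPlots
NULL

#' @rdname trioPlots
#' @export
plotSimilarity <- function(simTable) {
  ggplot(simTable,
         aes(x = .data$sim_culture_normal, y = .data$sim_culture_tumor)) +
    geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                colour = "grey50") +
    geom_point(size = 2) +
    labs(x = "Jaccard similarity, culture vs normal",
         y = "Jaccard similarity, culture vs tumor") +
    theme_bw()
}

#' @rdname trioPlots
#' @param mathTable output of \code{\link{cohortMathTable}}.
#' @export
plotMathPaired <- function(mathTable) {
  ggplot(mathTable,
         aes(x = .data$patient_id, y = .data$math,
             colour = .data$sample, group = .data$patient_id)) +
    geom_line(colour = "grey70") +
    geom_point(size = 2.5) +
    labs(x = "patient", y = "MATH score", colour = "sample") +
    theme_bw()
}

#' @rdname trioPlots
#' @param pca a \linkS4class{PcaResult} with at least 2 components.
#' @param patients patient label per row; default parsed from rownames.
#' @export
plotPca <- function(pca, patients = NULL) {
  coords <- pca@coordinates
  if (ncol(coords) < 2L) stop("plotPca needs at least 2 components")
  if (is.null(patients))
    patients <- sub(":[^:]*$", "", rownames(coords))
  df <- data.frame(PC1 = coords[, 1], PC2 = coords[, 2],
                   patient = patients,
                   sample = sub("^.*:", "", rownames(coords)))
  ggplot(df, aes(x = .data$PC1, y = .data$PC2, colour = .data$patient)) +
    geom_point(size = 2.5) +
    labs(x = sprintf("PC1 (%.1f%%)", 100 * pca@explainedVariance[1]),
         y = sprintf("PC2 (%.1f%%)", 100 * pca@explainedVariance[2])) +
    theme_bw()
}
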