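#' Jaccard similarity between two SNV sets
#'
#' \code{|a intersect b| / |a union b|}, the Jaccard index; the Jaccard
#' distance is its complement.  When both sets are empty the quantity is
#' undefined and \code{NA} is returned with a warning rather than a
#' silent 0 or 1.
#'
#' @param a,b character vectors of site keys (treated as sets).
#' @return numeric in [0, 1], or \code{NA} if both sets are empty.
#' @examples
#' jaccardSimilarity(c("k1", "k2", "k3"), c("k2", "k3", "k4"))  # 0.5
#' @export
jaccardSimilarity <- function(a, b) {
  a <- unique(a); b <- unique(b)
  if (!length(a) && !length(b)) {
    warning("Jaccard similarity undefined for two empty sets")
    return(NA_real_)
  }
  inter <- length(intersect(a, b))
  inter / (length(a) + length(b) - inter)
}

#' Percentage of a query SNV set shared with a reference set
#'
#' \code{100 * |query intersect reference| / |query|}.  Asymmetric: in the
#' fidelity analysis the query is the culture's SNV set and the reference
#' the tumor's (or normal's), answering "what fraction of the culture's
#' SNVs are also seen in the reference sample".
#'
#' @param query non-empty character vector of site keys.
#' @param reference character vector of site keys.
#' @return percentage in [0, 100].
#' @export
sharedPercentage <- function(query, reference) {
  query <- unique(query)
  if (!length(query))
    stop("shared percentage undefined for an empty query set")
  100 * length(intersect(query, unique(reference))) / length(query)
}

#' Venn overlap counts of two SNV sets
#'
#' @param a,b character vectors of site keys.
#' @return named integer vector \code{c(only_a, both, only_b)}; the three
#'   disjoint region sizes, with \code{only_a + both == |a|}.
#' @examples
#' vennCounts(c("k1", "k2", "k3"), c("k2", "k3", "k4"))  # 1, 2, 1
#' @export
vennCounts <- function(a, b) {
  a <- unique(a); b <- unique(b)
  both <- length(intersect(a, b))
  c(only_a = length(a) - both, both = both, only_b = length(b) - both)
}

#' Load a cancer-gene panel as genomic intervals
#'
#' Reads a gene panel — e.g. a driver-gene list such as the 125 cancer
#' genes of Vogelstein and colleagues, as interval annotations — from a
#' BED file (0-based half-open; 4th column gene symbol) or a tab-separated
#' table with columns \code{gene}, \code{chrom}, \code{start}, \code{end}
#' (same coordinate convention).  Chromosome names are normalized by
#' stripping any \code{"chr"} prefix, with a message, so panels and
#' callsets in different dialects still overlap.
#'
#' @param path panel file (\code{.bed} or TSV).
#' @return a \code{GRanges} with a \code{gene} metadata column (1-based
#'   closed coordinates, the GRanges convention).
#' @export
readGenePanel <- function(path) {
  if (!file.exists(path)) stop("panel file not found: ", path)
  if (grepl("\\.bed$", path, ignore.case = TRUE)) {
    gr <- import(path, format = "BED")
    mcols(gr)$gene <- mcols(gr)$name
  } else {
    df <- read.delim(path, stringsAsFactors = FALSE)
    need <- c("gene", "chrom", "start", "end")
    if (!all(need %in% names(df)))
      stop("panel TSV must have columns ", paste(need, collapse = ", "))
    # 0-based half-open -> 1-based closed
    gr <- GRanges(df$chrom, IRanges(df$start + 1L, df$end))
    mcols(gr)$gene <- df$gene
  }
  if (any(mcols(gr)$gene == "" | is.na(mcols(gr)$gene)))
    stop("panel gene symbols must be non-empty")
  if (any(GenomicRanges::width(gr) < 1L))
    stop("panel intervals must satisfy start < end")
  chrPrefixed <- grepl("^chr", seqlevels(gr))
  if (any(chrPrefixed)) {
    message("normalizing ", sum(chrPrefixed),
            " 'chr'-prefixed chromosome name(s) in panel")
    gr <- renameSeqlevels(gr, sub("^chr", "", seqlevels(gr)))
  }
  gr
}

#' Restrict an SNV set to a gene panel
#'
#' Keeps site keys whose position falls inside any panel interval.
#' Chromosome names on both sides are compared after stripping any
#' \code{"chr"} prefix; if the set and panel share no chromosome names at
#' all, a dialect mismatch is reported instead of silently returning an
#' empty set.
#'
#' @param s character vector of site keys.
#' @param panel a \code{GRanges} panel from \code{\link{readGenePanel}}
#'   (or any GRanges with 1-based closed intervals).
#' @return the subset of \code{s} inside the panel; always a subset of
#'   \code{s}, and idempotent.
#' @export
restrictToPanel <- function(s, panel) {
  if (!length(s) || !length(panel)) return(s[0])
  parsed <- parseSiteKeys(s)
  setChrom <- sub("^chr", "", parsed$chrom)
  panelChrom <- sub("^chr", "", as.character(seqnames(panel)))
  if (!any(unique(setChrom) %in% unique(panelChrom)))
    stop("no chromosome names in common between SNV set (",
         paste(utils::head(unique(parsed$chrom), 3), collapse = ","),
         ", ...) and panel (",
         paste(utils::head(unique(as.character(seqnames(panel))), 3),
               collapse = ","),
         ", ...): check the chr-prefix dialect")
  sitesGr <- GRanges(setChrom, IRanges(parsed$pos, width = 1L))
  panelNorm <- GRanges(panelChrom,
                       IRanges(start(panel), GenomicRanges::end(panel)))
  hits <- findOverlaps(sitesGr, panelNorm)
  s[unique(S4Vectors::queryHits(hits))]
}

#' Per-patient and cohort-level similarity of culture to tumor and normal
#'
#' For each patient computes the Jaccard similarity and shared-SNV
#' percentage of the Culture set against the Tumor and the Normal sets,
#' optionally restricted to a gene panel.  The cohort-level aggregate
#' shared percentages are attached as \code{attr(result, "aggregate")}:
#' \code{pooled_*} values pool counts across patients
#' (\code{100 * sum(intersections) / sum(culture set sizes)}) — the
#' natural reading of a statement like "in total, cultures share X% of
#' their SNVs" — while \code{mean_*} values average the per-patient
#' percentages; the two differ when culture set sizes differ.
#'
#' @param cohort list of \linkS4class{TrioCallset} objects with computed
#'   SNV sets.
#' @param panel optional \code{GRanges} gene panel; when supplied all sets
#'   are panel-restricted first.
#' @return data.frame with one row per patient: \code{patient_id},
#'   \code{sim_culture_tumor}, \code{sim_culture_normal},
#'   \code{shared_pct_culture_in_tumor},
#'   \code{shared_pct_culture_in_normal}, \code{panel_restricted};
#'   aggregate list in \code{attr(, "aggregate")}.
#' @export
cohortSimilarityTable <- function(cohort, panel = NULL) {
  rows <- vector("list", length(cohort))
  interT <- interN <- sizeC <- 0
  for (i in seq_along(cohort)) {
    cs <- cohort[[i]]
    stopifnot(is(cs, "TrioCallset"))
    setN <- snvSet(cs, "Normal")
    setT <- snvSet(cs, "Tumor")
    setC <- snvSet(cs, "Culture")
    if (!is.null(panel)) {
      setN <- restrictToPanel(setN, panel)
      setT <- restrictToPanel(setT, panel)
      setC <- restrictToPanel(setC, panel)
    }
    if (!length(setC))
      stop("patient ", patientID(cs),
           ": empty Culture SNV set; similarity undefined")
    rows[[i]] <- data.frame(
      patient_id = patientID(cs),
      sim_culture_tumor = jaccardSimilarity(setC, setT),
      sim_culture_normal = jaccardSimilarity(setC, setN),
      shared_pct_culture_in_tumor = sharedPercentage(setC, setT),
      shared_pct_culture_in_normal = sharedPercentage(setC, setN),
      panel_restricted = !is.null(panel),
      stringsAsFactors = FALSE)
    interT <- interT + length(intersect(setC, setT))
    interN <- interN + length(intersect(setC, setN))
    sizeC <- sizeC + length(setC)
  }
  out <- do.call(rbind, rows)
  attr(out, "aggregate") <- list(
    pooled_shared_pct_culture_in_tumor = 100 * interT / sizeC,
    pooled_shared_pct_culture_in_normal = 100 * interN / sizeC,
    mean_shared_pct_culture_in_tumor =
      mean(out$shared_pct_culture_in_tumor),
    mean_shared_pct_culture_in_normal =
      mean(out$shared_pct_culture_in_normal),
    pooled_culture_set_size = sizeC)
  out
}

#' Per-patient Venn counts of culture vs tumor SNV sets
#'
#' @inheritParams cohortSimilarityTable
#' @return data.frame with columns \code{patient_id}, \code{only_culture},
#'   \code{both}, \code{only_tumor}.
#' @export
cohortVennTable <- function(cohort, panel = NULL) {
  rows <- lapply(cohort, function(cs) {
    setT <- snvSet(cs, "Tumor")
    setC <- snvSet(cs, "Culture")
    if (!is.null(panel)) {
      setT <- restrictToPanel(setT, panel)
      setC <- restrictToPanel(setC, panel)
    }
    v <- vennCounts(setC, setT)
    data.frame(patient_id = patientID(cs),
               only_culture = unname(v["only_a"]),
               both = unname(v["both"]),
               only_tumor = unname(v["only_b"]),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
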