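#' Expected variant allele fraction under the purity/CCF dilution model
#'
#' Closed-form expected VAF of a clonal or subclonal mutation in a bulk
#' sample that mixes cancer and normal cells, assuming normal cells are
#' diploid and carry the reference allele:
#' \deqn{VAF = \frac{m \cdot ccf \cdot f}{2 (1 - f) + C_t \cdot f}}
#' where \eqn{ccf} is the cancer-cell fraction of the clone among cancer
#' cells, \eqn{f} the cancer-cell fraction of the sample (tumor purity, or
#' one minus the culture's normal-cell contamination), \eqn{m} the mutation
#' multiplicity and \eqn{C_t} the total copy number at the locus.  The
#' simulator is copy-neutral (\eqn{m = 1}, \eqn{C_t = 2}), under which a
#' truncal mutation in a pure sample has VAF 0.5.
#'
#' @param ccf cancer-cell fraction of the clone, in (0, 1].
#' @param cancerCellFraction cancer-cell fraction of the sample, in [0, 1].
#' @param multiplicity mutated copies per cancer cell (default 1).
#' @param totalCopyNumber total copy number at the locus (default 2, >= 1).
#' @return numeric expected VAF, vectorized over the arguments.
#' @examples
#' expectedVaf(1, 1)        # 0.5: pure diploid heterozygous
#' expectedVaf(1, 0.5)      # 0.25: 50% contamination halves the VAF
#' expectedVaf(0.4, 0.8)    # 0.16
#' @export
expectedVaf <- function(ccf, cancerCellFraction, multiplicity = 1L,
                        totalCopyNumber = 2L) {
  if (any(ccf <= 0 | ccf > 1))
    stop("ccf must lie in (0, 1]")
  if (any(cancerCellFraction < 0 | cancerCellFraction > 1))
    stop("cancerCellFraction must lie in [0, 1]")
  if (any(multiplicity < 1) || any(multiplicity > totalCopyNumber))
    stop("multiplicity must lie in [1, totalCopyNumber]")
  if (any(totalCopyNumber < 1))
    stop("totalCopyNumber must be >= 1")
  multiplicity * ccf * cancerCellFraction /
    (2 * (1 - cancerCellFraction) + totalCopyNumber * cancerCellFraction)
}

#' Default clone scenarios for a simulated cohort
#'
#' A deterministic per-patient subclone layout covering the discordance
#' modes seen when a culture is derived from a heterogeneous tumor:
#' \itemize{
#'   \item every patient carries a truncal clone (ccf 1, 100 private
#'     mutations) present in tumor and culture;
#'   \item most patients carry a subclone (ccf 0.4, 60 mutations) present
#'     in both samples;
#'   \item every third patient starting at the second (patients 2, 5, 8,
#'     ...) is a \emph{dropout} patient: the subclone fails to propagate in
#'     culture (\code{present_in_culture = FALSE});
#'   \item patient 4 (when present) is the \emph{rare-clone expansion}
#'     patient: a clone undetectable in the tumor (ccf 0.35,
#'     \code{present_in_tumor = FALSE}) grows out in culture.
#' }
#'
#' @param nPatients number of patients.
#' @return list of clone data.frames, one per patient (see
#'   \linkS4class{TrioSimConfig}).
#' @examples
#' defaultCloneScenarios(4)
#' @export
defaultCloneScenarios <- function(nPatients) {
  truncal <- data.frame(clone_id = "truncal", ccf = 1,
                        n_private_mutations = 100L,
                        present_in_tumor = TRUE, present_in_culture = TRUE,
                        stringsAsFactors = FALSE)
  lapply(seq_len(nPatients), function(i) {
    if (i == 4L) {
      expanded <- data.frame(clone_id = "culture_expanded", ccf = 0.35,
                             n_private_mutations = 60L,
                             present_in_tumor = FALSE,
                             present_in_culture = TRUE,
                             stringsAsFactors = FALSE)
      return(rbind(truncal, expanded))
    }
    sub <- data.frame(clone_id = "subclone1", ccf = 0.4,
                      n_private_mutations = 60L,
                      present_in_tumor = TRUE,
                      present_in_culture = i %% 3L != 2L,
                      stringsAsFactors = FALSE)
    rbind(truncal, sub)
  })
}

# Random unique sites: chromosome, 1-based position, ref/alt bases.
.randomSites <- function(n) {
  chrom <- as.character(sample.int(22L, n, replace = TRUE))
  pos <- integer(n)
  for (cc in unique(chrom)) {
    idx <- which(chrom == cc)
    pos[idx] <- sample.int(1e8L, length(idx))
  }
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1L), character(1))
  data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
             stringsAsFactors = FALSE)
}

# Draw observed counts for one sample column given true VAFs.
# Returns raw depth plus quality-filtered per-strand allele counts.
.sampleCounts <- function(trueVaf, cfg) {
  n <- length(trueVaf)
  depth <- switch(cfg@depthModel,
                  poisson = rpois(n, cfg@meanDepth),
                  fixed   = rep.int(as.integer(round(cfg@meanDepth)), n))
  altReads <- rbinom(n, depth, trueVaf)
  refReads <- depth - altReads
  qAlt <- rbinom(n, altReads, 1 - cfg@lowQualityReadRate)
  qRef <- rbinom(n, refReads, 1 - cfg@lowQualityReadRate)
  qAltFwd <- rbinom(n, qAlt, cfg@strandBias)
  qRefFwd <- rbinom(n, qRef, cfg@strandBias)
  data.frame(rawDepth = depth,
             qRefFwd = qRefFwd, qRefRev = qRef - qRefFwd,
             qAltFwd = qAltFwd, qAltRev = qAlt - qAltFwd)
}

.vcfHeaderLines <- function(sampleNames) {
  c("##fileformat=VCFv4.2",
    "##source=triohet simulator",
    sprintf("##contig=<ID=%d,length=200000000>", 1:22),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Raw read depth\">",
    paste0("##FORMAT=<ID=DP4,Number=4,Type=Integer,Description=",
           "\"Base-quality-filtered (Q>30) ref-forward, ref-reverse, ",
           "alt-forward, alt-reverse read counts\">"),
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", sampleNames), collapse = "\t"))
}

.formatSample <- function(cnt, trueVaf) {
  gt <- ifelse(trueVaf > 0, "0/1", "0/0")
  sprintf("%s:%d:%d,%d,%d,%d", gt, cnt$rawDepth,
          cnt$qRefFwd, cnt$qRefRev, cnt$qAltFwd, cnt$qAltRev)
}

#' Simulate a Normal/Tumor/Culture trio cohort
#'
#' For each patient, emits germline heterozygous SNVs (true VAF 0.5 in all
#' three conditions) and per-clone somatic SNVs whose true VAFs follow
#' \code{\link{expectedVaf}} under the configured tumor purity and culture
#' normal-cell contamination; clones absent from a sample
#' (\code{present_in_tumor}/\code{present_in_culture = FALSE}) have true
#' VAF 0 there.  Per site and sample, depth is drawn from the configured
#' depth model, alt reads as Binomial(depth, true VAF), low-quality reads
#' are thinned out of the quality-filtered counts, and quality-passing
#' reads are split across strands as Binomial(count, strandBias).  Output
#' is one VCF per patient (sample columns N, T, CR; FORMAT \code{DP} raw
#' depth and \code{DP4} quality-filtered ref-fwd, ref-rev, alt-fwd,
#' alt-rev counts) plus a tab-separated ground-truth sidecar.  Fully
#' deterministic given the config seed.
#'
#' @param config a \linkS4class{TrioSimConfig}.
#' @param dir output directory (created if needed).
#' @return invisibly, a list with \code{vcf} (named character vector of
#'   per-patient VCF paths), \code{truth} (the truth data.frame, also
#'   written to \code{truth.tsv}) and \code{truthPath}.
#' @examples
#' cfg <- TrioSimConfig(nPatients = 1, germlineSnvCount = 50, seed = 7)
#' out <- simulateTrioCohort(cfg, tempfile("cohort"))
#' head(out$truth)
#' @export
simulateTrioCohort <- function(config, dir) {
  stopifnot(is(config, "TrioSimConfig"))
  validObject(config)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  set.seed(config@seed)

  cultureCancerFraction <- 1 - config@cultureNormalFraction
  truth <- list()
  vcfPaths <- character(config@nPatients)
  patients <- sprintf("P%02d", seq_len(config@nPatients))

  for (i in seq_len(config@nPatients)) {
    pid <- patients[i]
    clones <- config@clones[[i]]
    nSom <- sum(clones$n_private_mutations)
    nGerm <- config@germlineSnvCount
    siteDf <- .randomSites(nGerm + nSom)
    origin <- c(rep("germline", nGerm),
                rep(clones$clone_id, clones$n_private_mutations))
    cloneIdx <- match(origin, clones$clone_id)  # NA for germline
    safeIdx <- ifelse(is.na(cloneIdx), 1L, cloneIdx)

    vafN <- ifelse(is.na(cloneIdx), 0.5, 0)
    vafT <- ifelse(is.na(cloneIdx), 0.5,
                   ifelse(clones$present_in_tumor[safeIdx],
                          expectedVaf(clones$ccf[safeIdx],
                                      config@tumorPurity), 0))
    vafC <- ifelse(is.na(cloneIdx), 0.5,
                   ifelse(clones$present_in_culture[safeIdx],
                          expectedVaf(clones$ccf[safeIdx],
                                      cultureCancerFraction), 0))

    ord <- order(as.integer(siteDf$chrom), siteDf$pos)
    siteDf <- siteDf[ord, ]
    origin <- origin[ord]
    vafN <- vafN[ord]; vafT <- vafT[ord]; vafC <- vafC[ord]

    cntN <- .sampleCounts(vafN, config)
    cntT <- .sampleCounts(vafT, config)
    cntC <- .sampleCounts(vafC, config)

    body <- paste(siteDf$chrom, siteDf$pos, ".", siteDf$ref, siteDf$alt,
                  ".", "PASS", ".", "GT:DP:DP4",
                  .formatSample(cntN, vafN),
                  .formatSample(cntT, vafT),
                  .formatSample(cntC, vafC),
                  sep = "\t")
    path <- file.path(dir, paste0(pid, ".vcf"))
    writeLines(c(.vcfHeaderLines(unname(DEFAULT_SAMPLE_MAP)), body), path)
    vcfPaths[i] <- path

    truth[[i]] <- data.frame(
      patient = pid,
      chrom = siteDf$chrom, pos = siteDf$pos,
      ref = siteDf$ref, alt = siteDf$alt,
      key = makeSiteKeys(siteDf$chrom, siteDf$pos, siteDf$ref, siteDf$alt),
      origin = origin,
      vaf_normal = vafN, vaf_tumor = vafT, vaf_culture = vafC,
      stringsAsFactors = FALSE)
  }

  truth <- do.call(rbind, truth)
  truthPath <- file.path(dir, "truth.tsv")
  writeTruth(truth, truthPath)
  names(vcfPaths) <- patients
  invisible(list(vcf = vcfPaths, truth = truth, truthPath = truthPath))
}

#' Read and write the simulator's ground-truth sidecar
#'
#' Tab-separated, one row per emitted mutation: patient, site coordinates
#' and alleles, site key, origin (\code{"germline"} or a clone id) and true
#' VAF per condition.  \code{readTruth(writeTruth(x))} round-trips
#' losslessly.
#'
#' @param truth a truth data.frame as returned by
#'   \code{\link{simulateTrioCohort}}.
#' @param path file path.
#' @return \code{writeTruth}: the path, invisibly. \code{readTruth}: the
#'   truth data.frame.
#' @export
writeTruth <- function(truth, path) {
  write.table(truth, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeTruth
#' @export
readTruth <- function(path) {
  read.delim(path, colClasses = c(
    patient = "character", chrom = "character", pos = "integer",
    ref = "character", alt = "character", key = "character",
    origin = "character", vaf_normal = "numeric", vaf_tumor = "numeric",
    vaf_culture = "numeric"))
}
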