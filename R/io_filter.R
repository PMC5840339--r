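#' Read a trio VCF into a TrioCallset
#'
#' Loads one patient's VCF and builds the per-site count table the filters
#' operate on.  Only biallelic SNV records are retained; indels, MNVs and
#' multi-allelic records are skipped with a counted warning (the count is
#' available in \code{\link{filterLog}} as \code{skipped_non_snv}).  The
#' three conditions are mapped to VCF sample columns through
#' \code{sampleMap}; each mapped column must exist.  Per condition the raw
#' depth is taken from the \code{DP} FORMAT field and the
#' base-quality-filtered per-strand allele counts from the four-integer
#' \code{DP4} field (ref-forward, ref-reverse, alt-forward, alt-reverse),
#' the dialect written by \code{\link{simulateTrioCohort}} and by
#' bcftools-style callers.  Upstream mapping-quality filtering (MAPQ,
#' unique mapping, duplicate removal) is an input contract of the VCF
#' producer, not re-applied here.
#'
#' @param path path to the VCF (plain or bgzipped).
#' @param patientID patient identifier; defaults to the file base name.
#' @param sampleMap named character vector mapping conditions
#'   \code{Normal}, \code{Tumor}, \code{Culture} to sample column names
#'   (default \code{c(Normal = "N", Tumor = "T", Culture = "CR")}).
#' @param depthField,strandField FORMAT field names for raw depth and the
#'   per-strand quality-filtered allele counts.
#' @return a \linkS4class{TrioCallset} (SNV sets not yet computed).
#' @seealso \code{\link{callSnvSets}}
#' @export
readTrioVcf <- function(path,
                        patientID = sub("\\.vcf(\\.gz|\\.bgz)?$", "",
                                        basename(path)),
                        sampleMap = DEFAULT_SAMPLE_MAP,
                        depthField = "DP", strandField = "DP4") {
  if (!file.exists(path)) stop("VCF not found: ", path)
  if (!all(TRIO_CONDITIONS %in% names(sampleMap)))
    stop("sampleMap must name all of ",
         paste(TRIO_CONDITIONS, collapse = ", "))
  vcf <- suppressWarnings(readVcf(path, genome = "simulated"))
  missingCols <- setdiff(unname(sampleMap[TRIO_CONDITIONS]), colnames(vcf))
  if (length(missingCols))
    stop("sample column(s) missing from ", basename(path), ": ",
         paste(missingCols, collapse = ", "))

  keep <- isSNV(vcf, singleAltOnly = TRUE)
  nSkipped <- sum(!keep)
  if (nSkipped > 0)
    warning(nSkipped, " non-SNV/multi-allelic record(s) skipped in ",
            basename(path))
  vcf <- vcf[keep]

  gr <- rowRanges(vcf)
  n <- length(gr)
  out <- GRanges(seqnames(gr), IRanges(start(gr), width = 1L))
  refB <- as.character(ref(vcf))
  altB <- if (n) as.character(unlist(alt(vcf))) else character()
  mcols(out)$ref <- refB
  mcols(out)$alt <- altB
  names(out) <- makeSiteKeys(as.character(seqnames(out)), start(out),
                             refB, altB)

  gen <- geno(vcf)
  if (!depthField %in% names(gen))
    stop("FORMAT field '", depthField, "' absent from ", basename(path))
  if (!strandField %in% names(gen))
    stop("FORMAT field '", strandField, "' absent from ", basename(path))
  dp <- gen[[depthField]]
  dp4 <- gen[[strandField]]
  for (cond in TRIO_CONDITIONS) {
    col <- sampleMap[[cond]]
    mcols(out)[[paste0("rawDepth_", cond)]] <-
      as.integer(if (n) dp[, col] else integer())
    for (j in seq_len(4L)) {
      nm <- c("qRefFwd", "qRefRev", "qAltFwd", "qAltRev")[j]
      mcols(out)[[paste0(nm, "_", cond)]] <-
        as.integer(if (n) dp4[, col, j] else integer())
    }
  }
  new("TrioCallset", patientID = patientID, sites = out,
      snvSets = list(), filterLog = list(skipped_non_snv = nSkipped))
}

#' SNV acceptance rules
#'
#' \code{passesSupport} implements the variant-support rule: a site is
#' supported in a condition when it has at least \code{minAltReads}
#' (default 3) variant-supporting reads of base quality Q > 30 and the
#' variant is seen on both genome strands (at least \code{minPerStrand},
#' default 1, quality-passing alt read on each strand).
#' \code{passesTrioCoverage} implements the trio-wide coverage rule: at
#' least \code{minDepth} (default 3) reads must cover the position in all
#' three conditions.  By default coverage counts any read (raw depth);
#' set \code{useQualityDepth = TRUE} to count only quality-passing reads.
#'
#' @param x a \linkS4class{TrioCallset}.
#' @param condition condition to evaluate support in.
#' @param minAltReads minimum quality-passing variant-supporting reads.
#' @param minPerStrand minimum quality-passing alt reads per strand.
#' @param minDepth minimum covering reads per condition.
#' @param useQualityDepth count quality-filtered instead of raw reads for
#'   coverage.
#' @return logical vector, one element per site of \code{x}.
#' @export
passesSupport <- function(x, condition, minAltReads = 3L,
                          minPerStrand = 1L) {
  stopifnot(is(x, "TrioCallset"))
  .checkCondition(condition)
  fwd <- mcols(x@sites)[[paste0("qAltFwd_", condition)]]
  rev <- mcols(x@sites)[[paste0("qAltRev_", condition)]]
  (fwd + rev >= minAltReads) & (fwd >= minPerStrand) & (rev >= minPerStrand)
}

#' @rdname passesSupport
#' @export
passesTrioCoverage <- function(x, minDepth = 3L, useQualityDepth = FALSE) {
  stopifnot(is(x, "TrioCallset"))
  ok <- rep(TRUE, length(x@sites))
  for (cond in TRIO_CONDITIONS) {
    depth <- if (useQualityDepth) {
      mcols(x@sites)[[paste0("qRefFwd_", cond)]] +
        mcols(x@sites)[[paste0("qRefRev_", cond)]] +
        mcols(x@sites)[[paste0("qAltFwd_", cond)]] +
        mcols(x@sites)[[paste0("qAltRev_", cond)]]
    } else {
      mcols(x@sites)[[paste0("rawDepth_", cond)]]
    }
    ok <- ok & (depth >= minDepth)
  }
  ok
}

#' Derive per-condition SNV sets from a trio callset
#'
#' Applies the acceptance rules: a site key enters a condition's SNV set
#' when it passes the trio-wide coverage rule
#' (\code{\link{passesTrioCoverage}}) and the support rule
#' (\code{\link{passesSupport}}) in that condition.  All three sets are
#' computed on the same site universe, so set comparisons between
#' conditions are well defined.
#'
#' @inheritParams passesSupport
#' @inheritParams passesTrioCoverage
#' @return the callset with its \code{snvSets} slot filled and per-rule
#'   rejection counts appended to \code{\link{filterLog}}.
#' @examples
#' cfg <- TrioSimConfig(nPatients = 1, germlineSnvCount = 30, seed = 11)
#' sim <- simulateTrioCohort(cfg, tempfile())
#' cs <- callSnvSets(readTrioVcf(sim$vcf[[1]]))
#' lengths(cs@snvSets)
#' @export
callSnvSets <- function(x, minAltReads = 3L, minPerStrand = 1L,
                        minDepth = 3L, useQualityDepth = FALSE) {
  stopifnot(is(x, "TrioCallset"))
  keys <- siteKeys(x)
  covOk <- passesTrioCoverage(x, minDepth, useQualityDepth)
  sets <- list()
  log <- x@filterLog
  log$n_sites <- length(keys)
  log$fail_trio_coverage <- sum(!covOk)
  for (cond in TRIO_CONDITIONS) {
    supOk <- passesSupport(x, cond, minAltReads, minPerStrand)
    sets[[cond]] <- keys[covOk & supOk]
    log[[paste0("fail_support_", cond)]] <- sum(covOk & !supOk)
  }
  x@snvSets <- sets
  x@filterLog <- log
  x
}

#' Write per-condition SNV sets to a TSV
#'
#' One row per site key present in at least one condition's accepted set,
#' sorted by key, with 0/1 membership columns for Normal, Tumor, Culture.
#'
#' @param x a \linkS4class{TrioCallset} with computed SNV sets.
#' @param path output file.
#' @return the path, invisibly.
#' @export
writeSnvSets <- function(x, path) {
  stopifnot(is(x, "TrioCallset"))
  if (!length(x@snvSets))
    stop("SNV sets not computed yet; run callSnvSets() first")
  keys <- sort(unique(unlist(x@snvSets, use.names = FALSE)))
  df <- data.frame(site_key = keys, stringsAsFactors = FALSE)
  for (cond in TRIO_CONDITIONS)
    df[[cond]] <- as.integer(keys %in% x@snvSets[[cond]])
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and filter a whole cohort
#'
#' Convenience wrapper: reads each patient's VCF and derives its SNV sets
#' with shared filter thresholds.
#'
#' @param vcfPaths named character vector of VCF paths (names = patient
#'   IDs; unnamed paths fall back to file base names).
#' @inheritParams callSnvSets
#' @param sampleMap condition-to-column mapping passed to
#'   \code{\link{readTrioVcf}}.
#' @return named list of \linkS4class{TrioCallset} objects.
#' @export
readTrioCohort <- function(vcfPaths, sampleMap = DEFAULT_SAMPLE_MAP,
                           minAltReads = 3L, minPerStrand = 1L,
                           minDepth = 3L, useQualityDepth = FALSE) {
  ids <- names(vcfPaths)
  if (is.null(ids))
    ids <- sub("\\.vcf(\\.gz|\\.bgz)?$", "", basename(vcfPaths))
  cohort <- lapply(seq_along(vcfPaths), function(i)
    callSnvSets(readTrioVcf(vcfPaths[[i]], patientID = ids[i],
                            sampleMap = sampleMap),
                minAltReads = minAltReads, minPerStrand = minPerStrand,
                minDepth = minDepth, useQualityDepth = useQualityDepth))
  names(cohort) <- ids
  cohort
}
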