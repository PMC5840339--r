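# Fixture builders used across the suite.  All fixtures are built in code.

.CONDS <- c("Normal", "Tumor", "Culture")

# Build a TrioCallset from a data.frame with chrom/pos/ref/alt and any of
# the per-condition count columns (rawDepth_Tumor, qAltFwd_Culture, ...).
# Unspecified counts default to rawDepth 30, qRef 10+10, qAlt 0+0.
testCallset <- function(tab, patient = "PT") {
  gr <- GenomicRanges::GRanges(as.character(tab$chrom),
                               IRanges::IRanges(tab$pos, width = 1L))
  S4Vectors::mcols(gr)$ref <- tab$ref
  S4Vectors::mcols(gr)$alt <- tab$alt
  names(gr) <- makeSiteKeys(tab$chrom, tab$pos, tab$ref, tab$alt)
  for (cond in .CONDS) {
    for (col in c("rawDepth", "qRefFwd", "qRefRev", "qAltFwd", "qAltRev")) {
      nm <- paste0(col, "_", cond)
      v <- if (nm %in% names(tab)) tab[[nm]]
      else if (col == "rawDepth") rep(30L, nrow(tab))
      else if (col %in% c("qRefFwd", "qRefRev")) rep(10L, nrow(tab))
      else rep(0L, nrow(tab))
      S4Vectors::mcols(gr)[[nm]] <- as.integer(v)
    }
  }
  methods::new("TrioCallset", patientID = patient, sites = gr,
               snvSets = list(), filterLog = list())
}

# A TrioCallset carrying only SNV key sets (for set-level operations).
setOnlyCallset <- function(patient, normal = character(),
                           tumor = character(), culture = character()) {
  methods::new("TrioCallset", patientID = patient,
               sites = GenomicRanges::GRanges(),
               snvSets = list(Normal = normal, Tumor = tumor,
                              Culture = culture),
               filterLog = list())
}

# Random site keys from a shared small universe.
keyUniverse <- function(n = 40) sprintf("1:%d_A/G", seq_len(n) * 10L)

# Write a minimal trio VCF (sample columns N, T, CR) from raw body lines.
writeTestVcf <- function(bodyLines, path) {
  header <- c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%d,length=200000000>", 1:22),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Raw depth\">",
    paste0("##FORMAT=<ID=DP4,Number=4,Type=Integer,Description=",
           "\"refF,refR,altF,altR\">"),
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
            "INFO", "FORMAT", "N", "T", "CR"), collapse = "\t"))
  writeLines(c(header, bodyLines), path)
  path
}

# One VCF body line with identical per-condition counts unless overridden.
vcfLine <- function(chrom, pos, ref, alt,
                    n = "0/1:30:10,10,5,5", t = n, cr = n) {
  paste(chrom, pos, ".", ref, alt, ".", "PASS", ".", "GT:DP:DP4",
        n, t, cr, sep = "\t")
}
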