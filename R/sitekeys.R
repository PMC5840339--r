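#' Site keys
#'
#' An SNV is identified throughout the package by the key
#' \code{"chrom:pos_ref/alt"} (1-based position).  \code{makeSiteKeys}
#' builds keys from components; \code{parseSiteKeys} inverts them.
#'
#' @param chrom,pos,ref,alt vectors of chromosome names, 1-based positions
#'   and single-base alleles.
#' @return \code{makeSiteKeys}: character vector of keys.
#'   \code{parseSiteKeys}: data.frame with columns \code{chrom},
#'   \code{pos}, \code{ref}, \code{alt}.
#' @examples
#' makeSiteKeys("1", 100, "A", "G")
#' parseSiteKeys("1:100_A/G")
#' @export
makeSiteKeys <- function(chrom, pos, ref, alt) {
  if (!length(chrom)) return(character())
  paste0(chrom, ":", pos, "_", ref, "/", alt)
}

#' @rdname makeSiteKeys
#' @param keys character vector of site keys.
#' @export
parseSiteKeys <- function(keys) {
  m <- regmatches(keys,
                  regexec("^(.+):([0-9]+)_([ACGTacgt]+)/([ACGTacgt]+)$", keys))
  bad <- vapply(m, length, integer(1)) != 5L
  if (any(bad))
    stop("malformed site key(s): ", paste(utils::head(keys[bad], 3),
                                          collapse = ", "))
  data.frame(
    chrom = vapply(m, `[`, character(1), 2L),
    pos   = as.integer(vapply(m, `[`, character(1), 3L)),
    ref   = vapply(m, `[`, character(1), 4L),
    alt   = vapply(m, `[`, character(1), 5L),
    stringsAsFactors = FALSE)
}
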