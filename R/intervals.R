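#' Mismatch-repair gene intervals (hg19)
#'
#' The hg19/GRCh37 genomic intervals of the four core mismatch-repair genes
#' (MLH1, MSH2, MSH6, PMS2), shipped as a plain-text fixture.  These are
#' the calling regions the ancient-genome arm uses when run against real
#' hg19-aligned data; synthetic runs use the simulated reference instead.
#'
#' @return data.frame with columns `gene`, `chrom`, `start`, `end`
#'   (1-based inclusive).
#' @export
#' @examples
#' mmr_gene_intervals()
mmr_gene_intervals <- function() {
  path <- system.file("extdata", "mmr_gene_intervals_hg19.tsv",
                      package = "paleovar", mustWork = TRUE)
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
}
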