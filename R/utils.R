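# Small sequence / numeric helpers shared across modules.

#' Reverse-complement DNA strings
#'
#' Case-preserving reverse complement of one or more DNA strings.
#'
#' @param x character vector of DNA sequences (A/C/G/T, case preserved;
#'   `-` and `N` pass through unchanged).
#' @return character vector of the same length.
#' @export
#' @examples
#' revcomp("ACGTac")  # "gtACGT"
revcomp <- function(x) {
  comp <- chartr("ACGTacgtNn", "TGCAtgcaNn", x)
  vapply(strsplit(comp, NULL), function(ch) paste(rev(ch), collapse = ""),
         character(1), USE.NAMES = FALSE)
}

#' Round half away from zero
#'
#' Rounds to `digits` decimals with exact halves moving away from zero
#' (0.25 -> 0.3 at one decimal), the convention used for all reported
#' percentages.  Base `round()` rounds half to even and would disagree with
#' printed proportions.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return numeric vector.
#' @export
round_half_up <- function(x, digits = 1) {
  scale <- 10^digits
  # add a tiny relative nudge so values intended as exact halves but stored
  # just below .5 in binary still round up
  sign(x) * floor(abs(x) * scale + 0.5 + 1e-9) / scale
}

# Phred helpers ---------------------------------------------------------

phred_to_errprob <- function(q) 10^(-q / 10)

errprob_to_phred <- function(p) {
  q <- -10 * log10(p)
  as.integer(round_half_up(q, 0))
}

qual_string_to_phred <- function(qual) {
  lapply(qual, function(s) as.integer(charToRaw(s)) - 33L)
}

phred_to_qual_string <- function(q) {
  vapply(q, function(v) rawToChar(as.raw(v + 33L)), character(1))
}

# FASTA ----------------------------------------------------------------

#' Read a single-sequence FASTA file
#'
#' @param path FASTA file.
#' @return named character vector of sequences (one element per record).
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  out <- as.character(ss)
  names(out) <- sub("\\s.*$", "", names(ss))
  out
}

#' Write sequences to FASTA
#'
#' @param seqs named character vector of DNA sequences.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  ss <- Biostrings::DNAStringSet(seqs)
  names(ss) <- names(seqs)
  Biostrings::writeXStringSet(ss, filepath = path, width = 70L)
  invisible(path)
}

# internal: substring of a reference (1-based inclusive), with bounds check
ref_slice <- function(reference, from, to) {
  reference <- unname(as.character(reference)[1])
  if (from < 1 || to > nchar(reference))
    stop("position ", from, "-", to, " outside reference (length ",
         nchar(reference), ")")
  substr(reference, from, to)
}

# internal: translate a DNA string via the standard genetic code
translate_dna <- function(seq) {
  seq <- toupper(seq)
  n <- nchar(seq) %/% 3
  if (n == 0) return("")
  codons <- substring(seq, 3 * seq_len(n) - 2, 3 * seq_len(n))
  aa <- Biostrings::GENETIC_CODE[codons]
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

# internal: deterministic per-purpose RNG scope.  Each simulator entry point
# derives its own stream from the config seed so outputs are byte-identical
# for identical configs while remaining independent across stages.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  set.seed(seed)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  expr
}
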