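# Shared fixtures, built in code.

# two-exon plus-strand toy transcript: exon1 g.101-200, exon2 g.301-400,
# CDS g.151..350 in transcript coordinates (c.1 = g.151, intron of 100 bp)
toy_plus <- function() {
  transcript_model("TOYP", "chr1", "+",
                   data.frame(start = c(101, 301), end = c(200, 400)),
                   cds_start = 151, cds_end = 350)
}

# minus-strand single-exon toy: c.1 = g.190, CDS runs g.190 down to g.110
toy_minus <- function() {
  transcript_model("TOYM", "chr1", "-",
                   data.frame(start = 101, end = 200),
                   cds_start = 190, cds_end = 110)
}

# two-exon minus-strand toy with an intron (exons g.101-200 and g.301-400;
# transcript starts in the genomic-right exon)
toy_minus_intron <- function() {
  transcript_model("TOYMI", "chr1", "-",
                   data.frame(start = c(101, 301), end = c(200, 400)),
                   cds_start = 390, cds_end = 111)
}

# deterministic 1 kb reference
toy_reference <- function(len = 1000, seed = 99) {
  with_seed <- getFromNamespace("with_seed", "paleovar")
  with_seed(seed, paste(sample(c("A", "C", "G", "T"), len, TRUE), collapse = ""))
}

# build one MAF block from named gapped texts (first species is the human
# reference row, forward strand); starts are ungapped offsets (0-based)
make_block <- function(texts, score = 100, starts = NULL, strands = NULL,
                       src_sizes = NULL) {
  sp <- names(texts)
  n <- length(sp)
  sizes <- nchar(gsub("-", "", unlist(texts)))
  if (is.null(starts)) starts <- rep(0L, n)
  if (is.null(strands)) strands <- rep("+", n)
  if (is.null(src_sizes)) src_sizes <- sizes + starts
  list(score = score,
       rows = data.frame(src = paste0(sp, ".chr1"),
                         start = as.integer(starts), size = as.integer(sizes),
                         strand = strands, src_size = as.integer(src_sizes),
                         text = unlist(texts, use.names = FALSE),
                         stringsAsFactors = FALSE))
}

# aligned-read row(s) in the read_sam() layout
make_read <- function(qname, pos, seq, qual = NULL, strand = "+",
                      duplicate = FALSE, chrom = "chr1") {
  if (is.null(qual)) qual <- strrep("F", nchar(seq))  # Phred 37
  data.frame(qname = qname,
             flag = (strand == "-") * 16L + duplicate * 1024L,
             chrom = chrom, pos = as.integer(pos), mapq = 60L,
             seq = seq, qual = qual, strand = strand,
             duplicate = duplicate, unmapped = FALSE,
             stringsAsFactors = FALSE)
}

# one-row catalog-style variant record
make_variant <- function(chrom = "chr1", pos, ref, alt) {
  list(chrom = chrom, pos = as.integer(pos), ref = ref, alt = alt)
}

# minimal valid catalog table row
catalog_row <- function(gene = "MLH1", chrom = "chr1", pos = 100, ref = "C",
                        alt = "T", hgvs = "c.1C>T",
                        sig = "Pathogenic", type = "missense") {
  data.frame(gene = gene, chrom = chrom, pos_1based = pos, ref = ref,
             alt = alt, hgvs_c = hgvs, clinical_significance = sig,
             variant_type = type, stringsAsFactors = FALSE)
}
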