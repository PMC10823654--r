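# Transcript models and HGVS cDNA <-> genomic coordinate conversion.
#
# Conventions: genomic positions are 1-based (VCF style); c.1 is the first
# base of the translation start; intronic offsets (+M / -M) count from the
# nearest exon boundary in transcript direction, switching sides at the
# intron midpoint.  On minus-strand transcripts alleles are given in
# transcript orientation in c. names and reverse-complemented to the genome
# forward strand.  Indels are emitted VCF-style, left-anchored on the base
# preceding the event.

#' Construct a transcript model
#'
#' @param gene gene symbol.
#' @param chrom chromosome name.
#' @param strand `"+"` or `"-"`.
#' @param exons data.frame with columns `start`, `end` (1-based closed
#'   genomic intervals, non-overlapping).
#' @param cds_start genomic position of the first base of the CDS (c.1);
#'   on minus-strand transcripts this is the numerically larger end.
#' @param cds_end genomic position of the last CDS base.
#' @return object of class `transcript_model`.
#' @export
#' @examples
#' tm <- transcript_model("TOY", "chr1", "+",
#'                        data.frame(start = 101, end = 200),
#'                        cds_start = 151, cds_end = 198)
#' cds_length(tm)  # 48
transcript_model <- function(gene, chrom, strand, exons, cds_start, cds_end) {
  stopifnot(strand %in% c("+", "-"),
            all(c("start", "end") %in% names(exons)),
            all(exons$start <= exons$end))
  exons <- exons[order(exons$start), c("start", "end")]
  if (nrow(exons) > 1 && any(exons$start[-1] <= exons$end[-nrow(exons)]))
    stop("exons overlap")

  # genomic positions in transcript (5'->3') order
  pos_list <- lapply(seq_len(nrow(exons)),
                     function(i) exons$start[i]:exons$end[i])
  tx <- unlist(pos_list)
  if (strand == "-") tx <- rev(tx)
  i0 <- match(cds_start, tx)
  i1 <- match(cds_end, tx)
  if (is.na(i0) || is.na(i1) || i1 < i0)
    stop("CDS bounds must lie inside exons, start before end in transcript order")

  obj <- list(gene = gene, chrom = chrom, strand = strand, exons = exons,
              cds_start = cds_start, cds_end = cds_end,
              cds_gpos = tx[i0:i1])   # genomic position of c.k at index k
  class(obj) <- "transcript_model"
  obj
}

#' @export
print.transcript_model <- function(x, ...) {
  cat("transcript_model", x$gene, paste0("(", x$chrom, x$strand, ")"),
      nrow(x$exons), "exons, CDS length", cds_length(x), "\n")
  invisible(x)
}

#' CDS length of a transcript model
#' @param model a `transcript_model`.
#' @return integer number of coding bases.
#' @export
cds_length <- function(model) length(model$cds_gpos)

# internal: is a genomic position exonic for this model?
is_exonic <- function(model, gpos) {
  any(model$exons$start <= gpos & gpos <= model$exons$end)
}

# internal: intron (genomic gap between adjacent exons) containing gpos,
# returned in *transcript* orientation: donor = exon base flanking the
# intron on the 5' (transcript) side, acceptor on the 3' side.
intron_context <- function(model, gpos) {
  ex <- model$exons
  for (i in seq_len(nrow(ex) - 1)) {
    lo <- ex$end[i] + 1; hi <- ex$start[i + 1] - 1
    if (gpos >= lo && gpos <= hi) {
      if (model$strand == "+") {
        return(list(donor_g = ex$end[i], acceptor_g = ex$start[i + 1],
                    d_from_donor = gpos - ex$end[i], len = hi - lo + 1))
      } else {
        return(list(donor_g = ex$start[i + 1], acceptor_g = ex$end[i],
                    d_from_donor = ex$start[i + 1] - gpos, len = hi - lo + 1))
      }
    }
  }
  NULL
}

# internal: (cds position, intron offset) for a genomic position
g_to_c <- function(model, gpos) {
  k <- match(gpos, model$cds_gpos)
  if (!is.na(k)) return(list(cds = k, offset = 0L))
  ic <- intron_context(model, gpos)
  if (is.null(ic)) stop("position ", gpos,
                        " is neither CDS-exonic nor intronic for ", model$gene)
  d <- ic$d_from_donor
  if (d <= ic$len %/% 2 || (ic$len %% 2 == 1 && d == ic$len %/% 2 + 1)) {
    anchor <- match(ic$donor_g, model$cds_gpos)
    if (is.na(anchor)) stop("intron flanks non-CDS exon sequence (unsupported)")
    list(cds = anchor, offset = d)
  } else {
    anchor <- match(ic$acceptor_g, model$cds_gpos)
    if (is.na(anchor)) stop("intron flanks non-CDS exon sequence (unsupported)")
    list(cds = anchor, offset = -(ic$len - d + 1L))
  }
}

# internal: genomic position for (cds position, offset)
c_to_g <- function(model, cds, offset = 0L) {
  L <- cds_length(model)
  if (cds < 1 || cds > L)
    stop("c.", cds, " beyond CDS length ", L, " of ", model$gene)
  g <- model$cds_gpos[cds]
  if (offset == 0L) return(g)
  dir <- if (model$strand == "+") 1L else -1L
  gout <- g + dir * offset
  if (is_exonic(model, gout))
    stop("offset ", offset, " from c.", cds, " does not land in an intron")
  gout
}

# internal: transcript-oriented base -> genome forward strand (and back)
tx_allele_to_fwd <- function(model, allele) {
  if (model$strand == "+") toupper(allele) else revcomp(toupper(allele))
}

# HGVS grammar subset ----------------------------------------------------

#' Parse an HGVS c. name (grammar subset)
#'
#' Supports substitutions (`c.76A>C`, `c.208-3C>T`), deletions with explicit
#' spans (`c.10_12del`, `c.10del`, optionally with stated bases), insertions
#' (`c.10_11insACT`) and duplications (`c.10_12dup`).
#'
#' @param hgvs_c the c. name.
#' @return list with `kind` plus positions/offsets/alleles.
#' @export
parse_hgvs_c <- function(hgvs_c) {
  x <- sub("^c\\.", "", hgvs_c)
  pp <- "(\\d+)([+-]\\d+)?"
  m <- regmatches(x, regexec(paste0("^", pp, "([ACGT])>([ACGT])$"), x))[[1]]
  if (length(m)) {
    return(list(kind = "sub", a = as.integer(m[2]),
                a_off = if (m[3] == "") 0L else as.integer(m[3]),
                ref = m[4], alt = m[5]))
  }
  m <- regmatches(x, regexec(paste0("^", pp, "(?:_", pp, ")?del([ACGT]*)$"), x))[[1]]
  if (length(m)) {
    return(list(kind = "del", a = as.integer(m[2]),
                a_off = if (m[3] == "") 0L else as.integer(m[3]),
                b = if (m[4] == "") as.integer(m[2]) else as.integer(m[4]),
                b_off = if (m[5] == "") 0L else as.integer(m[5]),
                seq = m[6]))
  }
  m <- regmatches(x, regexec(paste0("^", pp, "_", pp, "ins([ACGT]+)$"), x))[[1]]
  if (length(m)) {
    return(list(kind = "ins", a = as.integer(m[2]),
                a_off = if (m[3] == "") 0L else as.integer(m[3]),
                b = as.integer(m[4]),
                b_off = if (m[5] == "") 0L else as.integer(m[5]),
                seq = m[6]))
  }
  m <- regmatches(x, regexec(paste0("^", pp, "(?:_", pp, ")?dup$"), x))[[1]]
  if (length(m)) {
    return(list(kind = "dup", a = as.integer(m[2]),
                a_off = if (m[3] == "") 0L else as.integer(m[3]),
                b = if (m[4] == "") as.integer(m[2]) else as.integer(m[4]),
                b_off = if (m[5] == "") 0L else as.integer(m[5])))
  }
  stop("unsupported HGVS c. name: ", hgvs_c)
}

#' Convert an HGVS c. name to genomic coordinates
#'
#' Returns the variant on the genome forward strand, VCF-style (1-based,
#' indels anchored on the preceding base).
#'
#' @param model a [transcript_model()].
#' @param hgvs_c the c. name.
#' @param reference reference chromosome sequence (required for indels, and
#'   for checking stated reference alleles when `check_ref = TRUE`).
#' @param check_ref verify stated reference alleles against `reference`.
#' @return list with `chrom`, `pos`, `ref`, `alt`.
#' @export
#' @examples
#' tm <- transcript_model("TOY", "chr1", "+",
#'                        data.frame(start = 101, end = 200),
#'                        cds_start = 151, cds_end = 198)
#' cds_to_genomic(tm, "c.1A>G")  # pos 151, A>G
cds_to_genomic <- function(model, hgvs_c, reference = NULL, check_ref = !is.null(reference)) {
  v <- parse_hgvs_c(hgvs_c)
  chrom <- model$chrom

  if (v$kind == "sub") {
    g <- c_to_g(model, v$a, v$a_off)
    ref <- tx_allele_to_fwd(model, v$ref)
    alt <- tx_allele_to_fwd(model, v$alt)
    if (check_ref && ref_slice(reference, g, g) != ref)
      stop("reference mismatch at ", chrom, ":", g, " for ", hgvs_c)
    return(list(chrom = chrom, pos = g, ref = ref, alt = alt))
  }

  if (is.null(reference)) stop("indel conversion needs the reference sequence")

  if (v$kind == "del") {
    ga <- c_to_g(model, v$a, v$a_off); gb <- c_to_g(model, v$b, v$b_off)
    lo <- min(ga, gb); hi <- max(ga, gb)
    if (check_ref && nzchar(v$seq)) {
      stated <- tx_allele_to_fwd(model, v$seq)
      if (toupper(ref_slice(reference, lo, hi)) != stated)
        stop("stated deleted bases do not match reference for ", hgvs_c)
    }
    anchor <- lo - 1L
    if (anchor < 1) stop("deletion at reference start unsupported")
    return(list(chrom = chrom, pos = anchor,
                ref = toupper(ref_slice(reference, anchor, hi)),
                alt = toupper(ref_slice(reference, anchor, anchor))))
  }

  if (v$kind == "ins") {
    ga <- c_to_g(model, v$a, v$a_off); gb <- c_to_g(model, v$b, v$b_off)
    if (abs(ga - gb) != 1L) stop("insertion flanks must be adjacent: ", hgvs_c)
    anchor <- min(ga, gb)
    ins_fwd <- tx_allele_to_fwd(model, v$seq)
    base <- toupper(ref_slice(reference, anchor, anchor))
    return(list(chrom = chrom, pos = anchor, ref = base,
                alt = paste0(base, ins_fwd)))
  }

  if (v$kind == "dup") {
    ga <- c_to_g(model, v$a, v$a_off); gb <- c_to_g(model, v$b, v$b_off)
    lo <- min(ga, gb); hi <- max(ga, gb)
    dup_fwd <- toupper(ref_slice(reference, lo, hi))
    base <- toupper(ref_slice(reference, hi, hi))
    # duplication expressed as an insertion of the span after its last base
    return(list(chrom = chrom, pos = hi, ref = base,
                alt = paste0(base, dup_fwd)))
  }
  stop("unreachable")
}

#' Convert a genomic variant to an HGVS c. name
#'
#' Exact inverse of [cds_to_genomic()] for substitutions and simple
#' deletions/insertions whose footprint maps onto the transcript.
#'
#' @param model a [transcript_model()].
#' @param pos 1-based genomic position (VCF-style anchor for indels).
#' @param ref,alt forward-strand alleles.
#' @return the c. name as a string.
#' @export
genomic_to_cds <- function(model, pos, ref, alt) {
  ref <- toupper(ref); alt <- toupper(alt)
  fmt_off <- function(off) if (off == 0) "" else sprintf("%+d", off)

  if (nchar(ref) == 1 && nchar(alt) == 1) {
    cc <- g_to_c(model, pos)
    tref <- tx_allele_to_fwd(model, ref)  # complement back for minus strand
    talt <- tx_allele_to_fwd(model, alt)
    return(sprintf("c.%d%s%s>%s", cc$cds, fmt_off(cc$offset), tref, talt))
  }
  if (nchar(ref) > 1 && nchar(alt) == 1 && substr(ref, 1, 1) == alt) {
    span <- (pos + 1L):(pos + nchar(ref) - 1L)   # deleted genomic bases
    ends <- if (model$strand == "+") range(span) else rev(range(span))
    ca <- g_to_c(model, ends[1]); cb <- g_to_c(model, ends[2])
    lab <- function(cc) sprintf("%d%s", cc$cds, fmt_off(cc$offset))
    if (length(span) == 1) return(sprintf("c.%sdel", lab(ca)))
    return(sprintf("c.%s_%sdel", lab(ca), lab(cb)))
  }
  if (nchar(alt) > 1 && nchar(ref) == 1 && substr(alt, 1, 1) == ref) {
    ins_fwd <- substr(alt, 2, nchar(alt))
    flank <- c(pos, pos + 1L)
    ends <- if (model$strand == "+") flank else rev(flank)
    ca <- g_to_c(model, ends[1]); cb <- g_to_c(model, ends[2])
    ins_tx <- if (model$strand == "+") ins_fwd else revcomp(ins_fwd)
    return(sprintf("c.%d_%dins%s", ca$cds, cb$cds, ins_tx))
  }
  stop("unsupported allele pair for c. naming: ", ref, ">", alt)
}

# Effect annotation ------------------------------------------------------

#' Classify the molecular effect of a variant
#'
#' Minimal effect classifier over a single transcript model: codon
#' translation for CDS SNVs, the mod-3 rule for CDS indels, and a 2-bp
#' intron-side window for splice variants.  Positions in introns further
#' from a boundary are `intronic` (non-coding positions are lumped there).
#'
#' @param chrom,pos,ref,alt the variant, forward strand, VCF-style.
#' @param model a [transcript_model()].
#' @param reference reference chromosome sequence; the `ref` allele is
#'   checked against it and a mismatch is a hard error (it guards
#'   coordinate bugs).
#' @return one of `"synonymous"`, `"missense"`, `"stopgain"`, `"stoploss"`,
#'   `"splice"`, `"frameshift deletion"`, `"frameshift insertion"`,
#'   `"nonframeshift deletion"`, `"nonframeshift insertion"`, `"intronic"`.
#' @export
annotate_effect <- function(chrom, pos, ref, alt, model, reference) {
  ref <- toupper(ref); alt <- toupper(alt)
  if (!identical(chrom, model$chrom))
    stop("variant chromosome ", chrom, " does not match model ", model$chrom)
  seen <- toupper(ref_slice(reference, pos, pos + nchar(ref) - 1L))
  if (seen != ref)
    stop("reference mismatch at ", chrom, ":", pos, " (have ", seen,
         ", variant says ", ref, ")")

  splice_dist <- function(g) {
    ic <- intron_context(model, g)
    if (is.null(ic)) return(NA_integer_)
    min(ic$d_from_donor, ic$len - ic$d_from_donor + 1L)
  }

  if (nchar(ref) == 1 && nchar(alt) == 1) {       # SNV
    if (!is_exonic(model, pos)) {
      d <- splice_dist(pos)
      if (is.na(d)) return("intronic")            # outside the gene span
      return(if (d <= 2) "splice" else "intronic")
    }
    k <- match(pos, model$cds_gpos)
    if (is.na(k)) return("intronic")              # exonic but non-CDS (UTR)
    frame <- (k - 1L) %% 3L
    c0 <- k - frame
    if (c0 + 2L > cds_length(model)) return("missense")  # truncated terminal codon
    g3 <- model$cds_gpos[c0:(c0 + 2L)]
    bases <- vapply(g3, function(g) ref_slice(reference, g, g), character(1))
    if (model$strand == "-") bases <- chartr("ACGTacgt", "TGCAtgca", bases)
    ref_codon <- toupper(paste(bases, collapse = ""))
    talt <- tx_allele_to_fwd(model, alt)          # transcript-oriented alt
    alt_bases <- bases; alt_bases[frame + 1L] <- talt
    alt_codon <- toupper(paste(alt_bases, collapse = ""))
    aa_ref <- translate_dna(ref_codon); aa_alt <- translate_dna(alt_codon)
    if (aa_ref == aa_alt) return("synonymous")
    if (aa_alt == "*") return("stopgain")
    if (aa_ref == "*") return("stoploss")
    return("missense")
  }

  # indels: footprint = bases added/removed (anchor base excluded)
  is_del <- nchar(ref) > nchar(alt)
  indel_len <- abs(nchar(ref) - nchar(alt))
  if (is_del) {
    span <- (pos + 1L):(pos + nchar(ref) - 1L)
    d <- suppressWarnings(min(vapply(span, splice_dist, integer(1)), na.rm = TRUE))
    if (is.finite(d) && d <= 2) return("splice")
    in_cds <- any(span %in% model$cds_gpos)
    if (!in_cds) return("intronic")
    if (indel_len %% 3L == 0L) return("nonframeshift deletion")
    return("frameshift deletion")
  } else {
    # insertion between pos and pos+1
    d <- suppressWarnings(min(vapply(c(pos, pos + 1L), splice_dist, integer(1)),
                              na.rm = TRUE))
    if (is.finite(d) && d <= 2) return("splice")
    in_cds <- (pos %in% model$cds_gpos) && ((pos + 1L) %in% model$cds_gpos)
    if (!in_cds) return("intronic")
    if (indel_len %% 3L == 0L) return("nonframeshift insertion")
    return("frameshift insertion")
  }
}
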