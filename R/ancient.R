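# Ancient-genome arm: SAM text I/O, postmortem-damage profiling and quality
# rescaling, pileup variant calling, terminal-damage filtering, catalog
# matching, and chronology/geography summaries.
#
# Orientation convention: deamination chemistry is molecule-relative, so all
# damage offsets are computed in original-molecule coordinates.  For a
# reverse-strand alignment the molecule 5' end is the *right* end in
# reference coordinates, and a reference-orientation C>T mismatch on such a
# read is a molecule-orientation G>A (and vice versa).  Consequently, in
# reference coordinates, C>T damage candidates sit near the alignment left
# end and G>A candidates near the right end, for both strands.

# SAM text I/O -----------------------------------------------------------

#' Read a SAM text file
#'
#' Minimal SAM reader for ungapped single-segment alignments (CIGAR
#' `<n>M`); header lines are skipped, flags decoded into `strand`,
#' `duplicate` and `unmapped` columns.
#'
#' @param path SAM file.
#' @return data.frame with columns `qname`, `flag`, `chrom`, `pos`, `mapq`,
#'   `seq`, `qual`, `strand`, `duplicate`, `unmapped`.
#' @export
read_sam <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!startsWith(lines, "@") & nzchar(lines)]
  if (length(lines) == 0)
    return(data.frame(qname = character(), flag = integer(), chrom = character(),
                      pos = integer(), mapq = integer(), seq = character(),
                      qual = character(), strand = character(),
                      duplicate = logical(), unmapped = logical(),
                      stringsAsFactors = FALSE))
  f <- strsplit(lines, "\t", fixed = TRUE)
  get <- function(i) vapply(f, `[[`, character(1), i)
  cigar <- get(6)
  ok <- grepl("^[0-9]+M$", cigar) | cigar == "*"
  if (any(!ok)) stop("unsupported CIGAR (only <n>M handled): ",
                     cigar[!ok][1])
  flag <- as.integer(get(2))
  data.frame(
    qname = get(1), flag = flag, chrom = get(3), pos = as.integer(get(4)),
    mapq = as.integer(get(5)), seq = get(10), qual = get(11),
    strand = ifelse(bitwAnd(flag, 16L) > 0L, "-", "+"),
    duplicate = bitwAnd(flag, 1024L) > 0L,
    unmapped = bitwAnd(flag, 4L) > 0L,
    stringsAsFactors = FALSE
  )
}

#' Write reads as a SAM text file
#'
#' @param reads data.frame as returned by [read_sam()] (columns `qname`,
#'   `flag`, `chrom`, `pos`, `mapq`, `seq`, `qual`).
#' @param path output file.
#' @param ref_name,ref_len reference name and length for the `@SQ` line.
#' @return `path`, invisibly.
#' @export
write_sam <- function(reads, path, ref_name = "chr1", ref_len) {
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           sprintf("@SQ\tSN:%s\tLN:%d", ref_name, as.integer(ref_len)))
  reads <- reads[order(reads$pos), , drop = FALSE]
  body <- sprintf("%s\t%d\t%s\t%d\t%d\t%dM\t*\t0\t0\t%s\t%s",
                  reads$qname, reads$flag, reads$chrom, reads$pos, reads$mapq,
                  nchar(reads$seq), reads$seq, reads$qual)
  writeLines(c(hdr, body), path)
  invisible(path)
}

# internal: usable reads + fixed-length check
usable_reads <- function(reads) {
  r <- reads[!reads$duplicate & !reads$unmapped, , drop = FALSE]
  if (nrow(r) == 0) stop("no mapped, non-duplicate reads")
  if (length(unique(nchar(r$seq))) != 1)
    stop("mixed read lengths not supported by the vectorized path")
  r
}

# internal: molecule-orientation character matrices for reads and the
# reference under them; rows = reads, cols = molecule offset + 1
molecule_matrices <- function(reads, reference) {
  L <- nchar(reads$seq[1])
  refsub <- substring(reference, reads$pos, reads$pos + L - 1L)
  rev_sel <- reads$strand == "-"
  mol_read <- reads$seq; mol_ref <- refsub
  mol_read[rev_sel] <- revcomp(mol_read[rev_sel])
  mol_ref[rev_sel] <- revcomp(mol_ref[rev_sel])
  list(
    read = matrix(toupper(unlist(strsplit(mol_read, NULL))), ncol = L, byrow = TRUE),
    ref  = matrix(toupper(unlist(strsplit(mol_ref, NULL))), ncol = L, byrow = TRUE),
    L = L, rev_sel = rev_sel
  )
}

# Damage profile ---------------------------------------------------------

#' Estimate a postmortem-damage profile
#'
#' Per-offset mismatch rates in molecule coordinates: C-in-reference read
#' as T by offset from the 5' read end, G-in-reference read as A by offset
#' from the 3' end.  Reverse-strand alignments are flipped before counting.
#' Offsets with zero opportunities have rate `NA` (undefined, not zero).
#'
#' @param reads data.frame of aligned reads ([read_sam()]).
#' @param reference reference chromosome sequence.
#' @param max_offset largest offset profiled (default 25).
#' @return object of class `damage_profile`: list of data.frames `ct5` and
#'   `ga3`, each with `offset`, `rate`, `opportunities`, `hits`.
#' @export
estimate_damage_profile <- function(reads, reference, max_offset = 25L) {
  r <- usable_reads(reads)
  mm <- molecule_matrices(r, reference)
  K <- min(max_offset, mm$L - 1L)

  one_end <- function(from_ref, to_read, from_right) {
    off <- 0:K
    opp <- hits <- integer(K + 1L)
    for (o in off) {
      col <- if (from_right) mm$L - o else o + 1L
      is_opp <- mm$ref[, col] == from_ref
      opp[o + 1L] <- sum(is_opp)
      hits[o + 1L] <- sum(is_opp & mm$read[, col] == to_read)
    }
    data.frame(offset = off, rate = ifelse(opp > 0, hits / opp, NA_real_),
               opportunities = opp, hits = hits)
  }
  out <- list(ct5 = one_end("C", "T", FALSE), ga3 = one_end("G", "A", TRUE))
  class(out) <- "damage_profile"
  out
}

#' @export
print.damage_profile <- function(x, ...) {
  cat("damage_profile: CT at 5' offset 0 =",
      signif(x$ct5$rate[1], 3), "| GA at 3' offset 0 =",
      signif(x$ga3$rate[1], 3), "\n")
  invisible(x)
}

#' Fit an exponential decay to a damage profile
#'
#' Weighted log-linear fit `log(rate) = log(d0) - lambda * offset` over
#' offsets with observed hits, weighted by hit counts.
#'
#' @param profile a `damage_profile`.
#' @param end `"ct5"` or `"ga3"`.
#' @param max_offset largest offset used in the fit.
#' @return list with `d0` (fitted rate at offset 0), `lambda` (decay per
#'   base), and `rate0` (the raw offset-0 rate).
#' @export
fit_damage_decay <- function(profile, end = c("ct5", "ga3"), max_offset = 12L) {
  end <- match.arg(end)
  df <- profile[[end]]
  df <- df[df$offset <= max_offset & df$opportunities > 0 & df$hits > 0, ]
  if (nrow(df) < 2) stop("not enough informative offsets to fit a decay")
  fit <- stats::lm(log(rate) ~ offset, data = df, weights = df$hits)
  co <- stats::coef(fit)
  list(d0 = unname(exp(co[1])), lambda = unname(-co[2]),
       rate0 = profile[[end]]$rate[1])
}

#' Rescale base qualities at likely damage products
#'
#' Caps the quality of candidate damage bases (read T over reference C near
#' the 5' end, read A over reference G near the 3' end, molecule
#' orientation) at the Phred score of the profiled damage rate at that
#' offset: `-10*log10(rate)`.  All other bases are unchanged.
#'
#' @param reads data.frame of aligned reads.
#' @param profile a `damage_profile` estimated from the same library.
#' @param reference reference chromosome sequence.
#' @return the reads data.frame with adjusted `qual` strings.
#' @export
rescale_qualities <- function(reads, profile, reference) {
  r <- usable_reads(reads)
  mm <- molecule_matrices(r, reference)
  L <- mm$L
  qmat <- matrix(unlist(qual_string_to_phred(r$qual)), ncol = L, byrow = TRUE)
  qmat[mm$rev_sel, ] <- t(apply(qmat[mm$rev_sel, , drop = FALSE], 1, rev))

  cap_at <- function(rate) {
    if (is.na(rate) || rate <= 0) return(NA_integer_)
    max(0L, errprob_to_phred(rate))
  }
  for (tab_name in c("ct5", "ga3")) {
    tab <- profile[[tab_name]]
    for (i in seq_len(nrow(tab))) {
      cap <- cap_at(tab$rate[i])
      if (is.na(cap)) next
      o <- tab$offset[i]
      if (o > L - 1L) next
      col <- if (tab_name == "ct5") o + 1L else L - o
      hit <- if (tab_name == "ct5") mm$ref[, col] == "C" & mm$read[, col] == "T"
             else mm$ref[, col] == "G" & mm$read[, col] == "A"
      qmat[hit, col] <- pmin(qmat[hit, col], cap)
    }
  }

  qmat[mm$rev_sel, ] <- t(apply(qmat[mm$rev_sel, , drop = FALSE], 1, rev))
  out <- reads
  keep <- !reads$duplicate & !reads$unmapped
  out$qual[keep] <- apply(qmat, 1, function(v) rawToChar(as.raw(v + 33L)))
  out
}

# Pileup calling ---------------------------------------------------------

# internal: per-base genotype log10-likelihood contributions
# P(b|hom) = 1-e if b matches, e/3 otherwise; het averages the two alleles.
.geno_contrib <- function(is_alt_base, e) {
  p_homref <- ifelse(is_alt_base, e / 3, 1 - e)
  p_homalt <- ifelse(is_alt_base, 1 - e, e / 3)
  p_het <- (p_homref + p_homalt) / 2
  cbind(het = log10(p_het) - log10(p_homref),
        homalt = log10(p_homalt) - log10(p_homref))
}

#' Pileup variant calling over a region
#'
#' Piles bases with quality at or above `min_bq` from mapped, non-duplicate
#' reads and emits a call for every non-reference allele supported by at
#' least `min_alt` bases.  Each call carries depth, alt and terminal-alt
#' counts plus a diploid genotype log-likelihood-ratio (`llr`, best variant
#' genotype vs homozygous reference, base 10) computed from the base
#' qualities; calls whose `llr` is not positive are labelled `LOWSUPPORT`,
#' mirroring the genotype-evidence weighting a likelihood-based caller
#' applies to rescaled qualities.
#'
#' @param reads data.frame of aligned reads ([read_sam()]).
#' @param reference reference chromosome sequence.
#' @param region list/data.frame with `chrom`, `start`, `end` (1-based
#'   inclusive).
#' @param min_bq minimum base quality (default 1, so quality-0 bases are
#'   excluded).
#' @param min_alt minimum alt-supporting bases for a call (default 1).
#' @return list with `calls` (data.frame: `chrom`, `pos`, `ref`, `alt`,
#'   `depth`, `alt_count`, `terminal_alt_count`, `llr_het`, `llr_homalt`,
#'   `llr`, `qual`, `filter`) and `support` (per alt-supporting read:
#'   `call`, `qname`, `strand`, `bq`, `mol_type`, `mol_offset`,
#'   `is_terminal`, `contrib_het`, `contrib_homalt`).
#' @export
pileup_call <- function(reads, reference, region, min_bq = 1L, min_alt = 1L) {
  if (region$end > nchar(reference))
    stop("region extends beyond the reference")
  r <- reads[!reads$duplicate & !reads$unmapped &
             reads$chrom == region$chrom, , drop = FALSE]
  empty_calls <- data.frame(chrom = character(), pos = integer(),
                            ref = character(), alt = character(),
                            depth = integer(), alt_count = integer(),
                            terminal_alt_count = integer(),
                            llr_het = numeric(), llr_homalt = numeric(),
                            llr = numeric(), qual = numeric(),
                            filter = character(), stringsAsFactors = FALSE)
  empty_support <- data.frame(call = character(), qname = character(),
                              strand = character(), bq = integer(),
                              mol_type = character(), mol_offset = integer(),
                              is_terminal = logical(),
                              contrib_het = numeric(), contrib_homalt = numeric(),
                              stringsAsFactors = FALSE)
  if (nrow(r) == 0) return(list(calls = empty_calls, support = empty_support))
  read_len <- nchar(r$seq)

  # expand reads into (position, base, quality, read) tuples, one length
  # group at a time so mixed read lengths stay vectorized
  pv <- iv <- qv <- integer(0); bv <- character(0)
  for (grp in split(seq_len(nrow(r)), read_len)) {
    L <- read_len[grp[1]]
    base <- matrix(toupper(unlist(strsplit(r$seq[grp], NULL))),
                   ncol = L, byrow = TRUE)
    q <- matrix(unlist(qual_string_to_phred(r$qual[grp])),
                ncol = L, byrow = TRUE)
    pos <- outer(r$pos[grp], 0:(L - 1L), `+`)
    ridx <- matrix(rep(grp, L), ncol = L)
    keep <- pos >= region$start & pos <= region$end & q >= min_bq & base != "N"
    pv <- c(pv, pos[keep]); bv <- c(bv, base[keep])
    qv <- c(qv, q[keep]); iv <- c(iv, ridx[keep])
  }
  if (length(pv) == 0) return(list(calls = empty_calls, support = empty_support))

  width <- region$end - region$start + 1L
  depth <- tabulate(pv - region$start + 1L, nbins = width)
  refchars <- toupper(strsplit(substr(reference, region$start, region$end), NULL)[[1]])
  refv <- refchars[pv - region$start + 1L]

  mism <- bv != refv
  if (!any(mism)) return(list(calls = empty_calls, support = empty_support))
  cand <- unique(data.frame(pos = pv[mism], alt = bv[mism],
                            stringsAsFactors = FALSE))
  cand <- cand[order(cand$pos, cand$alt), , drop = FALSE]
  idx_by_pos <- split(seq_along(pv), pv)

  calls <- list(); support <- list()
  for (ci in seq_len(nrow(cand))) {
    p <- cand$pos[ci]; alt <- cand$alt[ci]
    at <- idx_by_pos[[as.character(p)]]
    refb <- refchars[p - region$start + 1L]
    is_alt <- bv[at] == alt
    n_alt <- sum(is_alt)
    if (n_alt < min_alt) next

    e <- phred_to_errprob(qv[at])
    contrib <- .geno_contrib(is_alt, e)
    # bases that are neither ref nor alt contribute e/3 under all three
    # genotypes at leading order; drop them from the ratio
    other <- bv[at] != refb & bv[at] != alt
    contrib[other, ] <- 0
    llr_het <- sum(contrib[, "het"]); llr_homalt <- sum(contrib[, "homalt"])
    llr <- max(llr_het, llr_homalt)

    # molecule-orientation mismatch type + damage-relevant terminal offset
    rows <- iv[at][is_alt]
    strands <- r$strand[rows]
    s_pos <- r$pos[rows]; e_pos <- r$pos[rows] + read_len[rows] - 1L
    fwd <- strands == "+"
    mol_ref <- ifelse(fwd, refb, chartr("ACGT", "TGCA", refb))
    mol_alt <- ifelse(fwd, alt, chartr("ACGT", "TGCA", alt))
    mol_type <- paste0(mol_ref, ">", mol_alt)
    off5 <- ifelse(fwd, p - s_pos, e_pos - p)   # molecule 5' offset
    off3 <- ifelse(fwd, e_pos - p, p - s_pos)   # molecule 3' offset
    mol_offset <- ifelse(mol_type == "C>T", off5,
                         ifelse(mol_type == "G>A", off3, pmin(off5, off3)))
    is_terminal <- (mol_type == "C>T" & off5 <= 1L) |
                   (mol_type == "G>A" & off3 <= 1L)

    id <- paste0(region$chrom, ":", p, ":", refb, ">", alt)
    calls[[length(calls) + 1L]] <- data.frame(
      chrom = region$chrom, pos = p, ref = refb, alt = alt,
      depth = depth[p - region$start + 1L], alt_count = n_alt,
      terminal_alt_count = sum(is_terminal),
      llr_het = llr_het, llr_homalt = llr_homalt, llr = llr,
      qual = round(10 * max(llr, 0), 1),
      filter = if (llr > 0) "PASS" else "LOWSUPPORT",
      stringsAsFactors = FALSE)
    support[[length(support) + 1L]] <- data.frame(
      call = id, qname = r$qname[rows], strand = strands,
      bq = qv[at][is_alt], mol_type = mol_type, mol_offset = mol_offset,
      is_terminal = is_terminal,
      contrib_het = contrib[is_alt, "het"],
      contrib_homalt = contrib[is_alt, "homalt"],
      stringsAsFactors = FALSE)
  }
  if (length(calls) == 0) return(list(calls = empty_calls, support = empty_support))
  calls <- do.call(rbind, calls)
  calls$call <- paste0(calls$chrom, ":", calls$pos, ":", calls$ref, ">", calls$alt)
  list(calls = calls, support = do.call(rbind, support))
}

#' Apply the 2-bp terminal damage exclusion
#'
#' For C>T and G>A calls (molecule orientation, per supporting read), the
#' alt-supporting reads whose site lies at offset 0 or 1 from the
#' damage-relevant read end are discounted.  A call with no support left is
#' `DAMAGE`; otherwise its alt count, depth and genotype evidence are
#' recomputed from the surviving reads and the call is `PASS` or
#' `LOWSUPPORT`.  Calls that are not C>T/G>A in any read pass untouched.
#'
#' @param pileup result of [pileup_call()].
#' @param min_alt minimum surviving alt reads.
#' @param min_llr minimum surviving genotype log10 likelihood ratio.
#' @return the pileup list with `calls$filter`, counts and `llr` updated,
#'   and `support$discounted` added.
#' @export
damage_filter <- function(pileup, min_alt = 1L, min_llr = 0) {
  calls <- pileup$calls; support <- pileup$support
  if (nrow(calls) == 0) return(pileup)
  support$discounted <- FALSE

  for (i in seq_len(nrow(calls))) {
    id <- calls$call[i]
    sup <- which(support$call == id)
    disc <- sup[support$is_terminal[sup] &
                support$mol_type[sup] %in% c("C>T", "G>A")]
    if (length(disc) == 0) next
    support$discounted[disc] <- TRUE
    remaining <- calls$alt_count[i] - length(disc)
    calls$alt_count[i] <- remaining
    calls$depth[i] <- calls$depth[i] - length(disc)
    if (remaining == 0L) {
      calls$filter[i] <- "DAMAGE"
      next
    }
    llr_het <- calls$llr_het[i] - sum(support$contrib_het[disc])
    llr_homalt <- calls$llr_homalt[i] - sum(support$contrib_homalt[disc])
    calls$llr_het[i] <- llr_het; calls$llr_homalt[i] <- llr_homalt
    calls$llr[i] <- max(llr_het, llr_homalt)
    calls$qual[i] <- round(10 * max(calls$llr[i], 0), 1)
    calls$filter[i] <- if (remaining >= min_alt && calls$llr[i] > min_llr)
      "PASS" else "LOWSUPPORT"
  }
  list(calls = calls, support = support)
}

#' Match filtered calls against the modern catalog
#'
#' Exact `(chrom, pos, ref, alt)` matches of `PASS` calls against catalog
#' records, reported separately per clinical class.
#'
#' @param calls calls data.frame (typically `damage_filter(...)$calls`).
#' @param catalog parsed catalog ([parse_catalog()]).
#' @param reference_checksum,catalog_checksum optional checksums of the two
#'   reference builds; if both are given and differ, matching is refused
#'   (coordinate-system mismatch).
#' @return data.frame of matches with catalog columns plus call depth and
#'   alt count; per-class counts in attribute `"by_class"`.
#' @export
match_catalog <- function(calls, catalog,
                          reference_checksum = NULL, catalog_checksum = NULL) {
  if (!is.null(reference_checksum) && !is.null(catalog_checksum) &&
      !identical(reference_checksum, catalog_checksum))
    stop("reference checksum mismatch between calls and catalog ",
         "(different builds/coordinate systems)")
  pass <- calls[calls$filter == "PASS", , drop = FALSE]
  key_call <- paste(pass$chrom, pass$pos, toupper(pass$ref), toupper(pass$alt))
  key_cat <- paste(catalog$chrom, catalog$pos, catalog$ref, catalog$alt)
  hit <- match(key_call, key_cat)
  sel <- !is.na(hit)
  out <- cbind(catalog[hit[sel], , drop = FALSE],
               data.frame(depth = pass$depth[sel],
                          alt_count = pass$alt_count[sel],
                          call_qual = pass$qual[sel]))
  rownames(out) <- NULL
  attr(out, "by_class") <- table(factor(out$clin_class, c("PV", "BV", "VUS")))
  out
}

#' Run the full ancient-sample pipeline
#'
#' Damage profile -> quality rescaling -> pileup -> 2-bp terminal filter ->
#' catalog match, for one sample.
#'
#' @param reads sample reads ([read_sam()]).
#' @param reference reference chromosome sequence.
#' @param region calling region (`chrom`, `start`, `end`).
#' @param catalog parsed catalog.
#' @param min_bq,min_alt pileup thresholds.
#' @return list with `profile`, `calls`, `support`, `matches`.
#' @export
run_ancient_sample <- function(reads, reference, region, catalog,
                               min_bq = 1L, min_alt = 1L) {
  profile <- estimate_damage_profile(reads, reference)
  rescaled <- rescale_qualities(reads, profile, reference)
  pu <- pileup_call(rescaled, reference, region, min_bq = min_bq,
                    min_alt = min_alt)
  pu <- damage_filter(pu, min_alt = min_alt)
  matches <- match_catalog(pu$calls, catalog)
  list(profile = profile, calls = pu$calls, support = pu$support,
       matches = matches)
}

# Chronology / geography -------------------------------------------------

#' Validate ancient-sample metadata
#'
#' @param metadata data.frame with `sample_id`, `date_lo`, `date_hi`
#'   (years BP, `date_lo` the younger bound), `lat`, `lon`, `region`,
#'   `group`.
#' @return the validated data.frame.
#' @export
validate_metadata <- function(metadata) {
  stopifnot(all(c("sample_id", "date_lo", "date_hi", "lat", "lon",
                  "region", "group") %in% names(metadata)))
  bad <- which(metadata$date_lo > metadata$date_hi)
  if (length(bad)) stop("date_lo > date_hi for: ",
                        paste(metadata$sample_id[bad], collapse = ", "))
  if (any(metadata$lat < -90 | metadata$lat > 90, na.rm = TRUE))
    stop("latitude outside [-90, 90]")
  if (any(metadata$lon < -180 | metadata$lon > 180, na.rm = TRUE))
    stop("longitude outside [-180, 180]")
  metadata
}

#' Chronology, geography and group summaries of PV-sharing samples
#'
#' Ranged dates are resolved by their midpoint; a sample exactly at the
#' cutoff counts as within it.  Hominin groups other than `modern_human`
#' are reported in the group table but never enter the modern-human time
#' bins.
#'
#' @param matches data.frame with at least `sample_id`, `variant_id`,
#'   `clin_class`, `gene` (concatenated per-sample [match_catalog()]
#'   output).
#' @param metadata validated sample metadata ([validate_metadata()]).
#' @param cutoff_bp chronology cutoff, years BP (default 10000).
#' @return list with `carriers` (per-sample table with midpoints),
#'   `carrier_level` and `pv_level` within-cutoff counts and percentages,
#'   `per_region`, `per_group`, and `per_pv` (carrier counts with
#'   oldest/newest dates).
#' @export
chronology_summary <- function(matches, metadata, cutoff_bp = 10000) {
  metadata <- validate_metadata(metadata)
  pv <- matches[matches$clin_class == "PV", , drop = FALSE]
  carriers <- unique(pv$sample_id)
  md <- metadata[metadata$sample_id %in% carriers, , drop = FALSE]
  no_date <- is.na(md$date_lo) | is.na(md$date_hi)
  if (any(no_date)) {
    warning("samples without dates excluded from time bins: ",
            paste(md$sample_id[no_date], collapse = ", "))
  }
  md$midpoint_bp <- (md$date_lo + md$date_hi) / 2

  modern <- md[md$group == "modern_human" & !is.na(md$midpoint_bp), , drop = FALSE]
  n_within <- sum(modern$midpoint_bp <= cutoff_bp)
  carrier_level <- list(
    n_within = n_within, n_total = nrow(modern),
    pct_within = if (nrow(modern)) proportion(n_within, nrow(modern)) else NA_real_)

  pv$midpoint_bp <- md$midpoint_bp[match(pv$sample_id, md$sample_id)]
  pv_modern <- pv[pv$sample_id %in% modern$sample_id, , drop = FALSE]
  per_pv_min <- tapply(pv_modern$midpoint_bp, pv_modern$variant_id, min)
  n_pv_within <- sum(per_pv_min <= cutoff_bp)
  pv_level <- list(
    n_within = n_pv_within, n_total = length(per_pv_min),
    pct_within = if (length(per_pv_min)) proportion(n_pv_within, length(per_pv_min))
                 else NA_real_)

  per_pv <- do.call(rbind, lapply(split(pv, pv$variant_id), function(d) {
    data.frame(variant_id = d$variant_id[1], gene = d$gene[1],
               n_carriers = length(unique(d$sample_id)),
               oldest_bp = suppressWarnings(max(d$midpoint_bp, na.rm = TRUE)),
               newest_bp = suppressWarnings(min(d$midpoint_bp, na.rm = TRUE)),
               stringsAsFactors = FALSE)
  }))
  rownames(per_pv) <- NULL

  list(carriers = md,
       carrier_level = carrier_level,
       pv_level = pv_level,
       per_region = table(md$region),
       per_group = table(md$group),
       per_pv = per_pv)
}

#' Export PV-sharing samples as GeoJSON points
#'
#' @param carriers the `carriers` table from [chronology_summary()].
#' @param path optional output file.
#' @return GeoJSON string, invisibly if written to `path`.
#' @export
geojson_points <- function(carriers, path = NULL) {
  features <- lapply(seq_len(nrow(carriers)), function(i) {
    list(type = "Feature",
         geometry = list(type = "Point",
                         coordinates = c(carriers$lon[i], carriers$lat[i])),
         properties = list(sample_id = carriers$sample_id[i],
                           region = carriers$region[i],
                           group = carriers$group[i],
                           midpoint_bp = carriers$midpoint_bp[i]))
  })
  gj <- jsonlite::toJSON(list(type = "FeatureCollection", features = features),
                         auto_unbox = TRUE, digits = NA)
  if (!is.null(path)) {
    writeLines(gj, path)
    return(invisible(as.character(gj)))
  }
  as.character(gj)
}

#' Write variant calls as VCF
#'
#' VCFv4.2 with `FILTER` in `PASS`/`DAMAGE`/`LOWSUPPORT` and depth/alt
#' counts in INFO.
#'
#' @param calls calls data.frame.
#' @param path output file.
#' @param sample_id label recorded in the header.
#' @return `path`, invisibly.
#' @export
write_calls_vcf <- function(calls, path, sample_id = "sample") {
  hdr <- c("##fileformat=VCFv4.2",
           paste0("##source=paleovar ancient-call sample=", sample_id),
           '##FILTER=<ID=DAMAGE,Description="Only 2-bp terminal C>T/G>A support">',
           '##FILTER=<ID=LOWSUPPORT,Description="Insufficient genotype evidence">',
           '##INFO=<ID=DP,Number=1,Type=Integer,Description="Depth">',
           '##INFO=<ID=AC,Number=1,Type=Integer,Description="Alt read count">',
           '##INFO=<ID=TAC,Number=1,Type=Integer,Description="Terminal alt read count">',
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  ord <- order(calls$chrom, calls$pos)
  c2 <- calls[ord, , drop = FALSE]
  body <- if (nrow(c2)) {
    sprintf("%s\t%d\t.\t%s\t%s\t%.1f\t%s\tDP=%d;AC=%d;TAC=%d",
            c2$chrom, c2$pos, c2$ref, c2$alt, c2$qual, c2$filter,
            c2$depth, c2$alt_count, c2$terminal_alt_count)
  } else character()
  writeLines(c(hdr, body), path)
  invisible(path)
}
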