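# Damage profiling, rescaling, pileup calling, terminal filtering, matching,
# chronology.

# 40 bp fixture reference with known C/G placement
fix_ref <- function() "AACATGACCGTTACGTAGCCATGCATCAGTACGGATCCAA"

test_that("undamaged reads give an all-zero profile; empty offsets are NA", {
  ref <- fix_ref()
  reads <- rbind(make_read("r1", 1, substr(ref, 1, 20)),
                 make_read("r2", 10, substr(ref, 10, 29)),
                 make_read("r3", 21, substr(ref, 21, 40), strand = "-"))
  prof <- estimate_damage_profile(reads, ref, max_offset = 10)
  expect_true(all(prof$ct5$rate[prof$ct5$opportunities > 0] == 0))
  expect_true(all(prof$ga3$rate[prof$ga3$opportunities > 0] == 0))
  expect_true(all(is.na(prof$ct5$rate[prof$ct5$opportunities == 0])))
})

test_that("profile counts respect molecule orientation of reverse reads", {
  ref <- "TTGTTTTTTT"   # G at position 3
  # reverse-strand read: molecule = revcomp(span), so reference G at pos 3
  # is a molecule C at 5' offset 7; an A in the aligned sequence there is a
  # molecule C>T damage product
  seqA <- "TTATTTTTTT"
  reads <- make_read("r1", 1, seqA, strand = "-")
  prof <- estimate_damage_profile(reads, ref, max_offset = 9)
  expect_equal(prof$ct5$hits[prof$ct5$offset == 7], 1L)
  expect_equal(sum(prof$ga3$hits), 0L)
  # the same aligned mismatch on a forward read is a molecule G>A at 3'
  # offset 7 instead
  prof_f <- estimate_damage_profile(make_read("r1", 1, seqA, "+"), ref,
                                    max_offset = 9)
  expect_equal(prof_f$ga3$hits[prof_f$ga3$offset == 7], 1L)
  expect_equal(sum(prof_f$ct5$hits), 0L)
})

test_that("quality rescaling caps damage candidates at the closed form", {
  ref <- "CCCCCCCCCC"
  reads <- make_read("r1", 1, "TCCCCCCCCT")   # T over C at both ends
  prof <- list(ct5 = data.frame(offset = 0:9, rate = c(0.5, rep(0, 9)),
                                opportunities = 10, hits = 0),
               ga3 = data.frame(offset = 0:9, rate = 0,
                                opportunities = 10, hits = 0))
  class(prof) <- "damage_profile"
  out <- rescale_qualities(reads, prof, ref)
  quals <- as.integer(charToRaw(out$qual[1])) - 33L
  expect_equal(quals[1], 3)              # -10*log10(0.5) rounds to 3
  expect_equal(quals[10], 37)            # T over C at 3' end: not a candidate
  expect_equal(quals[2:9], rep(37, 8))   # C over C never changes

  # all-zero profile leaves reads unchanged
  prof0 <- prof; prof0$ct5$rate <- 0
  expect_identical(rescale_qualities(reads, prof0, ref)$qual, reads$qual)
  # non-candidate mismatches (G over C) never change
  readsG <- make_read("r2", 1, "GCCCCCCCCC")
  expect_identical(rescale_qualities(readsG, prof, ref)$qual, readsG$qual)
})

test_that("pileup calls match a manual pileup of crafted reads", {
  ref <- fix_ref()   # position 8 is C
  reads <- rbind(
    make_read("a", 1, paste0(substr(ref, 1, 7), "T", substr(ref, 9, 20))),
    make_read("b", 2, paste0(substr(ref, 2, 7), "T", substr(ref, 9, 21))),
    make_read("c", 3, paste0(substr(ref, 3, 7), "T", substr(ref, 9, 22))),
    make_read("d", 1, substr(ref, 1, 20)),
    make_read("e", 5, substr(ref, 5, 24)))
  region <- list(chrom = "chr1", start = 1L, end = 40L)
  pu <- pileup_call(reads, ref, region)
  expect_equal(nrow(pu$calls), 1)
  expect_equal(pu$calls$pos, 8)
  expect_equal(pu$calls$ref, "C"); expect_equal(pu$calls$alt, "T")
  expect_equal(pu$calls$depth, 5); expect_equal(pu$calls$alt_count, 3)
  expect_equal(pu$calls$filter, "PASS")

  # all reads matching the reference produce no calls
  clean <- rbind(make_read("x", 1, substr(ref, 1, 20)),
                 make_read("y", 11, substr(ref, 11, 30)))
  expect_equal(nrow(pileup_call(clean, ref, region)$calls), 0)

  # quality-0 alt bases are excluded at the default min_bq = 1
  q0 <- paste0(strrep("F", 7), "!", strrep("F", 12))
  rq <- rbind(make_read("a", 1,
                        paste0(substr(ref, 1, 7), "T", substr(ref, 9, 20)),
                        qual = q0),
              make_read("d", 1, substr(ref, 1, 20)))
  expect_equal(nrow(pileup_call(rq, ref, region)$calls), 0)

  # duplicates are ignored
  dup <- rbind(make_read("a", 1, paste0(substr(ref, 1, 7), "T",
                                        substr(ref, 9, 20)), duplicate = TRUE),
               make_read("d", 1, substr(ref, 1, 20)))
  expect_equal(nrow(pileup_call(dup, ref, region)$calls), 0)
  expect_error(pileup_call(reads, ref, list(chrom = "chr1", start = 1, end = 99)),
               "beyond the reference")
})

test_that("pileup depth equals the sum of allele counts at call positions", {
  cfg <- sim_config(seed = 21, n_samples = 1)
  b <- simulate_bundle(cfg, ancient = FALSE)
  r <- simulate_ancient_reads(cfg, b$reference, "s1",
                              data.frame(pos = integer(), ref = character(),
                                         alt = character(), dosage = numeric()),
                              n_reads = 800L)
  region <- list(chrom = "chr1", start = 1L, end = cfg$ref_length)
  pu <- pileup_call(r$reads, b$reference, region)
  refchars <- strsplit(toupper(b$reference[[1]]), NULL)[[1]]
  for (i in utils::head(seq_len(nrow(pu$calls)), 25)) {
    p <- pu$calls$pos[i]
    covering <- r$reads[r$reads$pos <= p & p <= r$reads$pos + cfg$read_length - 1, ]
    bases <- toupper(substr(covering$seq, p - covering$pos + 1,
                            p - covering$pos + 1))
    expect_equal(pu$calls$depth[i], length(bases))
    counts <- table(factor(bases, c("A", "C", "G", "T")))
    expect_equal(sum(counts), pu$calls$depth[i])
    expect_equal(unname(counts[pu$calls$alt[i]]) +
                 pu$calls$terminal_alt_count[i] * 0,  # counts are pre-filter
                 pu$calls$alt_count[i])
  }
})

test_that("raising min_alt never increases the number of calls", {
  cfg <- sim_config(seed = 22)
  b <- simulate_bundle(cfg, ancient = FALSE)
  r <- simulate_ancient_reads(cfg, b$reference, "s1",
                              data.frame(pos = 400L, ref = "A", alt = "G",
                                         dosage = 1),
                              n_reads = 1500L)
  region <- list(chrom = "chr1", start = 1L, end = cfg$ref_length)
  n_calls <- vapply(1:4, function(ma)
    nrow(pileup_call(r$reads, b$reference, region, min_alt = ma)$calls),
    integer(1))
  expect_true(all(diff(n_calls) <= 0))
})

test_that("the 2-bp terminal rule discounts damage-candidate support", {
  ref <- "CTTTTTTTTG"
  region <- list(chrom = "chr1", start = 1L, end = 10L)

  # C>T supported only by two reads with the site at their first bases
  reads <- rbind(make_read("r1", 1, "TTTTT"),
                 make_read("r2", 1, "TTTTTT"),
                 make_read("r3", 2, substr(ref, 2, 8)))
  pu <- damage_filter(pileup_call(reads, ref, region))
  ct <- pu$calls[pu$calls$pos == 1, ]
  expect_equal(ct$filter, "DAMAGE")
  expect_equal(ct$alt_count, 0)

  # one mid-read supporting read + one terminal: PASS with alt_count 1
  ref2 <- "TTTCTTTTTT"
  reads2 <- rbind(make_read("m1", 1, "TTTTTTT"),          # site mid-read
                  make_read("m2", 4, "TTTTTTT"),          # site at offset 0
                  make_read("m3", 1, substr(ref2, 1, 9)))
  pu2 <- damage_filter(pileup_call(reads2, ref2, region))
  ct2 <- pu2$calls[pu2$calls$pos == 4, ]
  expect_equal(ct2$filter, "PASS")
  expect_equal(ct2$alt_count, 1)
  expect_equal(ct2$terminal_alt_count, 1)

  # A>G at a read start is outside the rule's scope
  ref3 <- "ATTTTTTTTT"
  reads3 <- rbind(make_read("a1", 1, "GTTTTT"),
                  make_read("a2", 1, "GTTTTTT"),
                  make_read("a3", 1, "GTTTTTTT"))
  pu3 <- damage_filter(pileup_call(reads3, ref3, region))
  ag <- pu3$calls[pu3$calls$pos == 1, ]
  expect_equal(ag$filter, "PASS")
  expect_equal(ag$alt_count, 3)

  # reverse-strand read: a reference C>T at its alignment left end is a
  # molecule G>A at the molecule 3' end -> still discounted
  reads4 <- rbind(make_read("v1", 1, "TTTTT", strand = "-"),
                  make_read("v2", 1, "TTTTTT", strand = "-"),
                  make_read("v3", 2, substr(ref, 2, 8)))
  pu4 <- damage_filter(pileup_call(reads4, ref, region))
  expect_equal(pu4$calls$filter[pu4$calls$pos == 1], "DAMAGE")
})

test_that("catalog matching is exact on chrom/pos/ref/alt", {
  catalog <- suppressMessages(parse_catalog(rbind(
    catalog_row(pos = 8, ref = "C", alt = "T", sig = "Pathogenic"),
    catalog_row(pos = 12, ref = "T", alt = "A", sig = "Benign"))))
  calls <- data.frame(chrom = "chr1", pos = c(8L, 12L, 8L),
                      ref = c("C", "T", "C"), alt = c("T", "G", "A"),
                      depth = 10L, alt_count = 5L, terminal_alt_count = 0L,
                      qual = 50, filter = c("PASS", "PASS", "PASS"),
                      stringsAsFactors = FALSE)
  m <- match_catalog(calls, catalog)
  expect_equal(nrow(m), 1)            # same position, different alt: no match
  expect_equal(m$clin_class, "PV")
  expect_equal(unname(attr(m, "by_class")[["PV"]]), 1L)
  # non-PASS calls never match
  calls$filter <- "DAMAGE"
  expect_equal(nrow(match_catalog(calls, catalog)), 0)
  expect_error(match_catalog(calls, catalog, reference_checksum = "aaa",
                             catalog_checksum = "bbb"),
               "checksum mismatch")
})

test_that("chronology bins, groups and geography summarize correctly", {
  md <- data.frame(
    sample_id = c("s1", "s2", "s3", "s4"),
    date_lo = c(4000, 14000, 9000, 40000),
    date_hi = c(6000, 16000, 11000, 45000),
    lat = c(10, 20, 30, 40), lon = c(0, 10, 20, 30),
    region = c("Europe", "Asia", "Europe", "Europe"),
    group = c("modern_human", "modern_human", "modern_human", "neanderthal"),
    stringsAsFactors = FALSE)
  matches <- data.frame(
    sample_id = c("s1", "s2", "s3", "s4"),
    variant_id = c("v1", "v1", "v2", "v3"),
    clin_class = "PV", gene = "MLH1", stringsAsFactors = FALSE)

  cs <- chronology_summary(matches, md)
  # midpoints 5000 and 15000 -> 50% within cutoff among those two; s3 at
  # exactly 10000 falls inside, so 2 of 3 modern carriers are within
  expect_equal(cs$carrier_level$n_total, 3)
  expect_equal(cs$carrier_level$n_within, 2)
  expect_equal(cs$carrier_level$pct_within, proportion(2, 3))
  # two-sample arithmetic of the worked example
  cs2 <- chronology_summary(matches[1:2, ], md[1:2, ])
  expect_equal(cs2$carrier_level$pct_within, 50.0)
  # the neanderthal is reported as a carrier but never enters the
  # modern-human time bins (n_total above is 3, not 4)
  expect_true("s4" %in% cs$carriers$sample_id)
  expect_equal(unname(cs$per_group[["neanderthal"]]), 1L)
  # per-PV roll-up
  expect_equal(cs$per_pv$n_carriers[cs$per_pv$variant_id == "v1"], 2)

  expect_error(validate_metadata(transform(md, date_lo = c(9000, 1, 1, 1))),
               "date_lo > date_hi")
  expect_error(validate_metadata(transform(md, lat = c(95, 0, 0, 0))),
               "latitude")

  gj <- jsonlite::fromJSON(geojson_points(cs$carriers), simplifyVector = FALSE)
  expect_equal(gj$type, "FeatureCollection")
  expect_equal(length(gj$features), nrow(cs$carriers))
})

test_that("the shipped hg19 gene-interval table is well formed", {
  iv <- mmr_gene_intervals()
  expect_setequal(iv$gene, c("MLH1", "MSH2", "MSH6", "PMS2"))
  expect_true(all(iv$start < iv$end))
  expect_equal(iv$chrom[iv$gene == "MLH1"], "chr3")
  expect_equal(iv$start[iv$gene == "PMS2"], 6012870)
})

test_that("SAM text round-trips and calls serialize as VCF", {
  ref_len <- 40L
  reads <- rbind(make_read("r1", 3, "ACGTACGT"),
                 make_read("r2", 10, "ACGTACGT", strand = "-"),
                 make_read("r3", 5, "ACGTACGT", duplicate = TRUE))
  f <- tempfile(fileext = ".sam")
  write_sam(reads, f, ref_len = ref_len)
  got <- read_sam(f)
  expect_equal(nrow(got), 3)
  expect_equal(sort(got$qname), sort(reads$qname))
  expect_equal(got$strand[got$qname == "r2"], "-")
  expect_true(got$duplicate[got$qname == "r3"])

  calls <- data.frame(chrom = "chr1", pos = 8L, ref = "C", alt = "T",
                      depth = 5L, alt_count = 3L, terminal_alt_count = 1L,
                      qual = 31.4, filter = "PASS", stringsAsFactors = FALSE)
  vf <- tempfile(fileext = ".vcf")
  write_calls_vcf(calls, vf)
  lines <- readLines(vf)
  expect_true(any(grepl("^##FILTER=<ID=DAMAGE", lines)))
  expect_match(lines[length(lines)], "DP=5;AC=3;TAC=1")
})
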