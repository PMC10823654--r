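# Catalog parsing/normalization, HGVS conversion, effect annotation.

test_that("clinical significance strings map to working classes", {
  tab <- rbind(
    catalog_row(sig = "Pathogenic"),
    catalog_row(pos = 110, sig = "Likely pathogenic"),
    catalog_row(pos = 120, sig = "Pathogenic/Likely pathogenic"),
    catalog_row(pos = 130, sig = "Benign"),
    catalog_row(pos = 140, sig = "Likely benign"),
    catalog_row(pos = 150, sig = "Benign/Likely benign"),
    catalog_row(pos = 160, sig = "Uncertain significance"),
    catalog_row(pos = 170, sig = "Conflicting interpretations of pathogenicity"),
    catalog_row(pos = 180, sig = "Conflicting interpretations of pathogenicity"))
  rec <- suppressMessages(parse_catalog(tab))
  expect_equal(nrow(rec), 7)
  expect_equal(rec$clin_class, c(rep("PV", 3), rep("BV", 3), "VUS"))
  expect_equal(attr(rec, "n_conflicting"), 2L)

  expect_warning(r2 <- parse_catalog(catalog_row(sig = "drug response")),
                 "unknown clinical significance")
  expect_equal(nrow(r2), 0)
  expect_error(parse_catalog(catalog_row(sig = "drug response"),
                             on_unknown = "error"),
               "unknown clinical significance")
  expect_error(suppressMessages(parse_catalog(catalog_row(ref = "X"))),
               "malformed")

  empty <- parse_catalog(catalog_row()[0, ])
  expect_equal(nrow(empty), 0)
  expect_equal(summarize_catalog(empty)$total, 0)
})

test_that("founder flags come from the side id list", {
  tab <- rbind(catalog_row(hgvs = "c.1C>T"),
               catalog_row(pos = 110, hgvs = "c.11C>T"))
  rec <- parse_catalog(tab, founder_ids = "MLH1:c.11C>T")
  expect_equal(rec$founder, c(FALSE, TRUE))
  f <- tempfile()
  writeLines(c("# founders", "", "MLH1:c.11C>T"), f)
  expect_equal(read_founder_ids(f), "MLH1:c.11C>T")
})

test_that("c. to genomic conversion matches the exhaustive toy-model map", {
  tm <- toy_plus()
  # definition of c.1
  v <- cds_to_genomic(tm, "c.1A>G")
  expect_equal(v$pos, 151); expect_equal(v$ref, "A"); expect_equal(v$alt, "G")
  # donor-side intronic offset: c.50 = g.200, so c.50+2 = g.202
  expect_equal(cds_to_genomic(tm, "c.50+2T>C")$pos, 202)
  # acceptor side: c.51 = g.301, c.51-2 = g.299
  expect_equal(cds_to_genomic(tm, "c.51-2A>G")$pos, 299)
  expect_error(cds_to_genomic(tm, "c.9999A>G"), "beyond CDS length")

  # enumeration oracle: walk the toy model by hand over all CDS + intron
  # positions and compare c_to_g against the enumerated map
  hand_map <- list()
  for (g in 151:200) hand_map[[length(hand_map) + 1]] <-
    list(g = g, cds = g - 150, off = 0)            # exon1 CDS: c.1..c.50
  for (g in 301:350) hand_map[[length(hand_map) + 1]] <-
    list(g = g, cds = g - 250, off = 0)            # exon2 CDS: c.51..c.100
  for (g in 201:250) hand_map[[length(hand_map) + 1]] <-
    list(g = g, cds = 50, off = g - 200)           # intron, donor half
  for (g in 251:300) hand_map[[length(hand_map) + 1]] <-
    list(g = g, cds = 51, off = -(301 - g))        # intron, acceptor half
  g_to_c <- getFromNamespace("g_to_c", "paleovar")
  c_to_g <- getFromNamespace("c_to_g", "paleovar")
  for (h in hand_map) {
    got <- g_to_c(tm, h$g)
    expect_equal(got$cds, h$cds, label = paste("g", h$g))
    expect_equal(got$offset, h$off, label = paste("g", h$g))
    expect_equal(c_to_g(tm, h$cds, h$off), h$g)
  }
})

test_that("minus-strand conversion reverse-complements alleles", {
  tmm <- toy_minus()
  v <- cds_to_genomic(tmm, "c.10C>T")   # c.10 = g.181; C>T reads G>A forward
  expect_equal(v$pos, 181)
  expect_equal(v$ref, "G"); expect_equal(v$alt, "A")
  expect_equal(genomic_to_cds(tmm, 181, "G", "A"), "c.10C>T")
  # reverse-complement identity: forward alleles complement the c. alleles
  expect_equal(revcomp(v$ref), "C"); expect_equal(revcomp(v$alt), "T")
})

test_that("substitution c. names round-trip through the genome", {
  for (tm in list(toy_plus(), toy_minus_intron())) {
    span <- range(tm$exons$start, tm$exons$end)
    for (g in seq(span[1] + 50, span[2] - 50, by = 7)) {
      cc <- tryCatch(getFromNamespace("g_to_c", "paleovar")(tm, g),
                     error = function(e) NULL)
      if (is.null(cc)) next
      name <- genomic_to_cds(tm, g, "A", "G")
      back <- cds_to_genomic(tm, name)
      expect_equal(back$pos, g, label = paste(tm$gene, "g", g))
      expect_equal(back$ref, "A"); expect_equal(back$alt, "G")
    }
  }
})

test_that("deletions and insertions convert consistently with the reference", {
  ref <- toy_reference()
  tm <- toy_plus()
  # 2-bp deletion of c.10_11 (g.160-161), anchored at g.159
  v <- cds_to_genomic(tm, "c.10_11del", reference = ref)
  expect_equal(v$pos, 159)
  expect_equal(nchar(v$ref), 3); expect_equal(nchar(v$alt), 1)
  expect_equal(v$ref, substr(ref, 159, 161))
  expect_equal(genomic_to_cds(tm, v$pos, v$ref, v$alt), "c.10_11del")
  # insertion between c.10 and c.11
  vi <- cds_to_genomic(tm, "c.10_11insTTG", reference = ref)
  expect_equal(vi$pos, 160)
  expect_equal(substr(vi$alt, 2, 4), "TTG")
  expect_equal(genomic_to_cds(tm, vi$pos, vi$ref, vi$alt), "c.10_11insTTG")
  # duplication is an anchored insertion after the span (c.10 = g.160)
  vd <- cds_to_genomic(tm, "c.10_12dup", reference = ref)
  expect_equal(vd$pos, 162)
  expect_equal(vd$alt, paste0(substr(ref, 162, 162), substr(ref, 160, 162)))
  # minus strand: inserted bases are reverse-complemented to the genome
  tmm <- toy_minus()
  vm <- cds_to_genomic(tmm, "c.10_11insAC", reference = ref)
  expect_equal(substr(vm$alt, 2, 3), "GT")
})

test_that("effect classification matches a translation oracle on all CDS SNVs", {
  ref <- toy_reference()
  tm <- toy_plus()
  L <- cds_length(tm)
  # independent oracle: rebuild and translate the whole CDS
  cds_seq <- paste(vapply(tm$cds_gpos, function(g) substr(ref, g, g),
                          character(1)), collapse = "")
  translate <- function(s) {
    n <- nchar(s) %/% 3
    paste(Biostrings::GENETIC_CODE[substring(s, 3 * (1:n) - 2, 3 * (1:n))],
          collapse = "")
  }
  prot_ref <- translate(cds_seq)
  n_checked <- 0
  for (cc in seq_len(L - L %% 3)) {
    g <- tm$cds_gpos[cc]
    base <- substr(ref, g, g)
    for (alt in setdiff(c("A", "C", "G", "T"), base)) {
      got <- annotate_effect("chr1", g, base, alt, tm, ref)
      mut <- cds_seq
      substr(mut, cc, cc) <- alt
      prot_alt <- translate(mut)
      codon_i <- (cc - 1) %/% 3 + 1
      aa_r <- substr(prot_ref, codon_i, codon_i)
      aa_a <- substr(prot_alt, codon_i, codon_i)
      want <- if (aa_r == aa_a) "synonymous"
              else if (aa_a == "*") "stopgain"
              else if (aa_r == "*") "stoploss"
              else "missense"
      expect_equal(got, want, label = paste("c.", cc, base, ">", alt))
      n_checked <- n_checked + 1
    }
  }
  expect_gt(n_checked, 250)
})

test_that("splice classification follows the 2-bp intron-side window", {
  ref <- toy_reference()
  tm <- toy_plus()
  # brute force over every intronic position of the toy transcript:
  # distance to the nearest exon boundary decides splice vs intronic
  for (g in 201:300) {
    d <- min(g - 200, 301 - g)
    base <- substr(ref, g, g)
    alt <- setdiff(c("A", "C", "G", "T"), base)[1]
    got <- annotate_effect("chr1", g, base, alt, tm, ref)
    expect_equal(got, if (d <= 2) "splice" else "intronic",
                 label = paste("g", g, "d", d))
  }
  # the c.208-3 pattern: 3 bp from the acceptor is intronic, 2 bp is splice
  expect_equal(annotate_effect("chr1", 298, substr(ref, 298, 298),
                               setdiff(c("A", "C", "G", "T"),
                                       substr(ref, 298, 298))[1], tm, ref),
               "intronic")
})

test_that("indel effects follow the mod-3 rule and reference is guarded", {
  ref <- toy_reference()
  tm <- toy_plus()
  a3 <- substr(ref, 159, 162)  # anchor + 3 deleted
  expect_equal(annotate_effect("chr1", 159, a3, substr(a3, 1, 1), tm, ref),
               "nonframeshift deletion")
  a2 <- substr(ref, 159, 161)
  expect_equal(annotate_effect("chr1", 159, a2, substr(a2, 1, 1), tm, ref),
               "frameshift deletion")
  b <- substr(ref, 160, 160)
  expect_equal(annotate_effect("chr1", 160, b, paste0(b, "AT"), tm, ref),
               "frameshift insertion")
  expect_equal(annotate_effect("chr1", 160, b, paste0(b, "ATA"), tm, ref),
               "nonframeshift insertion")
  wrong <- setdiff(c("A", "C", "G", "T"), substr(ref, 160, 160))[1]
  expect_error(annotate_effect("chr1", 160, wrong, "T", tm, ref),
               "reference mismatch")
})

test_that("catalog summary reproduces printed-style percentages", {
  rec <- data.frame(
    clin_class = c(rep("PV", 3), "VUS", rep("BV", 2)),
    gene = "G1", variant_type = "missense", stringsAsFactors = FALSE)
  s <- summarize_catalog(rec)
  expect_equal(s$class_counts$count, c(3L, 1L, 2L))
  expect_equal(sum(s$class_counts$pct), 100, tolerance = 0.11)

  one <- data.frame(clin_class = "PV", gene = "G1",
                    variant_type = "stopgain", stringsAsFactors = FALSE)
  expect_equal(summarize_catalog(one)$class_counts$pct[1], 100.0)
})

test_that("catalog VCF output is readable by an independent parser", {
  skip_if_not_installed("vcfR")
  tab <- rbind(catalog_row(pos = 110, hgvs = "c.11C>T"),
               catalog_row(pos = 100, hgvs = "c.1C>T"))
  rec <- parse_catalog(tab, founder_ids = "MLH1:c.1C>T")
  f <- tempfile(fileext = ".vcf")
  write_catalog_vcf(rec, f)
  v <- suppressWarnings(vcfR::read.vcfR(f, verbose = FALSE))
  expect_equal(as.integer(v@fix[, "POS"]), c(100L, 110L))
  expect_match(v@fix[1, "INFO"], "CLNCLASS=PV")
  expect_match(v@fix[1, "INFO"], "FOUNDER")
  expect_false(grepl("FOUNDER", v@fix[2, "INFO"]))
})
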