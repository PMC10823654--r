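# Deterministic synthetic-data generator: phylogeny, reference, transcript
# models, ClinVar-like catalog, MAF alignments with planted sharing, and
# damaged ancient reads with full truth sets.  Identical configs (same
# seed) reproduce byte-identical outputs; each stage draws from its own
# seed stream so stages stay independent.
#
# Damage model: single-stranded-overhang style -- independent per-base
# Bernoulli flips, C>T from the molecule 5' end and G>A from the 3' end,
# with probability d0 * exp(-lambda * offset).  Reads are uniform over the
# reference at fixed length; base qualities are constant Phred 37,
# including at artifact bases (the rescaler, not the simulator, handles
# them).

#' Simulation configuration
#'
#' Defaults define the standard synthetic study conditions: 10 species in
#' five clades, a 5 kb reference with two transcript models, 50 catalog
#' variants of which 5 carry conflicting interpretations, and a 20-sample
#' ancient cohort at 30x with damage d0 = 0.3, lambda = 0.3 per base.
#'
#' @param seed integer master seed.
#' @param n_species optional expected species count; it is an error for
#'   `clade_spec` not to sum to it.
#' @param clade_spec named integer vector, clade name -> species count; the
#'   first clade holds the human-analog reference species.
#' @param ref_length reference length in bases (>= 100).
#' @param n_variants_per_class named counts for `PV`, `BV`, `VUS`,
#'   `conflicting`.
#' @param coverage mean reads per base for ancient samples.
#' @param read_length ancient read length in bases.
#' @param damage_d0 damage probability at offset 0 (0-1).
#' @param damage_lambda exponential decay rate per base (>= 0).
#' @param mask_frac fraction of alignment columns soft-masked (lowercase).
#' @param n_samples ancient cohort size.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_species = NULL,
                       clade_spec = c(primate = 2L, euarchontoglires = 2L,
                                      laurasiatheria = 2L, aves = 2L,
                                      fish = 2L),
                       ref_length = 5000L,
                       n_variants_per_class = c(PV = 20L, BV = 15L, VUS = 15L,
                                                conflicting = 5L),
                       coverage = 30, read_length = 60L,
                       damage_d0 = 0.3, damage_lambda = 0.3,
                       mask_frac = 0.10, n_samples = 20L) {
  if (damage_d0 < 0 || damage_d0 > 1) stop("damage_d0 must lie in [0, 1]")
  if (damage_lambda < 0) stop("damage_lambda must be >= 0")
  if (coverage <= 0) stop("coverage must be positive")
  if (ref_length < 100) stop("ref_length must be at least 100")
  if (is.null(names(clade_spec)) || any(clade_spec < 1))
    stop("clade_spec must be a named vector of positive counts")
  if (!is.null(n_species) && sum(clade_spec) != n_species)
    stop("clade_spec counts sum to ", sum(clade_spec),
         ", not n_species = ", n_species)
  n_species <- sum(clade_spec)
  if (n_species < 2) stop("need at least 2 species")
  cfg <- list(seed = as.integer(seed), clade_spec = clade_spec,
              n_species = n_species, ref_length = as.integer(ref_length),
              n_variants_per_class = n_variants_per_class,
              coverage = coverage, read_length = as.integer(read_length),
              damage_d0 = damage_d0, damage_lambda = damage_lambda,
              mask_frac = mask_frac, n_samples = as.integer(n_samples))
  class(cfg) <- "sim_config"
  cfg
}

#' Species names of a configuration
#'
#' The reference species is `"human"`, first species of the first clade.
#'
#' @param config a [sim_config()].
#' @return character vector of species names, clade by clade.
#' @export
species_names <- function(config) {
  out <- character(0)
  for (j in seq_along(config$clade_spec)) {
    cl <- names(config$clade_spec)[j]
    nm <- paste0(cl, "_", seq_len(config$clade_spec[j]))
    if (j == 1) nm[1] <- "human"
    out <- c(out, nm)
  }
  out
}

#' Generate the species phylogeny
#'
#' Binary tree with strictly positive branch lengths; each clade is a
#' monophyletic balanced subtree and clades attach along a backbone with
#' stem lengths growing away from the reference clade, so later clades are
#' phylogenetically farther from the human analog.
#'
#' @param config a [sim_config()].
#' @return list with `tree` (`phylo`), `newick` (text) and `clade_map`
#'   (data.frame `species`, `clade`).
#' @export
make_phylogeny <- function(config) {
  sp <- species_names(config)
  clades <- rep(names(config$clade_spec), config$clade_spec)
  with_seed(config$seed + 101L, {
    bl <- function() sprintf("%.4f", stats::runif(1, 0.01, 0.06))
    build <- function(leaves) {
      if (length(leaves) == 1) return(leaves)
      k <- ceiling(length(leaves) / 2)
      sprintf("(%s:%s,%s:%s)", build(leaves[1:k]), bl(),
              build(leaves[(k + 1):length(leaves)]), bl())
    }
    subtrees <- vapply(names(config$clade_spec),
                       function(cl) build(sp[clades == cl]), character(1))
    acc <- subtrees[1]
    for (j in seq_along(subtrees)[-1]) {
      stem <- sprintf("%.4f", 0.05 * j + stats::runif(1, 0, 0.02))
      acc <- sprintf("(%s:%s,%s:%s)", acc, bl(), subtrees[j], stem)
    }
    newick <- paste0(acc, ";")
    list(tree = parse_newick(newick), newick = newick,
         clade_map = data.frame(species = sp, clade = clades,
                                stringsAsFactors = FALSE))
  })
}

#' Simulate the reference chromosome
#'
#' @param config a [sim_config()].
#' @return single DNA string of length `ref_length`, named `chr1`.
#' @export
simulate_reference <- function(config) {
  with_seed(config$seed + 7L, {
    s <- paste(sample(c("A", "C", "G", "T"), config$ref_length, replace = TRUE),
               collapse = "")
    stats::setNames(s, "chr1")
  })
}

#' Transcript models over the simulated reference
#'
#' Two fixed three-exon models: a plus-strand gene in the first half of the
#' reference and a minus-strand gene in the second half (to exercise
#' strand handling end to end).
#'
#' @param config a [sim_config()].
#' @return named list of [transcript_model()] objects.
#' @export
make_transcripts <- function(config) {
  if (config$ref_length < 5000)
    stop("default transcript models need ref_length >= 5000")
  list(
    MLH1 = transcript_model("MLH1", "chr1", "+",
                            data.frame(start = c(201, 901, 1601),
                                       end = c(700, 1400, 2100)),
                            cds_start = 251, cds_end = 2050),
    MSH2 = transcript_model("MSH2", "chr1", "-",
                            data.frame(start = c(2601, 3301, 4001),
                                       end = c(3100, 3800, 4500)),
                            cds_start = 4450, cds_end = 2651)
  )
}

# internal: one random variant spec on a transcript model
.random_variant <- function(model, reference, occupied) {
  L <- cds_length(model)
  for (attempt in 1:200) {
    kind <- sample(c("cds_snv", "splice_snv", "near_splice_snv",
                     "cds_del", "cds_ins"), 1,
                   prob = c(0.68, 0.06, 0.06, 0.14, 0.06))
    v <- NULL
    if (kind == "cds_snv") {
      cc <- sample(4:(L - 3), 1)
      g <- c_to_g(model, cc)
      ref <- toupper(ref_slice(reference, g, g))
      alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1)
      v <- list(pos = g, ref = ref, alt = alt)
    } else if (kind %in% c("splice_snv", "near_splice_snv")) {
      off <- if (kind == "splice_snv") sample(1:2, 1) else sample(3:5, 1)
      off <- off * sample(c(1L, -1L), 1)
      # anchor: exon-boundary CDS positions flanking an internal intron
      n_ex <- nrow(model$exons)
      bounds <- unlist(lapply(seq_len(n_ex - 1), function(i) {
        if (model$strand == "+") c(model$exons$end[i], model$exons$start[i + 1])
        else c(model$exons$start[i + 1], model$exons$end[i])
      }))
      bounds <- bounds[bounds %in% model$cds_gpos]
      anchor_g <- sample(bounds, 1)
      cc <- match(anchor_g, model$cds_gpos)
      # donor anchors take +, acceptor anchors take -
      dir <- if ((model$strand == "+") == (anchor_g %in% model$exons$end)) 1L else -1L
      off <- abs(off) * dir
      g <- tryCatch(c_to_g(model, cc, off), error = function(e) NULL)
      if (is.null(g)) next
      ref <- toupper(ref_slice(reference, g, g))
      alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1)
      v <- list(pos = g, ref = ref, alt = alt)
    } else if (kind == "cds_del") {
      len <- sample(1:4, 1)
      cc <- sample(4:(L - 3 - len), 1)
      gspan <- model$cds_gpos[cc:(cc + len - 1)]
      if (max(gspan) - min(gspan) != len - 1) next  # crosses an intron
      anchor <- min(gspan) - 1L
      if (anchor < 1 || is_exonic(model, anchor) == FALSE) next
      if (!(anchor %in% model$cds_gpos)) next
      v <- list(pos = anchor,
                ref = toupper(ref_slice(reference, anchor, max(gspan))),
                alt = toupper(ref_slice(reference, anchor, anchor)))
    } else {
      cc <- sample(4:(L - 4), 1)
      g1 <- model$cds_gpos[cc]; g2 <- model$cds_gpos[cc + 1]
      if (abs(g2 - g1) != 1) next
      anchor <- min(g1, g2)
      ins <- paste(sample(c("A", "C", "G", "T"), sample(1:3, 1), replace = TRUE),
                   collapse = "")
      base <- toupper(ref_slice(reference, anchor, anchor))
      v <- list(pos = anchor, ref = base, alt = paste0(base, ins))
    }
    foot <- (v$pos - 3L):(v$pos + nchar(v$ref) + 2L)
    if (any(foot %in% occupied)) next
    return(v)
  }
  stop("could not place a variant without collision")
}

#' Simulate a ClinVar-like catalog
#'
#' Emits records in all four label groups (PV/BV/VUS plus
#' conflicting-interpretation rows that downstream parsing must drop) with
#' mutually consistent genomic and c. names and effect types assigned by
#' [annotate_effect()].  Three PVs are designated founder variants.
#'
#' @param config a [sim_config()].
#' @param transcripts output of [make_transcripts()].
#' @param reference the simulated reference.
#' @return list with `table` (the raw TSV data.frame including conflicting
#'   rows), `founder_ids`, and `records` (the normalized usable records as
#'   [parse_catalog()] returns them).
#' @export
simulate_catalog <- function(config, transcripts, reference) {
  counts <- config$n_variants_per_class
  with_seed(config$seed + 211L, {
    sig_pool <- list(
      PV = c("Pathogenic", "Likely pathogenic", "Pathogenic/Likely pathogenic"),
      BV = c("Benign", "Likely benign", "Benign/Likely benign"),
      VUS = "Uncertain significance",
      conflicting = "Conflicting interpretations of pathogenicity")
    occupied <- integer(0)
    rows <- list()
    gi <- 0L
    for (cls in names(counts)) {
      for (k in seq_len(counts[[cls]])) {
        gi <- gi + 1L
        model <- transcripts[[(gi %% length(transcripts)) + 1L]]
        v <- .random_variant(model, reference, occupied)
        occupied <- c(occupied, (v$pos - 3L):(v$pos + nchar(v$ref) + 2L))
        rows[[gi]] <- data.frame(
          gene = model$gene, chrom = model$chrom, pos_1based = v$pos,
          ref = v$ref, alt = v$alt,
          hgvs_c = genomic_to_cds(model, v$pos, v$ref, v$alt),
          clinical_significance = sample(sig_pool[[cls]], 1),
          variant_type = annotate_effect(model$chrom, v$pos, v$ref, v$alt,
                                         model, reference),
          stringsAsFactors = FALSE)
      }
    }
    tab <- do.call(rbind, rows)
    pv_rows <- which(tab$clinical_significance %in% sig_pool$PV)
    founders <- sample(pv_rows, min(3L, length(pv_rows)))
    founder_ids <- paste0(tab$gene[founders], ":", tab$hgvs_c[founders])
    records <- suppressMessages(parse_catalog(tab, founder_ids = founder_ids))
    list(table = tab, founder_ids = founder_ids, records = records)
  })
}

#' Plant the cross-species sharing structure
#'
#' Sharing probability rises with clade rank (distance from the reference
#' clade) and is scaled per clinical class -- benign variants share widely,
#' pathogenic ones rarely -- emulating the gradient the cross-species
#' analysis is meant to detect.  Insertion variants are never planted as
#' shared.  Independently, each (variant, species) cell has a small chance
#' of being planted missing.
#'
#' @param config a [sim_config()].
#' @param records normalized catalog records.
#' @param clade_map data.frame `species`, `clade` from [make_phylogeny()].
#' @return list with elements `shared` and `missing`, each a list mapping
#'   variant_id -> character vector of species.
#' @export
plant_sharing <- function(config, records, clade_map) {
  sp <- setdiff(clade_map$species, "human")
  ranks <- match(clade_map$clade[match(sp, clade_map$species)],
                 names(config$clade_spec))
  K <- length(config$clade_spec)
  base_p <- seq(0.04, 0.40, length.out = K)[ranks]
  mult <- c(PV = 0.35, VUS = 1.2, BV = 2.2)
  with_seed(config$seed + 307L, {
    shared <- missing <- stats::setNames(vector("list", nrow(records)),
                                         records$variant_id)
    for (i in seq_len(nrow(records))) {
      p <- pmin(base_p * mult[[records$clin_class[i]]], 0.9)
      is_ins <- nchar(records$alt[i]) > nchar(records$ref[i])
      miss <- sp[stats::runif(length(sp)) < 0.08]
      rest <- setdiff(sp, miss)
      shr <- if (is_ins) character(0) else {
        idx <- match(rest, sp)
        rest[stats::runif(length(rest)) < p[idx]]
      }
      shared[[i]] <- shr
      missing[[i]] <- miss
    }
    list(shared = shared, missing = missing)
  })
}

#' Simulate MAF alignment blocks with planted sharing
#'
#' Builds one gapless alignment of all species to the reference, plants
#' shared alleles (alt base for SNVs, gaps over the deleted span for
#' deletions) and missing cells (gaps), soft-masks a fraction of columns,
#' slices the alignment into blocks (some non-reference rows emitted on the
#' negative strand, with MAF reverse-strand coordinates), and omits one
#' species from one block so an uncovered region exists.
#'
#' @param config a [sim_config()].
#' @param records normalized catalog records.
#' @param planted output of [plant_sharing()].
#' @param reference the simulated reference.
#' @param clade_map species/clade table.
#' @return list with `blocks` (for [write_maf()]), `truth` (variant x
#'   species character matrix of planted states) and `omitted`
#'   (species/interval of the dropped rows).
#' @export
simulate_alignment <- function(config, records, planted, reference, clade_map) {
  if (any(records$pos + nchar(records$ref) - 1L > config$ref_length) ||
      any(records$pos < 1L))
    stop("planted variant position outside the reference")
  sp_all <- clade_map$species
  sp_other <- setdiff(sp_all, "human")
  n <- config$ref_length
  refchars <- strsplit(toupper(reference[[1]]), NULL)[[1]]

  with_seed(config$seed + 401L, {
    rows <- stats::setNames(lapply(sp_all, function(s) refchars), sp_all)
    for (i in seq_len(nrow(records))) {
      v <- records[i, ]
      vid <- v$variant_id
      is_del <- nchar(v$ref) > nchar(v$alt)
      for (s in planted$shared[[vid]]) {
        if (is_del) {
          rows[[s]][(v$pos + 1L):(v$pos + nchar(v$ref) - 1L)] <- "-"
        } else if (nchar(v$ref) == 1 && nchar(v$alt) == 1) {
          rows[[s]][v$pos] <- v$alt
        }
      }
      for (s in planted$missing[[vid]]) rows[[s]][v$pos] <- "-"
    }
    mask_cols <- sort(sample.int(n, round(config$mask_frac * n)))
    for (s in sp_all) {
      sel <- rows[[s]][mask_cols] != "-"
      rows[[s]][mask_cols[sel]] <- tolower(rows[[s]][mask_cols[sel]])
    }

    # block boundaries clear of variant footprints
    n_blocks <- 5L
    cuts <- round(seq(0, n, length.out = n_blocks + 1L))
    foot <- unlist(lapply(seq_len(nrow(records)), function(i)
      (records$pos[i] - 1L):(records$pos[i] + nchar(records$ref[i]) + 1L)))
    for (b in 2:n_blocks) {
      while (cuts[b] %in% foot) cuts[b] <- cuts[b] + 1L
    }

    omit_species <- sp_other[length(sp_other)]
    omit_block <- 4L
    omitted <- list(species = omit_species,
                    start = cuts[omit_block] + 1L, end = cuts[omit_block + 1L])

    ungapped_sofar <- stats::setNames(integer(length(sp_all)), sp_all)
    total_ungapped <- stats::setNames(integer(length(sp_all)), sp_all)
    for (s in sp_all) {
      tot <- 0L
      for (b in seq_len(n_blocks)) {
        if (s == omit_species && b == omit_block) next
        seg <- rows[[s]][(cuts[b] + 1L):cuts[b + 1L]]
        tot <- tot + sum(seg != "-")
      }
      total_ungapped[s] <- tot
    }

    blocks <- list()
    for (b in seq_len(n_blocks)) {
      idx <- (cuts[b] + 1L):cuts[b + 1L]
      rws <- list()
      for (s in sp_all) {
        if (s == omit_species && b == omit_block) next
        text <- paste(rows[[s]][idx], collapse = "")
        size <- sum(rows[[s]][idx] != "-")
        start_plus <- ungapped_sofar[s]
        strand <- if (s != "human" && stats::runif(1) < 0.3) "-" else "+"
        start <- if (strand == "+") start_plus
                 else total_ungapped[s] - start_plus - size
        rws[[length(rws) + 1L]] <- data.frame(
          src = paste0(s, ".chr1"), start = start, size = size,
          strand = strand, src_size = total_ungapped[s], text = text,
          stringsAsFactors = FALSE)
        ungapped_sofar[s] <- ungapped_sofar[s] + size
      }
      blocks[[b]] <- list(score = 1000 - 10 * b,
                          rows = do.call(rbind, rws))
    }

    truth <- matrix("not_shared", nrow(records), length(sp_other),
                    dimnames = list(records$variant_id, sp_other))
    for (i in seq_len(nrow(records))) {
      vid <- records$variant_id[i]
      truth[i, planted$shared[[vid]]] <- "shared"
      truth[i, planted$missing[[vid]]] <- "missing"
      p <- records$pos[i]
      if (p >= omitted$start && p + nchar(records$ref[i]) - 1L <= omitted$end)
        truth[i, omit_species] <- "missing"
    }
    list(blocks = blocks, truth = truth, omitted = omitted)
  })
}

# Ancient cohort ---------------------------------------------------------

#' Default ancient-cohort metadata
#'
#' Twenty samples across six continents: most dated within the last 10,000
#' years, two older modern humans, one Neanderthal and one Denisovan --
#' the age structure the archeological arm expects (mostly Holocene, a
#' Pleistocene tail, and archaic hominins far older).
#'
#' @param config a [sim_config()].
#' @return validated metadata data.frame.
#' @export
default_metadata <- function(config) {
  regions <- c("Europe", "East Asia", "West Asia", "North America",
               "South America", "Africa", "Oceania")
  md <- data.frame(
    sample_id = sprintf("anc%02d", 1:20),
    date_lo = c(300, 700, 1200, 1800, 2300, 2900, 3400, 4100, 4800, 5300,
                5900, 6600, 7300, 8000, 8700, 9300, 12200, 28000, 42000, 60000),
    date_hi = c(500, 900, 1500, 2100, 2600, 3200, 3800, 4500, 5200, 5700,
                6400, 7100, 7800, 8500, 9200, 9800, 13100, 32000, 44600, 80000),
    lat = round(seq(-35, 62, length.out = 20), 2),
    lon = round(seq(-70, 130, length.out = 20), 2),
    region = regions[(0:19 %% length(regions)) + 1L],
    group = c(rep("modern_human", 18), "neanderthal", "denisovan"),
    stringsAsFactors = FALSE
  )
  md <- md[seq_len(min(config$n_samples, nrow(md))), , drop = FALSE]
  validate_metadata(md)
}

#' Default planted carriers
#'
#' Seven carriers of four distinct SNV pathogenic variants among the
#' modern-human samples (mostly heterozygous, one homozygote).
#'
#' @param config a [sim_config()].
#' @param records normalized catalog records.
#' @return data.frame `sample_id`, `variant_id`, `pos`, `ref`, `alt`,
#'   `dosage`.
#' @export
default_carriers <- function(config, records) {
  pv <- records[records$clin_class == "PV" &
                nchar(records$ref) == 1 & nchar(records$alt) == 1, ]
  pv <- pv[order(pv$pos), ]
  if (nrow(pv) < 4) stop("need at least 4 SNV pathogenic variants")
  pick <- pv[1:4, ]
  plan <- data.frame(
    sample_id = sprintf("anc%02d", 1:7),
    variant_idx = c(1, 1, 1, 2, 2, 3, 4),
    dosage = c(1, 1, 2, 1, 1, 1, 2))
  data.frame(sample_id = plan$sample_id,
             variant_id = pick$variant_id[plan$variant_idx],
             pos = pick$pos[plan$variant_idx],
             ref = pick$ref[plan$variant_idx],
             alt = pick$alt[plan$variant_idx],
             dosage = plan$dosage, stringsAsFactors = FALSE)
}

#' Simulate damaged ancient reads for one sample
#'
#' Uniform read placement at fixed length; planted variant alleles at the
#' requested dosage (heterozygotes draw each read's allele at 1/2);
#' terminal deamination as independent C>T (5') and G>A (3') flips in
#' molecule orientation with probability `d0 * exp(-lambda * offset)`;
#' every artifact is logged in the truth set.  Base qualities are constant
#' Phred 37 including at artifacts.
#'
#' @param config a [sim_config()].
#' @param reference the simulated reference.
#' @param sample_id sample label (also seeds the per-sample stream).
#' @param genotypes data.frame `pos`, `ref`, `alt`, `dosage` of SNV
#'   genotypes carried by the sample (0 rows for non-carriers).
#' @param n_reads read count; default `coverage * ref_length / read_length`.
#' @param sample_index integer used to derive the per-sample seed.
#' @return list with `reads` ([read_sam()] layout) and `artifacts`
#'   (data.frame `qname`, `offset`, `substitution`, `end`, `ref_pos`).
#' @export
simulate_ancient_reads <- function(config, reference, sample_id, genotypes,
                                   n_reads = NULL, sample_index = 1L) {
  L <- config$read_length
  n_ref <- config$ref_length
  if (nrow(genotypes) > 0 &&
      any(genotypes$pos < 1 | genotypes$pos > n_ref))
    stop("carrier variant outside the reference")
  if (is.null(n_reads))
    n_reads <- as.integer(round(config$coverage * n_ref / L))

  with_seed(config$seed + 1000L + sample_index, {
    starts <- sample.int(n_ref - L + 1L, n_reads, replace = TRUE)
    strand <- sample(c("+", "-"), n_reads, replace = TRUE)
    refchars <- strsplit(toupper(reference[[1]]), NULL)[[1]]
    fwd <- matrix(refchars[outer(starts, 0:(L - 1L), `+`)], ncol = L)

    for (gi in seq_len(nrow(genotypes))) {
      g <- genotypes[gi, ]
      covering <- which(starts <= g$pos & g$pos <= starts + L - 1L)
      if (length(covering) == 0) next
      takes_alt <- if (g$dosage >= 2) rep(TRUE, length(covering))
                   else stats::runif(length(covering)) < 0.5
      cols <- g$pos - starts[covering] + 1L
      sel <- covering[takes_alt]
      fwd[cbind(sel, cols[takes_alt])] <- toupper(g$alt)
    }

    # molecule orientation: reverse-complement the reverse-strand rows
    mol <- fwd
    rev_sel <- strand == "-"
    if (any(rev_sel)) {
      block <- mol[rev_sel, , drop = FALSE]
      block <- block[, L:1, drop = FALSE]
      block[] <- chartr("ACGT", "TGCA", block)
      mol[rev_sel, ] <- block
    }

    qnames <- sprintf("%s_r%05d", sample_id, seq_len(n_reads))
    p5 <- config$damage_d0 * exp(-config$damage_lambda * (0:(L - 1L)))
    artifacts <- list()

    is_c <- mol == "C"
    flip5 <- is_c & matrix(stats::runif(n_reads * L), ncol = L) <
      matrix(p5, n_reads, L, byrow = TRUE)
    if (any(flip5)) {
      w <- which(flip5, arr.ind = TRUE)
      artifacts[[1]] <- data.frame(
        qname = qnames[w[, 1]], offset = w[, 2] - 1L, substitution = "C>T",
        end = "5p", stringsAsFactors = FALSE)
      mol[flip5] <- "T"
    }
    is_g <- mol == "G"
    flip3 <- is_g & matrix(stats::runif(n_reads * L), ncol = L) <
      matrix(rev(p5), n_reads, L, byrow = TRUE)
    if (any(flip3)) {
      w <- which(flip3, arr.ind = TRUE)
      artifacts[[2]] <- data.frame(
        qname = qnames[w[, 1]], offset = L - w[, 2], substitution = "G>A",
        end = "3p", stringsAsFactors = FALSE)
      mol[flip3] <- "A"
    }
    artifacts <- if (length(artifacts)) do.call(rbind, artifacts)
                 else data.frame(qname = character(), offset = integer(),
                                 substitution = character(), end = character(),
                                 stringsAsFactors = FALSE)

    # back to reference orientation for the SAM records
    out_seq <- mol
    if (any(rev_sel)) {
      block <- out_seq[rev_sel, , drop = FALSE]
      block <- block[, L:1, drop = FALSE]
      block[] <- chartr("ACGT", "TGCA", block)
      out_seq[rev_sel, ] <- block
    }
    seqs <- apply(out_seq, 1, paste, collapse = "")
    # reference position of each artifact (for truth-set bookkeeping)
    if (nrow(artifacts) > 0) {
      ri <- match(artifacts$qname, qnames)
      molcol <- ifelse(artifacts$end == "5p", artifacts$offset + 1L,
                       L - artifacts$offset)
      refcol <- ifelse(strand[ri] == "+", molcol, L + 1L - molcol)
      artifacts$ref_pos <- starts[ri] + refcol - 1L
    } else artifacts$ref_pos <- integer(0)

    reads <- data.frame(
      qname = qnames,
      flag = ifelse(rev_sel, 16L, 0L),
      chrom = "chr1", pos = starts, mapq = 60L,
      seq = seqs, qual = strrep("F", L),  # Phred 37
      strand = strand, duplicate = FALSE, unmapped = FALSE,
      stringsAsFactors = FALSE)
    reads <- reads[order(reads$pos), , drop = FALSE]
    rownames(reads) <- NULL
    list(reads = reads, artifacts = artifacts)
  })
}

#' Run the whole generator
#'
#' Produces every pipeline input in memory: phylogeny, reference,
#' transcripts, catalog (with conflicting rows and founder list), planted
#' sharing, MAF blocks with truth, cohort metadata, carriers, and per-sample
#' damaged reads with artifact truth sets.
#'
#' @param config a [sim_config()].
#' @param ancient generate the ancient cohort too (default `TRUE`).
#' @return named list bundle of all simulated objects.
#' @export
simulate_bundle <- function(config = sim_config(), ancient = TRUE) {
  phy <- make_phylogeny(config)
  reference <- simulate_reference(config)
  transcripts <- make_transcripts(config)
  cat_sim <- simulate_catalog(config, transcripts, reference)
  planted <- plant_sharing(config, cat_sim$records, phy$clade_map)
  aln <- simulate_alignment(config, cat_sim$records, planted, reference,
                            phy$clade_map)
  out <- list(config = config, phylogeny = phy, reference = reference,
              transcripts = transcripts, catalog = cat_sim,
              planted = planted, alignment = aln)
  if (ancient) {
    md <- default_metadata(config)
    carriers <- default_carriers(config, cat_sim$records)
    samples <- list()
    for (i in seq_len(nrow(md))) {
      sid <- md$sample_id[i]
      gt <- carriers[carriers$sample_id == sid,
                     c("pos", "ref", "alt", "dosage"), drop = FALSE]
      samples[[sid]] <- simulate_ancient_reads(config, reference, sid, gt,
                                               sample_index = i)
    }
    out$metadata <- md
    out$carriers <- carriers
    out$samples <- samples
  }
  out
}

#' Write a simulated bundle to disk
#'
#' Emits the standard file formats: `reference.fa`, `tree.nwk`,
#' `clades.tsv`, `catalog.tsv`, `founders.txt`, `alignment.maf`,
#' `metadata.tsv`, one SAM per ancient sample under `sam/`, and
#' `truth.json`.
#'
#' @param bundle output of [simulate_bundle()].
#' @param outdir output directory (created).
#' @return `outdir`, invisibly.
#' @export
simulate_all <- function(bundle, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(bundle$reference, file.path(outdir, "reference.fa"))
  writeLines(bundle$phylogeny$newick, file.path(outdir, "tree.nwk"))
  utils::write.table(bundle$phylogeny$clade_map, file.path(outdir, "clades.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(bundle$catalog$table, file.path(outdir, "catalog.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(bundle$catalog$founder_ids, file.path(outdir, "founders.txt"))
  write_maf(bundle$alignment$blocks, file.path(outdir, "alignment.maf"))
  truth <- list(
    sharing = apply(bundle$alignment$truth, 1, as.list),
    omitted = bundle$alignment$omitted)
  if (!is.null(bundle$samples)) {
    utils::write.table(bundle$metadata, file.path(outdir, "metadata.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    dir.create(file.path(outdir, "sam"), showWarnings = FALSE)
    for (sid in names(bundle$samples)) {
      write_sam(bundle$samples[[sid]]$reads,
                file.path(outdir, "sam", paste0(sid, ".sam")),
                ref_name = "chr1", ref_len = bundle$config$ref_length)
    }
    truth$carriers <- bundle$carriers
    truth$n_artifacts <- vapply(bundle$samples,
                                function(s) nrow(s$artifacts), integer(1))
  }
  jsonlite::write_json(truth, file.path(outdir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(outdir)
}
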