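# Cross-species allele extraction and sharing classification.
#
# For each human variant, the aligned base(s) of every non-human species are
# read out of the MAF blocks covering the variant's reference footprint
# (1 base for a SNV, anchor + deleted span for deletions, the anchor for
# insertions).  Unaligned or gapped spans are missing data.  A species
# "shares" a variant when its aligned state equals the human alternate
# allele (case-insensitive; soft-masked lowercase bases are compared but
# flagged).  Overlapping blocks: the highest-scoring block covering the
# footprint wins, ties broken by file order; a species absent from that
# block is missing (no rescue from lower-scoring blocks).

# internal: chrom part of a MAF src field
maf_chrom <- function(src) sub("^[^.]*\\.", "", src)

#' Look up the aligned allele of one species at one variant
#'
#' @param variant list or one-row data.frame with `chrom`, `pos` (1-based),
#'   `ref`, `alt`.
#' @param blocks MAF blocks from [read_maf()].
#' @param species species name to extract.
#' @param reference_species name of the human-analog reference species in
#'   the MAF.
#' @return list with `species`, `bases` (gapped text over the footprint, or
#'   `NA`), `ins_bases` (text of human-gap columns after the anchor, for
#'   insertion variants), `masked` (any lowercase base), `block_score`,
#'   `missing`, `reason`.
#' @export
lookup_species_allele <- function(variant, blocks, species,
                                  reference_species = "human") {
  fp_len <- max(nchar(variant$ref), 1L)
  p0 <- variant$pos - 1L                       # 0-based footprint start
  obs <- list(species = species, bases = NA_character_, ins_bases = "",
              masked = FALSE, block_score = NA_real_,
              missing = TRUE, reason = "uncovered")

  # covering blocks, by the reference species row
  cover <- list()
  for (bi in seq_along(blocks)) {
    r <- blocks[[bi]]$rows
    hi <- which(vapply(r$src, maf_species, character(1)) == reference_species &
                vapply(r$src, maf_chrom, character(1)) == variant$chrom)
    if (length(hi) != 1) next
    h <- r[hi, ]
    if (h$strand != "+") next                  # reference rows are forward
    if (h$start <= p0 && (p0 + fp_len) <= h$start + h$size)
      cover[[length(cover) + 1L]] <- list(block = blocks[[bi]], href = h, ord = bi)
  }
  if (length(cover) == 0) return(obs)

  scores <- vapply(cover, function(x) x$block$score, numeric(1))
  best <- cover[[which.max(ifelse(is.na(scores), -Inf, scores))]]

  # map reference ungapped offsets to alignment columns
  hchars <- strsplit(best$href$text, NULL)[[1]]
  ungapped_idx <- cumsum(hchars != "-")        # 1-based ungapped count per col
  want <- (p0 - best$href$start + 1L):(p0 - best$href$start + fp_len)
  cols <- match(want, ungapped_idx)            # first col where count reached
  stopifnot(!anyNA(cols))

  srows <- best$block$rows
  si <- which(vapply(srows$src, maf_species, character(1)) == species)
  if (length(si) == 0) {
    obs$reason <- "absent"
    obs$block_score <- best$block$score
    return(obs)
  }
  schars <- strsplit(srows$text[si[1]], NULL)[[1]]
  bases <- paste(schars[cols], collapse = "")

  ins_bases <- ""
  if (nchar(variant$alt) > nchar(variant$ref)) {
    # inserted sequence lives in human-gap columns right after the anchor
    j <- cols[length(cols)] + 1L
    while (j <= length(hchars) && hchars[j] == "-") {
      if (schars[j] != "-") ins_bases <- paste0(ins_bases, schars[j])
      j <- j + 1L
    }
  }

  obs$bases <- bases
  obs$ins_bases <- ins_bases
  obs$masked <- grepl("[acgtn]", bases)
  obs$block_score <- best$block$score
  obs$missing <- FALSE
  obs$reason <- ""
  obs
}

#' Classify sharing of one observation
#'
#' A species is `shared` when its aligned state equals the human alternate
#' allele: equal base for SNVs, the post-deletion haplotype (gaps over the
#' deleted span) for deletions, the inserted sequence present between the
#' anchor columns for insertions.  Gapped/unaligned spans propagate as
#' `missing`; anything else is `not_shared`.
#'
#' @param variant list with `ref`, `alt`.
#' @param obs result of [lookup_species_allele()].
#' @return one of `"shared"`, `"not_shared"`, `"missing"`.
#' @export
classify_sharing <- function(variant, obs) {
  if (isTRUE(obs$missing)) return("missing")
  ref <- toupper(variant$ref); alt <- toupper(variant$alt)
  bases <- obs$bases

  if (nchar(ref) == 1 && nchar(alt) == 1) {          # SNV
    if (bases == "-") return("missing")
    return(if (toupper(bases) == alt) "shared" else "not_shared")
  }
  if (nchar(ref) > nchar(alt)) {                     # deletion
    anchor <- substr(bases, 1, 1)
    if (anchor == "-") return("missing")
    if (gsub("-", "", toupper(bases)) == alt) return("shared")
    return("not_shared")
  }
  # insertion: anchor must align; inserted sequence must appear in the
  # human-gap columns
  anchor <- substr(bases, 1, 1)
  if (anchor == "-") return("missing")
  ins <- substr(alt, 2, nchar(alt))
  if (toupper(obs$ins_bases) == ins && toupper(anchor) == ref) return("shared")
  "not_shared"
}

#' Build the full variant-by-species sharing matrix
#'
#' @param catalog parsed catalog ([parse_catalog()]).
#' @param blocks MAF blocks ([read_maf()]).
#' @param species_list species to score (the tree's leaves minus the
#'   reference); MAF species outside this list are excluded with a warning.
#' @param reference_species reference species name in the MAF.
#' @return list with `long` (variant_id, species, state, masked,
#'   block_score), `matrix` (variant x species character matrix of states),
#'   `per_variant` (shared-species counts) and `per_species` (shared-variant
#'   counts split by clin_class).
#' @export
build_sharing_matrix <- function(catalog, blocks, species_list,
                                 reference_species = "human") {
  maf_sp <- unique(unlist(lapply(blocks, function(b)
    vapply(b$rows$src, maf_species, character(1)))))
  extra <- setdiff(maf_sp, c(species_list, reference_species))
  if (length(extra))
    warning("MAF species not in species list, excluded: ",
            paste(extra, collapse = ", "))
  species_list <- setdiff(species_list, reference_species)

  n_v <- nrow(catalog); n_s <- length(species_list)
  state <- matrix(NA_character_, n_v, n_s,
                  dimnames = list(catalog$variant_id, species_list))
  masked <- matrix(FALSE, n_v, n_s)
  score <- matrix(NA_real_, n_v, n_s)
  for (i in seq_len(n_v)) {
    v <- catalog[i, ]
    for (j in seq_len(n_s)) {
      obs <- lookup_species_allele(v, blocks, species_list[j], reference_species)
      state[i, j] <- classify_sharing(v, obs)
      masked[i, j] <- isTRUE(obs$masked)
      score[i, j] <- obs$block_score
    }
  }

  long <- data.frame(
    variant_id = rep(catalog$variant_id, times = n_s),
    species = rep(species_list, each = n_v),
    state = as.vector(state),
    masked = as.vector(masked),
    block_score = as.vector(score),
    stringsAsFactors = FALSE
  )
  per_variant <- data.frame(
    variant_id = catalog$variant_id,
    clin_class = catalog$clin_class,
    n_shared = rowSums(state == "shared"),
    n_not_shared = rowSums(state == "not_shared"),
    n_missing = rowSums(state == "missing"),
    stringsAsFactors = FALSE
  )
  per_species <- data.frame(species = species_list, stringsAsFactors = FALSE)
  for (k in c("PV", "BV", "VUS")) {
    sel <- catalog$clin_class == k
    per_species[[paste0("shared_", k)]] <-
      if (any(sel)) colSums(state[sel, , drop = FALSE] == "shared") else 0L
  }
  list(long = long, matrix = state, per_variant = per_variant,
       per_species = per_species)
}

#' Aggregate sharing by clade along the tree
#'
#' Orders species by [heatmap_order()] (reference clade first), attaches
#' clades and patristic distance to the reference, and groups per-species
#' shared-PV counts by clade for the Kruskal-Wallis comparison.
#'
#' @param sharing result of [build_sharing_matrix()].
#' @param clade_map data.frame with columns `species`, `clade` (or a named
#'   character vector).
#' @param tree the species tree (`phylo`).
#' @param reference_species reference leaf label.
#' @return list with `species_table` (ordered per-species table) and
#'   `clade_groups` (clade -> per-species shared-PV counts).
#' @export
aggregate_by_clade <- function(sharing, clade_map, tree,
                               reference_species = "human") {
  if (!is.data.frame(clade_map))
    clade_map <- data.frame(species = names(clade_map),
                            clade = unname(clade_map), stringsAsFactors = FALSE)
  ps <- sharing$per_species
  uncovered <- setdiff(ps$species, clade_map$species)
  if (length(uncovered))
    stop("clade_map does not cover species: ", paste(uncovered, collapse = ", "))

  ord <- heatmap_order(tree, reference_species)
  ord <- ord[ord %in% ps$species]
  tab <- ps[match(ord, ps$species), , drop = FALSE]
  tab$clade <- clade_map$clade[match(tab$species, clade_map$species)]
  dm <- patristic_matrix(tree)
  tab$dist_to_reference <- dm[reference_species, tab$species]
  rownames(tab) <- NULL

  clade_levels <- unique(tab$clade)
  groups <- lapply(clade_levels, function(cl) tab$shared_PV[tab$clade == cl])
  names(groups) <- clade_levels
  list(species_table = tab, clade_groups = groups)
}

#' Contingency table of shared variants against functional domains
#'
#' Counts shared vs unshared variants inside vs outside the union of domain
#' intervals (0-based half-open), ready for a chi-squared test.
#'
#' @param variants data.frame with `pos` (1-based genomic) and logical
#'   `shared`.
#' @param domains data.frame with `start`, `end` (0-based half-open);
#'   overlapping intervals are merged with a warning.  May be empty.
#' @return 2x2 integer matrix, rows `inside`/`outside`, columns
#'   `shared`/`unshared`.
#' @export
domain_overlap_table <- function(variants, domains) {
  inside <- rep(FALSE, nrow(variants))
  if (!is.null(domains) && nrow(domains) > 0) {
    d <- domains[order(domains$start), c("start", "end"), drop = FALSE]
    merged <- d[1, , drop = FALSE]
    overlapped <- FALSE
    if (nrow(d) > 1) for (i in 2:nrow(d)) {
      last <- nrow(merged)
      if (d$start[i] < merged$end[last]) {
        overlapped <- TRUE
        merged$end[last] <- max(merged$end[last], d$end[i])
      } else merged <- rbind(merged, d[i, ])
    }
    if (overlapped) warning("overlapping domain intervals merged")
    p0 <- variants$pos - 1L                     # 0-based position
    for (i in seq_len(nrow(merged)))
      inside <- inside | (p0 >= merged$start[i] & p0 < merged$end[i])
  }
  m <- matrix(c(sum(inside & variants$shared), sum(inside & !variants$shared),
                sum(!inside & variants$shared), sum(!inside & !variants$shared)),
              nrow = 2, byrow = TRUE,
              dimnames = list(c("inside", "outside"), c("shared", "unshared")))
  storage.mode(m) <- "integer"
  m
}

#' Write sharing results as TSV
#'
#' @param sharing result of [build_sharing_matrix()].
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_sharing_tables <- function(sharing, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(sharing$long, file.path(dir, "sharing_long.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(sharing$per_species, file.path(dir, "sharing_per_species.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(sharing$per_variant, file.path(dir, "sharing_per_variant.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
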