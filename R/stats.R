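# Statistical layer: tie-corrected Kruskal-Wallis, Benjamini-Hochberg
# adjustment, Pearson chi-squared, printed-style proportions, and report
# assembly.  The test engines are base R (kruskal.test, chisq.test,
# p.adjust); this module owns validation, the refusal rules for degenerate
# input, and the result container.

new_test_result <- function(statistic, df, p_value, method, adjusted_p = NA_real_) {
  out <- list(statistic = unname(statistic), df = unname(df),
              p_value = unname(p_value), adjusted_p = adjusted_p,
              method = method)
  class(out) <- "paleovar_test"
  out
}

#' @export
print.paleovar_test <- function(x, ...) {
  cat(x$method, ": statistic =", signif(x$statistic, 6), ", df =", x$df,
      ", p =", signif(x$p_value, 4))
  if (!is.na(x$adjusted_p)) cat(", adjusted p =", signif(x$adjusted_p, 4))
  cat("\n")
  invisible(x)
}

#' Kruskal-Wallis rank-sum test on grouped values
#'
#' Tie-corrected Kruskal-Wallis H with the chi-squared approximation on
#' k-1 degrees of freedom.  Requires at least two non-empty groups; a
#' single group is refused.  When every pooled value is identical there is
#' no rank variation and the test degenerates to H = 0, p = 1.
#'
#' @param groups named list of numeric vectors (group label -> per-unit
#'   values).
#' @return a `paleovar_test` result.
#' @export
#' @examples
#' kruskal_wallis(list(a = 1:3, b = 4:6, c = 7:9))  # H = 7.2
kruskal_wallis <- function(groups) {
  if (!is.list(groups) || length(groups) < 2)
    stop("Kruskal-Wallis needs at least two groups; got ",
         if (is.list(groups)) length(groups) else 1,
         " (a single-clade comparison is undefined)")
  sizes <- lengths(groups)
  if (any(sizes == 0)) stop("every group needs at least one value")
  if (sum(sizes) < 3) stop("needs at least 3 values in total")
  pooled <- unlist(groups)
  if (length(unique(pooled)) == 1)
    return(new_test_result(0, length(groups) - 1L, 1,
                           "Kruskal-Wallis rank sum test"))
  ht <- stats::kruskal.test(groups)
  new_test_result(ht$statistic, ht$parameter, ht$p.value,
                  "Kruskal-Wallis rank sum test")
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param p_values numeric vector of p values in `[0, 1]`.
#' @return adjusted values, in input order, capped at 1.
#' @export
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03, 0.04))  # all 0.04
bh_adjust <- function(p_values) {
  if (any(is.na(p_values)) || any(p_values < 0 | p_values > 1))
    stop("p values must lie in [0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

#' Pearson chi-squared test on a contingency table
#'
#' No continuity correction by default (a flag is provided); zero margins
#' are refused.
#'
#' @param table counts matrix.
#' @param correct apply the Yates continuity correction (default `FALSE`).
#' @return a `paleovar_test` result.
#' @export
#' @examples
#' chi_squared(matrix(c(20, 10, 10, 20), 2))  # statistic 20/3
chi_squared <- function(table, correct = FALSE) {
  table <- as.matrix(table)
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop("contingency table has a zero margin")
  ht <- suppressWarnings(stats::chisq.test(table, correct = correct))
  new_test_result(ht$statistic, ht$parameter, ht$p.value,
                  "Pearson chi-squared test")
}

#' Printed-style proportion
#'
#' `100 * numerator / denominator`, rounded half away from zero to one
#' decimal -- the convention under which every reported percentage is
#' printed.
#'
#' @param numerator,denominator counts, `0 <= numerator <= denominator`,
#'   `denominator > 0`.
#' @return percentage with one decimal.
#' @export
#' @examples
#' proportion(197, 3369)  # 5.8
#' proportion(119, 121)   # 98.3
proportion <- function(numerator, denominator) {
  if (denominator <= 0) stop("denominator must be positive")
  if (numerator < 0 || numerator > denominator)
    stop("numerator must lie in [0, denominator]")
  round_half_up(100 * numerator / denominator, 1)
}

#' Assemble the result bundle
#'
#' Collects the analogs of the study's result tables: catalog summary,
#' per-species/per-clade sharing with the clade-level Kruskal-Wallis test,
#' per-gene PV/BV/VUS sharing comparisons (BH-adjusted as one family over
#' the genes), founder sharing, domain contingency, and the ancient
#' chronology/geography tables.  Significance is declared at adjusted
#' p < `alpha` (default 0.01, two-sided).
#'
#' @param catalog_summary [summarize_catalog()] output.
#' @param clade_aggregation [aggregate_by_clade()] output.
#' @param sharing [build_sharing_matrix()] output.
#' @param catalog the parsed catalog (for the founder and per-gene tables).
#' @param ancient [chronology_summary()] output, or `NULL` when the
#'   ancient arm was not run.
#' @param domain_table optional 2x2 matrix from [domain_overlap_table()].
#' @param alpha significance threshold on adjusted p values.
#' @return list with elements `catalog`, `species_sharing`, `clade_test`,
#'   `gene_class_tests`, `founder`, `domains`, `ancient`; missing
#'   prerequisites raise an error naming the stage.
#' @export
build_report <- function(catalog_summary, clade_aggregation, sharing, catalog,
                         ancient = NULL, domain_table = NULL, alpha = 0.01) {
  for (nm in c("catalog_summary", "clade_aggregation", "sharing", "catalog")) {
    if (is.null(get(nm)))
      stop("missing upstream table: ", nm)
  }
  st <- clade_aggregation$species_table

  clade_kw <- kruskal_wallis(clade_aggregation$clade_groups)
  clade_kw$adjusted_p <- bh_adjust(clade_kw$p_value)

  # per-gene comparison of PV vs BV vs VUS per-species shared counts,
  # BH-corrected across the genes as one family
  genes <- sort(unique(catalog$gene))
  gene_tests <- list()
  for (g in genes) {
    counts <- list()
    for (k in c("PV", "BV", "VUS")) {
      sel <- catalog$clin_class == k & catalog$gene == g
      counts[[k]] <- if (any(sel))
        colSums(sharing$matrix[sel, , drop = FALSE] == "shared") else NULL
    }
    counts <- Filter(Negate(is.null), counts)
    gene_tests[[g]] <- if (length(counts) >= 2) kruskal_wallis(counts) else NULL
  }
  gene_tests <- Filter(Negate(is.null), gene_tests)
  if (length(gene_tests)) {
    adj <- bh_adjust(vapply(gene_tests, `[[`, numeric(1), "p_value"))
    for (i in seq_along(gene_tests)) {
      gene_tests[[i]]$adjusted_p <- adj[i]
      gene_tests[[i]]$significant <- adj[i] < alpha
    }
  }

  founder_tab <- merge(
    catalog[catalog$founder & catalog$clin_class == "PV",
            c("variant_id", "gene", "hgvs_c")],
    sharing$per_variant[, c("variant_id", "n_shared")], by = "variant_id")

  domains <- if (!is.null(domain_table)) {
    list(table = domain_table, test = chi_squared(domain_table))
  } else NULL

  list(catalog = catalog_summary,
       species_sharing = st,
       clade_test = clade_kw,
       gene_class_tests = gene_tests,
       founder = founder_tab,
       domains = domains,
       ancient = ancient)
}
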