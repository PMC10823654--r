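# Phylogeny handling: parsing, patristic distances, display ordering.
# Trees are consumed as written (no re-rooting, no ladderization); the
# heavy lifting is delegated to 'ape'.

#' Parse a newick tree
#'
#' Reads a rooted newick string (or file) into an `ape::phylo` object,
#' enforcing the invariants the downstream analyses rely on: unique leaf
#' names, branch lengths present and non-negative.
#'
#' @param text newick string (used when `file` is `NULL`).
#' @param file optional path to a newick file.
#' @return an object of class `phylo`.
#' @export
#' @examples
#' tr <- parse_newick("((A:1,B:1):1,C:3);")
#' patristic_distance(tr, "A", "C")  # 5
parse_newick <- function(text = NULL, file = NULL) {
  if (!is.null(file)) text <- paste(readLines(file, warn = FALSE), collapse = "")
  stopifnot(is.character(text), length(text) == 1)
  # locate unbalanced parentheses before handing to ape, to report an offset
  chars <- strsplit(text, NULL)[[1]]
  depth <- 0L
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") depth <- depth - 1L
    if (depth < 0L) stop("unbalanced ')' at character ", i)
  }
  if (depth != 0L) stop("unbalanced '(' : ", depth, " unclosed at end of text")
  tree <- ape::read.tree(text = text)
  if (is.null(tree)) stop("newick parse failure")
  if (anyDuplicated(tree$tip.label))
    stop("duplicate leaf name: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]), collapse = ", "))
  if (is.null(tree$edge.length))
    stop("tree has no branch lengths")
  if (any(is.na(tree$edge.length)) || any(tree$edge.length < 0))
    stop("branch lengths must all be present and non-negative")
  tree
}

#' Patristic distance between two leaves
#'
#' Sum of branch lengths along the unique path between `leaf_a` and
#' `leaf_b`; symmetric, and zero iff the two labels are equal.
#'
#' @param tree a `phylo` tree.
#' @param leaf_a,leaf_b leaf labels.
#' @return numeric distance.
#' @export
patristic_distance <- function(tree, leaf_a, leaf_b) {
  for (lf in c(leaf_a, leaf_b))
    if (!lf %in% tree$tip.label) stop("unknown leaf: ", lf)
  if (leaf_a == leaf_b) return(0)
  d <- patristic_matrix(tree)
  d[leaf_a, leaf_b]
}

#' All-pairs patristic distance matrix
#'
#' @param tree a `phylo` tree.
#' @return symmetric numeric matrix with leaf labels as dimnames.
#' @export
patristic_matrix <- function(tree) {
  ape::cophenetic.phylo(tree)
}

#' Species display order following the tree
#'
#' Depth-first leaf order with, at every internal node, the child subtree
#' containing the designated reference leaf visited first.  The reference
#' (human-analog) species therefore comes first, followed by its closest
#' clade, and the order is deterministic for a given tree.
#'
#' @param tree a `phylo` tree.
#' @param reference leaf label of the reference species.
#' @return character vector of leaf labels.
#' @export
heatmap_order <- function(tree, reference) {
  if (!reference %in% tree$tip.label) stop("reference leaf not in tree: ", reference)
  n_tip <- length(tree$tip.label)
  children <- split(tree$edge[, 2], tree$edge[, 1])
  ref_id <- match(reference, tree$tip.label)

  contains_ref <- function(node) {
    if (node <= n_tip) return(node == ref_id)
    any(vapply(children[[as.character(node)]], contains_ref, logical(1)))
  }
  walk <- function(node) {
    if (node <= n_tip) return(tree$tip.label[node])
    kids <- children[[as.character(node)]]
    has_ref <- vapply(kids, contains_ref, logical(1))
    kids <- c(kids[has_ref], kids[!has_ref])  # stable: file order otherwise
    unlist(lapply(kids, walk))
  }
  root <- setdiff(tree$edge[, 1], tree$edge[, 2])[1]
  walk(root)
}

#' Export leaf-to-leaf distances as a long table
#'
#' @param tree a `phylo` tree.
#' @param path optional TSV output path.
#' @return data.frame with columns `leaf_a`, `leaf_b`, `distance`.
#' @export
distance_table <- function(tree, path = NULL) {
  m <- patristic_matrix(tree)
  df <- data.frame(
    leaf_a = rep(rownames(m), times = ncol(m)),
    leaf_b = rep(colnames(m), each = nrow(m)),
    distance = as.vector(m),
    stringsAsFactors = FALSE
  )
  df <- df[df$leaf_a < df$leaf_b, ]
  rownames(df) <- NULL
  if (!is.null(path))
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  df
}
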