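# Multiple alignment format (MAF) block reader/writer.
#
# MAF dialect: '##maf' header, 'a' lines opening a block, 's' lines holding
# per-species rows with 0-based strand-relative starts, ungapped sizes,
# source sizes and gapped text.  'e', 'i' and 'q' lines are tolerated and
# skipped.  Written and read as plain text; no compression.

#' Read MAF alignment blocks
#'
#' @param path MAF file.
#' @return list of blocks; each block is a list with `score` (numeric) and
#'   `rows` (data.frame: `src`, `start`, `size`, `strand`, `src_size`,
#'   `text`).  Species name is `src` up to the first `.`.
#' @export
read_maf <- function(path) {
  lines <- readLines(path, warn = FALSE)
  blocks <- list()
  cur <- NULL
  ordinal <- 0L

  flush <- function(cur) {
    if (is.null(cur) || length(cur$rows) == 0) return(NULL)
    rows <- do.call(rbind, cur$rows)
    widths <- nchar(rows$text)
    if (length(unique(widths)) != 1)
      stop("MAF block ", cur$ordinal, ": row texts have unequal lengths")
    ungapped <- nchar(gsub("-", "", rows$text))
    if (any(ungapped != rows$size))
      stop("MAF block ", cur$ordinal,
           ": ungapped text length disagrees with size field")
    list(score = cur$score, rows = rows)
  }

  for (ln in lines) {
    if (!nzchar(ln) || startsWith(ln, "#")) next
    tag <- substr(ln, 1, 1)
    if (tag == "a") {
      b <- flush(cur)
      if (!is.null(b)) blocks[[length(blocks) + 1L]] <- b
      ordinal <- ordinal + 1L
      score <- NA_real_
      m <- regmatches(ln, regexec("score=([-0-9.eE+]+)", ln))[[1]]
      if (length(m) == 2) score <- as.numeric(m[2])
      cur <- list(score = score, rows = list(), ordinal = ordinal)
    } else if (tag == "s") {
      if (is.null(cur)) stop("MAF: 's' line before any 'a' line")
      f <- strsplit(trimws(ln), "[ \t]+")[[1]]
      if (length(f) != 7) stop("MAF block ", ordinal, ": malformed s line")
      cur$rows[[length(cur$rows) + 1L]] <- data.frame(
        src = f[2], start = as.integer(f[3]), size = as.integer(f[4]),
        strand = f[5], src_size = as.integer(f[6]), text = f[7],
        stringsAsFactors = FALSE)
    }
    # 'e', 'i', 'q' lines: skipped
  }
  b <- flush(cur)
  if (!is.null(b)) blocks[[length(blocks) + 1L]] <- b
  blocks
}

#' Write MAF alignment blocks
#'
#' @param blocks list of blocks as returned by [read_maf()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_maf <- function(blocks, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##maf version=1 scoring=synthetic", con)
  for (b in blocks) {
    writeLines("", con)
    writeLines(sprintf("a score=%.1f", b$score), con)
    r <- b$rows
    for (i in seq_len(nrow(r))) {
      writeLines(sprintf("s %s %d %d %s %d %s", r$src[i], r$start[i],
                         r$size[i], r$strand[i], r$src_size[i], r$text[i]), con)
    }
  }
  invisible(path)
}

#' Forward-strand interval of a MAF row
#'
#' For a `-` strand row, MAF starts count from the reverse-strand origin;
#' the forward-strand 0-based half-open interval is
#' `[src_size - start - size, src_size - start)`.
#'
#' @param row one row of a block's `rows` data.frame (a one-row data.frame
#'   or list with `start`, `size`, `strand`, `src_size`).
#' @return integer vector `c(start, end)`, 0-based half-open, forward strand.
#' @export
maf_forward_coords <- function(row) {
  if (row$strand == "+") {
    c(start = row$start, end = row$start + row$size)
  } else {
    c(start = row$src_size - row$start - row$size,
      end = row$src_size - row$start)
  }
}

# internal: species name from a MAF src field ("species.chrom")
maf_species <- function(src) sub("\\..*$", "", src)
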