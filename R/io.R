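# Valid histone marks and chromatin states used throughout the package.
MARKS <- c("K4me3", "K27me3")
STATES <- c("K4", "K27", "BIVALENT", "NONE")

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read ChIP-seq peak calls from a BED file
#'
#' Reads a BED3+ file and tags every record with a histone mark and a
#' condition label.  Coordinates follow the BED convention: 0-based,
#' half-open.  `track`, `browser` and `#` comment lines are skipped.  When a
#' fifth column is present it is interpreted as the peak score.
#'
#' @param path Path to a tab-separated BED file.
#' @param mark Histone mark of the peaks, `"K4me3"` or `"K27me3"`.
#' @param condition Non-empty condition label (e.g. the cell line).
#' @return A data frame of class `peak_calls` with columns `chrom`, `start`,
#'   `end`, `score`, `mark`, `condition`, in file order.
#' @examples
#' bed <- tempfile(fileext = ".bed")
#' writeLines("chr1\t100\t500", bed)
#' read_bed(bed, mark = "K4me3", condition = "TG1")
#' @export
read_bed <- function(path, mark, condition) {
  if (!file.exists(path)) stop("file not found: ", path)
  mark <- match.arg(mark, MARKS)
  if (!is.character(condition) || length(condition) != 1L || !nzchar(condition))
    stop("`condition` must be a single non-empty label")

  lines <- readLines(path, warn = FALSE)
  keep <- which(nzchar(trimws(lines)) &
                  !grepl("^(#|track([[:space:]]|$)|browser([[:space:]]|$))", lines))
  if (!length(keep)) return(empty_peaks(mark, condition))

  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  nfld <- lengths(fields)
  if (any(nfld < 3L)) {
    bad <- keep[which(nfld < 3L)[1L]]
    stop(sprintf("%s: line %d: fewer than 3 tab-separated columns", path, bad))
  }
  chrom <- vapply(fields, `[[`, "", 1L)
  start <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2L)))
  end <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3L)))
  bad <- which(is.na(start) | is.na(end) | start != floor(start) |
                 end != floor(end) | start < 0 | end <= start)
  if (length(bad))
    stop(sprintf("%s: line %d: malformed coordinates '%s'",
                 path, keep[bad[1L]], lines[keep[bad[1L]]]))
  score <- rep(NA_real_, length(keep))
  has5 <- nfld >= 5L
  if (any(has5)) {
    s <- suppressWarnings(as.numeric(vapply(fields[has5], `[[`, "", 5L)))
    score[has5] <- s
    if (any(!is.na(s) & s < 0)) {
      bad <- keep[has5][which(!is.na(s) & s < 0)[1L]]
      stop(sprintf("%s: line %d: negative score", path, bad))
    }
  }
  peaks <- data.frame(chrom = chrom, start = as.integer(start),
                      end = as.integer(end), score = score,
                      mark = mark, condition = condition,
                      stringsAsFactors = FALSE)
  class(peaks) <- c("peak_calls", "data.frame")
  peaks
}

empty_peaks <- function(mark = character(), condition = character()) {
  peaks <- data.frame(chrom = character(), start = integer(), end = integer(),
                      score = numeric(),
                      mark = rep(mark, 0L), condition = rep(condition, 0L),
                      stringsAsFactors = FALSE)
  class(peaks) <- c("peak_calls", "data.frame")
  peaks
}

#' Write peak calls to a BED file
#'
#' Inverse of [read_bed()]: emits BED5 when any score is present, BED3
#' otherwise.  The mark and condition are call-level metadata and are not
#' stored in the file.
#'
#' @param peaks A `peak_calls` data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(peaks, path) {
  if (nrow(peaks) && any(!is.na(peaks$score))) {
    out <- sprintf("%s\t%d\t%d\t.\t%s", peaks$chrom, peaks$start, peaks$end,
                   ifelse(is.na(peaks$score), "0", format(peaks$score,
                                                          trim = TRUE)))
  } else {
    out <- sprintf("%s\t%d\t%d", peaks$chrom, peaks$start, peaks$end)
  }
  writeLines(out, path)
  invisible(path)
}

#' Read a gene table
#'
#' Reads a tab-separated gene model table with header columns `gene_id`,
#' `chrom`, `strand`, `tx_start`, `tx_end` (0-based half-open coordinates,
#' `#` comment lines allowed).  Rows sharing a `gene_id` -- multiple
#' transcripts of one gene -- are collapsed to the union interval
#' (minimum start, maximum end); they must lie on one chromosome.
#'
#' @param path Path to the TSV file.
#' @return A data frame of class `gene_table` with one row per gene, in
#'   first-appearance order.
#' @export
read_gene_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          comment.char = "#", stringsAsFactors = FALSE)
  need <- c("gene_id", "chrom", "strand", "tx_start", "tx_end")
  if (!all(need %in% names(df)))
    stop("gene table must have columns: ", paste(need, collapse = ", "))
  df <- df[need]
  if (!all(df$strand %in% c("+", "-")))
    stop("bad strand symbol: ",
         paste(unique(setdiff(df$strand, c("+", "-"))), collapse = ", "))
  if (any(!is.finite(df$tx_start)) || any(!is.finite(df$tx_end)))
    stop("non-numeric coordinates in gene table")
  if (any(df$tx_start < 0) || any(df$tx_end <= df$tx_start))
    stop("gene table requires 0 <= tx_start < tx_end")
  validate_gene_table(collapse_transcripts(df))
}

collapse_transcripts <- function(df) {
  first <- !duplicated(df$gene_id)
  if (all(first)) {
    out <- df
  } else {
    sp <- split(seq_len(nrow(df)), df$gene_id)
    chroms <- vapply(sp, function(i) length(unique(df$chrom[i])), 0L)
    if (any(chroms > 1L))
      stop("gene_id on multiple chromosomes: ",
           paste(names(sp)[chroms > 1L], collapse = ", "))
    out <- df[first, , drop = FALSE]
    out$tx_start <- vapply(sp[out$gene_id], function(i) min(df$tx_start[i]), 0)
    out$tx_end <- vapply(sp[out$gene_id], function(i) max(df$tx_end[i]), 0)
  }
  out$tx_start <- as.integer(out$tx_start)
  out$tx_end <- as.integer(out$tx_end)
  rownames(out) <- NULL
  class(out) <- c("gene_table", "data.frame")
  out
}

validate_gene_table <- function(genes) {
  if (anyDuplicated(genes$gene_id))
    stop("duplicate gene_id after collapse (internal error)")
  genes
}

#' Write a gene table
#'
#' @param genes A `gene_table` data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_table <- function(genes, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# coordinates are 0-based, half-open (BED convention)", con)
  utils::write.table(genes, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a GMT gene-set collection
#'
#' Standard GMT: one set per line, tab-separated `term_id`, description,
#' then member gene ids.  Members are deduplicated; empty sets are an error.
#'
#' @param path Path to the GMT file.
#' @return A named list of character vectors (one per set) of class
#'   `gene_sets`, with the per-term descriptions in
#'   `attr(, "descriptions")`.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(lines, "#")]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fields) < 3L))
    stop("GMT line with no members (need term, description, >=1 gene)")
  ids <- vapply(fields, `[[`, "", 1L)
  if (anyDuplicated(ids)) stop("duplicate term_id in GMT")
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- ids
  attr(sets, "descriptions") <- stats::setNames(
    vapply(fields, `[[`, "", 2L), ids)
  class(sets) <- "gene_sets"
  sets
}

#' Write a GMT gene-set collection
#'
#' @param sets A `gene_sets` object (or plain named list of id vectors).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path) {
  desc <- attr(sets, "descriptions") %||%
    stats::setNames(rep("", length(sets)), names(sets))
  out <- vapply(names(sets), function(id) {
    paste(c(id, desc[[id]], sets[[id]]), collapse = "\t")
  }, "")
  writeLines(out, path)
  invisible(path)
}

#' Read a weighted interaction edge list
#'
#' TSV with header `node_a`, `node_b`, `confidence` and optionally
#' `channel`.  Edges are undirected: each pair is canonicalized with
#' `node_a < node_b` and duplicates are collapsed keeping the maximum
#' confidence.  Self-edges or confidences outside `[0, 1]` are errors.
#'
#' @param path Path to the TSV file.
#' @return A data frame of class `edge_list` with columns `node_a`,
#'   `node_b`, `confidence`, `channel`.
#' @export
read_edges <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          comment.char = "#", stringsAsFactors = FALSE)
  if (!all(c("node_a", "node_b", "confidence") %in% names(df)))
    stop("edge list must have columns node_a, node_b, confidence")
  if (is.null(df$channel)) df$channel <- ""
  as_edge_list(df[c("node_a", "node_b", "confidence", "channel")])
}

#' Canonicalize an edge list
#'
#' @param df Data frame with `node_a`, `node_b`, `confidence` and optional
#'   `channel` columns.
#' @return Validated, canonicalized `edge_list` (see [read_edges()]).
#' @export
as_edge_list <- function(df) {
  if (is.null(df$channel)) df$channel <- ""
  if (any(df$node_a == df$node_b))
    stop("self-edge not allowed: ", df$node_a[df$node_a == df$node_b][1L])
  if (any(!is.finite(df$confidence)) ||
      any(df$confidence < 0) || any(df$confidence > 1))
    stop("edge confidence outside [0, 1]")
  swap <- df$node_a > df$node_b
  tmp <- df$node_a[swap]
  df$node_a[swap] <- df$node_b[swap]
  df$node_b[swap] <- tmp
  key <- paste(df$node_a, df$node_b, sep = "\r")
  if (anyDuplicated(key)) {
    best <- tapply(df$confidence, key, max)
    keep <- !duplicated(key)
    df <- df[keep, , drop = FALSE]
    # keep the row carrying the max confidence for each pair
    df$confidence <- as.numeric(best[paste(df$node_a, df$node_b, sep = "\r")])
  }
  rownames(df) <- NULL
  class(df) <- c("edge_list", "data.frame")
  df
}

#' Write an edge list
#'
#' @param edges An `edge_list` data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_edges <- function(edges, path) {
  utils::write.table(edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Construct an expression matrix
#'
#' Container for a log2 expression matrix (genes in rows, samples in
#' columns) plus the identifiers of a housekeeping panel used by
#' [housekeeping_normalize()].
#'
#' @param values Numeric matrix with gene row names and sample column
#'   names; no missing values.
#' @param housekeeping Character vector of housekeeping gene ids, a subset
#'   of the row names.
#' @return An object of class `expr_matrix`.
#' @export
expr_matrix <- function(values, housekeeping = character()) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must have gene row names and sample column names")
  if (anyNA(values)) stop("expression matrix contains missing values")
  if (anyDuplicated(rownames(values))) stop("duplicate gene ids")
  housekeeping <- unique(as.character(housekeeping))
  if (!all(housekeeping %in% rownames(values)))
    stop("housekeeping ids absent from the matrix: ",
         paste(setdiff(housekeeping, rownames(values)), collapse = ", "))
  structure(list(values = values, housekeeping = housekeeping),
            class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expr_matrix: %d genes x %d samples (%d housekeeping)\n",
              nrow(x$values), ncol(x$values), length(x$housekeeping)))
  invisible(x)
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

#' Read an expression matrix from TSV
#'
#' First column `gene_id`, remaining columns numeric sample values.  Ragged
#' rows or missing values are errors.
#'
#' @param path Path to the TSV file.
#' @param housekeeping Either a character vector of housekeeping gene ids
#'   or the path of a one-id-per-line text file; optional.
#' @return An `expr_matrix`.
#' @export
read_matrix <- function(path, housekeeping = character()) {
  if (!file.exists(path)) stop("file not found: ", path)
  nf <- utils::count.fields(path, sep = "\t", comment.char = "#")
  if (length(unique(nf)) > 1L)
    stop("ragged rows in matrix file: ", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          comment.char = "#", check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (names(df)[1L] != "gene_id")
    stop("first column of a matrix file must be 'gene_id'")
  m <- as.matrix(df[-1L])
  if (!is.numeric(m)) stop("non-numeric expression values in ", path)
  rownames(m) <- df$gene_id
  if (length(housekeeping) == 1L && file.exists(housekeeping))
    housekeeping <- readLines(housekeeping, warn = FALSE)
  housekeeping <- housekeeping[nzchar(trimws(housekeeping))]
  expr_matrix(m, housekeeping = housekeeping)
}

#' Write an expression matrix to TSV
#'
#' @param em An `expr_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(em, path) {
  df <- data.frame(gene_id = rownames(em$values), em$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
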