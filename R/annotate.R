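#' Build a flanked-window interval index over genes
#'
#' Each gene contributes the query window
#' `[max(0, tx_start - flank), tx_end + flank)` (0-based half-open); the
#' default flank of 20 kb implements the symmetric +/- 20 kb annotation
#' window around gene bodies.  The index is backed by a
#' [GenomicRanges::GRanges] object and answers 1-bp-resolution overlap
#' queries.
#'
#' @param genes A `gene_table` (see [read_gene_table()]).
#' @param flank Non-negative flank in bp added on both sides (default
#'   20000).
#' @return An object of class `gene_window_index`.
#' @export
build_interval_index <- function(genes, flank = 20000L) {
  stopifnot(is.numeric(flank), length(flank) == 1L, flank >= 0)
  flank <- as.integer(flank)
  win_start <- pmax(0L, genes$tx_start - flank)
  win_end <- genes$tx_end + flank
  gr <- GenomicRanges::GRanges(
    seqnames = as.character(genes$chrom),
    # convert 0-based half-open [s, e) to the 1-based closed IRanges [s+1, e]
    ranges = IRanges::IRanges(start = win_start + 1L, end = win_end))
  names(gr) <- genes$gene_id
  structure(list(gr = gr, genes = genes, flank = flank,
                 window_start = win_start, window_end = win_end),
            class = "gene_window_index")
}

#' @export
print.gene_window_index <- function(x, ...) {
  cat(sprintf("gene_window_index: %d genes, flank %d bp\n",
              length(x$gr), x$flank))
  invisible(x)
}

#' Query windows of a gene index
#'
#' @param index A `gene_window_index`.
#' @return Data frame `gene_id`, `chrom`, `win_start`, `win_end`
#'   (0-based half-open).
#' @export
index_windows <- function(index) {
  data.frame(gene_id = index$genes$gene_id,
             chrom = index$genes$chrom,
             win_start = index$window_start,
             win_end = index$window_end,
             stringsAsFactors = FALSE)
}

#' Assign histone marks to genes by windowed overlap
#'
#' A gene carries a mark if and only if at least one peak of that mark
#' overlaps its flanked window by >= 1 bp.  A peak may support several
#' genes; strand is ignored.  All peaks must share a single condition
#' label.  Peaks on chromosomes absent from the gene table are tallied in
#' the result (`n_unassigned_peaks`), not treated as errors.
#'
#' @param peaks A `peak_calls` data frame covering one condition (any mix
#'   of the two marks).
#' @param genes A `gene_table`.
#' @param flank Window flank in bp (default 20000).
#' @return An object of class `mark_assignment`: list with `condition`,
#'   `flank`, the per-gene data frame `assignment` (`gene_id`, `has_k4`,
#'   `has_k27`), per-mark support lists of peak row indices, and
#'   `n_unassigned_peaks`.
#' @export
assign_marks <- function(peaks, genes, flank = 20000L) {
  conds <- unique(peaks$condition)
  if (length(conds) > 1L)
    stop("peaks mix conditions: ", paste(conds, collapse = ", "))
  condition <- if (length(conds)) conds else NA_character_
  idx <- build_interval_index(genes, flank)

  assignment <- data.frame(gene_id = genes$gene_id,
                           has_k4 = FALSE, has_k27 = FALSE,
                           stringsAsFactors = FALSE)
  support <- list(
    K4me3 = stats::setNames(vector("list", nrow(genes)), genes$gene_id),
    K27me3 = stats::setNames(vector("list", nrow(genes)), genes$gene_id))
  n_unassigned <- 0L

  if (nrow(peaks)) {
    pk <- GenomicRanges::GRanges(
      seqnames = as.character(peaks$chrom),
      ranges = IRanges::IRanges(start = peaks$start + 1L, end = peaks$end))
    hits <- suppressWarnings(GenomicRanges::findOverlaps(pk, idx$gr))
    q <- S4Vectors::queryHits(hits)
    s <- S4Vectors::subjectHits(hits)
    for (m in MARKS) {
      sel <- peaks$mark[q] == m
      gidx <- s[sel]
      col <- if (m == "K4me3") "has_k4" else "has_k27"
      assignment[[col]][unique(gidx)] <- TRUE
      if (length(gidx)) {
        sp <- split(q[sel], gidx)
        support[[m]][as.integer(names(sp))] <- unname(sp)
      }
    }
    n_unassigned <- sum(!peaks$chrom %in% genes$chrom)
  }
  structure(list(condition = condition, flank = as.integer(flank),
                 assignment = assignment, support = support,
                 n_unassigned_peaks = n_unassigned),
            class = "mark_assignment")
}

#' @export
print.mark_assignment <- function(x, ...) {
  a <- x$assignment
  cat(sprintf(
    "mark_assignment (%s, flank %d bp): %d genes; K4me3 %d, K27me3 %d, both %d\n",
    x$condition, x$flank, nrow(a), sum(a$has_k4), sum(a$has_k27),
    sum(a$has_k4 & a$has_k27)))
  if (x$n_unassigned_peaks)
    cat(sprintf("  %d peaks on chromosomes absent from the gene table\n",
                x$n_unassigned_peaks))
  invisible(x)
}
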