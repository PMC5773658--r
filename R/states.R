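#' Classify genes into four chromatin states
#'
#' Maps the per-gene mark booleans of a [assign_marks()] result to the
#' four-state classification: H3K4me3 only (`K4`), H3K27me3 only (`K27`),
#' both marks (`BIVALENT`), neither (`NONE`).
#'
#' @param assignment A `mark_assignment`.
#' @return Named character vector (gene_id -> state), covering every gene
#'   of the gene universe exactly once.
#' @export
classify_states <- function(assignment) {
  a <- assignment$assignment
  state <- ifelse(a$has_k4 & a$has_k27, "BIVALENT",
           ifelse(a$has_k4, "K4",
           ifelse(a$has_k27, "K27", "NONE")))
  stats::setNames(state, a$gene_id)
}

#' Pair two per-condition state classifications
#'
#' @param states_a,states_b Named state vectors from [classify_states()]
#'   over the same gene universe.
#' @param conditions Length-2 character vector naming the reference and
#'   comparison conditions (transitions are reported A -> B).
#' @return A data frame of class `state_table` with columns `gene_id`,
#'   `state_a`, `state_b`; `attr(, "conditions")` holds the labels.
#' @export
state_table <- function(states_a, states_b, conditions = c("A", "B")) {
  if (length(states_a) != length(states_b) ||
      !setequal(names(states_a), names(states_b)))
    stop("state vectors cover different gene universes")
  bad <- setdiff(unique(c(states_a, states_b)), STATES)
  if (length(bad)) stop("unknown state: ", paste(bad, collapse = ", "))
  ids <- names(states_a)
  st <- data.frame(gene_id = ids,
                   state_a = unname(states_a[ids]),
                   state_b = unname(states_b[ids]),
                   stringsAsFactors = FALSE)
  attr(st, "conditions") <- as.character(conditions)
  class(st) <- c("state_table", "data.frame")
  st
}

#' Tabulate chromatin-state transitions between two conditions
#'
#' Counts genes by (state in condition A, state in condition B) into a
#' 4 x 4 matrix over `K4`, `K27`, `BIVALENT`, `NONE`, together with row
#' totals and row percentages (`100 * counts / row_total`).
#'
#' @param st A `state_table`.
#' @return An object of class `transition_matrix` with elements `counts`,
#'   `row_totals`, `percentages`, `conditions`, `n_genes`.
#' @seealso [transition_matrix_from_counts()] to build the object directly
#'   from a published count table.
#' @export
transition_matrix <- function(st) {
  counts <- table(factor(st$state_a, levels = STATES),
                  factor(st$state_b, levels = STATES))
  counts <- matrix(as.integer(counts), 4L, 4L,
                   dimnames = list(from = STATES, to = STATES))
  transition_matrix_from_counts(counts,
                                conditions = attr(st, "conditions"))
}

#' Build a transition matrix from a 4 x 4 count table
#'
#' Entry point for worked examples where the per-cell gene counts are
#' known (e.g. transcribed from a published figure) without the underlying
#' per-gene state table.
#'
#' @param counts 4 x 4 non-negative integer matrix with rows = state in
#'   condition A and columns = state in condition B, dimnames from
#'   `c("K4", "K27", "BIVALENT", "NONE")` in any order.
#' @param conditions Length-2 condition labels.
#' @return A `transition_matrix` object.
#' @export
transition_matrix_from_counts <- function(counts, conditions = c("A", "B")) {
  if (!is.matrix(counts) || any(dim(counts) != 4L))
    stop("`counts` must be a 4 x 4 matrix")
  if (is.null(dimnames(counts)) ||
      !setequal(rownames(counts), STATES) ||
      !setequal(colnames(counts), STATES))
    stop("`counts` dimnames must be the four states ",
         paste(STATES, collapse = "/"))
  counts <- counts[STATES, STATES]
  if (any(counts < 0) || any(counts != floor(counts)))
    stop("`counts` must be non-negative integers")
  storage.mode(counts) <- "integer"
  names(dimnames(counts)) <- c("from", "to")
  row_totals <- rowSums(counts)
  pct <- counts * NA_real_
  nz <- row_totals > 0
  pct[nz, ] <- 100 * counts[nz, , drop = FALSE] / row_totals[nz]
  structure(list(counts = counts, row_totals = row_totals,
                 percentages = pct,
                 conditions = as.character(conditions),
                 n_genes = sum(counts)),
            class = "transition_matrix")
}

#' @export
print.transition_matrix <- function(x, digits = 1, ...) {
  cat(sprintf("Chromatin-state transitions %s -> %s (%d genes)\n\nCounts:\n",
              x$conditions[1L], x$conditions[2L], x$n_genes))
  print(x$counts)
  cat("\nRow percentages:\n")
  print(round(x$percentages, digits))
  invisible(x)
}

#' @export
summary.transition_matrix <- function(object, ...) {
  chg <- change_fraction_by_origin(object)
  off <- object$n_genes - sum(diag(object$counts))
  cat(sprintf("%d genes; %d (%.1f%%) change state %s -> %s\n",
              object$n_genes, off, 100 * off / object$n_genes,
              object$conditions[1L], object$conditions[2L]))
  cat("Percent changed by origin state:\n")
  print(round(chg, 1))
  invisible(list(n_changed = off, by_origin = chg))
}

#' Genes whose chromatin state changes between conditions
#'
#' @param st A `state_table`.
#' @return Character vector of gene ids with `state_a != state_b`; its
#'   length equals the off-diagonal total of [transition_matrix()].
#' @export
changed_gene_set <- function(st) {
  st$gene_id[st$state_a != st$state_b]
}

#' Percent of genes changing state, per origin state
#'
#' For each state with a non-empty row, `100 * (row_total - diagonal) /
#' row_total`.  States with zero genes in condition A are omitted.
#'
#' @param tm A `transition_matrix`.
#' @return Named numeric vector of percentages.
#' @export
change_fraction_by_origin <- function(tm) {
  keep <- tm$row_totals > 0
  100 * (tm$row_totals[keep] - diag(tm$counts)[keep]) / tm$row_totals[keep]
}

#' Changed genes grouped by their final state
#'
#' The Venn-style layout: how many state-changing genes end up in each
#' state of the comparison condition.
#'
#' @param st A `state_table`.
#' @return Named integer vector over the four states; sums to
#'   `length(changed_gene_set(st))`.
#' @export
venn_summary <- function(st) {
  chg <- st$state_a != st$state_b
  tab <- table(factor(st$state_b[chg], levels = STATES))
  stats::setNames(as.integer(tab), STATES)
}
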