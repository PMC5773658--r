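#' Hypergeometric gene-set enrichment
#'
#' Over-representation analysis against a configurable background: for a
#' query of `n` genes drawn from a background of `N`, a term with `K`
#' background members and `k` query members gets the upper-tail
#' probability `p = P(X >= k)` under Hypergeometric(N, K, n).
#' Benjamini-Hochberg q-values are computed across the tested terms.
#' Query genes outside the background are dropped (and counted); terms are
#' size-filtered after intersection with the background.
#'
#' @param query Character vector of query gene ids.
#' @param sets A `gene_sets` collection (see [read_gmt()]).
#' @param background Character vector: the gene universe.
#' @param min_size,max_size Term-size guards applied to `K` (defaults 3
#'   and 2000).
#' @return Data frame of class `enrichment_result`, sorted by `p`, with
#'   columns `term_id`, `term_name`, `k`, `K`, `n`, `N`, `p`, `q`;
#'   `attr(, "n_query_dropped")` counts query ids outside the background.
#' @export
hypergeom_enrich <- function(query, sets, background,
                             min_size = 3L, max_size = 2000L) {
  background <- unique(as.character(background))
  if (!length(background)) stop("empty background")
  query0 <- unique(as.character(query))
  query <- intersect(query0, background)
  n_dropped <- length(query0) - length(query)

  N <- length(background)
  n <- length(query)
  desc <- attr(sets, "descriptions") %||%
    stats::setNames(rep("", length(sets)), names(sets))

  rows <- lapply(names(sets), function(id) {
    members <- intersect(sets[[id]], background)
    K <- length(members)
    if (K < min_size || K > max_size) return(NULL)
    k <- length(intersect(members, query))
    # upper tail including k itself: P(X >= k)
    p <- stats::phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
    data.frame(term_id = id, term_name = unname(desc[id]),
               k = k, K = K, n = n, N = N, p = p,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  if (is.null(res))
    res <- data.frame(term_id = character(), term_name = character(),
                      k = integer(), K = integer(), n = integer(),
                      N = integer(), p = numeric(), stringsAsFactors = FALSE)
  res$q <- bh_adjust(res$p)
  res <- res[order(res$p, res$term_id), , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "n_query_dropped") <- n_dropped
  class(res) <- c("enrichment_result", "data.frame")
  res
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate control; a thin wrapper around
#' [stats::p.adjust()] that preserves input order.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted q-values, same length and order as `p`.
#' @export
bh_adjust <- function(p) {
  if (any(!is.na(p) & (p < 0 | p > 1))) stop("p-values outside [0, 1]")
  stats::p.adjust(p, method = "BH")
}
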