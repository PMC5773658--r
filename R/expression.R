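#' Housekeeping normalization of a log2 expression matrix
#'
#' Per sample, subtracts the mean log2 signal of the housekeeping panel
#' from every gene, so the housekeeping panel has per-sample mean zero
#' afterwards.  Removes any per-sample additive offset exactly.
#'
#' @param em An `expr_matrix` with a non-empty housekeeping set.
#' @return The normalized `expr_matrix`.
#' @export
housekeeping_normalize <- function(em) {
  if (!inherits(em, "expr_matrix")) stop("`em` must be an expr_matrix")
  if (!length(em$housekeeping))
    stop("housekeeping set is empty; nothing to normalize against")
  hk_mean <- colMeans(em$values[em$housekeeping, , drop = FALSE])
  em$values <- sweep(em$values, 2L, hk_mean, `-`)
  em
}

#' Stratify expression by chromatin state with pairwise Welch tests
#'
#' Reproduces the state-vs-expression analysis: per-gene expression
#' (mean over the selected samples) is grouped by chromatin state, group
#' summaries are computed for `ALL` plus the four states, and all pairwise
#' two-sided Welch t tests among the states and of each state against
#' `ALL` are performed.  A monotone-ordering flag records whether
#' median(K4) > median(BIVALENT) > median(NONE) >= median(K27), the
#' pattern expected when the active mark drives expression.
#'
#' @param em An `expr_matrix`.
#' @param states Named state vector from [classify_states()].
#' @param samples Optional character/integer vector selecting the columns
#'   to average (default: all samples).
#' @param adjust Multiplicity correction for the pairwise grid, `"none"`
#'   (default, matching raw-p reporting) or `"BH"`.
#' @return Object of class `state_expression_summary`: `groups` data frame
#'   (state, n, mean, median, q1, q3), `pairwise` p-value matrix,
#'   `ordering_ok` flag, `n_missing_expression` count of universe genes
#'   absent from the matrix.
#' @export
stratify_and_test <- function(em, states, samples = NULL,
                              adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  vals <- em$values
  if (!is.null(samples)) vals <- vals[, samples, drop = FALSE]
  expr <- rowMeans(vals)

  present <- names(states)[names(states) %in% names(expr)]
  n_missing <- length(states) - length(present)
  x <- expr[present]
  g <- states[present]

  grp_levels <- c("ALL", STATES)
  groups <- do.call(rbind, lapply(grp_levels, function(s) {
    v <- if (s == "ALL") x else x[g == s]
    if (!length(v))
      return(data.frame(state = s, n = 0L, mean = NA_real_,
                        median = NA_real_, q1 = NA_real_, q3 = NA_real_))
    q <- stats::quantile(v, c(.25, .5, .75), names = FALSE)
    data.frame(state = s, n = length(v), mean = mean(v),
               median = q[2L], q1 = q[1L], q3 = q[3L])
  }))

  pw <- matrix(NA_real_, length(grp_levels), length(grp_levels),
               dimnames = list(grp_levels, grp_levels))
  pool <- c(list(ALL = x), split(x, factor(g, levels = STATES)))
  for (i in seq_along(grp_levels)) for (j in seq_along(grp_levels)) {
    if (j <= i) next
    a <- pool[[grp_levels[i]]]; b <- pool[[grp_levels[j]]]
    if (length(a) >= 2L && length(b) >= 2L &&
        (stats::sd(a) > 0 || stats::sd(b) > 0)) {
      p <- stats::t.test(a, b)$p.value  # Welch by default
      pw[i, j] <- pw[j, i] <- p
    }
  }
  if (adjust == "BH") {
    up <- upper.tri(pw)
    pw[up] <- bh_adjust(pw[up])
    pw[lower.tri(pw)] <- t(pw)[lower.tri(pw)]
  }

  med <- stats::setNames(groups$median, groups$state)
  ordering_ok <- isTRUE(med["K4"] > med["BIVALENT"] &&
                          med["BIVALENT"] > med["NONE"] &&
                          med["NONE"] >= med["K27"])
  structure(list(groups = groups, pairwise = pw,
                 ordering_ok = ordering_ok,
                 n_missing_expression = n_missing, adjust = adjust),
            class = "state_expression_summary")
}

#' @export
print.state_expression_summary <- function(x, ...) {
  cat("Expression by chromatin state\n")
  print(x$groups, row.names = FALSE)
  cat(sprintf("\nOrdering K4 > BIVALENT > NONE >= K27: %s\n",
              x$ordering_ok))
  if (x$n_missing_expression)
    cat(sprintf("%d universe genes had no expression values\n",
                x$n_missing_expression))
  cat(sprintf("Pairwise Welch p-values (%s):\n",
              if (x$adjust == "BH") "BH-adjusted" else "unadjusted"))
  print(signif(x$pairwise, 3))
  invisible(x)
}
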