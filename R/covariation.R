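#' Per-gene z-scores across tumor zones
#'
#' Standardizes each gene's expression across zones: `(x - mean) / sd`
#' with the sample standard deviation.  Genes with zero variance get all
#' zeros; a matrix with fewer than two zones is an error.
#'
#' @param zm Numeric matrix, genes in rows, zones in columns.
#' @return Matrix of the same shape containing z-scores.
#' @export
zone_zscore <- function(zm) {
  if (!is.matrix(zm) || !is.numeric(zm)) stop("`zm` must be a numeric matrix")
  if (ncol(zm) < 2L) stop("z-scoring needs >= 2 zones")
  mu <- rowMeans(zm)
  sdv <- apply(zm, 1L, stats::sd)
  z <- (zm - mu) / ifelse(sdv > 0, sdv, 1)
  z[sdv == 0, ] <- 0
  z
}

#' Correlation-circle principal component analysis
#'
#' PCA of the column-standardized matrix, i.e. the eigen-decomposition of
#' the Pearson correlation matrix of the variables.  Each variable's
#' "circle" coordinates are its Pearson correlations with the component
#' scores (F1, F2, ...).  Component signs are fixed deterministically:
#' each component is oriented so the lexicographically smallest variable
#' with a nonzero loading correlates positively with it.
#'
#' @param mat Numeric matrix, observations in rows, variables (genes) in
#'   columns; >= 3 observations, >= 2 variables, every variable with
#'   positive variance.
#' @return Object of class `pca_circle`: `scores` (observations x
#'   components), `explained` (variance fractions, non-increasing,
#'   summing to 1), `var_cor` (variables x components correlation
#'   matrix), `rotation`.
#' @export
pca_circle <- function(mat) {
  if (!is.matrix(mat) || !is.numeric(mat)) stop("`mat` must be numeric")
  if (nrow(mat) < 3L) stop("need >= 3 observations")
  if (ncol(mat) < 2L) stop("need >= 2 variables")
  if (is.null(colnames(mat)))
    colnames(mat) <- paste0("V", seq_len(ncol(mat)))
  sdv <- apply(mat, 2L, stats::sd)
  if (any(sdv == 0))
    stop("zero-variance variable: ",
         paste(colnames(mat)[sdv == 0], collapse = ", "))
  pr <- stats::prcomp(mat, center = TRUE, scale. = TRUE)
  scores <- pr$x
  explained <- pr$sdev^2 / sum(pr$sdev^2)
  # deterministic sign: smallest-id variable with nonzero loading positive
  ord <- order(colnames(mat))
  for (j in seq_len(ncol(scores))) {
    load <- pr$rotation[, j]
    nz <- ord[abs(load[ord]) > 1e-10]
    if (length(nz) && load[nz[1L]] < 0) {
      scores[, j] <- -scores[, j]
      pr$rotation[, j] <- -pr$rotation[, j]
    }
  }
  var_cor <- suppressWarnings(stats::cor(mat, scores))
  var_cor[is.na(var_cor)] <- 0  # components with zero score variance
  colnames(var_cor) <- colnames(scores) <- paste0("F", seq_len(ncol(scores)))
  structure(list(scores = scores, explained = explained,
                 var_cor = var_cor, rotation = pr$rotation),
            class = "pca_circle")
}

#' @export
print.pca_circle <- function(x, ...) {
  cat(sprintf("pca_circle: %d observations, %d variables\n",
              nrow(x$scores), nrow(x$var_cor)))
  ev <- utils::head(100 * x$explained, 3)
  cat(sprintf("explained variance: %s%%\n",
              paste(sprintf("%.1f", ev), collapse = ", ")))
  invisible(x)
}

#' Plot the correlation circle
#'
#' Draws the unit circle with each variable as a vector at its (F1, F2)
#' correlations, the standard display for variable co-variation.
#'
#' @param x A `pca_circle`.
#' @param highlight Optional variable ids drawn in a distinct color.
#' @param ... Further arguments passed to [graphics::plot()].
#' @export
plot.pca_circle <- function(x, highlight = character(), ...) {
  vc <- x$var_cor[, 1:2, drop = FALSE]
  graphics::plot(NA, xlim = c(-1.1, 1.1), ylim = c(-1.1, 1.1), asp = 1,
                 xlab = sprintf("F1 (%.1f%%)", 100 * x$explained[1L]),
                 ylab = sprintf("F2 (%.1f%%)", 100 * x$explained[2L]), ...)
  th <- seq(0, 2 * pi, length.out = 200)
  graphics::lines(cos(th), sin(th), col = "grey60")
  col <- ifelse(rownames(vc) %in% highlight, "red3", "grey30")
  graphics::arrows(0, 0, vc[, 1L], vc[, 2L], length = 0.06, col = col)
  graphics::text(vc[, 1L] * 1.06, vc[, 2L] * 1.06, rownames(vc),
                 cex = 0.7, col = col)
  invisible(x)
}

#' Co-variation of a query gene with a signature set
#'
#' Quantifies "the query co-varies with the signature along F1/F2" as the
#' cosine similarity between the query's (F1, F2) correlation vector and
#' the centroid of the signature genes' vectors; additionally reports
#' whether the query and the centroid agree in sign on F1 alone.
#'
#' @param pca A `pca_circle`.
#' @param query Variable id of the query gene.
#' @param signature Character vector of signature variable ids (>= 1
#'   present in the PCA).
#' @return List with `score` (cosine in `[-1, 1]`, `NA` if the centroid
#'   has zero length), `f1_sign_agreement` (logical), `centroid`, and
#'   `query_vec`.
#' @export
covariation_score <- function(pca, query, signature) {
  vc <- pca$var_cor[, 1:2, drop = FALSE]
  if (!query %in% rownames(vc)) stop("query not in PCA: ", query)
  signature <- intersect(setdiff(signature, query), rownames(vc))
  if (!length(signature)) stop("no signature gene present in the PCA")
  q <- vc[query, ]
  centroid <- colMeans(vc[signature, , drop = FALSE])
  nq <- sqrt(sum(q^2)); nc <- sqrt(sum(centroid^2))
  score <- if (nq == 0 || nc == 0) NA_real_ else
    sum(q * centroid) / (nq * nc)
  list(score = score,
       f1_sign_agreement = isTRUE(sign(q[1L]) == sign(centroid[1L]) &&
                                    sign(q[1L]) != 0),
       centroid = centroid, query_vec = q)
}
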