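# Shared fixtures and independent oracles, built in code at test time.

tmp_file <- function(lines, ext = ".tsv") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

# Brute-force all-pairs overlap oracle: a gene carries a mark iff any peak
# of that mark intersects [max(0, tx_start - flank), tx_end + flank) by
# >= 1 bp (0-based half-open intervals).
brute_assign <- function(peaks, genes, flank) {
  has <- sapply(c("K4me3", "K27me3"), function(m) {
    pk <- peaks[peaks$mark == m, , drop = FALSE]
    vapply(seq_len(nrow(genes)), function(i) {
      ws <- max(0, genes$tx_start[i] - flank)
      we <- genes$tx_end[i] + flank
      any(pk$chrom == genes$chrom[i] & pk$start < we & pk$end > ws)
    }, logical(1))
  })
  data.frame(gene_id = genes$gene_id,
             has_k4 = has[, "K4me3"], has_k27 = has[, "K27me3"],
             stringsAsFactors = FALSE)
}

rand_genes <- function(n, n_chroms = 2, max_pos = 1e6) {
  start <- sample.int(max_pos, n)
  data.frame(gene_id = sprintf("G%03d", seq_len(n)),
             chrom = paste0("chr", sample.int(n_chroms, n, replace = TRUE)),
             strand = sample(c("+", "-"), n, replace = TRUE),
             tx_start = start,
             tx_end = start + sample(500:20000, n, replace = TRUE),
             stringsAsFactors = FALSE) -> df
  class(df) <- c("gene_table", "data.frame")
  df
}

rand_peaks <- function(n, n_chroms = 2, max_pos = 1e6,
                       condition = "TG1") {
  start <- sample.int(max_pos, n)
  df <- data.frame(chrom = paste0("chr", sample.int(n_chroms, n, TRUE)),
                   start = start,
                   end = start + sample(100:5000, n, replace = TRUE),
                   score = NA_real_,
                   mark = sample(c("K4me3", "K27me3"), n, replace = TRUE),
                   condition = condition, stringsAsFactors = FALSE)
  class(df) <- c("peak_calls", "data.frame")
  df
}

# Two mean-zero unit vectors with exact sample correlation r.
exact_corr_pair <- function(n, r, seed = 1) {
  set.seed(seed)
  z1 <- rnorm(n); z2 <- rnorm(n)
  e1 <- z1 - mean(z1); e1 <- e1 / sqrt(sum(e1^2))
  z2 <- z2 - mean(z2); z2 <- z2 - sum(z2 * e1) * e1
  e2 <- z2 / sqrt(sum(z2^2))
  cbind(A = e1, B = r * e1 + sqrt(1 - r^2) * e2)
}

# Exhaustive hypergeometric upper-tail oracle: enumerate all C(N, n) draws
# of the query from the background and count those overlapping the term by
# >= k.  Feasible for N <= 12.
enum_hyper_p <- function(N, K, n, k) {
  draws <- utils::combn(N, n)
  marked <- seq_len(K)  # wlog the first K background genes are the term
  hits <- colSums(matrix(draws %in% marked, nrow = n))
  mean(hits >= k)
}

# Grid-search oracle for the single-hit Poisson log-likelihood maximum.
elda_grid_max <- function(assay, n_grid = 10000) {
  grid <- exp(seq(-10, 2, length.out = n_grid))
  max(vapply(grid, markshift:::elda_loglik, 0, assay = assay))
}
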