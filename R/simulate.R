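#' Simulation configuration
#'
#' Bundles every knob of the synthetic-data generators.  Defaults echo the
#' study conditions the pipeline targets: state priors of roughly
#' 48/10/10/32% for K4/K27/bivalent/none, a transition kernel whose rows
#' give ~13% change among K4 genes, 44% among K27, 49% among bivalent and
#' an overall change rate of 22%; expression means of 10/8/5.5/5 (log2,
#' sd 1) for K4/bivalent/none/K27; a 30-gene housekeeping panel;
#' limiting-dilution doses of 1, 5 and 10 cells/well with 16 wells each at
#' a true frequency of 1/5.  These defaults are illustrative,
#' paper-shaped conditions, not a reproduction of any dataset.
#'
#' @param seed Integer seed; every generator is a pure function of
#'   `(cfg, seed)`.
#' @param n_genes,n_chroms Gene-universe size and chromosome count.
#' @param gene_length Length-2 numeric: uniform bounds on gene length, bp.
#' @param state_priors Named probabilities over the four states (sum 1).
#' @param transition_kernel 4 x 4 row-stochastic matrix, rows/cols the
#'   four states, giving `P(state_B | state_A)`.
#' @param flank Annotation window flank, bp.
#' @param expr_means,expr_sd Per-state log2 expression means and common sd.
#' @param n_housekeeping,hk_mean,hk_sd Housekeeping panel size and its
#'   (tight) log2 distribution.
#' @param sample_offset_sd SD of the per-sample additive offset planted to
#'   exercise housekeeping normalization.
#' @param n_replicates Arrays per condition.
#' @param elda_lambda,elda_doses,elda_wells Limiting-dilution truth.
#' @param community_sizes,p_within,p_between Planted-community edge model.
#' @param chrom_length Optional chromosome length, bp; `Inf` disables the
#'   packing check.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_genes = 300L,
                       n_chroms = 3L,
                       gene_length = c(2000, 20000),
                       state_priors = c(K4 = 0.48, K27 = 0.10,
                                        BIVALENT = 0.10, NONE = 0.32),
                       transition_kernel = default_kernel(),
                       flank = 20000L,
                       expr_means = c(K4 = 10, BIVALENT = 8,
                                      NONE = 5.5, K27 = 5),
                       expr_sd = 1,
                       n_housekeeping = 30L,
                       hk_mean = 8, hk_sd = 0.05,
                       sample_offset_sd = 0.5,
                       n_replicates = 3L,
                       elda_lambda = 1 / 5,
                       elda_doses = c(1, 5, 10),
                       elda_wells = 16L,
                       community_sizes = c(8L, 8L, 8L),
                       p_within = 0.8,
                       p_between = 0.05,
                       chrom_length = Inf) {
  cfg <- list(seed = as.integer(seed), n_genes = as.integer(n_genes),
              n_chroms = as.integer(n_chroms), gene_length = gene_length,
              state_priors = state_priors[STATES],
              transition_kernel = transition_kernel,
              flank = as.integer(flank),
              expr_means = expr_means, expr_sd = expr_sd,
              n_housekeeping = as.integer(n_housekeeping),
              hk_mean = hk_mean, hk_sd = hk_sd,
              sample_offset_sd = sample_offset_sd,
              n_replicates = as.integer(n_replicates),
              elda_lambda = elda_lambda, elda_doses = elda_doses,
              elda_wells = as.integer(elda_wells),
              community_sizes = as.integer(community_sizes),
              p_within = p_within, p_between = p_between,
              chrom_length = chrom_length)
  if (abs(sum(cfg$state_priors) - 1) > 1e-9)
    stop("state_priors must sum to 1")
  k <- cfg$transition_kernel
  if (!is.matrix(k) || any(dim(k) != 4L) ||
      any(abs(rowSums(k) - 1) > 1e-9))
    stop("transition_kernel must be 4 x 4 row-stochastic")
  if (is.null(dimnames(k))) dimnames(k) <- list(STATES, STATES)
  cfg$transition_kernel <- k[STATES, STATES]
  if (cfg$expr_sd <= 0 || cfg$hk_sd <= 0) stop("sds must be > 0")
  class(cfg) <- "sim_config"
  cfg
}

#' Default paper-shaped transition kernel
#'
#' Row change fractions: K4 12.8% (0.8% to K27, 8.5% to bivalent, 3.5% to
#' none), K27 44% (4.5% to K4), bivalent 49% (34% to K4, 11.5% to K27),
#' and a NONE row solved so the overall change rate under the default
#' priors is 22%.
#'
#' @return 4 x 4 row-stochastic matrix.
#' @export
default_kernel <- function() {
  k <- rbind(
    K4       = c(K4 = 0.872, K27 = 0.008, BIVALENT = 0.085, NONE = 0.035),
    K27      = c(K4 = 0.045, K27 = 0.560, BIVALENT = 0.200, NONE = 0.195),
    BIVALENT = c(K4 = 0.340, K27 = 0.115, BIVALENT = 0.510, NONE = 0.035),
    NONE     = c(K4 = 0.100, K27 = 0.050, BIVALENT = 0.055, NONE = 0.795))
  k[STATES, STATES]
}

# Per-generator seed offsets keep the draws of different generators
# decoupled while remaining pure functions of cfg$seed.
sim_seed <- function(cfg, offset) set.seed((cfg$seed + offset) %% .Machine$integer.max)

#' Simulate a gene table with non-overlapping flanked windows
#'
#' Places genes sequentially along chromosomes with inter-gene gaps
#' strictly greater than twice the flank, so no two flanked windows
#' intersect and every peak maps to exactly one gene (the round-trip
#' recovery property).
#'
#' @param cfg A `sim_config`.
#' @return A `gene_table`.
#' @export
simulate_gene_table <- function(cfg) {
  sim_seed(cfg, 101L)
  n <- cfg$n_genes
  if (!n) return(collapse_transcripts(
    data.frame(gene_id = character(), chrom = character(),
               strand = character(), tx_start = integer(),
               tx_end = integer(), stringsAsFactors = FALSE)))
  chrom <- paste0("chr", rep_len(seq_len(cfg$n_chroms), n))
  len <- round(stats::runif(n, cfg$gene_length[1L], cfg$gene_length[2L]))
  gap <- 2L * cfg$flank + 1L + round(stats::runif(n, 0, cfg$flank))
  strand <- sample(c("+", "-"), n, replace = TRUE)
  start <- integer(n)
  cursor <- stats::setNames(rep(0, cfg$n_chroms),
                            paste0("chr", seq_len(cfg$n_chroms)))
  for (i in seq_len(n)) {
    start[i] <- cursor[chrom[i]] + gap[i]
    cursor[chrom[i]] <- start[i] + len[i]
  }
  if (any(cursor > cfg$chrom_length))
    stop("genes do not fit on chromosomes of length ", cfg$chrom_length,
         "; reduce n_genes or gene_length")
  df <- data.frame(gene_id = sprintf("G%04d", seq_len(n)), chrom = chrom,
                   strand = strand, tx_start = as.integer(start),
                   tx_end = as.integer(start + len),
                   stringsAsFactors = FALSE)
  collapse_transcripts(df)
}

#' Simulate a planted two-condition state table
#'
#' Condition-A states are drawn i.i.d. from the priors; condition-B
#' states from the transition kernel row of the condition-A state.
#'
#' @param cfg A `sim_config`.
#' @param genes Optional `gene_table` supplying the gene ids (default:
#'   ids `G0001..`).
#' @return A `state_table` with conditions `("A", "B")`.
#' @export
simulate_states <- function(cfg, genes = NULL) {
  sim_seed(cfg, 202L)
  ids <- if (is.null(genes)) sprintf("G%04d", seq_len(cfg$n_genes)) else
    genes$gene_id
  n <- length(ids)
  state_a <- sample(STATES, n, replace = TRUE, prob = cfg$state_priors)
  state_b <- vapply(state_a, function(s) {
    sample(STATES, 1L, prob = cfg$transition_kernel[s, ])
  }, "")
  state_table(stats::setNames(state_a, ids), stats::setNames(state_b, ids))
}

#' Render planted states as per-condition, per-mark peak calls
#'
#' The inverse of annotation: each gene emits one K4me3 peak inside its
#' body iff its state includes the active mark (`K4` or `BIVALENT`) and
#' one K27me3 peak iff it includes the repressive mark, with peak lengths
#' uniform on 200-500 bp (clipped to the gene body, mirroring sonication
#' fragment sizes).
#'
#' @param st A `state_table` over the genes of `genes`.
#' @param genes A `gene_table` (windows must not overlap for exact
#'   round-trip recovery; [simulate_gene_table()] guarantees this).
#' @param cfg A `sim_config`.
#' @return Named list `peaks[[condition]][[mark]]` of `peak_calls`.
#' @export
render_peaks <- function(st, genes, cfg) {
  sim_seed(cfg, 303L)
  stopifnot(setequal(st$gene_id, genes$gene_id))
  genes <- genes[match(st$gene_id, genes$gene_id), , drop = FALSE]
  conds <- attr(st, "conditions")
  out <- list()
  for (ci in 1:2) {
    state <- if (ci == 1L) st$state_a else st$state_b
    cond <- conds[ci]
    out[[cond]] <- list()
    for (m in MARKS) {
      want <- if (m == "K4me3") state %in% c("K4", "BIVALENT") else
        state %in% c("K27", "BIVALENT")
      idx <- which(want)
      if (!length(idx)) {
        out[[cond]][[m]] <- empty_peaks(m, cond)
        next
      }
      body_len <- genes$tx_end[idx] - genes$tx_start[idx]
      len <- pmin(round(stats::runif(length(idx), 200, 500)), body_len)
      offs <- floor(stats::runif(length(idx)) * (body_len - len + 1))
      pstart <- genes$tx_start[idx] + offs
      pk <- data.frame(chrom = genes$chrom[idx],
                       start = as.integer(pstart),
                       end = as.integer(pstart + len),
                       score = NA_real_, mark = m, condition = cond,
                       stringsAsFactors = FALSE)
      class(pk) <- c("peak_calls", "data.frame")
      out[[cond]][[m]] <- pk
    }
  }
  out
}

#' Simulate a state-coupled expression matrix
#'
#' Per gene and replicate sample, a normal draw around the state-specific
#' mean of the relevant condition; housekeeping genes come from a
#' dedicated tight distribution; a per-sample additive offset is planted
#' so that [housekeeping_normalize()] has real work to do.
#'
#' @param st A `state_table`.
#' @param cfg A `sim_config`.
#' @return An `expr_matrix` with samples `<cond>_rep<i>` for both
#'   conditions and housekeeping genes `HK001..`;
#'   `attr(, "sample_offsets")` holds the planted offsets.
#' @export
simulate_expression <- function(st, cfg) {
  sim_seed(cfg, 404L)
  conds <- attr(st, "conditions")
  samples <- paste0(rep(conds, each = cfg$n_replicates), "_rep",
                    rep(seq_len(cfg$n_replicates), 2L))
  hk_ids <- sprintf("HK%03d", seq_len(cfg$n_housekeeping))
  ids <- c(st$gene_id, hk_ids)
  m <- matrix(NA_real_, length(ids), length(samples),
              dimnames = list(ids, samples))
  for (j in seq_along(samples)) {
    cond_idx <- if (j <= cfg$n_replicates) 1L else 2L
    state <- if (cond_idx == 1L) st$state_a else st$state_b
    m[st$gene_id, j] <- stats::rnorm(nrow(st),
                                     cfg$expr_means[state], cfg$expr_sd)
    m[hk_ids, j] <- stats::rnorm(length(hk_ids), cfg$hk_mean, cfg$hk_sd)
  }
  offsets <- stats::rnorm(length(samples), 0, cfg$sample_offset_sd)
  m <- sweep(m, 2L, offsets, `+`)
  em <- expr_matrix(m, housekeeping = hk_ids)
  attr(em, "sample_offsets") <- stats::setNames(offsets, samples)
  em
}

#' Simulate a limiting-dilution assay
#'
#' Wells are positive with probability `1 - exp(-lambda * dose)`.
#'
#' @param cfg A `sim_config` (fields `elda_lambda`, `elda_doses`,
#'   `elda_wells`).
#' @param lambda Optional override of the true frequency.
#' @return A `dilution_assay`.
#' @export
simulate_dilution <- function(cfg, lambda = cfg$elda_lambda) {
  sim_seed(cfg, 505L)
  p <- -expm1(-lambda * cfg$elda_doses)
  pos <- stats::rbinom(length(cfg$elda_doses), cfg$elda_wells, p)
  dilution_assay(cfg$elda_doses, rep(cfg$elda_wells,
                                     length(cfg$elda_doses)), pos)
}

#' Simulate a planted-community interaction edge list
#'
#' Within-community pairs get edges with probability `p_within` and
#' confidences shifted above 0.7 (`0.7 + 0.3 * Beta(2, 2)`); between-
#' community pairs with probability `p_between` and confidences below 0.7
#' (`0.7 * Beta(2, 5)`), so thresholding at 0.7 recovers the communities
#' when the edge probabilities are extreme.
#'
#' @param cfg A `sim_config` (fields `community_sizes`, `p_within`,
#'   `p_between`).
#' @return List with `edges` (an `edge_list`) and `communities` (named
#'   membership vector).
#' @export
simulate_edges <- function(cfg) {
  sim_seed(cfg, 606L)
  sizes <- cfg$community_sizes
  n <- sum(sizes)
  nodes <- sprintf("TF%03d", seq_len(n))
  member <- stats::setNames(rep(seq_along(sizes), sizes), nodes)
  pairs <- utils::combn(n, 2L)
  same <- member[pairs[1L, ]] == member[pairs[2L, ]]
  prob <- ifelse(same, cfg$p_within, cfg$p_between)
  draw <- stats::runif(ncol(pairs)) < prob
  conf <- ifelse(same, 0.7 + 0.3 * stats::rbeta(ncol(pairs), 2, 2),
                 0.7 * stats::rbeta(ncol(pairs), 2, 5))
  df <- data.frame(node_a = nodes[pairs[1L, draw]],
                   node_b = nodes[pairs[2L, draw]],
                   confidence = conf[draw],
                   channel = ifelse(same[draw], "within", "between"),
                   stringsAsFactors = FALSE)
  list(edges = as_edge_list(df), communities = member)
}

#' Simulate a qPCR Ct table with planted fold changes
#'
#' For each target, Ct values follow `Ct = base_ct - log2(expression)`:
#' the treated sample's delta-Ct is shifted by `-log2(fold)` relative to
#' the control, with tight replicate noise; the TBP reference is constant
#' across samples up to noise.
#'
#' @param cfg A `sim_config`.
#' @param folds Named numeric vector of planted fold changes per target
#'   (default `c(GENEA = 2, GENEB = 0.25)`).
#' @param samples Length-2 labels `(treated, control)`.
#' @param n_rep Replicate wells per (target, sample).
#' @param ct_sd Replicate noise SD in cycles.
#' @return Data frame `target`, `sample`, `ct` including TBP reference
#'   wells; `attr(, "folds")` holds the truth.
#' @export
simulate_ct <- function(cfg, folds = c(GENEA = 2, GENEB = 0.25),
                        samples = c("treated", "control"),
                        n_rep = 3L, ct_sd = 0.05) {
  sim_seed(cfg, 707L)
  base_ct <- c(stats::setNames(rep(24, length(folds)), names(folds)),
               TBP = 20)
  rows <- list()
  for (g in c(names(folds), "TBP")) {
    for (s in samples) {
      shift <- if (g != "TBP" && s == samples[1L]) -log2(folds[[g]]) else 0
      rows[[paste(g, s)]] <- data.frame(
        target = g, sample = s,
        ct = stats::rnorm(n_rep, base_ct[[g]] + shift, ct_sd),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "folds") <- folds
  out
}
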