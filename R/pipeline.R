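#' Write a full synthetic input bundle to disk
#'
#' Materializes every file the pipeline consumes -- gene table, per
#' condition/mark BED peak files, expression matrix with housekeeping
#' panel, a GMT built from the planted states, an interaction edge list,
#' a dilution assay and a Ct table -- plus a `truth/` directory with the
#' planted parameters, so [run_pipeline()] can be exercised end to end
#' with known ground truth.
#'
#' @param cfg A `sim_config`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the list of generated objects and file paths.
#' @export
simulate_inputs <- function(cfg, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "truth"), showWarnings = FALSE)
  genes <- simulate_gene_table(cfg)
  st <- simulate_states(cfg, genes)
  peaks <- render_peaks(st, genes, cfg)
  em <- simulate_expression(st, cfg)
  edges <- simulate_edges(cfg)
  assay <- simulate_dilution(cfg)
  ct <- simulate_ct(cfg)

  paths <- list(genes = file.path(dir, "genes.tsv"),
                expr = file.path(dir, "expression.tsv"),
                housekeeping = file.path(dir, "housekeeping.txt"),
                gmt = file.path(dir, "sets.gmt"),
                edges = file.path(dir, "edges.tsv"),
                dilution = file.path(dir, "dilution.tsv"),
                ct = file.path(dir, "ct.tsv"))
  write_gene_table(genes, paths$genes)
  write_matrix(em, paths$expr)
  writeLines(em$housekeeping, paths$housekeeping)
  paths$peaks <- list()
  for (cond in names(peaks)) for (m in MARKS) {
    p <- file.path(dir, sprintf("peaks_%s_%s.bed", cond, m))
    write_bed(peaks[[cond]][[m]], p)
    paths$peaks[[cond]][[m]] <- p
  }
  # one gene set per condition-A state, a natural planted collection
  sets <- split(st$gene_id, st$state_a)
  sets <- sets[lengths(sets) > 0]
  attr(sets, "descriptions") <- stats::setNames(
    paste("genes in state", names(sets), "under", attr(st, "conditions")[1L]),
    names(sets))
  class(sets) <- "gene_sets"
  write_gmt(sets, paths$gmt)
  write_edges(edges$edges, paths$edges)
  utils::write.table(assay, paths$dilution, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(ct, paths$ct, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  utils::write.table(as.data.frame(st), file.path(dir, "truth", "states.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(node = names(edges$communities),
               community = edges$communities),
    file.path(dir, "truth", "communities.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(seed = cfg$seed, state_priors = as.list(cfg$state_priors),
         transition_kernel = cfg$transition_kernel,
         elda_lambda = cfg$elda_lambda, flank = cfg$flank),
    file.path(dir, "truth", "parameters.json"),
    auto_unbox = TRUE, digits = NA)
  invisible(list(genes = genes, states = st, peaks = peaks,
                 expression = em, edges = edges, dilution = assay,
                 ct = ct, paths = paths))
}

#' Run the chromatin-state pipeline end to end
#'
#' Executes annotate -> classify -> transitions -> expression ->
#' enrichment -> network -> PCA on file inputs, writing one TSV per stage,
#' a machine-readable `summary.json` and a human-readable `run.log` to the
#' output directory.  Any stage failure aborts with the failing stage
#' named.  The run is deterministic given (inputs, config).
#'
#' @param config Either a list or the path of a YAML file with entries:
#'   `conditions` (length-2, reference first), `genes` (gene-table path),
#'   `peaks` (per condition, per mark BED paths:
#'   `peaks$<cond>$K4me3` etc.), `flank` (default 20000), `expr` +
#'   `housekeeping` (optional expression inputs), `gmt` (optional gene
#'   sets), `edges`, `threshold` (default 0.7), `candidates`, `max_added`
#'   (optional network inputs), `pca_matrix`, `pca_query`,
#'   `pca_signature` (optional co-variation inputs).
#' @param out_dir Output directory.
#' @return Invisibly, a list with the per-stage objects and the summary.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  logfile <- file.path(out_dir, "run.log")
  cat(sprintf("markshift %s  started %s\n",
              as.character(utils::packageVersion("markshift")),
              format(Sys.time())), file = logfile)
  log_line <- function(...) {
    msg <- sprintf(...)
    message(msg)
    cat(msg, "\n", file = logfile, append = TRUE, sep = "")
  }
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(force(expr), error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
    log_line("stage %-12s ok (%.2f s)", name, proc.time()[["elapsed"]] - t0)
    res
  }
  conds <- config$conditions %||% c("A", "B")
  flank <- config$flank %||% 20000L
  summary <- list(conditions = conds, flank = flank)

  genes <- stage("genes", read_gene_table(config$genes))
  summary$n_genes <- nrow(genes)

  states <- list()
  for (cond in conds) {
    pk <- stage(paste0("annotate_", cond), {
      do.call(rbind, lapply(MARKS, function(m)
        read_bed(config$peaks[[cond]][[m]], mark = m, condition = cond)))
    })
    asn <- assign_marks(pk, genes, flank)
    utils::write.table(asn$assignment,
                       file.path(out_dir, sprintf("assign_%s.tsv", cond)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    states[[cond]] <- classify_states(asn)
  }
  st <- stage("states", state_table(states[[conds[1L]]],
                                    states[[conds[2L]]], conds))
  utils::write.table(as.data.frame(st), file.path(out_dir, "states.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  summary$state_counts_a <- as.list(table(factor(st$state_a, STATES)))

  tm <- stage("transitions", transition_matrix(st))
  tmat <- data.frame(from = rownames(tm$counts), tm$counts,
                     row_total = tm$row_totals,
                     check.names = FALSE)
  utils::write.table(tmat, file.path(out_dir, "transitions.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  changed <- changed_gene_set(st)
  writeLines(changed, file.path(out_dir, "changed_genes.txt"))
  summary$transition_counts <- tm$counts
  summary$transition_row_pct <- round(tm$percentages, 1)
  summary$n_changed <- length(changed)
  summary$pct_changed <- round(100 * length(changed) / nrow(st), 1)
  summary$pct_changed_by_origin <-
    as.list(round(change_fraction_by_origin(tm), 1))
  summary$venn_by_final_state <- as.list(venn_summary(st))

  if (!is.null(config$expr)) {
    em <- stage("expression", {
      em <- read_matrix(config$expr,
                        housekeeping = config$housekeeping %||% character())
      if (length(em$housekeeping)) em <- housekeeping_normalize(em)
      em
    })
    sx <- stratify_and_test(em, states[[conds[1L]]])
    utils::write.table(sx$groups,
                       file.path(out_dir, "expression_summary.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    summary$expression_ordering_ok <- sx$ordering_ok
    summary$expression_medians <-
      as.list(stats::setNames(round(sx$groups$median, 3), sx$groups$state))
  }

  if (!is.null(config$gmt)) {
    enr <- stage("enrichment", hypergeom_enrich(
      changed, read_gmt(config$gmt), background = genes$gene_id))
    utils::write.table(enr, file.path(out_dir, "enrichment.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    summary$n_enriched_terms_q05 <- sum(enr$q < 0.05)
  }

  if (!is.null(config$edges)) {
    net <- stage("network", {
      edges <- read_edges(config$edges)
      nodes <- if (!is.null(config$network_nodes))
        readLines(config$network_nodes, warn = FALSE) else
          unique(c(edges$node_a, edges$node_b))
      net <- filter_and_induce(edges, nodes,
                               threshold = config$threshold %||% 0.7)
      if (!is.null(config$candidates)) {
        aug <- augment_network(net,
                               readLines(config$candidates, warn = FALSE),
                               edges, max_added = config$max_added %||% 3L)
        summary$network_added <- aug$added
        net <- aug$network
      }
      net
    })
    comp <- data.frame(node = names(net$membership),
                       component = as.integer(net$membership))
    utils::write.table(comp, file.path(out_dir, "network_components.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    summary$network_components <- length(net$components)
    summary$network_largest_component <-
      if (length(net$components)) max(lengths(net$components)) else 0L
  }

  if (!is.null(config$pca_matrix)) {
    pca <- stage("pca", {
      zm <- read_matrix(config$pca_matrix)
      pca_circle(t(zm$values))
    })
    circ <- data.frame(gene = rownames(pca$var_cor),
                       pca$var_cor[, 1:2, drop = FALSE])
    utils::write.table(circ, file.path(out_dir, "pca_circle.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    summary$pca_explained_f1f2 <- round(pca$explained[1:2], 4)
    if (!is.null(config$pca_query) && !is.null(config$pca_signature)) {
      sig <- readLines(config$pca_signature, warn = FALSE)
      cv <- covariation_score(pca, config$pca_query, sig)
      summary$covariation_score <- round(cv$score, 4)
      summary$covariation_f1_sign_agreement <- cv$f1_sign_agreement
    }
  }

  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  log_line("pipeline complete: %s", out_dir)
  invisible(list(states = st, transitions = tm, summary = summary))
}
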