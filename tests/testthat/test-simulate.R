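test_that("generators are pure functions of the config seed", {
  cfg <- sim_config(seed = 5, n_genes = 60)
  expect_identical(simulate_gene_table(cfg), simulate_gene_table(cfg))
  expect_identical(simulate_states(cfg), simulate_states(cfg))
  expect_identical(simulate_dilution(cfg), simulate_dilution(cfg))
  expect_identical(simulate_edges(cfg), simulate_edges(cfg))
  cfg2 <- sim_config(seed = 6, n_genes = 60)
  expect_false(identical(simulate_states(cfg), simulate_states(cfg2)))
})

test_that("simulated flanked windows never overlap (brute force)", {
  cfg <- sim_config(seed = 3, n_genes = 80, n_chroms = 2)
  g <- simulate_gene_table(cfg)
  w <- index_windows(build_interval_index(g, cfg$flank))
  for (chr in unique(w$chrom)) {
    wc <- w[w$chrom == chr, ]
    wc <- wc[order(wc$win_start), ]
    if (nrow(wc) > 1)
      expect_true(all(wc$win_start[-1] >= wc$win_end[-nrow(wc)]))
  }
  expect_equal(nrow(simulate_gene_table(sim_config(n_genes = 0))), 0L)
  expect_error(simulate_gene_table(sim_config(n_genes = 500,
                                              chrom_length = 1e5)),
               "reduce n_genes")
})

test_that("identity kernel plants zero changes", {
  cfg <- sim_config(seed = 4, n_genes = 200,
                    transition_kernel = diag(4))
  st <- simulate_states(cfg)
  expect_equal(st$state_a, st$state_b)
  expect_length(changed_gene_set(st), 0L)
})

test_that("planted priors and kernel are recovered within 3 SDs", {
  cfg <- sim_config(seed = 10, n_genes = 10000)
  st <- simulate_states(cfg)
  # priors (multinomial bound per state)
  for (s in names(cfg$state_priors)) {
    p <- cfg$state_priors[[s]]
    phat <- mean(st$state_a == s)
    expect_lt(abs(phat - p), 3 * sqrt(p * (1 - p) / nrow(st)))
  }
  # kernel rows
  tm <- transition_matrix(st)
  for (s in rownames(cfg$transition_kernel)) {
    n_row <- tm$row_totals[[s]]
    for (t in colnames(cfg$transition_kernel)) {
      p <- cfg$transition_kernel[s, t]
      phat <- tm$counts[s, t] / n_row
      expect_lt(abs(phat - p),
                3 * sqrt(p * (1 - p) / n_row) + 1e-9)
    }
  }
  # overall change rate ~22% under the default kernel and priors
  planted <- sum(cfg$state_priors *
                   (1 - diag(cfg$transition_kernel[names(cfg$state_priors),
                                                   names(cfg$state_priors)])))
  expect_equal(planted, 0.22, tolerance = 0.005)
  frac <- length(changed_gene_set(st)) / nrow(st)
  expect_lt(abs(frac - planted), 3 * sqrt(planted * (1 - planted) / nrow(st)))
})

test_that("rendered peaks reflect the planted states gene by gene", {
  cfg <- sim_config(seed = 8, n_genes = 120)
  g <- simulate_gene_table(cfg)
  st <- simulate_states(cfg, g)
  pk <- render_peaks(st, g, cfg)
  # NONE gene: no peaks; BIVALENT gene: exactly one peak per mark
  for (cond_i in 1:2) {
    state <- if (cond_i == 1) st$state_a else st$state_b
    cond <- attr(st, "conditions")[cond_i]
    n_k4 <- sum(state %in% c("K4", "BIVALENT"))
    n_k27 <- sum(state %in% c("K27", "BIVALENT"))
    expect_equal(nrow(pk[[cond]]$K4me3), n_k4)
    expect_equal(nrow(pk[[cond]]$K27me3), n_k27)
  }
  # peaks sit within gene bodies
  all_pk <- rbind(pk$A$K4me3, pk$A$K27me3)
  ovl <- brute_assign(all_pk, g, 0)
  expect_equal(ovl$has_k4, st$state_a %in% c("K4", "BIVALENT"))
  expect_equal(ovl$has_k27, st$state_a %in% c("K27", "BIVALENT"))
})

test_that("planted states survive the full render -> annotate -> classify loop", {
  for (seed in c(1, 7, 19)) {
    cfg <- sim_config(seed = seed, n_genes = 100)
    g <- simulate_gene_table(cfg)
    st <- simulate_states(cfg, g)
    pk <- render_peaks(st, g, cfg)
    recovered <- lapply(c("A", "B"), function(cond) {
      classify_states(assign_marks(
        rbind(pk[[cond]]$K4me3, pk[[cond]]$K27me3), g, cfg$flank))
    })
    st2 <- state_table(recovered[[1]], recovered[[2]])
    m <- match(st$gene_id, st2$gene_id)
    expect_identical(st2$state_a[m], st$state_a)
    expect_identical(st2$state_b[m], st$state_b)
  }
})

test_that("expression generator recovers state means and planted offsets", {
  cfg <- sim_config(seed = 12, n_genes = 2000, n_replicates = 2)
  st <- simulate_states(cfg)
  em <- simulate_expression(st, cfg)
  norm <- housekeeping_normalize(em)
  # housekeeping panel centered on hk_mean: normalized group means are
  # (state mean - hk_mean) within 3 standard errors
  for (s in names(cfg$expr_means)) {
    idx <- st$gene_id[st$state_a == s]
    if (length(idx) < 30) next
    v <- rowMeans(norm$values[idx, 1:cfg$n_replicates, drop = FALSE])
    se <- sd(v) / sqrt(length(v))
    expect_lt(abs(mean(v) - (cfg$expr_means[[s]] - cfg$hk_mean)), 3 * se)
  }
  # planted per-sample offsets are removed by normalization up to hk noise
  offs <- attr(em, "sample_offsets")
  hk_noise <- 3 * cfg$hk_sd / sqrt(cfg$n_housekeeping)
  resid <- colMeans(em$values[em$housekeeping, ]) - cfg$hk_mean - offs
  expect_true(all(abs(resid) < hk_noise))
})

test_that("dilution generator honours the true frequency", {
  cfg <- sim_config(seed = 13)
  a0 <- simulate_dilution(cfg, lambda = 0)
  expect_equal(sum(a0$n_positive), 0L)  # lambda 0: all wells negative
  a <- simulate_dilution(cfg)
  expect_true(all(a$n_positive <= a$n_wells))
  expect_equal(a$dose, c(1, 5, 10))
})

test_that("extreme edge probabilities make components equal communities", {
  cfg <- sim_config(seed = 14, community_sizes = c(5L, 6L, 4L),
                    p_within = 1, p_between = 0)
  sim <- simulate_edges(cfg)
  net <- filter_and_induce(sim$edges, names(sim$communities),
                           threshold = 0.7)
  got <- lapply(net$components, sort)
  want <- lapply(split(names(sim$communities), sim$communities), sort)
  expect_setequal(got, unname(want))
})

test_that("planted qPCR folds are recovered within replicate noise", {
  cfg <- sim_config(seed = 15)
  ct <- simulate_ct(cfg, folds = c(GENEA = 2, GENEB = 0.25))
  expect_equal(ddct_fold_change(ct, "treated", "control", "GENEA"), 2,
               tolerance = 0.15)
  expect_equal(ddct_fold_change(ct, "treated", "control", "GENEB"), 0.25,
               tolerance = 0.05)
})
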