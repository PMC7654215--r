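# Generators: seeded determinism, planted-truth bookkeeping, and the
# statistical structure downstream stages assume.

test_that("identical configurations give identical outputs", {
  cfg <- synth_config(seed = 7, n_genes = 50, n_proteins = 60,
                      planted_module_size = 5, module_spokes = 4,
                      n_patients = 40, n_nuclei = 30)
  expect_identical(gen_expression_dataset(cfg), gen_expression_dataset(cfg))
  t1 <- suppressMessages(gen_interactome(cfg))
  t2 <- suppressMessages(gen_interactome(cfg))
  expect_identical(t1, t2)
  expect_identical(gen_disease_table(letters, cfg), gen_disease_table(letters, cfg))
  expect_identical(gen_survival_cohort(c("a", "b"), "a", cfg),
                   gen_survival_cohort(c("a", "b"), "a", cfg))
  expect_identical(gen_morphometry(cfg, c(N = 0.5, LR = 0.5)),
                   gen_morphometry(cfg, c(N = 0.5, LR = 0.5)))
})

test_that("expression generator plants the requested number of genes", {
  cfg <- synth_config(seed = 3, n_genes = 100, frac_expressed = 0.2)
  m <- gen_expression_dataset(cfg)
  expect_length(attr(m, "planted"), 20)
  expect_equal(dim(m), c(100, 3))
  expect_true(all(m > 0))
  cfg0 <- synth_config(seed = 3, n_genes = 10, frac_expressed = 0.05)
  expect_warning(gen_expression_dataset(cfg0), "no expressed genes planted")
})

test_that("planted genes rank higher within arrays than noise genes", {
  mean_rank_gap <- vapply(1:50, function(s) {
    cfg <- synth_config(seed = s, n_genes = 100, frac_expressed = 0.1)
    m <- gen_expression_dataset(cfg)
    planted <- rownames(m) %in% attr(m, "planted")
    r <- apply(m, 2, function(col) rank(-col))
    mean(r[planted, ]) - mean(r[!planted, ])
  }, 0)
  expect_lt(mean(mean_rank_gap), 0)
  # with well-separated components the gap should be large, not marginal
  expect_lt(mean(mean_rank_gap), -40)
})

test_that("interactome plants a clique-like module with high centrality", {
  cfg <- synth_config(seed = 11, n_proteins = 120, planted_module_size = 6,
                      module_spokes = 5)
  tab <- suppressMessages(gen_interactome(cfg))
  module <- attr(tab, "module")
  expect_length(module, 6)
  expect_gte(length(attr(tab, "anchors")), 2)
  # all module pairs present as edges
  key <- paste(pmin(tab$node_a, tab$node_b), pmax(tab$node_a, tab$node_b))
  pairs <- t(combn(sort(module), 2))
  expect_true(all(paste(pairs[, 1], pairs[, 2]) %in% key))
  # degenerate generator guard
  expect_error(gen_interactome(synth_config(n_proteins = 5,
                                            attachment_parameter = 5,
                                            planted_module_size = 2)),
               class = "hb_degenerate_generator")
})

test_that("module members out-rank the network in degree across seeds", {
  gaps <- vapply(1:20, function(s) {
    cfg <- synth_config(seed = s, n_proteins = 100, planted_module_size = 5,
                        module_spokes = 4)
    tab <- suppressMessages(gen_interactome(cfg))
    net <- suppressMessages(build_network(tab, 0))
    rec <- compute_centralities(net)
    mean(rec$degree[rec$node %in% attr(tab, "module")]) - mean(rec$degree)
  }, 0)
  expect_true(all(gaps > 0))
})

test_that("chemical link generation adds the expected edges", {
  cfg <- synth_config(seed = 5, n_proteins = 80, planted_module_size = 5,
                      module_spokes = 4)
  tab <- suppressMessages(gen_interactome(cfg))
  out <- suppressMessages(gen_chemical_links(tab, c("RSV", "DOXO"), 5, cfg,
                                             module_targets = 3))
  expect_equal(nrow(out) - nrow(tab), 10)
  expect_setequal(unique(out$kind_a[out$node_a %in% c("RSV", "DOXO")]),
                  "chemical")
  # explicit shared targets: both chemicals share all targets
  shared <- attr(tab, "module")
  out2 <- suppressMessages(gen_chemical_links(
    tab, c("RSV", "DOXO"), 5, cfg,
    targets = list(RSV = shared, DOXO = shared)))
  tg <- attr(out2, "chemical_targets")
  expect_setequal(tg$RSV, tg$DOXO)
  expect_error(
    suppressMessages(gen_chemical_links(
      tab, "RSV", 2, cfg, targets = list(RSV = c("NOPE1", "NOPE2")))),
    class = "hb_unknown_target")
})

test_that("disease table puts planted genes at the top of the scale", {
  cfg <- synth_config(seed = 9)
  genes <- sprintf("G%02d", 1:30)
  tab <- gen_disease_table(genes, cfg, planted = genes[1:4])
  expect_setequal(select_disease_genes(tab, confidence_cutoff = 1, top_n = 100),
                  genes[1:4])
  expect_identical(tab, gen_disease_table(genes, cfg, planted = genes[1:4]))
  # top-k selection size = min(k, passing rows)
  expect_length(select_disease_genes(tab, confidence_cutoff = 0, top_n = 7), 7)
  expect_length(select_disease_genes(tab, confidence_cutoff = 1, top_n = 7), 4)
  expect_error(gen_disease_table(character(0), cfg), class = "hb_bad_argument")
})

test_that("survival cohort respects censoring and hazard settings", {
  cfg0 <- synth_config(seed = 2, n_patients = 50, censoring_rate = 0)
  coh <- gen_survival_cohort(c("g1", "g2"), "g1", cfg0)
  expect_true(all(coh$event == 1))
  expect_equal(nrow(coh), 50)
  expect_error(gen_survival_cohort(
    "g1", "g1", synth_config(censoring_rate = 1)), class = "hb_bad_argument")
  expect_error(gen_survival_cohort("g1", "zz", cfg0),
               class = "hb_bad_argument")
})

test_that("null cohorts give uniform logrank p-values", {
  # planted_log_hazard = 0: the split carries no hazard information
  pvals <- vapply(1:200, function(s) {
    cfg <- synth_config(seed = s, n_patients = 80, planted_log_hazard = 0,
                        censoring_rate = 0.2)
    coh <- gen_survival_cohort("g1", "g1", cfg)
    grp <- median_split(coh, "g1")
    logrank_test(coh$time_months, coh$event, grp)$p_value
  }, 0)
  ks <- suppressWarnings(stats::ks.test(pvals, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("a planted hazard gene is detected with high power", {
  hits <- vapply(1:50, function(s) {
    cfg <- synth_config(seed = s, n_patients = 400, planted_log_hazard = 1)
    coh <- gen_survival_cohort("g1", "g1", cfg)
    grp <- median_split(coh, "g1")
    logrank_test(coh$time_months, coh$event, grp)$p_value < 0.05
  }, TRUE)
  expect_gte(mean(hits), 0.9)
})

test_that("morphometry generator round-trips through the classifier", {
  cfg <- synth_config(seed = 4, n_nuclei = 300)
  ctrl <- gen_morphometry_control(cfg)
  pure_n <- gen_morphometry(cfg, c(N = 1))
  cls <- classify_nuclei(pure_n, ctrl)
  expect_gte(mean(cls$class == "N"), 0.95)
  expect_equal(nrow(pure_n), 300)
  mix <- gen_morphometry(cfg, c(N = 0.4, SR = 0.2, SI = 0.1, LR = 0.2,
                                LIr = 0.1))
  cls2 <- classify_nuclei(mix, ctrl)
  expect_gte(mean(cls2$class == cls2$true_class), 0.9)
  expect_error(gen_morphometry(cfg, c(N = 0.5, SR = 0.4)),
               class = "hb_bad_argument")
})
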