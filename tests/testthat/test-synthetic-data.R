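test_that("generators are deterministic under a fixed seed", {
  p1 <- make_toy_model_pair(seed = 4)
  p2 <- make_toy_model_pair(seed = 4)
  expect_identical(p1, p2)

  c1 <- simulate_growth_curve(0.4, 0.1, 12, noise_sd = 0.01, seed = 9)
  c2 <- simulate_growth_curve(0.4, 0.1, 12, noise_sd = 0.01, seed = 9)
  expect_identical(c1, c2)

  d <- sim_design(seed = 11)
  expect_identical(simulate_peak_table(d), simulate_peak_table(d))

  g1 <- make_knowledge_graph(seed = 5)
  g2 <- make_knowledge_graph(seed = 5)
  expect_identical(igraph::as_edgelist(g1$graph), igraph::as_edgelist(g2$graph))
  expect_identical(g1$truth, g2$truth)
})

test_that("toy model pair plants a knockout effect under exactly one variant", {
  pair <- make_toy_model_pair(seed = 7)
  m <- pair$model
  ko <- pair$truth$affected_genes
  # wild type grows under both variants in both phases
  for (ph in c("pre", "post")) {
    expect_gt(solve_fba(m, pair$rules_m1, NULL, ph)$objective, 0)
    expect_gt(solve_fba(m, pair$rules_m1smart, NULL, ph)$objective, 0)
  }
  # rule sets differ and reference only known genes/reactions
  expect_gt(nrow(pair$rules_m1smart), nrow(pair$rules_m1))
  expect_true(all(pair$rules_m1smart$reaction %in% m$reactions))
  expect_true(all(setdiff(pair$rules_m1smart$gene, "-") %in% m$genes))
  # planted gene changes post-shift growth under exactly one variant
  g_m1 <- solve_fba(m, pair$rules_m1, ko, "post")$objective
  g_m1s <- solve_fba(m, pair$rules_m1smart, ko, "post")$objective
  wt <- solve_fba(m, pair$rules_m1, NULL, "post")$objective
  expect_equal(g_m1, wt, tolerance = 1e-8)
  expect_lt(g_m1s, 1e-8)
})

test_that("toy model precondition and retry diagnostics are enforced", {
  expect_error(make_toy_model_pair(n_internal_mets = 3), "n_internal_mets")
  expect_error(make_toy_model_pair(n_regulator_genes = 0), "n_regulator_genes")
  # padding the glycolysis chain keeps the wild type viable
  pair <- make_toy_model_pair(n_internal_mets = 8, seed = 2)
  expect_gte(nrow(pair$model$S), 8)
  expect_gt(solve_fba(pair$model, pair$rules_m1, NULL, "pre")$objective, 0)
})

test_that("growth-curve generator matches its piecewise-exponential contract", {
  # noiseless: log-OD slope before the shift equals pre_rate to 1e-9
  cv <- simulate_growth_curve(0.4, 0.1, 12, lag = 0, noise_sd = 0,
                              dt = 1 / 3, od0 = 0.005)
  pre <- cv$time < 12 - 1e-9
  slopes <- diff(log(cv$od_raw[pre])) / diff(cv$time[pre])
  expect_lt(max(abs(slopes - 0.4)), 1e-9)
  # readings clipped to the instrument range
  cv2 <- simulate_growth_curve(0.5, 0.2, 10, noise_sd = 0, horizon = 60,
                               od0 = 0.01)
  expect_true(all(cv2$od_raw >= 0 & cv2$od_raw <= 2))
  # rejected inputs
  expect_error(simulate_growth_curve(-0.1, 0.1, 5), "positive")
  expect_error(simulate_growth_curve(0.4, 0.1, 5, horizon = -1), "positive")
  # the instrument-response mode is undone by the calibration polynomial
  cv3 <- simulate_growth_curve(0.3, 0.1, 8, noise_sd = 0, od0 = 0.05,
                               instrument_response = TRUE, horizon = 12)
  true_od <- simulate_growth_curve(0.3, 0.1, 8, noise_sd = 0, od0 = 0.05,
                                   horizon = 12)$od_raw
  expect_equal(suppressWarnings(adjust_od(cv3$od_raw)), true_od,
               tolerance = 1e-8)
})

test_that("peak-table simulator plants recoverable effects and clean controls", {
  # planted two-fold phase effect recovers as a geometric-mean ratio near 2
  d <- sim_design(n_strains = 1, replicates_per_condition = 12, n_batches = 1,
                  n_features = 40, missing_rate = 0, noise_sd = 0.2,
                  biological_sd = 0, batch_sd = 0, drift_amplitude = 0,
                  seed = 21)
  eff <- list(phase_lfc = c(F0001 = 1))
  sim <- simulate_peak_table(d, eff)
  tab <- sim$table
  st <- tab$samples$class == "sample"
  x <- tab$intensity["F0001", st]
  post <- tab$samples$phase[st] == "post"
  ratio <- exp(mean(log(x[post]))) / exp(mean(log(x[!post])))
  expect_gt(ratio, 2 * 2^(-3 * 0.2 * sqrt(2 / 12)))
  expect_lt(ratio, 2 * 2^(3 * 0.2 * sqrt(2 / 12)))
  expect_identical(names(sim$truth$true_diff_features), "F0001")

  # unknown features in the effect spec are rejected
  expect_error(simulate_peak_table(d, list(phase_lfc = c(NOPE = 1))),
               "unknown features")

  # QC replicates are tighter than study samples before drift is added
  d2 <- sim_design(n_features = 60, missing_rate = 0, drift_amplitude = 0,
                   seed = 22)
  tab2 <- simulate_peak_table(d2)$table
  qc_cv <- apply(tab2$intensity[, tab2$samples$class == "QC"], 1,
                 function(v) stats::sd(v) / mean(v))
  sm_cv <- apply(tab2$intensity[, tab2$samples$class == "sample"], 1,
                 function(v) stats::sd(v) / mean(v))
  expect_gt(mean(sm_cv > qc_cv), 0.9)

  # blanks carry only the noise floor
  blanks <- tab2$intensity[, tab2$samples$class == "blank"]
  study <- tab2$intensity[, tab2$samples$class == "sample"]
  expect_true(all(rowMeans(blanks) < rowMeans(study)))

  # missingness encoded as zeros at roughly the design rate (study samples)
  d3 <- sim_design(missing_rate = 0.1, n_features = 200, seed = 23)
  tab3 <- simulate_peak_table(d3)$table
  z <- mean(tab3$intensity[, tab3$samples$class == "sample"] == 0)
  expect_gt(z, 0.07)
  expect_lt(z, 0.13)
})

test_that("design invariants are validated", {
  expect_error(sim_design(replicates_per_condition = 1), "replicates")
  expect_error(sim_design(qc_interval = 1), "qc_interval")
  expect_error(sim_design(missing_rate = 1), "missing_rate")
})

test_that("knowledge graph is connected, typed, with disjoint planted/decoy sets", {
  kg <- make_knowledge_graph(n_pathways = 6, n_compounds = 40, seed = 13)
  g <- kg$graph
  expect_true(igraph::is_connected(g))
  expect_setequal(unique(igraph::V(g)$type),
                  c("pathway", "reaction", "compound"))
  # every compound reachable from at least one pathway (connectivity contract)
  pw <- igraph::V(g)$name[igraph::V(g)$type == "pathway"]
  comp <- igraph::V(g)$name[igraph::V(g)$type == "compound"]
  reach <- igraph::subcomponent(g, pw[1])
  expect_true(all(comp %in% names(reach)))
  # planted pathway's flagged compounds: >= 3, disjoint from the decoy's
  expect_gte(length(kg$truth$input_compounds), 3)
  decoy_set <- kg$truth$pathway_compounds[[kg$truth$decoy_pathway]]
  expect_length(intersect(kg$truth$input_compounds, decoy_set), 0)
  expect_error(make_knowledge_graph(n_pathways = 1), "n_pathways")
})
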