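test_that("flux-sum matches its definition and equals turnover at steady state", {
  # chain ->A->: S row (+1, -1), v = (1,1)  =>  Phi_A = 1
  S <- matrix(c(1, -1), nrow = 1, dimnames = list("A", c("in", "out")))
  expect_equal(unname(flux_sum(S, c(1, 1))), 1)
  expect_equal(unname(flux_sum(S, c(0, 0))), 0)
  # homogeneity in the flux scale
  set.seed(2)
  S2 <- matrix(sample(-2:2, 30, TRUE), 5, 6,
               dimnames = list(paste0("m", 1:5), paste0("r", 1:6)))
  v <- rnorm(6)
  expect_equal(flux_sum(S2, 2 * v), 2 * flux_sum(S2, v))
  expect_error(flux_sum(S2, c(v[-6], NA)), "finite")
  # steady state: Phi equals the brute-force total production rate
  for (i in 1:50) {
    set.seed(i)
    nm <- sample(3:10, 1); nr <- nm + sample(2:5, 1)
    S3 <- matrix(sample(-2:2, nm * nr, TRUE), nm, nr)
    ns <- MASS::Null(t(S3))
    if (ncol(ns) == 0) next
    v3 <- drop(ns %*% rnorm(ncol(ns)))
    production <- apply(sweep(S3, 2, v3, `*`), 1, function(x) sum(pmax(x, 0)))
    expect_equal(unname(flux_sum(S3, v3)), production, tolerance = 1e-10)
  }
})

test_that("paired Wilcoxon comparison matches exact enumeration", {
  # identical matrices: nothing changes
  A <- matrix(rnorm(130), 10, 13)
  out <- compare_model_fluxes(A, A)
  expect_equal(out$fraction_changed, 0)
  expect_true(all(out$p_values == 1))
  # all-positive differences at n = 13: exact two-sided p = 2 / 2^13
  B <- A - abs(rnorm(130)) - 0.1
  out2 <- compare_model_fluxes(A, B)
  expect_equal(unname(out2$p_values), rep(2 / 2^13, 10), tolerance = 1e-12)
  # agreement with the sign-enumeration oracle on random pairs
  set.seed(77)
  for (i in 1:50) {
    x <- rnorm(13); y <- rnorm(13)
    got <- compare_model_fluxes(matrix(x, 1), matrix(y, 1))$p_values
    expect_equal(unname(got), signed_rank_exact_p(x, y), tolerance = 1e-12)
  }
  expect_error(compare_model_fluxes(A, A[, 1:5]), "identical dimensions")
})

test_that("Wilcoxon null rejection rate stays at the nominal level", {
  set.seed(5)
  A <- matrix(rnorm(500 * 13), 500, 13)
  B <- A + matrix(rnorm(500 * 13), 500, 13)
  out <- compare_model_fluxes(A, B, alpha = 0.1)
  mc <- 2 * sqrt(0.1 * 0.9 / 500)
  expect_lte(out$fraction_changed, 0.1 + 2 * mc)
})

test_that("Spearman rerouting distribution behaves under known transforms", {
  set.seed(6)
  # replicates share one rank order (scaled copies), as jittered FBA
  # solutions of one model do
  base <- rexp(150)
  A <- outer(base, c(0.9, 1, 1.1, 1.2))
  sp <- spearman_rerouting(A, A)
  expect_true(all(abs(sp$correlations - 1) < 1e-12))
  # monotone transform leaves ranks untouched
  sp2 <- spearman_rerouting(A, sqrt(A) + 2)
  expect_true(all(abs(sp2$correlations - 1) < 1e-12))
  # a large random reaction permutation decorrelates the profiles
  perm <- sample(nrow(A))
  sp3 <- spearman_rerouting(A, A[perm, ])
  expect_lt(abs(sp3$median), 0.2)
  # constant replicate excluded with a warning
  A2 <- A; A2[, 1] <- 1
  expect_warning(sp4 <- spearman_rerouting(A2, A), "constant")
  expect_true(all(is.na(sp4$correlations[1, ])))
  expect_error(spearman_rerouting(A[, 1, drop = FALSE], A), "2 replicates")
})

test_that("balanced accuracy follows its definition and conventions", {
  # perfect mixed-class prediction
  p <- matrix(c(TRUE, FALSE, TRUE, FALSE), 1)
  expect_equal(balanced_accuracy_eval(p, p)$balanced_accuracy, 1)
  # TP=1, FN=1, TN=3, FP=1 -> (0.5 + 0.75) / 2 = 0.625
  pred <- matrix(c(TRUE, FALSE, FALSE, FALSE, FALSE, TRUE), 1)
  obs <- matrix(c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE), 1)
  r <- balanced_accuracy_eval(pred, obs)
  expect_equal(r$balanced_accuracy, 0.625)
  expect_equal(c(r$tp, r$fn, r$tn, r$fp), c(1, 1, 3, 1))
  # all-positive predictor on balanced truth: sensitivity 1, specificity 0
  pr <- matrix(rep(TRUE, 6), 1)
  ob <- matrix(rep(c(TRUE, FALSE), 3), 1)
  expect_equal(balanced_accuracy_eval(pr, ob)$balanced_accuracy, 0.5)
  # zero-member convention: all-negative truth met by all-negative
  # predictions scores (0 + 1)/2, and an idle metabolite can reach 0
  quiet <- matrix(rep(FALSE, 4), 1)
  expect_equal(balanced_accuracy_eval(quiet, quiet)$balanced_accuracy, 0.5)
  wrong <- balanced_accuracy_eval(matrix(rep(TRUE, 4), 1),
                                  matrix(rep(FALSE, 4), 1))
  expect_equal(wrong$balanced_accuracy, 0)
  expect_error(balanced_accuracy_eval(matrix(logical(0), 1, 0),
                                      matrix(logical(0), 1, 0)), "empty")
})

test_that("closed-loop validation scores the generating variant perfectly", {
  pair <- make_toy_model_pair(seed = 1)
  m <- pair$model
  genes <- pair$truth$regulator_genes
  affected <- pair$truth$affected_genes
  map <- data.frame(metabolite = c("PYR", "ETH", "ATP", "NADH"),
                    feature_id = paste0("F", 1:4), stringsAsFactors = FALSE)
  alpha <- 5e-4   # resolvable by both the exact Wilcoxon floor and the t-test
  # observations planted exactly where the M1Smart rule difference acts:
  # the affected knockout loses all post-shift flux, nothing else changes
  diff_results <- list()
  for (g in genes) for (ph in c("pre", "post")) {
    hits <- if (g == affected && ph == "post") map$feature_id else character(0)
    tab <- make_obs_table(map, hits, seed = 100 + match(g, genes) * 2 +
                            (ph == "post"))
    diff_results[[paste(g, ph, sep = ".")]] <-
      fit_linear_model(tab, "strain", strain = "KO", reference = "WT",
                       covariates = character(0))
  }
  reports <- end_to_end_validation(
    m, list(M1 = pair$rules_m1, M1Smart = pair$rules_m1smart),
    genes, diff_results, map, alpha = alpha, seed = 7)
  # the variant that generated the planted effects recovers them perfectly
  expect_true(all(reports$M1Smart$balanced_accuracy == 1))
  expect_equal(sum(reports$M1Smart$tp), 4)
  # the reference variant predicts no change anywhere: specificity-only score
  expect_true(all(reports$M1$tp + reports$M1$fp == 0))
  expect_true(all(reports$M1$balanced_accuracy == 0.5))
  # permuted observations pull balanced accuracy to chance
  pred <- cbind(matrix(FALSE, 4, 7),
                matrix(TRUE, 4, 1))  # shape stand-in for permutation control
  set.seed(31)
  bas <- replicate(60, {
    obs_perm <- t(apply(pred, 1, sample))
    mean(balanced_accuracy_eval(pred, obs_perm)$balanced_accuracy)
  })
  expect_gt(mean(bas), 0.35)
  expect_lt(mean(bas), 0.65)
  # a side-by-side table mirrors the per-variant reports
  tv <- validation_table(reports)
  expect_setequal(unique(tv$model), c("M1", "M1Smart"))
  expect_equal(nrow(tv), 8)
})
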