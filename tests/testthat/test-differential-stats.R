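sim_lm_table <- function(nf, n_per_group, lfc = 0, sd = 0.3, batch_sd = 0,
                         seed = 1) {
  set.seed(seed)
  n <- 2 * n_per_group
  phase <- rep(c("pre", "post"), each = n_per_group)
  batch <- rep(1:2, length.out = n)
  L <- matrix(rnorm(nf * n, 14, sd), nf, n)
  L <- L + lfc * matrix(rep(phase == "post", each = nf), nf, n)
  if (batch_sd > 0) {
    be <- matrix(rnorm(nf * 2, 0, batch_sd), nf, 2)
    L <- L + be[, batch]
  }
  toy_peak_table(L, phase = phase, batch = batch)
}

test_that("linear model recovers a planted two-fold phase effect", {
  hits <- coefs <- numeric(0)
  for (seed in 1:5) {
    tab <- sim_lm_table(nf = 100, n_per_group = 6, lfc = 1, sd = 0.3,
                        seed = seed)
    d <- fit_linear_model(tab, "phase", covariates = "batch")
    hits <- c(hits, d$p_raw < 0.1)
    coefs <- c(coefs, d$coef_log2)
  }
  expect_gte(mean(hits), 0.95)
  expect_gte(mean(coefs >= 0.7 & coefs <= 1.3), 0.9)
  expect_true(all(d$fold_change > 0))
})

test_that("null and batch-only features give calibrated p-values", {
  tab <- sim_lm_table(nf = 2000, n_per_group = 6, lfc = 0, seed = 2)
  d <- fit_linear_model(tab, "phase", covariates = "batch")
  expect_gt(stats::ks.test(d$p_raw, "punif")$p.value, 0.01)
  # batch effect only, batch adjusted for: contrast p stays uniform
  tab2 <- sim_lm_table(nf = 2000, n_per_group = 6, lfc = 0, batch_sd = 1,
                       seed = 3)
  d2 <- fit_linear_model(tab2, "phase", covariates = "batch")
  expect_gt(stats::ks.test(d2$p_raw, "punif")$p.value, 0.01)
})

test_that("confounded designs and undersized groups are rejected", {
  tab <- sim_lm_table(nf = 5, n_per_group = 4, seed = 4)
  tab$samples$batch <- as.integer(tab$samples$phase == "post")  # collinear
  expect_error(fit_linear_model(tab, "phase", covariates = "batch"),
               "confounded")
  tab1 <- sim_lm_table(nf = 5, n_per_group = 1, seed = 5)
  expect_error(fit_linear_model(tab1, "phase", covariates = character(0)),
               "at least 2")
})

test_that("moderated p-values approach ordinary ones at large n", {
  tab <- sim_lm_table(nf = 300, n_per_group = 50, lfc = 0.2, seed = 6)
  d <- fit_linear_model(tab, "phase", covariates = "batch", moderate = TRUE)
  expect_lt(stats::median(abs(d$p_moderated - d$p_raw)), 0.005)
})

test_that("volcano rule uses strict thresholds on p and fold change", {
  diff <- structure(
    data.frame(feature_id = paste0("F", 1:10),
               coef_log2 = c(2, 1, 0.58, 1.2, 0.1, -1.5, 0.9, 0.58496250072,
                             3, -2),
               fold_change = 2^abs(c(2, 1, 0.58, 1.2, 0.1, -1.5, 0.9,
                                     0.58496250072, 3, -2)),
               direction = 1,
               p_raw = c(0.05, 0.2, 0.05, 0.01, 0.001, 0.099, 0.1, 0.05,
                         0.5, 0.0999),
               p_moderated = NA),
    class = c("diff_result", "data.frame"))
  # F8 has fold change exactly 1.5 (2^0.58496...) and p 0.05: excluded
  got <- volcano_classify(diff, p_threshold = 0.1, fc_threshold = 1.5)
  expect_setequal(got, c("F1", "F4", "F6", "F10"))
  # boundary: p exactly at threshold is excluded
  expect_false("F7" %in% got)
  expect_false("F8" %in% got)
})

test_that("correlation profiles cluster planted strain structure", {
  set.seed(12)
  nf <- 60
  base <- rnorm(nf, 14, 1)
  effAB <- rnorm(nf, 0, 1.5)
  effCD <- rnorm(nf, 0, 1.5)
  cols <- list()
  strains <- rep(c("A", "B", "C", "D"), each = 4)
  for (i in seq_along(strains)) {
    eff <- if (strains[i] %in% c("A", "B")) effAB else effCD
    cols[[i]] <- base + eff + rnorm(nf, 0, 0.2)
  }
  tab <- toy_peak_table(do.call(cbind, cols),
                        phase = rep("pre", 16), strain = strains)
  pr <- correlation_profiles(tab, group_by = "strain")
  k2 <- stats::cutree(pr$group_hclust, k = 2)
  expect_true(k2[["A"]] == k2[["B"]])
  expect_true(k2[["C"]] == k2[["D"]])
  expect_false(k2[["A"]] == k2[["C"]])
  # duplicated group correlates perfectly; negated profile anti-correlates
  gm <- pr$group_means
  expect_equal(stats::cor(gm[, 1], gm[, 1]), 1)
  centred <- gm[, 1] - mean(gm[, 1])
  expect_equal(stats::cor(centred, -centred), -1)
})

test_that("O-PLS-DA separates classes and honours its orthogonality contract", {
  set.seed(8)
  n <- 30; p <- 50
  y <- rep(c("pre", "post"), each = n / 2)
  X <- matrix(rnorm(n * p), n, p)
  X[y == "post", 1:50] <- X[y == "post", 1:50] + 3   # +3 sigma separation
  colnames(X) <- paste0("F", 1:p)
  m <- fit_opls_da(X, y, n_orthogonal = 1)
  expect_lt(abs(crossprod(m$t_pred, m$T_orth[, 1])), 1e-8)
  expect_equal(mean(opls_classify(m) == y), 1)
  # with no orthogonal component the model is the 1-component PLS solution
  m0 <- fit_opls_da(X, y, n_orthogonal = 0)
  Xc <- scale(X, scale = FALSE)
  yn <- as.numeric(factor(y)) - mean(as.numeric(factor(y)))
  w <- drop(crossprod(Xc, yn)); w <- w / sqrt(sum(w^2))
  expect_equal(abs(stats::cor(m0$t_pred, drop(Xc %*% w))), 1, tolerance = 1e-9)
  expect_error(fit_opls_da(X, y, n_orthogonal = 100), "rank")
  expect_error(fit_opls_da(X[1:5, ], y[c(1, 1, 1, 2, 2)]), "3 samples|two classes")
})

test_that("permuted labels destroy O-PLS-DA class separation", {
  set.seed(10)
  n <- 120; p <- 10
  y <- rep(c("pre", "post"), each = n / 2)
  X <- matrix(rnorm(n * p), n, p)
  colnames(X) <- paste0("F", 1:p)
  acc <- vapply(1:50, function(i) {
    yp <- sample(y)
    m <- fit_opls_da(X, yp, n_orthogonal = 1)
    mean(opls_classify(m) == yp)
  }, numeric(1))
  expect_gt(mean(acc), 0.35)
  expect_lt(mean(acc), 0.65)
})

test_that("feature selection honours loading rank and strict p threshold", {
  set.seed(14)
  n <- 24; p <- 20
  y <- rep(c("pre", "post"), each = n / 2)
  X <- matrix(rnorm(n * p, 14, 0.3), n, p)
  X[y == "post", 1] <- X[y == "post", 1] + 3    # strongest planted feature
  X[y == "post", 2] <- X[y == "post", 2] + 1
  colnames(X) <- paste0("F", 1:p)
  m <- fit_opls_da(X, y, n_orthogonal = 0)
  tab <- toy_peak_table(t(X), phase = y)
  tab$features$feature_id <- colnames(X)
  rownames(tab$intensity) <- colnames(X)
  d <- fit_linear_model(tab, "phase", covariates = character(0))
  sel <- select_discriminating_features(m, d, p_threshold = 0.05, top_n = 2)
  expect_equal(sel[1], "F1")
  # a feature with zero loading is never selected
  m2 <- m
  m2$p_pred["F2"] <- 0
  sel2 <- suppressWarnings(
    select_discriminating_features(m2, d, p_threshold = 0.05, top_n = p))
  expect_false("F2" %in% sel2)
  # p exactly at the threshold is excluded (strict)
  d2 <- d
  d2$p_raw[] <- 0.05
  expect_warning(sel3 <- select_discriminating_features(m, d2, 0.05, 5),
                 "qualify")
  expect_length(sel3, 0)
})
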