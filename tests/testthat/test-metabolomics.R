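make_filter_fixture <- function() {
  # 6 features engineered to trip exactly one rule each, plus one clean one
  n_s <- 9  # 6 study in batch 1, 3 in batch 2
  base <- matrix(1000, nrow = 6, ncol = n_s + 2)
  class <- c(rep("sample", n_s), "blank", "blank")
  batch <- c(rep(1, 6), rep(2, 3), 1, 2)
  # F1 clean; F2 below blank mean; F3 all zero (fill casualty);
  # F4 S/N < 10 via metadata; F5 under 2/3 detection in every batch; F6 clean
  base[2, class == "blank"] <- 2000
  base[3, class == "sample"] <- 0
  base[5, class == "sample"] <- c(1000, 1000, 1000, 0, 0, 0, 1000, 0, 0)
  base[, class == "blank"][c(1, 4, 5, 6), ] <- 1
  lm <- log2(pmax(base, 1))
  tab <- toy_peak_table(lm, phase = rep(c("pre", "post"), length.out = n_s + 2),
                        batch = batch, class = class)
  tab$intensity <- base  # keep exact zeros
  tab$features$sn <- c(100, 100, 100, 5, 100, 100)
  tab
}

test_that("peak filter applies the four removal rules and logs each", {
  tab <- make_filter_fixture()
  out <- filter_peaks(tab)
  expect_setequal(out$table$features$feature_id, c("F0001", "F0006"))
  lg <- out$log
  expect_equal(lg$rule[lg$feature_id == "F0002"], "blank")
  # all-zero feature trips the fill rule (and, trivially, blank/detection)
  expect_match(lg$rule[lg$feature_id == "F0003"], "fill")
  expect_equal(lg$rule[lg$feature_id == "F0004"], "sn")
  expect_equal(lg$rule[lg$feature_id == "F0005"], "detection")
  expect_false(any(lg$removed[lg$feature_id %in% c("F0001", "F0006")]))
  expect_true(lg$removed[lg$feature_id == "F0003"])
  # enabling the blank rule without blanks is an error
  tab2 <- tab
  keep <- tab$samples$class != "blank"
  tab2$intensity <- tab$intensity[, keep]
  tab2$samples <- tab$samples[keep, ]
  tab2$features$sn <- NULL
  expect_error(filter_peaks(tab2, blank_rule = TRUE), "blank")
})

test_that("peak filter matches a brute-force restatement of its rules", {
  for (seed in 1:8) {
    set.seed(seed)
    nf <- sample(10:50, 1)
    ns <- 12
    x <- matrix(2^rnorm(nf * (ns + 2), 10, 3), nf, ns + 2)
    x[sample(length(x), round(0.2 * length(x)))] <- 0
    class <- c(rep("sample", ns), "blank", "blank")
    batch <- c(rep(1:2, each = ns / 2), 1, 2)
    tab <- toy_peak_table(matrix(1, nf, ns + 2),
                          phase = rep("pre", ns + 2),
                          batch = batch, class = class)
    tab$intensity <- x
    got <- !filter_peaks(tab)$log$removed
    want <- filter_rules_bruteforce(tab)
    expect_identical(got, want)
  }
})

test_that("QC-RLSC removes planted injection-order drift", {
  set.seed(31)
  n <- 40
  ord <- 1:n
  class <- ifelse(ord %% 5 == 1, "QC", "sample")
  drift <- 1 + 0.01 * ord                     # 1 %/injection linear drift
  x <- matrix(1000 * drift * exp(rnorm(n, 0, 0.02)), nrow = 1)
  tab <- toy_peak_table(log2(x), phase = rep(c("pre", "post"), n / 2),
                        class = class)
  tab$intensity <- x
  cv <- function(v) stats::sd(v) / mean(v)
  before <- cv(x[1, class == "QC"])
  corr <- qc_rlsc(tab)
  after <- cv(corr$intensity[1, class == "QC"])
  expect_lt(after, 0.5 * before)
  # a drift-only feature stays rank-consistent with the de-drifted truth
  expect_gt(stats::cor(corr$intensity[1, class == "sample"],
                       x[1, class == "sample"] / drift[class == "sample"],
                       method = "spearman"), 0.9)
})

test_that("QC-RLSC is the identity for constant QCs and validates input", {
  n <- 20
  class <- ifelse(1:n %% 5 == 1, "QC", "sample")
  x <- matrix(rep(500, n), nrow = 1)
  tab <- toy_peak_table(log2(x), phase = rep("pre", n), class = class)
  tab$intensity <- x
  out <- qc_rlsc(tab)
  expect_equal(out$intensity, tab$intensity, tolerance = 1e-6)
  expect_error(qc_rlsc(tab, loess_span = 0), "loess_span")
  # all-zero QCs pass through unchanged with a warning
  x2 <- rbind(x, c(rep(0, n)))
  x2[2, class == "sample"] <- 100
  tab2 <- toy_peak_table(matrix(1, 2, n), phase = rep("pre", n), class = class)
  tab2$intensity <- x2
  expect_warning(out2 <- qc_rlsc(tab2), "all-zero")
  expect_equal(out2$intensity[2, ], x2[2, ])
})

test_that("batch alignment merges within tolerance and keeps singletons", {
  mk <- function(ids, mz, rt, batch, ident = ids) {
    f <- data.frame(feature_id = ids, mz = mz, rt = rt, adduct = "[M+H]+",
                    identification = ident, stringsAsFactors = FALSE)
    s <- data.frame(sample_id = paste0("B", batch, "_", 1:2), batch = batch,
                    injection_order = 1:2, class = "sample", strain = "WT",
                    phase = c("pre", "post"), stringsAsFactors = FALSE)
    peak_table(matrix(100, length(ids), 2), f, s)
  }
  a <- mk(c("X", "Y"), mz = c(200.000, 300.00), rt = c(2.0, 5.0), batch = 1)
  b <- mk(c("X", "Y"), mz = c(200.005, 300.02), rt = c(2.1, 5.1), batch = 2)
  merged <- align_batches(list(a, b))
  # X merges (delta mz 0.005 <= 0.01); Y splits (delta mz 0.02 > 0.01)
  expect_equal(nrow(merged$intensity), 3)
  xrow <- merged$intensity["X", ]
  expect_true(all(xrow == 100))
  yrows <- merged$intensity[grep("^Y", rownames(merged$intensity)), ]
  expect_equal(unname(sort(rowSums(yrows == 0))), c(2, 2))
  # three batches, feature in two of them: zeros for the third
  c3 <- mk("Z", mz = 400, rt = 7, batch = 3)
  a2 <- mk(c("X"), 200.000, 2.0, 1)
  b2 <- mk(c("X"), 200.004, 2.05, 2)
  m3 <- align_batches(list(a2, b2, c3))
  expect_equal(unname(m3$intensity["X", ]), c(100, 100, 100, 100, 0, 0))
  expect_equal(unname(m3$intensity["Z", ]), c(0, 0, 0, 0, 100, 100))
  # duplicate sample ids across batches are rejected
  bdup <- mk("X", 200.001, 2, 1)
  expect_error(align_batches(list(a, bdup)), "duplicate")
})

test_that("quantile normalization follows the rank-mean contract", {
  # hand-worked example: columns (2,4,6) and (1,2,3) both become (1.5,3,4.5)
  m <- cbind(c(2, 4, 6), c(3, 1, 2))
  out <- quantile_normalize(m)
  expect_equal(out[, 1], c(1.5, 3, 4.5))
  expect_equal(out[order(c(3, 1, 2)), 2], c(1.5, 3, 4.5))
  # identical columns are a fixed point
  m2 <- cbind(c(5, 1, 9), c(5, 1, 9))
  expect_equal(quantile_normalize(m2), m2)
  # post-condition: every column's sorted vector is identical
  set.seed(9)
  m3 <- matrix(rexp(600), 60, 10)
  q3 <- quantile_normalize(m3)
  ref <- sort(q3[, 1])
  for (j in 2:10) expect_equal(sort(q3[, j]), ref, tolerance = 1e-12)
  expect_error(quantile_normalize(m3[, 1, drop = FALSE]), "2 samples")
})

test_that("preprocessing chain runs in order and preserves sample classes", {
  d <- sim_design(n_features = 60, seed = 17)
  sim <- simulate_peak_table(d)
  out <- preprocess_peaks(sim$table)
  expect_s3_class(out$table, "peak_table")
  expect_lte(nrow(out$table$intensity), 60)
  expect_setequal(unique(out$table$samples$class),
                  unique(sim$table$samples$class))
  # identical upper marginals after the final normalization (ties from
  # missing zeros may differ between columns at the lowest ranks)
  q <- out$table$intensity
  top <- nrow(q) %/% 2
  ref <- utils::tail(sort(unname(q[, 1])), top)
  expect_equal(utils::tail(sort(unname(q[, 5])), top), ref, tolerance = 1e-9)
})
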