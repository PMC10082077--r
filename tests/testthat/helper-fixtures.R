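# Shared fixtures and independent oracles.

# Minimal 3-reaction chain: source -> A -> B -> sink, every step gene-gated.
chain_model <- function(uptake_ub = 1) {
  S <- rbind(A = c(1, -1, 0), B = c(0, 1, -1))
  colnames(S) <- c("r_in", "r_mid", "r_out")
  stoichiometric_model(S, lb = c(0, 0, 0), ub = c(uptake_ub, 10, 10),
                       gpr = c("gIN", "gMID", "gOUT"), objective = "r_out")
}

# Build a peak table directly from a log2 intensity matrix and group labels.
toy_peak_table <- function(log2_mat, phase, strain = NULL, batch = NULL,
                           class = NULL) {
  n <- ncol(log2_mat)
  f <- nrow(log2_mat)
  features <- data.frame(feature_id = sprintf("F%04d", seq_len(f)),
                         mz = seq(100, 900, length.out = f),
                         rt = seq(1, 10, length.out = f),
                         adduct = "[M+H]+", identification = "",
                         stringsAsFactors = FALSE)
  samples <- data.frame(sample_id = sprintf("S%03d", seq_len(n)),
                        batch = batch %||% rep(1, n),
                        injection_order = stats::ave(seq_len(n),
                                                     batch %||% rep(1, n),
                                                     FUN = seq_along),
                        class = class %||% rep("sample", n),
                        strain = strain %||% rep("WT", n),
                        phase = phase, stringsAsFactors = FALSE)
  peak_table(2^log2_mat, features, samples)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Exact two-sided signed-rank p by dynamic-programming enumeration of all
# 2^n sign assignments (independent of stats::wilcox.test / psignrank).
signed_rank_exact_p <- function(x, y) {
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) return(1)
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  maxw <- n * (n + 1) / 2
  counts <- c(1, rep(0, maxw))  # counts[w+1] = #assignments with statistic w
  for (rr in seq_len(n)) {
    shifted <- c(rep(0, rr), counts[seq_len(maxw + 1 - rr)])
    counts <- counts + shifted
  }
  total <- 2^n
  p_le <- sum(counts[seq_len(floor(W) + 1)]) / total
  p_ge <- sum(counts[(ceiling(W) + 1):(maxw + 1)]) / total
  min(1, 2 * min(p_le, p_ge))
}

# One strain-vs-reference peak table for closed-loop validation checks;
# features listed in `lfc_features` get a strong (8-fold) knockout shift.
make_obs_table <- function(map, lfc_features, n_per_group = 8, seed = 1) {
  set.seed(seed)
  nf <- nrow(map)
  n <- 2 * n_per_group
  strain <- rep(c("WT", "KO"), each = n_per_group)
  L <- matrix(rnorm(nf * n, 14, 0.2), nf, n)
  hit <- map$feature_id %in% lfc_features
  L[hit, strain == "KO"] <- L[hit, strain == "KO"] + 3
  tab <- toy_peak_table(L, phase = rep("pre", n), strain = strain)
  tab$features$feature_id <- map$feature_id
  rownames(tab$intensity) <- map$feature_id
  tab
}

# Brute-force re-statement of the four peak-filter rules, evaluated
# independently of filter_peaks().
filter_rules_bruteforce <- function(tab, fill_threshold = 0.1,
                                    sn_threshold = 10,
                                    detection_fraction = 2 / 3) {
  study <- tab$intensity[, tab$samples$class == "sample", drop = FALSE]
  blank <- tab$intensity[, tab$samples$class == "blank", drop = FALSE]
  batches <- tab$samples$batch[tab$samples$class == "sample"]
  vapply(seq_len(nrow(study)), function(f) {
    a <- mean(study[f, ]) <= mean(blank[f, ])
    b <- mean(study[f, ] > 0) < fill_threshold
    cc <- (mean(study[f, ]) / max(mean(blank[f, ]), .Machine$double.eps)) < sn_threshold
    d <- !any(vapply(unique(batches), function(bb) {
      mean(study[f, batches == bb] > 0) >= detection_fraction
    }, logical(1)))
    !(a || b || cc || d)
  }, logical(1))
}
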