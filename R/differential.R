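#' Per-feature covariate-adjusted differential abundance
#'
#' Fits an ordinary least-squares linear model per feature on log2 intensity
#' with the contrast term plus covariate dummies, and t-tests the contrast
#' coefficient. Zeros are replaced by half the minimum positive intensity of
#' the feature before the log transform. With `moderate = TRUE` an
#' empirical-Bayes moderated p-value is reported alongside (per-feature
#' variances shrunk toward a pooled prior, inflating the residual degrees of
#' freedom). Only study samples (class `sample`) enter the fit.
#'
#' @param table a [peak_table()] (normalized).
#' @param contrast `"phase"` (post vs pre, across all strains) or `"strain"`
#'   (one deletion strain vs the reference).
#' @param strain for `contrast = "strain"`: the strain to compare.
#' @param phase optional phase to restrict the samples to (recommended for
#'   strain contrasts: the study compares each deletant to the reference
#'   within the same phase).
#' @param reference reference strain id (default `"WT"`).
#' @param covariates character vector of sample-metadata columns entered as
#'   factor covariates (default `"batch"`; the across-shift analysis uses
#'   `c("strain", "batch")`).
#' @param moderate also compute empirical-Bayes moderated p-values.
#' @return a `diff_result` data.frame: `feature_id`, `coef_log2` (signed
#'   contrast coefficient), `fold_change` (`2^|coef|`), `direction` (sign),
#'   `p_raw`, `p_moderated`.
#' @export
fit_linear_model <- function(table, contrast = c("phase", "strain"),
                             strain = NULL, phase = NULL, reference = "WT",
                             covariates = "batch", moderate = FALSE) {
  contrast <- match.arg(contrast)
  stopifnot(inherits(table, "peak_table"))
  sm <- table$samples
  idx <- which(sm$class == "sample")
  if (!is.null(phase)) idx <- idx[sm$phase[idx] == phase]
  if (contrast == "strain") {
    if (is.null(strain)) stop("contrast = 'strain' needs a `strain`")
    idx <- idx[sm$strain[idx] %in% c(reference, strain)]
  }
  sm <- sm[idx, , drop = FALSE]
  X <- table$intensity[, idx, drop = FALSE]

  term <- if (contrast == "phase") {
    factor(sm$phase, levels = c("pre", "post"))
  } else {
    factor(sm$strain, levels = c(reference, strain))
  }
  if (any(table(term) < 2) || nlevels(droplevels(term)) < 2) {
    stop("each contrast group needs at least 2 samples")
  }
  df <- data.frame(.contrast = term)
  for (cv in covariates) {
    vals <- sm[[cv]]
    if (length(unique(vals)) > 1) df[[cv]] <- factor(vals)
  }
  design <- stats::model.matrix(~ ., data = df)
  if (qr(design)$rank < ncol(design)) {
    stop("confounded design: the contrast is collinear with the covariates (",
         paste(colnames(design), collapse = ", "), ")")
  }
  L <- log2_intensities(X)
  fit <- limma::lmFit(L, design)
  col <- grep("^\\.contrast", colnames(design))
  coef <- fit$coefficients[, col]
  t_ord <- coef / (fit$stdev.unscaled[, col] * fit$sigma)
  p_raw <- 2 * stats::pt(-abs(t_ord), fit$df.residual)
  p_mod <- if (moderate) {
    eb <- limma::eBayes(fit)
    eb$p.value[, col]
  } else {
    rep(NA_real_, length(coef))
  }
  out <- data.frame(feature_id = table$features$feature_id,
                    coef_log2 = as.numeric(coef),
                    fold_change = 2^abs(as.numeric(coef)),
                    direction = sign(as.numeric(coef)),
                    p_raw = as.numeric(p_raw),
                    p_moderated = as.numeric(p_mod),
                    stringsAsFactors = FALSE)
  structure(out, class = c("diff_result", "data.frame"),
            contrast = contrast, strain = strain, phase = phase,
            covariates = covariates)
}

# log2 with per-feature half-minimum-positive replacement of zeros
log2_intensities <- function(X) {
  L <- X
  for (f in seq_len(nrow(L))) {
    x <- L[f, ]
    pos <- x > 0
    if (!any(pos)) {
      L[f, ] <- 0
      next
    }
    if (any(!pos)) x[!pos] <- min(x[pos]) / 2
    L[f, ] <- log2(x)
  }
  L
}

#' Classify features as significantly changed (volcano rule)
#'
#' Flags a feature iff raw p < `p_threshold` and fold change > `fc_threshold`
#' (both strict).
#'
#' @param diff a `diff_result` from [fit_linear_model()].
#' @param p_threshold raw p-value threshold (0.1).
#' @param fc_threshold fold-change threshold (1.5).
#' @return character vector of flagged feature ids.
#' @export
volcano_classify <- function(diff, p_threshold = 0.1, fc_threshold = 1.5) {
  sel <- !is.na(diff$p_raw) & diff$p_raw < p_threshold &
    diff$fold_change > fc_threshold
  diff$feature_id[sel]
}

#' Correlation profiles and dendrograms of condition groups
#'
#' Averages log2 intensities across replicates within each (strain, phase)
#' group, then clusters: groups by average-linkage on 1 - Pearson r, features
#' by average-linkage on Euclidean distance over standardized profiles.
#' Groups with zero variance across features are dropped with a warning.
#'
#' @param table a [peak_table()].
#' @param group_by sample-metadata columns defining the groups.
#' @return list with `group_means` (features x groups, log2), `cor`
#'   (group correlation matrix), `group_hclust`, `feature_hclust`.
#' @export
correlation_profiles <- function(table, group_by = c("strain", "phase")) {
  stopifnot(inherits(table, "peak_table"))
  idx <- which(table$samples$class == "sample")
  sm <- table$samples[idx, , drop = FALSE]
  L <- log2_intensities(table$intensity[, idx, drop = FALSE])
  grp <- interaction(sm[, group_by, drop = FALSE], sep = ":", drop = TRUE)
  if (nlevels(grp) < 2) stop("need at least 2 groups")
  means <- vapply(levels(grp), function(g) {
    rowMeans(L[, grp == g, drop = FALSE])
  }, numeric(nrow(L)))
  rownames(means) <- table$features$feature_id
  sds <- apply(means, 2, stats::sd)
  if (any(sds == 0)) {
    warning("dropping zero-variance group(s): ",
            paste(colnames(means)[sds == 0], collapse = ", "))
    means <- means[, sds > 0, drop = FALSE]
  }
  if (ncol(means) < 2) stop("fewer than 2 groups with nonzero variance")
  r <- stats::cor(means, method = "pearson")
  group_h <- stats::hclust(stats::as.dist(1 - r), method = "average")
  Z <- t(scale(t(means)))
  Z[!is.finite(Z)] <- 0
  feature_h <- stats::hclust(stats::dist(Z), method = "average")
  list(group_means = means, cor = r,
       group_hclust = group_h, feature_hclust = feature_h)
}

#' Select phase-discriminating features backed by the linear model
#'
#' Ranks features by the absolute predictive loading of an O-PLS-DA model and
#' keeps the top `top_n` that are also significant in the linear model
#' (raw p < `p_threshold`, strict). Features with zero loading are never
#' selected.
#'
#' @param model an `opls_model` from [fit_opls_da()].
#' @param diff a `diff_result` computed on the same features.
#' @param p_threshold raw p-value threshold (0.05).
#' @param top_n maximum number of features to return.
#' @return character vector of selected feature ids, in loading order.
#' @export
select_discriminating_features <- function(model, diff, p_threshold = 0.05,
                                           top_n = 25) {
  loading <- model$p_pred
  if (is.null(names(loading))) stop("model loadings carry no feature names")
  common <- intersect(names(loading), diff$feature_id)
  if (!length(common)) stop("model and diff results share no features")
  loading <- loading[common]
  p <- diff$p_raw[match(common, diff$feature_id)]
  ok <- !is.na(p) & p < p_threshold & abs(loading) > 0
  ranked <- common[ok][order(-abs(loading[ok]))]
  if (length(ranked) < top_n) {
    warning("only ", length(ranked), " features qualify (requested ", top_n, ")")
  }
  utils::head(ranked, top_n)
}
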