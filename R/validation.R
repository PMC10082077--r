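#' Metabolite flux-sums from a flux solution
#'
#' The basal flux-sum of metabolite i is half the sum of absolute
#' stoichiometry-weighted fluxes through it,
#' \deqn{\Phi_i = 0.5 \sum_j |S_{ij} v_j|,}
#' which at steady state equals the metabolite's turnover (total production =
#' total consumption). Used as a per-metabolite proxy for metabolic activity.
#'
#' @param S stoichiometric matrix (metabolites x reactions), or a
#'   `stoich_model` (its S is used).
#' @param v flux vector (length = reactions), a `flux_solution`, or a
#'   reactions x replicates flux matrix.
#' @return named numeric vector of flux-sums per metabolite, or a
#'   metabolites x replicates matrix when `v` is a matrix.
#' @export
flux_sum <- function(S, v) {
  if (inherits(S, "stoich_model")) S <- S$S
  if (inherits(v, "flux_solution")) v <- v$v
  if (is.matrix(v)) {
    out <- apply(v, 2, function(col) flux_sum(S, col))
    rownames(out) <- rownames(S)
    return(out)
  }
  if (length(v) != ncol(S)) stop("flux vector length must match reactions")
  if (any(!is.finite(v))) stop("non-finite fluxes")
  0.5 * rowSums(abs(sweep(S, 2, v, `*`)))
}

#' Compare replicate flux matrices between two model variants
#'
#' Per reaction, a two-sided Wilcoxon signed-rank test on the paired
#' replicate differences (exact distribution for n <= 25; zero differences
#' dropped per the Wilcoxon convention, all-zero rows reported as p = 1 and
#' counted as not changed). Also reports the fraction of reactions with
#' p below `alpha`.
#'
#' @param fluxes_a,fluxes_b numeric matrices, reactions x replicates, with
#'   equal dimensions; replicates are paired by column index.
#' @param alpha significance threshold for "changed" (0.1).
#' @return list with `p_values` (named per reaction) and `fraction_changed`.
#' @export
compare_model_fluxes <- function(fluxes_a, fluxes_b, alpha = 0.1) {
  if (!all(dim(fluxes_a) == dim(fluxes_b))) {
    stop("flux matrices must have identical dimensions")
  }
  p <- vapply(seq_len(nrow(fluxes_a)), function(i) {
    wilcoxon_signed_rank(fluxes_a[i, ], fluxes_b[i, ])
  }, numeric(1))
  names(p) <- rownames(fluxes_a)
  list(p_values = p, fraction_changed = mean(p < alpha))
}

# two-sided paired Wilcoxon signed-rank p-value; zeros dropped, all-zero -> 1
wilcoxon_signed_rank <- function(x, y) {
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) return(1)
  suppressWarnings(
    stats::wilcox.test(d, exact = n <= 25, correct = TRUE)$p.value
  )
}

#' Pairwise Spearman correlations between two variants' simulations
#'
#' Computes the Spearman rank correlation over reactions for every
#' cross-model replicate pair (n_a x n_b pairs). A broad, low-median
#' distribution indicates flux rerouting (rank reordering) rather than a
#' uniform scaling of the same flux pattern.
#'
#' @inheritParams compare_model_fluxes
#' @return list with `correlations` (matrix, replicates of A x replicates of
#'   B; `NA` for pairs with a constant flux vector, excluded with a warning)
#'   and `median`.
#' @export
spearman_rerouting <- function(fluxes_a, fluxes_b) {
  if (ncol(fluxes_a) < 2 || ncol(fluxes_b) < 2) {
    stop("need at least 2 replicates per model")
  }
  const_a <- apply(fluxes_a, 2, function(v) stats::sd(v) == 0)
  const_b <- apply(fluxes_b, 2, function(v) stats::sd(v) == 0)
  rho <- suppressWarnings(
    stats::cor(fluxes_a, fluxes_b, method = "spearman")
  )
  rho[const_a, ] <- NA
  rho[, const_b] <- NA
  if (any(const_a) || any(const_b)) {
    warning(sum(const_a) + sum(const_b),
            " replicate(s) with constant fluxes excluded")
  }
  list(correlations = rho, median = stats::median(rho, na.rm = TRUE))
}

#' Score predicted against observed significant changes by balanced accuracy
#'
#' Treats per-metabolite flux-sum changes as predictors of measured species
#' accumulation: over the available comparisons (strain x phase), counts TP /
#' FP / TN / FN, and reports sensitivity, specificity, and balanced accuracy
#' = (sensitivity + specificity) / 2 per metabolite. A class with zero
#' members contributes a rate of 0, so a metabolite with no correct matches
#' can score 0.000 and an all-negative truth met by all-negative predictions
#' scores 0.5.
#'
#' @param predicted,observed logical matrices, metabolites x comparisons,
#'   with identical dimensions.
#' @return a `validation_report` data.frame: `metabolite`, `tp`, `fp`, `tn`,
#'   `fn`, `sensitivity`, `specificity`, `balanced_accuracy`; the comparison
#'   labels are kept in the `comparisons` attribute.
#' @export
balanced_accuracy_eval <- function(predicted, observed) {
  predicted <- as.matrix(predicted)
  observed <- as.matrix(observed)
  if (!all(dim(predicted) == dim(observed))) {
    stop("predicted and observed must have identical dimensions")
  }
  if (ncol(predicted) == 0) stop("empty comparison set")
  rows <- lapply(seq_len(nrow(predicted)), function(i) {
    p <- as.logical(predicted[i, ])
    o <- as.logical(observed[i, ])
    tp <- sum(p & o); fp <- sum(p & !o)
    tn <- sum(!p & !o); fn <- sum(!p & o)
    sens <- if (tp + fn > 0) tp / (tp + fn) else 0
    spec <- if (tn + fp > 0) tn / (tn + fp) else 0
    data.frame(metabolite = rownames(predicted)[i] %||% paste0("met", i),
               tp = tp, fp = fp, tn = tn, fn = fn,
               sensitivity = sens, specificity = spec,
               balanced_accuracy = (sens + spec) / 2)
  })
  structure(do.call(rbind, rows),
            class = c("validation_report", "data.frame"),
            comparisons = colnames(predicted))
}

#' End-to-end validation of model variants against measured accumulations
#'
#' For each model variant: every (knockout, phase) comparison gets replicate
#' FBA simulations for the deletion strain and the wild type (the same jitter
#' seed pairs the replicates), per-metabolite flux-sums, and a paired
#' Wilcoxon signed-rank test; "predicted positive" means flux-sum change with
#' p < `alpha`. "Observed positive" means the mapped feature's linear-model
#' p < `alpha` in that strain/phase. Metabolites without a feature mapping
#' are skipped and logged. Comparisons are pooled per metabolite across
#' strains and phases.
#'
#' @param model a `stoich_model`.
#' @param rule_sets named list of `regulatory_rules` variants
#'   (e.g. `list(M1 = ..., M1Smart = ...)`).
#' @param knockouts character vector of deletion genes to compare.
#' @param diff_results named list of `diff_result` objects keyed
#'   `"<knockout>.<phase>"` (strain-vs-reference contrasts).
#' @param metabolite_map data.frame with columns `metabolite`, `feature_id`
#'   linking model metabolites to measured features.
#' @param alpha significance threshold on both sides (0.1).
#' @param n_replicates replicate simulations per condition (13).
#' @param jitter_fraction exchange-bound jitter for [replicate_fluxes()].
#' @param seed integer seed.
#' @return named list (one per variant) of `validation_report`s; unmapped
#'   metabolites are recorded in the `unmapped` attribute of each report.
#' @export
end_to_end_validation <- function(model, rule_sets, knockouts, diff_results,
                                  metabolite_map, alpha = 0.1,
                                  n_replicates = 13, jitter_fraction = 0.05,
                                  seed = 1) {
  phases <- c("pre", "post")
  comps <- expand.grid(knockout = knockouts, phase = phases,
                       stringsAsFactors = FALSE)
  mapped <- metabolite_map[metabolite_map$metabolite %in% model$metabolites, ]
  unmapped <- setdiff(metabolite_map$metabolite, mapped$metabolite)
  if (!nrow(mapped)) stop("no metabolite in the map matches the model")
  out <- lapply(names(rule_sets), function(lbl) {
    rules <- rule_sets[[lbl]]
    pred <- obs <- matrix(NA, nrow(mapped), nrow(comps),
                          dimnames = list(mapped$metabolite,
                                          paste(comps$knockout, comps$phase,
                                                sep = ".")))
    for (ci in seq_len(nrow(comps))) {
      ko <- comps$knockout[ci]; ph <- comps$phase[ci]
      # same seed pairs the jitter draws of knockout and wild type
      f_ko <- replicate_fluxes(model, rules, ko, ph, n_replicates,
                               jitter_fraction, seed = seed + ci)
      f_wt <- replicate_fluxes(model, rules, NULL, ph, n_replicates,
                               jitter_fraction, seed = seed + ci)
      phi_ko <- flux_sum(model$S, f_ko)
      phi_wt <- flux_sum(model$S, f_wt)
      dr <- diff_results[[paste(ko, ph, sep = ".")]]
      if (is.null(dr)) stop("missing diff result for ", ko, ".", ph)
      for (mi in seq_len(nrow(mapped))) {
        met <- mapped$metabolite[mi]
        p_flux <- wilcoxon_signed_rank(phi_ko[met, ], phi_wt[met, ])
        pred[mi, ci] <- p_flux < alpha
        p_obs <- dr$p_raw[match(mapped$feature_id[mi], dr$feature_id)]
        obs[mi, ci] <- !is.na(p_obs) && p_obs < alpha
      }
    }
    rep <- balanced_accuracy_eval(pred, obs)
    attr(rep, "model_label") <- lbl
    attr(rep, "unmapped") <- unmapped
    rep
  })
  names(out) <- names(rule_sets)
  out
}

#' Side-by-side balanced-accuracy table for competing model variants
#'
#' @param reports named list of `validation_report`s (one per variant), as
#'   returned by [end_to_end_validation()].
#' @return data.frame with columns `metabolite`, `model`,
#'   `balanced_accuracy` plus the confusion counts.
#' @export
validation_table <- function(reports) {
  do.call(rbind, lapply(names(reports), function(lbl) {
    r <- reports[[lbl]]
    data.frame(metabolite = r$metabolite, model = lbl,
               balanced_accuracy = r$balanced_accuracy,
               tp = r$tp, fp = r$fp, tn = r$tn, fn = r$fn,
               row.names = NULL)
  }))
}
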