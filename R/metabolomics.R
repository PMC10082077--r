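#' Filter peaks by blank level, fill, signal-to-noise, and batch detection
#'
#' Removes features failing any of four rules, evaluated on the study samples
#' (class `sample`):
#' \enumerate{
#'   \item blank rule: mean over study samples <= mean over blanks;
#'   \item fill rule: fraction of study samples with a detected peak
#'     (intensity > 0) below `fill_threshold`;
#'   \item signal-to-noise rule: S/N below `sn_threshold` (taken from a
#'     feature-metadata column `sn` when present, otherwise computed as
#'     mean(study samples) / mean(blanks));
#'   \item detection rule: detected in fewer than `detection_fraction` of the
#'     study samples in every batch (a feature is kept iff it reaches the
#'     fraction in at least one batch; set `detection_mode = "every_batch"`
#'     for the complementary reading, requiring the fraction in all batches).
#' }
#' The removal log names every rule that fired for each removed feature.
#'
#' @param table a [peak_table()].
#' @param blank_rule apply rules that need blanks (1, and 3 when no `sn`
#'   column is present). An error is raised if enabled without blank samples.
#' @param fill_threshold minimum detected fraction over study samples (0.1).
#' @param sn_threshold minimum signal-to-noise ratio (10).
#' @param detection_fraction per-batch detection fraction (2/3).
#' @param detection_mode `"any_batch"` (default) or `"every_batch"`.
#' @return list with `table` (filtered peak table) and `log` (data.frame
#'   `feature_id`, `removed`, `rule`; `rule` names the first rule that fired).
#' @export
filter_peaks <- function(table, blank_rule = TRUE, fill_threshold = 0.1,
                         sn_threshold = 10, detection_fraction = 2 / 3,
                         detection_mode = c("any_batch", "every_batch")) {
  detection_mode <- match.arg(detection_mode)
  stopifnot(inherits(table, "peak_table"))
  s_idx <- sample_idx(table, "sample")
  b_idx <- sample_idx(table, "blank")
  if (!length(s_idx)) stop("no study samples in the table")
  if (blank_rule && !length(b_idx)) {
    stop("blank rule enabled but the table contains no blank samples")
  }
  X <- table$intensity
  study <- X[, s_idx, drop = FALSE]
  mean_study <- rowMeans(study)
  mean_blank <- if (length(b_idx)) rowMeans(X[, b_idx, drop = FALSE]) else NULL
  fill <- rowMeans(study > 0)
  sn <- if (!is.null(table$features$sn)) {
    table$features$sn
  } else if (length(b_idx)) {
    mean_study / pmax(mean_blank, .Machine$double.eps)
  } else {
    stop("no `sn` feature column and no blanks to compute S/N from")
  }
  batches <- table$samples$batch[s_idx]
  det_by_batch <- vapply(unique(batches), function(b) {
    rowMeans(study[, batches == b, drop = FALSE] > 0)
  }, numeric(nrow(X)))
  det_by_batch <- matrix(det_by_batch, nrow = nrow(X))
  det_ok <- if (detection_mode == "any_batch") {
    apply(det_by_batch >= detection_fraction, 1, any)
  } else {
    apply(det_by_batch >= detection_fraction, 1, all)
  }
  fired <- cbind(blank = if (blank_rule) mean_study <= mean_blank else FALSE,
                 fill = fill < fill_threshold,
                 sn = sn < sn_threshold,
                 detection = !det_ok)
  keep <- rowSums(fired) == 0
  rule <- apply(fired, 1, function(f) paste(colnames(fired)[f], collapse = ";"))
  log <- data.frame(feature_id = table$features$feature_id,
                    removed = !keep,
                    rule = rule,
                    stringsAsFactors = FALSE)
  list(table = subset_peak_table(table, f_idx = which(keep)), log = log)
}

#' QC-based robust LOESS signal drift correction (QC-RLSC)
#'
#' Per batch and per feature, fits a robust local regression (degree 1,
#' tricube weights, symmetric family) of the QC intensities against injection
#' order, evaluates the fit at every sample's injection order, and divides
#' each intensity by `fitted / median(QC)`. Batches with fewer than
#' `min_qc_loess` usable QCs for a feature fall back to median scaling.
#' Features whose QC intensities are all zero in a batch pass through
#' unchanged with a warning. Zero (missing) intensities stay zero.
#'
#' @param table a [peak_table()] with >= 2 QC samples per batch.
#' @param loess_span LOESS span in (0, 1].
#' @param min_qc_loess minimum non-missing QCs needed for a LOESS fit (4).
#' @return the drift-corrected [peak_table()].
#' @export
qc_rlsc <- function(table, loess_span = 0.75, min_qc_loess = 4) {
  stopifnot(inherits(table, "peak_table"))
  if (loess_span <= 0 || loess_span > 1) stop("loess_span must be in (0, 1]")
  X <- table$intensity
  sm <- table$samples
  skipped <- 0L
  for (b in unique(sm$batch)) {
    in_b <- which(sm$batch == b)
    qc <- in_b[sm$class[in_b] == "QC"]
    if (length(qc) < 2) stop("batch ", b, " has fewer than 2 QC samples")
    ord_all <- sm$injection_order[in_b]
    ord_qc <- sm$injection_order[qc]
    for (f in seq_len(nrow(X))) {
      y <- X[f, qc]
      pos <- y > 0
      if (!any(pos)) { skipped <- skipped + 1L; next }
      med <- stats::median(y[pos])
      if (sum(pos) >= min_qc_loess) {
        qc_df <- data.frame(ord = ord_qc[pos], y = y[pos])
        # sparse QC series routinely trip loess's pseudoinverse/neighborhood
        # notices; they are expected at this density and safe to silence
        fit <- tryCatch(
          suppressWarnings(
            stats::loess(y ~ ord, data = qc_df, span = loess_span, degree = 1,
                         family = "symmetric",
                         control = stats::loess.control(surface = "direct"))),
          error = function(e) NULL)
        fitted_all <- if (is.null(fit)) rep(med, length(in_b)) else
          suppressWarnings(stats::predict(fit, newdata = data.frame(ord = ord_all)))
      } else {
        fitted_all <- rep(med, length(in_b))
      }
      fac <- fitted_all / med
      fac[!is.finite(fac) | fac <= 0] <- 1
      X[f, in_b] <- X[f, in_b] / fac
    }
  }
  if (skipped > 0) {
    warning(skipped, " feature-batch combinations had all-zero QCs and were left uncorrected")
  }
  table$intensity <- X
  table
}

#' Concatenate drift-corrected batch tables into one peak table
#'
#' Features from different batches are merged into a single row iff their
#' identification labels match, their adducts match, |delta m/z| <= `mz_tol`
#' and |delta RT| <= `rt_tol`. Matching is greedy in ascending m/z with the
#' nearest-m/z candidate winning, which makes the output deterministic and
#' independent of batch order up to row ordering. Unmatched features are kept
#' as batch-specific rows with zeros for the other batches' samples.
#'
#' @param tables list of >= 2 [peak_table()] objects (one per batch).
#' @param mz_tol m/z tolerance in Da (0.01).
#' @param rt_tol retention-time tolerance in minutes (0.75).
#' @return the concatenated [peak_table()].
#' @export
align_batches <- function(tables, mz_tol = 0.01, rt_tol = 0.75) {
  if (length(tables) < 2) stop("need at least two batch tables")
  all_ids <- unlist(lapply(tables, function(t) t$samples$sample_id))
  if (anyDuplicated(all_ids)) stop("duplicate sample_ids across batches")
  master_feat <- tables[[1]]$features
  blocks <- list(tables[[1]]$intensity)
  for (k in 2:length(tables)) {
    tb <- tables[[k]]
    ord <- order(tb$features$mz)
    match_row <- rep(NA_integer_, nrow(tb$features))
    for (i in ord) {
      fi <- tb$features[i, ]
      cand <- which(master_feat$identification == fi$identification &
                      master_feat$adduct == fi$adduct &
                      abs(master_feat$mz - fi$mz) <= mz_tol &
                      abs(master_feat$rt - fi$rt) <= rt_tol)
      # a master row can absorb at most one feature per incoming batch
      cand <- setdiff(cand, match_row)
      if (length(cand)) {
        match_row[i] <- cand[which.min(abs(master_feat$mz[cand] - fi$mz))]
      }
    }
    new_rows <- which(is.na(match_row))
    if (length(new_rows)) {
      match_row[new_rows] <- nrow(master_feat) + seq_along(new_rows)
      master_feat <- rbind(master_feat, tb$features[new_rows, , drop = FALSE])
      blocks <- lapply(blocks, function(m) {
        rbind(m, matrix(0, length(new_rows), ncol(m)))
      })
    }
    blk <- matrix(0, nrow(master_feat), ncol(tb$intensity))
    blk[match_row, ] <- tb$intensity
    blocks[[k]] <- blk
  }
  intensity <- do.call(cbind, blocks)
  samples <- do.call(rbind, lapply(tables, function(t) t$samples))
  master_feat$feature_id <- make.unique(master_feat$feature_id)
  rownames(master_feat) <- NULL
  peak_table(intensity, master_feat, samples)
}

#' Quantile-normalize sample intensity distributions
#'
#' Forces every sample column onto the common distribution of rank-wise
#' means: sort each column, average across columns at each rank, and assign
#' the rank means back through each column's original ordering, ties
#' receiving the mean of their rank means. Zeros participate as ordinary
#' values, preserving the identical-marginals contract; set `mask_zeros` to
#' exclude them (zeros stay zero and only positive intensities are
#' normalized within each column).
#'
#' @param table a [peak_table()] (or bare numeric matrix) with >= 2 samples.
#' @param mask_zeros exclude zeros from normalization.
#' @return object of the same type with normalized intensities.
#' @export
quantile_normalize <- function(table, mask_zeros = FALSE) {
  X <- if (inherits(table, "peak_table")) table$intensity else as.matrix(table)
  if (ncol(X) < 2) stop("quantile normalization needs at least 2 samples")
  if (!mask_zeros) {
    Xn <- limma::normalizeQuantiles(X, ties = TRUE)
  } else {
    Xm <- X
    Xm[Xm == 0] <- NA
    Xn <- limma::normalizeQuantiles(Xm, ties = TRUE)
    Xn[is.na(Xn)] <- 0
  }
  dimnames(Xn) <- dimnames(X)
  if (inherits(table, "peak_table")) {
    table$intensity <- Xn
    table
  } else {
    Xn
  }
}

#' Run the full preprocessing chain on per-batch peak tables
#'
#' Filter, drift-correct per batch, concatenate, quantile-normalize, in the
#' order the measurements are processed upstream of the statistics.
#'
#' @param tables list of per-batch [peak_table()]s, or one multi-batch table
#'   (it is split by batch for drift correction).
#' @param ... thresholds passed to the stage functions.
#' @inheritParams filter_peaks
#' @inheritParams qc_rlsc
#' @inheritParams align_batches
#' @return list with `table` (the normalized table) and `filter_log`.
#' @export
preprocess_peaks <- function(tables, blank_rule = TRUE, fill_threshold = 0.1,
                             sn_threshold = 10, detection_fraction = 2 / 3,
                             loess_span = 0.75, mz_tol = 0.01, rt_tol = 0.75,
                             ...) {
  if (inherits(tables, "peak_table")) {
    tb <- tables
    tables <- lapply(unique(tb$samples$batch), function(b) {
      subset_peak_table(tb, s_idx = which(tb$samples$batch == b))
    })
  }
  tables <- lapply(tables, function(t) {
    filter_peaks(t, blank_rule = blank_rule, fill_threshold = fill_threshold,
                 sn_threshold = sn_threshold,
                 detection_fraction = detection_fraction)$table
  })
  tables <- lapply(tables, qc_rlsc, loess_span = loess_span)
  merged <- if (length(tables) > 1) {
    align_batches(tables, mz_tol = mz_tol, rt_tol = rt_tol)
  } else {
    tables[[1]]
  }
  # final filter pass on the merged table records the removal log
  flt <- filter_peaks(merged, blank_rule = FALSE, fill_threshold = fill_threshold,
                      sn_threshold = 0, detection_fraction = detection_fraction)
  norm <- quantile_normalize(flt$table)
  list(table = norm, filter_log = flt$log)
}
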