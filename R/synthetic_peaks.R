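#' Describe a synthetic metabolomics study design
#'
#' Captures the dimensions and noise structure of the simulated untargeted
#' LC-MS experiment: strains (first strain is the wild-type reference), two
#' phases (pre/post diauxic shift), replicates per strain-phase condition
#' within each batch, pooled QC samples injected every `qc_interval` study
#' injections, and extraction blanks at the head of each batch.
#'
#' @param n_strains number of strains (>= 2 recommended; first is `WT`).
#' @param replicates_per_condition replicates per strain x phase x batch
#'   (>= 2; the study used 3-6).
#' @param n_batches number of experimental batches.
#' @param qc_interval study injections between QC samples (>= 2).
#' @param n_features number of metabolite features.
#' @param missing_rate fraction of study-sample intensities set to zero
#'   (not detected), in [0, 1).
#' @param noise_sd technical noise sd on the log2 scale.
#' @param biological_sd extra replicate-to-replicate biological sd (log2).
#' @param batch_sd sd of per-feature multiplicative batch effects (log2).
#' @param drift_amplitude scale of the smooth injection-order drift (log2
#'   units across one batch).
#' @param n_blanks_per_batch extraction blanks per batch.
#' @param seed integer seed; fixed seed gives byte-identical output.
#' @return a `sim_design` list.
#' @export
sim_design <- function(n_strains = 4, replicates_per_condition = 3,
                       n_batches = 2, qc_interval = 5, n_features = 120,
                       missing_rate = 0.05, noise_sd = 0.3,
                       biological_sd = 0.15, batch_sd = 0.4,
                       drift_amplitude = 0.15, n_blanks_per_batch = 2,
                       seed = 1) {
  if (replicates_per_condition < 2) stop("replicates_per_condition must be >= 2")
  if (qc_interval < 2) stop("qc_interval must be >= 2")
  if (missing_rate < 0 || missing_rate >= 1) stop("missing_rate must be in [0, 1)")
  structure(list(n_strains = n_strains,
                 replicates_per_condition = replicates_per_condition,
                 n_batches = n_batches, qc_interval = qc_interval,
                 n_features = n_features, missing_rate = missing_rate,
                 noise_sd = noise_sd, biological_sd = biological_sd,
                 batch_sd = batch_sd, drift_amplitude = drift_amplitude,
                 n_blanks_per_batch = n_blanks_per_batch,
                 seed = as.integer(seed)),
            class = "sim_design")
}

#' Simulate an untargeted-metabolomics peak table with known ground truth
#'
#' Intensities are log-normal: on the log2 scale each study sample is the
#' feature's base level plus a per-feature multiplicative batch effect, a
#' smooth per-batch polynomial injection-order drift (shared by QC and study
#' samples), planted phase/strain effects on the designated features, and
#' Gaussian technical + biological noise. QC samples are draws around the
#' pooled study mean with technical noise only; blanks carry only a noise
#' floor. Missing values are encoded as zeros on study samples.
#'
#' @param design a [sim_design()].
#' @param effects `NULL` to plant defaults (15\% of features receive a
#'   two-fold phase effect with random sign), or a list with `phase_lfc`
#'   (named numeric, feature id -> signed log2 fold change post vs pre) and
#'   optional `strain_lfc` (named list: strain -> named numeric of log2 fold
#'   changes vs the reference). Referencing an unknown feature id is an error.
#' @return list with `table` (a [peak_table()]) and `truth` (a `ground_truth`
#'   list: `true_diff_features`, `strain_lfc`, `drift_profiles`).
#' @export
simulate_peak_table <- function(design, effects = NULL) {
  stopifnot(inherits(design, "sim_design"))
  with_seed(design$seed, simulate_peak_table_impl(design, effects))
}

simulate_peak_table_impl <- function(design, effects) {
  nf <- design$n_features
  fid <- sprintf("F%04d", seq_len(nf))
  strains <- c("WT", if (design$n_strains > 1)
    paste0("KO", seq_len(design$n_strains - 1)))
  phases <- c("pre", "post")

  # feature metadata
  features <- data.frame(
    feature_id = fid,
    mz = round(sort(stats::runif(nf, 70, 1000)), 4),
    rt = round(stats::runif(nf, 0.5, 10.5), 3),
    adduct = sample(c("[M+H]+", "[M+Na]+", "[M+K]+"), nf, replace = TRUE,
                    prob = c(0.7, 0.2, 0.1)),
    identification = ifelse(seq_len(nf) <= ceiling(0.4 * nf),
                            sprintf("CPD_%04d", seq_len(nf)), ""),
    stringsAsFactors = FALSE
  )

  # planted effects
  if (is.null(effects)) {
    n_diff <- max(1L, round(0.15 * nf))
    diff_ids <- sample(fid, n_diff)
    phase_lfc <- stats::setNames(sample(c(-1, 1), n_diff, replace = TRUE), diff_ids)
    strain_lfc <- list()
  } else {
    phase_lfc <- effects$phase_lfc %||% stats::setNames(numeric(0), character(0))
    strain_lfc <- effects$strain_lfc %||% list()
    bad <- setdiff(c(names(phase_lfc), unlist(lapply(strain_lfc, names))), fid)
    if (length(bad)) stop("effect spec references unknown features: ",
                          paste(unique(bad), collapse = ", "))
    if (any(phase_lfc == 0)) stop("planted log fold changes must be nonzero")
  }
  phase_vec <- stats::setNames(rep(0, nf), fid)
  phase_vec[names(phase_lfc)] <- phase_lfc
  strain_mat <- matrix(0, nf, length(strains), dimnames = list(fid, strains))
  for (s in names(strain_lfc)) strain_mat[names(strain_lfc[[s]]), s] <- strain_lfc[[s]]

  base <- stats::rnorm(nf, 17, 1.5)
  batch_eff <- cbind(0, matrix(stats::rnorm(nf * (design$n_batches - 1), 0,
                                            design$batch_sd),
                               nf, design$n_batches - 1))
  drift_profiles <- lapply(seq_len(design$n_batches), function(b) {
    c(c1 = stats::runif(1, -design$drift_amplitude, design$drift_amplitude),
      c2 = stats::runif(1, -design$drift_amplitude / 2, design$drift_amplitude / 2))
  })

  # pooled mean offset seen by QCs (equal mix of all study conditions)
  cond_grid <- expand.grid(strain = strains, phase = phases,
                           stringsAsFactors = FALSE)
  pooled_offset <- rowMeans(vapply(seq_len(nrow(cond_grid)), function(i) {
    phase_vec * (cond_grid$phase[i] == "post") + strain_mat[, cond_grid$strain[i]]
  }, numeric(nf)))

  cols <- list(); meta <- list()
  for (b in seq_len(design$n_batches)) {
    runsheet <- batch_runsheet(design, strains, phases, b)
    nruns <- nrow(runsheet)
    u <- (runsheet$injection_order - 1) / max(1, nruns - 1)
    drift <- drift_profiles[[b]]["c1"] * u + drift_profiles[[b]]["c2"] * u^2
    for (i in seq_len(nruns)) {
      cls <- runsheet$class[i]
      if (cls == "blank") {
        l2 <- stats::rnorm(nf, 6, 0.5)
      } else if (cls == "QC") {
        l2 <- base + batch_eff[, b] + pooled_offset + drift[i] +
          stats::rnorm(nf, 0, design$noise_sd / 3)
      } else {
        l2 <- base + batch_eff[, b] + drift[i] +
          phase_vec * (runsheet$phase[i] == "post") +
          strain_mat[, runsheet$strain[i]] +
          stats::rnorm(nf, 0, sqrt(design$noise_sd^2 + design$biological_sd^2))
      }
      x <- 2^l2
      if (cls == "sample" && design$missing_rate > 0) {
        x[stats::runif(nf) < design$missing_rate] <- 0
      }
      cols[[length(cols) + 1]] <- x
    }
    meta[[b]] <- runsheet
  }
  samples <- do.call(rbind, meta)
  tab <- peak_table(do.call(cbind, cols), features, samples)
  truth <- structure(list(true_diff_features = phase_lfc,
                          strain_lfc = strain_lfc,
                          drift_profiles = drift_profiles),
                     class = "ground_truth")
  list(table = tab, truth = truth)
}

# injection plan for one batch: blanks, then QC-bracketed study samples
batch_runsheet <- function(design, strains, phases, b) {
  conds <- expand.grid(rep = seq_len(design$replicates_per_condition),
                       phase = phases, strain = strains,
                       stringsAsFactors = FALSE)
  conds <- conds[sample(nrow(conds)), ]  # randomised run order
  rows <- list()
  push <- function(class, strain, phase) {
    rows[[length(rows) + 1]] <<- data.frame(class = class, strain = strain,
                                            phase = phase,
                                            stringsAsFactors = FALSE)
  }
  for (i in seq_len(design$n_blanks_per_batch)) push("blank", "", "")
  push("QC", "pooled", "")
  since_qc <- 0
  for (i in seq_len(nrow(conds))) {
    push("sample", conds$strain[i], conds$phase[i])
    since_qc <- since_qc + 1
    if (since_qc == design$qc_interval && i < nrow(conds)) {
      push("QC", "pooled", "")
      since_qc <- 0
    }
  }
  push("QC", "pooled", "")
  out <- do.call(rbind, rows)
  out$batch <- b
  out$injection_order <- seq_len(nrow(out))
  out$sample_id <- sprintf("B%d_%03d_%s", b, out$injection_order, out$class)
  out[, c("sample_id", "batch", "injection_order", "class", "strain", "phase")]
}
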