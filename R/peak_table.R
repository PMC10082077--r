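#' Construct an untargeted-metabolomics peak table
#'
#' Container for a features x samples intensity matrix with feature metadata
#' (m/z, retention time, adduct, identification) and sample metadata (batch,
#' injection order, class, strain, phase). Zero intensity encodes a
#' non-detected peak.
#'
#' @param intensity numeric matrix, features x samples, nonnegative.
#' @param features data.frame with at least `feature_id`, `mz`, `rt`,
#'   `adduct`, `identification`; one row per intensity row.
#' @param samples data.frame with at least `sample_id`, `batch`,
#'   `injection_order`, `class` (one of `sample`, `QC`, `blank`), `strain`,
#'   `phase`; one row per intensity column.
#' @return an object of class `peak_table`.
#' @export
peak_table <- function(intensity, features, samples) {
  intensity <- as.matrix(intensity)
  if (nrow(intensity) != nrow(features)) {
    stop("intensity rows must match feature metadata rows")
  }
  if (ncol(intensity) != nrow(samples)) {
    stop("intensity columns must match sample metadata rows")
  }
  need_f <- c("feature_id", "mz", "rt", "adduct", "identification")
  need_s <- c("sample_id", "batch", "injection_order", "class", "strain", "phase")
  if (!all(need_f %in% names(features))) {
    stop("feature metadata needs columns: ", paste(need_f, collapse = ", "))
  }
  if (!all(need_s %in% names(samples))) {
    stop("sample metadata needs columns: ", paste(need_s, collapse = ", "))
  }
  if (any(intensity < 0)) stop("intensities must be nonnegative")
  if (anyDuplicated(samples$sample_id)) stop("duplicate sample_ids")
  ok <- !vapply(split(samples$injection_order, samples$batch),
                anyDuplicated, integer(1)) > 0
  if (!all(ok)) stop("injection_order must be unique within batch")
  rownames(intensity) <- features$feature_id
  colnames(intensity) <- samples$sample_id
  structure(list(intensity = intensity,
                 features = as.data.frame(features, stringsAsFactors = FALSE),
                 samples = as.data.frame(samples, stringsAsFactors = FALSE)),
            class = "peak_table")
}

#' @export
print.peak_table <- function(x, ...) {
  cl <- table(x$samples$class)
  cat(sprintf("peak_table: %d features x %d samples (%s), %d batch(es)\n",
              nrow(x$intensity), ncol(x$intensity),
              paste(sprintf("%s=%d", names(cl), cl), collapse = ", "),
              length(unique(x$samples$batch))))
  invisible(x)
}

#' @export
dim.peak_table <- function(x) dim(x$intensity)

# indices of study/QC/blank columns
sample_idx <- function(x, cls) which(x$samples$class %in% cls)

#' Write / read a peak table as plain CSV files
#'
#' Three files are written under `path` with the given prefix:
#' `<prefix>_intensity.csv` (feature_id + one column per sample),
#' `<prefix>_features.csv`, and `<prefix>_samples.csv`.
#'
#' @param x a `peak_table`.
#' @param path directory.
#' @param prefix file-name prefix.
#' @return `write_peak_table` returns the three file paths invisibly;
#'   `read_peak_table` returns a `peak_table`.
#' @export
write_peak_table <- function(x, path, prefix = "peaks") {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  f <- file.path(path, paste0(prefix, c("_intensity.csv", "_features.csv",
                                        "_samples.csv")))
  utils::write.csv(data.frame(feature_id = x$features$feature_id,
                              x$intensity, check.names = FALSE),
                   f[1], row.names = FALSE)
  utils::write.csv(x$features, f[2], row.names = FALSE)
  utils::write.csv(x$samples, f[3], row.names = FALSE)
  invisible(f)
}

#' @rdname write_peak_table
#' @export
read_peak_table <- function(path, prefix = "peaks") {
  f <- file.path(path, paste0(prefix, c("_intensity.csv", "_features.csv",
                                        "_samples.csv")))
  ints <- utils::read.csv(f[1], check.names = FALSE)
  features <- utils::read.csv(f[2], stringsAsFactors = FALSE)
  features$identification[is.na(features$identification)] <- ""
  samples <- utils::read.csv(f[3], stringsAsFactors = FALSE)
  m <- as.matrix(ints[, -1, drop = FALSE])
  peak_table(m, features, samples)
}

# subset a peak table by feature and/or sample index
subset_peak_table <- function(x, f_idx = NULL, s_idx = NULL) {
  f_idx <- f_idx %||% seq_len(nrow(x$intensity))
  s_idx <- s_idx %||% seq_len(ncol(x$intensity))
  peak_table(x$intensity[f_idx, s_idx, drop = FALSE],
             x$features[f_idx, , drop = FALSE],
             x$samples[s_idx, , drop = FALSE])
}
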