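#' ROI time-series panel
#'
#' Container for one subject's timepoints-by-ROI signal matrix together with
#' the sampling interval and any nuisance regressors (supplied as columns;
#' motion parameters, tissue signals and scrubbing indicators are all treated
#' uniformly).
#'
#' @param data numeric matrix, timepoints x ROIs, all finite.
#' @param tr sampling interval in seconds.
#' @param roi_names character vector naming the columns.
#' @param confounds optional numeric matrix of nuisance regressors with the
#'   same number of rows as `data`.
#' @param subject_id identifier string.
#' @return An object of class `ts_panel`.
#' @export
time_series_panel <- function(data, tr, roi_names = NULL, confounds = NULL,
                              subject_id = "subject") {
  data <- as.matrix(data)
  stop_if_not(is.numeric(data) && all(is.finite(data)),
              "panel data must be finite numeric")
  stop_if_not(nrow(data) >= 2, "panel needs at least 2 timepoints")
  stop_if_not(is_number(tr) && tr > 0, "tr must be positive")
  roi_names <- roi_names %||% colnames(data) %||% default_roi_names(ncol(data))
  stop_if_not(length(roi_names) == ncol(data),
              "roi_names length must match ROI count")
  colnames(data) <- roi_names
  if (!is.null(confounds)) {
    confounds <- as.matrix(confounds)
    stop_if_not(nrow(confounds) == nrow(data),
                "confounds must have one row per timepoint")
    stop_if_not(all(is.finite(confounds)), "confounds must be finite")
  }
  structure(list(data = data, tr = tr, roi_names = roi_names,
                 confounds = confounds, subject_id = subject_id),
            class = "ts_panel")
}

#' @export
print.ts_panel <- function(x, ...) {
  cat(sprintf("<ts_panel> %s: %d timepoints x %d ROIs, TR %.3g s, %d confound column(s)\n",
              x$subject_id, nrow(x$data), ncol(x$data), x$tr,
              if (is.null(x$confounds)) 0L else ncol(x$confounds)))
  invisible(x)
}

#' Temporal signal-to-noise ratio and QC gate
#'
#' Per ROI, the temporal mean divided by the temporal standard deviation of
#' the raw (pre-denoising) series. The subject-level gate compares the mean
#' tSNR across ROIs with the threshold: below it, small (<0.5%) signal
#' fluctuations cannot be reliably detected at this scan length and the
#' subject is excluded. A zero-variance ROI yields an infinite tSNR and is
#' flagged.
#'
#' @param panel a [time_series_panel()].
#' @param threshold subject-level exclusion threshold (default 45).
#' @return List with `values` (named per-ROI tSNR), `mean_tsnr` and `pass`.
#' @export
tsnr <- function(panel, threshold = 45) {
  stop_if_not(inherits(panel, "ts_panel"), "panel must be a ts_panel")
  mu <- colMeans(panel$data)
  sdev <- apply(panel$data, 2, sd)
  vals <- ifelse(sdev == 0, Inf, abs(mu) / sdev)
  names(vals) <- panel$roi_names
  if (any(!is.finite(vals))) {
    ht_log("zero-variance ROI(s) in ", panel$subject_id, ": ",
           paste(panel$roi_names[!is.finite(vals)], collapse = ", "),
           " (tSNR reported as Inf)")
  }
  mean_tsnr <- mean(vals[is.finite(vals)])
  if (!length(vals[is.finite(vals)])) mean_tsnr <- Inf
  list(values = vals, mean_tsnr = mean_tsnr, pass = mean_tsnr >= threshold,
       threshold = threshold)
}

#' Regress nuisance signals out of a panel
#'
#' Replaces every ROI series by the residual of an ordinary least squares fit
#' on an intercept plus the panel's confound columns; the output is orthogonal
#' to each regressor. With no confounds this reduces to removing the temporal
#' mean. Collinear confound columns are dropped with a warning.
#'
#' @param panel a [time_series_panel()].
#' @return The residualized panel (confounds emptied: they are spent).
#' @export
regress_confounds <- function(panel) {
  stop_if_not(inherits(panel, "ts_panel"), "panel must be a ts_panel")
  tp <- nrow(panel$data)
  design <- cbind(intercept = rep(1, tp), panel$confounds)
  qd <- qr(design)
  if (qd$rank < ncol(design)) {
    keep <- qd$pivot[seq_len(qd$rank)]
    warning("dropping collinear confound column(s): ",
            paste(setdiff(colnames(design), colnames(design)[keep]), collapse = ", "),
            call. = FALSE)
    design <- design[, sort(keep), drop = FALSE]
    qd <- qr(design)
  }
  resid <- panel$data - design %*% qr.coef(qd, panel$data)
  time_series_panel(resid, tr = panel$tr, roi_names = panel$roi_names,
                    confounds = NULL, subject_id = panel$subject_id)
}

#' Linear detrend and band-pass filter
#'
#' Per ROI: remove the best-fit line, then zero all discrete-Fourier
#' components outside `[low_hz, high_hz]` (an ideal rectangular passband;
#' deterministic and parameter-free). The upper edge is clamped to the
#' Nyquist frequency `1/(2 tr)` when it exceeds it — with a 1.5 s sampling
#' interval the conventional 0.8 Hz print is unreachable and the filter is
#' effectively high-pass — and a residual best-fit line is removed after
#' filtering so the output carries no linear trend.
#'
#' @param panel a [time_series_panel()].
#' @param low_hz,high_hz passband edges in Hz (defaults 0.009 and 0.8).
#' @return The filtered panel.
#' @export
detrend_bandpass <- function(panel, low_hz = 0.009, high_hz = 0.8) {
  stop_if_not(inherits(panel, "ts_panel"), "panel must be a ts_panel")
  stop_if_not(is_number(low_hz) && low_hz >= 0, "low_hz must be nonnegative")
  stop_if_not(is_number(high_hz) && high_hz > low_hz,
              "high_hz must exceed low_hz")
  tp <- nrow(panel$data)
  nyquist <- 1 / (2 * panel$tr)
  if (high_hz > nyquist) {
    ht_log(sprintf("upper band edge %.3g Hz exceeds Nyquist %.3g Hz; clamped",
                   high_hz, nyquist))
    high_hz <- nyquist
  }
  tt <- seq_len(tp)
  detrend <- function(m) {
    r <- lsfit(tt, m, intercept = TRUE)$residuals
    matrix(r, nrow = tp) # lsfit drops the matrix shape for a single ROI
  }
  x <- detrend(panel$data)
  freq <- (seq_len(tp) - 1) / (tp * panel$tr)
  folded <- pmin(freq, 1 / panel$tr - freq)  # two-sided spectrum
  keep <- folded >= low_hz & folded <= high_hz
  xf <- mvfft(x)
  xf[!keep, ] <- 0
  x <- Re(mvfft(xf, inverse = TRUE)) / tp
  x <- detrend(x)
  time_series_panel(x, tr = panel$tr, roi_names = panel$roi_names,
                    confounds = panel$confounds, subject_id = panel$subject_id)
}

#' Fisher-z connectivity matrix
#'
#' Pearson correlation between every ROI pair, Fisher transformed
#' (`atanh(r)`), with the diagonal forced to zero. Correlations at the
#' boundary `|r| = 1` are clamped to `1 - 1e-7` before the transform so the
#' matrix stays finite.
#'
#' @param panel a (denoised) [time_series_panel()].
#' @return An object of class `conn_matrix` with fields `z`, `roi_names`,
#'   `subject_id`.
#' @export
correlation_matrix <- function(panel) {
  stop_if_not(inherits(panel, "ts_panel"), "panel must be a ts_panel")
  stop_if_not(nrow(panel$data) >= 3, "need at least 3 timepoints for correlation")
  sdev <- apply(panel$data, 2, sd)
  if (any(sdev == 0)) {
    stop("zero-variance ROI(s): ", paste(panel$roi_names[sdev == 0], collapse = ", "),
         call. = FALSE)
  }
  r <- cor(panel$data)
  clamp <- 1 - 1e-7
  if (any(abs(r[upper.tri(r)]) >= clamp)) {
    ht_log("correlation(s) at |r| >= 1 - 1e-7 clamped for ", panel$subject_id)
  }
  r[r > clamp] <- clamp
  r[r < -clamp] <- -clamp
  z <- atanh(r)
  diag(z) <- 0
  z <- (z + t(z)) / 2
  dimnames(z) <- list(panel$roi_names, panel$roi_names)
  structure(list(z = z, roi_names = panel$roi_names,
                 subject_id = panel$subject_id),
            class = "conn_matrix")
}

#' @export
print.conn_matrix <- function(x, ...) {
  cat(sprintf("<conn_matrix> %s: %d x %d Fisher-z matrix\n",
              x$subject_id, nrow(x$z), ncol(x$z)))
  invisible(x)
}

# strict-upper-triangle pairs in row-major order: (1,2),(1,3),...,(1,n),(2,3),...
upper_pairs <- function(n) {
  i <- rep(seq_len(n - 1), times = (n - 1):1)
  j <- unlist(lapply(seq_len(n - 1), function(k) (k + 1):n))
  cbind(i = i, j = j)
}

#' Vectorize the upper triangle of a connectivity matrix
#'
#' Extracts the strict upper triangle in row-major order, giving the
#' `n(n-1)/2`-element feature vector used for classification (990 features for
#' a 45-ROI hemisphere), together with the bijective map from feature position
#' to ROI pair.
#'
#' @param matrix a `conn_matrix` or a symmetric numeric matrix.
#' @param tol symmetry tolerance.
#' @return List with `values` and `index_map` (data.frame: feature, roi_i,
#'   roi_j), class `feature_vector`.
#' @export
vectorize_upper_triangle <- function(matrix, tol = 1e-10) {
  if (inherits(matrix, "conn_matrix")) {
    m <- matrix$z
    rn <- matrix$roi_names
  } else {
    m <- as.matrix(matrix)
    rn <- colnames(m) %||% default_roi_names(ncol(m))
  }
  check_symmetric(m, tol, "connectivity matrix")
  n <- ncol(m)
  pairs <- upper_pairs(n)
  values <- m[pairs]
  index_map <- data.frame(feature = seq_len(nrow(pairs)),
                          roi_i = rn[pairs[, "i"]], roi_j = rn[pairs[, "j"]],
                          i = pairs[, "i"], j = pairs[, "j"],
                          stringsAsFactors = FALSE)
  structure(list(values = values, index_map = index_map),
            class = "feature_vector")
}

#' Rebuild a symmetric matrix from a feature vector
#'
#' Inverse of [vectorize_upper_triangle()] (zero diagonal).
#'
#' @param fv a `feature_vector`.
#' @return A symmetric matrix.
#' @export
matrix_from_features <- function(fv) {
  stop_if_not(inherits(fv, "feature_vector"), "fv must be a feature_vector")
  im <- fv$index_map
  n <- max(im$j)
  m <- matrix(0, n, n)
  m[cbind(im$i, im$j)] <- fv$values
  m <- m + t(m)
  rn <- unique(c(im$roi_i, im$roi_j))
  dimnames(m) <- list(rn, rn)
  m
}

#' Average voxel columns into parcels
#'
#' Optional helper for data delivered at sub-ROI resolution: averages columns
#' sharing a 1-based parcel label into one representative series (label 0 =
#' background, dropped).
#'
#' @param data timepoints x voxels matrix.
#' @param labels integer vector of parcel labels per column.
#' @return timepoints x parcels matrix.
#' @export
average_parcels <- function(data, labels) {
  stop_if_not(ncol(data) == length(labels), "one label per column required")
  keep <- labels > 0
  labs <- labels[keep]
  m <- sapply(sort(unique(labs)), function(l) {
    rowMeans(data[, keep, drop = FALSE][, labs == l, drop = FALSE])
  })
  colnames(m) <- sprintf("ROI%02d", sort(unique(labs)))
  m
}

#' Denoise a panel and compute its connectivity matrix
#'
#' The full per-subject chain in its canonical order: QC gate on the raw
#' series, confound regression, linear detrend plus band-pass, Pearson
#' correlation, Fisher transform.
#'
#' @param panel a raw [time_series_panel()].
#' @param low_hz,high_hz passband edges.
#' @param tsnr_threshold QC threshold; `NULL` skips the gate.
#' @return A `conn_matrix`, or `NULL` with a message if the subject fails QC.
#' @export
panel_connectivity <- function(panel, low_hz = 0.009, high_hz = 0.8,
                               tsnr_threshold = 45) {
  if (!is.null(tsnr_threshold)) {
    qc <- tsnr(panel, tsnr_threshold)
    if (!qc$pass) {
      ht_log(sprintf("subject %s excluded: mean tSNR %.1f below threshold %s",
                     panel$subject_id, qc$mean_tsnr, tsnr_threshold))
      return(NULL)
    }
  }
  panel <- regress_confounds(panel)
  panel <- detrend_bandpass(panel, low_hz, high_hz)
  correlation_matrix(panel)
}

## ---- file formats ----

#' @rdname time_series_panel
#' @param panel,path panel object and file path for the TSV writers/readers.
#' @export
write_panel_tsv <- function(panel, path) {
  write.table(panel$data, path, sep = "\t", row.names = FALSE, quote = FALSE)
  if (!is.null(panel$confounds)) {
    write.table(panel$confounds, sub("\\.tsv$", "_confounds.tsv", path),
                sep = "\t", row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' @rdname time_series_panel
#' @param tr_read sampling interval to attach when reading.
#' @export
read_panel_tsv <- function(path, tr_read, subject_id = NULL) {
  data <- as.matrix(read.delim(path, check.names = FALSE))
  cpath <- sub("\\.tsv$", "_confounds.tsv", path)
  confounds <- if (file.exists(cpath)) as.matrix(read.delim(cpath)) else NULL
  time_series_panel(data, tr = tr_read, confounds = confounds,
                    subject_id = subject_id %||%
                      sub("\\.tsv$", "", basename(path)))
}

#' Write / read a connectivity matrix as CSV
#'
#' Full symmetric matrix with ROI names as header row and first column.
#'
#' @param cm a `conn_matrix`.
#' @param path file path.
#' @export
write_connectivity_csv <- function(cm, path) {
  m <- cm$z
  df <- data.frame(roi = rownames(m), m, check.names = FALSE)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_connectivity_csv
#' @param subject_id id attached on read.
#' @export
read_connectivity_csv <- function(path, subject_id = NULL) {
  df <- read.csv(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m <- (m + t(m)) / 2
  diag(m) <- 0
  structure(list(z = m, roi_names = rownames(m),
                 subject_id = subject_id %||% sub("\\.csv$", "", basename(path))),
            class = "conn_matrix")
}

#' Write a feature vector as CSV
#'
#' Long format with one row per ROI pair: `roi_i, roi_j, z`.
#'
#' @param fv a `feature_vector`.
#' @param path file path.
#' @export
write_feature_csv <- function(fv, path) {
  df <- data.frame(roi_i = fv$index_map$roi_i, roi_j = fv$index_map$roi_j,
                   z = fv$values, stringsAsFactors = FALSE)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
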