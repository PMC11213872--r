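# Feature-table processing between the raw aligned table and the
# statistics-ready matrix: rating filter, RF imputation, QC-based drift
# correction, RSD filter, presence filter, median normalization, log/Pareto.

#' Filter features by per-sample peak rating
#'
#' Retains features whose peak rating is strictly above `min_rating` in at
#' least `min_samples` samples. The rating is an integration-quality score in
#' `[0, 10]` supplied with the aligned table; missing ratings count as
#' failing.
#'
#' @param table A `feature_table` with a `ratings` matrix.
#' @param min_rating Strict lower rating bound (default 5).
#' @param min_samples Minimum number of samples above the bound (default 5).
#' @return Filtered `feature_table`.
#' @export
filter_by_peak_rating <- function(table, min_rating = 5, min_samples = 5L) {
  if (is.null(table$ratings)) {
    stop("no peak ratings present; supply a ratings matrix to feature_table()",
         call. = FALSE)
  }
  ok <- rowSums(table$ratings > min_rating, na.rm = TRUE) >= min_samples
  out <- ft_subset(table, features = ok)
  .log_stage(out, "peak_rating_filter", min_rating = min_rating,
             min_samples = min_samples, removed = sum(!ok))
}

#' Random-forest missing-value imputation
#'
#' Iterative random-forest imputation: missing entries are initialised with
#' the feature mean, then each feature with missing values is regressed on
#' all other features and its missing entries replaced by out-of-model
#' predictions. Iteration stops when the relative change of the imputed
#' values increases, or after `max_iter` rounds; the previous round is
#' returned in the former case. Observed entries are never altered and the
#' original detection mask is preserved.
#'
#' Features more than 50% missing are flagged with a warning; all-missing
#' features are an error.
#'
#' @param table A `feature_table` (any role mix; all samples are used).
#' @param n_trees Trees per forest (default 100).
#' @param max_iter Maximum iterations (default 10).
#' @param seed Integer seed; imputation is fully reproducible given it.
#' @return `feature_table` with no missing values.
#' @export
impute_missing <- function(table, n_trees = 100L, max_iter = 10L, seed = 1L) {
  x <- t(table$areas)  # samples x features for regression
  miss <- is.na(x)
  if (!any(miss)) {
    return(.log_stage(table, "impute", imputed = 0L, iterations = 0L))
  }
  frac_missing <- colMeans(miss)
  if (any(frac_missing == 1)) {
    stop("all-missing feature(s): ",
         paste(colnames(x)[frac_missing == 1], collapse = ", "),
         call. = FALSE)
  }
  flagged <- colnames(x)[frac_missing > 0.5]
  if (length(flagged)) {
    warning("feature(s) more than 50% missing: ",
            paste(flagged, collapse = ", "), call. = FALSE)
  }

  # mean initialisation
  for (j in which(frac_missing > 0)) {
    x[miss[, j], j] <- mean(x[!miss[, j], j])
  }
  targets <- order(frac_missing)  # least missing first
  targets <- targets[frac_missing[targets] > 0]

  prev_stat <- Inf
  iters <- 0L
  for (it in seq_len(max_iter)) {
    x_old <- x
    for (j in targets) {
      obs <- !miss[, j]
      df <- as.data.frame(x[, -j, drop = FALSE])
      names(df) <- paste0("p", seq_len(ncol(df)))
      fit <- ranger::ranger(
        y = x[obs, j], x = df[obs, , drop = FALSE],
        num.trees = n_trees, mtry = ncol(df),
        seed = seed + 7L * it + j, num.threads = 1L
      )
      x[!obs, j] <- stats::predict(fit, df[!obs, , drop = FALSE],
                                   num.threads = 1L)$predictions
    }
    iters <- it
    stat <- sum((x[miss] - x_old[miss])^2) / max(sum(x[miss]^2), .Machine$double.eps)
    if (stat >= prev_stat) {
      x <- x_old  # revert to the better iterate
      break
    }
    prev_stat <- stat
  }

  out <- table
  out$areas <- t(x)
  dimnames(out$areas) <- dimnames(table$areas)
  .log_stage(out, "impute", imputed = sum(miss), iterations = iters,
             n_trees = n_trees, seed = seed)
}

.qc_rsd <- function(areas, qc_idx) {
  q <- areas[, qc_idx, drop = FALSE]
  m <- rowMeans(q)
  s <- apply(q, 1L, stats::sd)
  ifelse(m > 0, 100 * s / m, NA_real_)
}

#' QC-based random-forest signal-drift correction
#'
#' For each feature, a random-forest regression (trained on the QC
#' injections only) models the systematic intensity drift as a function of
#' injection order plus the feature's most QC-correlated companion features.
#' The fitted drift at the QC injection orders is interpolated to every
#' sample's injection order with a monotone piecewise-cubic spline, all
#' intensities are divided by the interpolated drift, and the feature is
#' rescaled so its QC median is preserved exactly.
#'
#' Samples are treated as a single batch. Features with zero variance across
#' the QC injections are passed through unchanged and logged.
#'
#' @param table Imputed `feature_table` (no missing values) with >= 5 QC
#'   samples spread across the injection order.
#' @param n_trees Trees per feature forest (default 200).
#' @param n_predictors Number of correlated companion features used as
#'   predictors besides injection order (default 10).
#' @param seed Integer seed.
#' @return A list with `table` (corrected `feature_table`) and `report`
#'   (data.frame: `feature_id`, `rsd_before`, `rsd_after`, `constant`).
#' @export
qc_correct <- function(table, n_trees = 200L, n_predictors = 10L, seed = 1L) {
  if (any(is.na(table$areas))) {
    stop("table contains missing values; run impute_missing() first",
         call. = FALSE)
  }
  qc <- .qc_idx(table)
  if (length(qc) < 5L) {
    stop("QC correction requires at least 5 QC samples (found ",
         length(qc), ")", call. = FALSE)
  }
  ord <- table$samples$injection_order
  qc_ord <- ord[qc]
  p <- nrow(table$areas)
  areas <- table$areas
  qc_mat <- areas[, qc, drop = FALSE]
  rsd_before <- .qc_rsd(areas, qc)

  # QC-correlation matrix once; predictors per feature are its top partners
  qc_t <- t(qc_mat)
  sds <- apply(qc_t, 2L, stats::sd)
  constant <- sds == 0
  corr <- matrix(0, p, p)
  if (sum(!constant) > 1L) {
    corr[!constant, !constant] <- abs(stats::cor(qc_t[, !constant, drop = FALSE]))
  }
  diag(corr) <- 0

  corrected <- areas
  o <- order(qc_ord)
  ord_clamped <- pmin(pmax(ord, min(qc_ord)), max(qc_ord))
  for (j in seq_len(p)) {
    if (constant[j]) next
    partners <- order(corr[j, ], decreasing = TRUE)
    partners <- partners[seq_len(min(n_predictors, max(p - 1L, 0L)))]
    partners <- partners[corr[j, partners] > 0]
    xtrain <- data.frame(order = qc_ord,
                         qc_t[, partners, drop = FALSE])
    names(xtrain) <- c("order", paste0("p", seq_along(partners)))
    fit <- ranger::ranger(y = qc_mat[j, ], x = xtrain, num.trees = n_trees,
                          seed = seed + j, num.threads = 1L)
    # out-of-bag predictions at the QC points: the drift estimate must not
    # chase each QC's own technical noise
    drift_qc <- fit$predictions
    bad <- !is.finite(drift_qc)
    if (any(bad)) {
      drift_qc[bad] <- stats::predict(fit, xtrain[bad, , drop = FALSE],
                                      num.threads = 1L)$predictions
    }
    if (length(unique(drift_qc[o])) == 1L) {
      drift <- rep(drift_qc[1L], length(ord))
    } else {
      sf <- stats::splinefun(qc_ord[o], drift_qc[o], method = "monoH.FC")
      drift <- sf(ord_clamped)
    }
    med_drift <- stats::median(drift[qc])
    floor_val <- 1e-6 * max(abs(med_drift), 1)
    drift <- pmax(drift, floor_val)
    corr_j <- areas[j, ] / drift
    med_raw <- stats::median(areas[j, qc])
    med_new <- stats::median(corr_j[qc])
    if (med_new > 0) corr_j <- corr_j * med_raw / med_new
    corrected[j, ] <- corr_j
  }

  out <- table
  out$areas <- corrected
  rsd_after <- .qc_rsd(corrected, qc)
  report <- data.frame(feature_id = table$features$feature_id,
                       rsd_before = rsd_before, rsd_after = rsd_after,
                       constant = constant, stringsAsFactors = FALSE)
  out <- .log_stage(out, "qc_correct", n_trees = n_trees, seed = seed,
                    constant_features = sum(constant))
  list(table = out, report = report)
}

#' Filter features by QC relative standard deviation
#'
#' Removes features whose QC RSD exceeded `max_before` percent before drift
#' correction or exceeds `max_after` percent after it (RSD = 100 * sd / mean
#' over the QC injections; boundaries are inclusive maxima).
#'
#' @param table Corrected `feature_table`.
#' @param report The RSD report from [qc_correct()].
#' @param max_before Maximum pre-correction QC RSD in percent (default 50).
#' @param max_after Maximum post-correction QC RSD in percent (default 25).
#' @return Filtered `feature_table`.
#' @export
rsd_filter <- function(table, report, max_before = 50, max_after = 25) {
  stopifnot(identical(report$feature_id, table$features$feature_id))
  keep <- !is.na(report$rsd_before) & !is.na(report$rsd_after) &
    report$rsd_before <= max_before & report$rsd_after <= max_after
  out <- ft_subset(table, features = keep)
  .log_stage(out, "rsd_filter", max_before = max_before,
             max_after = max_after, removed = sum(!keep))
}

#' Filter features by presence in at least one study group
#'
#' Retains features detected (non-missing before imputation) in at least
#' `min_fraction` of the study samples of at least one group x timepoint
#' cell. Detection is judged on the original pre-imputation mask carried by
#' the table.
#'
#' @param table A `feature_table`.
#' @param min_fraction Minimum detected fraction within one cell
#'   (default 0.80).
#' @return Filtered `feature_table`.
#' @export
usable_hits_filter <- function(table, min_fraction = 0.80) {
  st <- .study_idx(table)
  if (length(st) == 0L) stop("no study samples present", call. = FALSE)
  cell <- interaction(table$samples$group[st], table$samples$timepoint[st],
                      drop = TRUE)
  det <- table$detected[, st, drop = FALSE]
  keep <- apply(det, 1L, function(d) {
    any(tapply(d, cell, mean) >= min_fraction)
  })
  out <- ft_subset(table, features = keep)
  .log_stage(out, "usable_hits_filter", min_fraction = min_fraction,
             removed = sum(!keep))
}

#' Normalize samples to the maximum peak-area median
#'
#' Each sample is scaled by `reference / median(sample)`, where the
#' reference is the largest per-sample median peak area among the QC and
#' study samples (blank and control-preparation samples do not set the
#' reference but are scaled alongside). After normalization every sample's
#' median equals the reference.
#'
#' @param table Imputed `feature_table` (no missing values).
#' @param reference `"max"` (default) for max-of-sample-medians, or
#'   `"median"` for median-of-sample-medians.
#' @return Normalized `feature_table`.
#' @export
normalize_median <- function(table, reference = c("max", "median")) {
  reference <- match.arg(reference)
  if (any(is.na(table$areas))) {
    stop("table contains missing values; run impute_missing() first",
         call. = FALSE)
  }
  med <- apply(table$areas, 2L, stats::median)
  if (any(med == 0)) {
    stop("sample(s) with zero median peak area: ",
         paste(table$samples$sample_id[med == 0], collapse = ", "),
         call. = FALSE)
  }
  ref_pool <- c(.qc_idx(table), .study_idx(table))
  if (length(ref_pool) == 0L) ref_pool <- seq_along(med)
  ref <- if (reference == "max") max(med[ref_pool]) else
    stats::median(med[ref_pool])
  out <- table
  out$areas <- sweep(table$areas, 2L, ref / med, `*`)
  .log_stage(out, "normalize_median", reference = reference,
             reference_value = ref)
}

#' Log transform and Pareto scale
#'
#' Entries are natural-log transformed, then each feature is centered to
#' mean zero and divided by the square root of its standard deviation.
#' Pareto scaling leaves each feature with variance equal to its pre-scaling
#' standard deviation, damping (rather than erasing) intensity differences
#' between features. Zero-variance features cannot be scaled and are
#' dropped with a log record.
#'
#' @param table Normalized `feature_table` with strictly positive entries.
#' @return Processed `feature_table` ready for multivariate statistics.
#' @export
log_pareto <- function(table) {
  offenders <- sum(table$areas <= 0, na.rm = TRUE)
  if (offenders > 0L || any(is.na(table$areas))) {
    stop("log transform requires strictly positive complete entries (",
         offenders, " non-positive, ", sum(is.na(table$areas)), " missing)",
         call. = FALSE)
  }
  lx <- log(table$areas)
  sds <- apply(lx, 1L, stats::sd)
  keep <- sds > 0
  lx <- lx[keep, , drop = FALSE]
  scaled <- (lx - rowMeans(lx)) / sqrt(sds[keep])
  out <- ft_subset(table, features = keep)
  out$areas <- scaled
  .log_stage(out, "log_pareto", dropped_constant = sum(!keep))
}

#' Run the full processing pipeline on a raw aligned table
#'
#' Convenience wrapper chaining rating filter, presence filter, imputation,
#' drift correction, RSD filter, median normalization and log/Pareto
#' scaling, with the stage order used throughout the package.
#'
#' @param table Raw `feature_table` (with ratings and missing values).
#' @param seed Integer seed for the random-forest stages.
#' @param min_rating,min_samples See [filter_by_peak_rating()].
#' @param min_fraction See [usable_hits_filter()].
#' @param max_before,max_after See [rsd_filter()].
#' @return List with `processed` (log/Pareto table for statistics),
#'   `normalized` (pre-log table for direction calls and ratios), and
#'   `rsd_report`.
#' @export
process_pipeline <- function(table, seed = 1L, min_rating = 5,
                             min_samples = 5L, min_fraction = 0.80,
                             max_before = 50, max_after = 25) {
  t1 <- filter_by_peak_rating(table, min_rating, min_samples)
  t2 <- usable_hits_filter(t1, min_fraction)
  t3 <- impute_missing(t2, seed = seed)
  qc <- qc_correct(t3, seed = seed)
  t4 <- rsd_filter(qc$table, qc$report, max_before, max_after)
  t5 <- normalize_median(t4)
  t6 <- log_pareto(t5)
  list(processed = t6, normalized = t5, rsd_report = qc$report)
}
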